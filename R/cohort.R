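#' Two-sigma 95% confidence limits
#'
#' The mean plus/minus twice the standard error of the mean — the rough
#' normal-theory interval conventional in small-n tracer studies (a
#' t-quantile is deliberately not used; see the package vignette).
#'
#' @param mean point estimate.
#' @param sem standard error of the mean (>= 0).
#' @return Numeric vector `c(lower, upper)` = mean -/+ 2 sem.
#' @export
#' @examples
#' ninety_five_cl(2.2, 0.6)  # 1.0 3.4
ninety_five_cl <- function(mean, sem) {
  if (!is.numeric(sem) || sem < 0) {
    stop("'sem' must be a non-negative number", call. = FALSE)
  }
  c(lower = mean - 2 * sem, upper = mean + 2 * sem)
}

cohort_quantities <- c("age_days", "activity_MBq", "admin_duration_s",
                       "n_rois", "sv_per_s", "V_mm_s", "s_per_mm",
                       "sv_per_min", "V_cm_min", "s_per_cm")

as_plant_table <- function(results) {
  if (is.data.frame(results)) return(results)
  stopifnot(is.list(results),
            all(vapply(results, inherits, logical(1), "transport_fit")))
  do.call(rbind, lapply(results, as.data.frame))
}

#' Aggregate transport estimates across plants
#'
#' Unweighted cross-plant mean, sample standard deviation (n - 1
#' denominator), standard error of the mean, coefficient of variation, and
#' two-sigma 95% confidence limits for each study quantity: plant age,
#' administered activity, administration duration, number of ROIs, trapping
#' rate sv, velocity V, and trapping per length s — the latter three also
#' in per-minute / centimetre units (converted per plant before averaging;
#' the conversions are linear so the converted mean equals the converted
#' statistic either way).
#'
#' @param results a list of [fit_transport()] objects, or a data frame with
#'   columns `plant_id`, `age_days`, `activity_MBq`, `admin_duration_s`,
#'   `n_rois`, `sv_per_s`, `V_mm_s`, and optionally `sv_sd_per_s` and
#'   `s_per_mm` (`s_per_mm` is derived as sv/V when absent).
#' @return An object of class `cohort_summary`: list with `n_plants`,
#'   `plants` (the per-plant table), and `stats` (data frame with one row
#'   per quantity and columns mean, sd, sem, cv_percent, cl_lower,
#'   cl_upper).
#' @export
summarize_cohort <- function(results) {
  plants <- as_plant_table(results)
  if (nrow(plants) < 2L) {
    stop("cohort dispersion statistics need at least 2 plants",
         call. = FALSE)
  }
  if (is.null(plants$s_per_mm)) {
    plants$s_per_mm <- plants$sv_per_s / plants$V_mm_s
  }
  plants$sv_per_min <- convert_units(plants$sv_per_s, "1/s", "1/min")
  plants$V_cm_min <- convert_units(plants$V_mm_s, "mm/s", "cm/min")
  plants$s_per_cm <- convert_units(plants$s_per_mm, "1/mm", "1/cm")
  n <- nrow(plants)
  quantities <- intersect(cohort_quantities, names(plants))
  stats <- do.call(rbind, lapply(quantities, function(q) {
    x <- plants[[q]]
    m <- mean(x)
    s <- stats::sd(x)
    sem <- s / sqrt(n)
    cl <- ninety_five_cl(m, sem)
    data.frame(quantity = q, mean = m, sd = s, sem = sem,
               cv_percent = 100 * s / abs(m),
               cl_lower = cl[["lower"]], cl_upper = cl[["upper"]],
               stringsAsFactors = FALSE)
  }))
  rownames(stats) <- stats$quantity
  structure(list(n_plants = n, plants = plants, stats = stats),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort summary over %d plants\n", x$n_plants))
  df <- x$stats
  df[-1L] <- lapply(df[-1L], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

# "mean(sd-in-trailing-digits)" notation, e.g. 0.000287(220): the s.d.
# expressed in units of the mean's last printed decimal place.
format_paren <- function(mean, sd, signif_digits = 3, decimals = NULL) {
  if (is.null(decimals)) {
    decimals <- max(0L, signif_digits - 1L - floor(log10(abs(mean))))
  }
  mean_str <- formatC(mean, format = "f", digits = decimals)
  dot <- regexpr(".", mean_str, fixed = TRUE)
  places <- if (dot > 0) nchar(mean_str) - dot else 0L
  sprintf("%s(%s)", mean_str, format(round(sd * 10^places)))
}

#' Render the per-plant and cohort results table
#'
#' Aligned plain-text table with one row per plant (age, administered
#' activity, administration duration, number of ROIs, sv as
#' mean(s.d.-in-trailing-digits), V, s) and a final cohort row labelled
#' "Mean (s.d., n = ...)". sv is shown to 3 significant figures, V to 3
#' decimals, s to 5 decimals.
#'
#' @inheritParams summarize_cohort
#' @return Character vector of table lines (also printed invisibly usable
#'   with `cat(..., sep = "\n")`).
#' @export
render_results_table <- function(results) {
  plants <- as_plant_table(results)
  if (is.null(plants$s_per_mm)) {
    plants$s_per_mm <- plants$sv_per_s / plants$V_mm_s
  }
  summ <- summarize_cohort(plants)
  st <- summ$stats
  sv_cell <- function(m, s) {
    if (is.na(s)) formatC(signif(m, 3), format = "fg") else format_paren(m, s, 3)
  }
  rows <- data.frame(
    Plant = plants$plant_id,
    `Age (days)` = formatC(plants$age_days, format = "g"),
    `Activity (MBq)` = formatC(plants$activity_MBq, format = "g"),
    `Admin. duration (s)` = formatC(plants$admin_duration_s, format = "g"),
    ROIs = formatC(plants$n_rois, format = "d"),
    `sv (1/s)` = mapply(sv_cell, plants$sv_per_s,
                        if (is.null(plants$sv_sd_per_s)) NA_real_
                        else plants$sv_sd_per_s),
    `V (mm/s)` = formatC(plants$V_mm_s, format = "f", digits = 3),
    `s = sv/V (1/mm)` = formatC(round(plants$s_per_mm, 5), format = "f",
                                digits = 5),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  cohort <- data.frame(
    Plant = sprintf("Mean (s.d., n = %d)", summ$n_plants),
    `Age (days)` = format_paren(st["age_days", "mean"],
                                st["age_days", "sd"], decimals = 1),
    `Activity (MBq)` = format_paren(st["activity_MBq", "mean"],
                                    st["activity_MBq", "sd"], decimals = 1),
    `Admin. duration (s)` = format_paren(st["admin_duration_s", "mean"],
                                         st["admin_duration_s", "sd"],
                                         decimals = 0),
    ROIs = "",
    `sv (1/s)` = format_paren(st["sv_per_s", "mean"], st["sv_per_s", "sd"], 3),
    `V (mm/s)` = format_paren(st["V_mm_s", "mean"], st["V_mm_s", "sd"],
                              decimals = 3),
    `s = sv/V (1/mm)` = format_paren(st["s_per_mm", "mean"],
                                     st["s_per_mm", "sd"], 2),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  rows <- rbind(rows, cohort)
  widths <- pmax(nchar(names(rows)),
                 vapply(rows, function(col) max(nchar(col)), integer(1)))
  pad <- function(cells) {
    paste(mapply(formatC, cells, width = widths,
                 MoreArgs = list(flag = "-")), collapse = "  ")
  }
  lines <- c(pad(names(rows)),
             pad(strrep("-", widths)),
             apply(rows, 1L, pad))
  unname(lines)
}
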