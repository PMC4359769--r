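#' Published per-plant transport estimates for Brassica oleracea
#'
#' Per-plant kinetic parameter estimates from a petiolar [18F]fluoride
#' micro-PET experiment on three young rapid-cycling Brassica oleracea
#' plants: plant age, administered activity, administration duration,
#' number of stem ROIs, the per-plant mean (and s.d.) trapping rate sv, and
#' the transport velocity V. The raw scanner data behind these estimates
#' were not released; this table is the reference point for the package's
#' derived quantities (s = sv/V, cohort statistics, unit conversions) and
#' sets the parameter ranges the synthetic cohort generator draws from.
#'
#' @return A data frame with columns `plant_id`, `age_days`,
#'   `activity_MBq`, `admin_duration_s`, `n_rois`, `sv_per_s`,
#'   `sv_sd_per_s`, `V_mm_s`, and the derived `s_per_mm` = sv/V.
#' @seealso [summarize_cohort()], [render_results_table()],
#'   [simulate_cohort()]
#' @export
#' @examples
#' ref <- reference_plants()
#' signif(ref$s_per_mm, 2)  # 0.00088 0.00034 0.00131
reference_plants <- function() {
  path <- system.file("extdata", "brassica_f18_plants.tsv",
                      package = "stemkinetics", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  df$s_per_mm <- mapply(trapping_per_length, df$sv_per_s, df$V_mm_s)
  df
}
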