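# Integration grid for a free curve: frame mid-times with the model's
# (0, 0) anchor prepended when sampling starts after administration.
free_grid <- function(G) {
  stopifnot(inherits(G, "tac"))
  t <- G$schedule$mid_time
  v <- G$values
  if (t[1L] > 0) {
    t <- c(0, t)
    v <- c(0, v)
  }
  list(t = t, v = v)
}

#' Upper integration bound at the half-height of the free curve
#'
#' Mean arrival times are computed from truncated moments of the free
#' curve G: integrating to infinity lets late-time model error (reversible
#' trapping, bidirectional movement) distort the time-position plot, so the
#' integrals are cut at the falling half-height of G. This returns the
#' first time after the peak at which G crosses down through
#' `fraction * max(G)`, located by linear interpolation between the
#' bracketing frame mid-times. If G never falls below that level the last
#' mid-time is returned.
#'
#' @param G a [tac()] holding the free curve (from a `kinetic_fit`).
#' @param fraction height fraction defining the cut; default 0.5. The
#'   truncated integral then covers roughly the first 50--70% of the free
#'   tracer passing the ROI.
#' @return Upper bound time (s).
#' @export
half_height_upper_bound <- function(G, fraction = 0.5) {
  g <- free_grid(G)
  peak <- max(g$v)
  if (!is.finite(peak) || peak <= 0) {
    stop(sprintf("curve '%s' is unfittable: free curve has no positive maximum",
                 G$roi_label), call. = FALSE)
  }
  level <- fraction * peak
  i_peak <- which.max(g$v)
  for (k in seq(i_peak + 1L, length.out = max(0L, length(g$v) - i_peak))) {
    if (g$v[k] < level && g$v[k - 1L] >= level) {
      return(g$t[k - 1L] + (g$t[k] - g$t[k - 1L]) *
               (g$v[k - 1L] - level) / (g$v[k - 1L] - g$v[k]))
    }
  }
  g$t[length(g$t)]
}

#' Truncated mean arrival time of the free tracer
#'
#' The first temporal moment of the free curve G up to an upper bound UB:
#' T = int_0^UB t G(t) dt / int_0^UB G(t) dt. Both integrals use the
#' trapezoidal rule on the frame mid-times (with G anchored at (0, 0) when
#' sampling starts after administration); the final partial interval is
#' split at UB by linear interpolation. T is invariant under positive
#' scaling of G and shifts by exactly dt when G and UB are shifted by dt.
#'
#' @param G a [tac()] holding the free curve.
#' @param upper_bound integration cutoff (s); `Inf` integrates the whole
#'   sampled curve. Typically [half_height_upper_bound()].
#' @return Mean arrival time (s).
#' @export
mean_arrival_time <- function(G, upper_bound = Inf) {
  g <- free_grid(G)
  t <- g$t
  v <- g$v
  if (is.finite(upper_bound) && upper_bound < t[length(t)]) {
    if (upper_bound <= t[1L]) {
      stop("'upper_bound' must exceed the first sample time", call. = FALSE)
    }
    keep <- t < upper_bound
    v_ub <- stats::approx(t, v, xout = upper_bound)$y
    t <- c(t[keep], upper_bound)
    v <- c(v[keep], v_ub)
  }
  dt <- diff(t)
  denom <- sum(dt * (v[-1L] + v[-length(v)]) / 2)
  if (!is.finite(denom) || denom <= 0) {
    stop(sprintf(
      "curve '%s' is unfittable: free curve has non-positive area up to %g s",
      G$roi_label, upper_bound), call. = FALSE)
  }
  tv <- t * v
  numer <- sum(dt * (tv[-1L] + tv[-length(tv)]) / 2)
  numer / denom
}

#' Leading-edge half-height arrival time
#'
#' A simpler arrival estimate using only the leading edge of the bolus: the
#' first time the free curve crosses up through `fraction * max(G)`,
#' located by linear interpolation between the bracketing mid-times.
#'
#' @inheritParams half_height_upper_bound
#' @return Arrival time (s).
#' @export
half_height_arrival_time <- function(G, fraction = 0.5) {
  g <- free_grid(G)
  peak <- max(g$v)
  if (!is.finite(peak) || peak <= 0) {
    stop(sprintf("curve '%s' is unfittable: free curve has no positive maximum",
                 G$roi_label), call. = FALSE)
  }
  level <- fraction * peak
  if (g$v[1L] >= level) return(g$t[1L])
  for (k in seq(2L, length(g$v))) {
    if (g$v[k] >= level) {
      return(g$t[k - 1L] + (g$t[k] - g$t[k - 1L]) *
               (level - g$v[k - 1L]) / (g$v[k] - g$v[k - 1L]))
    }
  }
  g$t[length(g$t)]
}

#' Fit transport velocity from arrival times at several stem positions
#'
#' Ordinary least squares of stem position (mm, response) on arrival time
#' (s, predictor): the slope is the average transport velocity V in mm/s,
#' carrying the unit directly. The intercept is unconstrained.
#'
#' @param arrival_time_s numeric vector of per-ROI arrival times (s), or a
#'   data frame with columns `arrival_time_s` and `position_mm`.
#' @param position_mm numeric vector of ROI stem positions (mm); ignored
#'   when `arrival_time_s` is a data frame.
#' @return A list with `V_mm_s` (slope), `intercept_mm`, `r_squared`, and
#'   `model` (the underlying `lm` fit).
#' @export
#' @examples
#' fit_velocity(c(100, 200, 300), c(10, 20, 30))$V_mm_s  # 0.1
fit_velocity <- function(arrival_time_s, position_mm = NULL) {
  if (is.data.frame(arrival_time_s)) {
    df <- arrival_time_s
    stopifnot(all(c("arrival_time_s", "position_mm") %in% names(df)))
  } else {
    df <- data.frame(arrival_time_s = as.numeric(arrival_time_s),
                     position_mm = as.numeric(position_mm))
  }
  if (nrow(df) < 2L) {
    stop("velocity fitting needs at least 2 arrival estimates",
         call. = FALSE)
  }
  if (length(unique(df$arrival_time_s)) < 2L) {
    stop("degenerate fit: all arrival times are identical", call. = FALSE)
  }
  fit <- stats::lm(position_mm ~ arrival_time_s, data = df)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((df$position_mm - mean(df$position_mm))^2)
  list(
    V_mm_s = unname(stats::coef(fit)[2L]),
    intercept_mm = unname(stats::coef(fit)[1L]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    model = fit
  )
}

#' Trapping probability per unit stem length
#'
#' The fitted trapping rate sv (1/s) is the product of the trapping
#' probability per unit length s (1/mm) and the local velocity v (mm/s);
#' dividing the per-plant mean sv by the fitted velocity V recovers s.
#'
#' @param sv_mean trapping rate per unit time (1/s).
#' @param V_mm_s transport velocity (mm/s), > 0.
#' @return s in 1/mm.
#' @export
trapping_per_length <- function(sv_mean, V_mm_s) {
  if (!is.numeric(V_mm_s) || length(V_mm_s) != 1L || !is.finite(V_mm_s) ||
      V_mm_s <= 0) {
    stop("'V_mm_s' must be a single positive number (non-positive velocity signals failed or reversed transport)",
         call. = FALSE)
  }
  sv_mean / V_mm_s
}

unit_factors <- list(
  "1/s->1/min" = 60,
  "mm/s->cm/min" = 6,
  "1/mm->1/cm" = 10,
  "fraction->percent" = 100
)

#' Convert between the units used for reporting transport parameters
#'
#' Exact scale-factor conversions between the native per-second/millimetre
#' units of the model and the per-minute/centimetre units conventional in
#' sap-flow reporting: 1/s to 1/min (x60), mm/s to cm/min (x6), 1/mm to
#' 1/cm (x10), and fraction to percent (x100), each also in reverse.
#'
#' @param value numeric value(s) to convert.
#' @param from,to unit strings among `"1/s"`, `"1/min"`, `"mm/s"`,
#'   `"cm/min"`, `"1/mm"`, `"1/cm"`, `"fraction"`, `"percent"`.
#' @return Converted value(s).
#' @export
#' @examples
#' convert_units(0.368, "mm/s", "cm/min")   # 2.208
#' convert_units(0.000253, "1/s", "1/min")  # 0.01518
convert_units <- function(value, from, to) {
  if (identical(from, to)) return(value)
  key <- paste0(from, "->", to)
  rev_key <- paste0(to, "->", from)
  if (!is.null(unit_factors[[key]])) {
    value * unit_factors[[key]]
  } else if (!is.null(unit_factors[[rev_key]])) {
    value / unit_factors[[rev_key]]
  } else {
    stop(sprintf("unsupported unit conversion: '%s' to '%s'", from, to),
         call. = FALSE)
  }
}
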