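#' Fit the stem transport model to one plant
#'
#' The full per-plant analysis: each ROI's TAC is shifted onto the
#' administration time axis, the free/trapped compartment model is fitted
#' per ROI to obtain the trapping rate sv (see [solve_trapping_rate()]),
#' the free curve's truncated mean arrival time (or its leading-edge
#' half-height alternative) is computed per ROI, and stem position is
#' regressed on arrival time to give the transport velocity V (mm/s). The
#' per-plant trapping probability per unit length is then s = mean(sv) / V.
#'
#' @param curves a list of [tac()]s on the scanner clock (e.g. from
#'   [read_tac_file()] or [observe_plant()]), one per ROI.
#' @param manifest a [plant_manifest()]; supplies the administration offset
#'   and the ROI positions (matched to curves by `roi_label`; curves whose
#'   label is absent from the manifest keep their own `position_mm`).
#' @param t_f final-condition time (s) on the administration axis, or
#'   `"standard"` (3300 s) / `"computed"` (last rebased mid-time); see
#'   [final_condition_time()].
#' @param target_fraction fraction of M(t_f) trapped at t_f; default 1.
#' @param method arrival-time estimator: `"mean_arrival"` (truncated first
#'   moment, default) or `"half_height_leading_edge"`.
#' @param half_height_fraction height fraction for the truncation bound
#'   and the leading-edge estimate; default 0.5.
#' @return An object of class `transport_fit` with components
#'   `plant_id`, `kinetic_fits` (per-ROI `kinetic_fit` list), `arrivals`
#'   (data frame: roi_label, position_mm, sv, arrival_time_s,
#'   upper_bound_s), `sv_mean`, `sv_sd` (1/s), `V_mm_s`, `intercept_mm`,
#'   `r_squared`, `s_per_mm`, `n_rois`, `method`, `t_f`, `target_fraction`,
#'   `velocity_model` (the `lm`), and `manifest`. Supported methods:
#'   `print`, `summary`, `coef`, `plot`, `predict`, `residuals`, `fitted`,
#'   `simulate`, `as.data.frame`.
#' @export
#' @examples
#' sim <- observe_plant(sim_truth(v = 0.368, s = 0.00084, rng_seed = 1))
#' fit <- fit_transport(sim$curves, sim$manifest)
#' coef(fit)
fit_transport <- function(curves, manifest, t_f = "standard",
                          target_fraction = 1,
                          method = c("mean_arrival",
                                     "half_height_leading_edge"),
                          half_height_fraction = 0.5) {
  method <- match.arg(method)
  stopifnot(inherits(manifest, "plant_manifest"))
  if (inherits(curves, "tac")) curves <- list(curves)
  stopifnot(all(vapply(curves, inherits, logical(1), "tac")))
  if (length(curves) < 2L) {
    stop("velocity fitting needs TACs from at least 2 stem positions",
         call. = FALSE)
  }

  rebased <- lapply(curves, function(cv) {
    cv <- rebase_to_administration(cv, manifest$admin_offset_s)
    pos <- manifest$roi_positions_mm[cv$roi_label]
    if (!is.na(pos)) cv$position_mm <- unname(pos)
    if (is.na(cv$position_mm)) {
      stop(sprintf("no stem position for ROI '%s' (not in manifest, none on curve)",
                   cv$roi_label), call. = FALSE)
    }
    cv
  })

  t_f_s <- if (is.character(t_f)) {
    final_condition_time(rebased[[1L]]$schedule, mode = t_f)
  } else {
    as.numeric(t_f)
  }

  kinetic_fits <- lapply(rebased, solve_trapping_rate, t_f = t_f_s,
                         target_fraction = target_fraction)
  arrivals <- do.call(rbind, lapply(kinetic_fits, function(kf) {
    ub <- half_height_upper_bound(kf$G, fraction = half_height_fraction)
    at <- if (method == "mean_arrival") {
      mean_arrival_time(kf$G, ub)
    } else {
      half_height_arrival_time(kf$G, fraction = half_height_fraction)
    }
    data.frame(roi_label = kf$M$roi_label, position_mm = kf$M$position_mm,
               sv = kf$sv, arrival_time_s = at, upper_bound_s = ub,
               stringsAsFactors = FALSE)
  }))

  vel <- fit_velocity(arrivals)
  sv_mean <- mean(arrivals$sv)
  structure(
    list(
      plant_id = manifest$plant_id,
      kinetic_fits = kinetic_fits,
      arrivals = arrivals,
      sv_mean = sv_mean,
      sv_sd = stats::sd(arrivals$sv),
      V_mm_s = vel$V_mm_s,
      intercept_mm = vel$intercept_mm,
      r_squared = vel$r_squared,
      s_per_mm = trapping_per_length(sv_mean, vel$V_mm_s),
      n_rois = nrow(arrivals),
      method = method,
      t_f = t_f_s,
      target_fraction = target_fraction,
      half_height_fraction = half_height_fraction,
      velocity_model = vel$model,
      manifest = manifest
    ),
    class = "transport_fit"
  )
}

#' @export
print.transport_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Stem transport fit for plant '%s' (%d ROIs, %s)\n",
              x$plant_id, x$n_rois, x$method))
  cat(sprintf("  trapping rate  sv = %.*g +/- %.*g 1/s\n",
              digits, x$sv_mean, 2, x$sv_sd))
  cat(sprintf("  velocity        V = %.*g mm/s (%.*g cm/min), R^2 = %.3f\n",
              digits, x$V_mm_s, digits,
              convert_units(x$V_mm_s, "mm/s", "cm/min"), x$r_squared))
  cat(sprintf("  trapping/length s = %.*g 1/mm\n", digits, x$s_per_mm))
  invisible(x)
}

#' @export
coef.transport_fit <- function(object, ...) {
  c(sv = object$sv_mean, V = object$V_mm_s,
    intercept = object$intercept_mm, s = object$s_per_mm)
}

#' @export
residuals.transport_fit <- function(object, ...) {
  stats::residuals(object$velocity_model)
}

#' @export
fitted.transport_fit <- function(object, ...) {
  stats::fitted(object$velocity_model)
}

#' Predict stem position of the bolus at given arrival times
#'
#' @param object a [fit_transport()] result.
#' @param newdata optional data frame with column `arrival_time_s`; the
#'   fitted arrival times are used when omitted.
#' @param ... unused.
#' @return Predicted positions (mm) from the velocity regression.
#' @export
predict.transport_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$velocity_model))
  stats::predict(object$velocity_model, newdata = newdata)
}

#' Simulate synthetic plants from a fitted transport model
#'
#' Uses the fitted velocity and per-length trapping probability as ground
#' truth for the forward simulator, observing each simulated plant through
#' the standard frame schedule at the fitted plant's ROI positions.
#'
#' @param object a [fit_transport()] result with `V_mm_s > 0`.
#' @param nsim number of plants to simulate.
#' @param seed optional integer seed.
#' @param noise_cv per-frame noise level; default 0.
#' @param ... unused.
#' @return A list of `nsim` [observe_plant()] results.
#' @export
simulate.transport_fit <- function(object, nsim = 1, seed = NULL,
                                   noise_cv = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  truth <- sim_truth(
    v = object$V_mm_s, s = object$s_per_mm,
    admin_duration_s = object$manifest$administration_duration_s,
    roi_positions_mm = sort(unname(object$manifest$roi_positions_mm)),
    noise_cv = noise_cv,
    administered_activity_Bq = object$manifest$administered_activity_Bq,
    age_days = object$manifest$age_days
  )
  lapply(seq_len(nsim), function(i) {
    observe_plant(truth, admin_offset_s = object$manifest$admin_offset_s)
  })
}

#' @export
summary.transport_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.transport_fit")
}

#' @export
print.summary.transport_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  (sv = %.3g 1/min, s = %.3g 1/cm; t_f = %g s, target %.0f%%)\n",
              convert_units(f$sv_mean, "1/s", "1/min"),
              convert_units(f$s_per_mm, "1/mm", "1/cm"),
              f$t_f, 100 * f$target_fraction))
  cat("\nPer-ROI fits:\n")
  df <- f$arrivals
  df$sv <- signif(df$sv, 4)
  df$arrival_time_s <- round(df$arrival_time_s, 1)
  df$upper_bound_s <- round(df$upper_bound_s, 1)
  print(df, row.names = FALSE)
  cat("\nVelocity regression (position_mm ~ arrival_time_s):\n")
  print(summary(f$velocity_model)$coefficients)
  invisible(x)
}

#' Plot a fitted stem transport model
#'
#' Two panels: the observed TAC of one ROI with its fitted free and
#' trapped components, and the time-position plot with the velocity
#' regression line.
#'
#' @param x a [fit_transport()] result.
#' @param roi index of the ROI shown in the TAC panel; default the last
#'   (most up-stem) ROI.
#' @param ... passed to [graphics::plot()].
#' @export
plot.transport_fit <- function(x, roi = length(x$kinetic_fits), ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  kf <- x$kinetic_fits[[roi]]
  t_min <- kf$M$schedule$mid_time / 60
  graphics::plot(t_min, kf$M$values, type = "b", pch = 16,
                 xlab = "time after administration (min)",
                 ylab = "concentration (1/mm)",
                 main = sprintf("ROI '%s' (%g mm)", kf$M$roi_label,
                                kf$M$position_mm), ...)
  graphics::lines(t_min, kf$G$values, col = "forestgreen", lwd = 2)
  graphics::lines(t_min, kf$B$values, col = "firebrick", lwd = 2)
  graphics::abline(v = x$arrivals$upper_bound_s[roi] / 60, lty = 3)
  graphics::legend("topright", c("observed M", "free G", "trapped B", "UB"),
                   col = c("black", "forestgreen", "firebrick", "black"),
                   lty = c(1, 1, 1, 3), pch = c(16, NA, NA, NA), bty = "n")
  graphics::plot(x$arrivals$arrival_time_s, x$arrivals$position_mm,
                 pch = 16, xlab = "mean arrival time (s)",
                 ylab = "stem position (mm)",
                 main = sprintf("V = %.3g mm/s", x$V_mm_s))
  graphics::abline(x$intercept_mm, x$V_mm_s, col = "steelblue", lwd = 2)
  invisible(x)
}

#' @export
as.data.frame.transport_fit <- function(x, ...) {
  data.frame(
    plant_id = x$plant_id,
    age_days = x$manifest$age_days,
    activity_MBq = x$manifest$administered_activity_Bq / 1e6,
    admin_duration_s = x$manifest$administration_duration_s,
    n_rois = x$n_rois,
    sv_per_s = x$sv_mean,
    sv_sd_per_s = x$sv_sd,
    V_mm_s = x$V_mm_s,
    s_per_mm = x$s_per_mm,
    r_squared = x$r_squared,
    stringsAsFactors = FALSE
  )
}
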