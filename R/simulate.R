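#' Ground truth for a synthetic stem-transport experiment
#'
#' Describes a plant in which a finite bolus of tracer, fed at the cut
#' petiole over `admin_duration_s` seconds, is advected up the stem at
#' constant velocity `v` while being irreversibly trapped with probability
#' `s` per unit length. The temporal input profile is a rectangle of the
#' administration duration smoothed by a Gaussian of s.d.
#' `dispersion_sigma0_s` (drop-by-drop feeding is not a sharp-edged pulse);
#' the profile's shape is fixed at administration and does not spread
#' further with position, matching the dispersion-free transport model the
#' fitter assumes.
#'
#' @param v bolus velocity (mm/s), > 0.
#' @param s trapping probability per unit length (1/mm), >= 0.
#' @param admin_duration_s administration duration (s), > 0; default 240.
#' @param admin_amplitude free-tracer plateau concentration at the node
#'   (1/mm, normalized units); default 1e-4. The fitted parameters are
#'   scale-free, so this only sets the overall TAC scale.
#' @param dispersion_sigma0_s temporal smoothing of the bolus edges at the
#'   node (s); default 30.
#' @param roi_positions_mm strictly increasing non-negative ROI positions
#'   (mm above the node); default 5, 10, ..., 30.
#' @param noise_cv per-frame coefficient of variation of the multiplicative
#'   Gaussian observation noise; 0 (default) is noise-free.
#' @param administered_activity_Bq nominal administered activity recorded
#'   in the manifest (Bq); default 7.2e6.
#' @param age_days nominal plant age recorded in the manifest; default 22.
#' @param rng_seed optional integer seed used by [observe_plant()].
#' @return An object of class `sim_truth`.
#' @seealso [observe_plant()], [simulate_cohort()]
#' @export
sim_truth <- function(v, s, admin_duration_s = 240, admin_amplitude = 1e-4,
                      dispersion_sigma0_s = 30,
                      roi_positions_mm = seq(5, 30, by = 5), noise_cv = 0,
                      administered_activity_Bq = 7.2e6, age_days = 22,
                      rng_seed = NULL) {
  stopifnot(is.numeric(v), length(v) == 1L, v > 0)
  stopifnot(is.numeric(s), length(s) == 1L, s >= 0)
  stopifnot(admin_duration_s > 0, admin_amplitude > 0,
            dispersion_sigma0_s >= 0, noise_cv >= 0)
  roi_positions_mm <- as.numeric(roi_positions_mm)
  if (any(roi_positions_mm < 0) || any(diff(roi_positions_mm) <= 0)) {
    stop("'roi_positions_mm' must be non-negative and strictly increasing",
         call. = FALSE)
  }
  structure(
    list(v = v, s = s, admin_duration_s = admin_duration_s,
         admin_amplitude = admin_amplitude,
         dispersion_sigma0_s = dispersion_sigma0_s,
         roi_positions_mm = roi_positions_mm, noise_cv = noise_cv,
         administered_activity_Bq = administered_activity_Bq,
         age_days = age_days, rng_seed = rng_seed),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic plant: v = %.3g mm/s, s = %.3g 1/mm (sv = %.3g 1/s), bolus %g s, noise CV %.0f%%\n",
    x$v, x$s, x$s * x$v, x$admin_duration_s, 100 * x$noise_cv))
  invisible(x)
}

# Smoothed rectangular input profile, plateau height 1: rect of duration D
# convolved with a Gaussian of s.d. sigma (closed form via the normal CDF),
# delayed by 3 sigma so the input is causal to within pnorm(-3) ~ 0.1%
# (tracer cannot be in the stem before administration starts at tau = 0).
bolus_profile <- function(tau, duration, sigma) {
  if (sigma <= 0) {
    as.numeric(tau >= 0 & tau < duration)
  } else {
    stats::pnorm(tau, 3 * sigma, sigma) -
      stats::pnorm(tau, 3 * sigma + duration, sigma)
  }
}

#' Free tracer concentration at a stem position (noise-free truth)
#'
#' G(x, t) = A exp(-s x) h(t - x/v): the input profile h advected to
#' position x with delay x/v, attenuated by the survival factor exp(-s x)
#' of free tracer that escaped trapping over the first x millimetres.
#'
#' @param truth a [sim_truth()].
#' @param x stem position (mm, >= 0).
#' @param times evaluation times (s, administration time axis).
#' @return Numeric vector of free concentrations at `times`.
#' @export
free_curve_at_position <- function(truth, x, times) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!is.numeric(x) || length(x) != 1L || x < 0) {
    stop("'x' must be a single non-negative position", call. = FALSE)
  }
  truth$admin_amplitude * exp(-truth$s * x) *
    bolus_profile(times - x / truth$v, truth$admin_duration_s,
                  truth$dispersion_sigma0_s)
}

#' Trapped tracer concentration at a stem position (noise-free truth)
#'
#' B(x, t) = s v int_0^t G(x, t') dt', evaluated by dense trapezoidal
#' quadrature (step <= `dt`). B is nondecreasing and saturates at
#' s v times the total free-tracer exposure at x, so the ratio of the
#' final trapped level to the area under G is exactly the rate sv the
#' kinetic fitter estimates.
#'
#' @inheritParams free_curve_at_position
#' @param dt quadrature step (s); default 1.
#' @return Numeric vector of trapped concentrations at `times`.
#' @export
trapped_curve_at_position <- function(truth, x, times, dt = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!is.numeric(x) || length(x) != 1L || x < 0) {
    stop("'x' must be a single non-negative position", call. = FALSE)
  }
  t_max <- max(times, 0)
  grid <- seq(0, t_max, by = dt)
  if (grid[length(grid)] < t_max) grid <- c(grid, t_max)
  G <- free_curve_at_position(truth, x, grid)
  n <- length(grid)
  cum <- c(0, cumsum(diff(grid) * (G[-1L] + G[-n]) / 2))
  B <- truth$s * truth$v * cum
  out <- stats::approx(grid, B, xout = pmax(times, 0), rule = 2)$y
  out[times < 0] <- 0
  out
}

#' Observe a synthetic plant through a PET frame schedule
#'
#' Generates the TACs a dynamic PET scan would record for each ROI of a
#' synthetic plant: the total concentration M = G + B is averaged over each
#' frame interval by dense quadrature, then multiplicative Gaussian noise
#' is applied independently per frame (each value scaled by
#' 1 + N(0, noise_cv^2), the usual proportional approximation to counting
#' noise in reconstructed, correction-weighted PET values). The schedule
#' is on the scanner clock; administration starts `admin_offset_s` seconds
#' in, so analysis should [rebase_to_administration()] first.
#'
#' @param truth a [sim_truth()].
#' @param schedule a [frame_schedule()] on the scanner clock; default
#'   [standard_frame_schedule()].
#' @param admin_offset_s seconds between scan start and administration
#'   start; default 60.
#' @param dt dense quadrature step for frame averaging (s); default 1.
#' @return A list with `curves` (list of [tac()] on the scanner clock),
#'   `manifest` (a [plant_manifest()]), and `truth`.
#' @export
#' @examples
#' sim <- observe_plant(sim_truth(v = 0.368, s = 0.00084, rng_seed = 1))
#' length(sim$curves)   # 6 ROIs
observe_plant <- function(truth, schedule = standard_frame_schedule(),
                          admin_offset_s = 60, dt = 1) {
  stopifnot(inherits(truth, "sim_truth"), inherits(schedule, "frame_schedule"))
  if (!is.null(truth$rng_seed)) set.seed(truth$rng_seed)
  n_frames <- length(schedule$frame_start)
  scan_end <- schedule$frame_start[n_frames] + schedule$frame_duration[n_frames]
  grid <- seq(0, scan_end, by = dt)                     # scanner clock
  t_admin <- grid - admin_offset_s
  positive <- t_admin >= 0
  curves <- lapply(seq_along(truth$roi_positions_mm), function(i) {
    x <- truth$roi_positions_mm[i]
    M <- numeric(length(grid))
    M[positive] <-
      free_curve_at_position(truth, x, t_admin[positive]) +
      trapped_curve_at_position(truth, x, t_admin[positive], dt = dt)
    frame_mean <- vapply(seq_len(n_frames), function(k) {
      a <- schedule$frame_start[k]
      b <- a + schedule$frame_duration[k]
      idx <- which(grid >= a - 1e-9 & grid <= b + 1e-9)
      tt <- grid[idx]
      mm <- M[idx]
      sum(diff(tt) * (mm[-1L] + mm[-length(mm)]) / 2) / (tt[length(tt)] - tt[1L])
    }, numeric(1))
    if (truth$noise_cv > 0) {
      frame_mean <- frame_mean * (1 + stats::rnorm(n_frames, 0, truth$noise_cv))
    }
    tac(schedule, frame_mean, roi_label = sprintf("roi%02d", i),
        position_mm = x)
  })
  positions <- truth$roi_positions_mm
  names(positions) <- vapply(curves, `[[`, character(1), "roi_label")
  manifest <- plant_manifest(
    plant_id = "synthetic",
    administered_activity_Bq = truth$administered_activity_Bq,
    administration_duration_s = truth$admin_duration_s,
    roi_positions_mm = positions,
    admin_offset_s = admin_offset_s,
    age_days = truth$age_days
  )
  list(curves = curves, manifest = manifest, truth = truth)
}

#' Simulate a cohort of synthetic plants
#'
#' Draws per-plant ground truths spanning the parameter ranges reported for
#' petiolar [18F]fluoride transport in young Brassica oleracea (velocity
#' 0.214--0.566 mm/s, trapping 0.00034--0.00131 1/mm, administration
#' 180--300 s, 5--8 ROIs at 5 mm spacing) and observes each plant through
#' the standard frame schedule.
#'
#' @param n_plants number of plants (>= 1); default 3.
#' @param seed integer seed making the whole cohort reproducible.
#' @param noise_cv per-frame noise level passed to each plant; default 0.
#' @param schedule scanner-clock [frame_schedule()]; default
#'   [standard_frame_schedule()].
#' @param admin_offset_s seconds between scan start and administration.
#' @return A list of [observe_plant()] results (elements `curves`,
#'   `manifest`, `truth`), with `manifest$plant_id` set to `"sim1"`,
#'   `"sim2"`, ...
#' @export
simulate_cohort <- function(n_plants = 3, seed = NULL, noise_cv = 0,
                            schedule = standard_frame_schedule(),
                            admin_offset_s = 60) {
  stopifnot(n_plants >= 1)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_plants), function(i) {
    n_rois <- sample(5:8, 1L)
    truth <- sim_truth(
      v = stats::runif(1, 0.214, 0.566),
      s = stats::runif(1, 0.00034, 0.00131),
      admin_duration_s = sample(c(180, 240, 300), 1L),
      roi_positions_mm = seq(5, by = 5, length.out = n_rois),
      noise_cv = noise_cv,
      administered_activity_Bq = stats::runif(1, 3e6, 10e6),
      age_days = sample(20:26, 1L)
    )
    sim <- observe_plant(truth, schedule = schedule,
                         admin_offset_s = admin_offset_s)
    sim$manifest$plant_id <- paste0("sim", i)
    sim
  })
}
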