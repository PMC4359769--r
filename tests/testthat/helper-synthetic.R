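# Shared fixtures: synthetic plants at the three reference configurations
# and small hand-built curves for geometry tests.

reference_truths <- function() {
  ref <- reference_plants()
  lapply(seq_len(nrow(ref)), function(i) {
    sim_truth(
      v = ref$V_mm_s[i], s = ref$s_per_mm[i],
      admin_duration_s = ref$admin_duration_s[i],
      roi_positions_mm = seq(5, by = 5, length.out = ref$n_rois[i])
    )
  })
}

# tac sampled on a dense 1 s grid from a value function of time
dense_tac <- function(f, t_end = 600, dt = 1, position_mm = NA_real_) {
  sched <- frame_schedule(seq(0, t_end - dt, by = dt), rep(dt, t_end / dt))
  tac(sched, f(sched$mid_time), position_mm = position_mm)
}

# symmetric triangle: 0 at t = 0, peak 1 at t = 300, 0 at t = 600
triangle_fun <- function(t) pmax(0, 1 - abs(t - 300) / 300)

# unit rectangle on [100, 200)
rect_fun <- function(t) as.numeric(t >= 100 & t < 200)
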