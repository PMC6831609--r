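# shared fixtures built in code

# the default 15 retained acquisition times
retained_times <- function() {
  acq <- acquisition_spec()
  acq$frame_times[acq$retained_indices]
}

# sample a known curve (plus optional recirculation bump and noise) at the
# default retained times
sampled_curve <- function(params, recirc_scale = 0, recirc_arrival = NULL,
                          noise_sd = 0, times = retained_times()) {
  y <- gv_eval(params, times)
  if (recirc_scale > 0) {
    shifted <- gv_params(params$A, recirc_arrival, params$alpha,
                         params$beta, baseline = 0)
    y <- y + recirc_scale * gv_eval(shifted, times)
  }
  if (noise_sd > 0) y <- y + rnorm(length(times), 0, noise_sd)
  list(times = times, densities = y)
}

# single-region miniature phantom: a disk with given kinetics on a small
# grid, noiseless by default
disk_phantom <- function(kinetics, grid = 24L, noise_sigma = 0, seed = 1L) {
  phantom_spec(
    list(region_spec("myocardium", center = c(grid / 2, grid / 2),
                     radius = grid / 4, kinetics = kinetics,
                     recirculation_scale = 0)),
    grid = grid,
    acquisition = acquisition_spec(noise_sigma = noise_sigma, seed = seed))
}
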