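# Shared synthetic sessions, generated once per test run and cached.

.pg_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .pg_cache)) assign(key, fn(), envir = .pg_cache)
  get(key, envir = .pg_cache)
}

# Small session with an imposed 2/1 engaged/disengaged split; enough
# frames (> 1000) for the shuffle null.
small_session <- function() {
  cached("small", function() {
    cfg <- gen_config(n_trials = 45, n_cells = 60, seed = 42)
    states <- rep(c("engaged", "disengaged"), c(30, 15))
    generate_session(cfg, seed = 42, states = states)
  })
}

# High-SNR engaged-only session: low but nonzero noise.
highsnr_session <- function() {
  cached("highsnr", function() {
    cfg <- gen_config(n_trials = 30, n_cells = 120, trial_amplitude_cv = 0.05,
                      noise_rate = 0.01, seed = 13)
    generate_session(cfg, seed = 13, states = rep("engaged", 30))
  })
}

# Noise-free, perfectly reliable session: recovers ground truth exactly.
clean_session <- function() {
  cached("clean", function() {
    cfg <- gen_config(n_trials = 24, n_cells = 20, trial_amplitude_cv = 0,
                      noise_rate = 0, speed_noise_sd = 0,
                      disengaged_field_loss = 0, disengaged_field_gain = 0,
                      disengaged_remap_fraction = 0,
                      disengaged_noise_scale = 1, seed = 7)
    generate_session(cfg, seed = 7,
                     states = rep("engaged", 24))
  })
}
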