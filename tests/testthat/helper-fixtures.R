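# Shared fixtures: all built in code at test time.

# Constant-weather environment: tavg = t_base + tu_per_day, fixed radiation.
# Thermal units then accumulate exactly tu_per_day per day, which makes
# phenology arithmetic checkable by hand.
constant_env <- function(days = 120, tu_per_day = 10, sr = 20, ppop = 8,
                         label = "const") {
  w <- structure(data.frame(
    date = as.Date("2020-01-01") + seq_len(days + 10) - 1,
    tavg_c = 8 + tu_per_day, sr_mj_m2 = sr),
    class = c("weather_series", "data.frame"))
  cgm_environment(label, w, "2020-01-01", days, ppop)
}

# Small DH dataset for ABC / evaluation tests (desk-scale architecture).
small_dataset <- function(n_lines = 150, n_markers = 28, seed = 99) {
  simulate_dataset(n_lines = n_lines, map = marker_genome(1.5, n_markers),
                   n_qtl = 8, per_trait = 2, seed = seed)
}

# Identity model operator: "yield" is the latent TLN itself. Used to cut
# the growth model out of ABC correctness checks.
identity_yield <- function(traits, env, params) traits[, "tln"]

# Memoised desk-scale experiment shared by the end-to-end checks, so the
# expensive replicated run happens once per test session.
desk_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_replicated_experiment(experiment_config(seed = 42))
    cache
  }
})
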