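# Shared pipeline runs, built lazily and cached for the whole test session.
# Seeds are fixed so every test sees the same data.

.run_cache <- new.env(parent = emptyenv())

# Default study conditions: 0.2 ppm mass error, 99% label enrichment,
# noise peaks, dropout, technical triplicates.
default_run <- function() {
  if (is.null(.run_cache$default)) {
    .run_cache$default <- run_pipeline(run_config(seed = 101L))
  }
  .run_cache$default
}

# Noiseless conditions: exact masses, no noise peaks, no dropout, no
# peak-time jitter, no isomer variants; the mass window is widened so the
# seed molecules and their first-generation products are observable and the
# generator's closure property applies to the whole molecule set.
noiseless_run <- function() {
  if (is.null(.run_cache$noiseless)) {
    sim <- sim_config(mass_error_ppm_sd = 0, n_noise = 0, dropout = 0,
                      peak_time_jitter = 0, mixed_isomer_fraction = 0,
                      seed = 202L)
    .run_cache$noiseless <- run_pipeline(
      run_config(sim = sim, mz_range = c(40, 1000), seed = 202L))
  }
  .run_cache$noiseless
}

# Tiny spectrum constructor for unit tests.
mk_spec <- function(mz, intensity = rep(100, length(mz)),
                    sn = rep(10, length(mz)), timepoint = 2, replicate = 1,
                    channel = "unlabeled") {
  new_spectrum(data.frame(mz = mz, intensity = intensity, sn = sn),
               timepoint, replicate, channel)
}

# Peak columns of a spectrum, without audit attributes.
peaks_of <- function(sp) {
  data.frame(mz = sp$mz, intensity = sp$intensity, sn = sp$sn)
}
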