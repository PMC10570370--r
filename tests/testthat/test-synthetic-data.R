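# Ground-truth simulation and peak-list rendering.

test_that("generation zero and zero probabilities return only the seeds", {
  cfg0 <- sim_config(n_generations = 0)
  m0 <- simulate_reaction_network(cfg0)
  expect_identical(sort(m0$formula), sort(cfg0$seeds$formula))
  expect_identical(m0$n_co, cfg0$seeds$n_co)

  cfgp <- sim_config(trans_probs = c(water_addition = 0, h2s_addition = 0,
                                     c2h2_addition = 0, carbonylation_h2o = 0,
                                     carbonylation_h2s = 0, reduction = 0),
                     mixed_isomer_fraction = 0)
  expect_identical(sort(simulate_reaction_network(cfgp)$formula),
                   sort(cfgp$seeds$formula))
})

test_that("deterministic acetylene chain expands exactly", {
  cfg <- sim_config(seeds = data.frame(formula = "C2H4O", n_co = 0L),
                    trans_probs = c(water_addition = 0, h2s_addition = 0,
                                    c2h2_addition = 1, carbonylation_h2o = 0,
                                    carbonylation_h2s = 0, reduction = 0),
                    n_generations = 3, mixed_isomer_fraction = 0)
  m <- simulate_reaction_network(cfg)
  expect_setequal(m$formula, c("C2H4O", "C4H6O", "C6H8O", "C8H10O"))
  expect_true(all(m$n_co == 0))
})

test_that("every molecule's composition equals its seed plus history deltas", {
  cfg <- sim_config(seed = 9)
  m <- simulate_reaction_network(cfg)
  tr <- transformations()
  for (i in seq_len(nrow(m))) {
    comp_i <- parse_formula(m$formula[i])
    acc <- parse_formula(m$seed_formula[i])
    if (nzchar(m$history[i])) {
      for (step in strsplit(m$history[i], ";")[[1]]) {
        acc <- comp_add(acc, tr[tr$name == step, c2netms:::.comp_cols])
      }
    }
    expect_identical(format_formula(acc), m$formula[i])
  }
})

test_that("addition reactions are gated on available unsaturation", {
  m <- simulate_reaction_network(sim_config(seed = 5))
  dbe <- m$c - m$h / 2 + 1
  expect_true(all(dbe >= 0))
})

test_that("alternative reaction multisets explain label-degree mixing", {
  # 2 x carbonylation(H2O) + 3 x reduction has the same elemental sum as
  # C2H2 + 4 x H2O but two more CO-derived carbons
  delta <- parse_formula("C2H10O4")
  sol <- feasible_co_counts(delta)
  expect_setequal(sol$n_co, c(0L, 2L))
  # every returned multiset really sums to the delta
  tr <- transformations()
  for (r in seq_len(nrow(sol))) {
    counts <- as.integer(sol[r, c("n_water", "n_h2s", "n_c2h2",
                                  "n_carb_h2o", "n_carb_h2s", "n_reduction")])
    acc <- comp()
    for (t in seq_len(6)) if (counts[t] > 0)
      for (k in seq_len(counts[t]))
        acc <- comp_add(acc, tr[t, c2netms:::.comp_cols])
    expect_identical(format_formula(acc), format_formula(delta))
  }
})

test_that("peak times follow sulfur count and jitter preserves the trend", {
  cfg <- sim_config(peak_time_jitter = 0)
  m <- assign_temporal_profiles(simulate_reaction_network(cfg), cfg)
  expect_true(all(m$peak_time[m$s >= 3] <= m$peak_time[m$s == 0][1]))
  # exact table lookup at jitter 0
  expect_true(all(m$peak_time == cfg$peak_time_by_s[pmin(m$s, 3) + 1]))

  # rank correlation between sulfur count and peak time stays negative
  # under default jitter (large molecule sample)
  cfg2 <- sim_config(n_generations = 7, max_molecules = 1000, seed = 77)
  m2 <- assign_temporal_profiles(simulate_reaction_network(cfg2), cfg2)
  expect_gt(nrow(m2), 300)
  rho <- stats::cor(m2$s, m2$peak_time, method = "spearman")
  expect_lt(rho, 0)
})

test_that("rendered peaks carry the expected isotope satellites", {
  cfg <- sim_config(seeds = data.frame(formula = "C2H4O2", n_co = 1L),
                    n_generations = 0, mass_error_ppm_sd = 0, n_noise = 0,
                    dropout = 0, peak_time_jitter = 0,
                    mixed_isomer_fraction = 0)
  m <- assign_temporal_profiles(simulate_reaction_network(cfg), cfg)
  m$amplitude <- 1000
  sp <- render_spectra(m, cfg, "unlabeled", m$peak_time, 1)
  expect_equal(sp$mz[1], 59.01385, tolerance = 1e-5)
  expect_equal(sp$mz[2], 60.01720, tolerance = 2e-5)
  expect_equal(sp$intensity[2] / sp$intensity[1], 0.011 * 2, tolerance = 1e-9)

  # full enrichment moves the monoisotopic signal by one 13C shift
  cfg2 <- sim_config(seeds = data.frame(formula = "C2H4O2", n_co = 1L),
                     n_generations = 0, mass_error_ppm_sd = 0, n_noise = 0,
                     dropout = 0, peak_time_jitter = 0, enrichment = 1,
                     mixed_isomer_fraction = 0)
  m2 <- assign_temporal_profiles(simulate_reaction_network(cfg2), cfg2)
  m2$amplitude <- 1000
  sp2 <- render_spectra(m2, cfg2, "13CO", m2$peak_time, 1)
  expect_equal(sp2$mz[1], 59.01385 + delta_13c, tolerance = 2e-5)
  expect_equal(max(sp2$intensity), 1000)

  # far from the peak time with a narrow kernel the signal is unrenderable
  cfg3 <- sim_config(seeds = data.frame(formula = "C2H4O2", n_co = 0L),
                     n_generations = 0, mass_error_ppm_sd = 0, n_noise = 0,
                     dropout = 0, peak_time_jitter = 0, kernel_log_sd = 0.3,
                     mixed_isomer_fraction = 0)
  m3 <- assign_temporal_profiles(simulate_reaction_network(cfg3), cfg3)
  m3$peak_time <- 2; m3$amplitude <- 1000
  sp3 <- render_spectra(m3, cfg3, "unlabeled", 168, 1)
  expect_equal(nrow(sp3), 0)
})

test_that("labelled-channel peaks sit at integer 13C shifts of the mono peak",
{
  cfg <- sim_config(mass_error_ppm_sd = 0, n_noise = 0, dropout = 0,
                    mixed_isomer_fraction = 0, seed = 12)
  m <- assign_temporal_profiles(simulate_reaction_network(cfg), cfg)
  sp <- render_spectra(m, cfg, "13CO", 72, 1)
  cc <- m[, c("c", "h", "o", "s", "na", "n13c")]
  mono <- ion_mz(cc, "deprotonated")
  nad <- ion_mz(cc[m$is_dicarboxylic & m$h >= 2, , drop = FALSE],
                "sodiated-deprotonated")
  base <- c(outer(c(mono, nad), 0:7 * delta_13c, `+`))
  expected <- c(base, base + delta_34s)
  for (mz in sp$mz) {
    d <- min(abs(expected - mz))
    expect_lt(d / mz * 1e6, 0.01)
  }
})

test_that("rendering is deterministic and independent of call order", {
  cfg <- sim_config(seed = 4)
  m <- assign_temporal_profiles(simulate_reaction_network(cfg), cfg)
  a <- render_spectra(m, cfg, "unlabeled", 24, 2)
  render_spectra(m, cfg, "13CO", 168, 1)  # interleaved other call
  b <- render_spectra(m, cfg, "unlabeled", 24, 2)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("persistent contaminants recur across replicates", {
  cfg <- sim_config(n_generations = 0, seed = 8)
  m <- assign_temporal_profiles(simulate_reaction_network(cfg), cfg)
  r1 <- render_spectra(m, cfg, "unlabeled", 24, 1)
  r2 <- render_spectra(m, cfg, "unlabeled", 24, 2)
  n_cons <- round(cfg$n_noise * cfg$noise_consistent_fraction)
  shared <- sum(vapply(r1$mz, function(z) any(abs(r2$mz - z) / z * 1e6 < 2), TRUE))
  expect_gte(shared, n_cons - 2)
})

test_that("ground truth round-trips losslessly and rejects malformed files", {
  cfg <- sim_config(seed = 6)
  m <- assign_temporal_profiles(simulate_reaction_network(cfg), cfg)
  f <- tempfile(fileext = ".csv")
  write_ground_truth(m, f)
  m2 <- read_ground_truth(f)
  expect_identical(m2$formula, m$formula)
  expect_identical(m2$n_co, m$n_co)
  expect_equal(m2$peak_time, m$peak_time)
  expect_equal(m2$amplitude, m$amplitude)
  expect_identical(m2$is_dicarboxylic, m$is_dicarboxylic)
  expect_identical(m2$history, m$history)

  # empty list still writes a parseable header
  write_ground_truth(m[0, ], f)
  expect_identical(nrow(read_ground_truth(f)), 0L)

  bad <- utils::read.csv(f)
  bad <- rbind(bad, data.frame(formula = "C-2H4", n_co = 0, s_count = 0,
                               peak_time_h = 2, amplitude = 1,
                               is_dicarboxylic = FALSE, history = "",
                               generation = 0, seed_formula = "C2H4",
                               is_isomer_variant = FALSE))
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_ground_truth(f), "cannot parse")
})

test_that("requested isomer-variant fraction is realized in the truth set", {
  cfg <- sim_config(mixed_isomer_fraction = 0.3, seed = 31)
  m <- simulate_reaction_network(cfg)
  frac <- mean(table(m$formula) >= 2)
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.4)
  # variants share their partner's composition but differ in CO carbons
  dup <- names(which(table(m$formula) == 2))
  for (f in dup) {
    pair <- m[m$formula == f, ]
    expect_identical(nrow(pair), 2L)
    expect_false(pair$n_co[1] == pair$n_co[2])
  }
})

test_that("unknown labelling channel is rejected", {
  cfg <- sim_config(n_generations = 0)
  m <- assign_temporal_profiles(simulate_reaction_network(cfg), cfg)
  expect_error(render_spectra(m, cfg, "deuterium", 2, 1), "unknown")
})
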