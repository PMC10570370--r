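# Peak filters, replicate consensus, recalibration, artifact filters.

test_that("s/n and mass-range boundaries are applied as stated", {
  sp <- mk_spec(mz = c(121.99, 150, 200, 900, 1000.01),
                intensity = rep(100, 5), sn = c(10, 5, 3.9, 4, 10))
  out <- filter_peaks(sp)
  # sn = 4 at the boundary is kept, 3.9 removed; both range boundaries closed
  expect_equal(out$mz, c(150, 900))
  # idempotent
  expect_identical(as.data.frame(filter_peaks(out)), as.data.frame(out))
})

test_that("replicate consensus keeps 2-of-3 signals and averages intensity", {
  r1 <- mk_spec(c(200.0000, 300.0000), intensity = c(90, 50), replicate = 1)
  r2 <- mk_spec(c(200.00002, 400.0000), intensity = c(110, 70), replicate = 2)
  r3 <- mk_spec(c(500.0000), intensity = c(10), replicate = 3)
  cons <- replicate_consensus(list(r1, r2, r3), tol_ppm = 0.5)
  # 200 appears in 2/3 (66.7% > 66%): kept with mean intensity 100;
  # 300, 400, 500 are singletons: removed
  expect_equal(nrow(cons), 1)
  expect_equal(cons$intensity, 100)
  expect_equal(cons$presence_fraction, 2 / 3)

  # permutation invariance in replicate order
  cons2 <- replicate_consensus(list(r3, r1, r2), tol_ppm = 0.5)
  expect_equal(as.data.frame(cons), as.data.frame(cons2))

  # mixed channels are rejected
  r4 <- mk_spec(200, channel = "13CO")
  expect_error(replicate_consensus(list(r1, r4)), "mixed channels")
})

test_that("affine recalibration removes a synthetic linear distortion", {
  ref <- c(150.1, 250.2, 350.3, 450.4)
  distorted <- ref * (1 + 2e-7)
  sp <- mk_spec(distorted)
  cal <- data.frame(observed = distorted, reference = ref)
  out <- recalibrate(sp, cal)
  expect_lt(max(abs(attr(out, "residual_ppm"))), 0.01)
  expect_lt(max(abs(ppm_error(out$mz, ref))), 0.01)

  # perfect calibrants give the identity map
  out2 <- recalibrate(mk_spec(ref), data.frame(observed = ref, reference = ref))
  expect_equal(attr(out2, "coefficients"), c(a = 1, b = 0), tolerance = 1e-10)

  expect_error(recalibrate(sp, cal[1, , drop = FALSE]), "at least two")
})

test_that("34S filter removes abundance-compatible satellites only", {
  m <- 300
  # satellite at the natural single-sulfur expectation (0.0421 * 1000 = 42.1)
  sp <- mk_spec(c(m, m + delta_34s), intensity = c(1000, 42))
  out <- remove_34s_isotopes(sp)
  expect_equal(out$mz, m)
  expect_equal(attr(out, "removed")$intensity, 42)
  # intensity far above the natural band survives
  sp2 <- mk_spec(c(m, m + delta_34s), intensity = c(1000, 500))
  expect_equal(nrow(remove_34s_isotopes(sp2)), 2)
  # no sulfur-compatible partner: unchanged; and idempotent
  sp3 <- mk_spec(c(m, m + 1.5), intensity = c(1000, 42))
  expect_identical(peaks_of(remove_34s_isotopes(sp3)), peaks_of(sp3))
  expect_identical(peaks_of(remove_34s_isotopes(out)), peaks_of(out))
})

test_that("wiggle filter removes only close faint satellites", {
  sp <- mk_spec(c(300, 300.004, 300.05), intensity = c(10000, 50, 50))
  out <- remove_wiggle_artifacts(sp)
  # 0.5% satellite within the window removed; distant faint peak kept
  expect_equal(out$mz, c(300, 300.05))
  # 5% satellite is kept
  sp2 <- mk_spec(c(300, 300.004), intensity = c(10000, 500))
  expect_equal(nrow(remove_wiggle_artifacts(sp2)), 2)
  # isolated peak untouched, filter idempotent
  expect_identical(peaks_of(remove_wiggle_artifacts(out)), peaks_of(out))
})

test_that("feature alignment tracks per-timepoint intensities", {
  mk_cons <- function(mz, inten, tp) {
    structure(data.frame(mz = mz, intensity = inten,
                         sn = rep(10, length(mz)),
                         presence_fraction = rep(1, length(mz)),
                         n_replicates = rep(3L, length(mz))),
              timepoint = tp, channel = "unlabeled",
              class = c("consensus", "data.frame"))
  }
  cl <- list(mk_cons(c(200, 300), c(5, 7), 2),
             mk_cons(c(200.00002, 400), c(9, 4), 24))
  al <- align_features(cl, tol_ppm = 0.5)
  expect_equal(nrow(al$features), 3)
  i200 <- which(abs(al$features$mz - 200) < 0.01)
  expect_equal(al$intensity[i200, ], c(5, 9))
  expect_equal(al$features$first_detection[i200], 2)
  i400 <- which(al$features$mz == 400)
  expect_equal(al$features$first_detection[i400], 24)
})

test_that("consensus on noiseless dropout-free triplicates keeps exactly the rendered peaks", {
  cfg <- sim_config(mass_error_ppm_sd = 0, n_noise = 0, dropout = 0,
                    mixed_isomer_fraction = 0, seed = 21)
  m <- assign_temporal_profiles(simulate_reaction_network(cfg), cfg)
  reps <- lapply(1:3, function(k) render_spectra(m, cfg, "unlabeled", 24, k))
  cons <- replicate_consensus(reps, tol_ppm = 0.5)
  expect_equal(nrow(cons), nrow(reps[[1]]))
  expect_true(all(cons$presence_fraction == 1))
})
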