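# 13C labelling-degree classification and mixed-annotation statistics.

mk_cons_peaks <- function(mz, intensity, tp = 168) {
  structure(data.frame(mz = mz, intensity = intensity,
                       sn = rep(10, length(mz)),
                       presence_fraction = rep(1, length(mz)),
                       n_replicates = rep(3L, length(mz))),
            timepoint = tp, channel = "unlabeled",
            class = c("consensus", "data.frame"))
}

mk_ann <- function(formula) {
  ann <- cbind(data.frame(formula = formula), parse_formula(formula))
  ann$theo_mz <- ion_mz(ann[, c("c", "h", "o", "s", "na", "n13c")])
  ann
}

test_that("natural-abundance expectation follows the per-carbon rule", {
  expect_equal(expected_natural_fraction(10, 1), 0.10)
  expect_equal(expected_natural_fraction(5, 0), 1)
  expect_equal(expected_natural_fraction(10, 2),
               choose(10, 2) * 0.01^2 * 0.99^8, tolerance = 1e-12)
  expect_equal(expected_natural_fraction(10, 2), 0.00415, tolerance = 1e-3)
  expect_error(expected_natural_fraction(3, 4), "exceed")
})

test_that("the doubling rule calls a degree at twice the natural signal", {
  ann <- mk_ann("C5H8O3")
  unlab <- mk_cons_peaks(ann$theo_mz, 1000)
  # M+1 at 120 surpasses 2 * (0.01 * 5) * 1000 = 100
  lab <- mk_cons_peaks(c(ann$theo_mz, ann$theo_mz + delta_13c), c(10, 120))
  res <- classify_label_degrees(ann, unlab, lab, normalize = FALSE)
  expect_true(1 %in% res$degrees)
  # at 99 the same degree is not called
  lab2 <- mk_cons_peaks(c(ann$theo_mz, ann$theo_mz + delta_13c), c(10, 99))
  res2 <- classify_label_degrees(ann, unlab, lab2, normalize = FALSE)
  expect_false(1 %in% res2$degrees)
  # no labelled-channel peaks at any shift: empty degree set
  lab3 <- mk_cons_peaks(500, 100)
  res3 <- classify_label_degrees(ann, unlab, lab3, normalize = FALSE)
  expect_length(res3$degrees, 0)
  # missing unlabeled reference peak is an error
  expect_error(classify_label_degrees(ann, mk_cons_peaks(500, 1), lab),
               "reference peak absent")
})

test_that("degree calls are scale invariant and monotone in intensity", {
  ann <- mk_ann("C6H8O2")
  unlab <- mk_cons_peaks(ann$theo_mz, 800)
  lab <- mk_cons_peaks(ann$theo_mz + c(0, 1, 2) * delta_13c, c(8, 150, 500))
  base <- classify_label_degrees(ann, unlab, lab, normalize = FALSE)
  for (fct in c(0.01, 1, 250)) {
    unlab2 <- mk_cons_peaks(ann$theo_mz, 800 * fct)
    lab2 <- mk_cons_peaks(ann$theo_mz + c(0, 1, 2) * delta_13c,
                          c(8, 150, 500) * fct)
    expect_identical(
      classify_label_degrees(ann, unlab2, lab2, normalize = FALSE)$degrees,
      base$degrees)
  }
  # raising a labelled intensity never removes a called degree
  lab3 <- mk_cons_peaks(ann$theo_mz + c(0, 1, 2) * delta_13c, c(8, 400, 500))
  res3 <- classify_label_degrees(ann, unlab, lab3, normalize = FALSE)
  expect_true(all(base$degrees %in% res3$degrees))
})

test_that("binomial rule with satellite correction suppresses M+1 echoes", {
  # c = 10, fully labelled twice: the labelled species' own natural M+1
  # sits at degree 3 and must not be called
  ann <- mk_ann("C10H16O3")
  unlab <- mk_cons_peaks(ann$theo_mz, 1000)
  lab <- mk_cons_peaks(ann$theo_mz + c(2, 3) * delta_13c, c(1000, 88))
  res <- classify_label_degrees(ann, unlab, lab, threshold_rule = "binomial",
                                normalize = FALSE)
  expect_true(2 %in% res$degrees)
  expect_false(3 %in% res$degrees)
  # without the lower-degree call the same intensity would be a real signal
  lab2 <- mk_cons_peaks(ann$theo_mz + 3 * delta_13c, 88)
  res2 <- classify_label_degrees(ann, unlab, lab2,
                                 threshold_rule = "binomial",
                                 normalize = FALSE)
  expect_true(3 %in% res2$degrees)
})

test_that("mixed fractions count multi-degree annotations per subspace", {
  ann <- mk_ann(c("C4H6O2", "C6H8O2", "C5H8O2", "C8H10O2", "C10H12O2",
                  "C4H6O3", "C5H6O3", "C6H8O3", "C7H8O3", "C8H10O3"))
  ann$label_degrees <- c(list(c(1L, 2L), 1L, 1L, 0L, 2L),
                         list(1L, 1L, 2L, integer(), 2L))
  tab <- mixed_fraction(ann)
  o2 <- tab[tab$subspace == "O2S0", ]
  expect_equal(o2$n, 5)
  expect_equal(o2$pct_mixed, 20)
  expect_equal(o2$pct_pure, 80)
  o3 <- tab[tab$subspace == "O3S0", ]
  expect_equal(o3$n, 4)  # the uncalled annotation is excluded
  expect_equal(o3$pct_mixed, 0)
  expect_equal(o3$pct_mixed + o3$pct_pure, 100)
})

test_that("building-block closure accepts degree pairs summing to c", {
  expect_true(cross_channel_check(4, 0L, 4L))
  expect_true(cross_channel_check(4, 1L, 3L))
  expect_false(cross_channel_check(4, 1L, 1L))
  expect_false(cross_channel_check(4, integer(), 3L))
  expect_true(cross_channel_check(6, c(1L, 2L), c(3L, 4L)))
})

test_that("recovered mixed fraction tracks the generator's isomer fraction", {
  sim <- sim_config(mixed_isomer_fraction = 0.3, seed = 303)
  run <- run_pipeline(run_config(sim = sim, som_iterations = 2000,
                                 seed = 303))
  ev <- evaluate_recovery(run)
  expect_lte(abs(ev$mixed_recovered_pct - 30), 5)
})
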