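# Heteroatom subspaces, saturation by label degree, adduct logic, series.

mk_ann2 <- function(formula, degrees = NULL, na_adduct = FALSE) {
  ann <- cbind(data.frame(formula = formula), parse_formula(formula))
  if (!is.null(degrees)) ann$label_degrees <- degrees
  ann$na_adduct <- rep_len(na_adduct, nrow(ann))
  partition_subspaces(ann)
}

test_that("subspace partition is exhaustive, disjoint and sodium-blind", {
  ann <- mk_ann2(c("C5H8O3", "C2H4OS", "C4H6O4"))
  expect_identical(ann$subspace, c("O3S0", "O1S1", "O4S0"))
  run <- default_run()
  part <- run$annotations$subspace
  expect_identical(length(part), nrow(run$annotations))
  expect_identical(part, paste0("O", run$annotations$o, "S",
                                run$annotations$s))
})

test_that("mean H/C per degree averages mixed annotations into each degree", {
  ann <- mk_ann2(c("C5H6O3", "C5H8O3", "C10H12O3"),
                 degrees = list(1L, c(1L, 2L), 2L))
  tab <- mean_hc_by_degree(ann)
  expect_equal(tab$mean_hc[tab$degree == 1], mean(c(6 / 5, 8 / 5)))
  expect_equal(tab$mean_hc[tab$degree == 2], mean(c(8 / 5, 12 / 10)))
  expect_equal(tab$n, c(2L, 2L))
  # single member: mean equals its own ratio; empty degrees omitted
  tab2 <- mean_hc_by_degree(mk_ann2("C4H6O3", degrees = list(2L)))
  expect_equal(tab2$mean_hc, 1.5)
  expect_identical(nrow(mean_hc_by_degree(mk_ann2("C4H6O3",
                                                  degrees = list(integer())))),
                   0L)
})

test_that("CHO4 class rules map degree and adduct status to candidates", {
  ann <- mk_ann2(c("C4H6O4", "C5H8O4", "C6H8O4", "C7H10O4"),
                 degrees = list(2L, 2L, 1L, 3L),
                 na_adduct = c(TRUE, FALSE, FALSE, FALSE))
  cls <- na_adduct_classify(ann)
  expect_equal(cls$class[cls$formula == "C4H6O4"], "dicarboxylic-candidate")
  expect_equal(cls$class[cls$formula == "C5H8O4"], "hydroxy-keto-candidate")
  expect_equal(cls$class[cls$formula == "C6H8O4"], "dihydroxy-acid-candidate")
  expect_equal(cls$class[cls$formula == "C7H10O4"], "diketo-acid-candidate")
  expect_false(any(cls$rule_violation))
  # a single label with an adduct contradicts the dicarboxylic logic
  bad <- na_adduct_classify(mk_ann2("C6H8O4", degrees = list(1L),
                                    na_adduct = TRUE))
  expect_true(bad$rule_violation)
})

test_that("C2 homologous series are maximal chains within one degree", {
  ann <- mk_ann2(c("C4H6O2", "C6H8O2", "C8H10O2"), degrees = list(1L, 1L, 1L))
  ser <- detect_c2_series(ann)
  expect_equal(max(ser$series_id), 1)
  expect_equal(ser$length[1], 3)
  expect_identical(ser$formula, c("C4H6O2", "C6H8O2", "C8H10O2"))
  # single compound: no series
  expect_identical(nrow(detect_c2_series(mk_ann2("C4H6O2",
                                                 degrees = list(1L)))), 0L)
  # a gap breaks the chain
  ann2 <- mk_ann2(c("C4H6O2", "C8H10O2"), degrees = list(1L, 1L))
  expect_identical(nrow(detect_c2_series(ann2)), 0L)
  # different degrees never join a chain
  ann3 <- mk_ann2(c("C4H6O2", "C6H8O2"), degrees = list(1L, 2L))
  expect_identical(nrow(detect_c2_series(ann3)), 0L)
})

test_that("series members share the H-parity of repeated C2H2 addition", {
  run <- default_run()
  ser <- run$series
  if (!is.null(ser) && nrow(ser)) {
    for (sid in unique(ser$series_id)) {
      mem <- parse_formula(ser$formula[ser$series_id == sid])
      expect_true(all(diff(mem$c) == 2))
      expect_true(all(diff(mem$h) == 2))
      expect_true(all(diff(mem$o) == 0))
      expect_true(all(diff(mem$s) == 0))
    }
  }
})

test_that("series recovery matches the generator's acetylene lineages", {
  run <- noiseless_run()
  mol <- run$molecules
  ann <- run$annotations
  # ground-truth chains: molecule pairs differing by one C2H2 step
  key <- paste(mol$c, mol$h, mol$o, mol$s)
  succ <- paste(mol$c + 2, mol$h + 2, mol$o, mol$s)
  pair_in_truth <- succ %in% key
  # restrict to pairs whose both ends were annotated
  ann_key <- paste(ann$c, ann$h, ann$o, ann$s)
  both_ann <- pair_in_truth & (key %in% ann_key) &
    (succ %in% ann_key)
  if (any(both_ann)) {
    ser <- detect_c2_series(ann[, c("formula", "c", "h", "o", "s", "na",
                                    "n13c")])
    ser_steps <- 0L
    for (sid in unique(ser$series_id))
      ser_steps <- ser_steps + sum(ser$series_id == sid) - 1L
    expect_gte(ser_steps / sum(both_ann), 0.9)
  }
})
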