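# Classification of 13C labelling degrees by comparing the unlabeled channel
# against a 13C-labelled channel, and mixed/pure annotation statistics.

#' Expected natural-abundance isotopologue fraction
#'
#' Relative intensity (to the monoisotopic peak) expected from natural 13C
#' alone: the linear per-carbon rule `p * nC` for a single substitution,
#' `choose(nC, k) p^k (1-p)^(nC-k)` for k >= 2, and 1 for k = 0.
#'
#' @param nC Number of carbon atoms.
#' @param k Number of 13C substitutions (`0 <= k <= nC`).
#' @param p Natural 13C abundance per carbon (default 0.01, the 1%-per-carbon
#'   convention used for the labelling threshold).
#' @return Expected intensity ratio.
#' @export
expected_natural_fraction <- function(nC, k, p = 0.01) {
  stopifnot(length(nC) == 1, length(k) == 1)
  if (k > nC) stop("k cannot exceed the carbon count")
  if (k < 0) stop("k must be non-negative")
  if (k == 0) return(1)
  if (k == 1) return(p * nC)
  choose(nC, k) * p^k * (1 - p)^(nC - k)
}

# Locate the intensity of the peak nearest to `target` within tol_ppm in a
# consensus peak list (0 when absent).
intensity_at <- function(consensus, target, tol_ppm) {
  d <- abs(consensus$mz - target) / target * 1e6
  j <- which(d <= tol_ppm)
  if (!length(j)) return(0)
  consensus$intensity[j[which.min(d[j])]]
}

#' Classify the 13C labelling degree(s) of one annotation
#'
#' For each candidate degree k, the labelled channel is searched at
#' `theo_mz + k * 1.00336` u; the degree is called when the intensity
#' relative to the unlabeled monoisotopic peak is at least twice the
#' expected natural-abundance signal ("surpassed by 100%"). Two threshold
#' rules are available:
#'
#' * `"linear"` (default): the expectation is `p * nC` for every degree
#'   k >= 1, the per-carbon convention. Because it scales with the carbon
#'   count, it also absorbs the natural M+1 satellites and enrichment
#'   residuals that accompany a genuinely labelled isotopologue.
#' * `"binomial"`: the expectation is [expected_natural_fraction()] plus the
#'   natural satellites implied by all lower degrees already called
#'   (isotopologue-aware correction); without that correction the binomial
#'   expectation for k >= 2 is so small that the M+1 satellite of any
#'   labelled species would be miscalled as an extra degree.
#'
#' Degree 0 is called when the labelled channel retains the unshifted
#' monoisotopic peak above twice the residual-unlabeled expectation.
#' Intensities are referenced to the unlabeled channel's monoisotopic peak
#' after per-channel total-intensity normalization.
#'
#' @param annotation One-row annotation (element counts and `theo_mz`).
#' @param unlabeled,labelled Consensus peak lists ([replicate_consensus()])
#'   of the two channels.
#' @param tol_ppm Peak-match tolerance in ppm.
#' @param p Natural 13C abundance used in the threshold (default 0.01).
#' @param k_max Largest degree tested (default 6).
#' @param threshold_rule `"linear"` or `"binomial"`.
#' @param residual_unlabeled Expected residual unlabeled fraction in the
#'   labelled channel (isotopic impurity of the labelled gas), default 0.01.
#' @param normalize Normalize channels to equal total intensity first.
#' @return List with `degrees` (sorted integer vector of called degrees) and
#'   `table` (per-degree observed/expected ratios and pass flags).
#' @export
classify_label_degrees <- function(annotation, unlabeled, labelled,
                                   tol_ppm = 0.5, p = 0.01, k_max = 6,
                                   threshold_rule = c("linear", "binomial"),
                                   residual_unlabeled = 0.01,
                                   normalize = TRUE) {
  threshold_rule <- match.arg(threshold_rule)
  nC <- annotation$c
  mono <- annotation$theo_mz
  ref <- intensity_at(unlabeled, mono, tol_ppm)
  if (ref <= 0)
    stop("monoisotopic reference peak absent from the unlabeled channel: ",
         annotation$formula)
  scale <- if (normalize && sum(labelled$intensity) > 0)
    sum(unlabeled$intensity) / sum(labelled$intensity) else 1

  ks <- 0:min(nC, k_max)
  obs <- vapply(ks, function(k)
    intensity_at(labelled, mono + k * delta_13c, tol_ppm) * scale / ref, 0)
  expected <- numeric(length(ks))
  passed <- logical(length(ks))
  called <- integer()
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (k == 0) {
      expected[i] <- residual_unlabeled
    } else if (threshold_rule == "linear") {
      expected[i] <- p * nC
    } else {
      sat <- 0
      for (j in called[called < k])
        sat <- sat + obs[ks == j] * expected_natural_fraction(nC - j, k - j, p)
      expected[i] <- expected_natural_fraction(nC, k, p) + sat
    }
    passed[i] <- obs[i] >= 2 * expected[i]
    if (passed[i]) called <- c(called, k)
  }
  list(degrees = called,
       table = data.frame(k = ks, observed = obs, expected = expected,
                          passed = passed))
}

#' Classify labelling degrees for a whole annotation table
#'
#' Applies [classify_label_degrees()] to every annotation, skipping (with an
#' empty degree set) annotations whose monoisotopic reference peak is absent
#' from the unlabeled channel.
#'
#' @param annotations Annotation data frame.
#' @param unlabeled,labelled Consensus peak lists, or lists of them (one per
#'   timepoint) together with `best_tp` giving the list index to use per
#'   annotation.
#' @param best_tp Optional integer vector: which element of
#'   `unlabeled`/`labelled` to compare for each annotation (the annotation's
#'   most intense timepoint). When `NULL`, single consensus objects are
#'   expected.
#' @param ... Passed to [classify_label_degrees()].
#' @return `annotations` with a list-column `label_degrees`.
#' @export
label_annotations <- function(annotations, unlabeled, labelled,
                              best_tp = NULL, ...) {
  degrees <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    ul <- if (is.null(best_tp)) unlabeled else unlabeled[[best_tp[i]]]
    lb <- if (is.null(best_tp)) labelled else labelled[[best_tp[i]]]
    res <- tryCatch(
      classify_label_degrees(annotations[i, , drop = FALSE], ul, lb, ...),
      error = function(e) list(degrees = integer()))
    degrees[[i]] <- res$degrees
  }
  annotations$label_degrees <- degrees
  annotations
}

#' Mixed vs pure annotation fractions per heteroatom subspace
#'
#' An annotation is mixed when it was called at two or more labelling
#' degrees (co-eluting isomers with different synthesis histories).
#' Percentages are over the annotations of each (O, S) subspace that
#' received at least one degree call, and sum to 100 per subspace.
#'
#' @param annotations Annotation data frame with list-column `label_degrees`
#'   (and element counts).
#' @return Data frame: `subspace`, `o`, `s`, `n`, `pct_mixed`, `pct_pure`.
#' @export
mixed_fraction <- function(annotations) {
  called <- lengths(annotations$label_degrees) > 0
  ann <- annotations[called, , drop = FALSE]
  if (!nrow(ann)) {
    return(data.frame(subspace = character(), o = integer(), s = integer(),
                      n = integer(), pct_mixed = numeric(),
                      pct_pure = numeric()))
  }
  key <- paste0("O", ann$o, "S", ann$s)
  mixed <- lengths(ann$label_degrees) >= 2
  agg <- do.call(rbind, lapply(split(seq_len(nrow(ann)), key), function(ii) {
    data.frame(subspace = key[ii[1]], o = ann$o[ii[1]], s = ann$s[ii[1]],
               n = length(ii),
               pct_mixed = 100 * mean(mixed[ii]),
               pct_pure = 100 * mean(!mixed[ii]))
  }))
  agg <- agg[order(agg$s, agg$o), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Cross-channel building-block closure check
#'
#' A composition whose called CO-label degree k and acetylene-label degree
#' k' satisfy k + k' = c is confirmed to be built exclusively from CO and
#' acetylene carbons.
#'
#' @param c_count Carbon count of the composition.
#' @param co_degrees Degrees called against the 13CO channel.
#' @param acetylene_degrees Degrees called against the 13C-acetylene channel.
#' @return `TRUE` when some pair of called degrees sums to the carbon count.
#' @export
cross_channel_check <- function(c_count, co_degrees, acetylene_degrees) {
  if (!length(co_degrees) || !length(acetylene_degrees)) return(FALSE)
  any(outer(co_degrees, acetylene_degrees, `+`) == c_count)
}
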