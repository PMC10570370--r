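# Peak-level filters, replicate consensus, recalibration and the two
# artifact filters applied before formula assignment.

#' Signal-to-noise and mass-range filter
#'
#' Retains peaks with `sn >= sn_min` (boundary kept) inside the closed m/z
#' interval `mz_range`. Idempotent; an empty result is not an error.
#'
#' @param spec A [new_spectrum()].
#' @param sn_min Minimum signal-to-noise ratio (default 4).
#' @param mz_range Closed m/z interval, default `c(122, 1000)`.
#' @return Filtered `spectrum`.
#' @export
filter_peaks <- function(spec, sn_min = 4, mz_range = c(122, 1000)) {
  keep <- spec$sn >= sn_min & spec$mz >= mz_range[1] & spec$mz <= mz_range[2]
  rebuild_spectrum(as.data.frame(spec)[keep, , drop = FALSE], spec)
}

# Single-linkage grouping of sorted m/z values: a new group starts where the
# gap to the previous value exceeds tol_ppm. Input must be sorted.
group_mz <- function(mz, tol_ppm) {
  if (!length(mz)) return(integer())
  gap <- diff(mz) / mz[-length(mz)] * 1e6
  cumsum(c(1L, as.integer(gap > tol_ppm)))
}

#' Replicate consensus peak list
#'
#' Aligns the peaks of technical replicates by single-linkage grouping on
#' sorted m/z within `tol_ppm` and retains groups present in more than
#' `min_fraction` of the replicates (strictly greater, so 2 of 3 replicates
#' pass the default 0.66). Group m/z is the median, intensity the mean over
#' the replicates in which the group was observed.
#'
#' @param specs List of >= 2 [new_spectrum()] objects from one timepoint and
#'   channel (mixed channels or timepoints are an error).
#' @param tol_ppm Alignment tolerance in ppm.
#' @param min_fraction Presence-fraction threshold (exclusive).
#' @return Data frame of class `consensus` with columns `mz`, `intensity`,
#'   `sn`, `presence_fraction`, `n_replicates`, and attributes `timepoint`
#'   and `channel`.
#' @export
replicate_consensus <- function(specs, tol_ppm = 0.5, min_fraction = 0.66) {
  stopifnot(length(specs) >= 2)
  meta <- lapply(specs, spectrum_meta)
  if (length(unique(vapply(meta, `[[`, "", "channel"))) != 1)
    stop("replicates of mixed channels cannot form a consensus")
  if (length(unique(vapply(meta, function(m) as.numeric(m$timepoint), 0))) != 1)
    stop("replicates of mixed timepoints cannot form a consensus")
  n_rep <- length(specs)
  pooled <- do.call(rbind, lapply(seq_along(specs), function(i) {
    df <- as.data.frame(specs[[i]])[c("mz", "intensity", "sn")]
    if (nrow(df)) df$rep <- i
    else df$rep <- integer()
    df
  }))
  empty <- data.frame(mz = numeric(), intensity = numeric(), sn = numeric(),
                      presence_fraction = numeric(), n_replicates = integer())
  if (is.null(pooled) || !nrow(pooled)) {
    return(structure(empty, timepoint = meta[[1]]$timepoint,
                     channel = meta[[1]]$channel,
                     class = c("consensus", "data.frame")))
  }
  pooled <- pooled[order(pooled$mz), , drop = FALSE]
  grp <- group_mz(pooled$mz, tol_ppm)
  out <- do.call(rbind, lapply(split(pooled, grp), function(g) {
    # a replicate contributing several peaks to one group counts once,
    # with its intensities summed
    per_rep <- tapply(g$intensity, g$rep, sum)
    data.frame(mz = stats::median(g$mz),
               intensity = mean(per_rep),
               sn = mean(g$sn),
               presence_fraction = length(per_rep) / n_rep,
               n_replicates = length(per_rep))
  }))
  out <- out[out$presence_fraction > min_fraction, , drop = FALSE]
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, timepoint = meta[[1]]$timepoint, channel = meta[[1]]$channel,
            class = c("consensus", "data.frame"))
}

#' Affine post-acquisition mass recalibration
#'
#' Fits the least-squares affine correction `mz' = a * mz + b` on a
#' calibration list of (observed, reference) pairs and applies it to every
#' peak. Residual calibrant errors (ppm) after correction are attached as
#' attribute `"residual_ppm"`.
#'
#' @param spec A [new_spectrum()].
#' @param calibrants Data frame with columns `observed` and `reference`
#'   (>= 2 rows).
#' @return Recalibrated `spectrum`.
#' @export
recalibrate <- function(spec, calibrants) {
  stopifnot(is.data.frame(calibrants),
            all(c("observed", "reference") %in% names(calibrants)))
  if (nrow(calibrants) < 2)
    stop("recalibration requires at least two calibrant pairs")
  fit <- stats::lm(reference ~ observed, data = calibrants)
  ab <- stats::coef(fit)
  corrected <- as.data.frame(spec)
  corrected$mz <- ab[2] * corrected$mz + ab[1]
  out <- rebuild_spectrum(corrected, spec)
  fitted_cal <- ab[2] * calibrants$observed + ab[1]
  attr(out, "residual_ppm") <- ppm_error(fitted_cal, calibrants$reference)
  attr(out, "coefficients") <- c(a = unname(ab[2]), b = unname(ab[1]))
  out
}

#' Remove natural 34S isotopologue peaks
#'
#' Heuristic reconstruction of an in-house isotope filter: a peak is removed
#' when it lies +1.99580 u (the 34S-32S mass shift) above a more intense
#' peak and its intensity relative to that parent is compatible with a
#' natural 34S isotopologue, i.e. within `band` times `p34 * s` for some
#' sulfur count `s` in `1..s_max`. Removed peaks are attached as attribute
#' `"removed"` for audit. Idempotent.
#'
#' @param spec A [new_spectrum()].
#' @param tol_ppm Match tolerance on the isotopologue spacing (ppm).
#' @param p34 Natural 34S abundance per sulfur (default 0.0421).
#' @param band Acceptance band around the expected relative intensity.
#' @param s_max Largest sulfur count considered.
#' @return Filtered `spectrum`.
#' @export
remove_34s_isotopes <- function(spec, tol_ppm = 1, p34 = 0.0421,
                                band = c(0.3, 3), s_max = 2) {
  df <- as.data.frame(spec)
  if (nrow(df) < 2) return(spec)
  drop <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    target <- df$mz[i] - delta_34s
    j <- which(abs(df$mz - target) / df$mz * 1e6 <= tol_ppm &
                 df$intensity > df$intensity[i])
    if (!length(j)) next
    ratio <- df$intensity[i] / max(df$intensity[j])
    expected <- p34 * seq_len(s_max)
    if (any(ratio / expected >= band[1] & ratio / expected <= band[2]))
      drop[i] <- TRUE
  }
  out <- rebuild_spectrum(df[!drop, , drop = FALSE], spec)
  attr(out, "removed") <- df[drop, , drop = FALSE]
  out
}

#' Remove wiggle (sidelobe) artifact peaks
#'
#' Heuristic reconstruction of an in-house artifact filter: removes
#' low-intensity satellites sitting within `window_u` of a dominant peak
#' when the dominant peak is at least `min_fold` times more intense and the
#' satellite is below `rel_max` of it. Removed peaks are attached as
#' attribute `"removed"`. Idempotent.
#'
#' @param spec A [new_spectrum()].
#' @param window_u Half-window in u (default 0.01).
#' @param rel_max Maximum relative intensity of a satellite (default 1%).
#' @param min_fold Minimum intensity fold of the dominant peak (default 50).
#' @return Filtered `spectrum`.
#' @export
remove_wiggle_artifacts <- function(spec, window_u = 0.01, rel_max = 0.01,
                                    min_fold = 50) {
  df <- as.data.frame(spec)
  if (nrow(df) < 2) return(spec)
  drop <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    near <- which(abs(df$mz - df$mz[i]) <= window_u)
    near <- setdiff(near, i)
    if (!length(near)) next
    big <- max(df$intensity[near])
    if (big >= min_fold * df$intensity[i] &&
        df$intensity[i] < rel_max * big)
      drop[i] <- TRUE
  }
  out <- rebuild_spectrum(df[!drop, , drop = FALSE], spec)
  attr(out, "removed") <- df[drop, , drop = FALSE]
  out
}

#' Align consensus peak lists across timepoints into features
#'
#' Pools the consensus peaks of all timepoints of one channel, groups them by
#' single-linkage within `tol_ppm`, and returns one feature per group with
#' its per-timepoint intensities (0 where undetected).
#'
#' @param consensus_list List of [replicate_consensus()] results, one per
#'   timepoint (same channel).
#' @param tol_ppm Alignment tolerance in ppm.
#' @return List with `features` (data frame: `feature_id`, `mz`,
#'   `n_timepoints`, `first_detection`, `max_intensity`), `intensity`
#'   (features x timepoints matrix), `detected` (logical matrix) and
#'   `timepoints`.
#' @export
align_features <- function(consensus_list, tol_ppm = 0.5) {
  tps <- unname(vapply(consensus_list,
                       function(x) as.numeric(attr(x, "timepoint")), 0))
  ord <- order(tps)
  consensus_list <- consensus_list[ord]
  tps <- tps[ord]
  pooled <- do.call(rbind, lapply(seq_along(consensus_list), function(i) {
    df <- as.data.frame(consensus_list[[i]])[c("mz", "intensity")]
    df$tp_idx <- rep(i, nrow(df))
    df
  }))
  if (is.null(pooled) || !nrow(pooled)) {
    return(list(features = data.frame(feature_id = integer(), mz = numeric(),
                                      n_timepoints = integer(),
                                      first_detection = numeric(),
                                      max_intensity = numeric()),
                intensity = matrix(0, 0, length(tps)),
                detected = matrix(FALSE, 0, length(tps)),
                timepoints = tps))
  }
  pooled <- pooled[order(pooled$mz), , drop = FALSE]
  grp <- group_mz(pooled$mz, tol_ppm)
  ng <- max(grp)
  mz <- as.numeric(tapply(pooled$mz, grp, stats::median))
  inten <- matrix(0, ng, length(tps))
  for (r in seq_len(nrow(pooled)))
    inten[grp[r], pooled$tp_idx[r]] <- inten[grp[r], pooled$tp_idx[r]] +
      pooled$intensity[r]
  detected <- inten > 0
  features <- data.frame(
    feature_id = seq_len(ng),
    mz = mz,
    n_timepoints = rowSums(detected),
    first_detection = tps[apply(detected, 1, which.max)],
    max_intensity = apply(inten, 1, max)
  )
  list(features = features, intensity = inten, detected = detected,
       timepoints = tps)
}
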