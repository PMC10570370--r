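# Elemental-formula assignment: brute-force enumeration (the oracle) and
# mass-difference-network propagation (the method), plus the elemental-ratio
# filters and sodium-adduct detection.

#' Default element-count bounds for formula enumeration
#' @export
default_bounds <- function() list(c = 40L, h = 80L, o = 10L, s = 5L, na = 1L)

# Apply the H/C and O/C annotation filters to a composition data frame,
# returning a logical keep vector.
ratio_keep <- function(x, hc_range = c(0.5, 2.5), oc_max = 1.5) {
  hc <- x$h / x$c
  oc <- x$o / x$c
  x$c > 0 & hc >= hc_range[1] & hc <= hc_range[2] & oc < oc_max
}

#' Brute-force formula assignment (enumeration oracle)
#'
#' Exhaustively enumerates CHOS compositions within the element bounds whose
#' ion m/z lies within `tol_ppm` of the observed value, sorted by absolute
#' mass error (ties: fewer heteroatoms, then formula string). Serves as the
#' independent reference against which the network assignment is validated.
#'
#' @param mz Observed m/z (single value, charge -1).
#' @param ion Ion type, see [ion_mz()].
#' @param tol_ppm Mass tolerance in ppm.
#' @param bounds Maximum element counts, see [default_bounds()].
#' @param ratio_filter If `TRUE`, apply the H/C in \[0.5, 2.5\] and O/C < 1.5
#'   pre-filters to the candidates.
#' @return Data frame of candidate compositions with `formula`, element
#'   counts, `theo_mz` and `error_ppm`; zero rows when nothing matches.
#' @export
brute_force_assign <- function(mz, ion = "deprotonated", tol_ppm = 0.5,
                               bounds = default_bounds(),
                               ratio_filter = FALSE) {
  stopifnot(length(mz) == 1, mz > 0)
  grid <- expand.grid(c = seq_len(bounds$c), o = 0:bounds$o, s = 0:bounds$s,
                      KEEP.OUT.ATTRS = FALSE)
  # neutral monoisotopic mass implied by the observed ion m/z
  m_target <- if (ion == "deprotonated") {
    mz + atomic_masses[["proton"]]
  } else {
    mz + 2 * atomic_masses[["proton"]] -
      (atomic_masses[["Na23"]] - atomic_masses[["electron"]])
  }
  rem <- m_target - grid$c * atomic_masses[["C12"]] -
    grid$o * atomic_masses[["O16"]] - grid$s * atomic_masses[["S32"]]
  h <- round(rem / atomic_masses[["H1"]])
  min_h <- if (ion == "deprotonated") 1L else 2L
  ok <- h >= min_h & h <= bounds$h
  grid <- grid[ok, , drop = FALSE]
  grid$h <- as.integer(h[ok])
  grid$na <- 0L
  grid$n13c <- 0L
  grid <- grid[c("c", "h", "o", "s", "na", "n13c")]
  theo <- ion_mz(grid, ion)
  err <- ppm_error(mz, theo)
  keep <- abs(err) <= tol_ppm
  grid <- grid[keep, , drop = FALSE]
  theo <- theo[keep]
  err <- err[keep]
  if (ratio_filter && nrow(grid)) {
    keep <- ratio_keep(grid)
    grid <- grid[keep, , drop = FALSE]
    theo <- theo[keep]
    err <- err[keep]
  }
  out <- cbind(data.frame(formula = format_formula(grid),
                          stringsAsFactors = FALSE), grid)
  out$theo_mz <- theo
  out$error_ppm <- err
  het <- out$o + out$s + out$na
  out <- out[order(abs(out$error_ppm), het, out$formula), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select seed annotations from the low-mass end of a peak list
#'
#' The lowest-mass confidently assignable peaks: every peak with
#' `mz <= mz_max` whose brute-force enumeration (with ratio filters) yields
#' exactly one candidate becomes a seed.
#'
#' @param peaks Data frame with a column `mz`.
#' @param tol_ppm Mass tolerance in ppm.
#' @param mz_max Upper m/z limit for seed candidates (default 200).
#' @param bounds Element-count bounds.
#' @return Annotation data frame (columns as [mdn_assign()] seeds expect):
#'   `mz`, `formula`, element counts, `theo_mz`, `error_ppm`, `source`.
#' @export
select_seed_annotations <- function(peaks, tol_ppm = 0.5, mz_max = 200,
                                    bounds = default_bounds()) {
  idx <- which(peaks$mz <= mz_max)
  out <- list()
  for (i in idx) {
    cand <- brute_force_assign(peaks$mz[i], "deprotonated", tol_ppm, bounds,
                               ratio_filter = TRUE)
    if (nrow(cand) == 1) {
      row <- cbind(data.frame(mz = peaks$mz[i]), cand)
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) {
    res <- data.frame(mz = numeric(), formula = character(), c = integer(),
                      h = integer(), o = integer(), s = integer(),
                      na = integer(), n13c = integer(), theo_mz = numeric(),
                      error_ppm = numeric())
  } else {
    res <- do.call(rbind, out)
  }
  res$source <- rep("seed-match", nrow(res))
  rownames(res) <- NULL
  res
}

#' Mass-difference-network formula assignment
#'
#' Breadth-first propagation of verified seed formulas across the reaction
#' mass differences: for every assigned peak and every transformation (both
#' directions), an unassigned peak within `tol_ppm` of the predicted m/z
#' receives the composition shifted by the transformation delta, provided
#' element counts stay valid and (optionally) the elemental-ratio filters
#' pass. Predicted m/z values are computed from the assigned composition
#' (not the observed peak), so mass errors do not accumulate along chains.
#' Conflicting assignments are resolved in favor of the smaller absolute
#' mass error; ties by fewer heteroatoms, then formula string. Every
#' assignment records its propagation path.
#'
#' @param peaks Data frame with column `mz` (one row per peak).
#' @param seeds Seed annotations: data frame with element-count columns and
#'   a formula or m/z binding; each seed's ion m/z must match a peak within
#'   `tol_ppm`, otherwise an error is raised.
#' @param trans Transformation table, see [transformations()].
#' @param tol_ppm Mass tolerance in ppm.
#' @param ratio_filter Apply H/C and O/C filters during propagation.
#' @return Annotation data frame: `peak_id`, `mz`, `formula`, element
#'   counts, `theo_mz`, `error_ppm`, `source` (`"seed-match"` or
#'   `"propagated"`), `path` (semicolon-joined transformation steps from the
#'   seed).
#' @export
mdn_assign <- function(peaks, seeds, trans = transformations(),
                       tol_ppm = 0.5, ratio_filter = TRUE) {
  n <- nrow(peaks)
  ord <- order(peaks$mz)
  mz_sorted <- peaks$mz[ord]

  if (!nrow(seeds)) stop("at least one seed annotation is required")
  seed_comps <- seeds[.comp_cols]
  seed_theo <- ion_mz(seed_comps, "deprotonated")

  # assignment state, indexed by position in the sorted peak vector
  comp_mat <- matrix(NA_integer_, n, 6, dimnames = list(NULL, .comp_cols))
  err <- rep(NA_real_, n)
  theo <- rep(NA_real_, n)
  src <- rep(NA_character_, n)
  path <- rep(NA_character_, n)

  find_peaks <- function(target) {
    tol <- target * tol_ppm * 1e-6
    lo <- findInterval(target - tol, mz_sorted) + 1L
    hi <- findInterval(target + tol, mz_sorted)
    if (lo > hi) integer() else lo:hi
  }

  heteroatoms <- function(v) v["o"] + v["s"] + v["na"]

  queue <- integer()
  for (k in seq_len(nrow(seeds))) {
    hits <- find_peaks(seed_theo[k])
    if (!length(hits))
      stop("seed peak absent from peak list: ", format_formula(seed_comps[k, ]))
    j <- hits[which.min(abs(mz_sorted[hits] - seed_theo[k]))]
    e <- ppm_error(mz_sorted[j], seed_theo[k])
    if (!is.na(err[j]) && abs(err[j]) <= abs(e)) next
    comp_mat[j, ] <- as.integer(seed_comps[k, ])
    err[j] <- e
    theo[j] <- seed_theo[k]
    src[j] <- "seed-match"
    path[j] <- format_formula(seed_comps[k, ])
    queue <- c(queue, j)
  }

  tr_delta <- as.matrix(trans[.comp_cols])
  tr_mass <- trans$delta_mass
  tr_name <- trans$name

  while (length(queue)) {
    j <- queue[1]
    queue <- queue[-1]
    base_comp <- comp_mat[j, ]
    base_theo <- theo[j]
    if (is.na(base_theo)) next
    for (t in seq_along(tr_name)) {
      for (sign in c(1L, -1L)) {
        cand <- base_comp + sign * tr_delta[t, ]
        if (any(cand < 0) || cand["c"] < 1 || cand["h"] < 1) next
        if (ratio_filter) {
          hc <- cand["h"] / cand["c"]
          oc <- cand["o"] / cand["c"]
          if (hc < 0.5 || hc > 2.5 || oc >= 1.5) next
        }
        cand_theo <- base_theo + sign * tr_mass[t]
        hits <- find_peaks(cand_theo)
        if (!length(hits)) next
        step <- paste0(if (sign > 0) "+" else "-", tr_name[t])
        for (p in hits) {
          e <- ppm_error(mz_sorted[p], cand_theo)
          if (!is.na(err[p])) {
            if (abs(err[p]) < abs(e) - 1e-12) next
            if (abs(abs(err[p]) - abs(e)) <= 1e-12) {
              # deterministic tie-break: fewer heteroatoms, then formula
              old_h <- heteroatoms(comp_mat[p, ])
              new_h <- heteroatoms(cand)
              if (old_h < new_h) next
              if (old_h == new_h) {
                oldf <- format_formula(as.data.frame(t(comp_mat[p, ])))
                newf <- format_formula(as.data.frame(t(cand)))
                if (oldf <= newf) next
              }
            }
            if (identical(unname(comp_mat[p, ]), unname(cand))) next
          }
          comp_mat[p, ] <- cand
          err[p] <- e
          theo[p] <- cand_theo
          src[p] <- "propagated"
          path[p] <- paste(path[j], step, sep = ";")
          queue <- c(queue, p)
        }
      }
    }
  }

  assigned <- which(!is.na(err))
  if (!length(assigned)) {
    return(data.frame(peak_id = integer(), mz = numeric(),
                      formula = character(), c = integer(), h = integer(),
                      o = integer(), s = integer(), na = integer(),
                      n13c = integer(), theo_mz = numeric(),
                      error_ppm = numeric(), source = character(),
                      path = character()))
  }
  cdf <- as.data.frame(comp_mat[assigned, , drop = FALSE])
  out <- cbind(data.frame(peak_id = ord[assigned], mz = mz_sorted[assigned]),
               data.frame(formula = format_formula(cdf),
                          stringsAsFactors = FALSE),
               cdf)
  out$theo_mz <- theo[assigned]
  out$error_ppm <- err[assigned]
  out$source <- src[assigned]
  out$path <- path[assigned]
  out <- out[order(out$peak_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Elemental-ratio annotation filter
#'
#' Retains annotations with H/C between 0.5 and 2.5 (inclusive) and
#' O/C strictly below 1.5.
#'
#' @param annotations Annotation data frame with element-count columns.
#' @param hc_range Closed H/C interval.
#' @param oc_max Exclusive O/C upper bound.
#' @return Filtered annotation data frame.
#' @export
filter_annotations <- function(annotations, hc_range = c(0.5, 2.5),
                               oc_max = 1.5) {
  out <- annotations[ratio_keep(annotations, hc_range, oc_max), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect sodium-adduct companion peaks
#'
#' For every annotation with at least two hydrogens, searches the peak list
#' for its \[M-2H+Na\]- companion within `tol_ppm` and flags the annotation.
#' Adducts are evidence attached to the neutral composition, not separate
#' annotations.
#'
#' @param annotations Annotation data frame.
#' @param peaks Data frame with columns `mz` (and optionally intensity).
#' @param tol_ppm Mass tolerance in ppm.
#' @return `annotations` with logical column `na_adduct` and the matched
#'   companion m/z in `na_adduct_mz` (NA when absent).
#' @export
detect_na_adducts <- function(annotations, peaks, tol_ppm = 0.5) {
  mz_sorted <- sort(peaks$mz)
  annotations$na_adduct <- FALSE
  annotations$na_adduct_mz <- NA_real_
  ok <- annotations$h >= 2
  if (any(ok)) {
    theo <- ion_mz(annotations[ok, .comp_cols], "sodiated-deprotonated")
    rows <- which(ok)
    for (i in seq_along(rows)) {
      tol <- theo[i] * tol_ppm * 1e-6
      lo <- findInterval(theo[i] - tol, mz_sorted) + 1L
      hi <- findInterval(theo[i] + tol, mz_sorted)
      if (lo <= hi) {
        annotations$na_adduct[rows[i]] <- TRUE
        hits <- mz_sorted[lo:hi]
        annotations$na_adduct_mz[rows[i]] <-
          hits[which.min(abs(hits - theo[i]))]
      }
    }
  }
  annotations
}

#' Flag isotopologue features in an aligned feature table
#'
#' Features sitting one 13C shift (+1.00336 u) above a co-detected feature
#' of more than twice their intensity, or one 34S shift (+1.99580 u) above a
#' co-detected feature of more than three times their intensity, are
#' isotopologue satellites of that feature rather than independent
#' compounds, and are excluded from formula assignment.
#'
#' @param features Feature data frame with columns `mz` and `max_intensity`.
#' @param tol_ppm Match tolerance in ppm.
#' @return Logical vector, `TRUE` for satellite features.
#' @export
flag_isotopologue_features <- function(features, tol_ppm = 1) {
  mz <- features$mz
  inten <- features$max_intensity
  flag <- logical(length(mz))
  for (i in seq_along(mz)) {
    for (shift in c(delta_13c, delta_34s)) {
      fold <- if (shift == delta_13c) 2 else 3
      j <- which(abs(mz - (mz[i] - shift)) / mz * 1e6 <= tol_ppm &
                   inten > fold * inten[i])
      if (length(j)) { flag[i] <- TRUE; break }
    }
  }
  flag
}
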