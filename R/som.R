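# Self-organizing-map clustering of temporal intensity profiles on a 2 x 4
# rectangular grid, plus cluster peak-time summaries.

#' Min-max scale temporal profiles
#'
#' Per-profile rescaling to \[0, 1\]: `(x - min) / (max - min)`; constant
#' profiles map to all zeros.
#'
#' @param x Numeric matrix, one profile per row.
#' @return Matrix of the same shape with rows in \[0, 1\].
#' @export
scale_profiles <- function(x) {
  x <- as.matrix(x)
  t(apply(x, 1, function(r) {
    rng <- max(r) - min(r)
    if (rng == 0) rep(0, length(r)) else (r - min(r)) / rng
  }))
}

#' Train an online self-organizing map
#'
#' Classic online SOM on a rectangular grid with a Gaussian neighborhood and
#' Euclidean best-matching-unit selection: at each iteration one profile is
#' drawn at random, its best-matching unit found, and all unit weights moved
#' toward it with a strength that decays with grid distance to the winner.
#' Learning rate and neighborhood radius decay linearly over the iterations.
#' Weights initialize uniformly in \[0, 1\] (the scaled data lie in the unit
#' cube). Deterministic given the seed.
#'
#' @param x Matrix of scaled profiles (rows), see [scale_profiles()].
#' @param grid Grid dimensions, default `c(2, 4)` (8 units).
#' @param lr Initial learning rate (default 0.1).
#' @param sigma Initial neighborhood radius in grid units (default 1.0).
#' @param iterations Training iterations (default 50000).
#' @param seed Integer seed for weight initialization and sampling.
#' @param lr_final,sigma_final Linear-decay end values.
#' @return Object of class `som_fit`: `weights` (units x variables), `grid`,
#'   `unit_coords`, `assignment` (best unit per profile), `centers` (mean
#'   scaled profile per occupied unit), `counts`, `quantization_error`, and
#'   the training parameters.
#' @export
train_som <- function(x, grid = c(2, 4), lr = 0.1, sigma = 1.0,
                      iterations = 50000, seed = 1L,
                      lr_final = 0.01, sigma_final = 0.01) {
  x <- as.matrix(x)
  if (!nrow(x)) stop("cannot train a SOM on zero profiles")
  n <- nrow(x); d <- ncol(x)
  n_units <- prod(grid)
  coords <- as.matrix(expand.grid(row = seq_len(grid[1]), col = seq_len(grid[2])))
  grid_d2 <- as.matrix(stats::dist(coords))^2

  with_seed(seed, {
    w <- matrix(stats::runif(n_units * d), n_units, d)
    pick <- sample.int(n, iterations, replace = TRUE)
    frac <- (seq_len(iterations) - 1) / max(iterations - 1, 1)
    lrs <- lr + (lr_final - lr) * frac
    sigmas <- sigma + (sigma_final - sigma) * frac
    for (it in seq_len(iterations)) {
      xi <- x[pick[it], ]
      diffs <- sweep(w, 2, xi)
      bmu <- which.min(rowSums(diffs * diffs))
      h <- lrs[it] * exp(-grid_d2[bmu, ] / (2 * sigmas[it]^2))
      w <- w - h * diffs
    }
  })

  d2 <- outer(rowSums(x^2), rowSums(w^2), `+`) - 2 * x %*% t(w)
  assignment <- max.col(-d2, ties.method = "first")
  qe <- mean(sqrt(pmax(d2[cbind(seq_len(n), assignment)], 0)))
  centers <- matrix(NA_real_, n_units, d)
  for (u in unique(assignment))
    centers[u, ] <- colMeans(x[assignment == u, , drop = FALSE])
  counts <- tabulate(assignment, n_units)
  structure(list(weights = w, grid = grid, unit_coords = coords,
                 assignment = assignment, centers = centers, counts = counts,
                 quantization_error = qe,
                 params = list(lr = lr, sigma = sigma, iterations = iterations,
                               seed = seed, lr_final = lr_final,
                               sigma_final = sigma_final)),
            class = "som_fit")
}

#' @export
print.som_fit <- function(x, ...) {
  cat(sprintf("SOM fit: %d x %d grid, %d profiles, %d occupied units\n",
              x$grid[1], x$grid[2], length(x$assignment), sum(x$counts > 0)))
  cat(sprintf("quantization error: %.4f\n", x$quantization_error))
  invisible(x)
}

#' Number of occupied SOM clusters
#' @param fit A [train_som()] fit.
#' @return Count of grid units with at least one assigned profile.
#' @export
n_occupied_clusters <- function(fit) sum(fit$counts > 0)

#' Peak time of a profile
#'
#' The timepoint at which the (scaled) profile is maximal; ties resolve to
#' the earliest timepoint. All-zero profiles have no peak and return `NA`.
#'
#' @param profile Numeric vector.
#' @param timepoints Timepoints in hours, same length.
#' @return Timepoint of the maximum, or `NA` for an all-zero profile.
#' @export
peak_time <- function(profile, timepoints) {
  stopifnot(length(profile) == length(timepoints))
  if (all(profile == 0) || all(is.na(profile))) return(NA_real_)
  timepoints[which.max(profile)]
}

#' Cluster summary table of a SOM fit
#'
#' @param fit A [train_som()] fit.
#' @param timepoints Timepoints (hours) of the profile grid.
#' @return Data frame: `unit`, `row`, `col`, `n`, `peak_time` (of the
#'   cluster center; NA for empty units).
#' @export
som_cluster_table <- function(fit, timepoints) {
  data.frame(unit = seq_len(prod(fit$grid)),
             row = fit$unit_coords[, "row"],
             col = fit$unit_coords[, "col"],
             n = fit$counts,
             peak_time = vapply(seq_len(prod(fit$grid)), function(u) {
               if (fit$counts[u] == 0) return(NA_real_)
               peak_time(fit$centers[u, ], timepoints)
             }, 0))
}

#' Per-subspace distribution of cluster peak times
#'
#' For every heteroatom subspace, the percentage of member annotations per
#' cluster peak time; rows sum to 100 within a subspace.
#'
#' @param subspace Character vector of subspace keys, one per profile.
#' @param cluster_peak_time Numeric vector of the peak time of each
#'   profile's cluster, one per profile.
#' @return Data frame: `subspace`, `peak_time`, `n`, `pct`.
#' @export
subspace_peaktime_distribution <- function(subspace, cluster_peak_time) {
  stopifnot(length(subspace) == length(cluster_peak_time))
  ok <- !is.na(cluster_peak_time)
  if (!any(ok))
    return(data.frame(subspace = character(), peak_time = numeric(),
                      n = integer(), pct = numeric()))
  df <- data.frame(subspace = subspace[ok], pt = cluster_peak_time[ok])
  out <- do.call(rbind, lapply(split(df, df$subspace), function(g) {
    tab <- table(g$pt)
    data.frame(subspace = g$subspace[1],
               peak_time = as.numeric(names(tab)),
               n = as.vector(tab, "integer"),
               pct = 100 * as.vector(tab, "integer") / nrow(g))
  }))
  rownames(out) <- NULL
  out
}

#' Synthetic temporal archetype profiles
#'
#' Generates profiles spanning eight distinct temporal shapes on the
#' sampling grid: a unimodal bump centered at each of the six timepoints,
#' an early plateau (high in the first half, sigmoid drop) and a late
#' plateau (sigmoid rise). Within an archetype, peak position, bump width
#' and the plateau breakpoint vary from profile to profile, emulating the
#' kinetic diversity of real compound profiles: the profile family spans a
#' two-dimensional manifold (peak position x profile width) rather than
#' eight isolated points, which is what a 2 x 4 map needs to unfold onto.
#' Used to exercise the SOM's cluster cardinality: the eight shapes should
#' occupy all eight units of the 2 x 4 grid.
#'
#' @param n_per Profiles per archetype (default 40, so 320 in total).
#' @param timepoints Timepoint grid (>= 6 values).
#' @param noise_sd Gaussian noise added before rescaling.
#' @param seed Integer seed.
#' @return Matrix of scaled profiles with attribute `"archetype"`.
#' @export
make_archetype_profiles <- function(n_per = 40,
                                    timepoints = c(2, 15, 24, 48, 72, 168),
                                    noise_sd = 0.15, seed = 1L) {
  stopifnot(length(timepoints) >= 6)
  m <- length(timepoints)
  idx <- seq_len(m)
  with_seed(seed, {
    rows <- list()
    arch <- integer()
    for (a in 1:8) {
      for (r in seq_len(n_per)) {
        if (a <= 6) {
          ctr <- a + stats::runif(1, -0.5, 0.5)
          wid <- stats::runif(1, 0.35, 1.5)
          p <- exp(-(idx - ctr)^2 / (2 * wid^2))
        } else {
          brk <- m / 2 + stats::runif(1, -0.7, 0.7)
          slope <- if (a == 7) 2.5 else -2.5
          p <- 1 / (1 + exp(slope * (idx - brk)))
        }
        rows[[length(rows) + 1L]] <- p + stats::rnorm(m, 0, noise_sd)
        arch <- c(arch, a)
      }
    }
    out <- scale_profiles(do.call(rbind, rows))
    attr(out, "archetype") <- arch
    out
  })
}
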