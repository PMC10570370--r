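# Synthetic ground-truth reaction network and peak-list rendering.
#
# The generator emulates the C2-addition chemistry of an acetylene/CO/NiS
# hydrothermal reaction: molecules grow from small seed compositions by the
# six reaction mass differences, carbonylation events mark CO-derived
# carbons (the expected 13CO label degree), sulfur-rich molecules peak
# early, and rendered spectra carry natural-isotope satellites, sodium
# adducts of dicarboxylic species, ppm-scale mass error and noise peaks.

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: technical triplicates at
#' six timepoints between 2 h and 7 days, FT-ICR-scale mass error (0.2 ppm
#' sd), natural 13C abundance 1.1% per carbon, natural 34S abundance 4.21%
#' per sulfur, and 99% isotopic purity of the labelled gases.
#'
#' @param seeds Data frame with columns `formula` and `n_co`: the starting
#'   compositions and how many of their carbons derive from CO. Defaults to
#'   the primary acetylene products: acetaldehyde C2H4O (hydration, 0 CO
#'   carbons), acrylic acid C3H4O2 (carbonylation, 1), thioacetic acid
#'   C2H4OS (0).
#' @param trans_probs Named per-generation reaction probabilities for the six
#'   transformations of [transformations()].
#' @param n_generations Number of reaction generations.
#' @param max_molecules Cap on the total number of distinct molecules.
#' @param timepoints Sampling times in hours.
#' @param replicates Technical replicates per timepoint.
#' @param mass_error_ppm_sd Gaussian m/z error (ppm).
#' @param n_noise Noise peaks per rendered spectrum.
#' @param noise_consistent_fraction Fraction of noise peaks that recur in all
#'   replicates of a timepoint/channel (persistent contaminants); the rest
#'   are drawn independently per replicate.
#' @param noise_intensity_meanlog,noise_intensity_sdlog Log-normal noise
#'   intensity parameters.
#' @param p13 Natural 13C abundance per carbon.
#' @param p34 Natural 34S abundance per sulfur.
#' @param dropout Per-replicate probability that a true peak is missing.
#' @param enrichment Isotopic purity of the labelled gases.
#' @param mixed_isomer_fraction Target fraction of compositions emitted by
#'   two molecules with different CO-carbon counts (co-eluting isomers).
#' @param na_adduct_fraction Intensity of the \[M-2H+Na\]- adduct of
#'   dicarboxylic molecules relative to their main peak.
#' @param kernel_log_sd Width (sd in log-time) of the unimodal temporal
#'   intensity kernel around each molecule's peak time.
#' @param amplitude_meanlog,amplitude_sdlog Log-normal abundance scale.
#' @param peak_time_by_s Peak time (h) for sulfur counts 0, 1, 2 and >= 3;
#'   must be values of `timepoints`. Encodes the early peaking of
#'   sulfur-rich compounds.
#' @param peak_time_jitter Probability that a molecule's peak time moves one
#'   grid step away from the sulfur-determined default.
#' @param noise_floor Intensity corresponding to s/n = 1.
#' @param min_intensity Peaks below this intensity are not rendered.
#' @param seed Integer seed from which all generator randomness derives.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seeds = data.frame(formula = c("C2H4O", "C3H4O2", "C2H4OS"),
                                          n_co = c(0L, 1L, 0L)),
                       trans_probs = c(water_addition = 0.2,
                                       h2s_addition = 0.2,
                                       c2h2_addition = 0.5,
                                       carbonylation_h2o = 0.3,
                                       carbonylation_h2s = 0.2,
                                       reduction = 0.2),
                       n_generations = 5,
                       max_molecules = 2000,
                       timepoints = c(2, 15, 24, 48, 72, 168),
                       replicates = 3,
                       mass_error_ppm_sd = 0.2,
                       n_noise = 30,
                       noise_consistent_fraction = 0.5,
                       noise_intensity_meanlog = log(150),
                       noise_intensity_sdlog = 0.6,
                       p13 = 0.011,
                       p34 = 0.0421,
                       dropout = 0.05,
                       enrichment = 0.99,
                       mixed_isomer_fraction = 0.1,
                       na_adduct_fraction = 0.3,
                       kernel_log_sd = 0.8,
                       amplitude_meanlog = log(2000),
                       amplitude_sdlog = 0.7,
                       peak_time_by_s = c(168, 72, 24, 2),
                       peak_time_jitter = 0.15,
                       noise_floor = 50,
                       min_intensity = 1,
                       seed = 1L) {
  stopifnot(is.data.frame(seeds), all(c("formula", "n_co") %in% names(seeds)),
            nrow(seeds) >= 1)
  stopifnot(all(trans_probs >= 0 & trans_probs <= 1),
            setequal(names(trans_probs), transformations()$name))
  stopifnot(n_generations >= 0, replicates >= 1,
            all(peak_time_by_s %in% timepoints),
            length(peak_time_by_s) == 4,
            enrichment > 0, enrichment <= 1,
            mass_error_ppm_sd >= 0, dropout >= 0, dropout < 1,
            mixed_isomer_fraction >= 0, mixed_isomer_fraction <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the ground-truth reaction network
#'
#' Starting from the seed compositions, every molecule in the current set
#' may undergo each of the six reactions per generation with its configured
#' probability; products are deduplicated on (composition, CO-carbon count)
#' and generation g retains all molecules of generation g-1. Carbonylation
#' events (with H2O or H2S) each add one CO-derived carbon; molecules with
#' at least two carbonylation-with-H2O events are flagged dicarboxylic.
#' A configurable fraction of compositions additionally receives a second
#' molecule with a different CO-carbon count, realized by an alternative
#' reaction multiset with the same elemental sum (co-eluting isomers).
#'
#' @param config A [sim_config()].
#' @return Data frame of ground-truth molecules: `formula`, element counts,
#'   `n_co` (CO-derived carbons), `generation`, `seed_formula`, `history`
#'   (semicolon-joined transformation names), `n_carbonyl_h2o`,
#'   `is_dicarboxylic`, `is_isomer_variant`.
#' @export
simulate_reaction_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tr <- transformations()
  seeds <- config$seeds
  sc <- parse_formula(seeds$formula)
  mol <- cbind(data.frame(formula = format_formula(sc), stringsAsFactors = FALSE),
               sc)
  mol$n_co <- as.integer(seeds$n_co)
  if (any(mol$n_co > mol$c)) stop("seed n_co exceeds its carbon count")
  mol$generation <- 0L
  mol$seed_formula <- mol$formula
  mol$history <- ""
  mol$n_carbonyl_h2o <- 0L
  mol$is_isomer_variant <- FALSE

  with_seed(derive_seed(config$seed, "network"), {
    for (g in seq_len(config$n_generations)) {
      n <- nrow(mol)
      if (n >= config$max_molecules) break
      idx <- rep(seq_len(n), each = nrow(tr))
      tdx <- rep(seq_len(nrow(tr)), times = n)
      p <- config$trans_probs[tr$name[tdx]]
      hit <- stats::runif(length(idx)) < p
      # additions across a double/triple bond (everything except the C2H2
      # addition, which brings its own unsaturation) require at least one
      # ring-or-double-bond equivalent in the substrate
      dbe <- mol$c[idx] - mol$h[idx] / 2 + 1
      needs_pi <- tr$name[tdx] != "c2h2_addition"
      hit <- hit & (!needs_pi | dbe >= 1)
      if (!any(hit)) next
      parents <- mol[idx[hit], , drop = FALSE]
      deltas <- tr[tdx[hit], , drop = FALSE]
      kids <- parents
      for (col in .comp_cols) kids[[col]] <- parents[[col]] + deltas[[col]]
      kids$formula <- format_formula(kids)
      kids$n_co <- parents$n_co + as.integer(deltas$adds_co_carbon)
      kids$generation <- g
      kids$history <- ifelse(nzchar(parents$history),
                             paste(parents$history, deltas$name, sep = ";"),
                             deltas$name)
      kids$n_carbonyl_h2o <- parents$n_carbonyl_h2o +
        as.integer(deltas$name == "carbonylation_h2o")
      mol <- rbind(mol, kids)
      mol <- mol[!duplicated(paste(mol$formula, mol$n_co)), , drop = FALSE]
      if (nrow(mol) > config$max_molecules)
        mol <- mol[seq_len(config$max_molecules), , drop = FALSE]
    }
    mol <- inject_mixed_isomers(mol, config)
  })
  mol$is_dicarboxylic <- mol$n_carbonyl_h2o >= 2L
  rownames(mol) <- NULL
  mol
}

#' Feasible CO-carbon counts for a composition delta
#'
#' Enumerates all non-negative integer reaction multisets
#' (water, H2S, C2H2, carbonylation-H2O, carbonylation-H2S, reduction)
#' whose elemental sum equals `delta`, and the CO-carbon count each implies.
#' Two multisets with different carbonylation totals explain how the same
#' elemental composition can carry different 13C label degrees (e.g.
#' 2 x CH2O2 + 3 x H2 has the same elemental sum as C2H2 + 4 x H2O but two
#' more CO-derived carbons).
#'
#' @param delta One-row composition data frame (product minus seed).
#' @return Data frame of solutions with columns `n_water`, `n_h2s`, `n_c2h2`,
#'   `n_carb_h2o`, `n_carb_h2s`, `n_reduction`, `n_co`.
#' @export
feasible_co_counts <- function(delta) {
  Dc <- delta$c; Dh <- delta$h; Do <- delta$o; Ds <- delta$s
  out <- list()
  if (Dh %% 2 != 0 || any(c(Dc, Dh, Do, Ds) < 0)) {
    return(data.frame(n_water = integer(), n_h2s = integer(),
                      n_c2h2 = integer(), n_carb_h2o = integer(),
                      n_carb_h2s = integer(), n_reduction = integer(),
                      n_co = integer()))
  }
  for (n4 in 0:min(Dc, Do %/% 2)) {
    for (n5 in 0:min(Ds, Dc - n4, Do - 2 * n4)) {
      rest <- Dc - n4 - n5
      if (rest %% 2 != 0) next
      n3 <- rest %/% 2
      n2 <- Ds - n5
      n1 <- Do - 2 * n4 - n5
      n6 <- Dh %/% 2 - (n1 + n2 + n3 + n4 + n5)
      if (min(n1, n2, n3, n6) < 0) next
      out[[length(out) + 1L]] <- data.frame(
        n_water = n1, n_h2s = n2, n_c2h2 = n3,
        n_carb_h2o = n4, n_carb_h2s = n5, n_reduction = n6,
        n_co = n4 + n5)
    }
  }
  if (!length(out)) {
    return(data.frame(n_water = integer(), n_h2s = integer(),
                      n_c2h2 = integer(), n_carb_h2o = integer(),
                      n_carb_h2s = integer(), n_reduction = integer(),
                      n_co = integer()))
  }
  do.call(rbind, out)
}

# Add isomer-variant molecules (same composition, different CO-carbon count)
# for a target fraction of compositions. Within the six-edge reaction set
# the CO-carbon count is almost uniquely determined by the composition
# (every edge adds exactly two hydrogens, so trading carbonylations against
# acetylene+water requires reduction-rich compositions outside the H/C
# filter); mixed label degrees therefore represent isomers formed through
# reactions outside the core edge list. Variants accordingly reuse the
# partner's composition with a CO-carbon count shifted by one and are
# tagged `is_isomer_variant`. Runs inside the generator's RNG stream.
inject_mixed_isomers <- function(mol, config) {
  if (config$mixed_isomer_fraction <= 0) return(mol)
  comps <- unique(mol$formula)
  target <- round(config$mixed_isomer_fraction * length(comps))
  if (target == 0) return(mol)
  single <- names(which(table(mol$formula) == 1))
  cand <- mol[mol$formula %in% single & mol$generation > 0, , drop = FALSE]
  cand <- cand[cand$c > cand$n_co | cand$n_co > 0, , drop = FALSE]
  if (!nrow(cand)) return(mol)
  pick <- cand[sample.int(nrow(cand), min(target, nrow(cand))), , drop = FALSE]
  v <- pick
  v$n_co <- ifelse(pick$n_co + 1L <= pick$c, pick$n_co + 1L, pick$n_co - 1L)
  v$is_isomer_variant <- TRUE
  rbind(mol, v)
}

#' Unimodal temporal intensity kernel
#'
#' Gaussian in log-time around the peak time, so each molecule's profile has
#' a single maximum on the sampling grid.
#'
#' @param t Time(s) in hours.
#' @param peak_time Peak time in hours.
#' @param log_sd Kernel width (sd of log-hours).
#' @return Kernel values in (0, 1], equal to 1 at `t == peak_time`.
#' @export
temporal_kernel <- function(t, peak_time, log_sd) {
  exp(-(log(t) - log(peak_time))^2 / (2 * log_sd^2))
}

#' Assign peak times and abundance scales
#'
#' Peak times follow the sulfur count through `config$peak_time_by_s`
#' (sulfur-rich molecules peak earlier); with probability
#' `config$peak_time_jitter` the peak time moves one step on the timepoint
#' grid. Amplitudes are log-normal; isomer variants receive an amplitude
#' comparable to their partner molecule (within about a factor 1.6), as
#' co-eluting isomers of wildly different abundance would not be detected
#' as mixed in the first place.
#'
#' @param molecules Output of [simulate_reaction_network()].
#' @param config The [sim_config()].
#' @return `molecules` with columns `peak_time` (h) and `amplitude`.
#' @export
assign_temporal_profiles <- function(molecules, config) {
  stopifnot(inherits(config, "sim_config"))
  tps <- sort(config$timepoints)
  with_seed(derive_seed(config$seed, "profiles"), {
    base <- config$peak_time_by_s[pmin(molecules$s, 3L) + 1L]
    idx <- match(base, tps)
    jit <- stats::runif(nrow(molecules)) < config$peak_time_jitter
    step <- sample(c(-1L, 1L), nrow(molecules), replace = TRUE)
    idx[jit] <- pmin(pmax(idx[jit] + step[jit], 1L), length(tps))
    molecules$peak_time <- tps[idx]
    molecules$amplitude <- stats::rlnorm(nrow(molecules),
                                         config$amplitude_meanlog,
                                         config$amplitude_sdlog)
    isv <- which(molecules$is_isomer_variant)
    if (length(isv)) {
      partner <- match(molecules$formula[isv], molecules$formula)
      molecules$amplitude[isv] <- molecules$amplitude[partner] *
        exp(stats::runif(length(isv), -0.5, 0.5))
      molecules$peak_time[isv] <- molecules$peak_time[partner]
    }
  })
  molecules
}

#' Labelling channels understood by the renderer
#' @export
label_channels <- c("unlabeled", "13CO", "13C-acetylene")

#' Construct a spectrum object
#'
#' A spectrum is a peak list (`mz`, `intensity`, `sn`) sorted by m/z with
#' timepoint, replicate and labelling-channel metadata attached as
#' attributes.
#'
#' @param peaks Data frame with columns `mz`, `intensity`, `sn`.
#' @param timepoint Timepoint in hours.
#' @param replicate Replicate id.
#' @param channel One of [label_channels].
#' @return Data frame of class `spectrum`.
#' @export
new_spectrum <- function(peaks, timepoint, replicate, channel) {
  stopifnot(all(c("mz", "intensity", "sn") %in% names(peaks)))
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(peaks, timepoint = timepoint, replicate = replicate,
            channel = channel, class = c("spectrum", "data.frame"))
}

#' Spectrum metadata
#' @param x A `spectrum`.
#' @return List with `timepoint`, `replicate`, `channel`.
#' @export
spectrum_meta <- function(x) {
  list(timepoint = attr(x, "timepoint"), replicate = attr(x, "replicate"),
       channel = attr(x, "channel"))
}

# Rebuild a spectrum keeping metadata, after row filtering.
rebuild_spectrum <- function(peaks, template) {
  m <- spectrum_meta(template)
  new_spectrum(as.data.frame(peaks), m$timepoint, m$replicate, m$channel)
}

#' Render one synthetic spectrum
#'
#' Every molecule contributes its deprotonated monoisotopic peak at
#' `amplitude * kernel(timepoint; peak_time)`. Depending on the channel, the
#' monoisotopic signal is shifted to the labelled isotopologue: in `"13CO"`
#' each of the `n_co` CO-derived carbons is 13C with probability
#' `enrichment`; in `"13C-acetylene"` the same applies to the `c - n_co`
#' acetylene-derived carbons. Natural-abundance satellites are added on top
#' of every rendered main peak: an M+1 13C peak at `p13 * (c - n13c)`
#' relative intensity and, for sulfur compounds, a 34S peak (+1.99580 u) at
#' `p34 * s`. Dicarboxylic molecules add an \[M-2H+Na\]- peak at
#' `na_adduct_fraction` of their main intensity. All m/z values receive
#' Gaussian ppm error, noise peaks are appended (a configurable fraction of
#' them shared across replicates), peaks drop out per replicate, and s/n is
#' intensity over the configured noise floor. The result is deterministic
#' given the configuration seed, independent of rendering order.
#'
#' @param molecules Molecules with temporal profiles
#'   (see [assign_temporal_profiles()]).
#' @param config The [sim_config()].
#' @param channel One of [label_channels].
#' @param timepoint Timepoint in hours (member of `config$timepoints`).
#' @param replicate Replicate number (1-based).
#' @return A [new_spectrum()] object.
#' @export
render_spectra <- function(molecules, config, channel, timepoint, replicate) {
  stopifnot(inherits(config, "sim_config"))
  if (!channel %in% label_channels)
    stop("unknown labelling channel: ", channel)
  stopifnot(timepoint %in% config$timepoints)
  stopifnot(all(c("peak_time", "amplitude") %in% names(molecules)) || nrow(molecules) == 0)

  peaks <- data.frame(mz = numeric(), intensity = numeric())
  if (nrow(molecules)) {
    base_int <- molecules$amplitude *
      temporal_kernel(timepoint, molecules$peak_time, config$kernel_log_sd)

    main <- list()
    for (i in seq_len(nrow(molecules))) {
      m <- molecules[i, , drop = FALSE]
      lab_n <- switch(channel,
                      "unlabeled" = 0L,
                      "13CO" = m$n_co,
                      "13C-acetylene" = m$c - m$n_co)
      if (lab_n == 0L) {
        js <- 0L; rel <- 1
      } else {
        js <- 0:lab_n
        rel <- stats::dbinom(js, lab_n, config$enrichment)
        keep <- rel >= 1e-4
        js <- js[keep]; rel <- rel[keep]
      }
      for (k in seq_along(js)) {
        mc <- m[, .comp_cols]; mc$n13c <- js[k]
        inten <- base_int[i] * rel[k]
        if (inten < config$min_intensity) next
        mono_mz <- ion_mz(mc, "deprotonated")
        rows <- data.frame(mz = mono_mz, intensity = inten)
        if (m$c - js[k] >= 1) {
          i1 <- inten * config$p13 * (m$c - js[k])
          if (i1 >= config$min_intensity)
            rows <- rbind(rows, data.frame(mz = mono_mz + delta_13c,
                                           intensity = i1))
        }
        if (m$s > 0) {
          i34 <- inten * config$p34 * m$s
          if (i34 >= config$min_intensity)
            rows <- rbind(rows, data.frame(mz = mono_mz + delta_34s,
                                           intensity = i34))
        }
        if (isTRUE(m$is_dicarboxylic) && m$h >= 2) {
          ina <- inten * config$na_adduct_fraction
          if (ina >= config$min_intensity)
            rows <- rbind(rows, data.frame(
              mz = ion_mz(mc, "sodiated-deprotonated"), intensity = ina))
        }
        main[[length(main) + 1L]] <- rows
      }
    }
    if (length(main)) peaks <- do.call(rbind, main)
    if (nrow(peaks)) {
      key <- round(peaks$mz, 7)
      agg <- stats::aggregate(intensity ~ key, data = cbind(peaks, key = key), sum)
      peaks <- data.frame(mz = agg$key, intensity = agg$intensity)
    }
  }

  # persistent contaminants: identical draw for every replicate of this
  # channel/timepoint
  n_cons <- round(config$n_noise * config$noise_consistent_fraction)
  cons <- with_seed(derive_seed(config$seed, "noise", channel, timepoint), {
    data.frame(mz = stats::runif(n_cons, 122, 1000),
               intensity = stats::rlnorm(n_cons, config$noise_intensity_meanlog,
                                         config$noise_intensity_sdlog))
  })

  with_seed(derive_seed(config$seed, "render", channel, timepoint, replicate), {
    if (nrow(peaks)) {
      keep <- stats::runif(nrow(peaks)) >= config$dropout
      peaks <- peaks[keep, , drop = FALSE]
    }
    n_free <- config$n_noise - n_cons
    noise <- data.frame(mz = stats::runif(n_free, 122, 1000),
                        intensity = stats::rlnorm(n_free,
                                                  config$noise_intensity_meanlog,
                                                  config$noise_intensity_sdlog))
    cons$intensity <- cons$intensity * exp(stats::rnorm(nrow(cons), 0, 0.1))
    peaks <- rbind(peaks, cons, noise)
    peaks$mz <- peaks$mz *
      (1 + stats::rnorm(nrow(peaks), 0, config$mass_error_ppm_sd) * 1e-6)
  })
  peaks <- peaks[peaks$intensity >= config$min_intensity, , drop = FALSE]
  peaks$sn <- peaks$intensity / config$noise_floor
  new_spectrum(peaks, timepoint, replicate, channel)
}

#' Render all spectra for a set of channels
#'
#' @param molecules Molecules with temporal profiles.
#' @param config The [sim_config()].
#' @param channels Subset of [label_channels].
#' @return Flat list of [new_spectrum()] objects, one per
#'   channel x timepoint x replicate.
#' @export
render_all_spectra <- function(molecules, config, channels = label_channels) {
  out <- list()
  for (ch in channels)
    for (tp in config$timepoints)
      for (r in seq_len(config$replicates))
        out[[length(out) + 1L]] <- render_spectra(molecules, config, ch, tp, r)
  out
}

#' Canonical spectrum file name
#' @param channel,timepoint,replicate Spectrum metadata.
#' @return File name like `"13CO_24h_rep2.csv"`.
#' @export
spectrum_filename <- function(channel, timepoint, replicate) {
  sprintf("%s_%gh_rep%d.csv", channel, timepoint, replicate)
}

#' Write / read ground-truth molecule tables
#'
#' Plain-CSV round trip of the generator output. `read_ground_truth()`
#' validates formulas and CO-carbon counts and errors on malformed files.
#'
#' @param molecules Ground-truth data frame.
#' @param path File path.
#' @return `read_ground_truth()` returns the molecule data frame.
#' @export
write_ground_truth <- function(molecules, path) {
  cols <- c("formula", "n_co", "s_count", "peak_time_h", "amplitude",
            "is_dicarboxylic", "history", "generation", "seed_formula",
            "is_isomer_variant")
  out <- data.frame(formula = molecules$formula,
                    n_co = molecules$n_co,
                    s_count = molecules$s,
                    peak_time_h = if ("peak_time" %in% names(molecules))
                      molecules$peak_time else NA_real_,
                    amplitude = if ("amplitude" %in% names(molecules))
                      molecules$amplitude else NA_real_,
                    is_dicarboxylic = molecules$is_dicarboxylic,
                    history = molecules$history,
                    generation = molecules$generation,
                    seed_formula = molecules$seed_formula,
                    is_isomer_variant = molecules$is_isomer_variant)
  utils::write.csv(out[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("formula", "n_co", "s_count", "peak_time_h", "amplitude",
            "is_dicarboxylic", "history")
  if (!all(need %in% names(raw)))
    stop("malformed ground-truth file: missing columns ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  cc <- parse_formula(raw$formula)  # errors on malformed formulas
  if (any(raw$n_co < 0 | raw$n_co > cc$c))
    stop("malformed ground-truth file: n_co outside [0, c]")
  if (any(cc$s != raw$s_count))
    stop("malformed ground-truth file: s_count inconsistent with formula")
  out <- cbind(data.frame(formula = raw$formula, stringsAsFactors = FALSE), cc)
  out$n_co <- as.integer(raw$n_co)
  out$peak_time <- raw$peak_time_h
  out$amplitude <- raw$amplitude
  out$is_dicarboxylic <- as.logical(raw$is_dicarboxylic)
  out$history <- raw$history
  if ("generation" %in% names(raw)) out$generation <- raw$generation
  if ("seed_formula" %in% names(raw)) out$seed_formula <- raw$seed_formula
  out$is_isomer_variant <- if ("is_isomer_variant" %in% names(raw))
    as.logical(raw$is_isomer_variant) else FALSE
  out
}

#' Write / read a peak-list CSV
#' @param spec A [new_spectrum()] object.
#' @param path File path.
#' @param timepoint,replicate,channel Metadata to attach on read.
#' @return `read_spectrum()` returns a `spectrum`.
#' @export
write_spectrum <- function(spec, path) {
  utils::write.csv(as.data.frame(spec)[c("mz", "intensity", "sn")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, timepoint, replicate, channel) {
  raw <- utils::read.csv(path)
  if (!all(c("mz", "intensity", "sn") %in% names(raw)))
    stop("malformed spectrum file: ", path)
  new_spectrum(raw, timepoint, replicate, channel)
}
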