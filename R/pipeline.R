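# End-to-end orchestration: simulate -> preprocess -> annotate -> label ->
# classify -> network -> SOM -> report, plus ground-truth evaluation.

#' Pipeline run configuration
#'
#' Bundles the simulation configuration with all analysis parameters. The
#' analysis defaults mirror the acquisition conventions the pipeline
#' emulates: s/n >= 4, m/z 122-1000, >66% replicate presence, 0.5 ppm
#' mass tolerance.
#'
#' @param sim A [sim_config()]; the input source unless `input_dir` is
#'   given (exactly one source of input is used).
#' @param input_dir Optional directory of peak-list CSVs named as
#'   [spectrum_filename()] (plus an optional `ground_truth.csv`); when set,
#'   spectra are read from disk instead of being simulated and `sim` only
#'   supplies the timepoint/replicate/channel layout.
#' @param sn_min Signal-to-noise threshold.
#' @param mz_range Closed m/z acceptance interval.
#' @param min_replicate_fraction Exclusive replicate-presence threshold.
#' @param tol_ppm Mass tolerance for alignment, assignment and label peaks.
#' @param seed_mz_max Upper m/z bound for network seed selection.
#' @param rescue Assign remaining peaks by unique brute-force enumeration.
#' @param rescue_tol_ppm Tighter tolerance for brute-force rescue.
#' @param rescue_min_timepoints Minimum detected timepoints for rescue.
#' @param use_34s_filter,use_wiggle_filter Enable the heuristic in-house
#'   artifact filters (off by default; the generator's natural 34S
#'   satellites are handled by isotopologue flagging during alignment).
#' @param label_rule Threshold rule for [classify_label_degrees()].
#' @param label_p Natural 13C abundance used by the labelling threshold.
#' @param k_max Largest labelling degree tested.
#' @param som_grid,som_lr,som_sigma,som_iterations SOM parameters
#'   (see [train_som()]).
#' @param out_dir Output directory for artifacts (`NULL` = in memory only).
#' @param seed Run seed; all stage randomness derives from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       input_dir = NULL,
                       sn_min = 4,
                       mz_range = c(122, 1000),
                       min_replicate_fraction = 0.66,
                       tol_ppm = 0.5,
                       seed_mz_max = 200,
                       rescue = TRUE,
                       rescue_tol_ppm = 0.3,
                       rescue_min_timepoints = 2,
                       use_34s_filter = FALSE,
                       use_wiggle_filter = FALSE,
                       label_rule = "linear",
                       label_p = 0.01,
                       k_max = 6,
                       som_grid = c(2, 4),
                       som_lr = 0.1,
                       som_sigma = 1.0,
                       som_iterations = 50000,
                       out_dir = NULL,
                       seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), tol_ppm > 0, sn_min >= 0,
            mz_range[1] < mz_range[2])
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input directory does not exist: ", input_dir)
  sim$seed <- seed
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

# Preprocess one channel: filter replicates, build one consensus per
# timepoint. Returns list of consensus objects ordered by timepoint.
preprocess_channel <- function(spectra, config) {
  metas <- lapply(spectra, spectrum_meta)
  tps <- sort(unique(vapply(metas, function(m) as.numeric(m$timepoint), 0)))
  out <- vector("list", length(tps))
  for (i in seq_along(tps)) {
    reps <- spectra[vapply(metas, function(m)
      as.numeric(m$timepoint) == tps[i], TRUE)]
    reps <- lapply(reps, function(sp) {
      sp <- filter_peaks(sp, config$sn_min, config$mz_range)
      if (config$use_34s_filter) sp <- remove_34s_isotopes(sp, config$tol_ppm * 2)
      if (config$use_wiggle_filter) sp <- remove_wiggle_artifacts(sp)
      sp
    })
    out[[i]] <- replicate_consensus(reps, config$tol_ppm,
                                    config$min_replicate_fraction)
  }
  names(out) <- as.character(tps)
  out
}

#' Run the full analysis pipeline on synthetic data
#'
#' Stages: simulate the ground-truth reaction network; render spectra for
#' the unlabeled and both labelled channels at every timepoint; filter and
#' build replicate consensus per timepoint; align timepoints into features
#' and flag isotopologue satellites; assign formulas (seed selection,
#' mass-difference-network propagation, optional brute-force rescue,
#' elemental-ratio filter, sodium-adduct detection); classify labelling
#' degrees against both labelled channels at each annotation's most intense
#' timepoint; summarize compound classes; build the molecular network; and
#' cluster temporal profiles with the SOM. Deterministic given the
#' configuration seed.
#'
#' @param config A [run_config()].
#' @return List of class `c2net_run` with elements `config`, `molecules`
#'   (ground truth), `consensus` (per channel), `features`, `annotations`,
#'   `mixed`, `subspace_hc`, `cho4_classes`, `series`, `network`,
#'   `class_shares`, `som`, `som_clusters`, `report`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim

  if (is.null(config$input_dir)) {
    mol <- simulate_reaction_network(sim)
    mol <- assign_temporal_profiles(mol, sim)
    load_channel <- function(ch) {
      spectra <- list()
      for (tp in sim$timepoints)
        for (r in seq_len(sim$replicates))
          spectra[[length(spectra) + 1L]] <- render_spectra(mol, sim, ch, tp, r)
      spectra
    }
  } else {
    if (!dir.exists(config$input_dir))
      stop("input directory does not exist: ", config$input_dir)
    gt <- file.path(config$input_dir, "ground_truth.csv")
    mol <- if (file.exists(gt)) read_ground_truth(gt) else NULL
    load_channel <- function(ch) {
      spectra <- list()
      for (tp in sim$timepoints)
        for (r in seq_len(sim$replicates)) {
          f <- file.path(config$input_dir, spectrum_filename(ch, tp, r))
          if (!file.exists(f)) stop("missing spectrum file: ", f)
          spectra[[length(spectra) + 1L]] <- read_spectrum(f, tp, r, ch)
        }
      spectra
    }
  }

  consensus <- lapply(stats::setNames(label_channels, label_channels),
                      function(ch) preprocess_channel(load_channel(ch), config))

  aligned <- align_features(consensus$unlabeled, config$tol_ppm)
  features <- aligned$features
  features$isotopologue <- flag_isotopologue_features(features)
  assignable <- features[!features$isotopologue, , drop = FALSE]

  if (!nrow(assignable)) return(empty_run(config, mol, consensus, aligned, features))

  seeds <- select_seed_annotations(assignable, config$tol_ppm,
                                   config$seed_mz_max)
  if (!nrow(seeds))
    stop("annotation stage failed: no confidently assignable seed peaks")
  ann <- mdn_assign(assignable, seeds, tol_ppm = config$tol_ppm)
  ann$feature_id <- assignable$feature_id[ann$peak_id]

  if (config$rescue) {
    left <- setdiff(seq_len(nrow(assignable)), ann$peak_id)
    left <- left[assignable$n_timepoints[left] >= config$rescue_min_timepoints]
    rows <- list()
    for (i in left) {
      cand <- brute_force_assign(assignable$mz[i], "deprotonated",
                                 config$rescue_tol_ppm, ratio_filter = TRUE)
      if (nrow(cand) == 1) {
        row <- cbind(data.frame(peak_id = i, mz = assignable$mz[i]), cand)
        row$source <- "brute-force"
        row$path <- cand$formula
        row$feature_id <- assignable$feature_id[i]
        rows[[length(rows) + 1L]] <- row
      }
    }
    if (length(rows)) ann <- rbind(ann, do.call(rbind, rows)[names(ann)])
  }
  ann <- filter_annotations(ann)

  fidx <- match(ann$feature_id, features$feature_id)
  ann$first_detection <- features$first_detection[fidx]
  ann$n_timepoints <- features$n_timepoints[fidx]
  ann <- detect_na_adducts(ann, features, config$tol_ppm)

  # labelling at each annotation's most intense timepoint
  best_tp <- apply(aligned$intensity[fidx, , drop = FALSE], 1, which.max)
  ann <- label_annotations(ann, consensus$unlabeled, consensus$`13CO`,
                           best_tp = best_tp, tol_ppm = config$tol_ppm,
                           p = config$label_p, k_max = config$k_max,
                           threshold_rule = config$label_rule)
  acet <- label_annotations(ann, consensus$unlabeled,
                            consensus$`13C-acetylene`, best_tp = best_tp,
                            tol_ppm = config$tol_ppm, p = config$label_p,
                            k_max = config$k_max,
                            threshold_rule = config$label_rule)
  ann$acetylene_degrees <- acet$label_degrees
  ann$c2_closure <- mapply(cross_channel_check, ann$c, ann$label_degrees,
                           ann$acetylene_degrees)

  ann <- partition_subspaces(ann)
  mixed <- mixed_fraction(ann)
  subspace_hc <- do.call(rbind, lapply(split(ann, ann$subspace), function(g) {
    tab <- mean_hc_by_degree(g)
    if (!nrow(tab)) return(NULL)
    cbind(data.frame(subspace = g$subspace[1]), tab)
  }))
  if (!is.null(subspace_hc)) rownames(subspace_hc) <- NULL
  cho4 <- na_adduct_classify(ann[ann$subspace == "O4S0", , drop = FALSE])
  series <- do.call(rbind, lapply(split(ann, ann$subspace), function(g) {
    s <- detect_c2_series(g)
    if (nrow(s)) s$subspace <- g$subspace[1]
    s
  }))
  if (!is.null(series) && nrow(series)) {
    series$series_id <- match(paste(series$subspace, series$series_id),
                              unique(paste(series$subspace, series$series_id)))
    rownames(series) <- NULL
  }

  net <- build_network(ann)
  detected_ann <- aligned$detected[fidx, , drop = FALSE]
  shares <- sulfur_class_shares(ann, detected_ann, aligned$timepoints)

  profiles <- scale_profiles(aligned$intensity[fidx, , drop = FALSE])
  som <- train_som(profiles, grid = config$som_grid, lr = config$som_lr,
                   sigma = config$som_sigma,
                   iterations = config$som_iterations,
                   seed = derive_seed(config$seed, "som"))
  som_clusters <- som_cluster_table(som, aligned$timepoints)
  ann$som_unit <- som$assignment
  ann$cluster_peak_time <- som_clusters$peak_time[som$assignment]
  peaktime_dist <- subspace_peaktime_distribution(ann$subspace,
                                                  ann$cluster_peak_time)

  report <- list(
    n_molecules = nrow(mol),
    n_features = nrow(features),
    n_annotated = nrow(ann),
    connectivity_pct = connectivity_fraction(net),
    n_series = if (is.null(series) || !nrow(series)) 0L
               else max(series$series_id),
    som_occupied = n_occupied_clusters(som)
  )

  run <- structure(list(config = config, molecules = mol,
                        consensus = consensus, aligned = aligned,
                        features = features, annotations = ann,
                        mixed = mixed, subspace_hc = subspace_hc,
                        cho4_classes = cho4, series = series, network = net,
                        class_shares = shares, som = som,
                        som_clusters = som_clusters,
                        peaktime_dist = peaktime_dist, report = report),
                   class = "c2net_run")
  if (!is.null(config$out_dir)) write_run_artifacts(run, config$out_dir)
  run
}

# Valid run object for inputs that yield no assignable peaks.
empty_run <- function(config, mol, consensus, aligned, features) {
  ann <- data.frame(peak_id = integer(), mz = numeric(), formula = character(),
                    c = integer(), h = integer(), o = integer(), s = integer(),
                    na = integer(), n13c = integer(), theo_mz = numeric(),
                    error_ppm = numeric(), source = character(),
                    path = character(), feature_id = integer())
  ann$label_degrees <- list()
  report <- list(n_molecules = if (is.null(mol)) NA_integer_ else nrow(mol),
                 n_features = nrow(features), n_annotated = 0L,
                 connectivity_pct = NA_real_, n_series = 0L,
                 som_occupied = 0L)
  run <- structure(list(config = config, molecules = mol,
                        consensus = consensus, aligned = aligned,
                        features = features, annotations = ann,
                        mixed = mixed_fraction(ann), subspace_hc = NULL,
                        cho4_classes = NULL, series = NULL,
                        network = igraph::make_empty_graph(0, directed = FALSE),
                        class_shares = NULL, som = NULL, som_clusters = NULL,
                        peaktime_dist = NULL, report = report),
                   class = "c2net_run")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.c2net_run <- function(x, ...) {
  r <- x$report
  cat("C2 reaction-network analysis run\n")
  cat(sprintf("  ground-truth molecules : %d\n", r$n_molecules))
  cat(sprintf("  aligned features       : %d\n", r$n_features))
  cat(sprintf("  annotated compositions : %d\n", r$n_annotated))
  if (!is.na(r$connectivity_pct))
    cat(sprintf("  network connectivity   : %.1f%%\n", r$connectivity_pct))
  cat(sprintf("  occupied SOM clusters  : %d\n", r$som_occupied))
  invisible(x)
}

# Serialize the run's tables; list-columns become semicolon-joined strings.
write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_ground_truth(run$molecules, file.path(out_dir, "ground_truth.csv"))
  utils::write.csv(run$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  ann <- run$annotations
  ann$label_degrees <- vapply(ann$label_degrees, paste, "", collapse = ";")
  ann$acetylene_degrees <- vapply(ann$acetylene_degrees, paste, "",
                                  collapse = ";")
  utils::write.csv(ann, file.path(out_dir, "annotations.csv"),
                   row.names = FALSE)
  utils::write.csv(run$mixed, file.path(out_dir, "mixed_fraction.csv"),
                   row.names = FALSE)
  if (!is.null(run$subspace_hc))
    utils::write.csv(run$subspace_hc,
                     file.path(out_dir, "subspace_mean_hc.csv"),
                     row.names = FALSE)
  if (!is.null(run$series) && nrow(run$series))
    utils::write.csv(run$series, file.path(out_dir, "c2_series.csv"),
                     row.names = FALSE)
  utils::write.csv(run$class_shares$sulfur,
                   file.path(out_dir, "sulfur_class_shares.csv"),
                   row.names = FALSE)
  utils::write.csv(run$som_clusters, file.path(out_dir, "som_clusters.csv"),
                   row.names = FALSE)
  export_network_graphml(run$network, file.path(out_dir, "network.graphml"))
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Evaluate pipeline recovery against the generator ground truth
#'
#' Formula matching is exact composition equality. Recall and the label
#' accuracy are computed over the observable ground truth (molecules whose
#' deprotonated monoisotopic m/z lies inside the configured mass range).
#' The noise false-annotation rate is the fraction of features matching no
#' rendered true peak (noise features) that nevertheless received a formula.
#'
#' @param run A [run_pipeline()] result.
#' @return List of class `recovery_report`: `formula_recall` (over all
#'   observable truth), `formula_recall_admissible` (over observable truth
#'   inside the H/C and O/C annotation window -- compositions outside it are
#'   excluded by the method's own filters and can never be annotated),
#'   `formula_precision`, `label_accuracy`, `noise_false_annotation_rate`,
#'   `connectivity_pct`, `n_truth_observable`, `n_annotated`,
#'   `n_noise_features`, `mixed_truth_pct`, `mixed_recovered_pct`.
#' @export
evaluate_recovery <- function(run) {
  stopifnot(inherits(run, "c2net_run"))
  cfg <- run$config
  mol <- run$molecules
  ann <- run$annotations

  mono_mz <- ion_mz(mol[.comp_cols], "deprotonated")
  observable <- mono_mz >= cfg$mz_range[1] & mono_mz <= cfg$mz_range[2]
  truth_forms <- unique(mol$formula[observable])
  admissible <- observable & ratio_keep(mol)
  truth_adm <- unique(mol$formula[admissible])
  ann_forms <- unique(ann$formula)

  recall <- if (length(truth_forms))
    mean(truth_forms %in% ann_forms) else NA_real_
  recall_adm <- if (length(truth_adm))
    mean(truth_adm %in% ann_forms) else NA_real_
  precision <- if (length(ann_forms))
    mean(ann_forms %in% unique(mol$formula)) else NA_real_

  # label accuracy: per observable annotated molecule, was its CO-carbon
  # count among the called degrees of its composition?
  called <- tapply(ann$label_degrees, ann$formula,
                   function(l) sort(unique(unlist(l))))
  mobs <- mol[observable & mol$formula %in% ann_forms, , drop = FALSE]
  label_hit <- vapply(seq_len(nrow(mobs)), function(i) {
    degs <- called[[mobs$formula[i]]]
    !is.null(degs) && mobs$n_co[i] %in% degs
  }, TRUE)
  label_accuracy <- if (nrow(mobs)) mean(label_hit) else NA_real_

  # noise features: not within tolerance of any rendered theoretical m/z
  true_mz <- rendered_true_mz(mol, run$config$sim)
  feat <- run$features
  is_true <- vapply(feat$mz, function(m)
    any(abs(true_mz - m) / m * 1e6 <= 3 * cfg$tol_ppm), TRUE)
  noise_feat <- feat$feature_id[!is_true]
  n_noise <- length(noise_feat)
  fp_rate <- if (n_noise) mean(noise_feat %in% ann$feature_id) else 0

  truth_mixed <- 100 * mean(table(mol$formula[observable]) >= 2)
  mixed_rec <- if (nrow(ann))
    100 * mean(lengths(ann$label_degrees[lengths(ann$label_degrees) > 0]) >= 2)
  else NA_real_

  structure(list(
    formula_recall = recall,
    formula_recall_admissible = recall_adm,
    formula_precision = precision,
    label_accuracy = label_accuracy,
    noise_false_annotation_rate = fp_rate,
    connectivity_pct = run$report$connectivity_pct,
    n_truth_observable = length(truth_forms),
    n_annotated = length(ann_forms),
    n_noise_features = n_noise,
    mixed_truth_pct = truth_mixed,
    mixed_recovered_pct = mixed_rec
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery against ground truth\n")
  cat(sprintf("  formula recall        : %.3f (%d observable compositions)\n",
              x$formula_recall, x$n_truth_observable))
  cat(sprintf("  recall (admissible)   : %.3f\n", x$formula_recall_admissible))
  cat(sprintf("  formula precision     : %.3f (%d annotated)\n",
              x$formula_precision, x$n_annotated))
  cat(sprintf("  label-degree accuracy : %.3f\n", x$label_accuracy))
  cat(sprintf("  noise false-annotation: %.3f (%d noise features)\n",
              x$noise_false_annotation_rate, x$n_noise_features))
  cat(sprintf("  connectivity          : %.1f%%\n", x$connectivity_pct))
  invisible(x)
}

# All theoretical m/z values the generator can emit for a molecule set:
# monoisotopic ion, labelled isotopologues, natural M+1 and 34S satellites,
# and the sodium adduct for dicarboxylic molecules.
rendered_true_mz <- function(mol, sim) {
  out <- numeric()
  for (i in seq_len(nrow(mol))) {
    m <- mol[i, , drop = FALSE]
    shifts <- unique(c(0L, m$n_co, m$c - m$n_co))
    shifts <- shifts[shifts >= 0 & shifts <= m$c]
    shifts <- unique(c(shifts, shifts + 1L))  # enrichment residuals / M+1
    shifts <- shifts[shifts <= m$c]
    base <- ion_mz(m[, .comp_cols], "deprotonated")
    mzs <- base + shifts * delta_13c
    if (m$s > 0) mzs <- c(mzs, base + delta_34s, base + shifts * delta_13c + delta_34s)
    if (isTRUE(m$is_dicarboxylic) && m$h >= 2) {
      na_base <- ion_mz(m[, .comp_cols], "sodiated-deprotonated")
      mzs <- c(mzs, na_base + shifts * delta_13c)
    }
    out <- c(out, mzs)
  }
  sort(unique(out))
}
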