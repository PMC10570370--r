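# Time-resolved molecular network over annotated compositions, connected by
# the six reaction mass differences, and its summary statistics.

#' Build the molecular network
#'
#' Nodes are the unique neutral annotated compositions (label-degree
#' variants collapse onto one node); an undirected edge labelled with the
#' transformation name joins every pair whose element-wise composition
#' difference equals a transformation delta exactly. Matching is by exact
#' composition (not an m/z window), so isobaric compositions can never be
#' joined spuriously; the edge direction attribute records the lower-mass
#' to higher-mass reading.
#'
#' @param annotations Annotation data frame with `formula` and element
#'   counts; optional columns `first_detection` (hours) and `label_degrees`
#'   become node attributes.
#' @param trans Transformation table, see [transformations()].
#' @return An `igraph` graph with node attributes `name` (formula), `mass`,
#'   `c`, `h`, `o`, `s`, `hc`, `oc`, `first_detection_h`, `degrees`, and
#'   edge attributes `transformation` and `from_lower_mass`.
#' @export
build_network <- function(annotations, trans = transformations()) {
  ann <- annotations[!duplicated(annotations$formula), , drop = FALSE]
  # collapse label-degree sets per composition
  if ("label_degrees" %in% names(annotations)) {
    degs <- tapply(annotations$label_degrees, annotations$formula,
                   function(l) sort(unique(unlist(l))))
    ann$degrees <- vapply(degs[ann$formula], paste, "", collapse = ";")
  } else {
    ann$degrees <- rep("", nrow(ann))
  }
  if ("first_detection" %in% names(annotations)) {
    fd <- tapply(annotations$first_detection, annotations$formula, min)
    ann$first_detection_h <- as.numeric(fd[ann$formula])
  } else {
    ann$first_detection_h <- rep(NA_real_, nrow(ann))
  }
  ann$mass <- monoisotopic_mass(ann[.comp_cols])
  key <- paste(ann$c, ann$h, ann$o, ann$s, sep = "_")
  edges <- list()
  for (t in seq_len(nrow(trans))) {
    tgt <- paste(ann$c + trans$c[t], ann$h + trans$h[t],
                 ann$o + trans$o[t], ann$s + trans$s[t], sep = "_")
    hit <- match(tgt, key)
    ok <- which(!is.na(hit))
    if (length(ok))
      edges[[length(edges) + 1L]] <- data.frame(
        from = ann$formula[ok], to = ann$formula[hit[ok]],
        transformation = trans$name[t],
        from_lower_mass = TRUE)
  }
  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(),
               transformation = character(), from_lower_mass = logical())
  vdf <- data.frame(name = ann$formula, mass = ann$mass,
                    c = ann$c, h = ann$h, o = ann$o, s = ann$s,
                    hc = ann$h / ann$c, oc = ann$o / ann$c,
                    first_detection_h = ann$first_detection_h,
                    degrees = ann$degrees)
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Fraction of network nodes connected to at least one other node
#'
#' @param net An `igraph` network from [build_network()].
#' @return Percentage (0-100) of nodes with degree >= 1.
#' @export
connectivity_fraction <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0) stop("connectivity of an empty network is undefined")
  100 * sum(igraph::degree(net) >= 1) / n
}

#' First detection time of each annotation
#'
#' @param detected Logical matrix (annotations x timepoints).
#' @param timepoints Timepoints in hours (column order of `detected`).
#' @return Numeric vector of first detection times; error if a row was never
#'   detected.
#' @export
first_detection_time <- function(detected, timepoints) {
  if (any(rowSums(detected) == 0))
    stop("annotation never detected at any timepoint")
  timepoints[apply(detected, 1, which.max)]
}

#' Per-timepoint heteroatom-class shares
#'
#' For every timepoint, the number and percentage of detected S-containing
#' annotations per sulfur count (shares among S-containing annotations), and
#' analogously oxygen-class shares among the CHO (sulfur-free) annotations.
#'
#' @param annotations Annotation data frame with element counts.
#' @param detected Logical matrix (rows matching `annotations`, columns
#'   timepoints).
#' @param timepoints Timepoints in hours.
#' @return List with data frames `sulfur` (`timepoint`, `s`, `n`, `pct`) and
#'   `oxygen` (`timepoint`, `o`, `n`, `pct`).
#' @export
sulfur_class_shares <- function(annotations, detected, timepoints) {
  stopifnot(nrow(annotations) == nrow(detected),
            ncol(detected) == length(timepoints))
  sulfur <- list(); oxygen <- list()
  for (j in seq_along(timepoints)) {
    idx <- which(detected[, j])
    s_ann <- annotations[idx, , drop = FALSE]
    s_ann <- s_ann[s_ann$s > 0, , drop = FALSE]
    if (nrow(s_ann)) {
      tab <- table(s_ann$s)
      sulfur[[length(sulfur) + 1L]] <- data.frame(
        timepoint = timepoints[j], s = as.integer(names(tab)),
        n = as.vector(tab, "integer"),
        pct = 100 * as.vector(tab, "integer") / nrow(s_ann))
    }
    o_ann <- annotations[idx, , drop = FALSE]
    o_ann <- o_ann[o_ann$s == 0, , drop = FALSE]
    if (nrow(o_ann)) {
      tab <- table(o_ann$o)
      oxygen[[length(oxygen) + 1L]] <- data.frame(
        timepoint = timepoints[j], o = as.integer(names(tab)),
        n = as.vector(tab, "integer"),
        pct = 100 * as.vector(tab, "integer") / nrow(o_ann))
    }
  }
  empty_s <- data.frame(timepoint = numeric(), s = integer(), n = integer(),
                        pct = numeric())
  empty_o <- data.frame(timepoint = numeric(), o = integer(), n = integer(),
                        pct = numeric())
  list(sulfur = if (length(sulfur)) do.call(rbind, sulfur) else empty_s,
       oxygen = if (length(oxygen)) do.call(rbind, oxygen) else empty_o)
}

#' Export the molecular network as GraphML
#'
#' @param net An `igraph` network from [build_network()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
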