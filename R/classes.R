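# Compound-class reasoning over heteroatom subspaces: per-degree saturation
# summaries, sodium-adduct logic for the CHO4 space, and detection of
# C2-homologous series.

#' Partition annotations into heteroatom subspaces
#'
#' Adds the (O, S) subspace key of the neutral composition; sodium is
#' ignored (adducts are evidence on the neutral composition).
#'
#' @param annotations Annotation data frame with element counts.
#' @return `annotations` with a `subspace` column (`"O3S0"`, `"O1S1"`, ...).
#' @export
partition_subspaces <- function(annotations) {
  annotations$subspace <- paste0("O", annotations$o, "S", annotations$s)
  annotations
}

#' Mean H/C ratio per labelling degree within a subspace
#'
#' Mixed annotations contribute to every degree they were called at. Degree
#' classes with no members are omitted.
#'
#' @param annotations Annotations of one subspace with list-column
#'   `label_degrees`.
#' @return Data frame: `degree`, `mean_hc`, `n`.
#' @export
mean_hc_by_degree <- function(annotations) {
  rows <- list()
  for (i in seq_len(nrow(annotations))) {
    for (k in annotations$label_degrees[[i]]) {
      rows[[length(rows) + 1L]] <-
        data.frame(degree = k, hc = annotations$h[i] / annotations$c[i])
    }
  }
  if (!length(rows))
    return(data.frame(degree = integer(), mean_hc = numeric(), n = integer()))
  df <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(df, df$degree), function(g)
    data.frame(degree = g$degree[1], mean_hc = mean(g$hc), n = nrow(g))))
  agg <- agg[order(agg$degree), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Default compound-class rules for the O4S0 subspace
#'
#' Degree-2 annotations with a sodium adduct are dicarboxylic-acid
#' candidates (a doubly deprotonated species retaining Na+ stays singly
#' charged); degree-2 without adduct are hydroxy-keto acid candidates;
#' degree-1 are dihydroxy acid candidates; degree-3 diketo acid candidates.
#' A single-label annotation with a sodium adduct contradicts the adduct
#' logic and is flagged as a rule violation.
#'
#' @return Data frame with columns `degree`, `na_adduct`, `class`,
#'   `violation`.
#' @export
cho4_class_rules <- function() {
  data.frame(
    degree = c(2L, 2L, 1L, 1L, 3L, 3L),
    na_adduct = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE),
    class = c("dicarboxylic-candidate", "hydroxy-keto-candidate",
              "dihydroxy-acid-candidate", "dihydroxy-acid-candidate",
              "diketo-acid-candidate", "diketo-acid-candidate"),
    violation = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE)
  )
}

#' Classify O4S0 annotations by labelling degree and sodium-adduct status
#'
#' Class labels are candidates, not identifications: exact-mass annotation
#' cannot fix functional-group positions. Mixed annotations receive one row
#' per called degree.
#'
#' @param annotations Annotations (one subspace, normally O4S0) with
#'   list-column `label_degrees` and logical `na_adduct`.
#' @param rules Rule table, see [cho4_class_rules()].
#' @return Data frame: `formula`, `degree`, `na_adduct`, `class`,
#'   `rule_violation`.
#' @export
na_adduct_classify <- function(annotations, rules = cho4_class_rules()) {
  rows <- list()
  for (i in seq_len(nrow(annotations))) {
    adduct <- isTRUE(annotations$na_adduct[i])
    for (k in annotations$label_degrees[[i]]) {
      hit <- rules[rules$degree == k & rules$na_adduct == adduct, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        formula = annotations$formula[i],
        degree = k,
        na_adduct = adduct,
        class = if (nrow(hit)) hit$class[1] else NA_character_,
        rule_violation = if (nrow(hit)) hit$violation[1] else FALSE
      )
    }
  }
  if (!length(rows))
    return(data.frame(formula = character(), degree = integer(),
                      na_adduct = logical(), class = character(),
                      rule_violation = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect C2-homologous series
#'
#' Maximal chains of compositions differing by repeated addition of the step
#' composition (default C2H2) within the same labelling degree. Each
#' composition belongs to at most one maximal chain per degree; chains of
#' length 1 are not series.
#'
#' @param annotations Annotation data frame with element counts and
#'   list-column `label_degrees` (annotations without degree calls can be
#'   searched with `degree = NA`).
#' @param step One-row composition data frame, default C2H2.
#' @return Data frame: `series_id`, `degree`, `formula`, `position` (1-based
#'   along the chain), `length`.
#' @export
detect_c2_series <- function(annotations, step = parse_formula("C2H2")) {
  has_deg <- "label_degrees" %in% names(annotations)
  expand <- list()
  for (i in seq_len(nrow(annotations))) {
    degs <- if (has_deg && length(annotations$label_degrees[[i]]))
      annotations$label_degrees[[i]] else NA_integer_
    for (k in degs)
      expand[[length(expand) + 1L]] <- cbind(
        annotations[i, c("formula", .comp_cols), drop = FALSE],
        data.frame(degree = k))
  }
  if (!length(expand))
    return(data.frame(series_id = integer(), degree = integer(),
                      formula = character(), position = integer(),
                      length = integer()))
  df <- do.call(rbind, expand)
  df <- df[!duplicated(paste(df$formula, df$degree)), , drop = FALSE]
  key <- function(c, h, o, s, deg) paste(c, h, o, s, deg, sep = "_")
  all_keys <- key(df$c, df$h, df$o, df$s, df$degree)
  pred_keys <- key(df$c - step$c, df$h - step$h, df$o - step$o,
                   df$s - step$s, df$degree)
  succ_keys <- key(df$c + step$c, df$h + step$h, df$o + step$o,
                   df$s + step$s, df$degree)
  has_pred <- pred_keys %in% all_keys
  heads <- which(!has_pred)
  out <- list()
  sid <- 0L
  for (hd in heads) {
    chain <- hd
    cur <- hd
    repeat {
      nxt <- match(succ_keys[cur], all_keys)
      if (is.na(nxt)) break
      chain <- c(chain, nxt)
      cur <- nxt
    }
    if (length(chain) < 2) next
    sid <- sid + 1L
    out[[sid]] <- data.frame(series_id = sid,
                             degree = df$degree[chain],
                             formula = df$formula[chain],
                             position = seq_along(chain),
                             length = length(chain))
  }
  if (!length(out))
    return(data.frame(series_id = integer(), degree = integer(),
                      formula = character(), position = integer(),
                      length = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
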