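#' Pairwise repertoire similarity score
#'
#' The number of unique productive CDR3 amino acid sequences shared by two
#' repertoires divided by the sum of their unique productive sequence
#' counts. The score is symmetric, lies in \[0, 0.5\], and equals 0.5 for
#' identical repertoires. Shared-set membership is binary: clone
#' frequencies are ignored. With `denominator = "union"` the Jaccard
#' variant (shared / union) is returned instead, for sensitivity analysis.
#'
#' @param a,b `trb_repertoire` objects (CDR3-filtered).
#' @param denominator "sum" (default) or "union".
#' @return numeric scalar.
#' @export
similarity_score <- function(a, b, denominator = c("sum", "union")) {
  denominator <- match.arg(denominator)
  sa <- names(productive_aa_counts(a))
  sb <- names(productive_aa_counts(b))
  if (!length(sa) && !length(sb)) {
    stop("both repertoires are empty of productive sequences")
  }
  shared <- length(intersect(sa, sb))
  if (denominator == "sum") {
    shared / (length(sa) + length(sb))
  } else {
    shared / length(union(sa, sb))
  }
}

#' Similarity matrix over a cohort
#'
#' Computes all pairwise similarity scores. PLHIV samples are ordered by
#' participant identifier and then collection date, followed by control
#' samples; each pair is labeled `within_participant`, `across_participant`
#' (two different PLHIV), `control_pair` (two controls) or `cross_cohort`.
#'
#' @param x a `trb_cohort` with at least two repertoires.
#' @param config an [analysis_config()]; supplies the CDR3 length filter
#'   and similarity denominator.
#' @return object of class `trb_similarity` with elements `sample_ids`,
#'   `values` (symmetric matrix, diagonal 0.5 for the "sum" denominator)
#'   and `labels` (character matrix).
#' @export
similarity_matrix <- function(x, config = analysis_config()) {
  st <- samples_table(x)
  if (nrow(st) < 2) stop("need at least two repertoires")
  is_ctrl <- st$group == "control"
  ord <- c(which(!is_ctrl)[str_order(st$participant_id[!is_ctrl],
                                     st$collection_date[!is_ctrl])],
           which(is_ctrl)[str_order(st$participant_id[is_ctrl],
                                    st$collection_date[is_ctrl])])
  st <- st[ord, , drop = FALSE]
  n <- nrow(st)
  sets <- lapply(st$sample_id, function(s) {
    names(productive_aa_counts(filter_cdr3(x$repertoires[[s]],
                                           config$min_cdr3_length)))
  })
  sizes <- lengths(sets)
  vals <- matrix(0, n, n, dimnames = list(st$sample_id, st$sample_id))
  labs <- matrix(NA_character_, n, n,
                 dimnames = list(st$sample_id, st$sample_id))
  use_sum <- config$similarity_denominator == "sum"
  for (i in seq_len(n)) {
    vals[i, i] <- if (sizes[i] > 0) 0.5 else NA_real_
    labs[i, i] <- "self"
    if (i == n) next
    for (j in seq((i + 1), n)) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      v <- if (use_sum) shared / (sizes[i] + sizes[j])
           else shared / length(union(sets[[i]], sets[[j]]))
      vals[i, j] <- vals[j, i] <- v
      lab <- if (st$participant_id[i] == st$participant_id[j]) {
        "within_participant"
      } else if (st$group[i] != "control" && st$group[j] != "control") {
        "across_participant"
      } else if (st$group[i] == "control" && st$group[j] == "control") {
        "control_pair"
      } else {
        "cross_cohort"
      }
      labs[i, j] <- labs[j, i] <- lab
    }
  }
  structure(list(sample_ids = st$sample_id, values = vals, labels = labs),
            class = "trb_similarity")
}

#' @export
print.trb_similarity <- function(x, ...) {
  cat("Pairwise repertoire similarity:", length(x$sample_ids), "samples\n")
  print(similarity_groups(x))
  invisible(x)
}

#' Summarize similarity scores by pair label
#'
#' Off-diagonal score distributions per pair label (within-participant,
#' across-participant, control pairs, cross-cohort), each pair counted
#' once.
#'
#' @param x a `trb_similarity`.
#' @return data.frame with per-label `n`, `median`, `mean`, `q25`, `q75`;
#'   attribute `distributions` holds the raw score vectors.
#' @export
similarity_groups <- function(x) {
  n <- length(x$sample_ids)
  ut <- upper.tri(x$values)
  labs <- x$labels[ut]
  vals <- x$values[ut]
  dist <- split(vals, labs)
  out <- data.frame(
    label = names(dist),
    n = lengths(dist),
    median = vapply(dist, median, 0),
    mean = vapply(dist, mean, 0),
    q25 = vapply(dist, quantile, 0, probs = 0.25, names = FALSE),
    q75 = vapply(dist, quantile, 0, probs = 0.75, names = FALSE),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "distributions") <- dist
  out
}
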