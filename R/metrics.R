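#' Analysis configuration
#'
#' Parameters for the depth-normalized repertoire analysis. Defaults mirror
#' the study design the package implements: repertoires are sampled down to
#' 5000 TRB nucleotide sequences, summary statistics are averaged over 100
#' downsampling iterations, CDR3 regions shorter than 7 amino acids are
#' discarded, samples with fewer than 5000 total sequences are excluded,
#' networks are built over the 5000 most frequent CDR3 amino acid
#' sequences, and clone tracking follows the 50 most abundant sequences.
#'
#' @param downsample_depth target total count per iteration.
#' @param downsample_iterations number of downsampling iterations averaged.
#' @param min_cdr3_length minimum CDR3 amino acid length retained.
#' @param min_repertoire_count QC threshold; repertoires with a total count
#'   strictly below it are excluded.
#' @param network_top_n clonotypes per repertoire entering the network.
#' @param track_top_n clonotypes per participant entering trajectories.
#' @param cumulative_ns N values for cumulative top-N clone frequencies.
#' @param rng_seed seed for the downsampling RNG (NULL uses the ambient
#'   stream).
#' @param similarity_denominator "sum" (the default: shared count divided by
#'   the sum of the two unique-sequence counts, maximum 0.5) or "union"
#'   (Jaccard, for sensitivity analysis).
#' @return object of class `trb_analysis_config`.
#' @export
analysis_config <- function(downsample_depth = 5000,
                            downsample_iterations = 100,
                            min_cdr3_length = 7,
                            min_repertoire_count = 5000,
                            network_top_n = 5000,
                            track_top_n = 50,
                            cumulative_ns = c(10, 100, 1000),
                            rng_seed = NULL,
                            similarity_denominator = c("sum", "union")) {
  cfg <- list(downsample_depth = as.integer(downsample_depth),
              downsample_iterations = as.integer(downsample_iterations),
              min_cdr3_length = as.integer(min_cdr3_length),
              min_repertoire_count = as.integer(min_repertoire_count),
              network_top_n = as.integer(network_top_n),
              track_top_n = as.integer(track_top_n),
              cumulative_ns = as.integer(cumulative_ns),
              rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
              similarity_denominator = match.arg(similarity_denominator))
  with(cfg, stopifnot(downsample_depth > 0, downsample_iterations > 0,
                      min_cdr3_length >= 1, min_repertoire_count > 0,
                      network_top_n > 0, track_top_n > 0,
                      all(cumulative_ns > 0)))
  structure(cfg, class = "trb_analysis_config")
}

#' Sequencing-depth QC filter
#'
#' A repertoire is excluded iff its total count is strictly less than the
#' configured minimum (default 5000): a sample with exactly 5000 sequences
#' is kept.
#'
#' @param x a `trb_repertoire`.
#' @param config an [analysis_config()].
#' @return list with `kept` (logical), `total_count`, and `reason` (NULL
#'   when kept).
#' @export
qc_filter_sample <- function(x, config = analysis_config()) {
  tc <- total_count(x)
  if (tc < config$min_repertoire_count) {
    list(kept = FALSE, total_count = tc,
         reason = sprintf("total count %d < %d", as.integer(tc),
                          config$min_repertoire_count))
  } else {
    list(kept = TRUE, total_count = tc, reason = NULL)
  }
}

#' CDR3 length filter
#'
#' Removes rearrangements whose CDR3 amino acid sequence is shorter than
#' `min_cdr3_length` residues; counts of retained rows are unchanged.
#'
#' @param x a `trb_repertoire`.
#' @param min_cdr3_length minimum length in amino acids (default 7), or an
#'   [analysis_config()].
#' @return a filtered `trb_repertoire`.
#' @export
filter_cdr3 <- function(x, min_cdr3_length = 7) {
  if (inherits(min_cdr3_length, "trb_analysis_config")) {
    min_cdr3_length <- min_cdr3_length$min_cdr3_length
  }
  r <- x$rearrangements
  x$rearrangements <- r[nchar(r$cdr3_aa) >= min_cdr3_length, , drop = FALSE]
  rownames(x$rearrangements) <- NULL
  x
}

#' Downsample a repertoire to a fixed depth
#'
#' Draws exactly `depth` sequence reads without replacement from the pool of
#' `total_count(x)` reads (multivariate hypergeometric over clones), then
#' re-aggregates over the CDR3 nucleotide sequence. When the repertoire has
#' exactly `depth` reads the input is returned unchanged.
#'
#' @param x a `trb_repertoire` with `total_count(x) >= depth`.
#' @param depth number of reads to draw.
#' @return a downsampled `trb_repertoire` whose counts sum to `depth`.
#' @export
downsample <- function(x, depth = 5000) {
  depth <- as.integer(depth)
  counts <- x$rearrangements$count
  tot <- sum(counts)
  if (tot < depth) {
    stop(sprintf("total_count %d is less than downsampling depth %d; %s",
                 as.integer(tot), depth,
                 "apply the QC filter before downsampling"))
  }
  if (tot == depth) return(x)
  # reads are labelled 1..tot in clone-block order; a uniform subset of
  # read labels induces multivariate hypergeometric clone counts
  drawn <- sample.int(tot, depth)
  bounds <- c(0, cumsum(counts))
  new_counts <- tabulate(findInterval(drawn - 0.5, bounds),
                         nbins = length(counts))
  r <- x$rearrangements
  r$count <- new_counts
  x$rearrangements <- aggregate_rearrangements(r[new_counts > 0, , drop = FALSE])
  x
}

#' Clonality score
#'
#' One minus the Shannon entropy of the clone frequency distribution
#' normalized by its maximum `ln R`: 0 for a perfectly even repertoire,
#' 1 for a monoclonal one. A single-clone repertoire returns 1 by
#' convention (the limit of maximal dominance; `ln 1 = 0` leaves the ratio
#' undefined).
#'
#' @param freqs frequency (or count) vector over unique clonotypes;
#'   normalized internally. Zeros are dropped.
#' @return dimensionless scalar in \[0, 1\].
#' @export
clonality <- function(freqs) {
  freqs <- freqs[!is.na(freqs)]
  if (!length(freqs)) stop("empty frequency vector")
  if (any(freqs < 0)) stop("negative frequencies")
  freqs <- freqs[freqs > 0]
  if (!length(freqs)) stop("all frequencies are zero")
  p <- freqs / sum(freqs)
  if (length(p) == 1L) return(1)
  h <- -sum(p * log(p))
  1 - h / log(length(p))
}

#' Gini coefficient of clone sizes
#'
#' Mean absolute difference form: `G = sum_ij |x_i - x_j| / (2 n sum(x))`,
#' 0 for perfectly even counts. Computed via the sorted-counts identity in
#' O(n log n).
#'
#' @param counts non-negative clone counts with a positive sum.
#' @return dimensionless scalar in \[0, 1).
#' @export
gini <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (!length(counts)) stop("empty count vector")
  if (any(counts < 0)) stop("negative counts")
  s <- sum(counts)
  if (s <= 0) stop("counts sum to zero")
  x <- sort(counts)
  n <- length(x)
  (2 * sum(seq_len(n) * x) - (n + 1) * s) / (n * s)
}

#' TRB sequence production efficiency
#'
#' The average number of distinct CDR3 nucleotide sequences encoding one
#' CDR3 amino acid sequence among productive rearrangements (convergent
#' recombination): unique productive nt count divided by unique productive
#' AA count. Nonproductive rows are ignored.
#'
#' @param x a `trb_repertoire` with at least one productive rearrangement.
#' @return numeric scalar >= 1.
#' @export
production_efficiency <- function(x) {
  r <- x$rearrangements[x$rearrangements$productive, , drop = FALSE]
  if (!nrow(r)) stop("repertoire has no productive rearrangements")
  length(unique(r$cdr3_nt)) / length(unique(r$cdr3_aa))
}

#' CDR3 amino acid length distribution
#'
#' Counts unique productive CDR3 amino acid sequences at each observed
#' length (template counts are ignored: two nucleotide variants of one AA
#' sequence contribute one). Also reports the unweighted median length over
#' unique sequences and the template-count-weighted median.
#'
#' @param x a `trb_repertoire` (normally CDR3-filtered).
#' @return list with `counts` (named integer vector keyed by length),
#'   `median_length` (over unique sequences) and `median_length_weighted`.
#' @export
length_distribution <- function(x) {
  pa <- productive_aa_counts(x)
  if (!length(pa)) {
    return(list(counts = setNames(integer(0), character(0)),
                median_length = NA_real_, median_length_weighted = NA_real_))
  }
  len <- nchar(names(pa))
  tab <- table(len)
  counts <- setNames(as.integer(tab), names(tab))
  list(counts = counts,
       median_length = median(len),
       median_length_weighted = median(rep(len, times = round(pa))))
}

#' Cumulative frequency of the top-N clonotypes
#'
#' For each N, the summed frequency of the N most frequent productive CDR3
#' amino acid clonotypes (all of them when fewer than N exist); ties at the
#' boundary are broken lexicographically.
#'
#' @param x a `trb_repertoire`.
#' @param ns integer vector of N values (default 10, 100, 1000).
#' @return named numeric vector, names are the N values; non-decreasing
#'   in N.
#' @export
cumulative_top_freq <- function(x, ns = c(10, 100, 1000)) {
  pa <- productive_aa_counts(x)
  if (!length(pa)) return(setNames(rep(NA_real_, length(ns)), ns))
  f <- cumsum(pa / sum(pa))
  setNames(vapply(ns, function(n) f[min(n, length(f))], 0), ns)
}

#' Depth-normalized repertoire summary
#'
#' Repeats `downsample_iterations` times: sample the repertoire down to
#' `downsample_depth` reads, apply the CDR3 length filter, and compute all
#' summary statistics; then report the arithmetic mean of every statistic
#' across iterations (unique counts therefore need not be integers).
#' Clonality, Gini, max clone frequency and cumulative top-N frequencies
#' operate on productive amino-acid clonotype frequencies; `unique_nt`
#' counts nucleotide keys; `gini_nt` is the Gini over nucleotide clone
#' counts, exposed alongside the amino-acid default. The full-repertoire
#' (not downsampled) unique productive AA count is reported separately as
#' `unique_productive_aa_full`.
#'
#' @param x a `trb_repertoire` that passed QC.
#' @param config an [analysis_config()]. When `rng_seed` is set the
#'   computation is reproducible and leaves the caller's RNG untouched.
#' @return object of class `trb_summary`.
#' @export
summarize_repertoire <- function(x, config = analysis_config()) {
  run <- function() {
    it <- config$downsample_iterations
    ns <- config$cumulative_ns
    acc <- list(unique_nt = 0, unique_productive_aa = 0, clonality = 0,
                gini = 0, gini_nt = 0, production_efficiency = 0,
                max_clone_freq = 0, median_length = 0)
    cum <- setNames(numeric(length(ns)), ns)
    len_acc <- list()
    for (i in seq_len(it)) {
      ds <- filter_cdr3(downsample(x, config$downsample_depth),
                        config$min_cdr3_length)
      pa <- productive_aa_counts(ds)
      if (!length(pa)) stop("no productive rearrangements after filtering")
      pf <- pa / sum(pa)
      acc$unique_nt <- acc$unique_nt + nrow(ds$rearrangements)
      acc$unique_productive_aa <- acc$unique_productive_aa + length(pa)
      acc$clonality <- acc$clonality + clonality(pf)
      acc$gini <- acc$gini + gini(pa)
      acc$gini_nt <- acc$gini_nt + gini(ds$rearrangements$count)
      acc$production_efficiency <- acc$production_efficiency +
        production_efficiency(ds)
      acc$max_clone_freq <- acc$max_clone_freq + pf[1]
      ld <- length_distribution(ds)
      acc$median_length <- acc$median_length + ld$median_length
      len_acc[[i]] <- ld$counts
      cum <- cum + cumulative_top_freq(ds, ns)
    }
    keys <- sort(unique(as.integer(unlist(lapply(len_acc, names)))))
    len_mean <- setNames(numeric(length(keys)), keys)
    for (l in len_acc) {
      len_mean[names(l)] <- len_mean[names(l)] + l
    }
    full <- filter_cdr3(x, config$min_cdr3_length)
    out <- lapply(acc, function(v) unname(v) / it)
    out$cumulative_top_freq <- cum / it
    out$length_distribution <- len_mean / it
    out$sample_id <- x$sample_id
    out$total_count <- total_count(x)
    out$unique_productive_aa_full <- length(productive_aa_counts(full))
    structure(out, class = "trb_summary")
  }
  if (is.null(config$rng_seed)) run() else {
    with_seed(derive_seed(config$rng_seed, hash_id(x$sample_id)), run())
  }
}

#' @export
print.trb_summary <- function(x, ...) {
  cat("Depth-normalized repertoire summary:", x$sample_id, "\n")
  cat(sprintf("  total count %s | unique productive AA (full) %d\n",
              format(x$total_count, big.mark = ","),
              x$unique_productive_aa_full))
  cat(sprintf("  mean over iterations: unique nt %.1f | unique AA %.1f\n",
              x$unique_nt, x$unique_productive_aa))
  cat(sprintf("  clonality %.4f | Gini %.4f | efficiency %.3f | max clone %.4f\n",
              x$clonality, x$gini, x$production_efficiency, x$max_clone_freq))
  cat("  cumulative top-N:",
      paste(sprintf("f(%s)=%.3f", names(x$cumulative_top_freq),
                    x$cumulative_top_freq), collapse = " "), "\n")
  invisible(x)
}

#' Depth-normalized summaries for a whole cohort
#'
#' Applies the QC filter and [summarize_repertoire()] to every sample.
#' Excluded samples are reported in the `excluded` attribute with the
#' recorded reason.
#'
#' @param x a `trb_cohort`.
#' @param config an [analysis_config()].
#' @return data.frame, one row per kept sample, with sample metadata and
#'   all summary statistics; cumulative top-N columns are named
#'   `cum_top_<N>`. Attribute `excluded` is a data.frame of dropped
#'   samples.
#' @export
cohort_metrics <- function(x, config = analysis_config()) {
  st <- samples_table(x)
  part <- x$participants[match(st$participant_id,
                               x$participants$participant_id), ]
  st$art_start_date <- part$art_start_date
  kept <- logical(nrow(st))
  reasons <- character(nrow(st))
  rows <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    rep_i <- x$repertoires[[st$sample_id[i]]]
    qc <- qc_filter_sample(rep_i, config)
    kept[i] <- qc$kept
    if (!qc$kept) {
      reasons[i] <- qc$reason
      next
    }
    s <- summarize_repertoire(rep_i, config)
    row <- data.frame(st[i, c("sample_id", "participant_id",
                              "collection_date", "group", "art_start_date")],
                      total_count = s$total_count,
                      unique_nt = s$unique_nt,
                      unique_productive_aa = s$unique_productive_aa,
                      unique_productive_aa_full = s$unique_productive_aa_full,
                      clonality = s$clonality,
                      gini = s$gini,
                      gini_nt = s$gini_nt,
                      production_efficiency = s$production_efficiency,
                      max_clone_freq = s$max_clone_freq,
                      median_cdr3_length = s$median_length,
                      stringsAsFactors = FALSE)
    cum <- as.list(s$cumulative_top_freq)
    names(cum) <- paste0("cum_top_", names(s$cumulative_top_freq))
    rows[[i]] <- cbind(row, as.data.frame(cum))
  }
  out <- do.call(rbind, rows[kept])
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  attr(out, "excluded") <- data.frame(
    sample_id = st$sample_id[!kept],
    total_count = vapply(st$sample_id[!kept],
                         function(s) total_count(x$repertoires[[s]]), 0),
    reason = reasons[!kept],
    stringsAsFactors = FALSE)
  out
}
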