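#' Holm-Bonferroni adjusted p-values
#'
#' Step-down adjustment with monotonicity enforcement, order-preserving in
#' the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
holm_bonferroni <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "holm")
}

# one rank-based two-group test; exact null for small samples without
# ties, normal approximation with continuity correction otherwise
.wilcox_row <- function(xa, xb, paired) {
  exact <- length(xa) <= 25 && length(xb) <= 25
  ht <- suppressWarnings(
    wilcox.test(xa, xb, paired = paired, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Compare repertoire metrics across sample groups
#'
#' For every metric and every pair of groups, an unpaired two-sided
#' Wilcoxon rank-sum (Mann-Whitney) test; optionally an additional paired
#' Wilcoxon signed-rank contrast of pre-ART vs post-ART within
#' participants, pairing each participant's pre sample closest to the ART
#' date with their post sample closest to it. All tests of one call form a
#' single family for the Holm-Bonferroni correction; a comparison is
#' significant when the adjusted p-value is below 0.05. The exact null
#' distribution is used for group sizes up to 25 (without ties), the
#' normal approximation with continuity correction otherwise.
#'
#' @param metrics data.frame from [cohort_metrics()] (or any table with a
#'   group column and numeric metric columns).
#' @param metric_cols character vector of metric column names.
#' @param group_col grouping column (default "group").
#' @param paired_pre_post also run the within-participant signed-rank
#'   contrast (needs `participant_id`, `collection_date`,
#'   `art_start_date` columns).
#' @return data.frame of class `trb_comparisons`: `metric`, `group_a`,
#'   `group_b`, `test` ("rank_sum" or "signed_rank"), `n_a`, `n_b`,
#'   `statistic`, `p_value`, `p_adjusted`, `significant`.
#' @export
compare_groups <- function(metrics, metric_cols, group_col = "group",
                           paired_pre_post = FALSE) {
  if (!group_col %in% names(metrics)) stop("no column '", group_col, "'")
  groups <- sort(unique(metrics[[group_col]]))
  if (length(groups) < 2) stop("need at least two groups")
  sizes <- table(metrics[[group_col]])
  if (any(sizes == 0)) stop("empty group")
  if (any(sizes < 2)) stop("every group needs at least two observations")
  rows <- list()
  for (metric in metric_cols) {
    if (!metric %in% names(metrics)) stop("no column '", metric, "'")
    for (pair in combn(groups, 2, simplify = FALSE)) {
      xa <- metrics[[metric]][metrics[[group_col]] == pair[1]]
      xb <- metrics[[metric]][metrics[[group_col]] == pair[2]]
      wt <- .wilcox_row(xa, xb, paired = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        metric = metric, group_a = pair[1], group_b = pair[2],
        test = "rank_sum", n_a = length(xa), n_b = length(xb),
        statistic = wt$statistic, p_value = wt$p_value,
        stringsAsFactors = FALSE)
    }
    if (paired_pre_post) {
      pp <- .paired_pre_post(metrics, metric, group_col)
      if (!is.null(pp)) rows[[length(rows) + 1]] <- pp
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_bonferroni(out$p_value)
  out$significant <- out$p_adjusted < 0.05
  rownames(out) <- NULL
  class(out) <- c("trb_comparisons", "data.frame")
  out
}

# pre/post samples nearest the ART date, one pair per participant
.paired_pre_post <- function(metrics, metric, group_col) {
  need <- c("participant_id", "collection_date", "art_start_date")
  if (!all(need %in% names(metrics))) return(NULL)
  pre <- metrics[metrics[[group_col]] == "pre", ]
  post <- metrics[metrics[[group_col]] == "post", ]
  pids <- intersect(pre$participant_id, post$participant_id)
  if (length(pids) < 2) return(NULL)
  pick <- function(df, pid) {
    d <- df[df$participant_id == pid, ]
    gap <- abs(as.numeric(d$collection_date - d$art_start_date))
    d[[metric]][which.min(gap)]
  }
  xa <- vapply(pids, function(p) pick(pre, p), 0)
  xb <- vapply(pids, function(p) pick(post, p), 0)
  wt <- .wilcox_row(xa, xb, paired = TRUE)
  data.frame(metric = metric, group_a = "pre", group_b = "post",
             test = "signed_rank", n_a = length(xa), n_b = length(xb),
             statistic = wt$statistic, p_value = wt$p_value,
             stringsAsFactors = FALSE)
}

#' @export
print.trb_comparisons <- function(x, ...) {
  cat("Group comparisons (Wilcoxon, Holm-Bonferroni corrected):\n")
  df <- as.data.frame(x)
  df$p_value <- signif(df$p_value, 3)
  df$p_adjusted <- signif(df$p_adjusted, 3)
  print(df)
  invisible(x)
}
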