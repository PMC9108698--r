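#' Most frequent amino-acid clonotypes of a repertoire
#'
#' The `n` highest-frequency productive CDR3 amino acid clonotypes, ties
#' broken lexicographically (the smaller sequence is kept); all clonotypes
#' when fewer than `n` exist.
#'
#' @param x a `trb_repertoire` (CDR3-filtered).
#' @param n number of clonotypes (default 5000).
#' @return character vector of CDR3 AA sequences.
#' @export
top_n_clonotypes <- function(x, n = 5000) {
  pa <- productive_aa_counts(x)
  names(pa)[seq_len(min(n, length(pa)))]
}

# All single-deletion variants of a set of strings, as a data.frame of
# (variant, source index, deleted position).
.deletion_variants <- function(strs) {
  L <- nchar(strs)
  idx <- rep(seq_along(strs), L)
  pos <- sequence(L)
  s <- strs[idx]
  data.frame(variant = paste0(substr(s, 1, pos - 1),
                              substr(s, pos + 1, nchar(s))),
             idx = idx, pos = pos, stringsAsFactors = FALSE)
}

# Enumerate unordered pairs within each key group (groups are cliques).
.pairs_within_groups <- function(keys, idx) {
  ok <- str_order(keys)
  k <- keys[ok]
  i <- idx[ok]
  r <- rle(k)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  res <- list()
  for (g in which(r$lengths > 1)) {
    members <- i[starts[g]:ends[g]]
    res[[length(res) + 1]] <- t(combn(members, 2))
  }
  if (!length(res)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, res)
}

#' Build the edit-distance-1 network of a clonotype set
#'
#' Nodes are unique CDR3 amino acid sequences; an edge connects two nodes
#' whose Levenshtein distance is exactly 1 (one substitution, insertion or
#' deletion, unit costs). Adjacency is found by length-bucketed
#' deletion-neighborhood hashing — substitution pairs share a
#' position-marked deletion key, indel pairs arise when one sequence equals
#' a single-deletion variant of another — which reproduces the quadratic
#' dynamic-programming adjacency exactly.
#'
#' @param clonotypes character vector of CDR3 AA sequences (deduplicated
#'   internally).
#' @return object of class `trb_network` with `nodes`, `edges` (data.frame
#'   `seq_a`, `seq_b`) and `degree` (named integer vector over all nodes,
#'   zeros included).
#' @export
build_network <- function(clonotypes) {
  nodes <- unique(as.character(clonotypes))
  n <- length(nodes)
  pairs <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    dv <- .deletion_variants(nodes)
    # substitutions: same length, identical after deleting the same position
    sub_keys <- paste0(dv$pos, "|", nchar(nodes)[dv$idx], "|", dv$variant)
    sub_pairs <- .pairs_within_groups(sub_keys, dv$idx)
    # indels: a node equals a deletion variant of a longer node
    vmap <- split(dv$idx, dv$variant)
    hit <- match(nodes, names(vmap))
    indel <- list()
    for (i in which(!is.na(hit))) {
      js <- unique(vmap[[hit[i]]])
      js <- js[js != i]
      if (length(js)) indel[[length(indel) + 1]] <- cbind(pmin(i, js),
                                                          pmax(i, js))
    }
    pairs <- rbind(sub_pairs,
                   if (length(indel)) do.call(rbind, indel)
                   else matrix(integer(0), ncol = 2))
    if (nrow(pairs)) {
      pairs <- cbind(pmin(pairs[, 1], pairs[, 2]),
                     pmax(pairs[, 1], pairs[, 2]))
      pairs <- pairs[!duplicated(paste(pairs[, 1], pairs[, 2])), ,
                     drop = FALSE]
      pairs <- pairs[str_order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    }
  }
  deg <- setNames(integer(n), nodes)
  if (nrow(pairs)) {
    tb <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = n)
    deg[] <- tb
  }
  structure(list(nodes = nodes,
                 edges = data.frame(seq_a = nodes[pairs[, 1]],
                                    seq_b = nodes[pairs[, 2]],
                                    stringsAsFactors = FALSE),
                 degree = deg),
            class = "trb_network")
}

#' @export
print.trb_network <- function(x, ...) {
  cat(sprintf("Edit-distance-1 CDR3 network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  cat(sprintf("  mean degree %.3f, max degree %d\n",
              if (length(x$degree)) mean(x$degree) else NA,
              if (length(x$degree)) max(x$degree) else NA))
  invisible(x)
}

#' Pooled degree distribution of a sample group
#'
#' Pools node degrees across the networks of one sample group (pre-ART,
#' post-ART or control; edges never cross repertoires) and reports, for
#' each degree k, the fraction of pooled nodes of that degree and the
#' complementary cumulative fraction P(degree >= k). A penalized-spline
#' smoother on log frequencies (smoothing parameter by generalized
#' cross-validation) provides the group trend curve in the spirit of a
#' generalized additive model regression line; it is omitted when too few
#' distinct degrees are observed.
#'
#' @param networks list of `trb_network` objects.
#' @param group label ("pre", "post", "control", or any string).
#' @param smooth fit the trend curve (default TRUE).
#' @return object of class `trb_degree_dist` with `group`, `table`
#'   (data.frame `k`, `frequency`, `ccdf`, `trend`), `per_network` (list of
#'   degree vectors, kept for bootstrapping) and `n_nodes`.
#' @export
degree_distribution <- function(networks, group = "all", smooth = TRUE) {
  if (!length(networks)) stop("need at least one network")
  per <- lapply(networks, function(nw) as.integer(nw$degree))
  pooled <- unlist(per)
  if (!length(pooled)) stop("networks contain no nodes")
  tab <- .degree_table(pooled)
  tab$trend <- NA_real_
  if (smooth) {
    pos <- tab$frequency > 0
    kk <- tab$k[pos]
    if (length(kk) >= 4) {
      basis <- max(3, min(10, length(kk) - 1))
      fit <- try(mgcv::gam(lf ~ s(k, k = basis),
                           data = data.frame(lf = log(tab$frequency[pos]),
                                             k = kk)),
                 silent = TRUE)
      if (!inherits(fit, "try-error")) {
        tab$trend <- exp(as.numeric(predict(fit,
                                            newdata = data.frame(k = tab$k))))
      }
    }
  }
  structure(list(group = group, table = tab, per_network = per,
                 n_nodes = length(pooled)),
            class = "trb_degree_dist")
}

.degree_table <- function(degrees) {
  kmax <- max(degrees)
  counts <- tabulate(degrees + 1L, nbins = kmax + 1L)
  freq <- counts / sum(counts)
  data.frame(k = 0:kmax, frequency = freq,
             ccdf = rev(cumsum(rev(freq))))
}

#' @export
print.trb_degree_dist <- function(x, ...) {
  cat(sprintf("Degree distribution [%s]: %d nodes pooled over %d network(s)\n",
              x$group, x$n_nodes, length(x$per_network)))
  print(head(x$table, 8))
  invisible(x)
}

# P(degree >= k) from a degree table; 1 below the support, 0 above it.
.ccdf_at <- function(dist, k) {
  tab <- dist$table
  if (k <= 0) return(1)
  if (k > max(tab$k)) return(0)
  tab$ccdf[match(k, tab$k)]
}

#' Compare degree-distribution tails between two groups
#'
#' Difference in the pooled complementary cumulative degree frequency at
#' `k_min` (fraction of nodes with degree >= k_min), `groupA - groupB`,
#' with a bootstrap percentile interval obtained by resampling repertoire
#' networks within each group.
#'
#' @param a,b `trb_degree_dist` objects.
#' @param k_min degree threshold (>= 0).
#' @param n_boot bootstrap replicates (default 200).
#' @param conf interval coverage (default 0.95).
#' @param seed optional RNG seed for the bootstrap.
#' @return list with `difference`, `k_min`, `ci` (length-2 vector) and the
#'   bootstrap replicates `boot`.
#' @export
compare_degree_tails <- function(a, b, k_min, n_boot = 200, conf = 0.95,
                                 seed = NULL) {
  if (k_min < 0) stop("k_min must be non-negative")
  point <- .ccdf_at(a, k_min) - .ccdf_at(b, k_min)
  boot_one <- function(per) {
    pick <- sample.int(length(per), replace = TRUE)
    pooled <- unlist(per[pick])
    mean(pooled >= k_min)
  }
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    boot_one(a$per_network) - boot_one(b$per_network)
  }, 0))
  alpha <- (1 - conf) / 2
  list(difference = point, k_min = k_min,
       ci = unname(quantile(boot, c(alpha, 1 - alpha))),
       boot = boot)
}
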