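#' Construct a TRB repertoire
#'
#' A repertoire is the collection of unique TRB CDR3 rearrangements detected
#' in one blood sample, aggregated over the CDR3 nucleotide sequence (the
#' clonal identity key), together with sample and participant identity.
#' Rows sharing a nucleotide sequence are merged by summing template counts.
#' Rows are stored in descending count order, ties broken lexicographically
#' by CDR3 amino acid and then nucleotide sequence, so that all downstream
#' tie-breaks are deterministic.
#'
#' @param rearrangements data.frame with columns `cdr3_nt`, `cdr3_aa`,
#'   `v_gene`, `j_gene`, `productive` (logical) and `count` (template count,
#'   at least 1 for every stored row; zero-count rows are dropped).
#' @param sample_id,participant_id character scalars.
#' @param collection_date a `Date` (may be NA for unanchored samples).
#' @return object of class `trb_repertoire` with elements `sample_id`,
#'   `participant_id`, `collection_date`, `rearrangements`.
#' @export
repertoire <- function(rearrangements, sample_id,
                       participant_id = sample_id,
                       collection_date = as.Date(NA)) {
  req <- c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene", "productive", "count")
  miss <- setdiff(req, names(rearrangements))
  if (length(miss)) {
    stop("rearrangements is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(rearrangements, stringsAsFactors = FALSE)[req]
  df$cdr3_nt <- toupper(as.character(df$cdr3_nt))
  df$cdr3_aa <- toupper(as.character(df$cdr3_aa))
  df$v_gene <- as.character(df$v_gene)
  df$j_gene <- as.character(df$j_gene)
  df$productive <- as.logical(df$productive)
  df$count <- as.numeric(df$count)
  if (nrow(df)) {
    if (anyNA(df$count) || any(df$count < 0)) {
      stop("negative or missing template count in rearrangement table")
    }
    df <- df[df$count >= 1, , drop = FALSE]
  }
  df <- aggregate_rearrangements(df)
  bad <- df$productive & grepl("*", df$cdr3_aa, fixed = TRUE)
  if (any(bad)) {
    stop("productive rearrangement contains a stop codon: ",
         df$cdr3_aa[which(bad)[1]])
  }
  bad_len <- df$productive & nchar(df$cdr3_nt) != 3L * nchar(df$cdr3_aa)
  if (any(bad_len)) {
    stop("productive rearrangement where nchar(cdr3_nt) != 3 * nchar(cdr3_aa): ",
         df$cdr3_aa[which(bad_len)[1]])
  }
  structure(list(sample_id = as.character(sample_id)[1],
                 participant_id = as.character(participant_id)[1],
                 collection_date = as.Date(collection_date),
                 rearrangements = df),
            class = "trb_repertoire")
}

# Merge duplicate cdr3_nt rows (sum counts, keep first annotation) and
# impose the canonical ordering.
aggregate_rearrangements <- function(df) {
  if (!nrow(df)) {
    rownames(df) <- NULL
    return(df)
  }
  if (anyDuplicated(df$cdr3_nt)) {
    tot <- rowsum(df$count, df$cdr3_nt)
    df <- df[!duplicated(df$cdr3_nt), , drop = FALSE]
    df$count <- tot[match(df$cdr3_nt, rownames(tot)), 1]
  }
  df <- df[str_order(-df$count, df$cdr3_aa, df$cdr3_nt), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Total template count of a repertoire
#'
#' The sum of the per-rearrangement template counts, i.e. the number of
#' sequenced T-cell genomes the sample yielded.
#' @param x a `trb_repertoire`.
#' @return numeric scalar.
#' @export
total_count <- function(x) sum(x$rearrangements$count)

#' Productive amino-acid clonotype counts
#'
#' Aggregates template counts of productive rearrangements over the CDR3
#' amino acid sequence. The result is sorted by descending count with
#' lexicographic tie-break, the ordering every top-N operation in the
#' package relies on.
#'
#' @param x a `trb_repertoire`.
#' @return named numeric vector (names are CDR3 AA sequences).
#' @export
productive_aa_counts <- function(x) {
  r <- x$rearrangements[x$rearrangements$productive, , drop = FALSE]
  if (!nrow(r)) return(setNames(numeric(0), character(0)))
  tot <- rowsum(r$count, r$cdr3_aa)
  v <- setNames(tot[, 1], rownames(tot))
  v[str_order(-v, names(v))]
}

#' @export
print.trb_repertoire <- function(x, ...) {
  cat("TRB repertoire", x$sample_id,
      sprintf("(participant %s, %s)\n", x$participant_id,
              format(x$collection_date)))
  pa <- productive_aa_counts(x)
  cat(sprintf("  %d unique CDR3 nt sequences, total count %s\n",
              nrow(x$rearrangements),
              format(total_count(x), big.mark = ",")))
  cat(sprintf("  %d unique productive CDR3 AA sequences\n", length(pa)))
  invisible(x)
}

#' @export
summary.trb_repertoire <- function(object, ...) {
  pa <- productive_aa_counts(object)
  out <- list(sample_id = object$sample_id,
              total_count = total_count(object),
              unique_nt = nrow(object$rearrangements),
              unique_productive_aa = length(pa),
              clonality = if (length(pa)) clonality(pa / sum(pa)) else NA_real_,
              gini = if (length(pa)) gini(pa) else NA_real_,
              max_clone_freq = if (length(pa)) max(pa) / sum(pa) else NA_real_)
  class(out) <- "summary.trb_repertoire"
  out
}

#' @export
print.summary.trb_repertoire <- function(x, ...) {
  cat("Repertoire", x$sample_id, "(full, not depth-normalized)\n")
  cat(sprintf("  total count %s | unique nt %d | unique productive AA %d\n",
              format(x$total_count, big.mark = ","), x$unique_nt,
              x$unique_productive_aa))
  cat(sprintf("  clonality %.4f | Gini %.4f | max clone freq %.4f\n",
              x$clonality, x$gini, x$max_clone_freq))
  invisible(x)
}

#' Assemble a cohort dataset
#'
#' Bundles repertoires with participant-level metadata: treatment group,
#' ART start date, MHC genotype and serial clinical measurements. Sample
#' group labels follow the convention that a sample is pre-ART iff its
#' collection date precedes the ART start date; control participants carry
#' no ART date.
#'
#' @param repertoires list of `trb_repertoire` objects.
#' @param participants data.frame with columns `participant_id`, `group`
#'   ("plhiv" or "control") and `art_start_date` (`Date`, NA for controls).
#' @param mhc named list mapping participant_id to a character vector of
#'   HLA allele names.
#' @param clinical optional data.frame with columns `participant_id`,
#'   `date`, `viral_load` (copies/mL) and `cd4_count` (cells/uL).
#' @return object of class `trb_cohort`.
#' @export
cohort <- function(repertoires, participants, mhc = list(), clinical = NULL) {
  stopifnot(is.list(repertoires))
  names(repertoires) <- vapply(repertoires, function(r) r$sample_id, "")
  if (anyDuplicated(names(repertoires))) stop("duplicate sample_id in cohort")
  participants <- as.data.frame(participants, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "art_start_date")
  miss <- setdiff(need, names(participants))
  if (length(miss)) stop("participants missing column(s): ",
                         paste(miss, collapse = ", "))
  participants$art_start_date <- as.Date(participants$art_start_date)
  pids <- vapply(repertoires, function(r) r$participant_id, "")
  unknown <- setdiff(pids, participants$participant_id)
  if (length(unknown)) {
    stop("repertoire participant(s) absent from participants table: ",
         paste(unique(unknown), collapse = ", "))
  }
  ctrl <- participants$group == "control"
  if (any(ctrl & !is.na(participants$art_start_date))) {
    stop("control participants must not carry an ART start date")
  }
  structure(list(repertoires = repertoires,
                 participants = participants,
                 mhc = mhc,
                 clinical = clinical,
                 truth = NULL),
            class = "trb_cohort")
}

#' Per-sample table of a cohort
#'
#' One row per repertoire with participant, collection date and derived
#' group label ("pre", "post" or "control").
#' @param x a `trb_cohort`.
#' @return data.frame.
#' @export
samples_table <- function(x) {
  reps <- x$repertoires
  df <- data.frame(
    sample_id = vapply(reps, function(r) r$sample_id, ""),
    participant_id = vapply(reps, function(r) r$participant_id, ""),
    collection_date = as.Date(vapply(reps, function(r)
      as.character(r$collection_date), "")),
    stringsAsFactors = FALSE)
  pm <- x$participants[match(df$participant_id, x$participants$participant_id), ]
  grp <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (pm$group[i] == "control") {
      grp[i] <- "control"
    } else {
      if (is.na(pm$art_start_date[i])) {
        stop("PLHIV participant ", df$participant_id[i],
             " has no ART start date; cannot assign pre/post label")
      }
      grp[i] <- if (df$collection_date[i] < pm$art_start_date[i]) "pre" else "post"
    }
  }
  df$group <- grp
  rownames(df) <- NULL
  df
}

#' @export
print.trb_cohort <- function(x, ...) {
  st <- samples_table(x)
  cat("TRB cohort:", nrow(x$participants), "participants,",
      nrow(st), "repertoires\n")
  print(table(st$group))
  invisible(x)
}

#' Combine two cohorts
#'
#' Typically a PLHIV cohort and a control cohort generated separately.
#' Sample and participant identifiers must not clash.
#' @param a,b `trb_cohort` objects.
#' @return a `trb_cohort`.
#' @export
combine_cohorts <- function(a, b) {
  if (length(intersect(names(a$repertoires), names(b$repertoires)))) {
    stop("cohorts share sample identifiers")
  }
  if (length(intersect(a$participants$participant_id,
                       b$participants$participant_id))) {
    stop("cohorts share participant identifiers")
  }
  out <- cohort(c(a$repertoires, b$repertoires),
                rbind(a$participants, b$participants),
                mhc = c(a$mhc, b$mhc),
                clinical = rbind(a$clinical, b$clinical))
  out$truth <- list(a = a$truth, b = b$truth)
  out
}
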