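# Longitudinal clone tracking, database annotation with MHC-restriction
# filtering, specificity-group propagation, and candidate-public clonotype
# discovery. Presence for tracking and public-clonotype detection is
# assessed on full (non-downsampled) repertoires: downsampling is a
# depth-normalization device for summary statistics, not a detection
# filter.

# frequency matrix (productive AA x timepoint) over a participant's
# serial repertoires, sorted by collection date
.clone_freq_matrix <- function(reps) {
  dates <- as.Date(vapply(reps, function(r) as.character(r$collection_date),
                          ""))
  if (anyNA(dates)) stop("all repertoires need a collection date")
  reps <- reps[order(dates)]
  dates <- sort(dates)
  freqs <- lapply(reps, function(r) {
    pa <- productive_aa_counts(r)
    pa / sum(pa)
  })
  all_aa <- sort(unique(unlist(lapply(freqs, names))))
  m <- matrix(0, length(all_aa), length(reps),
              dimnames = list(all_aa, vapply(reps, function(r) r$sample_id,
                                             "")))
  for (j in seq_along(freqs)) m[names(freqs[[j]]), j] <- freqs[[j]]
  attr(m, "dates") <- dates
  m
}

#' Track the most abundant clones of a participant
#'
#' Selects the `n` amino-acid clonotypes with the highest maximum frequency
#' across the participant's serial repertoires (so exactly `n` trajectories
#' are followed, as an alluvial plot displays) and emits their full
#' frequency trajectories, zeros included. Each clone is labeled
#' `first_observed = "pre_art"` iff its earliest nonzero frequency precedes
#' the ART start date.
#'
#' @param reps list of `trb_repertoire` objects from one participant, at
#'   least two timepoints.
#' @param art_date the participant's ART start date (`Date`). Pass `NULL`
#'   for a control participant (first_observed becomes NA); a missing
#'   (`NA`) date for a treated participant is an error.
#' @param n number of clones to track (default 50).
#' @return data.frame of class `trb_trajectories`: `participant_id`,
#'   `cdr3_aa`, `collection_date`, `frequency`, `first_observed`, `label`
#'   (initialized to "private"; see [label_trajectories()]).
#' @export
track_top_clones <- function(reps, art_date, n = 50) {
  if (length(reps) < 2) stop("need at least two timepoints")
  if (!is.null(art_date) && is.na(art_date)) {
    stop("ART start date is required to assign pre/post labels; ",
         "pass NULL for control participants")
  }
  pid <- unique(vapply(reps, function(r) r$participant_id, ""))
  if (length(pid) != 1) stop("repertoires come from different participants")
  m <- .clone_freq_matrix(reps)
  dates <- attr(m, "dates")
  maxf <- apply(m, 1, max)
  sel <- rownames(m)[str_order(-maxf, rownames(m))][seq_len(min(n, nrow(m)))]
  first_date <- as.Date(vapply(sel, function(aa)
    as.character(dates[which(m[aa, ] > 0)[1]]), ""))
  first_obs <- if (is.null(art_date)) {
    rep(NA_character_, length(sel))
  } else {
    ifelse(first_date < art_date, "pre_art", "post_art")
  }
  out <- data.frame(
    participant_id = pid,
    cdr3_aa = rep(sel, each = ncol(m)),
    collection_date = rep(dates, times = length(sel)),
    frequency = as.vector(t(m[sel, , drop = FALSE])),
    first_observed = rep(first_obs, each = ncol(m)),
    label = "private",
    stringsAsFactors = FALSE)
  class(out) <- c("trb_trajectories", "data.frame")
  out
}

#' Track top clones for every eligible participant of a cohort
#'
#' @param x a `trb_cohort`.
#' @param n clones per participant (default 50).
#' @return combined `trb_trajectories` data.frame over all PLHIV
#'   participants with at least two timepoints.
#' @export
track_cohort <- function(x, n = 50) {
  st <- samples_table(x)
  out <- list()
  for (pid in unique(st$participant_id)) {
    rows <- st[st$participant_id == pid, ]
    if (nrow(rows) < 2) next
    part <- x$participants[x$participants$participant_id == pid, ]
    if (part$group == "control") next
    if (is.na(part$art_start_date)) {
      stop("PLHIV participant ", pid, " has no ART start date")
    }
    out[[pid]] <- track_top_clones(x$repertoires[rows$sample_id],
                                   part$art_start_date, n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("trb_trajectories", "data.frame")
  res
}

.bind_dbs <- function(dbs) {
  if (is.data.frame(dbs)) return(dbs)
  do.call(rbind, dbs)
}

#' Annotate a CDR3 sequence against reference databases
#'
#' Exact amino-acid match against annotated-clonotype databases. A match is
#' MHC-consistent iff the participant's genotype contains the record's
#' restricting allele (family-level database entries match any allele of
#' the family). The returned label is the antigen source of the consistent
#' matches ("CMV", "EBV", "HIV" or "other_public"); when the same CDR3 is
#' annotated to several pathogens the source with the most consistent
#' records wins and ties fall to "other_public". Matches that fail the MHC
#' filter are still reported but contribute no label.
#'
#' @param cdr3_aa a CDR3 amino acid sequence.
#' @param participant_alleles the participant's HLA alleles.
#' @param dbs annotation data.frame (or list of them) from
#'   [read_annotation_db()].
#' @param enforce_mhc apply the MHC-consistency filter (default TRUE).
#' @return list with `label` (NA when no qualifying match), `matches`
#'   (data.frame of all matching records) and `mhc_consistent` (logical
#'   per match).
#' @export
annotate_cdr3 <- function(cdr3_aa, participant_alleles, dbs,
                          enforce_mhc = TRUE) {
  db <- .bind_dbs(dbs)
  hits <- db[db$cdr3_aa == toupper(cdr3_aa), , drop = FALSE]
  if (!nrow(hits)) {
    return(list(label = NA_character_,
                matches = hits, mhc_consistent = logical(0)))
  }
  consistent <- vapply(hits$mhc_allele, function(a) {
    nzchar(a) && hla_match(a, participant_alleles)
  }, TRUE, USE.NAMES = FALSE)
  use <- if (enforce_mhc) consistent else rep(TRUE, nrow(hits))
  label <- NA_character_
  if (any(use)) {
    src <- hits$antigen_source[use]
    tab <- sort(table(src), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    label <- if (length(top) > 1) "other_public"
             else if (top == "other") "other_public" else top
  }
  list(label = label, matches = hits, mhc_consistent = consistent)
}

#' Propagate database annotation through specificity groups
#'
#' A specificity group is seeded when at least one member carries a direct
#' database annotation. Seeded groups are then filtered by the predicted
#' MHC restriction: the group is kept only when its predicted allele is
#' compatible with a seeding record's allele and is carried by the
#' participant. Unseeded members of kept groups receive
#' `likely_<source>` labels ("likely_CMV", "likely_EBV", "likely_HIV",
#' "likely_other"); a member supported by conflicting sources falls to
#' "likely_other".
#'
#' @param groups a `trb_specificity_groups` list ([read_gliph_groups()]).
#' @param dbs annotation data.frame(s).
#' @param participant_alleles the participant's HLA alleles.
#' @return named character vector mapping member CDR3s (those without a
#'   direct annotation) to likely labels; empty when nothing propagates.
#' @export
propagate_specificity <- function(groups, dbs, participant_alleles) {
  db <- .bind_dbs(dbs)
  votes <- list()
  for (g in groups) {
    seeded <- db[db$cdr3_aa %in% g$member_cdr3s, , drop = FALSE]
    if (!nrow(seeded)) next
    if (!nzchar(g$predicted_mhc)) next
    compat <- vapply(seeded$mhc_allele, function(a)
      nzchar(a) && hla_compatible(g$predicted_mhc, a), TRUE,
      USE.NAMES = FALSE)
    if (!any(compat)) next
    if (!hla_match(g$predicted_mhc, participant_alleles)) next
    sources <- seeded$antigen_source[compat]
    unseeded <- setdiff(g$member_cdr3s, db$cdr3_aa)
    for (aa in unseeded) votes[[aa]] <- c(votes[[aa]], sources)
  }
  if (!length(votes)) return(setNames(character(0), character(0)))
  out <- vapply(votes, function(src) {
    tab <- sort(table(src), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1 || top == "other") "likely_other"
    else paste0("likely_", top)
  }, "")
  out
}

#' Find candidate public clonotypes
#'
#' Productive CDR3 amino acid sequences observed (template count at least
#' `min_count`) in the repertoires of two or more PLHIV participants but
#' absent from the annotation databases. For each candidate the per-carrier
#' detection fraction (repertoires detected / repertoires total) and the
#' HLA alleles shared by all carriers are reported.
#'
#' @param x a `trb_cohort`.
#' @param dbs annotation data.frame(s); pass an empty data.frame when no
#'   database is available.
#' @param min_count minimum template count for "observed" (default 1, i.e.
#'   any nonzero detection).
#' @return data.frame of class `trb_public_candidates`: `cdr3_aa`,
#'   `n_carriers`, list-columns `carriers`, `detection` (named fractions)
#'   and `shared_alleles`.
#' @export
find_public_candidates <- function(x, dbs = NULL, min_count = 1) {
  st <- samples_table(x)
  plhiv <- st[st$group != "control", , drop = FALSE]
  by_part <- split(plhiv$sample_id, plhiv$participant_id)
  presence <- lapply(by_part, function(sids) {
    tabs <- lapply(sids, function(s) {
      r <- x$repertoires[[s]]$rearrangements
      r <- r[r$productive & r$count >= min_count, , drop = FALSE]
      unique(r$cdr3_aa)
    })
    tabs
  })
  part_sets <- lapply(presence, function(tabs) unique(unlist(tabs)))
  carrier_counts <- table(unlist(part_sets))
  cand <- names(carrier_counts)[carrier_counts >= 2]
  if (!is.null(dbs)) {
    db <- .bind_dbs(dbs)
    if (nrow(db)) cand <- setdiff(cand, db$cdr3_aa)
  }
  cand <- sort(cand)
  rows <- lapply(cand, function(aa) {
    carriers <- names(part_sets)[vapply(part_sets, function(s) aa %in% s,
                                        TRUE)]
    det <- vapply(carriers, function(p) {
      mean(vapply(presence[[p]], function(s) aa %in% s, TRUE))
    }, 0)
    shared <- Reduce(intersect, x$mhc[carriers])
    list(aa = aa, carriers = carriers, det = det,
         shared = if (is.null(shared)) character(0) else shared)
  })
  out <- data.frame(
    cdr3_aa = vapply(rows, function(r) r$aa, ""),
    n_carriers = vapply(rows, function(r) length(r$carriers), 0L),
    stringsAsFactors = FALSE)
  out$carriers <- lapply(rows, function(r) r$carriers)
  out$detection <- lapply(rows, function(r) r$det)
  out$shared_alleles <- lapply(rows, function(r) r$shared)
  out <- out[str_order(-out$n_carriers, out$cdr3_aa), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trb_public_candidates", "data.frame")
  out
}

#' Apply the full label precedence to clone trajectories
#'
#' Direct database match (MHC-consistent) beats a propagated likely-label,
#' which beats candidate-public status, which beats private. Every clone
#' holds exactly one label.
#'
#' @param traj a `trb_trajectories` data.frame.
#' @param x the `trb_cohort` the trajectories came from.
#' @param dbs annotation data.frame(s).
#' @param groups optional `trb_specificity_groups`.
#' @param min_count passed to [find_public_candidates()].
#' @return `traj` with the `label` column filled.
#' @export
label_trajectories <- function(traj, x, dbs, groups = NULL, min_count = 1) {
  cand <- find_public_candidates(x, dbs, min_count)$cdr3_aa
  for (pid in unique(traj$participant_id)) {
    alleles <- x$mhc[[pid]]
    idx <- traj$participant_id == pid
    aas <- unique(traj$cdr3_aa[idx])
    likely <- if (!is.null(groups)) {
      propagate_specificity(groups, dbs, alleles)
    } else setNames(character(0), character(0))
    lab <- vapply(aas, function(aa) {
      direct <- annotate_cdr3(aa, alleles, dbs)$label
      if (!is.na(direct)) return(direct)
      if (aa %in% names(likely)) return(likely[[aa]])
      if (aa %in% cand) return("candidate_public")
      "private"
    }, "")
    traj$label[idx] <- lab[match(traj$cdr3_aa[idx], aas)]
  }
  traj
}

#' Summed frequency of database-annotated sequences per repertoire
#'
#' For every repertoire, the summed frequency of productive clonotypes with
#' a database match, split by antigen source and by whether MHC consistency
#' is enforced. Rows are emitted for every source so that group
#' comparisons see zeros. Enforcing MHC consistency can only remove
#' matches, never add them.
#'
#' @param x a `trb_cohort`.
#' @param dbs annotation data.frame(s).
#' @return data.frame: `sample_id`, `participant_id`, `group`,
#'   `antigen_source`, `mhc_enforced`, `frequency`.
#' @export
annotated_abundance_by_group <- function(x, dbs) {
  db <- .bind_dbs(dbs)
  st <- samples_table(x)
  sources <- c("CMV", "EBV", "HIV", "other")
  rows <- list()
  for (i in seq_len(nrow(st))) {
    pa <- productive_aa_counts(x$repertoires[[st$sample_id[i]]])
    pf <- pa / sum(pa)
    alleles <- x$mhc[[st$participant_id[i]]]
    hits <- db[db$cdr3_aa %in% names(pf), , drop = FALSE]
    consistent <- if (nrow(hits)) vapply(hits$mhc_allele, function(a)
      nzchar(a) && hla_match(a, alleles), TRUE, USE.NAMES = FALSE)
      else logical(0)
    for (enforce in c(FALSE, TRUE)) {
      use <- if (enforce) hits[consistent, , drop = FALSE] else hits
      for (src in sources) {
        aa_src <- unique(use$cdr3_aa[use$antigen_source == src])
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = st$sample_id[i],
          participant_id = st$participant_id[i],
          group = st$group[i],
          antigen_source = src,
          mhc_enforced = enforce,
          frequency = sum(pf[aa_src]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
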