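# Column maps for the two tabular rearrangement dialects the pipeline
# accepts. The productive/frame flag is optional in both: when the column is
# absent, productivity is computed as "no stop codon and nt length divisible
# by 3".
.dialect_maps <- list(
  immunoseq = list(
    cdr3_nt = "nucleotide",
    cdr3_aa = "aminoAcid",
    count_templates = c("count (templates/reads)", "templates", "count"),
    count_reads = c("reads", "count (templates/reads)", "count"),
    v_gene = "vGeneName",
    j_gene = "jGeneName",
    productive = "sequenceStatus"),
  airr = list(
    cdr3_nt = "junction",
    cdr3_aa = "junction_aa",
    count_templates = "duplicate_count",
    count_reads = "duplicate_count",
    v_gene = "v_call",
    j_gene = "j_call",
    productive = "productive")
)

.pick_col <- function(tab, candidates, what, dialect) {
  hit <- candidates[candidates %in% names(tab)]
  if (!length(hit)) {
    stop(sprintf("%s table is missing required column '%s'",
                 dialect, candidates[1]))
  }
  hit[1]
}

#' Read a rearrangement table into a repertoire
#'
#' Reads one tab-separated rearrangement table (immunoSEQ export dialect or
#' AIRR rearrangement format), validates it, aggregates rows over the CDR3
#' nucleotide sequence and returns a [repertoire()].
#'
#' @param path file path.
#' @param dialect "immunoseq" or "airr".
#' @param sample_id defaults to the file name without extension.
#' @param participant_id,collection_date passed to [repertoire()].
#' @param count_source "templates" (default) or "reads"; selects the count
#'   column where an immunoSEQ export carries both.
#' @return a `trb_repertoire`.
#' @export
read_rearrangement_table <- function(path,
                                     dialect = c("immunoseq", "airr"),
                                     sample_id = NULL,
                                     participant_id = NULL,
                                     collection_date = as.Date(NA),
                                     count_source = c("templates", "reads")) {
  dialect <- match.arg(dialect)
  count_source <- match.arg(count_source)
  if (!file.exists(path)) stop("file does not exist: ", path)
  map <- .dialect_maps[[dialect]]
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  nt_col <- .pick_col(tab, map$cdr3_nt, "cdr3_nt", dialect)
  aa_col <- .pick_col(tab, map$cdr3_aa, "cdr3_aa", dialect)
  cnt_col <- .pick_col(tab,
                       if (count_source == "templates") map$count_templates
                       else map$count_reads,
                       "count", dialect)
  v_col <- .pick_col(tab, map$v_gene, "v_gene", dialect)
  j_col <- .pick_col(tab, map$j_gene, "j_gene", dialect)
  cnt <- suppressWarnings(as.numeric(tab[[cnt_col]]))
  if (nrow(tab) && (anyNA(cnt) || any(cnt < 0))) {
    stop("negative or non-numeric count in column '", cnt_col, "'")
  }
  aa <- toupper(tab[[aa_col]])
  nt <- toupper(tab[[nt_col]])
  if (map$productive %in% names(tab)) {
    pr_raw <- tab[[map$productive]]
    productive <- if (dialect == "immunoseq") {
      pr_raw == "In"
    } else {
      toupper(pr_raw) %in% c("T", "TRUE", "1")
    }
  } else {
    productive <- !grepl("*", aa, fixed = TRUE) & nchar(nt) %% 3L == 0L
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (is.null(participant_id)) participant_id <- sample_id
  repertoire(data.frame(cdr3_nt = nt, cdr3_aa = aa,
                        v_gene = tab[[v_col]], j_gene = tab[[j_col]],
                        productive = productive, count = cnt,
                        stringsAsFactors = FALSE),
             sample_id = sample_id, participant_id = participant_id,
             collection_date = collection_date)
}

#' Write a repertoire as a rearrangement table
#'
#' Inverse of [read_rearrangement_table()]: re-reading the written file
#' reproduces the repertoire exactly (counts and sequences bit-identical).
#'
#' @param x a `trb_repertoire`.
#' @param path output file path.
#' @param dialect "immunoseq" or "airr".
#' @export
write_rearrangement_table <- function(x, path,
                                      dialect = c("immunoseq", "airr")) {
  dialect <- match.arg(dialect)
  r <- x$rearrangements
  out <- if (dialect == "immunoseq") {
    data.frame(
      nucleotide = r$cdr3_nt,
      aminoAcid = r$cdr3_aa,
      `count (templates/reads)` = r$count,
      vGeneName = r$v_gene,
      jGeneName = r$j_gene,
      sequenceStatus = ifelse(r$productive, "In",
                              ifelse(grepl("*", r$cdr3_aa, fixed = TRUE),
                                     "Stop", "Out")),
      check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    data.frame(
      junction = r$cdr3_nt,
      junction_aa = r$cdr3_aa,
      duplicate_count = r$count,
      v_call = r$v_gene,
      j_call = r$j_gene,
      productive = ifelse(r$productive, "T", "F"),
      stringsAsFactors = FALSE)
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write rearrangement table to ", path)
  invisible(path)
}

.antigen_source <- function(x) {
  x <- as.character(x)
  out <- rep("other", length(x))
  out[grepl("CMV|cytomegalo|HHV-?5", x, ignore.case = TRUE)] <- "CMV"
  out[grepl("EBV|epstein|HHV-?4", x, ignore.case = TRUE)] <- "EBV"
  out[grepl("HIV|human immunodef", x, ignore.case = TRUE)] <- "HIV"
  out
}

.db_column_maps <- list(
  vdjdb = list(cdr3 = c("cdr3", "CDR3"),
               species = c("antigen.species", "Antigen species"),
               epitope = c("antigen.epitope", "Epitope"),
               mhc = c("mhc.a", "MHC A")),
  mcpas = list(cdr3 = "CDR3.beta.aa",
               species = "Pathology",
               epitope = "Epitope.peptide",
               mhc = "MHC"),
  generic = list(cdr3 = "cdr3_aa",
                 species = "antigen_source",
                 epitope = "epitope",
                 mhc = "mhc_allele")
)

#' Read an annotated-clonotype database
#'
#' Loads a VDJdb or McPAS-TCR style TSV export of annotated TRB CDR3
#' sequences. MHC allele names are normalized to two-field resolution; the
#' original string is retained in `mhc_raw`. Unparseable HLA strings are
#' kept with an empty `mhc_allele` and a warning. Duplicate records (same
#' CDR3, epitope, normalized MHC and database) are collapsed.
#'
#' @param path TSV file path.
#' @param db_name "vdjdb", "mcpas", or "generic" (columns `cdr3_aa`,
#'   `antigen_source`, `epitope`, `mhc_allele`).
#' @return data.frame with columns `cdr3_aa`, `antigen_source` (CMV, EBV,
#'   HIV or other), `epitope`, `mhc_allele`, `mhc_raw`, `db_name`.
#' @export
read_annotation_db <- function(path, db_name = c("vdjdb", "mcpas", "generic")) {
  db_name <- match.arg(db_name)
  if (!file.exists(path)) stop("file does not exist: ", path)
  map <- .db_column_maps[[db_name]]
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  empty <- data.frame(cdr3_aa = character(0), antigen_source = character(0),
                      epitope = character(0), mhc_allele = character(0),
                      mhc_raw = character(0), db_name = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(tab)) return(empty)
  cdr3_col <- .pick_col(tab, map$cdr3, "cdr3", db_name)
  mhc_col <- .pick_col(tab, map$mhc, "mhc", db_name)
  sp_col <- map$species[map$species %in% names(tab)][1]
  ep_col <- map$epitope[map$epitope %in% names(tab)][1]
  if ("gene" %in% names(tab)) tab <- tab[tab$gene %in% c("TRB", ""), , drop = FALSE]
  if (!nrow(tab)) return(empty)
  parsed <- hla_parse(tab[[mhc_col]])
  if (any(!parsed$valid)) {
    warning(sum(!parsed$valid), " record(s) with unparseable HLA string kept",
            " with empty mhc_allele")
  }
  rec <- data.frame(
    cdr3_aa = toupper(tab[[cdr3_col]]),
    antigen_source = if (!is.na(sp_col)) .antigen_source(tab[[sp_col]])
                     else rep("other", nrow(tab)),
    epitope = if (!is.na(ep_col)) toupper(tab[[ep_col]]) else "",
    mhc_allele = ifelse(parsed$valid, parsed$two_field, ""),
    mhc_raw = tab[[mhc_col]],
    db_name = db_name,
    stringsAsFactors = FALSE)
  rec <- rec[nzchar(rec$cdr3_aa), , drop = FALSE]
  key <- paste(rec$cdr3_aa, rec$epitope, rec$mhc_allele, rec$db_name, sep = "\r")
  rec <- rec[!duplicated(key), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Read GLIPH2-style specificity groups
#'
#' Parses a cluster file in GLIPH2 output layout: one line per specificity
#' group, tab-separated columns for the group identifier (motif), the
#' predicted MHC restriction (may be empty) and the member CDR3 amino acid
#' sequences (space/comma separated). Malformed lines are skipped with a
#' warning reporting their number.
#'
#' @param path TSV file path with header columns `group_id` (or `pattern` /
#'   `index`), `predicted_mhc` (or `HLA`), `members` (or `TcRb`).
#' @return list of specificity groups, each a list with `group_id`,
#'   `member_cdr3s` (uppercased character vector) and `predicted_mhc`.
#' @export
read_gliph_groups <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  tab <- tryCatch(
    read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
               colClasses = "character", fill = TRUE),
    error = function(e) NULL)
  if (is.null(tab) || !nrow(tab)) return(structure(list(),
                                                   class = "trb_specificity_groups"))
  id_col <- intersect(c("group_id", "pattern", "index"), names(tab))[1]
  mhc_col <- intersect(c("predicted_mhc", "HLA", "hla"), names(tab))[1]
  mem_col <- intersect(c("members", "TcRb", "member_cdr3s"), names(tab))[1]
  if (is.na(id_col) || is.na(mem_col)) {
    stop("specificity group file needs a group id and a members column")
  }
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(tab))) {
    gid <- tab[[id_col]][i]
    mems <- toupper(strsplit(trimws(tab[[mem_col]][i]), "[,; ]+")[[1]])
    mems <- unique(mems[nzchar(mems)])
    if (is.na(gid) || !nzchar(gid) || !length(mems)) {
      skipped <- skipped + 1L
      next
    }
    mhc <- if (!is.na(mhc_col)) tab[[mhc_col]][i] else ""
    if (is.na(mhc)) mhc <- ""
    out[[length(out) + 1L]] <- list(group_id = gid, member_cdr3s = mems,
                                    predicted_mhc = mhc)
  }
  if (skipped > 0L) {
    warning("skipped ", skipped, " malformed specificity-group line(s)")
  }
  structure(out, class = "trb_specificity_groups")
}

#' Read a clinical metadata table
#'
#' Tab-separated, columns `participant_id`, `date`, `viral_load`
#' (copies/mL), `cd4_count` (cells/uL).
#' @param path TSV file path.
#' @return data.frame with typed columns.
#' @export
read_clinical_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "date", "viral_load", "cd4_count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab$participant_id <- as.character(tab$participant_id)
  tab$date <- as.Date(tab$date)
  tab$viral_load <- as.numeric(tab$viral_load)
  tab$cd4_count <- as.numeric(tab$cd4_count)
  tab
}

#' Read an MHC genotype table
#'
#' Tab-separated, columns `participant_id` and `alleles` (comma-separated
#' HLA allele names).
#' @param path TSV file path.
#' @return named list mapping participant_id to a character vector of alleles.
#' @export
read_mhc_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(c("participant_id", "alleles"), names(tab))
  if (length(miss)) stop("MHC table missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- lapply(tab$alleles, function(a) {
    v <- trimws(strsplit(a, ",")[[1]])
    v[nzchar(v)]
  })
  names(out) <- tab$participant_id
  out
}

#' Write a cohort to a directory
#'
#' Writes one rearrangement table per sample plus `samples.tsv` (sample to
#' participant/date mapping), `participants.tsv`, `clinical.tsv`, `mhc.tsv`
#' and, for synthetic cohorts, `truth.json` with the generator ground truth.
#'
#' @param x a `trb_cohort`.
#' @param dir output directory (created if needed).
#' @param dialect rearrangement dialect to write.
#' @return invisibly, the directory.
#' @export
write_cohort <- function(x, dir, dialect = c("immunoseq", "airr")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- samples_table(x)
  st$file <- paste0(st$sample_id, ".tsv")
  for (i in seq_len(nrow(st))) {
    write_rearrangement_table(x$repertoires[[st$sample_id[i]]],
                              file.path(dir, st$file[i]), dialect)
  }
  write.table(st, file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(x$participants, file.path(dir, "participants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(x$clinical)) {
    write.table(x$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (length(x$mhc)) {
    mhc_tab <- data.frame(participant_id = names(x$mhc),
                          alleles = vapply(x$mhc, paste, "", collapse = ","),
                          stringsAsFactors = FALSE)
    write.table(mhc_tab, file.path(dir, "mhc.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(x$truth)) {
    jsonlite::write_json(x$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory path.
#' @param dialect rearrangement dialect of the per-sample tables.
#' @param count_source passed to [read_rearrangement_table()].
#' @return a `trb_cohort`.
#' @export
read_cohort <- function(dir, dialect = c("immunoseq", "airr"),
                        count_source = c("templates", "reads")) {
  dialect <- match.arg(dialect)
  st <- read.delim(file.path(dir, "samples.tsv"), stringsAsFactors = FALSE,
                   colClasses = "character")
  parts <- read.delim(file.path(dir, "participants.tsv"),
                      stringsAsFactors = FALSE, colClasses = "character")
  parts$art_start_date <- as.Date(ifelse(parts$art_start_date %in%
                                           c("", "NA"), NA,
                                         parts$art_start_date))
  reps <- lapply(seq_len(nrow(st)), function(i) {
    read_rearrangement_table(file.path(dir, st$file[i]), dialect,
                             sample_id = st$sample_id[i],
                             participant_id = st$participant_id[i],
                             collection_date = as.Date(st$collection_date[i]),
                             count_source = count_source)
  })
  clin_path <- file.path(dir, "clinical.tsv")
  clin <- if (file.exists(clin_path)) read_clinical_table(clin_path) else NULL
  mhc_path <- file.path(dir, "mhc.tsv")
  mhc <- if (file.exists(mhc_path)) read_mhc_table(mhc_path) else list()
  cohort(reps, parts, mhc = mhc, clinical = clin)
}
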