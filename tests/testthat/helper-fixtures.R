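# In-code fixtures: small repertoires with hand-controlled counts. A fixed
# codon per amino acid gives deterministic CDR3 nucleotide sequences whose
# translation matches the amino acid string; `alt = TRUE` switches to a
# synonymous alternative so one AA clonotype can carry several nt variants.

.codon_a <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT",
              "*" = "TAA")
.codon_b <- c(A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
              G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTC",
              M = "ATG", N = "AAC", P = "CCC", Q = "CAG", R = "CGC",
              S = "TCC", T = "ACC", V = "GTC", W = "TGG", Y = "TAC",
              "*" = "TAG")

fix_nt <- function(aa, alt = FALSE) {
  tab <- if (alt) .codon_b else .codon_a
  vapply(strsplit(aa, ""), function(ch) paste(tab[ch], collapse = ""), "")
}

make_rep <- function(aa, counts, nt = fix_nt(aa),
                     productive = !grepl("\\*", aa),
                     sample_id = "S1", participant_id = sample_id,
                     date = as.Date("2010-01-01"),
                     v = "TRBV19", j = "TRBJ2-1") {
  repertoire(data.frame(cdr3_nt = nt, cdr3_aa = aa,
                        v_gene = v, j_gene = j,
                        productive = productive, count = counts,
                        stringsAsFactors = FALSE),
             sample_id = sample_id, participant_id = participant_id,
             collection_date = date)
}

# random productive CDR3-like strings (C...F) for property tests
rand_cdr3 <- function(n, len = 15) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  unique(vapply(seq_len(n), function(i) {
    paste0("C", paste(sample(aa, len - 2, replace = TRUE), collapse = ""), "F")
  }, ""))
}

# small single-participant cohort wrapper
make_cohort <- function(reps, group = "plhiv",
                        art = as.Date("2010-06-01"), mhc = list()) {
  pids <- unique(vapply(reps, function(r) r$participant_id, ""))
  parts <- data.frame(participant_id = pids, group = group,
                      art_start_date = if (group == "control") as.Date(NA)
                                       else art,
                      stringsAsFactors = FALSE)
  cohort(reps, parts, mhc = mhc)
}

# annotation database rows in the package's normalized layout
make_db <- function(cdr3, source, allele, epitope = "", db_name = "vdjdb") {
  parsed <- hla_parse(allele)
  data.frame(cdr3_aa = cdr3, antigen_source = source, epitope = epitope,
             mhc_allele = ifelse(parsed$valid, parsed$two_field, ""),
             mhc_raw = allele, db_name = db_name, stringsAsFactors = FALSE)
}
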