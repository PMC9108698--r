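#' Parse HLA allele names
#'
#' Accepts mixed-resolution allele names as they appear in annotation
#' databases and genotype reports ("HLA-B*44", "B*44:02",
#' "HLA-B*44:03:01") and extracts locus, allele family (first field) and
#' protein (second field). Comparison elsewhere in the package happens at
#' two-field resolution; a family-only name is a wildcard for the whole
#' family.
#'
#' @param x character vector of allele names.
#' @return data.frame with columns `raw`, `locus`, `family`, `protein`
#'   (NA when absent), `two_field` (normalized string, NA when unparseable)
#'   and `valid`.
#' @export
hla_parse <- function(x) {
  x <- as.character(x)
  out <- data.frame(raw = x, locus = NA_character_, family = NA_integer_,
                    protein = NA_integer_, two_field = NA_character_,
                    valid = FALSE, stringsAsFactors = FALSE)
  if (!length(x)) return(out)
  m <- regexec("^(?:HLA-)?([A-Za-z]+[0-9]*)\\*([0-9]+)(?::([0-9]+))?", x)
  hits <- regmatches(x, m)
  for (i in seq_along(x)) {
    h <- hits[[i]]
    if (length(h) < 3 || !nzchar(h[2]) || !nzchar(h[3])) next
    out$locus[i] <- toupper(h[2])
    out$family[i] <- as.integer(h[3])
    if (length(h) >= 4 && nzchar(h[4])) out$protein[i] <- as.integer(h[4])
    out$two_field[i] <- if (is.na(out$protein[i])) {
      sprintf("%s*%02d", out$locus[i], out$family[i])
    } else {
      sprintf("%s*%02d:%02d", out$locus[i], out$family[i], out$protein[i])
    }
    out$valid[i] <- TRUE
  }
  out
}

#' Match a database allele against a genotype
#'
#' A database allele matches a genotype allele when locus and family agree
#' and, where both names carry a protein (second) field, the protein fields
#' agree too. A family-only database entry such as "HLA-B*44" therefore
#' matches a participant carrying HLA-B*44:03:01.
#'
#' @param allele single allele name (any resolution).
#' @param genotype character vector of the participant's alleles.
#' @return logical scalar; FALSE when `allele` is unparseable.
#' @export
hla_match <- function(allele, genotype) {
  a <- hla_parse(allele)
  if (!a$valid[1] || !length(genotype)) return(FALSE)
  g <- hla_parse(genotype)
  any(g$valid & g$locus == a$locus[1] & g$family == a$family[1] &
        (is.na(a$protein[1]) | is.na(g$protein) | g$protein == a$protein[1]))
}

# Are two allele names compatible (same locus+family, protein fields agree
# when both present)? Used for GLIPH-predicted vs database restriction.
hla_compatible <- function(a, b) {
  pa <- hla_parse(a); pb <- hla_parse(b)
  if (!pa$valid[1] || !pb$valid[1]) return(FALSE)
  pa$locus[1] == pb$locus[1] && pa$family[1] == pb$family[1] &&
    (is.na(pa$protein[1]) || is.na(pb$protein[1]) ||
       pa$protein[1] == pb$protein[1])
}
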