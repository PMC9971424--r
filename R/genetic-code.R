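# Standard genetic code tables shared by all codon-level statistics.
# Six-fold amino acids (Leu, Ser, Arg) are treated as single six-membered
# synonymous families; Met, Trp and the three stop codons never enter
# synonymous statistics.

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

ALL_CODONS <- names(GENETIC_CODE_TABLE)

STOP_CODONS <- ALL_CODONS[GENETIC_CODE_TABLE == "*"]

SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

#' @noRd
codon_aa <- function(codon) unname(GENETIC_CODE_TABLE[codon])

# synonymous families: sense codons grouped by amino acid, singletons
# (Met, Trp) dropped
SYN_FAMILIES <- local({
  fam <- split(SENSE_CODONS, GENETIC_CODE_TABLE[SENSE_CODONS])
  fam[vapply(fam, length, 1L) >= 2L]
})

FAMILY_SIZE <- vapply(SYN_FAMILIES, length, 1L)

# Wright's degeneracy classes: 9 two-fold, 1 three-fold (Ile), 5 four-fold,
# 3 six-fold families
DEGENERACY_CLASSES <- split(names(SYN_FAMILIES), FAMILY_SIZE)

# the 59 codons of synonymous families (sense minus ATG, TGG)
SYN_CODONS <- unname(unlist(SYN_FAMILIES))

#' @noRd
third_base <- function(codon) substring(codon, 3L, 3L)

# for each synonymous family, which bases occur at the third position
FAMILY_THIRD_BASES <- lapply(SYN_FAMILIES, function(cods) unique(third_base(cods)))

#' Split a CDS into frame-0 codons
#'
#' @param cds a single nucleotide string (character scalar or `DNAString`).
#' @return character vector of uppercase codons.
#' @noRd
split_codons <- function(cds) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length (", n, ") is not divisible by 3", call. = FALSE)
  }
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' @noRd
is_unambiguous_codon <- function(codons) {
  grepl("^[ACGT]{3}$", codons)
}

#' Translate a CDS under the standard genetic code
#' @noRd
translate_cds <- function(cds) {
  paste(GENETIC_CODE_TABLE[split_codons(cds)], collapse = "")
}
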