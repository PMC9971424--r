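# Per-gene codon usage indices: Wright's effective number of codons (ENC),
# Sharp & Li's codon adaptation index (CAI), relative synonymous codon usage
# (RSCU), Peden's synonymous third-position base usage (A3s/T3s/C3s/G3s) and
# positional GC content.

#' Count frame-0 codons of a coding sequence
#'
#' Tallies the 64 codons of a CDS read in frame 0. Stop codons and codons
#' containing an ambiguous base (anything outside A/C/G/T) are never counted;
#' they appear with count zero.
#'
#' @param cds coding sequence (character scalar or `DNAString`), length
#'   divisible by 3.
#' @return named integer vector over all 64 codons with attribute
#'   `n_codons_used` (the number of codons actually tallied).
#' @examples
#' count_codons("ATGAAATAA")
#' @export
count_codons <- function(cds) {
  codons <- split_codons(cds)
  keep <- is_unambiguous_codon(codons) & !(codons %in% STOP_CODONS)
  counts <- table(factor(codons[keep], levels = ALL_CODONS))
  out <- as.integer(counts)
  names(out) <- ALL_CODONS
  attr(out, "n_codons_used") <- sum(out)
  out
}

#' Codon count matrix for a set of coding sequences
#'
#' @param cds_set `DNAStringSet` or named character vector of CDS.
#' @return integer matrix, genes x 64 codons.
#' @export
codon_count_matrix <- function(cds_set) {
  cds_set <- as.character(cds_set)
  m <- t(vapply(cds_set, function(s) as.integer(count_codons(s)),
                integer(length(ALL_CODONS))))
  colnames(m) <- ALL_CODONS
  if (!is.null(names(cds_set))) rownames(m) <- names(cds_set)
  m
}

# Wright's codon homozygosity for one synonymous family:
# F = (n * sum(p_i^2) - 1) / (n - 1), defined for n >= 2
wright_f <- function(family_counts) {
  n <- sum(family_counts)
  if (n < 2L) return(NA_real_)
  p <- family_counts / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Effective number of codons (Wright)
#'
#' ENC estimates how far a gene departs from uniform use of synonymous
#' codons: 20 means exactly one codon per amino acid, 61 uniform use of all
#' synonyms. Per-family homozygosities F are averaged within degeneracy
#' classes (9 two-fold, 1 three-fold, 5 four-fold, 3 six-fold) and
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6.
#'
#' When the three-fold (Ile) or a six-fold class has no family with at least
#' two codons, its class mean is imputed as the mean of the two-fold and
#' four-fold class means; if the two-fold or four-fold class itself is
#' missing, ENC is `NA`. Finite-sample estimates above 61 are capped at 61.
#'
#' @param counts codon counts as returned by [count_codons()].
#' @return ENC in `[20, 61]`, or `NA` when undefined.
#' @export
enc <- function(counts) {
  f_by_class <- lapply(DEGENERACY_CLASSES, function(aas) {
    f <- vapply(aas, function(aa) wright_f(counts[SYN_FAMILIES[[aa]]]),
                numeric(1))
    f <- f[!is.na(f)]
    if (length(f) == 0L) NA_real_ else mean(f)
  })
  f2 <- f_by_class[["2"]]; f3 <- f_by_class[["3"]]
  f4 <- f_by_class[["4"]]; f6 <- f_by_class[["6"]]
  if (is.na(f2) || is.na(f4)) return(NA_real_)
  if (is.na(f3)) f3 <- (f2 + f4) / 2
  if (is.na(f6)) f6 <- (f2 + f4) / 2
  if (any(c(f2, f3, f4, f6) <= 0)) return(NA_real_)
  value <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(value, 61)
}

#' Relative synonymous codon usage
#'
#' RSCU is the observed codon count divided by the count expected under
#' uniform use of the synonyms: `k * n_ij / sum_j(n_ij)` for a family of
#' size k. Families with zero total usage get `NA` (never 0).
#'
#' @param counts codon counts as returned by [count_codons()].
#' @return named numeric vector over the 59 synonymous-family codons.
#' @export
rscu <- function(counts) {
  out <- rep(NA_real_, length(SYN_CODONS))
  names(out) <- SYN_CODONS
  for (aa in names(SYN_FAMILIES)) {
    cods <- SYN_FAMILIES[[aa]]
    tot <- sum(counts[cods])
    if (tot > 0) out[cods] <- length(cods) * counts[cods] / tot
  }
  out
}

#' Relative adaptiveness weights for the codon adaptation index
#'
#' Sharp & Li weights: within each synonymous family,
#' `w_ij = RSCU_ij / max_j RSCU_ij`, computed from codon counts pooled over
#' a reference gene set. Codons unobserved in the reference receive a
#' pseudo-count (default 0.5) before RSCU is formed, so no weight is zero.
#'
#' @param reference_counts pooled codon counts of the reference set.
#' @param pseudo_count value substituted for zero reference counts.
#' @param reference short description recorded with the weights.
#' @return object of class `cai_weights`: named numeric vector of weights in
#'   (0, 1] over the 59 synonymous-family codons.
#' @export
cai_weights <- function(reference_counts, pseudo_count = 0.5,
                        reference = "user-supplied reference counts") {
  if (sum(reference_counts[SYN_CODONS]) == 0) {
    stop("empty reference: no synonymous-family codons counted", call. = FALSE)
  }
  w <- rep(NA_real_, length(SYN_CODONS))
  names(w) <- SYN_CODONS
  for (aa in names(SYN_FAMILIES)) {
    cods <- SYN_FAMILIES[[aa]]
    n <- as.numeric(reference_counts[cods])
    n[n == 0] <- pseudo_count
    w[cods] <- n / max(n)
  }
  structure(w, reference = reference, class = c("cai_weights", "numeric"))
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness weights of a gene's codons,
#' excluding Met, Trp and stop codons: `CAI = exp(mean(log w))`. 1 means the
#' gene uses only optimal codons.
#'
#' @param counts codon counts as returned by [count_codons()].
#' @param weights relative adaptiveness weights from [cai_weights()].
#' @return CAI in (0, 1], or `NA` when the gene has no eligible codons.
#' @export
cai <- function(counts, weights) {
  n <- as.numeric(counts[SYN_CODONS])
  w <- as.numeric(weights[SYN_CODONS])
  keep <- n > 0 & !is.na(w)
  L <- sum(n[keep])
  if (L == 0) return(NA_real_)
  exp(sum(n[keep] * log(w[keep])) / L)
}

#' Base composition of a coding sequence
#'
#' Computes global GC over the full CDS, positional GC1/GC2/GC3 over sense
#' codons, GC12 = (GC1+GC2)/2, Peden's A3s/T3s/C3s/G3s (usage of each base at
#' synonymous third positions relative to the codons whose amino acid could
#' carry that base there), and GC3s (G+C share of synonymous third positions
#' among codons whose family offers a G or C synonym). Codons containing
#' ambiguous bases are skipped at the codon level; ambiguous bases are
#' dropped from the global GC numerator and denominator.
#'
#' @param cds coding sequence, length divisible by 3.
#' @return named numeric vector with elements `gc, gc1, gc2, gc3, gc12,
#'   gc3s, a3s, t3s, c3s, g3s`.
#' @export
composition <- function(cds) {
  cds_chr <- toupper(as.character(cds))
  bases <- strsplit(cds_chr, "")[[1]]
  acgt <- bases[bases %in% c("A", "C", "G", "T")]
  gc <- if (length(acgt)) mean(acgt %in% c("G", "C")) else NA_real_

  codons <- split_codons(cds_chr)
  codons <- codons[is_unambiguous_codon(codons)]
  sense <- codons[!(codons %in% STOP_CODONS)]

  pos_gc <- function(pos) {
    if (length(sense) == 0L) return(NA_real_)
    mean(substring(sense, pos, pos) %in% c("G", "C"))
  }
  gc1 <- pos_gc(1L); gc2 <- pos_gc(2L); gc3 <- pos_gc(3L)

  # Peden X3s: numerator = codons of synonymous families with base X at the
  # third position; denominator = codons of families that could have X there
  syn <- sense[sense %in% SYN_CODONS]
  x3s <- vapply(c(A = "A", T = "T", C = "C", G = "G"), function(base) {
    eligible_fams <- names(FAMILY_THIRD_BASES)[
      vapply(FAMILY_THIRD_BASES, function(b) base %in% b, logical(1))]
    eligible <- syn[GENETIC_CODE_TABLE[syn] %in% eligible_fams]
    if (length(eligible) == 0L) return(NA_real_)
    sum(third_base(eligible) == base) / length(eligible)
  }, numeric(1))

  gc_fams <- names(FAMILY_THIRD_BASES)[
    vapply(FAMILY_THIRD_BASES, function(b) any(c("G", "C") %in% b), logical(1))]
  gc_eligible <- syn[GENETIC_CODE_TABLE[syn] %in% gc_fams]
  gc3s <- if (length(gc_eligible) == 0L) NA_real_ else
    mean(third_base(gc_eligible) %in% c("G", "C"))

  c(gc = gc, gc1 = gc1, gc2 = gc2, gc3 = gc3, gc12 = (gc1 + gc2) / 2,
    gc3s = gc3s, a3s = unname(x3s["A"]), t3s = unname(x3s["T"]),
    c3s = unname(x3s["C"]), g3s = unname(x3s["G"]))
}

#' Per-gene composition profiles for a gene catalog
#'
#' Computes the full set of codon usage indices for every retained gene of a
#' catalog: ENC, CAI, positional GC, synonymous third-position base usage,
#' flank GC and CDS length.
#'
#' The CAI reference defaults to the pooled codon counts of the 5% of genes
#' with the lowest ENC (the most biased genes); supply `weights` to override.
#'
#' @param catalog a `gene_catalog` from [load_catalog()] or
#'   [simulate_catalog()].
#' @param weights optional [cai_weights()] object overriding the default
#'   reference.
#' @param reference_fraction fraction of lowest-ENC genes pooled for the
#'   default CAI reference.
#' @return data.frame with one row per retained gene: `gene_id, label, enc,
#'   cai, gc, gc1, gc2, gc3, gc12, gc3s, a3s, t3s, c3s, g3s, gcf,
#'   cds_length`, plus attributes `counts` (genes x 64 matrix) and `weights`.
#' @export
composition_profiles <- function(catalog, weights = NULL,
                                 reference_fraction = 0.05) {
  stopifnot(inherits(catalog, "gene_catalog"))
  rec <- retained_records(catalog)
  cds <- catalog$cds[rec$gene_id]
  counts <- codon_count_matrix(cds)
  enc_v <- apply(counts, 1L, enc)
  if (is.null(weights)) {
    ord <- order(enc_v)
    n_ref <- max(1L, ceiling(reference_fraction * sum(!is.na(enc_v))))
    ref_ids <- rec$gene_id[ord[seq_len(n_ref)]]
    pooled <- colSums(counts[ref_ids, , drop = FALSE])
    weights <- cai_weights(pooled,
                           reference = sprintf(
                             "pooled counts of the %d lowest-ENC genes", n_ref))
  }
  cai_v <- apply(counts, 1L, cai, weights = weights)
  comp <- t(vapply(as.character(cds), composition, numeric(10)))
  gcf <- vapply(rec$gene_id, function(id)
    flank_gc_pair(catalog$flank_up[[id]], catalog$flank_down[[id]]),
    numeric(1))
  out <- data.frame(
    gene_id = rec$gene_id, label = rec$label,
    enc = unname(enc_v), cai = unname(cai_v),
    comp, gcf = unname(gcf),
    cds_length = nchar(as.character(cds)),
    row.names = NULL, check.names = FALSE)
  attr(out, "counts") <- counts
  attr(out, "weights") <- weights
  out
}

#' Write a composition profile table to TSV
#'
#' @param profiles data.frame from [composition_profiles()].
#' @param path output file.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
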