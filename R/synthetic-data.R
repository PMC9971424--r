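# Seeded synthetic genomes for end-to-end testing: two gene classes sharing
# an amino-acid composition but with within-family synonymous preferences
# diverged by a controllable tilt, heterogeneous per-gene GC3, exon/intron
# structure separating single-exon from multiple-exon genes, noncoding
# flanks, per-gene expression, and codon alignments evolved at known omega.

#' Configuration of the synthetic genome generator
#'
#' Class 2 (MEG) within-family codon probabilities are tilted from class 1
#' (SEG) by `exp(+delta)` on a fixed preferred half of each family and
#' `exp(-delta)` on the rest, then renormalized, so amino-acid usage is
#' identical in expectation and any between-class signal is purely
#' synonymous. The preferred halves alternate third-position endings across
#' families, so `delta` does not shift class GC3. Per-gene GC3
#' heterogeneity comes from a gene-level latent pressure on G/C-ending
#' synonyms.
#'
#' @param n_chromosomes chromosomes to emit.
#' @param n_seg,n_meg genes per class (SEG = single exon, MEG = 2-10
#'   exons).
#' @param mean_length_codons named vector, mean CDS length in codons per
#'   class (log-normal across genes).
#' @param length_sdlog log-sd of CDS length.
#' @param min_length_codons lower truncation of gene length.
#' @param delta between-class synonymous preference divergence (0 =
#'   identical preferences). The default is calibrated so the between-class
#'   synonymous share of total inertia falls in the low single-digit
#'   percent range typical of real SEG/MEG comparisons.
#' @param gc3_spread total sd of the per-gene latent GC3 pressure (logit
#'   scale); a named vector `c(seg=, meg=)` gives each class its own spread
#'   (the default makes single-exon genes compositionally more
#'   heterogeneous, as observed in rice), a scalar applies to both.
#' @param gc3_common_spread scale of the amino-acid-level GC pressure; the
#'   amino-acid tilt applied to a gene is
#'   `gc12_coupling * gc3_common_spread * z_std`, where `z_std` is the
#'   gene's latent GC3 pressure standardized within its class, so the
#'   amino-acid usage distribution is identical between classes while
#'   GC12 still tracks GC3 within every class.
#' @param gc12_coupling strength of the amino-acid-level GC dependence;
#'   positive values induce the positive GC12-GC3 correlation seen in real
#'   genomes (the neutrality-plot signal). 0 leaves GC12 independent of
#'   GC3.
#' @param gc3_shift overall mean of the latent GC3 pressure.
#' @param class_gc3_shift additive latent GC3 shift applied to class 1
#'   (SEG) genes only; 0 keeps the two classes' GC3 identical in
#'   expectation.
#' @param expr_meanlog,expr_sdlog log-normal expression parameters.
#' @param expr_gc3_coupling strength of the expression-GC3 dependence (0 =
#'   none).
#' @param flank_gc GC fraction of intergenic/flank sequence.
#' @param intron_gc GC fraction of introns.
#' @param intron_length_range min/max intron length (bp).
#' @param intergenic_range min/max intergenic gap (bp); the minimum must
#'   exceed twice the flank width so flanks stay noncoding.
#' @param omega,t nonsynonymous/synonymous rate ratio and total divergence
#'   time for ortholog pair evolution.
#' @param seed integer seed recorded in all outputs.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chromosomes = 2L,
                             n_seg = 700L, n_meg = 2520L,
                             mean_length_codons = c(seg = 300, meg = 530),
                             length_sdlog = 0.35,
                             min_length_codons = 100L,
                             delta = 0.25,
                             gc3_spread = c(seg = 3.5, meg = 0.4),
                             gc3_common_spread = 0.45,
                             gc12_coupling = 1.5,
                             gc3_shift = 0.2,
                             class_gc3_shift = 0,
                             expr_meanlog = 0, expr_sdlog = 1,
                             expr_gc3_coupling = 1.2,
                             flank_gc = 0.45,
                             intron_gc = 0.40,
                             intron_length_range = c(80L, 300L),
                             intergenic_range = c(500L, 1500L),
                             omega = 0.2, t = 0.4,
                             seed = 1L) {
  stopifnot(delta >= 0, n_seg > 0, n_meg > 0,
            min_length_codons >= 4L,
            intergenic_range[1L] > 400L)
  structure(as.list(environment()), class = "synthetic_config")
}

# random DNA at a given GC content
random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

# class-specific within-family preference vectors: class 1 uniform, class 2
# tilted by exp(+/-delta) on a fixed split alternating third-base endings
class_preferences <- function(delta) {
  prefs <- list()
  for (aa in names(SYN_FAMILIES)) {
    cods <- sort(SYN_FAMILIES[[aa]])
    k <- length(cods)
    preferred <- cods[seq(1L, k, by = 2L)]  # alternating split
    p1 <- stats::setNames(rep(1 / k, k), cods)
    w <- ifelse(cods %in% preferred, exp(delta), exp(-delta))
    p2 <- stats::setNames(w / sum(w), cods)
    prefs[[aa]] <- list(class1 = p1, class2 = p2)
  }
  prefs
}

# mean G+C fraction at codon positions 1-2 per amino acid (constant within
# most families), used for the amino-acid-level GC coupling
AA_GC12 <- local({
  gc12_codon <- function(codon) {
    mean(strsplit(substr(codon, 1, 2), "")[[1]] %in% c("G", "C"))
  }
  fam <- split(SENSE_CODONS, GENETIC_CODE_TABLE[SENSE_CODONS])
  vapply(fam, function(cods) mean(vapply(cods, gc12_codon, numeric(1))),
         numeric(1))
})

# sample a CDS: ATG + internal sense codons + stop; amino acids drawn with
# probability proportional to family size (plus Met/Trp) tilted by the
# shared GC pressure, codons within a family from the class preference
# tilted by the gene's total latent GC3 pressure
sample_cds <- function(n_codons, prefs, which_class, gc3_latent,
                       aa_tilt = 0) {
  n_internal <- n_codons - 2L
  aa_pool <- c(names(SYN_FAMILIES), "M", "W")
  aa_w <- c(FAMILY_SIZE, M = 1, W = 1)
  aa_w <- aa_w * exp(aa_tilt * (AA_GC12[aa_pool] - mean(AA_GC12)))
  aas <- sample(aa_pool, n_internal, replace = TRUE, prob = aa_w / sum(aa_w))
  codons <- character(n_internal)
  for (aa in unique(aas)) {
    idx <- which(aas == aa)
    if (aa == "M") { codons[idx] <- "ATG"; next }
    if (aa == "W") { codons[idx] <- "TGG"; next }
    p <- prefs[[aa]][[which_class]]
    gc_end <- third_base(names(p)) %in% c("G", "C")
    w <- p * exp(ifelse(gc_end, gc3_latent, 0))
    codons[idx] <- sample(names(p), length(idx), replace = TRUE,
                          prob = w / sum(w))
  }
  paste0("ATG", paste(codons, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

#' Simulate a genome FASTA + GFF3 with two gene classes
#'
#' Writes `genome.fasta`, `annotation.gff3` and `truth.tsv` under `dir` and
#' returns their paths together with the truth table (per-gene class,
#' latent GC3 pressure, realized GC3 and placement). All generated genes
#' pass every catalog filter, so a round trip through [load_catalog()]
#' retains them all.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if absent).
#' @return list: `fasta`, `gff3`, `truth_path`, `truth` (data.frame),
#'   `config`.
#' @export
simulate_catalog <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefs <- class_preferences(config$delta)

  n_total <- config$n_seg + config$n_meg
  classes <- sample(rep(c("SEG", "MEG"), c(config$n_seg, config$n_meg)))
  gene_ids <- sprintf("gene%04d", seq_len(n_total))
  meanlog <- log(config$mean_length_codons[
    ifelse(classes == "SEG", "seg", "meg")]) - config$length_sdlog^2 / 2
  lens <- pmax(config$min_length_codons,
               round(stats::rlnorm(n_total, meanlog, config$length_sdlog)))
  spread <- if (length(config$gc3_spread) == 1L) {
    rep(config$gc3_spread, n_total)
  } else {
    unname(config$gc3_spread[ifelse(classes == "SEG", "seg", "meg")])
  }
  z <- stats::rnorm(n_total, config$gc3_shift, spread) +
    ifelse(classes == "SEG", config$class_gc3_shift, 0)

  chrom_of <- rep(seq_len(config$n_chromosomes), length.out = n_total)
  chrom_seq <- stats::setNames(vector("list", config$n_chromosomes),
                               sprintf("Chr%d", seq_len(config$n_chromosomes)))
  for (i in seq_along(chrom_seq)) chrom_seq[[i]] <- character(0)
  chrom_pos <- rep(0L, config$n_chromosomes)
  gff <- c("##gff-version 3")
  truth <- vector("list", n_total)

  for (g in seq_len(n_total)) {
    cls <- classes[g]
    which_class <- if (cls == "SEG") "class1" else "class2"
    z_std <- (z[g] - config$gc3_shift -
                if (cls == "SEG") config$class_gc3_shift else 0) / spread[g]
    cds <- sample_cds(lens[g], prefs, which_class, z[g],
                      aa_tilt = config$gc12_coupling *
                        config$gc3_common_spread * z_std)
    nc <- nchar(cds)
    max_exons <- max(2L, min(10L, nc %/% 30L))
    n_exons <- if (cls == "SEG") 1L else sample(2:max_exons, 1L)
    # split the CDS into exon pieces of at least 30 bp: distribute the
    # slack above the minimum with uniformly placed cut points
    if (n_exons == 1L) {
      piece_len <- nc
    } else {
      slack <- nc - 30L * n_exons
      cuts <- sort(sample.int(slack + 1L, n_exons - 1L, replace = TRUE) - 1L)
      piece_len <- 30L + diff(c(0L, cuts, slack))
    }
    introns <- if (n_exons > 1L) {
      vapply(seq_len(n_exons - 1L), function(i)
        random_dna(sample(seq(config$intron_length_range[1L],
                              config$intron_length_range[2L]), 1L),
                   config$intron_gc), character(1))
    } else character(0)

    # plus-strand gene body and CDS segment coordinates relative to start
    pieces <- substring(cds,
                        c(1L, cumsum(piece_len)[-n_exons] + 1L),
                        cumsum(piece_len))
    body <- pieces[1L]
    rel <- matrix(0L, n_exons, 2L)
    rel[1L, ] <- c(1L, piece_len[1L])
    if (n_exons > 1L) {
      for (i in 2:n_exons) {
        body <- paste0(body, introns[i - 1L], pieces[i])
        rel[i, 1L] <- nchar(body) - piece_len[i] + 1L
        rel[i, 2L] <- nchar(body)
      }
    }
    strand <- sample(c("+", "-"), 1L)
    body_out <- if (strand == "-") as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(body))) else body
    body_len <- nchar(body_out)

    ci <- chrom_of[g]
    gap <- sample(seq(config$intergenic_range[1L],
                      config$intergenic_range[2L]), 1L)
    spacer <- random_dna(gap, config$flank_gc)
    gstart <- chrom_pos[ci] + gap + 1L
    gend <- gstart + body_len - 1L
    chrom_seq[[ci]] <- c(chrom_seq[[ci]], spacer, body_out)
    chrom_pos[ci] <- gend

    abs_seg <- if (strand == "+") {
      cbind(gstart + rel[, 1L] - 1L, gstart + rel[, 2L] - 1L)
    } else {
      cbind(gstart + body_len - rel[, 2L], gstart + body_len - rel[, 1L])
    }
    abs_seg <- abs_seg[order(abs_seg[, 1L]), , drop = FALSE]

    chrom_name <- names(chrom_seq)[ci]
    gid <- gene_ids[g]; tid <- paste0(gid, ".1")
    lines <- c(
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              chrom_name, gstart, gend, strand, gid),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              chrom_name, gstart, gend, strand, tid, gid),
      sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              chrom_name, abs_seg[, 1L], abs_seg[, 2L], strand, tid,
              seq_len(n_exons), tid),
      sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
              chrom_name, abs_seg[, 1L], abs_seg[, 2L], strand, tid,
              seq_len(n_exons), tid))
    gff <- c(gff, lines)

    truth[[g]] <- data.frame(
      gene_id = gid, class = cls, chromosome = chrom_name,
      start = gstart, end = gend, strand = strand,
      n_exons = n_exons, length_codons = lens[g],
      gc3_latent = z[g],
      gc3 = unname(composition(cds)["gc3"]),
      stringsAsFactors = FALSE)
  }

  # trailing intergenic sequence so the last gene has a full flank
  for (ci in seq_along(chrom_seq)) {
    chrom_seq[[ci]] <- c(chrom_seq[[ci]], random_dna(600L, config$flank_gc))
  }
  genome <- Biostrings::DNAStringSet(
    vapply(chrom_seq, paste, character(1), collapse = ""))
  names(genome) <- names(chrom_seq)

  fasta <- file.path(dir, "genome.fasta")
  gff3 <- file.path(dir, "annotation.gff3")
  truth_path <- file.path(dir, "truth.tsv")
  Biostrings::writeXStringSet(genome, fasta)
  writeLines(gff, gff3)
  truth_df <- do.call(rbind, truth)
  truth_df$seed <- config$seed
  utils::write.table(truth_df, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fasta, gff3 = gff3, truth_path = truth_path,
       truth = truth_df, config = config)
}

#' Simulate per-gene expression values
#'
#' Log-normal expression with a configurable dependence on each gene's
#' realized GC3 (standardized), and no dependence on flank GC.
#'
#' @param truth truth table from [simulate_catalog()].
#' @param config the [synthetic_config()] used (supplies
#'   `expr_meanlog`, `expr_sdlog`, `expr_gc3_coupling`, `seed`).
#' @param path optional TSV output path.
#' @return data.frame: `gene_id`, `expression`.
#' @export
simulate_expression <- function(truth, config, path = NULL) {
  set.seed(config$seed + 104729L)
  gc3 <- truth$gc3
  zgc <- if (stats::sd(gc3) > 0) (gc3 - mean(gc3)) / stats::sd(gc3) else 0 * gc3
  log_e <- config$expr_meanlog + config$expr_gc3_coupling * zgc +
    stats::rnorm(nrow(truth), 0, config$expr_sdlog)
  out <- data.frame(gene_id = truth$gene_id, expression = exp(log_e),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Evolve a codon-aligned sequence pair at known omega
#'
#' Draws a random ancestor of sense codons and evolves two independent
#' branches of length `t/2` under a continuous-time codon model:
#' single-nucleotide neighbor moves, synonymous changes at base rate 1/3
#' per site, nonsynonymous at `omega/3`, moves into stop codons forbidden.
#' Under neutrality (`omega = 1`) the expected divergence is about `t`
#' substitutions per site between the two tips.
#'
#' @param length_codons number of codons.
#' @param omega nonsynonymous/synonymous rate ratio (> 0).
#' @param t total divergence time between the pair (> 0).
#' @param seed integer seed.
#' @return character vector of two aligned in-frame CDS strings.
#' @export
evolve_pair <- function(length_codons, omega, t, seed = 1L) {
  stopifnot(omega > 0, t >= 0, length_codons >= 1L)
  set.seed(seed)
  ancestor <- sample(SENSE_CODONS, length_codons, replace = TRUE)
  evolve_branch <- function(codons, time) {
    for (i in seq_along(codons)) {
      elapsed <- 0
      cur <- codons[i]
      repeat {
        nb <- codon_neighbors(cur)
        rate <- vapply(nb, function(x) {
          if (GENETIC_CODE_TABLE[[x]] == "*") return(0)
          if (GENETIC_CODE_TABLE[[x]] == GENETIC_CODE_TABLE[[cur]]) 1 / 3
          else omega / 3
        }, numeric(1))
        R <- sum(rate)
        if (R <= 0) break
        elapsed <- elapsed + stats::rexp(1L, R)
        if (elapsed > time) break
        cur <- sample(nb, 1L, prob = rate / R)
      }
      codons[i] <- cur
    }
    codons
  }
  tip1 <- evolve_branch(ancestor, t / 2)
  tip2 <- evolve_branch(ancestor, t / 2)
  c(paste(tip1, collapse = ""), paste(tip2, collapse = ""))
}
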