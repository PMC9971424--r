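# Gene catalog construction: read a genome FASTA + GFF3 annotation, pick the
# longest-CDS isoform per gene, apply the exclusion filters, classify genes
# as single-exon (SEG) or multiple-exon (MEG), and extract CDS and
# noncoding flanks.

NONCODING_TYPES <- c("ncRNA", "tRNA", "rRNA", "snoRNA", "snRNA", "miRNA",
                     "lnc_RNA", "lincRNA", "antisense_RNA", "pre_miRNA",
                     "SRP_RNA", "RNase_MRP_RNA", "ncRNA_gene")

TRANSCRIPT_TYPES <- c("mRNA", "transcript")

EXCLUSION_REASONS <- c("unknown_chromosome", "noncoding_rna", "bad_start_stop",
                       "internal_stop", "short_cds", "single_exon_isoform")

#' Configuration for gene catalog construction
#'
#' @param min_cds_len minimum CDS length in bp (shorter genes are excluded
#'   as `short_cds`).
#' @param flank_width width in bp of the noncoding flank extracted on each
#'   side of the gene span (truncated at chromosome ends).
#' @param start_codons valid start codons.
#' @param stop_codons valid stop codons.
#' @param exclude_chrom_pattern regular expression; genes on matching
#'   chromosome names (unanchored scaffolds such as ChrSy/ChrUn) are
#'   excluded as `unknown_chromosome`.
#' @param sei_policy handling of genes whose longest-CDS isoform is
#'   single-exon while another isoform is multi-exon: `"exclude"` drops them
#'   as `single_exon_isoform` (alternative-splicing artefacts of multi-exon
#'   genes); `"representative"` classifies them by the representative
#'   isoform's exon count.
#' @return a list of class `catalog_config`.
#' @export
catalog_config <- function(min_cds_len = 300L,
                           flank_width = 200L,
                           start_codons = "ATG",
                           stop_codons = c("TAA", "TAG", "TGA"),
                           exclude_chrom_pattern = "^Chr(Sy|Un)",
                           sei_policy = c("exclude", "representative")) {
  sei_policy <- match.arg(sei_policy)
  structure(list(min_cds_len = as.integer(min_cds_len),
                 flank_width = as.integer(flank_width),
                 start_codons = toupper(start_codons),
                 stop_codons = toupper(stop_codons),
                 exclude_chrom_pattern = exclude_chrom_pattern,
                 sei_policy = sei_policy),
            class = "catalog_config")
}

first_parent <- function(parent_list) {
  vapply(parent_list, function(p) if (length(p)) p[[1]] else NA_character_,
         character(1))
}

#' Load a gene catalog from FASTA + GFF3
#'
#' Reads the genome and annotation, selects the longest-CDS isoform as each
#' gene's representative, extracts the spliced, strand-corrected CDS and the
#' flanking noncoding sequence, applies the exclusion filters in a fixed
#' order (unknown_chromosome, noncoding_rna, bad_start_stop, internal_stop,
#' short_cds, single_exon_isoform; a gene failing several filters records
#' the first), and labels the survivors SEG or MEG.
#'
#' @param fasta_path genome FASTA.
#' @param gff_path GFF3 annotation with gene/mRNA/exon/CDS features linked
#'   by Parent attributes.
#' @param config a [catalog_config()].
#' @return object of class `gene_catalog`: `records` (data.frame of gene_id,
#'   chromosome, start, end, strand, exon_count, n_isoforms, cds_length,
#'   label, exclusion_reason), `cds`, `flank_up`, `flank_down`
#'   (`DNAStringSet`s keyed by gene_id), `genome`, `genome_lengths`,
#'   `config`, `provenance`.
#' @export
load_catalog <- function(fasta_path, gff_path, config = catalog_config()) {
  stopifnot(file.exists(fasta_path), file.exists(gff_path))
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- tryCatch(
    rtracklayer::import(gff_path, format = "gff3"),
    error = function(e) stop("malformed GFF3 '", gff_path, "': ",
                             conditionMessage(e), call. = FALSE))
  build_catalog(genome, gr, config,
                provenance = list(fasta = fasta_path, gff3 = gff_path,
                                  config = unclass(config)))
}

# core construction from parsed objects (shared with the simulator round trip)
build_catalog <- function(genome, gr, config, provenance) {
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  gene_ids <- genes$ID
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene IDs in GFF3: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  tx <- gr[type %in% c(TRANSCRIPT_TYPES, NONCODING_TYPES)]
  tx_parent <- first_parent(tx$Parent)
  tx_type <- as.character(tx$type)
  cds_feat <- gr[type == "CDS"]
  cds_parent <- first_parent(cds_feat$Parent)
  exon_feat <- gr[type == "exon"]
  exon_parent <- first_parent(exon_feat$Parent)

  n <- length(genes)
  rec <- data.frame(
    gene_id = gene_ids,
    chromosome = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    exon_count = NA_integer_,
    n_isoforms = 0L,
    cds_length = 0L,
    label = rep("EXCLUDED", n),
    exclusion_reason = rep("", n),
    stringsAsFactors = FALSE)

  cds_seqs <- character(n)
  up_seqs <- character(n)
  down_seqs <- character(n)
  chrom_char <- lapply(genome, as.character)
  tx_by_gene <- split(seq_along(tx), tx_parent)
  cds_by_tx <- split(seq_along(cds_feat), cds_parent)
  exon_count_by_tx <- table(exon_parent)
  # plain vectors: per-gene work avoids repeated S4 subsetting
  tx_id_vec <- as.character(tx$ID)
  cds_start <- GenomicRanges::start(cds_feat)
  cds_end <- GenomicRanges::end(cds_feat)
  cds_width <- cds_end - cds_start + 1L

  for (i in seq_len(n)) {
    gid <- rec$gene_id[i]
    chrom <- rec$chromosome[i]
    g_tx <- tx_by_gene[[gid]]
    if (is.null(g_tx)) g_tx <- integer(0)
    coding_tx <- g_tx[tx_type[g_tx] %in% TRANSCRIPT_TYPES]
    nc_tx <- g_tx[tx_type[g_tx] %in% NONCODING_TYPES]
    rec$n_isoforms[i] <- length(coding_tx)

    # filter 1: unknown chromosome (configured scaffold pattern or absent
    # from the genome FASTA)
    if (grepl(config$exclude_chrom_pattern, chrom) ||
        !(chrom %in% names(genome))) {
      rec$exclusion_reason[i] <- "unknown_chromosome"
      next
    }
    # filter 2: noncoding RNA gene (no coding isoform)
    if (length(coding_tx) == 0L) {
      rec$exclusion_reason[i] <- "noncoding_rna"
      next
    }

    # representative isoform = longest total CDS (ties: first transcript ID)
    tx_ids <- tx_id_vec[coding_tx]
    cds_len <- vapply(tx_ids, function(tid)
      sum(cds_width[cds_by_tx[[tid]]]), integer(1))
    ord <- order(-cds_len, tx_ids)
    rep_tx <- tx_ids[ord[1L]]
    rec$cds_length[i] <- cds_len[ord[1L]]

    seg_idx <- cds_by_tx[[rep_tx]]
    if (length(seg_idx) == 0L) {
      rec$exclusion_reason[i] <- "noncoding_rna"
      next
    }
    seg_idx <- seg_idx[order(cds_start[seg_idx])]
    chrom_str <- chrom_char[[chrom]]
    pieces <- substring(chrom_str, cds_start[seg_idx], cds_end[seg_idx])
    cds <- paste(pieces, collapse = "")
    if (rec$strand[i] == "-") {
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    }
    cds_seqs[i] <- cds

    # exon count of the representative isoform (CDS segments if the GFF3
    # carries no exon features)
    n_exon <- if (rep_tx %in% names(exon_count_by_tx))
      as.integer(exon_count_by_tx[[rep_tx]]) else 0L
    if (n_exon == 0L) n_exon <- length(seg_idx)
    rec$exon_count[i] <- n_exon

    # flanks: genomic sequence adjacent to the gene span, truncated at
    # chromosome ends; flank_up is 5' of the gene relative to its strand
    L <- nchar(chrom_str)
    fw <- config$flank_width
    left <- substr(chrom_str, max(1L, rec$start[i] - fw), rec$start[i] - 1L)
    right <- substr(chrom_str, rec$end[i] + 1L, min(L, rec$end[i] + fw))
    if (rec$start[i] <= 1L) left <- ""
    if (rec$end[i] >= L) right <- ""
    if (rec$strand[i] == "-") {
      rc <- function(s) if (nchar(s)) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s))) else ""
      up_seqs[i] <- rc(right); down_seqs[i] <- rc(left)
    } else {
      up_seqs[i] <- left; down_seqs[i] <- right
    }

    # filter 3: abnormal start and/or stop codon
    nc <- nchar(cds)
    bad_frame <- nc %% 3L != 0L || nc < 6L
    start_ok <- !bad_frame && substr(cds, 1L, 3L) %in% config$start_codons
    stop_ok <- !bad_frame && substr(cds, nc - 2L, nc) %in% config$stop_codons
    if (bad_frame || !start_ok || !stop_ok) {
      rec$exclusion_reason[i] <- "bad_start_stop"
      next
    }
    # filter 4: internal termination codon
    codons <- split_codons(cds)
    internal <- codons[-length(codons)]
    if (any(internal %in% STOP_CODONS)) {
      rec$exclusion_reason[i] <- "internal_stop"
      next
    }
    # filter 5: short CDS
    if (nc < config$min_cds_len) {
      rec$exclusion_reason[i] <- "short_cds"
      next
    }
    # filter 6: single-exon isoform of a multi-exon gene
    if (length(coding_tx) > 1L && config$sei_policy == "exclude") {
      other_multi <- any(vapply(setdiff(tx_ids, rep_tx), function(tid) {
        ne <- if (tid %in% names(exon_count_by_tx))
          as.integer(exon_count_by_tx[[tid]]) else 0L
        if (ne == 0L) ne <- length(cds_by_tx[[tid]])
        ne >= 2L
      }, logical(1)))
      if (n_exon == 1L && other_multi) {
        rec$exclusion_reason[i] <- "single_exon_isoform"
        next
      }
    }
    rec$label[i] <- "RETAINED"
  }

  keep <- rec$label == "RETAINED"
  cds_set <- Biostrings::DNAStringSet(cds_seqs)
  up_set <- Biostrings::DNAStringSet(up_seqs)
  down_set <- Biostrings::DNAStringSet(down_seqs)
  names(cds_set) <- names(up_set) <- names(down_set) <- rec$gene_id

  catalog <- structure(list(
    records = rec,
    cds = cds_set, flank_up = up_set, flank_down = down_set,
    genome = genome,
    genome_lengths = stats::setNames(Biostrings::width(genome), names(genome)),
    config = config, provenance = provenance),
    class = "gene_catalog")
  classify(catalog)
}

#' Classify retained genes as SEG or MEG
#'
#' A retained gene with a single exon is a single-exon gene (SEG); any
#' retained gene with two or more exons is a multiple-exon gene (MEG).
#' Excluded genes keep their label and reason.
#'
#' @param catalog a `gene_catalog`.
#' @return the catalog with `records$label` set to SEG/MEG/EXCLUDED.
#' @export
classify <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  rec <- catalog$records
  open <- rec$label != "EXCLUDED"
  rec$label[open] <- ifelse(rec$exon_count[open] == 1L, "SEG", "MEG")
  catalog$records <- rec
  catalog
}

#' @noRd
retained_records <- function(catalog) {
  catalog$records[catalog$records$label %in% c("SEG", "MEG"), , drop = FALSE]
}

#' GC content of the noncoding flanks of a gene
#'
#' Pools the upstream and downstream flanks and returns their G+C fraction;
#' ambiguous bases are dropped from numerator and denominator. `NA` (never
#' 0) when both flanks are empty.
#'
#' @param catalog a `gene_catalog`.
#' @param gene_id gene identifier(s); default all retained genes.
#' @return named numeric vector of flank GC fractions.
#' @export
flank_gc <- function(catalog, gene_id = retained_records(catalog)$gene_id) {
  vapply(gene_id, function(id)
    flank_gc_pair(catalog$flank_up[[id]], catalog$flank_down[[id]]),
    numeric(1))
}

flank_gc_pair <- function(up, down) {
  s <- paste0(as.character(up), as.character(down))
  bases <- strsplit(toupper(s), "")[[1]]
  bases <- bases[bases %in% c("A", "C", "G", "T")]
  if (length(bases) == 0L) return(NA_real_)
  mean(bases %in% c("G", "C"))
}

#' Partition chromosomes into equal regions and count genes per region
#'
#' Splits every chromosome into `n_bins` equal (within 1 bp) intervals,
#' computes the GC content of each region's genomic sequence, and counts the
#' retained SEGs and MEGs whose midpoint falls in the region.
#'
#' @param catalog a `gene_catalog` with labels assigned.
#' @param n_bins number of regions per chromosome.
#' @return data.frame with columns `chromosome, region_index, region_start,
#'   region_end, region_gc, seg_count, meg_count`.
#' @export
bin_chromosomes <- function(catalog, n_bins = 10L) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  rec <- retained_records(catalog)
  out <- list()
  for (chrom in names(catalog$genome)) {
    L <- catalog$genome_lengths[[chrom]]
    breaks <- round(seq(0, L, length.out = n_bins + 1L))
    starts <- breaks[-(n_bins + 1L)] + 1L
    ends <- breaks[-1L]
    chrom_seq <- as.character(catalog$genome[[chrom]])
    gc <- vapply(seq_len(n_bins), function(b) {
      bases <- strsplit(substr(chrom_seq, starts[b], ends[b]), "")[[1]]
      bases <- bases[bases %in% c("A", "C", "G", "T")]
      if (length(bases) == 0L) NA_real_ else mean(bases %in% c("G", "C"))
    }, numeric(1))
    on_chrom <- rec[rec$chromosome == chrom, , drop = FALSE]
    mid <- floor((on_chrom$start + on_chrom$end) / 2)
    bin <- findInterval(mid, breaks, left.open = TRUE, rightmost.closed = TRUE)
    bin <- pmin(pmax(bin, 1L), n_bins)
    seg_count <- tabulate(bin[on_chrom$label == "SEG"], n_bins)
    meg_count <- tabulate(bin[on_chrom$label == "MEG"], n_bins)
    out[[chrom]] <- data.frame(
      chromosome = chrom, region_index = seq_len(n_bins),
      region_start = starts, region_end = ends, region_gc = gc,
      seg_count = seg_count, meg_count = meg_count,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write catalog outputs (gene table TSV + retained CDS FASTA)
#'
#' @param catalog a `gene_catalog`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_catalog <- function(catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "gene_table.tsv")
  utils::write.table(catalog$records, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fasta <- file.path(dir, "retained_cds.fasta")
  keep <- retained_records(catalog)$gene_id
  Biostrings::writeXStringSet(catalog$cds[keep], fasta)
  invisible(c(gene_table = tsv, cds_fasta = fasta))
}

#' @export
print.gene_catalog <- function(x, ...) {
  rec <- x$records
  cat("gene_catalog:", nrow(rec), "genes on", length(x$genome),
      "chromosomes\n")
  cat("  SEG:", sum(rec$label == "SEG"),
      " MEG:", sum(rec$label == "MEG"),
      " excluded:", sum(rec$label == "EXCLUDED"), "\n")
  if (any(rec$label == "EXCLUDED")) {
    tab <- table(rec$exclusion_reason[rec$label == "EXCLUDED"])
    for (r in names(tab)) cat("    ", r, ": ", tab[[r]], "\n", sep = "")
  }
  invisible(x)
}
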