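# Fixtures built in code: hand-made FASTA/GFF3 catalogs exercising every
# exclusion filter, random valid CDS, and a cached small synthetic run
# shared by tests that need a realistic catalog.

SENSE_NO_STOP <- names(oracle_code)[oracle_code != "*"]

# a filter-clean CDS: ATG + random sense codons (no Met/Trp constraint) + TAA
rand_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0("ATG",
         paste(sample(SENSE_NO_STOP, n_codons - 2, replace = TRUE),
               collapse = ""),
         "TAA")
}

# deterministic filler DNA (GC = 0.5)
filler <- function(n) {
  paste(rep_len(c("A", "C", "G", "T"), n), collapse = "")
}

gff_line <- function(chrom, type, start, end, strand, attrs) {
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
          chrom, type, start, end, strand, attrs)
}

# one gene violating each filter plus two clean genes (one SEG, one MEG)
write_filter_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(424)
  spacer <- 300L
  chr1 <- ""
  gff <- c("##gff-version 3")
  pos <- 0L

  add_gene <- function(gid, body, features) {
    start <- pos + spacer + 1L
    chr1 <<- paste0(chr1, filler(spacer), body)
    pos <<- pos + spacer + nchar(body)
    gff <<- c(gff, features(start, start + nchar(body) - 1L))
    invisible(start)
  }

  # clean single-exon gene
  cds1 <- rand_cds(102)
  add_gene("g_seg", cds1, function(s, e) c(
    gff_line("Chr1", "gene", s, e, "+", "ID=g_seg"),
    gff_line("Chr1", "mRNA", s, e, "+", "ID=g_seg.1;Parent=g_seg"),
    gff_line("Chr1", "exon", s, e, "+", "ID=g_seg.1.e1;Parent=g_seg.1"),
    gff_line("Chr1", "CDS", s, e, "+", "ID=g_seg.1.c1;Parent=g_seg.1")))

  # clean two-exon gene: CDS split 150 + 156 around a 90 bp intron
  cds2 <- rand_cds(102)
  intron <- filler(90)
  body2 <- paste0(substr(cds2, 1, 150), intron, substr(cds2, 151, 306))
  add_gene("g_meg", body2, function(s, e) c(
    gff_line("Chr1", "gene", s, e, "+", "ID=g_meg"),
    gff_line("Chr1", "mRNA", s, e, "+", "ID=g_meg.1;Parent=g_meg"),
    gff_line("Chr1", "exon", s, s + 149L, "+", "ID=g_meg.1.e1;Parent=g_meg.1"),
    gff_line("Chr1", "exon", s + 240L, e, "+", "ID=g_meg.1.e2;Parent=g_meg.1"),
    gff_line("Chr1", "CDS", s, s + 149L, "+", "ID=g_meg.1.c1;Parent=g_meg.1"),
    gff_line("Chr1", "CDS", s + 240L, e, "+", "ID=g_meg.1.c2;Parent=g_meg.1")))

  # noncoding RNA gene
  add_gene("g_nc", filler(200), function(s, e) c(
    gff_line("Chr1", "gene", s, e, "+", "ID=g_nc"),
    gff_line("Chr1", "tRNA", s, e, "+", "ID=g_nc.1;Parent=g_nc"),
    gff_line("Chr1", "exon", s, e, "+", "ID=g_nc.1.e1;Parent=g_nc.1")))

  # abnormal start codon
  cds4 <- paste0("GGG", substr(rand_cds(102), 4, 306))
  add_gene("g_badstart", cds4, function(s, e) c(
    gff_line("Chr1", "gene", s, e, "+", "ID=g_badstart"),
    gff_line("Chr1", "mRNA", s, e, "+", "ID=g_badstart.1;Parent=g_badstart"),
    gff_line("Chr1", "exon", s, e, "+", "ID=g_badstart.1.e1;Parent=g_badstart.1"),
    gff_line("Chr1", "CDS", s, e, "+", "ID=g_badstart.1.c1;Parent=g_badstart.1")))

  # internal stop codon at codon 50
  cds5 <- rand_cds(102)
  cds5 <- paste0(substr(cds5, 1, 147), "TAA", substr(cds5, 151, 306))
  add_gene("g_intstop", cds5, function(s, e) c(
    gff_line("Chr1", "gene", s, e, "+", "ID=g_intstop"),
    gff_line("Chr1", "mRNA", s, e, "+", "ID=g_intstop.1;Parent=g_intstop"),
    gff_line("Chr1", "exon", s, e, "+", "ID=g_intstop.1.e1;Parent=g_intstop.1"),
    gff_line("Chr1", "CDS", s, e, "+", "ID=g_intstop.1.c1;Parent=g_intstop.1")))

  # short CDS (150 bp < 300)
  cds6 <- rand_cds(50)
  add_gene("g_short", cds6, function(s, e) c(
    gff_line("Chr1", "gene", s, e, "+", "ID=g_short"),
    gff_line("Chr1", "mRNA", s, e, "+", "ID=g_short.1;Parent=g_short"),
    gff_line("Chr1", "exon", s, e, "+", "ID=g_short.1.e1;Parent=g_short.1"),
    gff_line("Chr1", "CDS", s, e, "+", "ID=g_short.1.c1;Parent=g_short.1")))

  # single-exon isoform of a multi-exon gene: the longest-CDS isoform is
  # intronless while a shorter isoform has two exons
  cds7 <- rand_cds(104)   # 312 bp single-exon isoform (representative)
  add_gene("g_sei", cds7, function(s, e) c(
    gff_line("Chr1", "gene", s, e, "+", "ID=g_sei"),
    gff_line("Chr1", "mRNA", s, e, "+", "ID=g_sei.1;Parent=g_sei"),
    gff_line("Chr1", "exon", s, e, "+", "ID=g_sei.1.e1;Parent=g_sei.1"),
    gff_line("Chr1", "CDS", s, e, "+", "ID=g_sei.1.c1;Parent=g_sei.1"),
    gff_line("Chr1", "mRNA", s, e - 60L, "+", "ID=g_sei.2;Parent=g_sei"),
    gff_line("Chr1", "exon", s, s + 119L, "+", "ID=g_sei.2.e1;Parent=g_sei.2"),
    gff_line("Chr1", "exon", s + 180L, e - 60L, "+", "ID=g_sei.2.e2;Parent=g_sei.2"),
    gff_line("Chr1", "CDS", s, s + 119L, "+", "ID=g_sei.2.c1;Parent=g_sei.2"),
    gff_line("Chr1", "CDS", s + 180L, e - 60L, "+", "ID=g_sei.2.c2;Parent=g_sei.2")))

  chr1 <- paste0(chr1, filler(spacer))

  # gene on an unanchored scaffold
  cds8 <- rand_cds(102)
  chrsy <- paste0(filler(spacer), cds8, filler(spacer))
  gff <- c(gff,
           gff_line("ChrSy", "gene", spacer + 1L, spacer + 306L, "+",
                    "ID=g_unknown"),
           gff_line("ChrSy", "mRNA", spacer + 1L, spacer + 306L, "+",
                    "ID=g_unknown.1;Parent=g_unknown"),
           gff_line("ChrSy", "CDS", spacer + 1L, spacer + 306L, "+",
                    "ID=g_unknown.1.c1;Parent=g_unknown.1"))

  fasta <- file.path(dir, "genome.fasta")
  gff3 <- file.path(dir, "annotation.gff3")
  writeLines(c(">Chr1", chr1, ">ChrSy", chrsy), fasta)
  writeLines(gff, gff3)
  list(fasta = fasta, gff3 = gff3,
       clean_cds = c(g_seg = cds1, g_meg = cds2))
}

# small synthetic run shared by several tests; built once per session
.small_run_cache <- new.env(parent = emptyenv())
get_small_run <- function() {
  if (!is.null(.small_run_cache$run)) return(.small_run_cache$run)
  cfg <- synthetic_config(seed = 101, n_seg = 60L, n_meg = 216L,
                          mean_length_codons = c(seg = 120, meg = 160),
                          min_length_codons = 100L)
  dir <- file.path(tempdir(), "codonica-small-run")
  sim <- simulate_catalog(cfg, dir)
  catalog <- load_catalog(sim$fasta, sim$gff3)
  profiles <- composition_profiles(catalog)
  .small_run_cache$run <- list(config = cfg, sim = sim, catalog = catalog,
                               profiles = profiles,
                               counts = attr(profiles, "counts"))
  .small_run_cache$run
}

# default-scale study-condition run, shared by the calibration checks
get_full_run <- function() {
  if (!is.null(.small_run_cache$full)) return(.small_run_cache$full)
  cfg <- synthetic_config(seed = 41)
  dir <- file.path(tempdir(), "codonica-full-run")
  sim <- simulate_catalog(cfg, dir)
  catalog <- load_catalog(sim$fasta, sim$gff3)
  profiles <- composition_profiles(catalog)
  .small_run_cache$full <- list(config = cfg, sim = sim, catalog = catalog,
                                profiles = profiles,
                                counts = attr(profiles, "counts"))
  .small_run_cache$full
}
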