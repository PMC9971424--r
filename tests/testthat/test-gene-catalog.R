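test_that("minus-strand multi-segment CDS is spliced and reverse-complemented", {
  dir <- file.path(tempdir(), "minus-fixture")
  dir.create(dir, showWarnings = FALSE)
  set.seed(99)
  chr <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  # two CDS segments on the minus strand at [501,650] and [801,956]
  writeLines(c(">Chr1", chr), file.path(dir, "g.fasta"))
  writeLines(c(
    "##gff-version 3",
    gff_line("Chr1", "gene", 501L, 956L, "-", "ID=gm"),
    gff_line("Chr1", "mRNA", 501L, 956L, "-", "ID=gm.1;Parent=gm"),
    gff_line("Chr1", "CDS", 501L, 650L, "-", "ID=c1;Parent=gm.1"),
    gff_line("Chr1", "CDS", 801L, 956L, "-", "ID=c2;Parent=gm.1")),
    file.path(dir, "g.gff3"))
  catalog <- load_catalog(file.path(dir, "g.fasta"),
                          file.path(dir, "g.gff3"))
  expected <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(substr(chr, 501, 650),
                                 substr(chr, 801, 956)))))
  expect_equal(as.character(catalog$cds[["gm"]]), expected)
  expect_equal(catalog$records$exon_count, 2L)
})

test_that("the longest-CDS isoform is the representative", {
  dir <- file.path(tempdir(), "isoform-fixture")
  dir.create(dir, showWarnings = FALSE)
  cds_long <- rand_cds(200, seed = 7)    # 600 bp
  cds_short <- substr(cds_long, 1, 297)  # 300 bp prefix (invalid stop, unused)
  chr <- paste0(filler(300), cds_long, filler(300))
  writeLines(c(">Chr1", chr), file.path(dir, "g.fasta"))
  s <- 301L
  writeLines(c(
    "##gff-version 3",
    gff_line("Chr1", "gene", s, s + 599L, "+", "ID=gi"),
    gff_line("Chr1", "mRNA", s, s + 599L, "+", "ID=gi.1;Parent=gi"),
    gff_line("Chr1", "CDS", s, s + 599L, "+", "ID=gi.1c;Parent=gi.1"),
    gff_line("Chr1", "mRNA", s, s + 299L, "+", "ID=gi.2;Parent=gi"),
    gff_line("Chr1", "CDS", s, s + 299L, "+", "ID=gi.2c;Parent=gi.2")),
    file.path(dir, "g.gff3"))
  catalog <- load_catalog(file.path(dir, "g.fasta"),
                          file.path(dir, "g.gff3"))
  expect_equal(catalog$records$cds_length, 600L)
  expect_equal(as.character(catalog$cds[["gi"]]), cds_long)
})

test_that("each exclusion filter fires once on the eight-gene fixture", {
  fx <- write_filter_fixture(file.path(tempdir(), "filter-fixture"))
  catalog <- load_catalog(fx$fasta, fx$gff3)
  rec <- catalog$records
  expect_equal(nrow(rec), 8L)
  retained <- rec[rec$label != "EXCLUDED", ]
  expect_equal(sort(retained$gene_id), c("g_meg", "g_seg"))
  expect_equal(rec$label[rec$gene_id == "g_seg"], "SEG")
  expect_equal(rec$label[rec$gene_id == "g_meg"], "MEG")
  reasons <- setNames(rec$exclusion_reason, rec$gene_id)
  expect_equal(reasons[["g_nc"]], "noncoding_rna")
  expect_equal(reasons[["g_badstart"]], "bad_start_stop")
  expect_equal(reasons[["g_intstop"]], "internal_stop")
  expect_equal(reasons[["g_short"]], "short_cds")
  expect_equal(reasons[["g_sei"]], "single_exon_isoform")
  expect_equal(reasons[["g_unknown"]], "unknown_chromosome")
  # count conservation: exactly one reason per excluded gene
  expect_equal(sum(rec$label == "EXCLUDED") + nrow(retained), nrow(rec))
  expect_true(all(rec$exclusion_reason[rec$label == "EXCLUDED"] != ""))
  expect_true(all(rec$exclusion_reason[rec$label != "EXCLUDED"] == ""))
  # extracted clean CDS match construction and translate without stops
  expect_equal(as.character(catalog$cds[["g_seg"]]), fx$clean_cds[["g_seg"]])
  for (id in retained$gene_id) {
    aa <- codonica:::translate_cds(as.character(catalog$cds[[id]]))
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("the representative-isoform policy keeps SEI genes when configured", {
  fx <- write_filter_fixture(file.path(tempdir(), "filter-fixture2"))
  catalog <- load_catalog(fx$fasta, fx$gff3,
                          catalog_config(sei_policy = "representative"))
  rec <- catalog$records
  expect_equal(rec$label[rec$gene_id == "g_sei"], "SEG")
})

test_that("retained CDS written to FASTA read back identically", {
  fx <- write_filter_fixture(file.path(tempdir(), "filter-fixture3"))
  catalog <- load_catalog(fx$fasta, fx$gff3)
  out <- write_catalog(catalog, file.path(tempdir(), "catalog-out"))
  back <- Biostrings::readDNAStringSet(out[["cds_fasta"]])
  keep <- catalog$records$gene_id[catalog$records$label != "EXCLUDED"]
  expect_equal(as.character(back), as.character(catalog$cds[keep]))
})

test_that("flank GC pools both flanks and drops ambiguous bases", {
  expect_equal(codonica:::flank_gc_pair("GGCC", "GGCC"), 1)
  expect_equal(codonica:::flank_gc_pair("ATAT", "ATAT"), 0)
  # pooled unambiguous bases A,T,G,C,A,A: two of six are G or C
  expect_equal(codonica:::flank_gc_pair("ATGC", "AANN"), 1 / 3)
  expect_true(is.na(codonica:::flank_gc_pair("", "")))
  expect_true(is.na(codonica:::flank_gc_pair("NNN", "NN")))
})

test_that("chromosome binning partitions into equal regions and counts by midpoint", {
  run <- get_small_run()
  rt <- bin_chromosomes(run$catalog, n_bins = 10)
  for (chrom in names(run$catalog$genome)) {
    rows <- rt[rt$chromosome == chrom, ]
    expect_equal(nrow(rows), 10L)
    L <- run$catalog$genome_lengths[[chrom]]
    expect_equal(rows$region_start[1], 1L)
    expect_equal(rows$region_end[10], as.integer(L))
    expect_true(all(rows$region_start[-1] == rows$region_end[-10] + 1L))
    widths <- rows$region_end - rows$region_start + 1L
    expect_lte(diff(range(widths)), 1L)
  }
  rec <- run$catalog$records
  expect_equal(sum(rt$seg_count), sum(rec$label == "SEG"))
  expect_equal(sum(rt$meg_count), sum(rec$label == "MEG"))
  # rank correlation downstream agrees with a brute-force implementation
  ok <- is.finite(rt$region_gc)
  expect_equal(cor(rt$region_gc[ok], rt$seg_count[ok], method = "spearman"),
               oracle_spearman(rt$region_gc[ok], rt$seg_count[ok]),
               tolerance = 1e-10)
  expect_error(bin_chromosomes(run$catalog, n_bins = 0), "n_bins")
})

test_that("a gene midpoint on a region boundary goes to the earlier region", {
  dir <- file.path(tempdir(), "bin-fixture")
  dir.create(dir, showWarnings = FALSE)
  chr <- paste0(filler(94), rand_cds(102, seed = 5), filler(1000 - 94 - 306))
  writeLines(c(">Chr1", chr), file.path(dir, "g.fasta"))
  # gene spanning 95..400: midpoint 247 -> region 3 of width-100 bins; then
  # check the documented boundary case with a synthetic record
  writeLines(c(
    "##gff-version 3",
    gff_line("Chr1", "gene", 95L, 400L, "+", "ID=gb"),
    gff_line("Chr1", "mRNA", 95L, 400L, "+", "ID=gb.1;Parent=gb"),
    gff_line("Chr1", "CDS", 95L, 400L, "+", "ID=gb.1c;Parent=gb.1")),
    file.path(dir, "g.gff3"))
  catalog <- load_catalog(file.path(dir, "g.fasta"), file.path(dir, "g.gff3"))
  rt <- bin_chromosomes(catalog, n_bins = 10)
  expect_equal(rt$seg_count[rt$region_index == 3], 1L)
  # midpoint exactly 100 (gene 95..105) falls in region 1
  catalog$records$start <- 95L
  catalog$records$end <- 105L
  rt2 <- bin_chromosomes(catalog, n_bins = 10)
  expect_equal(rt2$seg_count[rt2$region_index == 1], 1L)
})

test_that("missing input files and malformed GFF3 raise named errors", {
  expect_error(load_catalog("nope.fasta", "nope.gff3"))
  dir <- file.path(tempdir(), "bad-gff")
  dir.create(dir, showWarnings = FALSE)
  writeLines(c(">Chr1", filler(100)), file.path(dir, "g.fasta"))
  writeLines(c("##gff-version 3", "Chr1\tonly\tthree"),
             file.path(dir, "bad.gff3"))
  expect_error(load_catalog(file.path(dir, "g.fasta"),
                            file.path(dir, "bad.gff3")),
               "bad.gff3")
})
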