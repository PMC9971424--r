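test_that("codon counting tallies frame-0 codons and skips stops and ambiguity", {
  x <- count_codons("ATGAAATAA")
  expect_equal(x[["ATG"]], 1L)
  expect_equal(x[["AAA"]], 1L)
  expect_equal(x[["TAA"]], 0L)
  expect_equal(attr(x, "n_codons_used"), 2L)

  y <- count_codons("AAANNNAAA")
  expect_equal(y[["AAA"]], 2L)
  expect_equal(attr(y, "n_codons_used"), 2L)

  expect_error(count_codons("ATGA"), "divisible by 3")

  # one copy of every sense non-Met/Trp codon
  cds59 <- paste(codonica:::SYN_CODONS, collapse = "")
  z <- count_codons(cds59)
  expect_true(all(z[codonica:::SYN_CODONS] == 1L))
  expect_equal(attr(z, "n_codons_used"), 59L)
})

test_that("Wright's homozygosity matches hand evaluation", {
  # two-fold family with counts (3,1): F = (4 * 0.625 - 1) / 3 = 0.5
  expect_equal(codonica:::wright_f(c(3, 1)), 0.5)
  expect_equal(codonica:::wright_f(c(5, 5)), (10 * 0.5 - 1) / 9)
  expect_true(is.na(codonica:::wright_f(c(1, 0))))
})

test_that("ENC hits its bounds: 20 for one codon per family, ~61 for uniform usage", {
  one_each <- integer(64)
  names(one_each) <- names(Biostrings::GENETIC_CODE)
  for (fam in codonica:::SYN_FAMILIES) one_each[fam[1]] <- 20L
  expect_equal(enc(one_each), 20)

  set.seed(11)
  cds <- paste(sample(codonica:::SYN_CODONS, 10000, replace = TRUE),
               collapse = "")
  expect_gt(enc(count_codons(cds)), 59.5)
  expect_lte(enc(count_codons(cds)), 61)
})

test_that("ENC never decreases when within-family usage gets more even", {
  # both profiles skewed enough to stay below the 61 cap
  mild <- strong <- integer(64)
  names(mild) <- names(strong) <- names(Biostrings::GENETIC_CODE)
  for (fam in codonica:::SYN_FAMILIES) {
    mild[fam] <- c(4L, rep(1L, length(fam) - 1L))
    strong[fam] <- c(16L, rep(1L, length(fam) - 1L))
  }
  expect_lt(enc(mild), 61)
  expect_gt(enc(mild), enc(strong))
})

test_that("RSCU matches hand values and is missing (not 0) for absent families", {
  counts <- integer(64)
  names(counts) <- names(Biostrings::GENETIC_CODE)
  counts[c("AAA", "AAG")] <- c(3L, 1L)   # Lys
  r <- rscu(counts)
  expect_equal(r[["AAA"]], 1.5)
  expect_equal(r[["AAG"]], 0.5)
  expect_true(is.na(r[["GGG"]]))

  for (fam in codonica:::SYN_FAMILIES) counts[fam] <- 7L
  expect_true(all(abs(rscu(counts) - 1) < 1e-12))
})

test_that("CAI weights are RSCU ratios with pseudo-count smoothing", {
  counts <- integer(64)
  names(counts) <- names(Biostrings::GENETIC_CODE)
  for (fam in codonica:::SYN_FAMILIES) counts[fam] <- 5L
  counts[c("AAA", "AAG")] <- c(9L, 1L)
  w <- cai_weights(counts)
  expect_equal(w[["AAA"]], 1)
  expect_equal(w[["AAG"]], 1 / 9)
  expect_equal(w[["TTT"]], 1)  # (5,5) family

  counts[c("AAA", "AAG")] <- c(8L, 0L)
  w2 <- cai_weights(counts, pseudo_count = 0.5)
  expect_equal(w2[["AAG"]], 0.5 / 8)

  empty <- integer(64)
  names(empty) <- names(Biostrings::GENETIC_CODE)
  expect_error(cai_weights(empty), "empty reference")
})

test_that("CAI is the geometric mean of weights and ignores Met/Trp", {
  counts <- integer(64)
  names(counts) <- names(Biostrings::GENETIC_CODE)
  w <- rep(1, 59)
  names(w) <- codonica:::SYN_CODONS
  counts[c("AAA", "TTT")] <- c(2L, 3L)
  expect_equal(cai(counts, w), 1)

  w[["AAA"]] <- 1; w[["AAG"]] <- 0.5
  counts[] <- 0L
  counts[c("AAA", "AAG")] <- c(1L, 1L)
  expect_equal(cai(counts, w), sqrt(0.5))

  counts[["ATG"]] <- 5L  # Met must not change CAI
  expect_equal(cai(counts, w), sqrt(0.5))

  counts[] <- 0L
  expect_true(is.na(cai(counts, w)))
})

test_that("composition handles degenerate single-codon input", {
  comp <- composition(strrep("GGG", 40))
  expect_equal(comp[["g3s"]], 1)
  expect_equal(comp[["a3s"]], 0)
  expect_equal(comp[["c3s"]], 0)
  expect_equal(comp[["t3s"]], 0)
  expect_equal(comp[["gc3"]], 1)
  expect_equal(comp[["gc12"]], (comp[["gc1"]] + comp[["gc2"]]) / 2)
})

test_that("all indices agree with brute-force oracles on random CDS", {
  set.seed(202)
  ref_counts <- count_codons(rand_cds(4000))
  w <- cai_weights(ref_counts)
  w_oracle <- w  # same weights fed to both routes; CAI formula under test
  for (i in 1:50) {
    cds <- rand_cds(sample(80:200, 1))
    counts <- count_codons(cds)
    expect_equal(as.integer(counts), as.integer(oracle_counts(cds)))
    e1 <- enc(counts); e2 <- oracle_enc(oracle_counts(cds))
    expect_equal(e1, e2, tolerance = 1e-12)
    r1 <- rscu(counts); r2 <- oracle_rscu(oracle_counts(cds))
    expect_equal(r1[sort(names(r1))], r2[sort(names(r2))],
                 tolerance = 1e-12)
    expect_equal(cai(counts, w), oracle_cai(oracle_counts(cds), w_oracle),
                 tolerance = 1e-12)
    expect_equal(composition(cds), oracle_composition(cds),
                 tolerance = 1e-12)
  }
})

test_that("ENC and CAI rank genes oppositely on a shared bias axis", {
  set.seed(303)
  n <- 120
  bias <- runif(n, 0, 3)
  genes <- vapply(seq_len(n), function(i) {
    codons <- unlist(lapply(codonica:::SYN_FAMILIES, function(fam) {
      k <- length(fam)
      w <- exp(bias[i] * (seq_len(k) == 1))
      sample(fam, 30, replace = TRUE, prob = w / sum(w))
    }))
    paste(sample(codons), collapse = "")
  }, character(1))
  counts <- codon_count_matrix(genes)
  enc_v <- apply(counts, 1, enc)
  w <- cai_weights(colSums(counts[order(enc_v)[1:6], , drop = FALSE]))
  cai_v <- apply(counts, 1, cai, weights = w)
  expect_lt(cor(enc_v, cai_v, method = "spearman"), 0)
})
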