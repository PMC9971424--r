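random_usage_matrix <- function(n, lambda = 4) {
  m <- matrix(rpois(n * 59, lambda), n, 59)
  colnames(m) <- codonica:::SYN_CODONS
  rownames(m) <- paste0("g", seq_len(n))
  m[rowSums(m) == 0, 1] <- 1L
  m
}

test_that("chi-square inertia matches hand values and the brute-force double sum", {
  m <- matrix(c(10, 0, 0, 10), 2, 2)
  expect_equal(ca_inertia(m)$total_inertia, 1)

  # rows proportional to the column margin: independence, inertia 0
  ind <- outer(c(2, 4, 6), c(1, 2, 3, 4))
  expect_equal(ca_inertia(ind)$total_inertia, 0, tolerance = 1e-14)

  set.seed(21)
  for (i in 1:5) {
    m <- random_usage_matrix(20)
    res <- ca_inertia(m)
    expect_equal(res$total_inertia, oracle_inertia(m), tolerance = 1e-12)
    ev_all <- svd((m / sum(m) - outer(rowSums(m), colSums(m)) / sum(m)^2) /
                    sqrt(outer(rowSums(m), colSums(m)) / sum(m)^2))$d^2
    expect_equal(sum(ev_all), res$total_inertia, tolerance = 1e-10)
  }
})

test_that("table construction validates classes and drops empty genes", {
  m <- random_usage_matrix(4)
  tab <- build_table(m, c("A", "A", "B", "B"))
  expect_equal(dim(tab$matrix), c(4L, 59L))
  expect_equal(nlevels(tab$col_block), 18L)
  expect_error(build_table(m, c("A", "A", "A", "B")), "fewer than 2")

  m2 <- rbind(m, onlymet = 0L)
  expect_message(
    tab2 <- build_table(m2, c("A", "A", "B", "B", "A")),
    "dropping 1")
  expect_equal(nrow(tab2$matrix), 4L)
  expect_true("onlymet" %in% tab2$dropped)
})

test_that("the four inertia components satisfy all additivity identities", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(8:25, 1)
    m <- random_usage_matrix(n, lambda = sample(2:6, 1))
    cls <- sample(c("A", "B", "C")[seq_len(sample(2:3, 1))], n,
                  replace = TRUE)
    if (min(table(cls)) < 2) next
    tab <- build_table(m, cls)
    dec <- ica_decompose(tab)
    tot <- dec$total_inertia
    expect_equal(sum(dec$components), tot, tolerance = 1e-10)
    expect_equal(dec$components[["bb"]] + dec$components[["bw"]],
                 ca_inertia(rowsum(tab$matrix, tab$row_class))$total_inertia,
                 tolerance = 1e-10)
    expect_equal(dec$components[["bb"]] + dec$components[["wb"]],
                 ca_inertia(t(rowsum(t(tab$matrix),
                                     tab$col_block)))$total_inertia,
                 tolerance = 1e-10)
    # every elementary analysis's eigenvalues sum to its inertia
    dec_full <- ica_decompose(tab, n_eigen = 100L)
    for (e in dec_full$elementary) {
      expect_equal(sum(e$eigenvalues), e$inertia, tolerance = 1e-9)
      expect_true(all(e$eigenvalues >= 0))
    }
  }
})

test_that("identical class-mean profiles give zero between-class inertia", {
  set.seed(41)
  base <- random_usage_matrix(6)
  m <- rbind(base, base)  # class 2 duplicates class 1 row-wise
  rownames(m) <- paste0("g", 1:12)
  tab <- build_table(m, rep(c("A", "B"), each = 6))
  dec <- ica_decompose(tab)
  expect_equal(dec$components[["bb"]] + dec$components[["bw"]], 0,
               tolerance = 1e-12)
})

test_that("synonymous-only divergence appears purely in the within-block part", {
  # class 2 = class 1 with synonymous codons permuted within families:
  # amino-acid totals untouched, so the between x between component is 0
  set.seed(51)
  base <- random_usage_matrix(8)
  perm <- base
  for (fam in codonica:::SYN_FAMILIES) {
    perm[, fam] <- perm[, sample(fam), drop = FALSE]
  }
  colnames(perm) <- colnames(base)
  m <- rbind(base, perm)
  rownames(m) <- paste0("g", 1:16)
  tab <- build_table(m, rep(c("A", "B"), each = 8))
  dec <- ica_decompose(tab)
  expect_equal(dec$components[["bb"]], 0, tolerance = 1e-12)
  expect_gt(dec$components[["bw"]], 0)
})

test_that("percentages are invariant to scaling all counts", {
  set.seed(61)
  m <- random_usage_matrix(10)
  cls <- rep(c("A", "B"), each = 5)
  p1 <- ica_decompose(build_table(m, cls))$percentages
  p2 <- ica_decompose(build_table(m * 7L, cls))$percentages
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("label permutation collapses the between-class synonymous share", {
  # chance between-class inertia shrinks with gene count, so this runs at
  # the default study scale
  run <- get_full_run()
  tab <- build_table(run$counts, run$profiles$label)
  observed <- between_class_synonymous_pct(tab)
  set.seed(71)
  perm_vals <- replicate(200, {
    between_class_synonymous_pct(tab$matrix,
                                 classes = sample(tab$row_class))
  })
  expect_lt(median(perm_vals), 0.01 * observed)
})

test_that("the between-class synonymous share increases with the preference divergence", {
  pcts <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(delta) {
    cfg <- synthetic_config(seed = 55, delta = delta, n_seg = 40L,
                            n_meg = 60L,
                            mean_length_codons = c(seg = 150, meg = 150),
                            gc3_spread = 0.6)
    sim <- simulate_catalog(cfg, file.path(tempdir(), "delta-grid"))
    catalog <- load_catalog(sim$fasta, sim$gff3)
    prof <- composition_profiles(catalog)
    between_class_synonymous_pct(build_table(attr(prof, "counts"),
                                             prof$label))
  }, numeric(1))
  expect_true(all(diff(pcts) > 0))
})
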