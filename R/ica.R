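# Correspondence analysis of a genes x codons table and its internal
# decomposition: with rows partitioned into gene classes and columns into
# amino-acid blocks, the total chi-square inertia splits exactly into four
# components (between/within class x between/within block) and nine
# elementary analyses, following the nested-centering scheme of internal
# correspondence analysis (Lobry & Chessel).

#' Build a genes x codons usage table with row and column partitions
#'
#' @param counts genes x codons count matrix (64 or 59 columns; extra
#'   columns are subset), e.g. the `counts` attribute of
#'   [composition_profiles()] or [codon_count_matrix()].
#' @param classes factor or character vector of row classes (gene type, GC3
#'   band, expression band, function set), one per gene.
#' @param codons `"59"` (default: sense codons minus Met and Trp, so
#'   singleton blocks do not dilute the synonymous component) or `"61"` (all
#'   sense codons).
#' @return object of class `codon_usage_table`: `matrix`, `row_class`
#'   (factor), `col_block` (factor of amino acids), `dropped` (gene ids with
#'   zero included codons).
#' @export
build_table <- function(counts, classes, codons = c("59", "61")) {
  codons <- match.arg(codons)
  included <- if (codons == "59") SYN_CODONS else SENSE_CODONS
  stopifnot(is.matrix(counts), length(classes) == nrow(counts))
  m <- counts[, included, drop = FALSE]
  classes <- factor(classes)
  zero <- rowSums(m) == 0
  dropped <- character(0)
  if (any(zero)) {
    dropped <- rownames(m)[zero]
    message("dropping ", sum(zero),
            " gene(s) with no included codons: ",
            paste(utils::head(dropped, 5), collapse = ", "))
    m <- m[!zero, , drop = FALSE]
    classes <- classes[!zero]
  }
  classes <- droplevels(classes)
  small <- names(which(table(classes) < 2L))
  if (length(small)) {
    stop("class(es) with fewer than 2 genes: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  structure(list(
    matrix = m,
    row_class = classes,
    col_block = factor(GENETIC_CODE_TABLE[included], levels = unique(GENETIC_CODE_TABLE[included])),
    dropped = dropped),
    class = "codon_usage_table")
}

# collapse a count matrix by a factor over rows
collapse_rows <- function(m, f) {
  rowsum(m, f, reorder = FALSE)
}

#' Chi-square inertia and eigenvalues of a contingency table
#'
#' Total inertia is `sum((f_ij - f_i. f_.j)^2 / (f_i. f_.j))` over relative
#' frequencies (chi-square / N); eigenvalues are the squared singular values
#' of the standardized residual matrix and sum to the total inertia.
#' Zero-margin rows and columns are dropped.
#'
#' @param x a `codon_usage_table` or a non-negative count matrix.
#' @param n_eigen number of leading eigenvalues to return.
#' @return list with `total_inertia` and `eigenvalues`.
#' @export
ca_inertia <- function(x, n_eigen = 10L) {
  m <- if (inherits(x, "codon_usage_table")) x$matrix else x
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (length(m) == 0L || sum(m) == 0) {
    return(list(total_inertia = 0, eigenvalues = numeric(0)))
  }
  P <- m / sum(m)
  r <- rowSums(P); cc <- colSums(P)
  E <- outer(r, cc)
  S <- (P - E) / sqrt(E)
  ev <- svd(S, nu = 0, nv = 0)$d^2
  ev[ev < 1e-12] <- 0
  list(total_inertia = sum(S^2),
       eigenvalues = utils::head(ev, n_eigen))
}

# eigenvalues (squared singular values) of a standardized residual matrix
resid_eigen <- function(S, n_eigen = 10L) {
  ev <- svd(S, nu = 0, nv = 0)$d^2
  ev[ev < 1e-12] <- 0
  utils::head(ev, n_eigen)
}

#' Internal correspondence analysis inertia decomposition
#'
#' Decomposes the total chi-square inertia of a genes x codons table, with
#' rows partitioned into gene classes and columns into amino-acid blocks,
#' into the four internal components:
#' between-class x between-block (amino-acid usage differences between
#' classes), between-class x within-block (synonymous codon usage
#' differences between classes), within-class x between-block, and
#' within-class x within-block. The between components are the inertias of
#' the class- and block-collapsed tables; additivity (the four components
#' sum to the total, as do both margins) is exact.
#'
#' Nine elementary analyses (rows in total/between/within x columns in
#' total/between/within) are reported, each with its inertia, percentage of
#' the total, and leading eigenvalues (default 10).
#'
#' @param table a `codon_usage_table` from [build_table()].
#' @param n_eigen number of leading eigenvalues per elementary analysis.
#' @return object of class `ica_decomposition`: `total_inertia`,
#'   `components` (named numeric: bb, bw, wb, ww), `percentages`,
#'   `elementary` (list of nine entries with `inertia`, `pct`,
#'   `eigenvalues`), `n_genes`, `n_codons`, `classes`.
#' @export
ica_decompose <- function(table, n_eigen = 10L) {
  stopifnot(inherits(table, "codon_usage_table"))
  m <- table$matrix
  k <- table$row_class
  B <- table$col_block
  nonzero_col <- colSums(m) > 0
  m <- m[, nonzero_col, drop = FALSE]
  B <- droplevels(B[nonzero_col])

  N <- sum(m)
  P <- m / N
  r <- rowSums(P); cc <- colSums(P)
  rho_m <- rowsum(r, k, reorder = FALSE)                # class masses
  rho <- stats::setNames(as.vector(rho_m), rownames(rho_m))
  gam_m <- rowsum(cc, B, reorder = FALSE)               # block masses
  gam <- stats::setNames(as.vector(gam_m), rownames(gam_m))

  Q <- collapse_rows(P, k)                              # classes x codons
  Pb <- t(collapse_rows(t(P), B))                       # genes x blocks
  M <- collapse_rows(Pb, k)                             # classes x blocks

  sq <- sqrt(outer(r, cc))

  # expected tables under the nested centerings
  E_ind <- outer(r, cc)
  E_class <- (r / rho[as.character(k)]) * Q[as.character(k), , drop = FALSE]
  E_block <- t((t(Pb[, as.character(B), drop = FALSE]) /
                  gam[as.character(B)]) * cc)
  E_both <- outer(r / rho[as.character(k)], cc / gam[as.character(B)]) *
    M[as.character(k), as.character(B), drop = FALSE]

  S_total <- (P - E_ind) / sq
  S_wclass <- (P - E_class) / sq
  S_wblock <- (P - E_block) / sq
  S_ww <- (P - E_class - E_block + E_both) / sq

  # collapsed-table residuals (between analyses)
  std_resid <- function(tab) {
    rr <- rowSums(tab); ccc <- colSums(tab)
    (tab - outer(rr, ccc)) / sqrt(outer(rr, ccc))
  }
  S_bclass <- std_resid(Q)                              # between-class, total
  S_bblock <- std_resid(Pb)                             # total, between-block
  S_bb <- std_resid(M)                                  # between x between

  # cross residuals: within-block centering of the class-collapsed table,
  # and within-class centering of the block-collapsed table
  Mk <- M                                               # classes x blocks
  E_block_Q <- t((t(Mk[, as.character(B), drop = FALSE]) /
                    gam[as.character(B)]) * cc)
  S_bw <- (Q - E_block_Q) / sqrt(outer(rho, cc))
  E_class_Pb <- (r / rho[as.character(k)]) * Mk[as.character(k), , drop = FALSE]
  S_wb <- (Pb - E_class_Pb) / sqrt(outer(r, gam))

  total <- sum(S_total^2)
  comp <- c(bb = sum(S_bb^2), bw = sum(S_bw^2),
            wb = sum(S_wb^2), ww = sum(S_ww^2))

  elem <- list(
    total_total = S_total,
    between_class_total = S_bclass,
    within_class_total = S_wclass,
    total_between_block = S_bblock,
    total_within_block = S_wblock,
    between_class_between_block = S_bb,
    between_class_within_block = S_bw,
    within_class_between_block = S_wb,
    within_class_within_block = S_ww)
  elementary <- lapply(elem, function(S) {
    inertia <- sum(S^2)
    list(inertia = inertia,
         pct = 100 * inertia / total,
         eigenvalues = resid_eigen(S, n_eigen))
  })

  structure(list(
    total_inertia = total,
    components = comp,
    percentages = 100 * comp / total,
    elementary = elementary,
    n_genes = nrow(m), n_codons = ncol(m),
    classes = levels(k)),
    class = "ica_decomposition")
}

#' Between-class synonymous percentage of a codon usage table
#'
#' The share of total inertia attributable to synonymous codon usage
#' differences between gene classes (the between-class x within-block
#' component), computed directly from the collapse identities. This is the
#' statistic recomputed by the resampling procedures.
#'
#' @param table a `codon_usage_table`, or a count matrix with `classes`.
#' @param classes row classes when `table` is a bare matrix.
#' @return percentage in `[0, 100]`.
#' @export
between_class_synonymous_pct <- function(table, classes = NULL) {
  if (inherits(table, "codon_usage_table")) {
    m <- table$matrix; k <- table$row_class; B <- table$col_block
  } else {
    m <- table; k <- factor(classes)
    B <- factor(GENETIC_CODE_TABLE[colnames(m)],
                levels = unique(GENETIC_CODE_TABLE[colnames(m)]))
  }
  total <- ca_inertia(m)$total_inertia
  Q <- collapse_rows(m, k)
  M <- t(collapse_rows(t(Q), B))
  bw <- ca_inertia(Q)$total_inertia - ca_inertia(M)$total_inertia
  100 * bw / total
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat("Internal correspondence analysis (", x$n_genes, " genes x ",
      x$n_codons, " codons; classes: ",
      paste(x$classes, collapse = ", "), ")\n", sep = "")
  cat(sprintf("  total inertia: %.6g\n", x$total_inertia))
  p <- x$percentages
  cat(sprintf("  between-class x between-block: %6.2f%%\n", p["bb"]))
  cat(sprintf("  between-class x within-block : %6.2f%%  (synonymous, between classes)\n",
              p["bw"]))
  cat(sprintf("  within-class  x between-block: %6.2f%%\n", p["wb"]))
  cat(sprintf("  within-class  x within-block : %6.2f%%\n", p["ww"]))
  cat(sprintf("  margins: between-class %.2f%% / within-class %.2f%%; between-block %.2f%% / within-block %.2f%%\n",
              p["bb"] + p["bw"], p["wb"] + p["ww"],
              p["bb"] + p["wb"], p["bw"] + p["ww"]))
  invisible(x)
}

#' Write an ICA decomposition report to JSON
#'
#' @param decomposition an `ica_decomposition`.
#' @param path output JSON file.
#' @export
write_ica_report <- function(decomposition, path) {
  x <- decomposition
  report <- list(
    total_inertia = x$total_inertia,
    components = as.list(x$components),
    percentages = as.list(x$percentages),
    elementary = lapply(x$elementary, function(e)
      list(inertia = e$inertia, pct = e$pct,
           eigenvalues = as.numeric(e$eigenvalues))),
    n_genes = x$n_genes, n_codons = x$n_codons, classes = x$classes)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
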