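# Significance procedures for the between-class synonymous percentage:
# size-matched subsampling of the larger class, and random reassignment of
# genes to classes, each recomputing the internal-decomposition statistic.
# Replicate i draws from its own derived substream so results do not depend
# on evaluation order.

replicate_seeds <- function(seed, n_iter) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_iter)
}

new_permutation_result <- function(observed, replicates, n_iter, seed,
                                   kind) {
  structure(list(
    observed = observed,
    replicates = replicates,
    mean = mean(replicates),
    sd = stats::sd(replicates),
    empirical_p = (1 + sum(replicates >= observed)) / (n_iter + 1),
    n_iter = n_iter, seed = seed, kind = kind),
    class = "permutation_result")
}

#' Size-matched subsampling null for the between-class synonymous share
#'
#' Each replicate draws `sample_size` genes without replacement from the
#' larger class, keeps the smaller class intact, and recomputes the
#' between-class synonymous (within amino-acid block) percentage of total
#' inertia — the procedure used to check that a class-size imbalance does
#' not drive the observed value.
#'
#' @param table a `codon_usage_table` with exactly two row classes.
#' @param sample_size genes drawn from the larger class per replicate;
#'   default the size of the smaller class.
#' @param n_iter number of replicates.
#' @param seed integer seed; recorded in the result.
#' @return object of class `permutation_result`: `observed`, `replicates`,
#'   `mean`, `sd`, `empirical_p` (add-one rule), `n_iter`, `seed`.
#' @export
subsample_null <- function(table, sample_size = NULL, n_iter = 1000L,
                           seed = 1L) {
  stopifnot(inherits(table, "codon_usage_table"))
  k <- table$row_class
  sizes <- table(k)
  if (length(sizes) != 2L) {
    stop("subsample_null requires exactly two classes", call. = FALSE)
  }
  big <- names(sizes)[which.max(sizes)]
  small <- setdiff(names(sizes), big)
  if (is.null(sample_size)) sample_size <- min(sizes)
  if (sample_size > sizes[[big]]) {
    stop("sample_size (", sample_size, ") exceeds the larger class (",
         sizes[[big]], ")", call. = FALSE)
  }
  observed <- between_class_synonymous_pct(table)
  big_idx <- which(k == big)
  small_idx <- which(k == small)
  seeds <- replicate_seeds(seed, n_iter)
  replicates <- vapply(seq_len(n_iter), function(i) {
    set.seed(seeds[i])
    take <- sample(big_idx, sample_size)
    idx <- c(small_idx, take)
    between_class_synonymous_pct(table$matrix[idx, , drop = FALSE],
                                 classes = k[idx])
  }, numeric(1))
  new_permutation_result(observed, replicates, n_iter, seed, "subsample")
}

#' Label-permutation null for the between-class synonymous share
#'
#' Each replicate randomly reassigns genes to classes (preserving class
#' sizes) and recomputes the between-class synonymous percentage; the
#' empirical p-value positions the observed value in this null.
#'
#' @inheritParams subsample_null
#' @return object of class `permutation_result`.
#' @export
label_permutation <- function(table, n_iter = 1000L, seed = 1L) {
  stopifnot(inherits(table, "codon_usage_table"))
  k <- table$row_class
  if (nlevels(k) < 2L) stop("need at least two classes", call. = FALSE)
  observed <- between_class_synonymous_pct(table)
  seeds <- replicate_seeds(seed, n_iter)
  replicates <- vapply(seq_len(n_iter), function(i) {
    set.seed(seeds[i])
    between_class_synonymous_pct(table$matrix, classes = sample(k))
  }, numeric(1))
  new_permutation_result(observed, replicates, n_iter, seed,
                         "label_permutation")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("%s: observed %.4f%%, null %.4f%% +/- %.4f%% (n_iter = %d, seed = %d)\n",
              x$kind, x$observed, x$mean, x$sd, x$n_iter, x$seed))
  cat(sprintf("  empirical p = %.4g\n", x$empirical_p))
  invisible(x)
}

#' Write a permutation result to JSON
#'
#' @param result a `permutation_result`.
#' @param path output JSON file.
#' @param replicates also include the replicate values.
#' @export
write_permutation_report <- function(result, path, replicates = FALSE) {
  out <- list(kind = result$kind, observed = result$observed,
              mean = result$mean, sd = result$sd,
              empirical_p = result$empirical_p,
              n_iter = result$n_iter, seed = result$seed)
  if (replicates) out$replicates <- result$replicates
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
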