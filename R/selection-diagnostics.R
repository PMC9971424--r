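# Mutation-selection diagnostics: the ENC plot against its theoretical
# mutation-only curve, the neutrality plot (GC12 on GC3) regression, slope
# comparison between gene classes, and the GC3/expression/function band
# construction.

#' Expected ENC under pure compositional (mutational) bias
#'
#' The theoretical ENC of a gene whose codon usage is determined solely by
#' its synonymous third-position G+C content:
#' `ENC_exp = 2 + GC3s + 29 / (GC3s^2 + (1 - GC3s)^2)`.
#'
#' @param gc3s synonymous third-position G+C fraction(s) in `[0, 1]`.
#' @return expected ENC value(s).
#' @examples
#' enc_expected(c(0, 0.5, 1))  # 31.0, 60.5, 32.0
#' @export
enc_expected <- function(gc3s) {
  if (any(!is.finite(gc3s)) || any(gc3s < 0 | gc3s > 1)) {
    stop("gc3s must lie in [0, 1]", call. = FALSE)
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENC plot analysis
#'
#' Computes each gene's deviation from the theoretical curve
#' (`ENC_obs - ENC_exp(GC3s)`) and, per group, a polynomial regression of
#' ENC on GC3s plus the fraction of genes falling below the curve. Genes
#' lying on the curve indicate composition-driven usage; genes below it
#' indicate additional selection on codon usage.
#'
#' @param enc observed ENC values.
#' @param gc3s synonymous third-position G+C fractions.
#' @param group optional group labels (e.g. SEG/MEG); a single group when
#'   omitted.
#' @param degree polynomial degree of the fitted regression line.
#' @return list with `deviations` (data.frame: gc3s, enc, enc_exp,
#'   deviation, group) and `fits` (per group: coefficients, r.squared, n,
#'   frac_below; groups with fewer than 3 complete genes report deviations
#'   only).
#' @export
enc_plot <- function(enc, gc3s, group = NULL, degree = 2L) {
  if (is.null(group)) group <- rep("all", length(enc))
  stopifnot(length(enc) == length(gc3s), length(group) == length(enc))
  ok <- is.finite(enc) & is.finite(gc3s)
  dev <- ifelse(ok, enc - enc_expected(ifelse(ok, gc3s, 0.5)), NA_real_)
  deviations <- data.frame(gc3s = gc3s, enc = enc,
                           enc_exp = ifelse(ok, enc - dev, NA_real_),
                           deviation = dev, group = as.character(group),
                           stringsAsFactors = FALSE)
  fits <- lapply(split(deviations[ok, , drop = FALSE],
                       deviations$group[ok]), function(d) {
    frac_below <- mean(d$deviation < 0)
    if (nrow(d) < 3L) {
      return(list(coefficients = NULL, r.squared = NA_real_, n = nrow(d),
                  frac_below = frac_below))
    }
    fit <- stats::lm(enc ~ stats::poly(gc3s, degree, raw = TRUE), data = d)
    list(coefficients = unname(stats::coef(fit)),
         r.squared = suppressWarnings(summary(fit))$r.squared,
         n = nrow(d), frac_below = frac_below)
  })
  list(deviations = deviations, fits = fits, degree = degree)
}

#' Neutrality plot regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 (mean of first- and second-position GC)
#' on GC3, with the Spearman rank correlation alongside. A slope near 1
#' indicates that a shared mutational pressure drives all three codon
#' positions; flatter slopes indicate selection or conservation at the
#' first two positions.
#'
#' @param gc12 per-gene GC12 values.
#' @param gc3 per-gene GC3 values.
#' @return list of class `regression_fit`: `slope`, `intercept`, `r`
#'   (Spearman), `p_value` (Spearman), `slope_p` (OLS slope t-test), `n`,
#'   `residual_sd`. `slope` is `NA` when GC3 has zero variance.
#' @export
neutrality_fit <- function(gc12, gc3) {
  ok <- is.finite(gc12) & is.finite(gc3)
  gc12 <- gc12[ok]; gc3 <- gc3[ok]
  n <- length(gc3)
  if (n < 3L) stop("need at least 3 paired finite values", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(gc12, gc3, method = "spearman", exact = FALSE))
  if (stats::var(gc3) == 0) {
    fit <- list(slope = NA_real_, intercept = mean(gc12),
                slope_p = NA_real_, residual_sd = stats::sd(gc12))
  } else {
    lmfit <- stats::lm(gc12 ~ gc3)
    sm <- suppressWarnings(summary(lmfit))  # exact fits warn harmlessly
    fit <- list(slope = unname(stats::coef(lmfit)[2L]),
                intercept = unname(stats::coef(lmfit)[1L]),
                slope_p = sm$coefficients[2L, 4L],
                residual_sd = sm$sigma)
  }
  structure(c(fit, list(r = unname(ct$estimate), p_value = ct$p.value,
                        n = n)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression fit (n = %d): slope %.4f, intercept %.4f\n",
              x$n, x$slope, x$intercept))
  cat(sprintf("  Spearman r = %.3f (p = %.3g)\n", x$r, x$p_value))
  invisible(x)
}

#' Test whether two groups have different regression slopes
#'
#' Fits a pooled linear model with a group indicator and slope interaction
#' (`y ~ x * group`) and returns the two-sided p-value of the interaction
#' term.
#'
#' @param x_a,y_a paired values of the first group.
#' @param x_b,y_b paired values of the second group.
#' @return list: `p_value`, `slope_a`, `slope_b`, `n_a`, `n_b`.
#' @export
compare_slopes <- function(x_a, y_a, x_b, y_b) {
  ok_a <- is.finite(x_a) & is.finite(y_a)
  ok_b <- is.finite(x_b) & is.finite(y_b)
  if (sum(ok_a) < 3L || sum(ok_b) < 3L) {
    stop("each group needs at least 3 paired finite values", call. = FALSE)
  }
  d <- data.frame(
    x = c(x_a[ok_a], x_b[ok_b]),
    y = c(y_a[ok_a], y_b[ok_b]),
    g = factor(rep(c("a", "b"), c(sum(ok_a), sum(ok_b)))))
  fit <- stats::lm(y ~ x * g, data = d)
  cf <- summary(fit)$coefficients
  slopes <- c(a = unname(stats::coef(fit)["x"]),
              b = unname(stats::coef(fit)["x"] + stats::coef(fit)["x:gb"]))
  list(p_value = cf["x:gb", 4L],
       slope_a = slopes[["a"]], slope_b = slopes[["b"]],
       n_a = sum(ok_a), n_b = sum(ok_b))
}

#' Band genes into groups by thresholds or matched sizes
#'
#' Threshold banding assigns each value to a band bounded by strictly
#' decreasing thresholds, closed on the upper edge: with thresholds
#' `c(0.8, 0.7, 0.6, 0.5)` the bands are `>= 0.8`, `0.8-0.7`, `0.7-0.6`,
#' `0.6-0.5`, `< 0.5` (a value equal to a threshold joins the higher band).
#' When `matched_sizes` is given, values are instead rank-ordered
#' (decreasing, stable) and cut so group sizes match the template exactly —
#' the construction used to give expression bands the same sizes as GC3
#' bands.
#'
#' @param values finite numeric values, one per gene.
#' @param thresholds strictly decreasing band boundaries; may be `NULL`
#'   when `matched_sizes` is given (bands are then labelled `band1`,
#'   `band2`, ... from the top).
#' @param matched_sizes optional integer vector of group sizes summing to
#'   `length(values)`.
#' @return list of class `group_assignment`: `group` (factor, one per
#'   value, highest band first), `boundaries`, `sizes`.
#' @export
make_groups <- function(values, thresholds, matched_sizes = NULL) {
  stopifnot(all(is.finite(values)))
  if (is.null(thresholds)) {
    if (is.null(matched_sizes)) {
      stop("thresholds are required unless matched_sizes is given",
           call. = FALSE)
    }
    n_groups <- length(matched_sizes)
    band_labels <- paste0("band", seq_len(n_groups))
  } else {
    if (is.unsorted(rev(thresholds), strictly = TRUE)) {
      stop("thresholds must be strictly decreasing", call. = FALSE)
    }
    n_groups <- length(thresholds) + 1L
    band_labels <- c(paste0(">=", thresholds[1L]),
                     if (length(thresholds) > 1L)
                       paste0(thresholds[-length(thresholds)], "-",
                              thresholds[-1L]),
                     paste0("<", thresholds[length(thresholds)]))
  }
  if (is.null(matched_sizes)) {
    idx <- n_groups - findInterval(values, rev(thresholds))
  } else {
    matched_sizes <- as.integer(matched_sizes)
    if (length(matched_sizes) != n_groups) {
      stop("matched_sizes must have one entry per band", call. = FALSE)
    }
    if (sum(matched_sizes) != length(values)) {
      stop("matched_sizes must sum to length(values)", call. = FALSE)
    }
    rk <- order(order(-values))  # stable decreasing ranks, ties by position
    idx <- findInterval(rk - 1L, cumsum(c(0L, matched_sizes)),
                        rightmost.closed = FALSE)
    idx <- pmin(idx, n_groups)
  }
  group <- factor(band_labels[idx], levels = band_labels)
  structure(list(group = group,
                 boundaries = thresholds,
                 sizes = as.integer(table(group))),
            class = "group_assignment")
}
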