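# Independent brute-force oracles, written from first principles against a
# hard-coded standard genetic code (classical TCAG nesting), deliberately
# sharing no code with the package internals.

oracle_code <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aas, codons)
})

oracle_families <- local({
  sense <- names(oracle_code)[oracle_code != "*"]
  fam <- split(sense, oracle_code[sense])
  fam[vapply(fam, length, 1L) >= 2L]
})

oracle_split <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

oracle_counts <- function(cds) {
  codons <- oracle_split(toupper(cds))
  codons <- codons[grepl("^[ACGT]{3}$", codons)]
  codons <- codons[oracle_code[codons] != "*"]
  out <- integer(64)
  names(out) <- names(oracle_code)
  for (cd in codons) out[cd] <- out[cd] + 1L
  out
}

oracle_enc <- function(counts) {
  f_of <- function(cods) {
    n <- sum(counts[cods])
    if (n < 2) return(NA_real_)
    p <- counts[cods] / n
    (n * sum(p^2) - 1) / (n - 1)
  }
  fam_size <- vapply(oracle_families, length, 1L)
  class_mean <- function(k) {
    f <- vapply(oracle_families[fam_size == k], f_of, numeric(1))
    f <- f[!is.na(f)]
    if (!length(f)) NA_real_ else mean(f)
  }
  f2 <- class_mean(2); f3 <- class_mean(3)
  f4 <- class_mean(4); f6 <- class_mean(6)
  if (is.na(f2) || is.na(f4)) return(NA_real_)
  if (is.na(f3)) f3 <- (f2 + f4) / 2
  if (is.na(f6)) f6 <- (f2 + f4) / 2
  if (any(c(f2, f3, f4, f6) <= 0)) return(NA_real_)
  min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)
}

oracle_rscu <- function(counts) {
  out <- c()
  for (fam in oracle_families) {
    tot <- sum(counts[fam])
    vals <- if (tot == 0) rep(NA_real_, length(fam)) else
      length(fam) * counts[fam] / tot
    out <- c(out, stats::setNames(vals, fam))
  }
  out
}

oracle_cai <- function(counts, w) {
  num <- 0; L <- 0
  for (fam in oracle_families) {
    for (cd in fam) {
      if (counts[cd] > 0) {
        num <- num + counts[cd] * log(w[cd])
        L <- L + counts[cd]
      }
    }
  }
  if (L == 0) return(NA_real_)
  unname(exp(num / L))
}

oracle_composition <- function(cds) {
  codons <- oracle_split(toupper(cds))
  codons <- codons[grepl("^[ACGT]{3}$", codons)]
  sense <- codons[oracle_code[codons] != "*"]
  posgc <- function(i) mean(substring(sense, i, i) %in% c("G", "C"))
  syn_aas <- names(oracle_families)
  syn <- sense[oracle_code[sense] %in% syn_aas]
  third_of <- function(cods) substring(cods, 3, 3)
  x3s <- sapply(c("A", "T", "C", "G"), function(b) {
    elig_aa <- syn_aas[vapply(oracle_families, function(f)
      b %in% third_of(f), logical(1))]
    elig <- syn[oracle_code[syn] %in% elig_aa]
    if (!length(elig)) return(NA_real_)
    sum(third_of(elig) == b) / length(elig)
  })
  gc_aa <- syn_aas[vapply(oracle_families, function(f)
    any(third_of(f) %in% c("G", "C")), logical(1))]
  gce <- syn[oracle_code[syn] %in% gc_aa]
  gc3s <- if (!length(gce)) NA_real_ else
    mean(third_of(gce) %in% c("G", "C"))
  bases <- strsplit(toupper(cds), "")[[1]]
  bases <- bases[bases %in% c("A", "C", "G", "T")]
  c(gc = mean(bases %in% c("G", "C")),
    gc1 = posgc(1), gc2 = posgc(2), gc3 = posgc(3),
    gc12 = (posgc(1) + posgc(2)) / 2, gc3s = gc3s,
    a3s = unname(x3s["A"]), t3s = unname(x3s["T"]),
    c3s = unname(x3s["C"]), g3s = unname(x3s["G"]))
}

oracle_inertia <- function(m) {
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  P <- m / sum(m)
  r <- rowSums(P); cc <- colSums(P)
  tot <- 0
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      e <- r[i] * cc[j]
      tot <- tot + (P[i, j] - e)^2 / e
    }
  }
  unname(tot)
}

# NG86 oracle: per-codon site fractions and pathway-averaged differences
oracle_ng86_sites <- function(codon) {
  aa <- oracle_code[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substring(codon, pos, pos))) {
      nb <- paste0(substring(codon, 1, pos - 1), b,
                   substring(codon, pos + 1, 3))
      if (oracle_code[[nb]] == aa) s <- s + 1 / 3
    }
  }
  s
}

oracle_ng86_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  ords <- if (length(pos) == 1) list(pos) else if (length(pos) == 2) {
    list(pos, rev(pos))
  } else {
    list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
         pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  }
  res <- lapply(ords, function(ord) {
    cur <- c1; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- paste0(substring(cur, 1, p - 1), substring(c2, p, p),
                    substring(cur, p + 1, 3))
      if (oracle_code[[nxt]] == "*") blocked <- TRUE
      if (oracle_code[[nxt]] == oracle_code[[cur]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  })
  ok <- Filter(function(x) !x$blocked, res)
  if (!length(ok)) ok <- res
  c(sd = mean(vapply(ok, `[[`, 1, "sd")),
    nd = mean(vapply(ok, `[[`, 1, "nd")))
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mean((rx - mean(rx)) * (ry - mean(ry))) /
    (stats::sd(rx) * stats::sd(ry)) * length(x) / (length(x) - 1)
}
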