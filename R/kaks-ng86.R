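# Nei-Gojobori (1986) Ka/Ks on codon-aligned sequence pairs: synonymous and
# nonsynonymous site counting by single-mutation enumeration under the
# standard genetic code, pathway-averaged difference counting for multi-hit
# codons, and Jukes-Cantor multiple-hit correction.

NT <- c("A", "C", "G", "T")

# the 9 single-nucleotide neighbors of a codon
codon_neighbors <- function(codon) {
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(NT, substr(codon, pos, pos))) {
      nb <- codon
      substr(nb, pos, pos) <- b
      out <- c(out, nb)
    }
  }
  out
}

# per-codon synonymous site count: at each position, the fraction of the 3
# possible single-base changes that are synonymous; changes to stop codons
# count as nonsynonymous, so s + n = 3 for every sense codon
syn_sites_one <- function(codon) {
  aa <- GENETIC_CODE_TABLE[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(NT, substr(codon, pos, pos))) {
      nb <- codon
      substr(nb, pos, pos) <- b
      if (GENETIC_CODE_TABLE[[nb]] == aa) s <- s + 1 / 3
    }
  }
  s
}

SYN_SITES <- vapply(SENSE_CODONS, syn_sites_one, numeric(1))

# pathway-averaged synonymous/nonsynonymous difference counts between two
# codons: all orderings of the differing positions are enumerated, pathways
# passing through a stop codon are excluded (all pathways used as fallback
# when every one is blocked), and sd/nd are averaged with equal weight
count_codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  ndiff <- length(pos)
  if (ndiff == 0L) return(c(sd = 0, nd = 0))
  orderings <- if (ndiff == 1L) list(pos) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    }
    perms(pos)
  }
  paths <- lapply(orderings, function(ord) {
    cur <- c1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GENETIC_CODE_TABLE[[nxt]] == "*") blocked <- TRUE
      if (GENETIC_CODE_TABLE[[nxt]] == GENETIC_CODE_TABLE[[cur]]) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd = sd, nd = nd, blocked = as.numeric(blocked))
  })
  pm <- do.call(rbind, paths)
  use <- pm[, "blocked"] == 0
  if (!any(use)) use <- rep(TRUE, nrow(pm))
  c(sd = mean(pm[use, "sd"]), nd = mean(pm[use, "nd"]))
}

jukes_cantor <- function(p) {
  if (!is.finite(p)) return(NA_real_)
  if (p >= 3 / 4) return(NA_real_)
  -3 / 4 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka/Ks for a codon-aligned pair
#'
#' Counts synonymous and nonsynonymous sites per codon by single-mutation
#' enumeration under the standard genetic code (averaged over the two
#' sequences), counts observed differences with equal-weight averaging over
#' all minimal substitution pathways (stop-crossing pathways excluded), and
#' corrects the proportions with the Jukes-Cantor formula
#' `d = -(3/4) log(1 - 4p/3)`. Codons containing a gap (`-`), an ambiguous
#' base, or a stop in either sequence are skipped pairwise.
#'
#' @param seq1,seq2 in-frame codon-aligned nucleotide strings of equal
#'   length divisible by 3.
#' @return object of class `kaks_estimate`: `ka`, `ks` (substitutions per
#'   site; `NA` at saturation, p >= 3/4), `omega` (= ka/ks; `NA` when ks is
#'   0 or undefined), `s_sites`, `n_sites`, `sd`, `nd`, `n_codons` (aligned
#'   codons used).
#' @export
ng86 <- function(seq1, seq2) {
  s1 <- toupper(as.character(seq1)); s2 <- toupper(as.character(seq2))
  if (nchar(s1) != nchar(s2)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  if (nchar(s1) %% 3L != 0L) {
    stop("alignment length must be divisible by 3", call. = FALSE)
  }
  c1 <- split_codons(s1); c2 <- split_codons(s2)
  usable <- is_unambiguous_codon(c1) & is_unambiguous_codon(c2) &
    !(c1 %in% STOP_CODONS) & !(c2 %in% STOP_CODONS)
  c1 <- c1[usable]; c2 <- c2[usable]
  n_codons <- length(c1)
  if (n_codons == 0L) {
    return(structure(list(ka = NA_real_, ks = NA_real_, omega = NA_real_,
                          s_sites = 0, n_sites = 0, sd = 0, nd = 0,
                          n_codons = 0L), class = "kaks_estimate"))
  }
  s_sites <- (sum(SYN_SITES[c1]) + sum(SYN_SITES[c2])) / 2
  n_sites <- 3 * n_codons - s_sites
  diffs <- mapply(count_codon_diffs, c1, c2)
  sd_total <- sum(diffs["sd", ])
  nd_total <- sum(diffs["nd", ])
  ps <- if (s_sites > 0) sd_total / s_sites else NA_real_
  pn <- if (n_sites > 0) nd_total / n_sites else NA_real_
  ks <- jukes_cantor(ps)
  ka <- jukes_cantor(pn)
  omega <- if (is.na(ks) || ks == 0) NA_real_ else ka / ks
  structure(list(ka = ka, ks = ks, omega = omega,
                 s_sites = s_sites, n_sites = n_sites,
                 sd = sd_total, nd = nd_total, n_codons = n_codons),
            class = "kaks_estimate")
}

#' @export
print.kaks_estimate <- function(x, ...) {
  cat(sprintf("NG86: Ka = %.4f, Ks = %.4f, omega = %.4f (%d codons; S = %.1f, N = %.1f)\n",
              x$ka, x$ks, x$omega, x$n_codons, x$s_sites, x$n_sites))
  invisible(x)
}

#' NG86 on paired FASTA input
#'
#' Reads one or more FASTA files, each containing two in-frame aligned
#' sequences, and returns a Ka/Ks table.
#'
#' @param paths FASTA file(s), two sequences per file.
#' @return data.frame: `pair_id, ka, ks, omega, s_sites, n_sites`.
#' @export
ng86_fasta <- function(paths) {
  rows <- lapply(paths, function(p) {
    seqs <- Biostrings::readDNAStringSet(p)
    if (length(seqs) != 2L) {
      stop("'", p, "' must contain exactly two sequences", call. = FALSE)
    }
    est <- ng86(seqs[[1L]], seqs[[2L]])
    data.frame(pair_id = sub("\\.[^.]*$", "", basename(p)),
               ka = est$ka, ks = est$ks, omega = est$omega,
               s_sites = est$s_sites, n_sites = est$n_sites,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
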