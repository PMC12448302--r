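# d2* oligonucleotide-frequency dissimilarity ------------------------------
#
# Compositional distance between two genomes based on k-mer counts centered
# by each sequence's own order-r Markov expectation.  Low d2* between a
# virus and a candidate host indicates shared genomic signature beyond what
# the low-order background model explains, a classic virus-host signal.

as_dna <- function(x) {
  if (methods::is(x, "DNAString")) return(x)
  if (methods::is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    return(x[[1L]])
  }
  Biostrings::DNAString(toupper(as.character(x)))
}

# k-mer counts summed over the forward and reverse-complement strands
strand_sym_counts <- function(seq, width) {
  Biostrings::oligonucleotideFrequency(seq, width = width) +
    Biostrings::oligonucleotideFrequency(Biostrings::reverseComplement(seq),
                                         width = width)
}

# index of the sub-word w[start .. start+len-1] for every word of size k,
# with words coded 0..4^k-1 in lexicographic (A<C<G<T) order
subword_index <- function(idx, k, start, len) {
  (idx %/% 4^(k - start - len + 1)) %% 4^len
}

# Expected k-mer counts under the sequence's own order-r Markov model:
#   E[w] = prod_j C_{r+1}(w[j..j+r]) / prod_j C_r(w[j..j+r-1])
# with counts taken from the same (strand-symmetrised) sequence.
markov_expected_counts <- function(counts_k, counts_r1, counts_r, k, r) {
  idx <- seq_len(4^k) - 1
  num <- rep(1, 4^k)
  for (j in seq_len(k - r)) {        # windows of length r+1 at offsets 0..k-r-1
    num <- num * counts_r1[subword_index(idx, k, j, r + 1) + 1]
  }
  den <- rep(1, 4^k)
  if (k - r >= 2) {
    for (j in 2:(k - r)) {           # interior windows of length r
      den <- den * counts_r[subword_index(idx, k, j, r) + 1]
    }
  }
  e <- ifelse(den > 0, num / den, 0)
  e[num == 0] <- 0
  e
}

#' d2* oligonucleotide frequency dissimilarity
#'
#' Counts k-mers on both strands of each sequence, centers them by the
#' expectation under the sequence's own order-`markov_order` Markov model
#' (estimated from its `(markov_order+1)`-mer counts), and returns
#' `d2* = (1 - S) / 2` where `S` is the normalised inner product of the
#' centered, expectation-scaled count vectors.  Values lie in `[0, 1]`;
#' small values indicate compositional congruence (the conventional
#' virus-host evidence threshold is `d2* <= 0.2`).
#'
#' @param x,y DNA sequences (`DNAString`, single-sequence `DNAStringSet`,
#'   or character).
#' @param k Word size (default 6).
#' @param markov_order Order of the background Markov model (default 2);
#'   must be smaller than `k`.
#' @return A single d2* value; the number of words excluded for zero
#'   expected count is attached as attribute `n_excluded`.
#' @export
d2star <- function(x, y, k = 6, markov_order = 2) {
  stopifnot(k > markov_order, markov_order >= 0)
  x <- as_dna(x); y <- as_dna(y)
  floor_len <- 10 * 4^markov_order
  if (length(x) < floor_len || length(y) < floor_len)
    stop("sequences must be at least ", floor_len,
         " bp for order-", markov_order, " estimation")
  r <- markov_order
  stats_one <- function(s) {
    ck <- strand_sym_counts(s, k)
    cr1 <- strand_sym_counts(s, r + 1)
    cr <- if (r >= 1) strand_sym_counts(s, r) else sum(cr1)
    e <- markov_expected_counts(ck, cr1, cr, k, r)
    list(n = as.numeric(ck), e = e)
  }
  sx <- stats_one(x); sy <- stats_one(y)
  valid <- sx$e > 0 & sy$e > 0
  n_excluded <- sum(!valid)
  ctx <- (sx$n - sx$e)[valid]; ex <- sx$e[valid]
  cty <- (sy$n - sy$e)[valid]; ey <- sy$e[valid]
  num <- sum(ctx * cty / sqrt(ex * ey))
  den <- sqrt(sum(ctx^2 / ex)) * sqrt(sum(cty^2 / ey))
  s_norm <- if (den > 0) num / den else 0
  out <- 0.5 * (1 - s_norm)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Pairwise d2* between viral and host genomes
#'
#' @param viruses,hosts Named `DNAStringSet` objects (or named lists of
#'   sequences).
#' @inheritParams d2star
#' @param threshold Pairs with `d2* <= threshold` are flagged as putative
#'   oligonucleotide-frequency (onf) evidence (default 0.2).
#' @return A list with `matrix` (viruses x hosts d2* values) and
#'   `evidence` (data frame `virus`, `host`, `method = "onf"`, `score`).
#' @export
d2star_screen <- function(viruses, hosts, k = 6, markov_order = 2,
                          threshold = 0.2) {
  vn <- names(viruses); hn <- names(hosts)
  stopifnot(!is.null(vn), !is.null(hn))
  m <- matrix(NA_real_, length(viruses), length(hosts),
              dimnames = list(vn, hn))
  for (i in seq_along(viruses)) {
    for (j in seq_along(hosts)) {
      m[i, j] <- as.numeric(d2star(viruses[[i]], hosts[[j]], k, markov_order))
    }
  }
  hit <- which(m <= threshold, arr.ind = TRUE)
  evidence <- data.frame(virus = vn[hit[, 1L]], host = hn[hit[, 2L]],
                         method = rep("onf", nrow(hit)),
                         score = m[hit])
  list(matrix = m, evidence = evidence)
}
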