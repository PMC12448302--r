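# SNV calling and gene-level microdiversity metrics ------------------------
#
# Works on per-site nucleotide pileup profiles (contig, 1-based position,
# reference base, A/C/G/T counts) plus codon-framed gene models.  SNV
# density is reported per kb of sufficiently covered sequence; pN/pS uses
# expected-site normalisation under the standard genetic code with equal
# mutation rates (Nei-Gojobori-style site counting).

BASES <- c("A", "C", "G", "T")

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# per-codon synonymous-site fraction table for all 64 codons, computed once
codon_site_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    codons <- as.character(Biostrings::mkAllStrings(BASES, 3))
    s <- vapply(codons, function(cd) {
      aa <- codon_aa(cd)
      nsyn <- 0L
      for (pos in 1:3) {
        for (b in setdiff(BASES, substr(cd, pos, pos))) {
          mut <- cd
          substr(mut, pos, pos) <- b
          if (codon_aa(mut) == aa) nsyn <- nsyn + 1L
        }
      }
      nsyn / 3
    }, numeric(1L))
    tab <<- s
    tab
  }
})

#' Call single-nucleotide variants from a pileup profile
#'
#' A position with coverage at least `min_cov` yields one SNV per
#' non-reference base whose frequency (count / coverage) is at least
#' `min_freq` and whose count is at least `min_count`.
#'
#' @param pileup Data frame with columns `contig`, `pos` (1-based), `ref`,
#'   `nA`, `nC`, `nG`, `nT`.
#' @param min_cov Minimum coverage to consider a position (default 5).
#' @param min_freq Minimum alternate allele frequency (default 0.05).
#' @param min_count Minimum alternate allele count (default 2).
#' @return Data frame of SNVs (`contig`, `pos`, `ref`, `alt`, `freq`,
#'   `coverage`).  The number of zero-coverage positions skipped is
#'   attached as attribute `n_zero_coverage`.
#' @export
call_snvs <- function(pileup, min_cov = 5, min_freq = 0.05, min_count = 2) {
  need <- c("contig", "pos", "ref", "nA", "nC", "nG", "nT")
  stopifnot(all(need %in% names(pileup)))
  counts <- as.matrix(pileup[, c("nA", "nC", "nG", "nT")])
  colnames(counts) <- BASES
  coverage <- rowSums(counts)
  n_zero <- sum(coverage == 0)
  rows <- list()
  ok <- which(coverage >= min_cov)
  for (i in ok) {
    ref <- toupper(pileup$ref[i])
    for (b in setdiff(BASES, ref)) {
      cnt <- counts[i, b]
      if (cnt >= min_count && cnt / coverage[i] >= min_freq) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig = pileup$contig[i], pos = pileup$pos[i], ref = ref,
          alt = b, freq = cnt / coverage[i], coverage = coverage[i])
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), freq = numeric(), coverage = numeric())
  rownames(out) <- NULL
  attr(out, "n_zero_coverage") <- n_zero
  out
}

#' SNV density per kilobase
#'
#' `1000 * (number of distinct SNV positions) / covered_length`, where
#' `covered_length` counts positions with coverage at or above the calling
#' threshold.
#'
#' @param snvs SNV data frame (from [call_snvs()]).
#' @param covered_length Number of sufficiently covered positions (bp).
#' @return SNVs/kb, or `NA` when `covered_length` is zero.
#' @export
snv_density <- function(snvs, covered_length) {
  if (covered_length <= 0) return(NA_real_)
  1000 * length(unique(paste(snvs$contig, snvs$pos))) / covered_length
}

#' Covered length of a pileup
#'
#' @inheritParams call_snvs
#' @return Number of positions with coverage at least `min_cov`.
#' @export
covered_length <- function(pileup, min_cov = 5) {
  sum(rowSums(pileup[, c("nA", "nC", "nG", "nT")]) >= min_cov)
}

#' Expected numbers of nonsynonymous and synonymous sites
#'
#' For each codon of an in-frame coding sequence, each of the three
#' alternative bases at each position is classified synonymous or
#' nonsynonymous by amino-acid identity under the standard genetic code;
#' a site contributes the synonymous fraction of its three possible
#' mutations to `S_sites` and the remainder to `N_sites`, so
#' `N_sites + S_sites = 3 * n_codons` exactly.
#'
#' @param sequence Coding sequence (character or `DNAString`), length
#'   divisible by 3, read in frame from its first base.
#' @return A list with `N_sites`, `S_sites`, `n_codons`,
#'   `n_skipped_codons` (codons containing ambiguous bases), and
#'   `internal_stop` (flag: an in-frame stop before the final codon).
#' @export
expected_sites <- function(sequence) {
  seq <- toupper(as.character(sequence))
  L <- nchar(seq)
  if (L %% 3 != 0) stop("sequence length not divisible by 3")
  codons <- substring(seq, seq(1, L, 3), seq(3, L, 3))
  clean <- grepl("^[ACGT]{3}$", codons)
  st <- codon_site_table()
  s_sites <- sum(st[codons[clean]])
  n_codons <- sum(clean)
  aas <- codon_aa(codons[clean])
  internal_stop <- any(aas[-length(aas)] == "*")
  list(N_sites = 3 * n_codons - s_sites, S_sites = s_sites,
       n_codons = n_codons, n_skipped_codons = sum(!clean),
       internal_stop = internal_stop)
}

complement_base <- function(b) {
  chartr("ACGT", "TGCA", b)
}

# Map an SNV on the contig into (codon index, position in codon, strand-
# corrected ref/alt) for a gene; NULL when outside the gene.
snv_in_gene_frame <- function(pos, ref, alt, start, end, strand) {
  if (pos < start || pos > end) return(NULL)
  if (strand == "+") {
    gpos <- pos - start + 1L
  } else {
    gpos <- end - pos + 1L
    ref <- complement_base(ref)
    alt <- complement_base(alt)
  }
  list(codon = (gpos - 1L) %/% 3L + 1L, offset = (gpos - 1L) %% 3L + 1L,
       ref = ref, alt = alt)
}

#' Gene-level pN/pS and SNV density
#'
#' Maps SNVs into the codon frame of a gene (strand-aware), classifies
#' each alternate allele as synonymous or nonsynonymous against the
#' reference codon, and computes
#' `pN/pS = (N_obs / N_sites) / (S_obs / S_sites)`.  When `S_obs = 0` the
#' ratio is undefined and reported `NA`; when `N_obs = 0` with
#' `S_obs > 0` the ratio is 0.  Multi-allelic positions contribute one
#' observation per alternate allele.
#'
#' @param gene One-row data frame (or list) with `gene_id`, `contig`,
#'   `start`, `end`, `strand` (1-based inclusive coordinates; length
#'   divisible by 3).
#' @param contig_seq Sequence of the gene's contig (character or
#'   `DNAString`).
#' @param snvs SNV data frame (from [call_snvs()]).
#' @param gene_covered_length Optional number of sufficiently covered
#'   positions within the gene; defaults to gene length (appropriate for
#'   uniformly covered simulations).
#' @return A data frame row with `gene_id`, `N_obs`, `S_obs`, `N_sites`,
#'   `S_sites`, `pnps`, `snvs_kb`.
#' @export
gene_pnps <- function(gene, contig_seq, snvs, gene_covered_length = NULL) {
  start <- gene$start; end <- gene$end; strand <- gene$strand
  glen <- end - start + 1L
  if (glen %% 3 != 0) stop("gene length not divisible by 3")
  contig_seq <- toupper(as.character(contig_seq))
  gseq <- substr(contig_seq, start, end)
  if (strand == "-")
    gseq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(gseq)))
  sites <- expected_sites(gseq)
  codons <- substring(gseq, seq(1, glen, 3), seq(3, glen, 3))
  snvs <- snvs[snvs$contig == gene$contig, , drop = FALSE]
  n_obs <- 0L; s_obs <- 0L; n_pos <- character()
  for (i in seq_len(nrow(snvs))) {
    fr <- snv_in_gene_frame(snvs$pos[i], snvs$ref[i], snvs$alt[i],
                            start, end, strand)
    if (is.null(fr)) next
    cd <- codons[fr$codon]
    if (!grepl("^[ACGT]{3}$", cd)) next
    if (substr(cd, fr$offset, fr$offset) != fr$ref) {
      warning("SNV reference base disagrees with gene sequence at ",
              gene$contig, ":", snvs$pos[i])
      next
    }
    mut <- cd
    substr(mut, fr$offset, fr$offset) <- fr$alt
    if (codon_aa(mut) == codon_aa(cd)) s_obs <- s_obs + 1L
    else n_obs <- n_obs + 1L
    n_pos <- c(n_pos, paste(gene$contig, snvs$pos[i]))
  }
  pnps <- if (s_obs == 0) {
    if (n_obs == 0) NA_real_ else NA_real_
  } else {
    (n_obs / sites$N_sites) / (s_obs / sites$S_sites)
  }
  covered <- if (is.null(gene_covered_length)) glen else gene_covered_length
  data.frame(gene_id = gene$gene_id, N_obs = n_obs, S_obs = s_obs,
             N_sites = sites$N_sites, S_sites = sites$S_sites,
             pnps = pnps,
             snvs_kb = 1000 * length(unique(n_pos)) / covered)
}

#' Compare an evolutionary metric between groups
#'
#' Pairwise two-sided Wilcoxon rank-sum tests (via
#' [wilcoxon_rank_sum()]) between all group pairs, with per-group
#' medians.  No multiplicity adjustment is applied.
#'
#' @param values Numeric vector of per-genome metric values (`NA`s are
#'   dropped).
#' @param groups Group labels, one per value.
#' @return A list with `medians` (named vector) and `tests` (data frame:
#'   `group_1`, `group_2`, `statistic`, `p_value`).
#' @export
compare_metric_groups <- function(values, groups) {
  ok <- !is.na(values)
  values <- values[ok]; groups <- as.character(groups)[ok]
  split_vals <- split(values, groups)
  if (length(split_vals) < 2L) stop("need at least two groups")
  if (any(vapply(split_vals, length, 1L) == 0L)) stop("empty group")
  gn <- names(split_vals)
  cmb <- combn(gn, 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1L, i]; b <- cmb[2L, i]
    w <- wilcoxon_rank_sum(split_vals[[a]], split_vals[[b]])
    data.frame(group_1 = a, group_2 = b, statistic = w$statistic,
               p_value = w$p_value)
  }))
  list(medians = vapply(split_vals, stats::median, numeric(1L)),
       tests = tests)
}
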