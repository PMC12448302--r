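# Seeded pileup generators with planted variants of known synonymy ---------

#' Generate a synthetic viral contig with codon-framed genes
#'
#' Builds a random contig consisting of consecutive protein-coding genes
#' (ATG start, no in-frame internal stops, alternating strands optional)
#' separated by short intergenic spacers.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (default 3).
#' @param n_codons Codons per gene including the start (default 100).
#' @param intergenic Spacer length between genes (default 30).
#' @param strands Strand per gene, recycled (default `"+"`).
#' @return A list with `sequence` (character) and `genes` (data frame
#'   `contig`, `gene_id`, `start`, `end`, `strand`).
#' @export
generate_viral_contig <- function(seed, n_genes = 3, n_codons = 100,
                                  intergenic = 30, strands = "+") {
  stopifnot(n_genes >= 1, n_codons >= 2)
  strands <- rep_len(strands, n_genes)
  stops <- c("TAA", "TAG", "TGA")
  with_seed(seed, {
    sense_codons <- setdiff(
      as.character(Biostrings::mkAllStrings(BASES, 3)), stops)
    genes <- list()
    parts <- character()
    pos <- 1L
    for (g in seq_len(n_genes)) {
      spacer <- random_dna(intergenic)
      body <- paste(c("ATG",
                      sample(sense_codons, n_codons - 1L, replace = TRUE)),
                    collapse = "")
      if (strands[g] == "-")
        body <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(body)))
      parts <- c(parts, spacer, body)
      start <- pos + intergenic
      end <- start + 3L * n_codons - 1L
      genes[[g]] <- data.frame(contig = "ctg_sim",
                               gene_id = sprintf("gene_%02d", g),
                               start = start, end = end,
                               strand = strands[g])
      pos <- end + 1L
    }
    parts <- c(parts, random_dna(intergenic))
    list(sequence = paste(parts, collapse = ""),
         genes = do.call(rbind, genes))
  })
}

#' Plant variants of known synonymy on a contig
#'
#' Chooses distinct positions uniformly at random, assigns each a uniform
#' random alternate base and an allele frequency, and records the true
#' synonymy of each variant (synonymous / nonsynonymous / intergenic)
#' against the gene models and the standard genetic code.
#'
#' @param seed Integer seed.
#' @param sequence Contig sequence (character).
#' @param genes Gene-model data frame (`contig`, `start`, `end`,
#'   `strand`).
#' @param n_variants Number of variants to plant.
#' @param freq_range Allele-frequency range (default `c(0.2, 0.5)`, which
#'   keeps planted alternates comfortably above the SNV-calling frequency
#'   floor at the coverages the generator is used with).
#' @param positions Optional explicit positions (1-based); default
#'   uniform random distinct positions.
#' @param coding_only If `TRUE`, restrict positions to coding regions.
#' @return Data frame `contig`, `pos`, `ref`, `alt`, `freq`, `synonymy`.
#' @export
plant_variants <- function(seed, sequence, genes, n_variants,
                           freq_range = c(0.2, 0.5), positions = NULL,
                           coding_only = FALSE) {
  seqch <- strsplit(toupper(sequence), "")[[1L]]
  L <- length(seqch)
  contig <- genes$contig[1L]
  with_seed(seed, {
    if (is.null(positions)) {
      cand <- seq_len(L)
      if (coding_only) {
        in_gene <- rep(FALSE, L)
        for (g in seq_len(nrow(genes)))
          in_gene[genes$start[g]:genes$end[g]] <- TRUE
        cand <- cand[in_gene]
      }
      positions <- sort(sample(cand, n_variants))
    }
    if (any(positions < 1 | positions > L))
      stop("planted position outside contig length")
    ref <- seqch[positions]
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L),
                  character(1L))
    freq <- runif(length(positions), freq_range[1L], freq_range[2L])
    synonymy <- vapply(seq_along(positions), function(i) {
      p <- positions[i]
      hit <- which(genes$start <= p & genes$end >= p)
      if (!length(hit)) return("intergenic")
      g <- genes[hit[1L], ]
      fr <- snv_in_gene_frame(p, ref[i], alt[i], g$start, g$end, g$strand)
      gseq <- substr(paste(seqch, collapse = ""), g$start, g$end)
      if (g$strand == "-")
        gseq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(gseq)))
      cd <- substr(gseq, 3L * (fr$codon - 1L) + 1L, 3L * fr$codon)
      mut <- cd
      substr(mut, fr$offset, fr$offset) <- fr$alt
      if (codon_aa(mut) == codon_aa(cd)) "synonymous" else "nonsynonymous"
    }, character(1L))
    data.frame(contig = contig, pos = positions, ref = ref, alt = alt,
               freq = freq, synonymy = synonymy, row.names = NULL)
  })
}

#' Generate a per-site pileup profile with planted variants
#'
#' Coverage at each site is Poisson(`mean_coverage`); base counts are
#' multinomial around the reference base, the planted alternate at its
#' true frequency, and uniform sequencing errors at rate `error_rate`.
#'
#' @param seed Integer seed.
#' @param sequence Contig sequence (character).
#' @param variants Planted-variant data frame (from [plant_variants()]),
#'   or `NULL` for none.
#' @param mean_coverage Mean per-site coverage (>= 1).
#' @param error_rate Per-base sequencing error rate in `[0, 0.5)`.
#' @param contig Contig id (default taken from `variants`, else
#'   `"ctg_sim"`).
#' @return Pileup data frame (`contig`, `pos`, `ref`, `nA`, `nC`, `nG`,
#'   `nT`).
#' @export
generate_pileup <- function(seed, sequence, variants = NULL,
                            mean_coverage = 100, error_rate = 0,
                            contig = NULL) {
  stopifnot(mean_coverage >= 1, error_rate >= 0, error_rate < 0.5)
  seqch <- strsplit(toupper(sequence), "")[[1L]]
  L <- length(seqch)
  if (is.null(contig))
    contig <- if (!is.null(variants) && nrow(variants)) variants$contig[1L]
              else "ctg_sim"
  alt_of <- rep(NA_character_, L)
  freq_of <- rep(0, L)
  if (!is.null(variants) && nrow(variants)) {
    if (any(variants$pos < 1 | variants$pos > L))
      stop("planted position outside contig length")
    alt_of[variants$pos] <- variants$alt
    freq_of[variants$pos] <- variants$freq
  }
  with_seed(seed, {
    cov <- rpois(L, mean_coverage)
    counts <- matrix(0L, L, 4L, dimnames = list(NULL, BASES))
    for (i in seq_len(L)) {
      if (cov[i] == 0L) next
      q <- setNames(numeric(4L), BASES)
      q[seqch[i]] <- 1 - freq_of[i]
      if (!is.na(alt_of[i])) q[alt_of[i]] <- q[alt_of[i]] + freq_of[i]
      p <- q * (1 - error_rate) + (1 - q) * (error_rate / 3)
      counts[i, ] <- rmultinom(1L, cov[i], p)[, 1L]
    }
    data.frame(contig = contig, pos = seq_len(L), ref = seqch,
               nA = counts[, "A"], nC = counts[, "C"], nG = counts[, "G"],
               nT = counts[, "T"])
  })
}
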