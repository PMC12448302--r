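# Virus-host linkage prediction -------------------------------------------
#
# Four evidence channels: (i) nucleotide homology over precomputed
# BLAST-like hit tables, (ii) shared tRNAs (exact full-length duplicates),
# (iii) CRISPR spacer matches, (iv) d2* oligonucleotide-frequency distance
# (see d2star.R).  Evidence is then integrated into per-virus host
# assignments with method-count and CRISPR/tRNA tie-break rules.

#' Filter nucleotide homology hits into virus-host evidence
#'
#' Retains alignment hits that simultaneously satisfy all five thresholds:
#' query (viral) coverage, percent identity, alignment length, bit score,
#' and e-value.  Coverage is computed against the viral (query) sequence
#' length.
#'
#' @param hits Data frame of BLAST-like hits with columns `qseqid`
#'   (virus), `sseqid` (host), `pident`, `length`, `bitscore`, `evalue`,
#'   and either `coverage` (fraction of the query aligned) or `qstart`,
#'   `qend`, `qlen` from which coverage is derived.
#' @param min_coverage,min_identity,min_length,min_bitscore,max_evalue
#'   Retention thresholds; defaults are coverage >= 0.75, identity >= 70,
#'   length >= 1500 bp, bit score >= 50, e-value <= 0.001.
#' @return Data frame of evidence records (`virus`, `host`,
#'   `method = "homology"`, `score` = bit score) with one row per
#'   retained hit.  Malformed rows (missing required fields) are dropped
#'   with a warning.
#' @export
filter_homology <- function(hits, min_coverage = 0.75, min_identity = 70,
                            min_length = 1500, min_bitscore = 50,
                            max_evalue = 0.001) {
  hits <- as.data.frame(hits)
  need <- c("qseqid", "sseqid", "pident", "length", "bitscore", "evalue")
  if (!all(need %in% names(hits)))
    stop("hit table missing columns: ",
         paste(setdiff(need, names(hits)), collapse = ", "))
  if (!"coverage" %in% names(hits)) {
    if (!all(c("qstart", "qend", "qlen") %in% names(hits)))
      stop("hit table needs either `coverage` or qstart/qend/qlen")
    hits$coverage <- (abs(hits$qend - hits$qstart) + 1) / hits$qlen
  }
  used <- c(need, "coverage")
  bad <- !stats::complete.cases(hits[used])
  if (any(bad)) {
    warning(sum(bad), " malformed hit row(s) dropped")
    hits <- hits[!bad, ]
  }
  keep <- hits$coverage >= min_coverage &
    hits$pident >= min_identity &
    hits$length >= min_length &
    hits$bitscore >= min_bitscore &
    hits$evalue <= max_evalue
  out <- hits[keep, ]
  data.frame(virus = as.character(out$qseqid), host = as.character(out$sseqid),
             method = rep("homology", nrow(out)), score = out$bitscore,
             row.names = NULL)
}

# split "recordID|genomeID" FASTA headers
split_piped_names <- function(nms, what) {
  parts <- strsplit(nms, "|", fixed = TRUE)
  if (any(vapply(parts, length, 1L) < 2L))
    stop(what, " names must follow 'recordID|genomeID'")
  data.frame(record = vapply(parts, `[[`, "", 1L),
             genome = vapply(parts, `[[`, "", 2L))
}

#' Match viral and host tRNAs
#'
#' Emits evidence when a viral tRNA is an exact, full-length duplicate of
#' a host tRNA (100% identity and coverage).  Both strands are compared,
#' since the orientation of a tRNA relative to the assembled contig is
#' arbitrary.
#'
#' @param viral_trnas,host_trnas Named `DNAStringSet`s; names follow
#'   `trnaID|genomeID` so each tRNA is attributed to its genome.
#' @return Data frame of evidence records (`virus`, `host`,
#'   `method = "trna"`, `score` = tRNA length), deduplicated per
#'   virus-host pair.
#' @export
match_trna <- function(viral_trnas, host_trnas) {
  empty <- data.frame(virus = character(), host = character(),
                      method = character(), score = numeric())
  if (length(viral_trnas) == 0L || length(host_trnas) == 0L) return(empty)
  v <- split_piped_names(names(viral_trnas), "viral tRNA")
  h <- split_piped_names(names(host_trnas), "host tRNA")
  vseq <- toupper(as.character(viral_trnas))
  hseq <- toupper(as.character(host_trnas))
  hrc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(hseq)))
  rows <- list()
  for (i in seq_along(vseq)) {
    hit <- hseq == vseq[i] | hrc == vseq[i]
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        virus = v$genome[i], host = h$genome[hit],
        method = "trna", score = nchar(vseq[i]))
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[!duplicated(out[c("virus", "host")]), , drop = FALSE]
}

#' Match CRISPR spacers against viral genomes
#'
#' A spacer links its source host to a viral genome when some full-length
#' window of the genome, on either strand, differs from the spacer at no
#' more than `max_mismatch` positions AND the implied identity
#' `(L - mismatches) / L` is at least `min_identity` percent AND coverage
#' (always 1 for full-length windows) is at least `min_coverage`.  The
#' identity constraint means a single mismatch only qualifies for spacers
#' of length >= 20.
#'
#' @param spacers Named `DNAStringSet`; names follow `spacerID|hostID`.
#' @param viral_genomes Named `DNAStringSet` of viral sequences.
#' @param max_mismatch Maximum mismatches over the complete spacer length
#'   (default 1).
#' @param min_identity Minimum percent identity (default 95).
#' @param min_coverage Minimum spacer coverage (default 0.95).
#' @param min_spacer_length Spacers shorter than this are rejected
#'   outright (sanity floor, default 15).
#' @return Data frame of evidence records (`virus`, `host`,
#'   `method = "crispr"`, `score` = minimum mismatch count observed),
#'   deduplicated per virus-host pair.  Spacers containing non-ACGT
#'   characters are skipped with a warning.
#' @export
match_spacers <- function(spacers, viral_genomes, max_mismatch = 1,
                          min_identity = 95, min_coverage = 0.95,
                          min_spacer_length = 15) {
  empty <- data.frame(virus = character(), host = character(),
                      method = character(), score = numeric())
  if (length(spacers) == 0L || length(viral_genomes) == 0L) return(empty)
  sp <- split_piped_names(names(spacers), "spacer")
  vn <- names(viral_genomes)
  stopifnot(!is.null(vn))
  seqs <- toupper(as.character(spacers))
  clean <- grepl("^[ACGT]+$", seqs)
  if (!all(clean)) {
    warning(sum(!clean), " spacer(s) with non-ACGT characters skipped")
  }
  rows <- list()
  for (i in which(clean)) {
    L <- nchar(seqs[i])
    if (L < min_spacer_length) next
    if (1 < min_coverage) next  # full-length windows always give coverage 1
    # largest mismatch count satisfying both the mismatch cap and identity
    mm_cap <- min(max_mismatch, floor(L * (1 - min_identity / 100)))
    if (mm_cap < 0) next
    pat <- Biostrings::DNAString(seqs[i])
    patrc <- Biostrings::reverseComplement(pat)
    for (j in seq_along(viral_genomes)) {
      best <- NA_integer_
      for (mm in 0:mm_cap) {
        nfwd <- Biostrings::countPattern(pat, viral_genomes[[j]],
                                         max.mismatch = mm)
        nrev <- Biostrings::countPattern(patrc, viral_genomes[[j]],
                                         max.mismatch = mm)
        if (nfwd + nrev > 0) { best <- mm; break }
      }
      if (!is.na(best)) {
        rows[[length(rows) + 1L]] <- data.frame(
          virus = vn[j], host = sp$genome[i], method = "crispr",
          score = best)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(score ~ virus + host, data = out, FUN = min)
  data.frame(virus = agg$virus, host = agg$host,
             method = "crispr", score = agg$score)
}

#' Integrate multi-channel evidence into virus-host links
#'
#' Per virus: (1) a single candidate host is kept as-is; (2) with multiple
#' candidates, only those supported by the maximal number of distinct
#' methods survive; (3) if the survivors still span more than one phylum,
#' only those with CRISPR or tRNA support are kept; (4) if no survivor has
#' CRISPR/tRNA support in case (3), all candidates for that virus are
#' dropped (no phylum-level assignment can be defended).
#'
#' @param evidence Data frame of evidence records with columns `virus`,
#'   `host`, `method` (values among `homology`, `trna`, `crispr`, `onf`).
#' @param taxonomy Data frame mapping `host` to `phylum`; must cover every
#'   host appearing in `evidence`.
#' @return Data frame of links: `virus`, `host`, `phylum`, `n_methods`,
#'   `methods` (comma-separated, sorted).  Deterministic and invariant to
#'   the order of the evidence rows.
#' @export
integrate_links <- function(evidence, taxonomy) {
  stopifnot(all(c("virus", "host", "method") %in% names(evidence)),
            all(c("host", "phylum") %in% names(taxonomy)))
  if (nrow(evidence) == 0L)
    return(data.frame(virus = character(), host = character(),
                      phylum = character(), n_methods = integer(),
                      methods = character()))
  tax <- setNames(as.character(taxonomy$phylum), taxonomy$host)
  missing <- setdiff(unique(evidence$host), names(tax))
  if (length(missing))
    stop("hosts missing from taxonomy: ", paste(missing, collapse = ", "))
  ev <- unique(evidence[c("virus", "host", "method")])
  rows <- lapply(split(ev, ev$virus), function(e) {
    per_host <- lapply(split(e$method, e$host), function(m) sort(unique(m)))
    n_meth <- vapply(per_host, length, 1L)
    keep <- names(per_host)[n_meth == max(n_meth)]
    if (length(keep) > 1L) {
      phyla <- unique(tax[keep])
      if (length(phyla) > 1L) {
        has_ct <- vapply(per_host[keep], function(m)
          any(m %in% c("crispr", "trna")), logical(1L))
        keep <- keep[has_ct]
        if (!length(keep)) return(NULL)
      }
    }
    keep <- sort(keep)
    data.frame(virus = e$virus[1L], host = keep, phylum = unname(tax[keep]),
               n_methods = unname(n_meth[keep]),
               methods = vapply(per_host[keep], paste, "", collapse = ","))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(virus = character(), host = character(),
                      phylum = character(), n_methods = integer(),
                      methods = character()))
  out <- out[order(out$virus, out$host), ]
  rownames(out) <- NULL
  out
}

#' Virus-host abundance statistics for predicted links
#'
#' For each predicted link and sample with positive host abundance,
#' computes the virus-to-host ratio `VHR = viral RPKM / host RPKM`, then
#' reports Spearman correlations of host abundance against virus abundance
#' and against VHR, overall and per viral lifestyle class, plus the
#' per-sample lytic:temperate abundance ratio.
#'
#' @param links Data frame with columns `virus`, `host` (e.g. from
#'   [integrate_links()]).
#' @param virus_abundance,host_abundance Abundance matrices (rows =
#'   genomes, columns = samples) sharing the same sample set.
#' @param lifestyles Optional named character vector mapping virus ids to
#'   `"lytic"`/`"temperate"`/`"unknown"`.
#' @return A list with `pairs` (long data frame: `virus`, `host`,
#'   `sample`, `virus_rpkm`, `host_rpkm`, `vhr`, `lifestyle`),
#'   `correlations` (data frame of Spearman rho/p per comparison and
#'   lifestyle class), `lytic_temperate_ratio` (per-sample ratio, NA when
#'   no temperate abundance), and `n_excluded` (pair-samples dropped for
#'   zero host abundance).
#' @export
linkage_stats <- function(links, virus_abundance, host_abundance,
                          lifestyles = NULL) {
  samples <- intersect(colnames(virus_abundance), colnames(host_abundance))
  if (!length(samples)) stop("no shared samples between abundance tables")
  links <- links[links$virus %in% rownames(virus_abundance) &
                   links$host %in% rownames(host_abundance), , drop = FALSE]
  n_pairs <- nrow(links)
  if (n_pairs == 0L) {
    pairs <- data.frame(virus = character(), host = character(),
                        sample = character(), virus_rpkm = numeric(),
                        host_rpkm = numeric(), vhr = numeric(),
                        lifestyle = character())
    n_excluded <- 0L
  } else {
    long <- data.frame(
      virus = rep(links$virus, each = length(samples)),
      host = rep(links$host, each = length(samples)),
      sample = rep(samples, times = n_pairs))
    long$virus_rpkm <- virus_abundance[cbind(long$virus, long$sample)]
    long$host_rpkm <- host_abundance[cbind(long$host, long$sample)]
    excl <- long$host_rpkm <= 0
    n_excluded <- sum(excl)
    pairs <- long[!excl, , drop = FALSE]
    pairs$vhr <- pairs$virus_rpkm / pairs$host_rpkm
    pairs$lifestyle <- if (is.null(lifestyles))
      rep(NA_character_, nrow(pairs)) else unname(lifestyles[pairs$virus])
    rownames(pairs) <- NULL
  }
  cor_row <- function(x, y, comparison, class) {
    if (length(x) < 3L || stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
      return(data.frame(comparison = comparison, class = class,
                        rho = NA_real_, p_value = NA_real_, n = length(x)))
    ct <- spearman_cor(x, y)
    data.frame(comparison = comparison, class = class, rho = ct$rho,
               p_value = ct$p_value, n = length(x))
  }
  classes <- c("all", if (!is.null(lifestyles))
    setdiff(unique(pairs$lifestyle), NA))
  correlations <- do.call(rbind, lapply(classes, function(cl) {
    sub <- if (cl == "all") pairs else pairs[pairs$lifestyle %in% cl, ]
    rbind(cor_row(sub$host_rpkm, sub$virus_rpkm, "host_vs_virus", cl),
          cor_row(sub$host_rpkm, sub$vhr, "host_vs_vhr", cl))
  }))
  lt_ratio <- NULL
  if (!is.null(lifestyles)) {
    lyt <- rownames(virus_abundance)[lifestyles[rownames(virus_abundance)] %in% "lytic"]
    tmp <- rownames(virus_abundance)[lifestyles[rownames(virus_abundance)] %in% "temperate"]
    lsum <- colSums(virus_abundance[lyt, samples, drop = FALSE])
    tsum <- colSums(virus_abundance[tmp, samples, drop = FALSE])
    lt_ratio <- ifelse(tsum > 0, lsum / tsum, NA_real_)
    names(lt_ratio) <- samples
  }
  list(pairs = pairs, correlations = correlations,
       lytic_temperate_ratio = lt_ratio, n_excluded = n_excluded)
}
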