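# Independent oracles used to cross-check the package implementations.
# These deliberately use naive algorithms and their own coding paths
# (plain string/loop arithmetic) rather than the package internals.

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force beta-MNTD for two community columns over a distance matrix
bmntd_oracle <- function(xa, xb, D, weighted = TRUE) {
  ia <- which(xa > 0); ib <- which(xb > 0)
  wa <- if (weighted) xa[ia] / sum(xa[ia]) else rep(1 / length(ia), length(ia))
  wb <- if (weighted) xb[ib] / sum(xb[ib]) else rep(1 / length(ib), length(ib))
  s <- 0
  for (k in seq_along(ia)) {
    s <- s + wa[k] * min(D[ia[k], ib])
  }
  for (k in seq_along(ib)) {
    s <- s + wb[k] * min(D[ib[k], ia])
  }
  unname(s) / 2
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# naive full-scan Hamming spacer matcher: does any full-length window on
# either strand of `genome` sit within the joint mismatch/identity caps?
spacer_scan_oracle <- function(spacer, genome, max_mm = 1, min_ident = 95) {
  L <- nchar(spacer)
  mm_cap <- min(max_mm, floor(L * (1 - min_ident / 100)))
  if (mm_cap < 0) return(FALSE)
  gch <- strsplit(genome, "")[[1L]]
  n_win <- length(gch) - L + 1L
  if (n_win < 1L) return(FALSE)
  for (s in c(spacer, revcomp_chr(spacer))) {
    sch <- strsplit(s, "")[[1L]]
    mm <- integer(n_win)
    for (j in seq_len(L)) {
      mm <- mm + (gch[seq_len(n_win) + j - 1L] != sch[j])
    }
    if (any(mm <= mm_cap)) return(TRUE)
  }
  FALSE
}

# direct-formula d2* transcription using plain string ops and per-word loops
d2star_oracle <- function(x, y, k = 3, r = 1) {
  count_words <- function(seq, w) {
    words <- character()
    for (s in c(seq, revcomp_chr(seq))) {
      n <- nchar(s)
      words <- c(words, substring(s, 1:(n - w + 1L), w:n))
    }
    tab <- table(words)
    setNames(as.numeric(tab), names(tab))
  }
  get0n <- function(tab, w) if (w %in% names(tab)) tab[[w]] else 0
  kmers <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)), 1L,
                 paste, collapse = "")
  stats_one <- function(seq) {
    ck <- count_words(seq, k)
    cr1 <- count_words(seq, r + 1L)
    cr <- count_words(seq, r)
    n <- e <- numeric(length(kmers))
    for (i in seq_along(kmers)) {
      w <- kmers[i]
      n[i] <- get0n(ck, w)
      num <- 1
      for (j in 1:(k - r)) num <- num * get0n(cr1, substr(w, j, j + r))
      den <- 1
      if (k - r >= 2) {
        for (j in 2:(k - r)) den <- den * get0n(cr, substr(w, j, j + r - 1L))
      }
      e[i] <- if (den > 0) num / den else 0
      if (num == 0) e[i] <- 0
    }
    list(n = n, e = e)
  }
  sx <- stats_one(x); sy <- stats_one(y)
  valid <- sx$e > 0 & sy$e > 0
  ctx <- (sx$n - sx$e)[valid]; ex <- sx$e[valid]
  cty <- (sy$n - sy$e)[valid]; ey <- sy$e[valid]
  s_norm <- sum(ctx * cty / sqrt(ex * ey)) /
    (sqrt(sum(ctx^2 / ex)) * sqrt(sum(cty^2 / ey)))
  0.5 * (1 - s_norm)
}

# run blastn (standard local aligner) between viral queries and host
# subjects, returning a hit table in the package's 13-column convention
blast_hits_oracle <- function(viruses, hosts) {
  td <- tempfile("blast")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  vf <- file.path(td, "v.fa"); hf <- file.path(td, "h.fa")
  out <- file.path(td, "hits.tsv")
  write_fasta(viruses, vf)
  write_fasta(hosts, hf)
  system2("makeblastdb", c("-in", hf, "-dbtype", "nucl",
                           "-logfile", "/dev/null"))
  system2("blastn",
          c("-query", vf, "-db", hf, "-task", "blastn", "-out", out,
            "-outfmt", shQuote(paste("6 qseqid sseqid pident length",
                                     "mismatch gapopen qstart qend sstart",
                                     "send evalue bitscore qlen"))))
  if (!file.size(out)) {
    return(data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      bitscore = numeric(), evalue = numeric(),
                      coverage = numeric()))
  }
  read_blast_hits(out)
}

# hand-solved ordinary least squares via the normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}
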