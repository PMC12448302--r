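test_that("homology filter applies all five thresholds jointly", {
  base <- data.frame(qseqid = "v1", sseqid = "h1", pident = 71,
                     length = 2000, bitscore = 60, evalue = 1e-10,
                     coverage = 0.80)
  expect_identical(nrow(filter_homology(base)), 1L)
  low_id <- transform(base, pident = 69)
  expect_identical(nrow(filter_homology(low_id)), 0L)
  short <- transform(base, length = 1400)
  expect_identical(nrow(filter_homology(short)), 0L)
  low_cov <- transform(base, coverage = 0.74)
  expect_identical(nrow(filter_homology(low_cov)), 0L)
  weak <- transform(base, bitscore = 49)
  expect_identical(nrow(filter_homology(weak)), 0L)
  loose_e <- transform(base, evalue = 0.01)
  expect_identical(nrow(filter_homology(loose_e)), 0L)
  # malformed rows are dropped with a warning, not fatal
  expect_warning(out <- filter_homology(rbind(base, transform(base, pident = NA))),
                 "malformed")
  expect_identical(nrow(out), 1L)
})

test_that("tRNA matching requires exact full-length duplication, either strand", {
  t_seq <- random_seq(75)
  vt <- Biostrings::DNAStringSet(setNames(t_seq, "t1|v1"))
  ht <- Biostrings::DNAStringSet(setNames(t_seq, "t9|h1"))
  expect_identical(match_trna(vt, ht)$host, "h1")

  sub <- t_seq
  substr(sub, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(sub, 10, 10))[1]
  ht2 <- Biostrings::DNAStringSet(setNames(sub, "t9|h1"))
  expect_identical(nrow(match_trna(vt, ht2)), 0L)

  ht3 <- Biostrings::DNAStringSet(setNames(revcomp_chr(t_seq), "t9|h1"))
  expect_identical(match_trna(vt, ht3)$host, "h1")
})

test_that("spacer matching enforces the joint mismatch/identity rule", {
  set.seed(31)
  genome <- random_seq(5000)
  sp30 <- substr(genome, 1001, 1030)
  g <- Biostrings::DNAStringSet(setNames(genome, "v1"))

  ev <- match_spacers(Biostrings::DNAStringSet(setNames(sp30, "s1|h1")), g)
  expect_identical(ev$virus, "v1")
  expect_identical(ev$score, 0L)

  sp30mm <- sp30
  substr(sp30mm, 7, 7) <- setdiff(c("A", "C", "G", "T"), substr(sp30mm, 7, 7))[1]
  ev1 <- match_spacers(Biostrings::DNAStringSet(setNames(sp30mm, "s1|h1")), g)
  expect_identical(ev1$score, 1L)

  # 19-nt spacer with one mismatch: identity 94.7% < 95, so no match
  sp19 <- substr(genome, 2001, 2019)
  substr(sp19, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(sp19, 5, 5))[1]
  ev2 <- match_spacers(Biostrings::DNAStringSet(setNames(sp19, "s1|h1")), g)
  expect_identical(nrow(ev2), 0L)

  expect_warning(
    out <- match_spacers(Biostrings::DNAStringSet(setNames("ACGTNACGTNACGTNACGTNACGTN",
                                                           "s1|h1")), g),
    "non-ACGT")
  expect_identical(nrow(out), 0L)
})

test_that("spacer matching equals the naive Hamming-scan oracle", {
  set.seed(17)
  for (i in 1:20) {
    genome <- random_seq(10000)
    L <- sample(18:40, 1)
    spacer <- if (i %% 2 == 0) {
      # planted (possibly mutated, possibly reverse-complemented) window
      st <- sample(1000:8000, 1)
      sp <- substr(genome, st, st + L - 1)
      if (i %% 4 == 0) {
        p <- sample(L, 1)
        substr(sp, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(sp, p, p)), 1)
      }
      if (i %% 8 == 0) sp <- revcomp_chr(sp)
      sp
    } else random_seq(L)
    got <- nrow(match_spacers(
      Biostrings::DNAStringSet(setNames(spacer, "s|h")),
      Biostrings::DNAStringSet(setNames(genome, "v")))) > 0
    expect_identical(got, spacer_scan_oracle(spacer, genome),
                     info = paste("instance", i))
  }
})

test_that("d2* is zero on self, symmetric, bounded, and matches the oracle", {
  set.seed(23)
  x <- random_seq(2000); y <- random_seq(2000)
  expect_lt(abs(as.numeric(d2star(x, x))), 1e-12)
  dxy <- as.numeric(d2star(x, y))
  dyx <- as.numeric(d2star(y, x))
  expect_equal(dxy, dyx, tolerance = 1e-12)
  expect_true(dxy >= 0 && dxy <= 1)
  expect_error(d2star(random_seq(50), y), "at least")

  # independent direct-formula transcription at k = 3, order = 1
  for (i in 1:3) {
    a <- random_seq(2000); b <- random_seq(2000)
    expect_equal(as.numeric(d2star(a, b, k = 3, markov_order = 1)),
                 d2star_oracle(a, b, k = 3, r = 1), tolerance = 1e-10)
  }
})

test_that("d2* of a virus emitted from its host's model is smaller than to foreign hosts", {
  closer <- logical(20)
  for (i in 1:20) {
    g <- generate_virus_host_genomes(seed = 500 + i, n_viruses = 1,
                                     n_hosts = 2,
                                     planted = data.frame(virus = 1, host = 1,
                                                          channel = "onf"),
                                     virus_length = 3000, host_length = 12000)
    d_own <- as.numeric(d2star(g$viruses[[1]], g$hosts[[1]]))
    d_foreign <- as.numeric(d2star(g$viruses[[1]], g$hosts[[2]]))
    closer[i] <- d_own < d_foreign
  }
  expect_gte(sum(closer), 18)
})

test_that("evidence integration reproduces the tie-break rules", {
  tax <- data.frame(host = c("A", "B", "C"), phylum = c("P1", "P2", "P1"))
  # multi-method support wins
  ev1 <- data.frame(virus = "V",
                    host = c("A", "A", "B"),
                    method = c("homology", "trna", "onf"))
  out1 <- integrate_links(ev1, tax)
  expect_identical(out1$host, "A")
  # cross-phylum tie: only CRISPR/tRNA-backed candidates survive
  ev2 <- data.frame(virus = "V", host = c("A", "B"),
                    method = c("homology", "crispr"))
  out2 <- integrate_links(ev2, tax)
  expect_identical(out2$host, "B")
  # single host, single method: kept
  ev3 <- data.frame(virus = "V", host = "C", method = "onf")
  expect_identical(integrate_links(ev3, tax)$host, "C")
  # cross-phylum tie with no CRISPR/tRNA support: dropped entirely
  ev4 <- data.frame(virus = "V", host = c("A", "B"),
                    method = c("homology", "onf"))
  expect_identical(nrow(integrate_links(ev4, tax)), 0L)
  # same-phylum tie: both kept
  ev5 <- data.frame(virus = "V", host = c("A", "C"),
                    method = c("homology", "homology"))
  expect_identical(sort(integrate_links(ev5, tax)$host), c("A", "C"))

  expect_error(integrate_links(data.frame(virus = "V", host = "Z",
                                          method = "onf"), tax),
               "missing from taxonomy")
})

test_that("integration is idempotent and order-invariant", {
  set.seed(13)
  tax <- data.frame(host = paste0("h", 1:6),
                    phylum = rep(c("P1", "P2", "P3"), 2))
  ev <- data.frame(
    virus = sample(paste0("v", 1:8), 60, replace = TRUE),
    host = sample(tax$host, 60, replace = TRUE),
    method = sample(c("homology", "trna", "crispr", "onf"), 60, replace = TRUE))
  base <- integrate_links(ev, tax)
  shuffled <- integrate_links(ev[sample(nrow(ev)), ], tax)
  expect_identical(base, shuffled)
  dup <- integrate_links(rbind(ev, ev), tax)
  expect_identical(base, dup)
})

test_that("virus-host ratio statistics behave on planted correlations", {
  links <- data.frame(virus = "v1", host = "h1")
  va <- matrix(10, 1, 1, dimnames = list("v1", "s1"))
  ha <- matrix(5, 1, 1, dimnames = list("h1", "s1"))
  st <- linkage_stats(links, va, ha)
  expect_equal(st$pairs$vhr, 2)

  set.seed(19)
  n <- 100
  hostab <- matrix(runif(n, 1, 10), 1, n,
                   dimnames = list("h1", paste0("s", 1:n)))
  virab <- 0.5 * hostab + matrix(rnorm(n, 0, 0.5), 1, n)
  virab[virab < 0] <- 0.01
  rownames(virab) <- "v1"
  st2 <- linkage_stats(links, virab, hostab)
  hv <- st2$correlations[st2$correlations$comparison == "host_vs_virus" &
                           st2$correlations$class == "all", ]
  expect_gt(hv$rho, 0)
  expect_lt(hv$p_value, 0.05)

  # all hosts absent: empty report, full exclusion tally
  ha0 <- matrix(0, 1, n, dimnames = list("h1", paste0("s", 1:n)))
  st3 <- linkage_stats(links, virab, ha0)
  expect_identical(nrow(st3$pairs), 0L)
  expect_identical(st3$n_excluded, as.integer(n))
})
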