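test_that("all generators are byte-identical under a fixed seed", {
  cfg <- scenario_config(1, 6, 30, "well_mixed")
  expect_identical(generate_community(cfg), generate_community(cfg))

  g1 <- generate_virus_host_genomes(seed = 4, n_viruses = 6, n_hosts = 3,
                                    virus_length = 1500, host_length = 6000)
  g2 <- generate_virus_host_genomes(seed = 4, n_viruses = 6, n_hosts = 3,
                                    virus_length = 1500, host_length = 6000)
  expect_identical(as.character(g1$viruses), as.character(g2$viruses))
  expect_identical(as.character(g1$hosts), as.character(g2$hosts))
  expect_identical(g1$truth, g2$truth)

  ct <- generate_viral_contig(3, n_genes = 1, n_codons = 40)
  tv <- plant_variants(4, ct$sequence, ct$genes, 5)
  expect_identical(generate_pileup(5, ct$sequence, tv),
                   generate_pileup(5, ct$sequence, tv))
})

test_that("generator configurations are validated", {
  expect_error(scenario_config(1, 4, 20, "dispersal_limited_islands",
                               n_islands = 5), "n_islands")
  expect_error(scenario_config(1, 1, 20, "well_mixed"))
  expect_error(scenario_config(1, 4, 20, "well_mixed", birth_rate = 0))
  expect_error(generate_pileup(1, "ACGTACGT", mean_coverage = 0))
  expect_error(generate_pileup(1, "ACGTACGT", error_rate = 0.6))
  ct <- generate_viral_contig(3, n_genes = 1, n_codons = 40)
  bad <- data.frame(contig = "ctg_sim", pos = 10000, ref = "A", alt = "C",
                    freq = 0.5)
  expect_error(generate_pileup(1, ct$sequence, bad), "outside contig")
})

test_that("fully disjoint islands give Bray-Curtis 1 between islands", {
  cfg <- scenario_config(2, 6, 40, "dispersal_limited_islands",
                         n_islands = 2, island_overlap = 0)
  sim <- generate_community(cfg)
  bc <- bray_curtis(sim$table)
  isl <- sim$truth$island_of_sample
  for (i in 1:5) for (j in (i + 1):6) {
    if (isl[i] != isl[j]) expect_equal(bc[i, j], 1)
  }
})

test_that("planted linkage truth is honest about channels", {
  plan <- data.frame(virus = c(1, 2), host = c(1, 2),
                     channel = c("crispr", "trna"))
  g <- generate_virus_host_genomes(seed = 6, n_viruses = 3, n_hosts = 2,
                                   planted = plan, virus_length = 1500,
                                   host_length = 6000)
  # an exact-copy spacer occurs verbatim in the viral genome
  sp <- g$spacers[startsWith(names(g$spacers), "spacer_001")]
  expect_identical(
    Biostrings::countPattern(sp[[1]], g$viruses[["vOTU_001"]]) +
      Biostrings::countPattern(Biostrings::reverseComplement(sp[[1]]),
                               g$viruses[["vOTU_001"]]) > 0, TRUE)
  # unplanted virus 3 is absent from the truth table
  expect_false("vOTU_003" %in% g$truth$virus)
  # channels are reported only where planted
  expect_setequal(g$truth$channel, c("crispr", "trna"))
})

test_that("planted homology satisfies all five thresholds under blastn", {
  g <- generate_virus_host_genomes(seed = 7, n_viruses = 4, n_hosts = 2,
                                   planted = data.frame(virus = 1:2,
                                                        host = 1:2,
                                                        channel = "homology"))
  hits <- blast_hits_oracle(g$viruses, g$hosts)
  ev <- filter_homology(hits)
  expect_true(all(c("vOTU_001", "vOTU_002") %in% ev$virus))
  expect_identical(ev$host[ev$virus == "vOTU_001"], "MAG_001")
  expect_identical(ev$host[ev$virus == "vOTU_002"], "MAG_002")
})

test_that("pileups honour the planted error model", {
  ct <- generate_viral_contig(12, n_genes = 1, n_codons = 100)
  # error 0, no variants: every covered site is monoallelic
  pu <- generate_pileup(13, ct$sequence, NULL, mean_coverage = 50,
                        error_rate = 0)
  counts <- as.matrix(pu[, c("nA", "nC", "nG", "nT")])
  expect_true(all(rowSums(counts > 0) <= 1))
  expect_identical(nrow(call_snvs(pu)), 0L)

  # planted frequency 0.5 at coverage 1000 lands within +/- 0.05
  tv <- data.frame(contig = "ctg_sim", pos = 50,
                   ref = substr(ct$sequence, 50, 50),
                   alt = setdiff(c("A", "C", "G", "T"),
                                 substr(ct$sequence, 50, 50))[1],
                   freq = 0.5)
  pu2 <- generate_pileup(14, ct$sequence, tv, mean_coverage = 1000,
                         error_rate = 0)
  row <- pu2[pu2$pos == 50, ]
  obs <- row[[paste0("n", tv$alt)]] / sum(row[, c("nA", "nC", "nG", "nT")])
  expect_lt(abs(obs - 0.5), 0.05)

  # with sequencing errors, non-planted bases appear at roughly the error rate
  pu3 <- generate_pileup(15, ct$sequence, NULL, mean_coverage = 200,
                         error_rate = 0.03)
  counts3 <- as.matrix(pu3[, c("nA", "nC", "nG", "nT")])
  ref_idx <- match(pu3$ref, c("A", "C", "G", "T"))
  err <- 1 - counts3[cbind(seq_len(nrow(counts3)), ref_idx)] / rowSums(counts3)
  expect_lt(abs(mean(err) - 0.03), 0.01)
})

test_that("rc_null_process abundances are exchangeable with the RC null", {
  # feeding null-assembled data back through rc_bray (same pool) gives
  # RC values whose distribution is uniform on [-1, 1]: the
  # Kolmogorov-Smirnov test is not rejected over independent pairs
  set.seed(77)
  nt <- 60
  occ <- runif(nt, 0.2, 0.8)
  ab <- rlnorm(nt, 0, 1); ab <- ab / sum(ab)
  rcv <- vapply(1:500, function(i) {
    cfg <- scenario_config(3000 + i, 2, nt, "rc_null_process",
                           pool_occupancy = occ, pool_abundance = ab)
    sim <- generate_community(cfg)
    rc_bray(sim$table, n_null = 199, seed = 6000 + i,
            pool = list(occupancy = occ, abundance = ab))[1, 2]
  }, numeric(1))
  expect_gt(mean(abs(rcv) < 0.95), 0.90)
  ks <- suppressWarnings(stats::ks.test(rcv, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})
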