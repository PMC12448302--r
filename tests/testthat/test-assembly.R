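small_tree <- function() {
  ape::read.tree(text = "((A:1,B:2):1.5,(C:1,D:1):0.5);")
}

test_that("beta-MNTD collapses correctly on trivial communities", {
  tr <- small_tree()
  # identical communities share every taxon: nearest distance zero
  tab <- cbind(s1 = c(A = 1, B = 2, C = 0, D = 0),
               s2 = c(A = 1, B = 2, C = 0, D = 0))
  expect_equal(beta_mntd(tab, tr)["s1", "s2"], 0)

  # single-taxon communities: beta-MNTD equals the patristic distance
  tab2 <- cbind(s1 = c(A = 3, B = 0, C = 0, D = 0),
                s2 = c(A = 0, B = 0, C = 2, D = 0))
  D <- ape::cophenetic.phylo(tr)
  expect_equal(beta_mntd(tab2, tr)["s1", "s2"], D["A", "C"])

  missing <- rbind(tab2, E = c(1, 1))
  expect_error(beta_mntd(missing, tr), "E")
})

test_that("beta-MNTD agrees with a brute-force oracle and picante", {
  set.seed(21)
  nt <- 12
  tr <- ape::rphylo(nt, 1, 0)
  tr$tip.label <- paste0("t", seq_len(nt))
  tab <- matrix(rpois(nt * 5, 1.5), nt, 5,
                dimnames = list(tr$tip.label, paste0("s", 1:5)))
  tab[, colSums(tab) == 0] <- 1
  for (s in 1:5) if (sum(tab[, s]) == 0) tab[1, s] <- 1
  D <- ape::cophenetic.phylo(tr)[rownames(tab), rownames(tab)]
  got <- beta_mntd(tab, tr)
  for (pair in list(c(1, 2), c(2, 5), c(3, 4))) {
    expect_equal(got[pair[1], pair[2]],
                 bmntd_oracle(tab[, pair[1]], tab[, pair[2]], D),
                 tolerance = 1e-12)
  }
  ref <- as.matrix(picante::comdistnt(t(tab), D, abundance.weighted = TRUE))
  expect_equal(unname(got), unname(ref[colnames(tab), colnames(tab)]),
               tolerance = 1e-10)
})

test_that("beta-NTI matches exhaustive tip-permutation enumeration", {
  tr <- small_tree()
  tab <- cbind(s1 = c(A = 2, B = 1, C = 0, D = 0),
               s2 = c(A = 0, B = 0, C = 1, D = 3))
  perms <- t(all_perms(4))       # 4 x 24, all distinct shuffles
  got <- beta_nti(tab, tr, perms = perms)
  D <- ape::cophenetic.phylo(tr)[rownames(tab), rownames(tab)]
  obs <- bmntd_oracle(tab[, 1], tab[, 2], D)
  nulls <- apply(perms, 2L, function(p) {
    Dp <- D[p, p]
    bmntd_oracle(tab[, 1], tab[, 2], Dp)
  })
  expect_equal(got["s1", "s2"], (obs - mean(nulls)) / sd(nulls),
               tolerance = 1e-10)
})

test_that("degenerate nulls yield NA beta-NTI with a warning", {
  tr <- small_tree()
  tab <- cbind(s1 = c(A = 1, B = 1, C = 1, D = 1),
               s2 = c(A = 1, B = 1, C = 1, D = 1))
  expect_warning(bn <- beta_nti(tab, tr, n_null = 25, seed = 1),
                 "degenerate")
  expect_true(is.na(bn["s1", "s2"]))
  expect_identical(attr(bn, "n_undefined"), 1L)
})

test_that("a constant added to all patristic distances cancels in beta-NTI", {
  # lengthening every terminal branch by c/2 adds c to all tip distances;
  # with single-taxon communities the same shift hits observed and null
  tr <- small_tree()
  tab <- cbind(s1 = c(A = 1, B = 0, C = 0, D = 0),
               s2 = c(A = 0, B = 0, C = 1, D = 0))
  perms <- t(all_perms(4))
  tr2 <- tr
  tips <- tr2$edge[, 2] <= length(tr2$tip.label)
  tr2$edge.length[tips] <- tr2$edge.length[tips] + 2.5
  b1 <- beta_nti(tab, tr, perms = perms)
  b2 <- beta_nti(tab, tr2, perms = perms)
  expect_equal(b1["s1", "s2"], b2["s1", "s2"], tolerance = 1e-10)
})

test_that("RC_Bray respects its bounds and degenerate endpoints", {
  set.seed(9)
  tab <- matrix(rpois(20 * 6, 3) + 1, 20, 6,
                dimnames = list(paste0("t", 1:20), paste0("s", 1:6)))
  rc <- rc_bray(tab, n_null = 99, seed = 4)
  expect_true(all(rc >= -1 & rc <= 1))
  expect_identical(rc, t(rc))

  # identical samples: observed BC = 0, below every null draw
  dup <- cbind(tab, s_dup = tab[, 1])
  colnames(dup) <- c(colnames(tab), "s_dup")
  rc2 <- rc_bray(dup, n_null = 99, seed = 4)
  expect_equal(rc2["s1", "s_dup"], -1)

  # RC is monotone in the observed dissimilarity for a fixed null sample
  nulls <- runif(999)
  obs <- seq(0, 1, length.out = 21)
  vals <- vapply(obs, function(o) hadalvirome:::rc_from_null(o, nulls),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(hadalvirome:::rc_from_null(2, nulls), 1)
})

test_that("process classification reproduces the five threshold rules", {
  expect_identical(classify_pair(2.5, 0.3), "heterogeneous_selection")
  # selection takes precedence over the RC rules
  expect_identical(classify_pair(-2.5, 0.99), "homogeneous_selection")
  expect_identical(classify_pair(0, 0.97), "dispersal_limitation")
  expect_identical(classify_pair(0, -0.97), "homogenizing_dispersal")
  expect_identical(classify_pair(0, 0), "drift")
  # strict inequalities: exact threshold values fall to the undominated class
  expect_identical(classify_pair(2, 0.99), "drift")
  expect_identical(classify_pair(-2, -0.99), "drift")
  expect_identical(classify_pair(0, 0.95), "drift")
  expect_identical(classify_pair(0, -0.95), "drift")
  expect_identical(classify_pair(NA, 0.5), NA_character_)
})

test_that("assembly partition fractions are normalised per group", {
  cfg <- scenario_config(8, 8, 40, "well_mixed")
  sim <- generate_community(cfg)
  pt <- suppressWarnings(partition_assembly(sim$table, sim$tree,
                                            metadata = sim$metadata,
                                            group = "trench",
                                            n_null = 99, seed = 2))
  sums <- rowSums(pt$fractions[, -1])
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_setequal(pt$fractions$group, c("Trench_A", "Trench_B"))
  # group with a single sample is skipped with a warning
  md <- sim$metadata
  md$solo <- c("g1", rep("g2", 7))
  expect_warning(
    pt2 <- partition_assembly(sim$table, sim$tree, metadata = md,
                              group = "solo", n_null = 49, seed = 2),
    "skipped")
  expect_identical(unique(pt2$pairs$group), "g2")
})
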