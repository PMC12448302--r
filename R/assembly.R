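# Null-model partitioning of community assembly ---------------------------
#
# The two-step framework: (1) beta-NTI, the z-score of the observed
# between-community mean-nearest-taxon distance (beta-MNTD) against a null
# built by shuffling taxon labels across the phylogeny's tips; (2) for
# pairs not dominated by selection (|bNTI| < 2), the Bray-Curtis-based
# Raup-Crick index RC_Bray from probabilistic reassembly of each community
# out of the regional species pool.  (bNTI, RC_Bray) then classify each
# sample pair into one of five assembly processes.

# presence/weight bookkeeping shared by beta_mntd and beta_nti
community_structure <- function(table, weighted) {
  pres <- lapply(seq_len(ncol(table)), function(s) which(table[, s] > 0))
  wts <- lapply(seq_len(ncol(table)), function(s) {
    x <- table[pres[[s]], s]
    if (weighted) x / sum(x) else rep(1 / length(x), length(x))
  })
  if (any(vapply(pres, length, 1L) == 0L))
    stop("samples with zero richness: ",
         paste(colnames(table)[vapply(pres, length, 1L) == 0L], collapse = ", "))
  list(pres = pres, wts = wts)
}

taxon_distance_matrix <- function(table, tree) {
  missing <- setdiff(rownames(table)[rowSums(table) > 0], tree$tip.label)
  if (length(missing))
    stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
  D <- ape::cophenetic.phylo(tree)
  D[rownames(table), rownames(table), drop = FALSE]
}

#' Between-community mean nearest taxon distance (beta-MNTD)
#'
#' For each pair of samples, the abundance-weighted mean of the patristic
#' distance from every taxon in one community to its nearest taxon in the
#' other, averaged over both directions.  A taxon shared by both
#' communities contributes a nearest distance of zero.
#'
#' @param table Abundance matrix, taxa in rows, samples in columns.
#' @param tree A rooted `phylo` tree whose tips cover all taxa with
#'   positive abundance.
#' @param weighted If `TRUE` (default) taxa are weighted by within-sample
#'   relative abundance; otherwise each present taxon gets weight
#'   1/richness.
#' @return Symmetric sample-by-sample matrix of beta-MNTD values.
#' @export
beta_mntd <- function(table, tree, weighted = TRUE) {
  table <- check_abundance_table(table)
  D <- taxon_distance_matrix(table, tree)
  cs <- community_structure(table, weighted)
  n <- ncol(table)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  res <- .bmntd_engine(D,
                       lapply(cs$pres, function(i) i - 1L),
                       cs$wts,
                       pairs - 1L,
                       matrix(seq_len(nrow(D)) - 1L, ncol = 1L))
  out <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  out[pairs] <- res$obs
  out[pairs[, 2:1, drop = FALSE]] <- res$obs
  out
}

#' Beta nearest taxon index (beta-NTI)
#'
#' Standardises observed beta-MNTD against a null distribution obtained by
#' shuffling taxon labels across the tips of the phylogeny (one global
#' shuffle per randomisation, shared by all sample pairs):
#' `bNTI = (bMNTD_obs - mean_null) / sd_null`.  `|bNTI| > 2` signals a
#' dominant role of selection.
#'
#' @inheritParams beta_mntd
#' @param n_null Number of null randomisations (default 999).
#' @param seed Optional integer seed for the tip shuffles.
#' @param perms Optional integer matrix of explicit tip permutations
#'   (`n_taxa` rows, one column per randomisation, values `1..n_taxa`
#'   indexing `rownames(table)`).  Used to enumerate all permutations on
#'   small instances; overrides `n_null`/`seed`.
#' @return Symmetric matrix of bNTI values with `NA` for degenerate pairs
#'   (null standard deviation zero); the number of such pairs is attached
#'   as attribute `n_undefined`, and a warning is raised when any occur.
#' @export
beta_nti <- function(table, tree, n_null = 999, seed = NULL, weighted = TRUE,
                     perms = NULL) {
  table <- check_abundance_table(table)
  D <- taxon_distance_matrix(table, tree)
  nt <- nrow(D)
  if (is.null(perms)) {
    stopifnot(n_null >= 1)
    perms <- with_seed(seed,
      vapply(seq_len(n_null), function(i) sample.int(nt), integer(nt)))
  } else {
    perms <- as.matrix(perms)
    stopifnot(nrow(perms) == nt, all(perms >= 1), all(perms <= nt))
  }
  cs <- community_structure(table, weighted)
  n <- ncol(table)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  res <- .bmntd_engine(D,
                       lapply(cs$pres, function(i) i - 1L),
                       cs$wts,
                       pairs - 1L,
                       perms - 1L)
  mu <- rowMeans(res$null)
  sdv <- apply(res$null, 1L, sd)
  bnti <- ifelse(sdv > 0, (res$obs - mu) / sdv, NA_real_)
  n_undef <- sum(is.na(bnti))
  if (n_undef > 0)
    warning(n_undef, " sample pair(s) with degenerate null (sd = 0); ",
            "bNTI reported as NA")
  out <- matrix(NA_real_, n, n,
                dimnames = list(colnames(table), colnames(table)))
  diag(out) <- 0
  out[pairs] <- bnti
  out[pairs[, 2:1, drop = FALSE]] <- bnti
  attr(out, "n_undefined") <- n_undef
  out
}

#' Convert an RPKM table to integer counts for Raup-Crick resampling
#'
#' Scales each sample to a fixed total and rounds; any positive abundance
#' is preserved as at least one individual so richness is unchanged.
#'
#' @inheritParams bray_curtis
#' @param sample_total Target number of individuals per sample.
#' @return Integer matrix of the same shape.
#' @export
discretize_rpkm <- function(table, sample_total = 1000) {
  table <- check_abundance_table(table)
  counts <- round(sweep(table, 2, colSums(table), "/") * sample_total)
  counts[table > 0 & counts < 1] <- 1
  storage.mode(counts) <- "integer"
  counts
}

# Assemble one null community: draw `richness` species without replacement
# with probability proportional to `occ`, then distribute the remaining
# `total - richness` individuals over the drawn species with probability
# proportional to pool relative abundance `ab` (each drawn species starts
# with one individual).  Exponential-key sampling is equivalent to
# successive probability-proportional draws without replacement.
null_assemble <- function(occ, ab, richness, total) {
  n <- length(occ)
  keys <- rexp(n) / occ
  drawn <- order(keys)[seq_len(richness)]
  x <- integer(n)
  x[drawn] <- 1L
  if (total > richness)
    x[drawn] <- x[drawn] + rmultinom(1L, total - richness, ab[drawn])[, 1L]
  x
}

rc_from_null <- function(obs, null, eps = 1e-10) {
  2 * ((sum(null < obs - eps) + 0.5 * sum(abs(null - obs) <= eps)) /
         length(null) - 0.5)
}

#' Bray-Curtis-based Raup-Crick index (RC_Bray)
#'
#' For each sample pair, compares the observed Bray-Curtis dissimilarity
#' against dissimilarities between communities probabilistically
#' reassembled from the regional pool: species are drawn without
#' replacement with probability proportional to occupancy until the
#' observed richness is reached, then abundance quanta are assigned with
#' probability proportional to pool relative abundance until the observed
#' total is reached.  With `n_rep` the number of null replicates,
#' `RC = 2 * ((#[null < obs] + 0.5 #[null = obs]) / n_rep - 0.5)`, in
#' `[-1, 1]`.  `RC > 0.95` signals dispersal limitation, `RC < -0.95`
#' homogenising dispersal.
#'
#' @inheritParams bray_curtis
#' @param n_null Number of null replicates (default 999).
#' @param seed Optional integer seed.
#' @param sample_total Fixed per-sample total used to discretise RPKM
#'   values into individuals (see [discretize_rpkm()]); ignored when the
#'   table is already integer counts.
#' @param pool Optional list with elements `occupancy` and `abundance`
#'   (length `nrow(table)`) specifying the regional pool; by default both
#'   are estimated from the table (fraction of samples occupied; mean
#'   within-sample relative abundance).
#' @return Symmetric matrix of RC_Bray values.
#' @export
rc_bray <- function(table, n_null = 999, seed = NULL, sample_total = 1000,
                    pool = NULL) {
  table <- check_abundance_table(table)
  if (ncol(table) < 2L) stop("need at least two samples")
  counts <- if (is.integer(table)) table else discretize_rpkm(table, sample_total)
  richness <- colSums(counts > 0)
  if (any(richness == 0))
    stop("samples with zero richness: ",
         paste(colnames(counts)[richness == 0], collapse = ", "))
  totals <- colSums(counts)
  if (is.null(pool)) {
    occ <- rowMeans(counts > 0)
    ab <- rowMeans(sweep(counts, 2, totals, "/"))
  } else {
    occ <- pool$occupancy
    ab <- pool$abundance
    stopifnot(length(occ) == nrow(counts), length(ab) == nrow(counts))
  }
  n <- ncol(counts)
  obs <- as.matrix(vegan::vegdist(t(counts), method = "bray"))
  lt <- matrix(0, n, n)
  eq <- matrix(0, n, n)
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      nullcomm <- vapply(seq_len(n), function(s)
        null_assemble(occ, ab, richness[s], totals[s]), integer(nrow(counts)))
      nullbc <- as.matrix(vegan::vegdist(t(nullcomm), method = "bray"))
      lt <- lt + (nullbc < obs - 1e-10)
      eq <- eq + (abs(nullbc - obs) <= 1e-10)
    }
  })
  rc <- 2 * ((lt + 0.5 * eq) / n_null - 0.5)
  diag(rc) <- 0
  dimnames(rc) <- dimnames(obs)
  rc
}

#' Classify a sample pair into one of five assembly processes
#'
#' Applies the threshold rules: `bNTI > 2` heterogeneous selection;
#' `bNTI < -2` homogeneous selection; otherwise `|bNTI| < 2` combined with
#' `RC > 0.95` dispersal limitation, `RC < -0.95` homogenising dispersal,
#' `|RC| < 0.95` drift.  All inequalities are strict; a value falling
#' exactly on a threshold drops through to the undominated class, which is
#' labelled `"drift"`.
#'
#' @param bnti,rc Numeric vectors (recycled) of beta-NTI and RC_Bray
#'   values.
#' @return Character vector of process labels; `NA` where `bnti` is `NA`.
#' @examples
#' classify_pair(c(2.5, -2.5, 0, 0, 0), c(0.3, 0.99, 0.97, -0.97, 0))
#' @export
classify_pair <- function(bnti, rc) {
  stopifnot(length(bnti) == length(rc) || length(bnti) == 1L || length(rc) == 1L)
  n <- max(length(bnti), length(rc))
  bnti <- rep_len(bnti, n); rc <- rep_len(rc, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(bnti)
  out[ok & bnti > 2] <- "heterogeneous_selection"
  out[ok & bnti < -2] <- "homogeneous_selection"
  rest <- ok & is.na(out)
  out[rest & abs(bnti) < 2 & rc > 0.95] <- "dispersal_limitation"
  out[rest & abs(bnti) < 2 & rc < -0.95] <- "homogenizing_dispersal"
  out[rest & is.na(out)] <- "drift"
  out
}

assembly_process_levels <- c("heterogeneous_selection", "homogeneous_selection",
                             "dispersal_limitation", "homogenizing_dispersal",
                             "drift")

#' Partition community assembly processes per group
#'
#' Runs [beta_nti()] and [rc_bray()] over a table, classifies every
#' unordered within-group sample pair with [classify_pair()], and reports
#' per-group fractions of the five processes over classified pairs.
#'
#' @inheritParams beta_nti
#' @param metadata Optional data frame with a `sample` column matching the
#'   table's samples.
#' @param group Optional name of a grouping column in `metadata`; when
#'   `NULL` all samples form one group called `"all"`.
#' @param sample_total Passed to [rc_bray()].
#' @return A list with `pairs` (data frame: `sample_i`, `sample_j`,
#'   `group`, `bnti`, `rc_bray`, `process`), `fractions` (data frame of
#'   per-group process fractions over classified pairs, summing to 1), and
#'   `n_undefined` (pairs excluded for degenerate bNTI nulls).
#' @export
partition_assembly <- function(table, tree, metadata = NULL, group = NULL,
                               n_null = 999, seed = NULL, weighted = TRUE,
                               sample_total = 1000) {
  table <- check_abundance_table(table)
  samples <- colnames(table)
  grp <- if (is.null(group)) {
    setNames(rep("all", length(samples)), samples)
  } else {
    stopifnot(!is.null(metadata), group %in% names(metadata))
    setNames(as.character(metadata[[group]]), metadata$sample)[samples]
  }
  sizes <- base::table(grp)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("groups skipped (fewer than 2 samples): ",
            paste(small, collapse = ", "))
  }
  keep_groups <- setdiff(names(sizes), small)

  bnti <- beta_nti(table, tree, n_null = n_null,
                   seed = if (is.null(seed)) NULL else derive_seed(seed, "bnti"),
                   weighted = weighted)
  rc <- rc_bray(table, n_null = n_null,
                seed = if (is.null(seed)) NULL else derive_seed(seed, "rc"),
                sample_total = sample_total)

  rows <- list()
  for (g in keep_groups) {
    s <- samples[grp == g]
    idx <- which(upper.tri(matrix(0, length(s), length(s))), arr.ind = TRUE)
    rows[[g]] <- data.frame(
      sample_i = s[idx[, 1L]], sample_j = s[idx[, 2L]], group = g,
      bnti = bnti[cbind(s[idx[, 1L]], s[idx[, 2L]])],
      rc_bray = rc[cbind(s[idx[, 1L]], s[idx[, 2L]])])
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  pairs$process <- classify_pair(pairs$bnti, pairs$rc_bray)

  classified <- pairs[!is.na(pairs$process), ]
  fr <- do.call(rbind, lapply(split(classified$process, classified$group),
    function(p) {
      tab <- base::table(factor(p, levels = assembly_process_levels))
      as.numeric(tab) / length(p)
    }))
  fractions <- data.frame(group = rownames(fr), fr, row.names = NULL)
  names(fractions)[-1L] <- assembly_process_levels

  list(pairs = pairs, fractions = fractions,
       n_undefined = sum(is.na(pairs$process)))
}
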