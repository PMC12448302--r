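# Community ecology statistics --------------------------------------------
#
# Diversity, dissimilarity, group-difference and distance-decay statistics
# over vOTU x sample relative-abundance (RPKM) tables.  Tables are numeric
# matrices with taxa in rows and samples in columns, both dimensions named.

check_abundance_table <- function(table, require_positive_samples = TRUE) {
  if (!is.matrix(table)) table <- as.matrix(table)
  if (!is.numeric(table)) stop("abundance table must be numeric")
  if (any(table < 0)) stop("abundance table contains negative entries")
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop("abundance table must have taxon row names and sample column names")
  if (anyDuplicated(rownames(table))) stop("duplicate taxon ids")
  if (anyDuplicated(colnames(table))) stop("duplicate sample ids")
  if (require_positive_samples) {
    tot <- colSums(table)
    if (any(tot <= 0))
      stop("samples with zero total abundance: ",
           paste(colnames(table)[tot <= 0], collapse = ", "))
  }
  table
}

#' Bray-Curtis dissimilarity matrix
#'
#' Computes `BC(i, j) = sum |x - y| / sum (x + y)` over taxa for every
#' unordered pair of samples in an abundance table.
#'
#' @param table Numeric matrix, taxa in rows, samples in columns; values are
#'   nonnegative relative abundances (RPKM).
#' @return A symmetric sample-by-sample matrix with zero diagonal and
#'   entries in `[0, 1]`.
#' @examples
#' tab <- cbind(s1 = c(a = 1, b = 0), s2 = c(a = 1, b = 2))
#' bray_curtis(tab)["s1", "s2"]  # 0.5
#' @export
bray_curtis <- function(table) {
  table <- check_abundance_table(table)
  if (ncol(table) < 2L) stop("need at least two samples")
  d <- as.matrix(vegan::vegdist(t(table), method = "bray"))
  diag(d) <- 0
  d
}

#' Shannon and Simpson alpha diversity
#'
#' Per-sample Shannon entropy `H = -sum p log p` (natural log) and
#' Gini-Simpson index `1 - sum p^2`, where `p` are within-sample relative
#' abundances.
#'
#' @inheritParams bray_curtis
#' @return A data frame with columns `sample`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(table) {
  table <- check_abundance_table(table)
  data.frame(
    sample  = colnames(table),
    shannon = vegan::diversity(t(table), index = "shannon"),
    simpson = vegan::diversity(t(table), index = "simpson"),
    row.names = NULL
  )
}

#' Analysis of similarities (ANOSIM)
#'
#' Tests whether between-group dissimilarities exceed within-group
#' dissimilarities, using the rank-based R statistic and a group-label
#' permutation test with the add-one p estimator
#' `p = (1 + #[R_perm >= R_obs]) / (1 + n_perm)`.
#'
#' @param d Symmetric dissimilarity matrix (e.g. from [bray_curtis()]).
#' @param groups Factor or character vector of group labels, one per sample.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @return A list with elements `statistic` (R), `p_value`, and `n_perm`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  if (length(groups) != ncol(d)) stop("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least two groups")
  if (any(sizes < 2L))
    stop("groups with fewer than 2 members: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  fit <- with_seed(seed,
    vegan::anosim(stats::as.dist(d), groups, permutations = n_perm))
  list(statistic = unname(fit$statistic),
       p_value   = unname(fit$signif),
       n_perm    = n_perm)
}

#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the mean Earth
#' radius), vectorised over coordinate pairs.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 1)  # ~111.195 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90), all(abs(c(lon1, lon2)) <= 180))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088 * 1000) / 1000
}

#' Pairwise geographic distances for a metadata table
#'
#' @param metadata Data frame with columns `sample`, `latitude`,
#'   `longitude`.
#' @return Symmetric matrix of great-circle distances in km, with sample
#'   ids as dimnames.
#' @export
pairwise_geo_km <- function(metadata) {
  stopifnot(all(c("sample", "latitude", "longitude") %in% names(metadata)))
  n <- nrow(metadata)
  m <- matrix(0, n, n, dimnames = list(metadata$sample, metadata$sample))
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    m[i, j] <- m[j, i] <- haversine_km(
      metadata$latitude[i], metadata$longitude[i],
      metadata$latitude[j], metadata$longitude[j])
  }
  m
}

#' Distance-decay regression
#'
#' Ordinary least squares regression of pairwise community dissimilarity
#' (or similarity) on a pairwise predictor such as geographic distance or
#' depth difference, over all unordered sample pairs.  The p value is the
#' two-sided t test on the slope.
#'
#' @param d Dissimilarity matrix.
#' @param predictor Matrix of pairwise predictor values with the same
#'   dimensions as `d`, or a vector matching the lower triangle of `d`.
#' @param orientation `"dissimilarity"` (default) regresses `d` itself;
#'   `"similarity"` regresses `1 - d`.  Both orientations are exposed
#'   because decay relationships are reported in either convention.
#' @return A list with `slope`, `intercept`, `r_squared`, `p_value`, and
#'   `n_pairs`.
#' @export
distance_decay <- function(d, predictor,
                           orientation = c("dissimilarity", "similarity")) {
  orientation <- match.arg(orientation)
  d <- as.matrix(d)
  y <- d[lower.tri(d)]
  x <- if (is.matrix(predictor)) {
    stopifnot(all(dim(predictor) == dim(d)))
    predictor[lower.tri(predictor)]
  } else as.numeric(predictor)
  if (length(x) != length(y)) stop("predictor does not match pair count")
  if (length(y) < 3L) stop("need at least 3 pairs")
  if (stats::var(x) == 0) stop("predictor has zero variance")
  if (orientation == "similarity") y <- 1 - y
  fit <- lm(y ~ x)
  s <- summary(fit)
  list(slope     = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = s$r.squared,
       p_value   = unname(s$coefficients[2L, 4L]),
       n_pairs   = length(y))
}

# Exact two-sided p for the rank-sum statistic by full enumeration of all
# choose(n + m, n) assignments of the pooled mid-ranks.  Handles ties.
wilcoxon_enumerate <- function(x, y) {
  r <- rank(c(x, y))
  n <- length(x); m <- length(y)
  w_obs <- sum(r[seq_len(n)])
  idx <- combn(n + m, n)
  w_all <- colSums(matrix(r[idx], nrow = n))
  eps <- 1e-9
  p_le <- mean(w_all <= w_obs + eps)
  p_ge <- mean(w_all >= w_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test with mid-ranks for ties.  Small samples
#' (both sizes at most 20) use exact enumeration (the signed Wilcoxon
#' distribution when there are no ties, full enumeration of rank
#' assignments when there are); larger samples use the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric vectors.
#' @param method `"auto"` (size-based choice), `"exact"`, or `"normal"`.
#' @return A list with `statistic` (the Mann-Whitney U for `x`),
#'   `p_value`, and `method` actually used.
#' @export
wilcoxon_rank_sum <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n)])
  u <- w - n * (n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- switch(method,
    auto   = n <= 20 && m <= 20,
    exact  = TRUE,
    normal = FALSE)
  if (use_exact) {
    if (!ties) {
      p <- min(1, 2 * min(pwilcox(u, n, m), 1 - pwilcox(u - 1, n, m)))
      return(list(statistic = u, p_value = p, method = "exact"))
    }
    if (choose(n + m, n) <= 5e5) {
      return(list(statistic = u, p_value = wilcoxon_enumerate(x, y),
                  method = "exact"))
    }
    # ties and too many assignments to enumerate: fall through
  }
  mu <- n * m / 2
  tie_tab <- table(c(x, y))
  sigma2 <- n * m / 12 *
    ((n + m + 1) - sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p_value = 1, method = "normal"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(statistic = u, p_value = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, with a two-sided p value from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return A list with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("zero rank variance")
  rho <- cor(rx, ry)
  if (abs(rho) >= 1 - 1e-12) return(list(rho = sign(rho), p_value = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * pt(-abs(tstat), df = n - 2))
}
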