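# Seeded community generators ----------------------------------------------
#
# Produce vOTU x sample abundance tables, a matching Yule phylogeny with
# positive branch lengths, and sample metadata under controllable assembly regimes so
# that the null-model machinery can be validated against known ground
# truth:
#   well_mixed                 every sample is an independent multinomial
#                              draw from one regional pool
#   selection_gradient         taxa carry a Brownian (phylogenetically
#                              conserved) trait and samples filter taxa by
#                              an environmental optimum along a gradient
#   dispersal_limited_islands  islands draw from disjoint-biased subsets
#                              of a shared pool
#   rc_null_process            samples are assembled by exactly the
#                              Raup-Crick null procedure of rc_bray()

#' Configuration for a community simulation scenario
#'
#' @param seed Integer root seed; identical seed + configuration
#'   reproduces identical output.
#' @param n_samples Number of samples (>= 2).
#' @param n_taxa Number of taxa (>= 2).
#' @param regime One of `"well_mixed"`, `"selection_gradient"`,
#'   `"dispersal_limited_islands"`, `"rc_null_process"`.
#' @param gradient_strength Positive scalar; larger values sharpen the
#'   environmental filter of the selection regime (default 4).
#' @param n_islands Number of islands for the dispersal regime (default
#'   3); must not exceed `n_samples`.
#' @param island_overlap Probability mass a sample places outside its own
#'   island's taxon subset (default 0, fully disjoint).
#' @param pool_occupancy,pool_abundance Optional regional-pool vectors of
#'   length `n_taxa` for the `rc_null_process` regime; defaults are drawn
#'   from Uniform(0.2, 0.8) occupancy and log-normal abundance.
#' @param sample_total Individuals per sample (default 1000).
#' @param birth_rate Speciation rate of the Yule tree (default 1).
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(seed, n_samples, n_taxa,
                            regime = c("well_mixed", "selection_gradient",
                                       "dispersal_limited_islands",
                                       "rc_null_process"),
                            gradient_strength = 4, n_islands = 3,
                            island_overlap = 0, pool_occupancy = NULL,
                            pool_abundance = NULL, sample_total = 1000,
                            birth_rate = 1) {
  regime <- match.arg(regime)
  stopifnot(n_samples >= 2, n_taxa >= 2, sample_total >= 1,
            birth_rate > 0, gradient_strength > 0,
            island_overlap >= 0, island_overlap < 1)
  if (regime == "dispersal_limited_islands" && n_islands > n_samples)
    stop("n_islands must not exceed n_samples")
  if (n_islands < 1) stop("n_islands must be positive")
  if (!is.null(pool_occupancy))
    stopifnot(length(pool_occupancy) == n_taxa, all(pool_occupancy > 0))
  if (!is.null(pool_abundance))
    stopifnot(length(pool_abundance) == n_taxa, all(pool_abundance > 0))
  structure(list(seed = seed, n_samples = n_samples, n_taxa = n_taxa,
                 regime = regime, gradient_strength = gradient_strength,
                 n_islands = n_islands, island_overlap = island_overlap,
                 pool_occupancy = pool_occupancy,
                 pool_abundance = pool_abundance,
                 sample_total = sample_total, birth_rate = birth_rate),
            class = "scenario_config")
}

simulate_metadata <- function(n_samples) {
  # two trenches at plausible hadal coordinates; depth increases along
  # each trench axis, sediment layers cycle 2-cm steps
  trench <- rep(c("Trench_A", "Trench_B"), length.out = n_samples)
  base <- data.frame(
    trench = c("Trench_A", "Trench_B"),
    lat0 = c(-31.9, -35.2), lon0 = c(-177.3, 104.6),
    depth0 = c(9500, 7600))
  idx <- match(trench, base$trench)
  along <- stats::ave(seq_len(n_samples), trench, FUN = seq_along)
  data.frame(
    sample = sprintf("S%02d", seq_len(n_samples)),
    latitude = base$lat0[idx] + 0.08 * along + rnorm(n_samples, 0, 0.01),
    longitude = base$lon0[idx] + 0.05 * along + rnorm(n_samples, 0, 0.01),
    water_depth_m = base$depth0[idx] + 120 * along +
      round(rnorm(n_samples, 0, 40)),
    layer_cm = 2 * ((along - 1) %% 5 + 1),
    trench = trench)
}

#' Generate a synthetic viral community data set
#'
#' @param config A [scenario_config()] object.
#' @return A list with `table` (taxa x samples abundance matrix), `tree`
#'   (`phylo`), `metadata` (data frame), and regime-specific `truth`
#'   (e.g. island assignments, traits, or the regional pool used).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_samples; nt <- config$n_taxa
  taxa <- sprintf("vOTU_%04d", seq_len(nt))
  samples <- sprintf("S%02d", seq_len(n))

  tree <- with_seed(derive_seed(config$seed, "tree"), {
    tr <- ape::rphylo(nt, birth = config$birth_rate, death = 0)
    tr$tip.label <- taxa
    tr
  })

  pool <- with_seed(derive_seed(config$seed, "pool"), {
    occ <- config$pool_occupancy
    if (is.null(occ)) occ <- runif(nt, 0.2, 0.8)
    ab <- config$pool_abundance
    if (is.null(ab)) ab <- rlnorm(nt, 0, 1)
    list(occupancy = occ, abundance = ab / sum(ab))
  })

  truth <- list(pool = pool)
  table <- with_seed(derive_seed(config$seed, "abundance"), {
    switch(config$regime,
      well_mixed = {
        vapply(seq_len(n), function(s)
          rmultinom(1L, config$sample_total, pool$abundance)[, 1L],
          numeric(nt))
      },
      selection_gradient = {
        trait <- with_seed(derive_seed(config$seed, "trait"),
          ape::rTraitCont(tree, model = "BM", sigma = 1))
        trait <- trait[taxa]
        optima <- seq(min(trait), max(trait), length.out = n)
        width <- sd(trait) / config$gradient_strength
        truth$trait <- trait
        truth$optima <- optima
        vapply(seq_len(n), function(s) {
          w <- pool$abundance * exp(-(trait - optima[s])^2 / (2 * width^2))
          rmultinom(1L, config$sample_total, w)[, 1L]
        }, numeric(nt))
      },
      dispersal_limited_islands = {
        island_of_sample <- rep(seq_len(config$n_islands), length.out = n)
        island_of_taxon <- rep(seq_len(config$n_islands), length.out = nt)
        island_of_taxon <- sample(island_of_taxon)
        truth$island_of_sample <- island_of_sample
        truth$island_of_taxon <- island_of_taxon
        vapply(seq_len(n), function(s) {
          w <- pool$abundance *
            ifelse(island_of_taxon == island_of_sample[s], 1,
                   config$island_overlap)
          rmultinom(1L, config$sample_total, w)[, 1L]
        }, numeric(nt))
      },
      rc_null_process = {
        richness <- pmax(2L, rbinom(n, nt, mean(pool$occupancy)))
        truth$richness <- richness
        vapply(seq_len(n), function(s)
          null_assemble(pool$occupancy, pool$abundance, richness[s],
                        config$sample_total), numeric(nt))
      })
  })
  dimnames(table) <- list(taxa, samples)

  metadata <- with_seed(derive_seed(config$seed, "metadata"),
                        simulate_metadata(n))
  list(table = table, tree = tree, metadata = metadata, truth = truth)
}
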