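# Seed plumbing -----------------------------------------------------------
#
# All generators draw their randomness from one root seed.  Sub-streams are
# derived deterministically by mixing the root seed with a text label
# (derive_seed), so multi-part fixtures (tree + table + metadata, or
# genomes + spacers + pileups) are reproducible independently of the order
# in which parts are generated.  All derived seeds stay in [1, 2^31 - 2].

#' Derive a labelled sub-seed from a root seed
#'
#' Deterministically mixes an integer root seed with a character label to
#' produce a new seed.  Used internally so that the independent random
#' streams of a multi-part simulation (tree, abundances, genomes, pileups)
#' all flow from a single user-visible seed.
#'
#' @param seed Integer root seed.
#' @param label Character scalar naming the stream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "tree")
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label),
            length(label) == 1L)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1048573
  # 2147483647 = 2^31 - 1 (prime); multiplier 48271 is a classic MINSTD root
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  as.integer((s * 48271 + h * 7919 + 12345) %% 2147483646 + 1)
}

# Evaluate expr with a locally-set RNG state; the caller's state is restored
# afterwards.  A NULL seed leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}
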