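# Seeded virus/host genome generators with planted linkage signals ---------
#
# Host genomes are emitted from host-specific random Markov models of
# order `host_markov_order` (default 3).  The order exceeds the order-2
# background model that the d2* statistic centres on, so a viral sequence
# emitted from a host's model shares genuine compositional signal with
# that host after centring, while other hosts (their own models) do not.
# Channel plantings:
#   homology  a long viral segment is copied into the host with 20% of
#             positions substituted (80% identity, gap-free)
#   trna      an identical 75-nt tRNA-like sequence is placed in both
#   crispr    a 25-40 nt spacer is copied (optionally with exactly one
#             mismatch) from the virus into the spacer set of the host
#   onf       the whole viral sequence is emitted from the host's own
#             Markov model

random_markov_model <- function(order, concentration = 0.35) {
  n_states <- 4^order
  tr <- matrix(rgamma(n_states * 4, shape = concentration), n_states, 4)
  tr / rowSums(tr)
}

markov_sequence <- function(model, length) {
  order <- round(log(nrow(model), 4))
  cumtr <- t(apply(model, 1L, cumsum))
  u <- runif(length)
  out <- integer(length)
  state <- sample.int(nrow(model), 1L) - 1L
  base_mod <- 4^(order - 1)
  for (i in seq_len(length)) {
    row <- state + 1L
    b <- 1L + (u[i] > cumtr[row, 1L]) + (u[i] > cumtr[row, 2L]) +
      (u[i] > cumtr[row, 3L])
    out[i] <- b
    state <- (state %% base_mod) * 4 + (b - 1L)
  }
  paste(BASES[out], collapse = "")
}

random_dna <- function(length, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
}

substitute_positions <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1L]]
  for (p in positions) {
    ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Default linkage planting plan
#'
#' Assigns the four evidence channels round-robin over virus-host pairs:
#' viruses `1..(4 * pairs_per_channel)` each get one channel against hosts
#' cycling `1..n_hosts`; remaining viruses stay unplanted (negative
#' controls).
#'
#' @param n_viruses,n_hosts Genome counts.
#' @param pairs_per_channel Planted pairs per channel (default 4).
#' @return Data frame `virus`, `host`, `channel` (integer indices).
#' @export
default_linkage_plan <- function(n_viruses, n_hosts, pairs_per_channel = 4) {
  channels <- c("homology", "trna", "crispr", "onf")
  n_planted <- min(n_viruses, 4 * pairs_per_channel)
  data.frame(virus = seq_len(n_planted),
             host = (seq_len(n_planted) - 1L) %% n_hosts + 1L,
             channel = rep(channels, length.out = n_planted))
}

#' Generate virus and host genomes with planted linkage signals
#'
#' @param seed Integer root seed.
#' @param n_viruses,n_hosts Numbers of viral and host genomes (>= 1).
#' @param planted Data frame with columns `virus`, `host` (integer
#'   indices) and `channel` (one of `homology`, `trna`, `crispr`, `onf`);
#'   defaults to [default_linkage_plan()].
#' @param virus_length,host_length Genome lengths in bp.
#' @param host_markov_order Order of the host-specific background model
#'   (default 3).
#' @param homology_identity Identity of the planted homologous segment
#'   (default 0.8, i.e. substitutions at 20% of positions).
#' @param homology_coverage Fraction of the viral genome copied into the
#'   host (default 0.85).
#' @param crispr_mismatches 0 or 1 planted spacer mismatches (default 0).
#' @return A list with `viruses`, `hosts`, `spacers`, `trnas` (named
#'   `DNAStringSet`s; spacer/tRNA names follow `recordID|genomeID`) and
#'   `truth` (the planted linkage data frame with genome ids).
#' @export
generate_virus_host_genomes <- function(seed, n_viruses = 20, n_hosts = 10,
                                        planted = NULL,
                                        virus_length = 3000,
                                        host_length = 20000,
                                        host_markov_order = 3,
                                        homology_identity = 0.8,
                                        homology_coverage = 0.85,
                                        crispr_mismatches = 0) {
  stopifnot(n_viruses >= 1, n_hosts >= 1,
            crispr_mismatches %in% c(0L, 1L),
            homology_identity > 0.7, homology_identity <= 1,
            homology_coverage > 0.75, homology_coverage <= 1)
  if (is.null(planted)) planted <- default_linkage_plan(n_viruses, n_hosts)
  stopifnot(all(planted$virus >= 1), all(planted$virus <= n_viruses),
            all(planted$host >= 1), all(planted$host <= n_hosts),
            all(planted$channel %in% c("homology", "trna", "crispr", "onf")))
  vids <- sprintf("vOTU_%03d", seq_len(n_viruses))
  hids <- sprintf("MAG_%03d", seq_len(n_hosts))

  models <- with_seed(derive_seed(seed, "host_models"),
    lapply(seq_len(n_hosts), function(i)
      random_markov_model(host_markov_order)))

  hosts <- with_seed(derive_seed(seed, "hosts"),
    vapply(seq_len(n_hosts), function(i)
      markov_sequence(models[[i]], host_length), character(1L)))

  onf_host_of_virus <- rep(NA_integer_, n_viruses)
  oi <- planted$channel == "onf"
  onf_host_of_virus[planted$virus[oi]] <- planted$host[oi]
  viruses <- with_seed(derive_seed(seed, "viruses"),
    vapply(seq_len(n_viruses), function(i) {
      if (!is.na(onf_host_of_virus[i]))
        markov_sequence(models[[onf_host_of_virus[i]]], virus_length)
      else random_dna(virus_length, gc = runif(1L, 0.35, 0.65))
    }, character(1L)))

  spacers <- character(); spacer_names <- character()
  trnas_v <- character(); trnas_v_names <- character()
  trnas_h <- character(); trnas_h_names <- character()

  with_seed(derive_seed(seed, "planting"), {
    for (r in seq_len(nrow(planted))) {
      vi <- planted$virus[r]; hi <- planted$host[r]
      ch <- planted$channel[r]
      if (ch == "homology") {
        seg_len <- ceiling(homology_coverage * virus_length)
        vstart <- sample.int(virus_length - seg_len + 1L, 1L)
        seg <- substr(viruses[vi], vstart, vstart + seg_len - 1L)
        n_mut <- round((1 - homology_identity) * seg_len)
        seg_mut <- substitute_positions(seg,
          sample.int(seg_len, n_mut))
        hstart <- sample.int(host_length - seg_len + 1L, 1L)
        hosts[hi] <- paste0(substr(hosts[hi], 1L, hstart - 1L), seg_mut,
                            substr(hosts[hi], hstart + seg_len, host_length))
      } else if (ch == "trna") {
        t_seq <- random_dna(75, gc = 0.55)
        vpos <- sample.int(nchar(viruses[vi]) - 75L + 1L, 1L)
        viruses[vi] <- paste0(substr(viruses[vi], 1L, vpos - 1L), t_seq,
                              substr(viruses[vi], vpos + 75L,
                                     nchar(viruses[vi])))
        hpos <- sample.int(nchar(hosts[hi]) - 75L + 1L, 1L)
        hosts[hi] <- paste0(substr(hosts[hi], 1L, hpos - 1L), t_seq,
                            substr(hosts[hi], hpos + 75L, nchar(hosts[hi])))
        trnas_v <- c(trnas_v, t_seq)
        trnas_v_names <- c(trnas_v_names,
                           sprintf("trna_v%03d|%s", r, vids[vi]))
        trnas_h <- c(trnas_h, t_seq)
        trnas_h_names <- c(trnas_h_names,
                           sprintf("trna_h%03d|%s", r, hids[hi]))
      } else if (ch == "crispr") {
        sp_len <- sample(25:40, 1L)
        vpos <- sample.int(nchar(viruses[vi]) - sp_len + 1L, 1L)
        sp <- substr(viruses[vi], vpos, vpos + sp_len - 1L)
        if (crispr_mismatches == 1L)
          sp <- substitute_positions(sp, sample.int(sp_len, 1L))
        spacers <- c(spacers, sp)
        spacer_names <- c(spacer_names,
                          sprintf("spacer_%03d|%s", r, hids[hi]))
      }
      # onf handled at virus emission
    }
    # decoy spacers from host backgrounds, attributed truthfully, so the
    # crispr channel has negative controls
    for (hi in seq_len(n_hosts)) {
      sp_len <- sample(25:40, 1L)
      hpos <- sample.int(nchar(hosts[hi]) - sp_len + 1L, 1L)
      spacers <- c(spacers, substr(hosts[hi], hpos, hpos + sp_len - 1L))
      spacer_names <- c(spacer_names,
                        sprintf("spacer_bg%03d|%s", hi, hids[hi]))
    }
  })

  truth <- data.frame(virus = vids[planted$virus], host = hids[planted$host],
                      channel = planted$channel)
  list(
    viruses = setNames(Biostrings::DNAStringSet(viruses), vids),
    hosts = setNames(Biostrings::DNAStringSet(hosts), hids),
    spacers = setNames(Biostrings::DNAStringSet(spacers), spacer_names),
    trnas_viral = setNames(Biostrings::DNAStringSet(trnas_v), trnas_v_names),
    trnas_host = setNames(Biostrings::DNAStringSet(trnas_h), trnas_h_names),
    truth = truth)
}
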