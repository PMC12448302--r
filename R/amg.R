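# Curation of candidate auxiliary metabolic genes (AMGs) and viral
# lifestyle calls over annotated viral genomes --------------------------------

amg_denylist <- c("nucleotide metabolism", "DNA-related reactions",
                  "modification of viral components", "ribosomal proteins",
                  "transcriptional/translational regulators", "viral invasion")

#' Built-in denylist of invalid AMG categories
#'
#' Functional categories that disqualify a candidate AMG: genes in
#' nucleotide metabolism, DNA-related reactions, modification of viral
#' components, ribosomal proteins, transcriptional/translational
#' regulators, and viral invasion are core viral housekeeping rather than
#' host metabolism.
#'
#' @return Character vector of category labels.
#' @export
amg_denylist_categories <- function() amg_denylist

#' Curate candidate AMGs
#'
#' Applies the retention filters to a table of annotated genes.  A
#' candidate AMG is retained iff:
#' bit score >= 60; auxiliary score <= 3; its function is not on the
#' denylist; at least two viral-like genes sit among its two nearest
#' neighbours on each side (counted jointly over the window of up to four
#' genes); and it is NOT both within `end_window` bp of a contig end and
#' adjacent (immediate neighbour, or overlapping a listed repeat) to a
#' tRNA gene or inverted/direct repeat.
#'
#' @param genes Data frame of annotated genes ordered by position within
#'   each contig, with columns `contig`, `gene_id`, `start`, `end`,
#'   `strand`, `is_viral_like`, `is_candidate_amg`, `is_trna`,
#'   `function_id`, `bit_score`, `auxiliary_score`, `denylist_category`
#'   (`NA`/`"none"` when clean).
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @param repeats Optional data frame of repeat features with columns
#'   `contig`, `start`, `end`.
#' @param end_window Distance from a contig end (bp) within which the
#'   tRNA/repeat adjacency filter applies (default 5000).
#' @param min_flanking Minimum viral-like genes required in the
#'   neighbour window (default 2).
#' @return Data frame of retained AMGs (`gene_id`, `contig`,
#'   `function_id`) with a `passed_filters` column listing the filters
#'   each retained gene passed.
#' @export
curate_amgs <- function(genes, contig_lengths, repeats = NULL,
                        end_window = 5000, min_flanking = 2) {
  need <- c("contig", "gene_id", "start", "end", "is_viral_like",
            "is_candidate_amg", "is_trna", "function_id", "bit_score",
            "auxiliary_score", "denylist_category")
  if (!all(need %in% names(genes)))
    stop("gene table missing columns: ",
         paste(setdiff(need, names(genes)), collapse = ", "))
  dl <- genes$denylist_category
  dl[is.na(dl) | dl == ""] <- "none"
  unknown <- setdiff(unique(dl), c("none", amg_denylist))
  if (length(unknown))
    stop("unknown denylist label(s): ", paste(unknown, collapse = ", "))
  genes$denylist_category <- dl

  out <- list()
  for (ctg in unique(genes$contig)) {
    g <- genes[genes$contig == ctg, ]
    if (is.unsorted(g$start)) stop("genes not ordered by position on ", ctg)
    if (!ctg %in% names(contig_lengths))
      stop("missing length for contig ", ctg)
    len <- contig_lengths[[ctg]]
    n <- nrow(g)
    for (i in which(g$is_candidate_amg)) {
      passed <- character()
      if (!(g$bit_score[i] >= 60)) next
      passed <- c(passed, "bit_score")
      if (!(g$auxiliary_score[i] <= 3)) next
      passed <- c(passed, "auxiliary_score")
      if (g$denylist_category[i] != "none") next
      passed <- c(passed, "denylist")
      nbr <- setdiff(c(i - 2L, i - 1L, i + 1L, i + 2L), c(0L, -1L))
      nbr <- nbr[nbr >= 1L & nbr <= n]
      if (sum(g$is_viral_like[nbr]) < min_flanking) next
      passed <- c(passed, "flanking_viral_genes")
      near_end <- g$start[i] <= end_window || g$end[i] >= len - end_window + 1
      if (near_end) {
        adj <- setdiff(c(i - 1L, i + 1L), c(0L))
        adj <- adj[adj >= 1L & adj <= n]
        near_trna <- any(g$is_trna[adj])
        near_repeat <- FALSE
        if (!is.null(repeats)) {
          rp <- repeats[repeats$contig == ctg, , drop = FALSE]
          if (nrow(rp))
            near_repeat <- any(rp$start <= g$end[i] + end_window &
                                 rp$end >= g$start[i] - end_window)
        }
        if (near_trna || near_repeat) next
      }
      passed <- c(passed, "genome_end")
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g$gene_id[i], contig = ctg,
        function_id = g$function_id[i],
        passed_filters = paste(passed, collapse = ","))
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), contig = character(),
                      function_id = character(), passed_filters = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify viral lifestyle from lysogeny markers
#'
#' A contig is `temperate` when it carries any lysogeny-marker gene
#' (integrases, recombinases, transposases, excisionases, CI/Cro
#' repressors, parAB) or was flagged as a provirus; otherwise `lytic` if
#' upstream tools called it lytic; otherwise `unknown`.
#'
#' @param genes Data frame with columns `contig` and `is_lysogeny_marker`.
#' @param provirus Named logical vector (contig ids) of provirus flags.
#' @param upstream_lytic Named logical vector (contig ids): `TRUE` when an
#'   upstream identification tool called the contig lytic.
#' @return Data frame `contig`, `lifestyle`.
#' @export
classify_lifestyle <- function(genes, provirus = NULL, upstream_lytic = NULL) {
  contigs <- unique(genes$contig)
  marker <- vapply(contigs, function(ctg)
    any(genes$is_lysogeny_marker[genes$contig == ctg]), logical(1L))
  pv <- if (is.null(provirus)) setNames(rep(FALSE, length(contigs)), contigs)
        else provirus
  lyt <- if (is.null(upstream_lytic))
    setNames(rep(FALSE, length(contigs)), contigs) else upstream_lytic
  lifestyle <- ifelse(marker | (contigs %in% names(pv)[pv]), "temperate",
                      ifelse(contigs %in% names(lyt)[lyt], "lytic", "unknown"))
  data.frame(contig = contigs, lifestyle = lifestyle, row.names = NULL)
}

#' AMG relative abundance per function and sample
#'
#' The abundance of a function in a sample is the summed RPKM of the
#' vOTUs that carry at least one retained AMG of that function; a vOTU
#' contributes once per function regardless of copy number.
#'
#' @param amgs Data frame of retained AMGs (from [curate_amgs()]) with
#'   columns `contig`, `function_id`.
#' @param table vOTU abundance matrix (rows = vOTUs, columns = samples).
#' @param votu_map Optional named character vector mapping contig ids to
#'   vOTU ids (default: contig id == vOTU id).
#' @return Function-by-sample abundance matrix.
#' @export
amg_abundance <- function(amgs, table, votu_map = NULL) {
  table <- check_abundance_table(table, require_positive_samples = FALSE)
  votus <- if (is.null(votu_map)) setNames(amgs$contig, amgs$contig)
           else votu_map
  mapped <- unname(votus[amgs$contig])
  bad <- unique(amgs$contig[is.na(mapped) | !(mapped %in% rownames(table))])
  if (length(bad))
    stop("contigs not mapped to vOTUs in the table: ",
         paste(bad, collapse = ", "))
  funs <- sort(unique(amgs$function_id))
  out <- matrix(0, length(funs), ncol(table),
                dimnames = list(funs, colnames(table)))
  for (f in funs) {
    carriers <- unique(mapped[amgs$function_id == f])
    out[f, ] <- colSums(table[carriers, , drop = FALSE])
  }
  out
}

#' Demonstration contig for the AMG curation filters
#'
#' A hand-constructed annotated contig carrying seven candidate AMGs, of
#' which exactly three are designed to survive [curate_amgs()] with
#' default settings: one mid-contig candidate flanked by viral-like genes
#' on both sides, one with exactly the minimum two viral-like neighbours,
#' and one near a contig end but with no adjacent tRNA or repeat.  The
#' four designed failures violate, respectively, the auxiliary-score
#' ceiling, the denylist, the flanking-gene minimum, and the
#' genome-end/tRNA-adjacency rule.
#'
#' @return A list with `genes` (annotation data frame), `contig_lengths`,
#'   and `expected_survivors` (the three gene ids designed to pass).
#' @export
amg_demo_contig <- function() {
  path <- system.file("extdata", "amg_demo_genes.tsv",
                      package = "hadalvirome", mustWork = TRUE)
  genes <- read.delim(path, stringsAsFactors = FALSE)
  genes$denylist_category[genes$denylist_category == "none"] <- NA
  list(genes = genes,
       contig_lengths = c(ctg_demo = 58000),
       expected_survivors = c("g01", "g04", "g12"))
}
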