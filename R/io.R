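# Plain-text readers and writers for the pipeline's tabular formats --------
#
# Abundance TSV: first column vOTU id, remaining columns one per sample.
# Metadata TSV: sample, latitude, longitude, water_depth_m, layer_cm,
# trench.  Pileup TSV: contig, pos (1-based), ref, nA, nC, nG, nT.
# Gene-model TSV: contig, gene_id, start, end, strand (1-based inclusive).
# Hit TSV: the standard 12 BLAST outfmt-6 columns plus qlen.

#' Read / write a vOTU abundance table
#'
#' @param path TSV path.  First column holds vOTU ids; remaining columns
#'   are samples (RPKM values).
#' @return Numeric matrix, taxa in rows.
#' @export
read_abundance_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  check_abundance_table(m, require_positive_samples = FALSE)
}

#' @rdname read_abundance_table
#' @param table Abundance matrix.
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(vOTU = rownames(table), table, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample`, `latitude`, `longitude`,
#'   `water_depth_m`, `layer_cm`, and optionally `trench`.
#' @return Data frame; coordinate and depth sanity checks applied.
#' @export
read_sample_metadata <- function(path) {
  md <- read.delim(path)
  need <- c("sample", "latitude", "longitude", "water_depth_m", "layer_cm")
  if (!all(need %in% names(md)))
    stop("metadata missing columns: ",
         paste(setdiff(need, names(md)), collapse = ", "))
  stopifnot(all(abs(md$latitude) <= 90), all(abs(md$longitude) <= 180),
            all(md$water_depth_m > 0))
  md
}

#' Read a per-site pileup profile
#'
#' @param path TSV with columns `contig`, `pos`, `ref`, `nA`, `nC`, `nG`,
#'   `nT`.
#' @return Data frame.
#' @export
read_pileup <- function(path) {
  p <- read.delim(path)
  need <- c("contig", "pos", "ref", "nA", "nC", "nG", "nT")
  if (!all(need %in% names(p)))
    stop("pileup missing columns: ",
         paste(setdiff(need, names(p)), collapse = ", "))
  stopifnot(!anyDuplicated(p[c("contig", "pos")]),
            all(p[c("nA", "nC", "nG", "nT")] >= 0))
  p
}

#' Read gene models
#'
#' @param path TSV with columns `contig`, `gene_id`, `start`, `end`,
#'   `strand` (1-based inclusive).
#' @return Data frame.
#' @export
read_gene_models <- function(path) {
  g <- read.delim(path)
  need <- c("contig", "gene_id", "start", "end", "strand")
  if (!all(need %in% names(g)))
    stop("gene models missing columns: ",
         paste(setdiff(need, names(g)), collapse = ", "))
  stopifnot(all(g$start <= g$end), all(g$strand %in% c("+", "-")))
  g
}

#' Read a BLAST-like hit table (12 standard columns plus query length)
#'
#' @param path TSV without header, columns: qseqid, sseqid, pident,
#'   length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#'   bitscore, qlen.
#' @return Data frame with named columns and a derived `coverage`
#'   column (aligned query bp / query length).
#' @export
read_blast_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore", "qlen")
  h <- read.delim(path, header = FALSE)
  if (ncol(h) != length(cols))
    stop("expected ", length(cols), " columns, found ", ncol(h))
  names(h) <- cols
  h$coverage <- (abs(h$qend - h$qstart) + 1) / h$qlen
  h
}

#' Read a host taxonomy table
#'
#' @param path TSV with columns `host`, `phylum`.
#' @return Data frame.
#' @export
read_taxonomy <- function(path) {
  t <- read.delim(path)
  if (!all(c("host", "phylum") %in% names(t)))
    stop("taxonomy needs columns host, phylum")
  t
}

#' Write sequences to FASTA
#'
#' @param seqs Named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
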