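#' Built-in exact protein search
#'
#' Desk-scale replacement for an external aligner: Smith-Waterman local
#' alignment of every query against every database protein (BLOSUM62,
#' affine gaps, open 11 / extend 1), converted to percent identity
#' (identities / alignment columns) and query coverage (aligned query span /
#' query length), then filtered with the same contract as
#' [load_tabular_hits()]. Deterministic; intended for inputs up to a few
#' thousand proteins.
#'
#' Bit scores use the gapped BLOSUM62 Karlin-Altschul parameters
#' (lambda 0.267, K 0.041) and e-values the m*n search-space product.
#'
#' @param queries named character vector (query id -> sequence) or a
#'   data.frame with `query_id` and `sequence`.
#' @param db named character vector (gene id -> sequence) or a protein-db
#'   data.frame ([build_protein_db()]); names/`gene_id` become subject ids.
#' @param min_qcov,min_pid filtering thresholds in percent.
#' @return hit data.frame in the [load_tabular_hits()] layout.
#' @export
builtin_search <- function(queries, db, min_qcov = 70, min_pid = 35) {
  queries <- as_seq_vector(queries, c("query_id", "sequence"))
  db <- as_seq_vector(db, c("gene_id", "sequence"))
  if (!length(queries) || !length(db)) return(empty_hits())
  subj_set <- Biostrings::AAStringSet(db)
  db_res <- sum(nchar(db))
  out <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    qlen <- nchar(q)
    aln <- Biostrings::pairwiseAlignment(
      pattern = subj_set, subject = Biostrings::AAString(q),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    raw <- Biostrings::score(aln)
    cols <- Biostrings::nchar(aln)
    ident <- 100 * Biostrings::nmatch(aln) / cols
    qs <- Biostrings::start(Biostrings::subject(aln))
    qe <- Biostrings::end(Biostrings::subject(aln))
    qcov <- 100 * (qe - qs + 1) / qlen
    bits <- (0.267 * raw - log(0.041)) / log(2)
    ev <- qlen * db_res * 2^(-bits)
    keep <- raw > 0 & cols > 0
    out[[i]] <- data.frame(
      query_id = names(queries)[i], subject_id = names(db),
      pct_identity = ident, query_cover = qcov, evalue = ev,
      bit_score = bits,
      q_start = qs, q_end = qe,
      s_start = Biostrings::start(Biostrings::pattern(aln)),
      s_end = Biostrings::end(Biostrings::pattern(aln)),
      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  filter_hits(do.call(rbind, out), min_qcov, min_pid)
}

as_seq_vector <- function(x, cols) {
  if (is.data.frame(x)) return(stats::setNames(x[[cols[2]]], x[[cols[1]]]))
  if (is.null(names(x)) && length(x)) stop("sequences must be named")
  x
}

#' Serialize hits to BLAST 12-column tabular format
#'
#' Writes `qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore qcovhsp` (13 columns, i.e. outfmt 6 plus per-HSP
#' query coverage). Round-trips through [load_tabular_hits()].
#'
#' @param hits hit data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  aln_len <- abs(hits$q_end - hits$q_start) + 1
  mism <- round(aln_len * (1 - hits$pct_identity / 100))
  tb <- data.frame(hits$query_id, hits$subject_id,
                   sprintf("%.3f", hits$pct_identity), aln_len, mism, 0L,
                   hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                   format(hits$evalue, digits = 3),
                   sprintf("%.1f", hits$bit_score),
                   sprintf("%.3f", hits$query_cover))
  utils::write.table(tb, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
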