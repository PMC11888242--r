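#' Build the searchable protein database with genomic-context headers
#'
#' Every gene becomes one FASTA entry whose header encodes the genomic
#' context as pipe-delimited fields
#' `genome|contig|start|end|strand|locus|product` (coordinates 1-based
#' inclusive, strand `+`/`-`). Pipe characters inside free-text fields are
#' replaced by `_` so the header always round-trips. Entries are ordered by
#' (genome, contig, start).
#'
#' @param contigs list of `gator_contig`.
#' @param fasta_path optional path; when given the FASTA file is written.
#' @return data.frame with columns `header`, `gene_id`, `sequence` plus the
#'   context fields.
#' @export
build_protein_db <- function(contigs, fasta_path = NULL) {
  idx <- contig_index(contigs)
  g <- all_genes(contigs)
  if (is.null(g) || !nrow(g)) {
    db <- data.frame(header = character(), gene_id = character(),
                     genome_id = character(), contig_id = character(),
                     start = integer(), end = integer(), strand = integer(),
                     locus_tag = character(), product = character(),
                     sequence = character(), stringsAsFactors = FALSE)
  } else {
    genome_id <- unname(idx[g$contig_id])
    locus <- sanitize_field(g$locus_tag)
    prod <- sanitize_field(g$product)
    if (any(grepl("\\|", c(g$locus_tag, g$product))))
      message("pipe characters in locus/product sanitized to '_' in headers")
    db <- data.frame(
      header = sprintf("%s|%s|%d|%d|%s|%s|%s",
                       sanitize_field(genome_id), sanitize_field(g$contig_id),
                       g$start + 1L, g$end,
                       ifelse(g$strand > 0, "+", "-"), locus, prod),
      gene_id = g$gene_id, genome_id = genome_id, contig_id = g$contig_id,
      start = g$start, end = g$end, strand = g$strand,
      locus_tag = locus, product = prod, sequence = g$protein_seq,
      stringsAsFactors = FALSE)
    db <- db[order(db$genome_id, db$contig_id, db$start), , drop = FALSE]
    rownames(db) <- NULL
  }
  if (!is.null(fasta_path)) {
    dir.create(dirname(fasta_path), recursive = TRUE, showWarnings = FALSE)
    write_fasta(stats::setNames(db$sequence, db$header), fasta_path)
  }
  db
}

sanitize_field <- function(x) gsub("\\|", "_", x)

#' Parse a protein-database header back into its context fields
#'
#' Inverse of the header grammar used by [build_protein_db()].
#'
#' @param header character vector of headers.
#' @return data.frame with `genome_id`, `contig_id`, `start` (0-based),
#'   `end`, `strand`, `locus_tag`, `product`.
#' @export
parse_db_header <- function(header) {
  parts <- strsplit(header, "|", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 7L
  if (any(bad)) stop("malformed protein-db header: ", header[bad][1])
  m <- do.call(rbind, lapply(parts, function(p)
    c(p[1:6], paste(p[-(1:6)], collapse = "|"))))
  data.frame(genome_id = m[, 1], contig_id = m[, 2],
             start = as.integer(m[, 3]) - 1L, end = as.integer(m[, 4]),
             strand = ifelse(m[, 5] == "+", 1L, -1L),
             locus_tag = m[, 6], product = m[, 7], stringsAsFactors = FALSE)
}

#' @rdname read_fasta
#' @param x named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    writeLines(substring(s, seq(1, nchar(s), width),
                         pmin(seq(width, nchar(s) + width - 1, width), nchar(s))),
               con)
  }
  invisible(path)
}

#' Read/write protein FASTA
#'
#' Thin wrappers over [Biostrings::readAAStringSet()] returning/accepting
#' plain named character vectors, which the rest of the package uses.
#'
#' @return `read_fasta()`: named character vector (full headers as names).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}
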