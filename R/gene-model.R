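#' Internal gene table
#'
#' Genes are held as a data.frame with one row per CDS. Coordinates are
#' 0-based half-open internally; all file I/O converts to/from the GenBank
#' 1-based inclusive convention.
#'
#' Columns: `gene_id` (opaque, unique within a run), `contig_id`, `start`,
#' `end`, `strand` (+1/-1), `locus_tag`, `product`, `protein_seq`,
#' `contig_edge` (logical).
#'
#' @param gene_id,contig_id,start,end,strand,locus_tag,product,protein_seq,contig_edge
#'   vectors of equal length (scalars recycled).
#' @return data.frame of class `gator_genes`.
#' @export
gene_table <- function(gene_id = character(), contig_id = character(),
                       start = integer(), end = integer(), strand = integer(),
                       locus_tag = "", product = "", protein_seq = character(),
                       contig_edge = FALSE) {
  n <- length(gene_id)
  rec <- function(x) if (length(x) == 1L && n != 1L) rep(x, n) else x
  locus_tag <- rec(locus_tag); product <- rec(product)
  contig_edge <- rec(contig_edge)
  df <- data.frame(
    gene_id = as.character(gene_id),
    contig_id = as.character(contig_id),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.integer(strand),
    locus_tag = as.character(locus_tag),
    product = as.character(product),
    protein_seq = as.character(protein_seq),
    contig_edge = as.logical(contig_edge),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    stopifnot(all(df$start >= 0L), all(df$start < df$end),
              all(df$strand %in% c(1L, -1L)))
    if (anyDuplicated(df$gene_id)) stop("gene_id values must be unique")
  }
  class(df) <- c("gator_genes", "data.frame")
  df
}

#' Construct a contig
#'
#' A contig bundles an ordered gene table with its identifier, length and
#' (optionally) nucleotide sequence. Genes are sorted by start position.
#'
#' @param contig_id contig identifier.
#' @param length contig length in bp.
#' @param genome_id identifier of the genome the contig belongs to.
#' @param genes a gene table (see [gene_table()]).
#' @param seq contig nucleotide sequence as a single string, or `NA`.
#' @return list of class `gator_contig`.
#' @export
contig <- function(contig_id, length, genome_id, genes = gene_table(),
                   seq = NA_character_) {
  length <- as.integer(length)
  if (nrow(genes)) {
    if (any(genes$end > length))
      stop("gene coordinates exceed contig length on ", contig_id)
    genes <- genes[order(genes$start, genes$end), , drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(list(contig_id = as.character(contig_id), length = length,
                 genome_id = as.character(genome_id), genes = genes,
                 seq = seq),
            class = "gator_contig")
}

#' @export
print.gator_contig <- function(x, ...) {
  cat(sprintf("<contig %s (%s): %d bp, %d genes>\n",
              x$contig_id, x$genome_id, x$length, nrow(x$genes)))
  invisible(x)
}

#' Flag genes near contig edges
#'
#' Marks every gene lying within `edge_bp` of either contig end, signalling
#' possible truncation of a cluster by an assembly break.
#'
#' @param contigs list of `gator_contig`.
#' @param edge_bp distance threshold in bp (default 500).
#' @return the contig list with `contig_edge` updated on every gene.
#' @export
flag_contig_edges <- function(contigs, edge_bp = 500L) {
  stopifnot(edge_bp >= 0)
  lapply(contigs, function(ct) {
    g <- ct$genes
    if (nrow(g))
      ct$genes$contig_edge <- g$start < edge_bp | (ct$length - g$end) < edge_bp
    ct
  })
}

# Pool all genes of a contig list into one gene table.
all_genes <- function(contigs) {
  do.call(rbind, c(lapply(unname(contigs), function(ct) ct$genes),
                   list(make.row.names = FALSE)))
}

# genome_id lookup: named vector contig_id -> genome_id
contig_index <- function(contigs) {
  stats::setNames(vapply(contigs, function(ct) ct$genome_id, ""),
                  vapply(contigs, function(ct) ct$contig_id, ""))
}
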