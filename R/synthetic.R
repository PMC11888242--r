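#' Specification of a synthetic planted-cluster dataset
#'
#' Describes a deterministic set of synthetic genomes carrying copies of one
#' cluster template: an ordered run of required-query genes, optional-query
#' genes and filler genes with fixed intergenic gaps (drawn once from
#' `gap_range`). Each genome carries one or more loci; a locus is one of
#'
#' * `exact` - a byte-identical duplicate of the template layout,
#' * `dropout` - the template minus one gene (`drop` = template gene id),
#' * `decoy` - the template minus the first required gene (never a window),
#' * `replace` - one gene's protein replaced by an unrelated sequence
#'   (`replace` = template gene id),
#' * `mutated` - every protein point-mutated to `identity` percent.
#'
#' A locus with `at_edge = TRUE` is placed within 500 bp of the contig
#' start, producing contig-edge-flagged genes. Loci on one contig are
#' separated by more than the default chaining distance so each yields its
#' own window; unrelated noise genes are placed on a second contig.
#'
#' @param n_genomes number of genomes.
#' @param n_required,n_optional,n_filler cluster template composition.
#' @param protein_len min/max filler and query protein length (aa).
#' @param gap_range min/max intergenic gap within the template (bp).
#' @param margin bp of bare sequence flanking each locus (> the contig-edge
#'   distance, < the window extension so flanks stay empty).
#' @param locus_gap bp between loci on one contig (> default chaining
#'   distance + two window extensions).
#' @param loci list (length `n_genomes`) of lists of locus descriptors
#'   (`list(type =, drop =, replace =, identity =, at_edge =, contig =)`);
#'   `NULL` plants one exact copy per genome.
#' @param n_noise unrelated genes placed on the noise contig.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(n_genomes = 5, n_required = 2, n_optional = 1,
                       n_filler = 3, protein_len = c(60, 110),
                       gap_range = c(200, 2000), margin = 3000,
                       locus_gap = 110000, loci = NULL, n_noise = 2,
                       seed = 1) {
  if (is.null(loci))
    loci <- rep(list(list(list(type = "exact"))), n_genomes)
  if (length(loci) != n_genomes) stop("loci must have one entry per genome")
  structure(list(n_genomes = n_genomes, n_required = n_required,
                 n_optional = n_optional, n_filler = n_filler,
                 protein_len = protein_len, gap_range = gap_range,
                 margin = margin, locus_gap = locus_gap, loci = loci,
                 n_noise = n_noise, seed = as.integer(seed)),
            class = "plant_spec")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len_range) {
  n <- sample(len_range[1]:len_range[2], 1)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# One fixed codon per amino acid under the bacterial code.
codon_map <- function() {
  gc <- Biostrings::getGeneticCode("11")
  gc <- gc[order(names(gc))]
  tapply(names(gc), gc, `[`, 1)
}

reverse_translate <- function(aa, cmap) {
  paste0(paste(cmap[strsplit(aa, "")[[1]]], collapse = ""), "TAA")
}

#' Point-mutate a protein to a target global identity
#'
#' Substitutes `round((1 - target/100) * L)` positions with different
#' residues, then verifies by global alignment that the achieved identity is
#' within two percentage points of the target; sequences too short to reach
#' the target that closely raise an error.
#'
#' @param seq amino-acid string.
#' @param target_identity percent in (0, 100].
#' @param seed optional seed (RNG state is restored on exit).
#' @return mutated sequence.
#' @export
mutate_protein <- function(seq, target_identity, seed = NULL) {
  stopifnot(target_identity > 0, target_identity <= 100)
  if (target_identity == 100) return(seq)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old))
    set.seed(seed)
  }
  L <- nchar(seq)
  k <- round((1 - target_identity / 100) * L)
  achieved <- 100 * (L - k) / L
  if (abs(achieved - target_identity) > 2)
    stop("target identity ", target_identity,
         "% unreachable within 2 points on a ", L, "-aa sequence")
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(L, k)
  chars[pos] <- vapply(chars[pos],
                       function(a) sample(setdiff(AA20, a), 1), "")
  out <- paste(chars, collapse = "")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(out), Biostrings::AAString(seq), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  meas <- 100 * Biostrings::nmatch(aln) / max(L, Biostrings::nchar(aln))
  if (abs(meas - target_identity) > 2)
    stop("mutated sequence measured at ", round(meas, 1),
         "% identity; target ", target_identity, "% missed")
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Generate synthetic genomes with planted clusters and ground truth
#'
#' Builds the dataset described by a [plant_spec()]: contigs with real
#' nucleotide sequence (proteins reverse-translated with the bacterial
#' code), the required/optional query set (the planted proteins
#' themselves), and truth tables listing every planted window, its expected
#' gene content under the default homology thresholds, expected duplicate
#' groups and expected per-gene conservation. Deterministic under the
#' spec's seed; the caller's RNG state is untouched.
#'
#' @param spec a [plant_spec()].
#' @param out_dir optional directory: genomes are written as GenBank files
#'   plus `truth_windows.tsv`, `truth_conservation.tsv` and query FASTAs.
#' @return list: `contigs`, `queries` (data.frame), `truth` (list with
#'   `windows`, `conservation`, `n_dedup_groups`, `clusters`), `spec`.
#' @export
generate_synthetic <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "plant_spec"))
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(spec$seed)
  cmap <- codon_map()

  req_ids <- sprintf("req%d", seq_len(spec$n_required))
  opt_ids <- if (spec$n_optional) sprintf("opt%d", seq_len(spec$n_optional)) else character()
  fil_ids <- if (spec$n_filler) sprintf("fil%d", seq_len(spec$n_filler)) else character()
  # template order: required genes interleaved with fillers, optionals, rest
  tmpl_ids <- character()
  fi <- 1L
  for (r in req_ids) {
    tmpl_ids <- c(tmpl_ids, r)
    if (fi <= spec$n_filler) { tmpl_ids <- c(tmpl_ids, fil_ids[fi]); fi <- fi + 1L }
  }
  tmpl_ids <- c(tmpl_ids, opt_ids, if (fi <= spec$n_filler) fil_ids[fi:spec$n_filler])
  tmpl_seq <- stats::setNames(
    vapply(tmpl_ids, function(i) random_protein(spec$protein_len), ""), tmpl_ids)
  tmpl_gap <- if (length(tmpl_ids) > 1)
    round(stats::runif(length(tmpl_ids) - 1, spec$gap_range[1], spec$gap_range[2]))
  else integer()

  queries <- data.frame(
    query_id = c(req_ids, opt_ids),
    sequence = unname(tmpl_seq[c(req_ids, opt_ids)]),
    role = c(rep("required", length(req_ids)), rep("optional", length(opt_ids))),
    stringsAsFactors = FALSE)

  contigs <- list(); truth_rows <- list(); clusters <- list()
  for (gi in seq_len(spec$n_genomes)) {
    genome_id <- sprintf("syng%02d", gi)
    built <- build_genome(spec, gi, genome_id, tmpl_ids, tmpl_seq, tmpl_gap,
                          req_ids, cmap)
    contigs <- c(contigs, built$contigs)
    truth_rows <- c(truth_rows, built$truth)
    clusters <- c(clusters, built$clusters)
  }
  truth_windows <- do.call(rbind, truth_rows)
  valid <- truth_windows[truth_windows$is_window, , drop = FALSE]
  conservation <- vapply(tmpl_ids, function(id)
    mean(vapply(strsplit(valid$present, ","), function(p) id %in% p, TRUE)),
    0)
  truth <- list(windows = truth_windows, conservation = conservation,
                n_dedup_groups = length(unique(valid$signature)),
                clusters = clusters, template_ids = tmpl_ids,
                template_gaps = tmpl_gap)
  contigs <- flag_contig_edges(contigs)
  res <- list(contigs = contigs, queries = queries, truth = truth, spec = spec)
  if (!is.null(out_dir)) write_synthetic(res, out_dir)
  res
}

build_genome <- function(spec, gi, genome_id, tmpl_ids, tmpl_seq, tmpl_gap,
                         req_ids, cmap) {
  loci <- spec$loci[[gi]]
  parts <- list(); genes <- list(); truth <- list(); clusters <- list()
  pos <- 0L; k <- 0L
  append_gene <- function(id, aa, strand, at) {
    nt <- reverse_translate(aa, cmap)
    if (strand < 0)
      nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    list(nt = nt, start = at, end = at + nchar(nt), id = id, aa = aa,
         strand = strand)
  }
  for (li in seq_along(loci)) {
    loc <- loci[[li]]
    loc_type <- loc$type %||% "exact"
    lead <- if (isTRUE(loc$at_edge) && li == 1L) 100L else
      if (li == 1L) spec$margin else spec$locus_gap
    pos <- pos + lead
    ids <- tmpl_ids
    seqs <- tmpl_seq
    dropped <- character()
    if (loc_type == "dropout") {
      if (is.null(loc$drop) || !(loc$drop %in% ids))
        stop("dropout locus must name a template gene to drop")
      dropped <- loc$drop
    } else if (loc_type == "decoy") {
      dropped <- loc$drop %||% req_ids[1]
    } else if (loc_type == "replace") {
      if (is.null(loc$replace) || !(loc$replace %in% ids))
        stop("replace locus must name a template gene")
      seqs[loc$replace] <- random_protein(spec$protein_len)
    } else if (loc_type == "mutated") {
      seqs[] <- vapply(seqs, mutate_protein,
                       target_identity = loc$identity %||% 50, "")
    } else if (loc_type != "exact") stop("unknown locus type: ", loc_type)
    keep <- !(ids %in% dropped)
    loc_start <- pos
    coords <- list()
    for (t in seq_along(ids)) {
      if (keep[t]) {
        k <- k + 1L
        ge <- append_gene(sprintf("%s_g%03d_%s", genome_id, k, ids[t]),
                          seqs[[t]],
                          if (startsWith(ids[t], "fil")) -1L else 1L, pos)
        parts[[length(parts) + 1L]] <- list(at = pos, nt = ge$nt)
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = ge$id, tmpl = ids[t], start = ge$start, end = ge$end,
          strand = ge$strand, aa = ge$aa, stringsAsFactors = FALSE)
        coords[[length(coords) + 1L]] <- data.frame(start = ge$start,
                                                    end = ge$end)
        pos <- ge$end
      }
      if (t < length(ids)) pos <- pos + tmpl_gap[t]   # gap kept on dropout? no:
      if (t < length(ids) && !keep[t]) pos <- pos - tmpl_gap[t]
    }
    present <- ids[keep]
    sig_extra <- character()
    if (loc_type == "replace") {
      present <- setdiff(present, loc$replace)
      # the replacement protein is a window member nothing else shares
      sig_extra <- sprintf("new:%s:%d", genome_id, li)
    }
    if (loc_type == "mutated" && (loc$identity %||% 50) < 35) present <- character()
    truth[[length(truth) + 1L]] <- data.frame(
      genome_id = genome_id, contig_id = paste0(genome_id, "_ctg1"),
      locus_type = loc_type, core_start = loc_start, core_end = pos,
      is_window = all(req_ids %in% ids[keep]) &&
        !(loc_type == "mutated" && (loc$identity %||% 50) < 35),
      present = paste(present, collapse = ","),
      signature = paste(sort(c(present, sig_extra)), collapse = ","),
      stringsAsFactors = FALSE)
    clusters[[length(clusters) + 1L]] <- do.call(rbind, coords)
  }
  g1 <- do.call(rbind, genes)
  ct_len <- pos + spec$margin
  seq1 <- assemble_sequence(parts, ct_len)
  main <- contig(paste0(genome_id, "_ctg1"), ct_len, genome_id,
                 gene_table(gene_id = g1$gene_id,
                            contig_id = paste0(genome_id, "_ctg1"),
                            start = g1$start, end = g1$end,
                            strand = g1$strand,
                            locus_tag = g1$gene_id,
                            product = paste0("synthetic ", g1$tmpl),
                            protein_seq = g1$aa),
                 seq1)
  out <- list(main)
  if (spec$n_noise > 0) {
    np <- list(); ng <- list(); pos2 <- spec$margin
    for (j in seq_len(spec$n_noise)) {
      aa <- random_protein(spec$protein_len)
      ge <- append_gene(sprintf("%s_noise%02d", genome_id, j), aa, 1L, pos2)
      np[[j]] <- list(at = pos2, nt = ge$nt)
      ng[[j]] <- data.frame(gene_id = ge$id, start = ge$start, end = ge$end,
                            aa = aa, stringsAsFactors = FALSE)
      pos2 <- ge$end + 1000L
    }
    ng <- do.call(rbind, ng)
    len2 <- pos2 + spec$margin
    out <- c(out, list(contig(paste0(genome_id, "_ctg2"), len2, genome_id,
                              gene_table(gene_id = ng$gene_id,
                                         contig_id = paste0(genome_id, "_ctg2"),
                                         start = ng$start, end = ng$end,
                                         strand = 1L, locus_tag = ng$gene_id,
                                         product = "synthetic noise",
                                         protein_seq = ng$aa),
                              assemble_sequence(np, len2))))
  }
  list(contigs = out, truth = truth, clusters = clusters)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assemble_sequence <- function(parts, total_len) {
  pieces <- character(); cur <- 0L
  for (p in parts) {
    if (p$at > cur) pieces <- c(pieces, strrep("a", p$at - cur))
    pieces <- c(pieces, p$nt)
    cur <- p$at + nchar(p$nt)
  }
  if (total_len > cur) pieces <- c(pieces, strrep("a", total_len - cur))
  toupper(paste(pieces, collapse = ""))
}

write_synthetic <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  by_genome <- split(res$contigs,
                     vapply(res$contigs, `[[`, "", "genome_id"))
  for (gid in names(by_genome))
    write_contigs_genbank(by_genome[[gid]],
                          file.path(out_dir, paste0(gid, ".gbk")))
  utils::write.table(res$truth$windows,
                     file.path(out_dir, "truth_windows.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(gene = names(res$truth$conservation),
               conservation = unname(res$truth$conservation)),
    file.path(out_dir, "truth_conservation.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  q <- res$queries
  write_fasta(stats::setNames(q$sequence[q$role == "required"],
                              q$query_id[q$role == "required"]),
              file.path(out_dir, "queries_required.faa"))
  if (any(q$role == "optional"))
    write_fasta(stats::setNames(q$sequence[q$role == "optional"],
                                q$query_id[q$role == "optional"]),
                file.path(out_dir, "queries_optional.faa"))
  invisible(out_dir)
}

#' Write a list of contigs as one multi-record GenBank file
#'
#' @param contigs list of `gator_contig` (one genome).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contigs_genbank <- function(contigs, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (ct in contigs) {
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   BCT %s",
                       ct$contig_id, ct$length, "01-JAN-2000"), con)
    writeLines(sprintf("DEFINITION  synthetic contig %s of %s.",
                       ct$contig_id, ct$genome_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", ct$length), con)
    g <- ct$genes
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i] + 1L, g$end[i])
      if (g$strand[i] < 0) loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf('                     /locus_tag="%s"', g$locus_tag[i]), con)
      writeLines(sprintf('                     /product="%s"', g$product[i]), con)
      writeLines(wrap_qualifier("translation", g$protein_seq[i]), con)
    }
    if (!is.na(ct$seq)) {
      writeLines("ORIGIN", con)
      writeLines(format_origin(ct$seq), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
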