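# Fixture builders shared across the suite. Everything is generated in code;
# nothing is read from disk except files the tests themselves write.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_prot <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

# A contig with n genes of fixed length/gap; protein sequences random unless
# supplied. Starts at `offset`.
toy_contig <- function(n, gene_len = 300, gap = 200, offset = 2000,
                       contig_id = "c1", genome_id = "g1", proteins = NULL,
                       length_pad = 2000) {
  starts <- offset + (seq_len(n) - 1) * (gene_len + gap)
  ends <- starts + gene_len
  if (is.null(proteins)) proteins <- vapply(rep(gene_len %/% 3, n), rand_prot, "")
  contig(contig_id, max(ends) + length_pad, genome_id,
         gene_table(gene_id = sprintf("%s_%s_g%02d", genome_id, contig_id, seq_len(n)),
                    contig_id = contig_id, start = starts, end = ends,
                    strand = 1L, locus_tag = sprintf("L%02d", seq_len(n)),
                    product = "toy", protein_seq = proteins))
}

# One window over all n genes of a toy contig, with anchors at the given
# gene indices (1-based). Query q<i> maps to anchor i; the first is
# required, the rest optional, so every anchor is query-assigned.
toy_window <- function(n, anchors, gene_len = 300, gap = 200,
                       proteins = NULL) {
  ct <- toy_contig(n, gene_len, gap, proteins = proteins)
  ids <- ct$genes$gene_id
  dict <- stats::setNames(lapply(anchors, function(i) ids[i]),
                          sprintf("q%d", seq_along(anchors)))
  req <- "q1"
  opt <- setdiff(names(dict), req)
  w <- call_windows(list(ct), dict, req, opt,
                    window_params(required_distance = 1e7,
                                  window_extension = 1e7))
  stopifnot(length(w) == 1)
  w[[1]]
}

# Independent brute-force window caller: connected components of the
# pairwise gap graph over required-hit genes, then the all-required test.
# Returns a list of sorted gene-id vectors (core cluster members).
brute_force_windows <- function(contigs, dict, required_ids, cutoff) {
  out <- list()
  req_genes <- unique(unlist(dict[required_ids]))
  for (ct in contigs) {
    g <- ct$genes[ct$genes$gene_id %in% req_genes, , drop = FALSE]
    n <- nrow(g)
    if (!n) next
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      adj[i, j] <- gene_gap(g$start[i], g$end[i], g$start[j], g$end[j]) <= cutoff
    comp <- rep(NA_integer_, n); cid <- 0L
    for (i in seq_len(n)) {
      if (!is.na(comp[i])) next
      cid <- cid + 1L; queue <- i
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (!is.na(comp[v])) next
        comp[v] <- cid
        queue <- c(queue, which(adj[v, ] & is.na(comp)))
      }
    }
    for (k in unique(comp)) {
      members <- g$gene_id[comp == k]
      ok <- all(vapply(required_ids,
                       function(q) any(members %in% dict[[q]]), TRUE))
      if (ok) out[[length(out) + 1L]] <- sort(members)
    }
  }
  out
}

# Core required-hit gene sets from call_windows output, for comparison with
# the brute force (extension 0, no merging).
called_core_sets <- function(windows, dict, required_ids) {
  req_genes <- unique(unlist(dict[required_ids]))
  lapply(windows, function(w) sort(intersect(w$genes$gene_id, req_genes)))
}

set_sort <- function(sets) sets[order(vapply(sets, paste, "", collapse = ","))]

# dictionary straight from generator truth: query id -> planted gene ids
make_truth_dict <- function(syn) {
  genes <- do.call(rbind, lapply(syn$contigs, function(ct) ct$genes))
  dict <- lapply(syn$queries$query_id, function(q)
    genes$gene_id[grepl(paste0("_", q, "$"), genes$gene_id)])
  stats::setNames(dict, syn$queries$query_id)
}

# Count SVG elements of a class without requiring xml2.
svg_count <- function(path, class) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  lengths(regmatches(txt, gregexpr(sprintf('class="%s"', class), txt)))
}

svg_attr_values <- function(path, attr) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  m <- regmatches(txt, gregexpr(sprintf('%s="[^"]*"', attr), txt))[[1]]
  sub(sprintf('%s="([^"]*)"', attr), "\\1", m)
}

# Small planted-cluster run: generator fixture -> mined results, reused by
# several files. Cached per session.
mined_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- plant_spec(n_genomes = 7, seed = 11, loci = c(
      rep(list(list(list(type = "exact"))), 5),
      list(list(list(type = "dropout", drop = "opt1"))),
      list(list(list(type = "decoy")))))
    syn <- generate_synthetic(spec, out_dir = file.path(tempdir(), "synfix"))
    cfg <- gator_config(
      genomes = list.files(file.path(tempdir(), "synfix"),
                           pattern = "gbk$", full.names = TRUE),
      required = file.path(tempdir(), "synfix", "queries_required.faa"),
      optional = file.path(tempdir(), "synfix", "queries_optional.faa"),
      out_dir = file.path(tempdir(), "synout"), seed = 11)
    res <- suppressMessages(gator_mine(cfg))
    cache <<- list(spec = spec, syn = syn, cfg = cfg, res = res)
    cache
  }
})
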