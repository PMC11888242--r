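#' Window-calling parameters
#'
#' `required_distance` is the maximum intergenic gap allowed between genes
#' hit by required queries when chaining them into one cluster (default
#' 85,900 bp, the 95th percentile of intergenic distances observed in
#' experimentally validated biosynthetic gene clusters). `window_extension`
#' is the flank added on both sides of the called core span (default
#' 10,000 bp). `edge_bp` is the contig-edge flag distance (default 500 bp).
#'
#' @param required_distance,window_extension,edge_bp non-negative bp values.
#' @return list of class `gator_params`.
#' @export
window_params <- function(required_distance = 85900, window_extension = 10000,
                          edge_bp = 500) {
  stopifnot(required_distance >= 0, window_extension >= 0, edge_bp >= 0)
  structure(list(required_distance = required_distance,
                 window_extension = window_extension, edge_bp = edge_bp),
            class = "gator_params")
}

#' Intergenic gap between two gene spans
#'
#' Gap between the spans; overlapping or adjacent genes have distance 0.
#' @param s1,e1,s2,e2 0-based half-open coordinates of the two genes.
#' @return non-negative bp.
#' @export
gene_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

#' Estimate the default chaining distance from reference clusters
#'
#' Pools, over a set of reference gene clusters, the intergenic distance of
#' every within-cluster gene pair (gap between spans; overlapping genes
#' contribute 0) and returns a percentile of the pooled distribution by
#' linear interpolation. The shipped default of 85,900 bp is the 95th
#' percentile over curated biosynthetic gene clusters.
#'
#' @param clusters list; each element a data.frame/matrix with `start` and
#'   `end` columns (0-based half-open) for >= 2 genes.
#' @param percentile percentile in (0, 100].
#' @return distance in bp.
#' @export
estimate_default_distance <- function(clusters, percentile = 95) {
  pool <- unlist(lapply(clusters, function(cl) {
    cl <- as.data.frame(cl)
    n <- nrow(cl)
    if (n < 2) return(numeric())
    idx <- utils::combn(n, 2)
    gene_gap(cl$start[idx[1, ]], cl$end[idx[1, ]],
             cl$start[idx[2, ]], cl$end[idx[2, ]])
  }))
  if (!length(pool)) stop("no gene pairs available to pool distances from")
  unname(stats::quantile(pool, percentile / 100, type = 7))
}

#' Call GATOR windows
#'
#' On each contig, genes hit by required queries are chained by
#' single-linkage with intergenic gap <= `required_distance` (or by
#' complete linkage, i.e. all pairwise gaps within the cutoff, when
#' `linkage = "complete"`). A chain containing at least one hit for every
#' required query yields one window: the core span covers the chain's
#' required-hit genes, is extended by `window_extension` on both sides and
#' clamped to the contig; every gene overlapping the extended span is
#' included, and optional-query hits are annotated wherever they fall
#' inside. Windows whose extended spans overlap on the same contig are
#' merged (toggleable). Window ids are `<genome>|<contig>|w<k>` with `k` by
#' ascending span start.
#'
#' @param contigs list of `gator_contig`.
#' @param hit_dictionary named list query id -> gene ids
#'   ([build_hit_dictionary()]).
#' @param required_ids,optional_ids query id vectors; `required_ids`
#'   non-empty.
#' @param params [window_params()].
#' @param merge_overlapping merge windows with overlapping extended spans.
#' @param linkage `"single"` (chain consecutive gaps) or `"complete"`
#'   (all pairwise gaps within the cutoff).
#' @return list of `gator_window`; empty when no contig satisfies all
#'   required queries.
#' @export
call_windows <- function(contigs, hit_dictionary, required_ids,
                         optional_ids = character(), params = window_params(),
                         merge_overlapping = TRUE,
                         linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (!length(required_ids)) stop("required_ids must be non-empty")
  stopifnot(all(required_ids %in% names(hit_dictionary)))
  req_genes <- unique(unlist(hit_dictionary[required_ids]))

  windows <- list()
  for (ct in contigs) {
    g <- ct$genes
    if (!nrow(g)) next
    ri <- which(g$gene_id %in% req_genes)
    if (!length(ri)) next
    chains <- chain_genes(g[ri, , drop = FALSE], params$required_distance,
                          linkage)
    for (ch in chains) {
      chg <- g[ri[ch], , drop = FALSE]
      hit_q <- required_ids[vapply(required_ids, function(q)
        any(chg$gene_id %in% hit_dictionary[[q]]), TRUE)]
      if (length(hit_q) < length(required_ids)) next
      core <- c(min(chg$start), max(chg$end))
      span <- c(max(0, core[1] - params$window_extension),
                min(ct$length, core[2] + params$window_extension))
      windows[[length(windows) + 1L]] <-
        make_window(ct, span, hit_dictionary, required_ids, optional_ids)
    }
  }
  if (merge_overlapping) windows <- merge_window_spans(windows, contigs,
                                                      hit_dictionary,
                                                      required_ids, optional_ids)
  assign_window_ids(windows)
}

# Single-linkage: components of consecutive-gap chaining on start-sorted
# genes. Complete linkage: maximal runs whose all pairwise gaps pass.
chain_genes <- function(g, cutoff, linkage) {
  o <- order(g$start, g$end)
  g <- g[o, , drop = FALSE]
  n <- nrow(g)
  if (linkage == "single") {
    run_end <- cummax(g$end)
    gaps <- if (n > 1) pmax(0, g$start[-1] - run_end[-n]) else numeric()
    brk <- c(0L, which(gaps > cutoff), n)
    chains <- lapply(seq_len(length(brk) - 1L),
                     function(i) (brk[i] + 1L):brk[i + 1L])
  } else {
    chains <- list(); i <- 1L
    while (i <= n) {
      j <- i
      while (j < n && all(gene_gap(g$start[i:j], g$end[i:j],
                                   g$start[j + 1L], g$end[j + 1L]) <= cutoff))
        j <- j + 1L
      chains[[length(chains) + 1L]] <- i:j
      i <- j + 1L
    }
  }
  lapply(chains, function(ix) o[ix])
}

make_window <- function(ct, span, hit_dictionary, required_ids, optional_ids) {
  g <- ct$genes
  inside <- g$start < span[2] & g$end > span[1]   # any overlap
  wg <- g[inside, , drop = FALSE]
  rownames(wg) <- NULL
  hits <- window_hits(wg$gene_id, hit_dictionary, required_ids, optional_ids)
  seq <- if (!is.na(ct$seq)) substr(ct$seq, span[1] + 1L, span[2]) else NA_character_
  structure(list(window_id = NA_character_, genome_id = ct$genome_id,
                 contig_id = ct$contig_id, span_start = span[1],
                 span_end = span[2], genes = wg, hits = hits, seq = seq),
            class = "gator_window")
}

window_hits <- function(gene_ids, hit_dictionary, required_ids, optional_ids) {
  rows <- list()
  for (q in c(required_ids, optional_ids)) {
    hit <- intersect(gene_ids, hit_dictionary[[q]])
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = hit, query_id = q,
        role = if (q %in% required_ids) "required" else "optional",
        stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), query_id = character(),
               role = character(), stringsAsFactors = FALSE)
}

merge_window_spans <- function(windows, contigs, hit_dictionary,
                               required_ids, optional_ids) {
  if (length(windows) < 2) return(windows)
  key <- vapply(windows, function(w) paste(w$genome_id, w$contig_id, sep = "\r"), "")
  ct_by_id <- stats::setNames(contigs, vapply(contigs, `[[`, "", "contig_id"))
  out <- list()
  for (k in unique(key)) {
    ws <- windows[key == k]
    sp <- do.call(rbind, lapply(ws, function(w) c(w$span_start, w$span_end)))
    o <- order(sp[, 1], sp[, 2]); sp <- sp[o, , drop = FALSE]; ws <- ws[o]
    cur <- sp[1, ]
    ct <- ct_by_id[[ws[[1]]$contig_id]]
    for (i in seq_len(nrow(sp))[-1]) {
      if (sp[i, 1] < cur[2]) {
        cur[2] <- max(cur[2], sp[i, 2])
      } else {
        out[[length(out) + 1L]] <- make_window(ct, cur, hit_dictionary,
                                               required_ids, optional_ids)
        cur <- sp[i, ]
      }
    }
    out[[length(out) + 1L]] <- make_window(ct, cur, hit_dictionary,
                                           required_ids, optional_ids)
  }
  out
}

assign_window_ids <- function(windows) {
  if (!length(windows)) return(windows)
  key <- vapply(windows, function(w) paste(w$genome_id, w$contig_id, sep = "\r"), "")
  starts <- vapply(windows, `[[`, 0, "span_start")
  o <- order(key, starts)
  windows <- windows[o]; key <- key[o]
  k <- stats::ave(seq_along(windows), key, FUN = seq_along)
  for (i in seq_along(windows))
    windows[[i]]$window_id <- sprintf("%s|%s|w%03d", windows[[i]]$genome_id,
                                      windows[[i]]$contig_id, k[i])
  windows
}

#' @export
print.gator_window <- function(x, ...) {
  cat(sprintf("<GATOR window %s: %s:%d-%d (%d bp), %d genes, %d query hits>\n",
              x$window_id, x$contig_id, x$span_start, x$span_end,
              x$span_end - x$span_start, nrow(x$genes), nrow(x$hits)))
  invisible(x)
}

#' Window genomic length in bp
#' @param window a `gator_window`.
#' @return `span_end - span_start`.
#' @export
window_length <- function(window) window$span_end - window$span_start

#' Annotate a called window with query roles and modular flags
#'
#' Adds, per gene, the matched query (`gator_hit`), its role
#' (`gator_query`: required/optional/None), and `gator_nrps`/`gator_pks`
#' booleans from the gene's modular category. A gene claimed by several
#' queries is resolved with precedence required > optional; ties within a
#' role are broken by highest bit score (when a hit table is supplied),
#' then lexicographic query id.
#'
#' @param window a `gator_window` from [call_windows()].
#' @param categories named vector gene id -> modular category.
#' @param homology_hits optional hit table used for bit-score tie-breaks.
#' @return the window with annotation columns on `$genes`.
#' @export
annotate_window <- function(window, categories = NULL, homology_hits = NULL) {
  g <- window$genes
  g$gator_query <- "None"
  g$gator_hit <- NA_character_
  h <- window$hits
  if (nrow(h)) {
    h$rank_role <- ifelse(h$role == "required", 0L, 1L)
    h$bit <- 0
    if (!is.null(homology_hits) && nrow(homology_hits)) {
      key <- paste(homology_hits$query_id, homology_hits$subject_id)
      bit <- tapply(homology_hits$bit_score, key, max)
      hb <- bit[paste(h$query_id, h$gene_id)]
      h$bit <- ifelse(is.na(hb), 0, hb)
    }
    h <- h[order(h$gene_id, h$rank_role, -h$bit, h$query_id), , drop = FALSE]
    multi <- h$gene_id[duplicated(h$gene_id)]
    if (length(multi))
      message("gene(s) matched by multiple queries; precedence applied: ",
              paste(unique(multi), collapse = ", "))
    best <- h[!duplicated(h$gene_id), , drop = FALSE]
    ix <- match(best$gene_id, g$gene_id)
    g$gator_query[ix] <- best$role
    g$gator_hit[ix] <- best$query_id
  }
  cat_of <- if (is.null(categories)) stats::setNames(character(), character()) else categories
  gc <- cat_of[g$gene_id]
  gc[is.na(gc)] <- "NONE"
  g$gator_nrps <- gc %in% c("NRPS", "HYBRID")
  g$gator_pks <- gc %in% c("PKS", "HYBRID")
  window$genes <- g
  window
}
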