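#' Run configuration for the mining workflow
#'
#' Collects every tunable of a run in one serializable list. Writing the
#' resolved configuration next to the outputs makes any run reproducible
#' from its own record.
#'
#' @param genomes GenBank file paths (used by the `pre` stage), or `NULL`
#'   when `db_dir` already holds a built database.
#' @param db_dir directory holding/receiving the protein database.
#' @param required,optional query FASTA paths.
#' @param out_dir output directory of the mining stage.
#' @param query_cover,identity homology thresholds in percent (defaults
#'   70 / 35).
#' @param e_value domain-hit threshold (default 1e-4).
#' @param required_distance,window_extension,edge_distance distances in bp
#'   (defaults 85900 / 10000 / 500).
#' @param sigma,sigma_mode focal-score weight kernel settings.
#' @param dedup_mode `"one_directional"` (default) or `"mutual"`.
#' @param hybrid_mode modular-category matching, `"inclusive"` or
#'   `"strict"`.
#' @param merge_overlapping merge windows with overlapping spans.
#' @param linkage required-gene chaining, `"single"` or `"complete"`.
#' @param conservation_basis `"deduplicated"` (default) or `"all"`.
#' @param diamond_hits,query_domtbl,db_domtbl optional paths to external
#'   engine outputs (DIAMOND-style tabular; HMMER-style domain tables for
#'   the queries and the database). When absent the built-in search runs
#'   and no modular domains are assigned unless tables are given.
#' @param taxonomy optional TSV path (`window_id` or `genome_id` plus rank
#'   columns) for the diversity report.
#' @param figures draw SVG figures.
#' @param seed seed echoed into the configuration record.
#' @return list of class `gator_config`.
#' @export
gator_config <- function(genomes = NULL, db_dir = NULL, required = NULL,
                         optional = NULL, out_dir = "gator_out",
                         query_cover = 70, identity = 35, e_value = 1e-4,
                         required_distance = 85900, window_extension = 10000,
                         edge_distance = 500, sigma = NULL,
                         sigma_mode = "index",
                         dedup_mode = c("one_directional", "mutual"),
                         hybrid_mode = c("inclusive", "strict"),
                         merge_overlapping = TRUE,
                         linkage = c("single", "complete"),
                         conservation_basis = c("deduplicated", "all"),
                         diamond_hits = NULL, query_domtbl = NULL,
                         db_domtbl = NULL, taxonomy = NULL, figures = TRUE,
                         seed = 1L) {
  stopifnot(query_cover >= 0, query_cover <= 100, identity >= 0,
            identity <= 100, e_value >= 0, required_distance >= 0,
            window_extension >= 0, edge_distance >= 0)
  cfg <- list(genomes = genomes, db_dir = db_dir, required = required,
              optional = optional, out_dir = out_dir,
              query_cover = query_cover, identity = identity,
              e_value = e_value, required_distance = required_distance,
              window_extension = window_extension,
              edge_distance = edge_distance, sigma = sigma,
              sigma_mode = sigma_mode,
              dedup_mode = match.arg(dedup_mode),
              hybrid_mode = match.arg(hybrid_mode),
              merge_overlapping = merge_overlapping,
              linkage = match.arg(linkage),
              conservation_basis = match.arg(conservation_basis),
              diamond_hits = diamond_hits, query_domtbl = query_domtbl,
              db_domtbl = db_domtbl, taxonomy = taxonomy, figures = figures,
              seed = as.integer(seed))
  class(cfg) <- "gator_config"
  cfg
}

#' Build the protein and modular-domain databases (stage 1)
#'
#' Parses the input genomes, flags contig-edge genes, writes the
#' context-header protein FASTA, assigns every protein a modular category
#' (from a HMMER-style domain table when available, otherwise NONE), and
#' records a manifest with input checksums so reruns are verifiable.
#'
#' @param genomes GenBank file paths.
#' @param out_dir database directory.
#' @param db_domtbl optional HMMER-style domain table over the database
#'   proteins (ids = gene ids).
#' @param e_value domain e-value threshold.
#' @param edge_distance contig-edge distance in bp.
#' @return invisible list: `contigs`, `db`, `categories`, `manifest`.
#' @export
gator_pre <- function(genomes, out_dir, db_domtbl = NULL, e_value = 1e-4,
                      edge_distance = 500) {
  if (!length(genomes)) stop("no input genomes")
  contigs <- unlist(lapply(genomes, parse_genbank), recursive = FALSE)
  if (!sum(vapply(contigs, function(ct) nrow(ct$genes), 0L)))
    stop("no CDS features found in the input genomes")
  contigs <- flag_contig_edges(contigs, edge_distance)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  db <- build_protein_db(contigs, file.path(out_dir, "protein_db.faa"))
  dom <- if (!is.null(db_domtbl)) load_domain_hits(db_domtbl, e_value)
         else empty_domain_hits()
  categories <- categorize_proteins(db$gene_id, dom)
  utils::write.table(
    data.frame(gene_id = names(categories), category = unname(categories)),
    file.path(out_dir, "modular_categories.tsv"), sep = "\t",
    row.names = FALSE, quote = FALSE)
  manifest <- list(
    inputs = as.list(tools::md5sum(genomes)),
    n_contigs = length(contigs), n_proteins = nrow(db),
    n_modular = sum(categories != "NONE"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(contigs = contigs, db = db, categories = categories,
                 manifest = manifest))
}

#' Run the full mining workflow (stage 2)
#'
#' Screens the queries, resolves homology (external tabular files or the
#' built-in search), calls and annotates windows, deduplicates, computes
#' presence-absence and focal scores, the diversity report when taxonomy is
#' supplied, and the SVG figures; writes the full output tree
#' (`windows_genbanks/`, `presence_absence/`, `gator_scores/`,
#' `concatenated_scores/`, `deduplication_process/`,
#' `gator_conservation_plots/`, `gator_neighborhood_plots/`, summary CSV,
#' resolved configuration and log). A run that calls zero windows exits
#' cleanly with an explicit report.
#'
#' @param config a [gator_config()].
#' @param contigs optional pre-parsed contig list (skips re-reading
#'   `config$genomes`).
#' @param queries optional pre-built query data.frame (`query_id`,
#'   `sequence`, `role`).
#' @return invisible list with `windows`, `unique_windows`, `dedup`,
#'   `gfs`, `hits`, `conservation`, `entropy`, `summary`.
#' @export
gator_mine <- function(config, contigs = NULL, queries = NULL) {
  stopifnot(inherits(config, "gator_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "gator_run.log")
  logit <- make_logger(logf)
  logit("run started")
  cfg_echo <- config
  cfg_echo$genomes <- as.list(config$genomes)
  jsonlite::write_json(lapply(unclass(cfg_echo), function(x)
    if (is.null(x)) NA else x),
    file.path(out, "run_config.json"), auto_unbox = TRUE, pretty = TRUE)
  logit("parameters: qcov=%g pid=%g evalue=%g dist=%g ext=%g edge=%g",
        config$query_cover, config$identity, config$e_value,
        config$required_distance, config$window_extension,
        config$edge_distance)

  if (is.null(contigs)) {
    contigs <- unlist(lapply(config$genomes, parse_genbank),
                      recursive = FALSE)
  }
  contigs <- flag_contig_edges(contigs, config$edge_distance)
  db <- build_protein_db(contigs)
  logit("database: %d proteins on %d contigs", nrow(db), length(contigs))

  if (is.null(queries))
    queries <- read_query_fasta(config$required, config$optional)
  qdom <- if (!is.null(config$query_domtbl))
    load_domain_hits(config$query_domtbl, config$e_value) else empty_domain_hits()
  scr <- screen_queries(queries, qdom)
  logit("queries: %d required, %d optional (%d modular)",
        sum(queries$role == "required"), sum(queries$role == "optional"),
        nrow(scr$modular))

  ddom <- if (!is.null(config$db_domtbl))
    load_domain_hits(config$db_domtbl, config$e_value) else empty_domain_hits()
  categories <- categorize_proteins(db$gene_id, ddom)

  db_seqs <- stats::setNames(db$sequence, db$gene_id)
  qh <- if (!is.null(config$diamond_hits)) {
    load_tabular_hits(config$diamond_hits, config$query_cover,
                      config$identity,
                      stats::setNames(nchar(queries$sequence),
                                      queries$query_id))
  } else {
    builtin_search(stats::setNames(queries$sequence, queries$query_id),
                   db_seqs, config$query_cover, config$identity)
  }
  dict <- build_hit_dictionary(scr$queries, qh, categories,
                               config$hybrid_mode)

  req_ids <- queries$query_id[queries$role == "required"]
  opt_ids <- queries$query_id[queries$role == "optional"]
  params <- window_params(config$required_distance,
                          config$window_extension, config$edge_distance)
  windows <- call_windows(contigs, dict, req_ids, opt_ids, params,
                          config$merge_overlapping, config$linkage)
  if (!length(windows)) {
    logit("no windows: no contig satisfies all required queries")
    writeLines("no windows", file.path(out, "NO_WINDOWS.txt"))
    return(invisible(list(windows = list(), unique_windows = list(),
                          dedup = NULL, gfs = NULL, hits = NULL,
                          conservation = NULL, entropy = NULL,
                          summary = NULL)))
  }
  windows <- lapply(windows, annotate_window, categories = categories,
                    homology_hits = qh)
  logit("called %d window(s)", length(windows))

  gb_dir <- file.path(out, "windows_genbanks")
  for (w in windows) write_window_genbank(w, gb_dir)
  summary <- write_summary_table(windows,
                                 file.path(out, "gator_windows_summary.csv"))

  wh <- window_homology(windows, min_qcov = config$query_cover,
                        min_pid = config$identity)
  dd <- deduplicate(windows, wh, mutual = config$dedup_mode == "mutual",
                    sigma = config$sigma, mode = config$sigma_mode,
                    out_dir = out)
  logit("deduplication: %d unique of %d", length(dd$unique),
        length(windows))
  basis <- if (config$conservation_basis == "deduplicated") dd$unique
           else windows
  m <- all_vs_all(basis, wh, sigma = config$sigma, mode = config$sigma_mode,
                  out_dir = out)

  cl <- cluster_gfs(m)
  conservation <- list()
  if (config$figures) {
    cons_dir <- file.path(out, "gator_conservation_plots")
    nb_dir <- file.path(out, "gator_neighborhood_plots")
    for (w in basis) {
      pa <- presence_absence(w, basis, wh)
      prof <- conservation_profile(w, pa)
      conservation[[w$window_id]] <- prof
      safe <- gsub("[^A-Za-z0-9._-]", "_", w$window_id)
      draw_conservation(w, prof, file.path(cons_dir, paste0(safe, ".svg")))
      draw_neighborhood(w, basis, m[, w$window_id], wh,
                        file.path(nb_dir, paste0(safe, ".svg")))
    }
    if (length(basis) >= 2)
      draw_heatmap(m, cl, file.path(out, "concatenated_scores",
                                    "gfs_heatmap.svg"))
  } else {
    for (w in basis)
      conservation[[w$window_id]] <-
        conservation_profile(w, presence_absence(w, basis, wh))
  }

  entropy <- NULL
  if (!is.null(config$taxonomy)) {
    tx <- utils::read.delim(config$taxonomy, stringsAsFactors = FALSE)
    entropy <- window_entropy_report(basis, tx)
    if (!is.null(entropy))
      utils::write.csv(entropy, file.path(out, "gator_diversity.csv"),
                       row.names = FALSE)
  }
  export_network_tables(m, basis, out)
  logit("run finished")
  invisible(list(windows = windows, unique_windows = dd$unique, dedup = dd,
                 gfs = m, hits = wh, conservation = conservation,
                 entropy = entropy, summary = summary))
}

# Entropy over the windows of this run (one family per rank column).
window_entropy_report <- function(windows, tx) {
  gid <- vapply(windows, `[[`, "", "genome_id")
  wid <- vapply(windows, `[[`, "", "window_id")
  key <- if ("window_id" %in% names(tx)) tx$window_id else tx$genome_id
  if (is.null(key)) return(NULL)
  ranks <- setdiff(names(tx), c("window_id", "genome_id", "family_id"))
  ix <- match(if ("window_id" %in% names(tx)) wid else gid, key)
  if (all(is.na(ix))) return(NULL)
  rows <- lapply(ranks, function(r) {
    lab <- tx[[r]][ix]
    lab <- lab[!is.na(lab)]
    if (!length(lab)) return(NULL)
    data.frame(rank = r, H = shannon_entropy(table(lab)),
               n_taxa = length(unique(lab)), n_windows = length(lab))
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

make_logger <- function(path) {
  function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
        file = path, append = TRUE)
    invisible(msg)
  }
}
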