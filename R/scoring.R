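#' Proximity weights for a focal window
#'
#' Genes assigned to required or optional queries are anchors and carry the
#' maximum weight of 1; every other gene is weighted by a decaying normal
#' (Gaussian) kernel of its distance to each anchor,
#' `w = exp(-d^2 / (2 sigma^2))`, taking the maximum over anchors. Distance
#' is measured in gene ordinal index by default (making the score invariant
#' to intergenic-length noise); a bp mode measures between gene midpoints.
#' The default bandwidth is `sigma = max(1, n_genes / 6)` in index mode.
#'
#' @param window a `gator_window` with at least one query-assigned gene.
#' @param sigma kernel bandwidth; `NULL` for the default (index mode:
#'   `max(1, n/6)`; bp mode: 10000).
#' @param mode `"index"` or `"bp"`.
#' @return object of class `gator_weights`: list with `window_id` and
#'   `weights` (named by gene id, in gene order, all in (0, 1]).
#' @export
compute_weights <- function(window, sigma = NULL, mode = c("index", "bp")) {
  mode <- match.arg(mode)
  g <- window$genes
  n <- nrow(g)
  anchors <- which(g$gene_id %in% window$hits$gene_id)
  if (!length(anchors))
    stop("window ", window$window_id, " has no query-assigned gene; cannot score")
  if (mode == "index") {
    pos <- seq_len(n)
    if (is.null(sigma)) sigma <- max(1, n / 6)
  } else {
    pos <- (g$start + g$end) / 2
    if (is.null(sigma)) sigma <- 10000
  }
  d2 <- outer(pos, pos[anchors], function(a, b) (a - b)^2)
  w <- apply(exp(-d2 / (2 * sigma^2)), 1, max)
  structure(list(window_id = window$window_id,
                 weights = stats::setNames(w, g$gene_id)),
            class = "gator_weights")
}

#' Homology hits among the proteins of a window set
#'
#' Builds the pooled protein database of all windows' genes and searches it
#' all-vs-all, either with the built-in aligner or by filtering a
#' pre-computed tabular file whose ids are gene ids.
#'
#' @param windows list of `gator_window`.
#' @param search either a function with the [builtin_search()] signature or
#'   a pre-computed hit data.frame.
#' @param min_qcov,min_pid filtering thresholds in percent.
#' @return hit data.frame (gene id vs gene id).
#' @export
window_homology <- function(windows, search = builtin_search,
                            min_qcov = 70, min_pid = 35) {
  if (is.data.frame(search)) return(filter_hits(search, min_qcov, min_pid))
  prots <- unlist(lapply(windows, function(w)
    stats::setNames(w$genes$protein_seq, w$genes$gene_id)))
  prots <- prots[!duplicated(names(prots))]
  search(prots, prots, min_qcov = min_qcov, min_pid = min_pid)
}

#' Gene-level presence-absence of a focal window against targets
#'
#' Cell (t, g) is TRUE iff focal gene g has at least one passing homology
#' hit to any protein of window t. The focal window's own row is all TRUE
#' by self-alignment.
#'
#' @param focal the focal `gator_window`.
#' @param targets list of `gator_window` (may include the focal window).
#' @param hits gene-vs-gene hit table from [window_homology()].
#' @return logical matrix, rows = target window ids, columns = focal gene
#'   ids.
#' @export
presence_absence <- function(focal, targets, hits) {
  fg <- focal$genes$gene_id
  member <- lapply(targets, function(w) w$genes$gene_id)
  names(member) <- vapply(targets, `[[`, "", "window_id")
  by_query <- split(hits$subject_id, hits$query_id)
  m <- matrix(FALSE, nrow = length(targets), ncol = length(fg),
              dimnames = list(names(member), fg))
  for (g in fg) {
    subj <- c(by_query[[g]], g)   # a gene is always present in its own window
    hit_w <- vapply(member, function(ids) any(ids %in% subj), TRUE)
    m[, g] <- hit_w
  }
  m
}

#' GATOR Focal Score of one target row
#'
#' The proximity-weighted fraction of the focal window's genes found in the
#' target: `sum(w * present) / sum(w)`. Each focal gene contributes at most
#' once regardless of hit multiplicity. Ranges over [0, 1]; the focal window
#' against itself scores exactly 1.
#'
#' @param presence_row logical vector over focal genes.
#' @param weights `gator_weights` (or bare numeric vector) aligned to the
#'   focal genes.
#' @return score in [0, 1].
#' @export
gfs <- function(presence_row, weights) {
  w <- if (inherits(weights, "gator_weights")) weights$weights else weights
  stopifnot(length(w) == length(presence_row), all(w > 0))
  sum(w[presence_row]) / sum(w)
}

#' All-vs-all GATOR Focal Score matrix
#'
#' Column j holds the score of every window evaluated against focal window
#' j. Optionally exports per-focal presence-absence CSVs
#' (`presence_absence/`), per-focal score tables (`gator_scores/`) and the
#' concatenated matrix (`concatenated_scores/`) under `out_dir`.
#'
#' @param windows list of >= 1 annotated `gator_window`.
#' @param hits gene-vs-gene hit table ([window_homology()]).
#' @param sigma,mode weight parameters ([compute_weights()]).
#' @param out_dir optional export directory.
#' @return numeric matrix, rows and columns named by window id (class
#'   `gator_gfs`).
#' @export
all_vs_all <- function(windows, hits, sigma = NULL, mode = "index",
                       out_dir = NULL) {
  ids <- vapply(windows, `[[`, "", "window_id")
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (j in seq_along(windows)) {
    focal <- windows[[j]]
    w <- compute_weights(focal, sigma = sigma, mode = mode)
    pa <- presence_absence(focal, windows, hits)
    m[, j] <- apply(pa, 1, gfs, weights = w)
    if (!is.null(out_dir)) {
      safe <- gsub("[^A-Za-z0-9._-]", "_", focal$window_id)
      pa_dir <- file.path(out_dir, "presence_absence")
      sc_dir <- file.path(out_dir, "gator_scores")
      dir.create(pa_dir, recursive = TRUE, showWarnings = FALSE)
      dir.create(sc_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(data.frame(window_id = rownames(pa), pa * 1L,
                                  check.names = FALSE),
                       file.path(pa_dir, paste0(safe, ".csv")),
                       row.names = FALSE)
      utils::write.csv(data.frame(window_id = ids, gfs = m[, j]),
                       file.path(sc_dir, paste0(safe, ".csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(out_dir)) {
    cc <- file.path(out_dir, "concatenated_scores")
    dir.create(cc, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(window_id = rownames(m), m,
                                check.names = FALSE),
                     file.path(cc, "gfs_matrix.csv"), row.names = FALSE)
  }
  class(m) <- c("gator_gfs", class(m))
  m
}

#' Deduplicate identical GATOR windows by focal score
#'
#' Focal windows are processed in descending genomic length (ties broken by
#' window id). Any not-yet-removed window scoring GFS >= 1 - tol against the
#' current focal is deemed identical, removed and mapped to the focal
#' representative; removed windows leave the comparison space before the
#' next iteration, and a window that has already served as focal is a final
#' representative. With `mutual = TRUE` removal additionally requires the
#' reverse score to reach 1, so a shorter strict-subset window is kept.
#'
#' @param windows list of annotated `gator_window`.
#' @param hits gene-vs-gene hit table ([window_homology()]).
#' @param tol identity tolerance on the score (default 1e-9).
#' @param mutual require identity in both directions.
#' @param sigma,mode weight parameters.
#' @param out_dir optional directory; the process log is written under
#'   `deduplication_process/`.
#' @return list with `unique` (kept windows, original calling order),
#'   `map` (named list representative id -> removed ids) and `log`
#'   (data.frame of processing steps).
#' @export
deduplicate <- function(windows, hits, tol = 1e-9, mutual = FALSE,
                        sigma = NULL, mode = "index", out_dir = NULL) {
  ids <- vapply(windows, `[[`, "", "window_id")
  lens <- vapply(windows, window_length, 0)
  ord <- order(-lens, ids)
  removed <- logical(length(windows))
  done <- logical(length(windows))   # served as focal: final representative
  map <- list()
  log <- list()
  step <- 0L
  for (f in ord) {
    if (removed[f]) next
    step <- step + 1L
    done[f] <- TRUE
    others <- which(!removed & !done)
    if (!length(others)) {
      log[[length(log) + 1L]] <- data.frame(step = step, focal_id = ids[f],
                                            removed_id = NA_character_,
                                            gfs = NA_real_)
      next
    }
    w <- compute_weights(windows[[f]], sigma = sigma, mode = mode)
    pa <- presence_absence(windows[[f]], windows[others], hits)
    sc <- apply(pa, 1, gfs, weights = w)
    dup <- sc >= 1 - tol
    if (mutual && any(dup)) {
      for (k in which(dup)) {
        t <- others[k]
        wt <- compute_weights(windows[[t]], sigma = sigma, mode = mode)
        pat <- presence_absence(windows[[t]], windows[f], hits)
        dup[k] <- gfs(pat[1, ], wt) >= 1 - tol
      }
    }
    if (any(dup)) {
      rem <- others[dup]
      removed[rem] <- TRUE
      map[[ids[f]]] <- ids[rem]
      log[[length(log) + 1L]] <- data.frame(step = step, focal_id = ids[f],
                                            removed_id = ids[rem],
                                            gfs = unname(sc[dup]))
    } else {
      log[[length(log) + 1L]] <- data.frame(step = step, focal_id = ids[f],
                                            removed_id = NA_character_,
                                            gfs = NA_real_)
    }
  }
  log <- do.call(rbind, log)
  if (!is.null(out_dir)) {
    dd <- file.path(out_dir, "deduplication_process")
    dir.create(dd, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(log, file.path(dd, "deduplication_log.csv"),
                     row.names = FALSE)
  }
  list(unique = windows[!removed], map = map, log = log)
}
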