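#' Load and filter BLAST/DIAMOND tabular homology hits
#'
#' Reads 12+-column tabular output (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore [qcovhsp]`). When a 13th
#' column is present it is taken as the per-HSP query coverage; otherwise
#' coverage is derived as aligned query span / query length, which requires
#' `query_lengths`. Rows failing the identity or coverage threshold are
#' dropped; malformed rows are skipped with a warning.
#'
#' Defaults mirror the mining workflow: 70% query cover, 35% identity.
#'
#' @param path tabular file.
#' @param min_qcov,min_pid filtering thresholds in percent.
#' @param query_lengths named integer vector (query id -> length in aa);
#'   only needed when the file has no coverage column.
#' @return data.frame of hits: `query_id`, `subject_id`, `pct_identity`,
#'   `query_cover`, `evalue`, `bit_score`, `q_start`, `q_end`, `s_start`,
#'   `s_end`.
#' @export
load_tabular_hits <- function(path, min_qcov = 70, min_pid = 35,
                              query_lengths = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- strsplit(lines, "\t")
  short <- vapply(rows, length, 0L) < 12L
  if (any(short)) {
    warning(sum(short), " malformed row(s) skipped in ", basename(path),
            call. = FALSE)
    rows <- rows[!short]
  }
  if (!length(rows)) return(empty_hits())
  m <- do.call(rbind, lapply(rows, function(r) r[1:min(13, length(r))]))
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  df <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                   pct_identity = num(3), aln_len = num(4),
                   q_start = num(7), q_end = num(8),
                   s_start = num(9), s_end = num(10),
                   evalue = num(11), bit_score = num(12),
                   stringsAsFactors = FALSE)
  if (ncol(m) >= 13) {
    df$query_cover <- num(13)
  } else {
    if (is.null(query_lengths))
      stop("no coverage column and no query_lengths supplied")
    qlen <- query_lengths[df$query_id]
    df$query_cover <- 100 * (abs(df$q_end - df$q_start) + 1) / as.numeric(qlen)
  }
  bad <- is.na(df$pct_identity) | is.na(df$query_cover) | is.na(df$bit_score)
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) skipped in ", basename(path),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  df$aln_len <- NULL
  filter_hits(df, min_qcov, min_pid)
}

filter_hits <- function(df, min_qcov, min_pid) {
  df <- df[df$pct_identity >= min_pid & df$query_cover >= min_qcov, ,
           drop = FALSE]
  rownames(df) <- NULL
  df[c("query_id", "subject_id", "pct_identity", "query_cover", "evalue",
       "bit_score", "q_start", "q_end", "s_start", "s_end")]
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), query_cover = numeric(),
             evalue = numeric(), bit_score = numeric(),
             q_start = numeric(), q_end = numeric(),
             s_start = numeric(), s_end = numeric(), stringsAsFactors = FALSE)
}

#' Default HMM-profile-name to modular-domain mapping
#'
#' Maps profile names (as they appear in a HMMER domain table) to the four
#' modular domains: adenylation (A) and condensation (C) for NRPS,
#' acyltransferase (AT) and ketosynthase (KS) for PKS. The shipped table
#' covers the common profile names; pass your own named vector to
#' [load_domain_hits()] to extend it.
#'
#' @return named character vector profile name -> {A, C, AT, KS}.
#' @export
default_profile_map <- function() {
  path <- system.file("extdata", "domain_profiles.tsv", package = "gatorgc")
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tb$domain, tb$profile)
}

#' Load and filter HMMER-style per-domain hits
#'
#' Reads a `--domtblout`-style whitespace-delimited table (comment lines
#' starting with `#` ignored). Column layout follows HMMER: target name (1),
#' query/profile name (4), independent e-value (13), score (14), envelope
#' coordinates (20, 21). Hits above `max_evalue` are dropped; profiles not
#' present in `profile_map` are ignored with a message.
#'
#' @param path domain-table file.
#' @param max_evalue e-value threshold (default 1e-4).
#' @param profile_map named vector profile name -> domain
#'   ({A, C, AT, KS}); defaults to the shipped table.
#' @return data.frame: `protein_id`, `domain`, `evalue`, `score`,
#'   `env_start`, `env_end`.
#' @export
load_domain_hits <- function(path, max_evalue = 1e-4,
                             profile_map = default_profile_map()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_domain_hits())
  rows <- strsplit(trimws(lines), "\\s+")
  keep <- vapply(rows, length, 0L) >= 21L
  if (any(!keep))
    warning(sum(!keep), " malformed domain row(s) skipped", call. = FALSE)
  rows <- rows[keep]
  if (!length(rows)) return(empty_domain_hits())
  df <- data.frame(
    protein_id = vapply(rows, `[`, "", 1L),
    profile = vapply(rows, `[`, "", 4L),
    evalue = as.numeric(vapply(rows, `[`, "", 13L)),
    score = as.numeric(vapply(rows, `[`, "", 14L)),
    env_start = as.integer(vapply(rows, `[`, "", 20L)),
    env_end = as.integer(vapply(rows, `[`, "", 21L)),
    stringsAsFactors = FALSE)
  unknown <- !(df$profile %in% names(profile_map))
  if (any(unknown))
    message(sum(unknown), " domain hit(s) with unmapped profile name ignored: ",
            paste(unique(df$profile[unknown]), collapse = ", "))
  df <- df[!unknown & df$evalue <= max_evalue, , drop = FALSE]
  df$domain <- unname(profile_map[df$profile])
  rownames(df) <- NULL
  df[c("protein_id", "domain", "evalue", "score", "env_start", "env_end")]
}

empty_domain_hits <- function() {
  data.frame(protein_id = character(), domain = character(),
             evalue = numeric(), score = numeric(),
             env_start = integer(), env_end = integer(),
             stringsAsFactors = FALSE)
}

#' Classify a protein's modular category from its domain content
#'
#' Rule-based: at least one adenylation (A) and one condensation (C) domain
#' make an NRPS; at least one acyltransferase (AT) and one ketosynthase (KS)
#' domain make a PKS; satisfying both rules makes an NRPS-PKS hybrid;
#' anything else is NONE. Counts drive the rules; positions and ordering do
#' not matter.
#'
#' @param domains character vector of domain labels ({A, C, AT, KS}) seen on
#'   one protein (already e-value filtered).
#' @return one of `"NRPS"`, `"PKS"`, `"HYBRID"`, `"NONE"`.
#' @export
classify_modularity <- function(domains) {
  nrps <- any(domains == "A") && any(domains == "C")
  pks <- any(domains == "AT") && any(domains == "KS")
  if (nrps && pks) "HYBRID" else if (nrps) "NRPS" else if (pks) "PKS" else "NONE"
}

#' Categorize every database protein
#'
#' @param protein_ids ids of all proteins under consideration.
#' @param domain_hits filtered domain-hit table ([load_domain_hits()]).
#' @return named character vector protein id -> category (NONE when the
#'   protein has no modular domains).
#' @export
categorize_proteins <- function(protein_ids, domain_hits = empty_domain_hits()) {
  cats <- stats::setNames(rep("NONE", length(protein_ids)), protein_ids)
  if (nrow(domain_hits)) {
    by_prot <- split(domain_hits$domain, domain_hits$protein_id)
    got <- intersect(names(by_prot), protein_ids)
    cats[got] <- vapply(by_prot[got], classify_modularity, "")
  }
  cats
}

#' Screen query proteins for modular domains
#'
#' Assigns every query a modular category from the supplied domain evidence
#' and partitions the set into modular (NRPS/PKS/hybrid) and non-modular
#' queries. Modular queries are later matched by category membership in the
#' modular-domains database rather than by sequence similarity.
#'
#' @param queries data.frame with `query_id`, `sequence`, `role`
#'   (required/optional).
#' @param domain_hits domain-hit table whose `protein_id` values are query
#'   ids (e.g. from running the queries through the domain scan).
#' @return list with `queries` (input plus a `category` column), `modular`
#'   and `non_modular` (row subsets).
#' @export
screen_queries <- function(queries, domain_hits = empty_domain_hits()) {
  stopifnot(all(c("query_id", "sequence", "role") %in% names(queries)))
  if (anyDuplicated(queries$query_id))
    stop("query ids must be unique across required and optional sets")
  queries$category <- unname(categorize_proteins(queries$query_id, domain_hits))
  list(queries = queries,
       modular = queries[queries$category != "NONE", , drop = FALSE],
       non_modular = queries[queries$category == "NONE", , drop = FALSE])
}

#' Build the query -> subject-gene dictionary
#'
#' Non-modular queries map to the database genes they hit in the filtered
#' homology table. Modular queries map to every database protein whose
#' modular category matches the query's: inclusively (default) an NRPS query
#' matches NRPS and HYBRID subjects, a PKS query matches PKS and HYBRID, and
#' a HYBRID query matches HYBRID only; in strict mode categories must be
#' equal.
#'
#' @param queries screened query data.frame (with `category`).
#' @param homology_hits filtered hit table; `query_id` are query ids,
#'   `subject_id` are database gene ids.
#' @param db_categories named vector gene id -> category
#'   ([categorize_proteins()]).
#' @param hybrid_mode `"inclusive"` or `"strict"`.
#' @return named list query id -> character vector of gene ids (possibly
#'   empty).
#' @export
build_hit_dictionary <- function(queries, homology_hits,
                                 db_categories,
                                 hybrid_mode = c("inclusive", "strict")) {
  hybrid_mode <- match.arg(hybrid_mode)
  match_cats <- function(cat) {
    if (hybrid_mode == "strict") return(cat)
    switch(cat, NRPS = c("NRPS", "HYBRID"), PKS = c("PKS", "HYBRID"),
           HYBRID = "HYBRID", cat)
  }
  out <- stats::setNames(vector("list", nrow(queries)), queries$query_id)
  for (i in seq_len(nrow(queries))) {
    qid <- queries$query_id[i]
    if (queries$category[i] == "NONE") {
      out[[qid]] <- unique(homology_hits$subject_id[
        homology_hits$query_id == qid])
    } else {
      out[[qid]] <- names(db_categories)[
        db_categories %in% match_cats(queries$category[i])]
    }
  }
  out
}

#' Read required/optional query FASTA files
#'
#' @param required,optional FASTA paths (`optional` may be `NULL`).
#' @return data.frame `query_id`, `sequence`, `role`. Ids are the first
#'   whitespace-delimited token of each header.
#' @export
read_query_fasta <- function(required, optional = NULL) {
  take <- function(path, role) {
    x <- read_fasta(path)
    ids <- vapply(strsplit(names(x), "\\s+"), `[`, "", 1L)
    data.frame(query_id = ids, sequence = unname(x), role = role,
               stringsAsFactors = FALSE)
  }
  q <- take(required, "required")
  if (!is.null(optional) && file.exists(optional))
    q <- rbind(q, take(optional, "optional"))
  if (anyDuplicated(q$query_id))
    stop("query ids must be unique across required and optional files")
  if (any(!nzchar(q$sequence))) stop("empty query sequence")
  q
}
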