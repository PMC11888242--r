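#' Parse a GenBank flat file into contigs
#'
#' Reads one or more GenBank records and extracts every CDS feature with its
#' coordinates, strand, locus tag, product and protein sequence. When the
#' `/translation` qualifier is absent the protein is translated from the CDS
#' nucleotide span with the bacterial genetic code (table 11); a CDS whose
#' span contains an internal stop under that code is skipped with a warning.
#' Coordinates are converted from GenBank 1-based inclusive to the internal
#' 0-based half-open convention. Non-CDS features and pseudogenes are
#' ignored.
#'
#' Compound (`join`) locations use the minimal enclosing span for the gene
#' coordinates, while the translation fallback joins the exon spans; such
#' CDS are reported via `message()`.
#'
#' @param path GenBank flat file (possibly multi-record).
#' @param genome_id genome label attached to every contig; defaults to the
#'   file name without extension.
#' @return list of `gator_contig`, one per record, genes sorted by start.
#' @export
parse_genbank <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("cannot read GenBank file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines)))
    stop("not a GenBank flat file (no LOCUS line): ", path)
  if (is.null(genome_id))
    genome_id <- sub("\\.(gb|gbk|gbff|genbank)$", "", basename(path))

  # split into records at '//'
  rec_end <- grep("^//", lines)
  rec_start <- c(1L, head(rec_end, -1) + 1L)
  if (!length(rec_end)) { rec_start <- 1L; rec_end <- length(lines) }

  contigs <- vector("list", length(rec_start))
  for (r in seq_along(rec_start)) {
    rl <- lines[rec_start[r]:rec_end[r]]
    contigs[[r]] <- parse_genbank_record(rl, genome_id)
  }
  contigs[!vapply(contigs, is.null, TRUE)]
}

parse_genbank_record <- function(rl, genome_id) {
  locus_i <- grep("^LOCUS", rl)
  if (!length(locus_i)) return(NULL)
  toks <- strsplit(trimws(rl[locus_i[1]]), "\\s+")[[1]]
  contig_id <- toks[2]
  bp_i <- match("bp", toks)
  ct_len <- if (!is.na(bp_i) && bp_i > 1) as.integer(toks[bp_i - 1]) else NA_integer_

  feat_i <- grep("^FEATURES", rl)
  origin_i <- grep("^ORIGIN", rl)
  seq_str <- NA_character_
  if (length(origin_i)) {
    sl <- rl[(origin_i[1] + 1L):length(rl)]
    sl <- sl[!grepl("^//", sl)]
    seq_str <- toupper(gsub("[^A-Za-z]", "", paste(sl, collapse = "")))
    if (!nzchar(seq_str)) seq_str <- NA_character_
  }
  if (is.na(ct_len)) ct_len <- if (!is.na(seq_str)) nchar(seq_str) else 0L

  feats <- list()
  if (length(feat_i)) {
    fend <- if (length(origin_i)) origin_i[1] - 1L else length(rl)
    fl <- rl[(feat_i[1] + 1L):fend]
    feats <- parse_feature_block(fl)
  }

  genes <- list(); skipped <- 0L
  k <- 0L
  for (f in feats) {
    if (f$key != "CDS") next
    if (!is.null(f$qualifiers$pseudo)) next
    loc <- parse_location(f$location)
    if (is.null(loc)) next
    k <- k + 1L
    prot <- f$qualifiers$translation
    if (is.null(prot)) {
      prot <- translate_cds(seq_str, loc)
      if (is.null(prot)) {
        warning("skipping CDS at ", f$location, " on ", contig_id,
                ": cannot translate (missing sequence or internal stop)",
                call. = FALSE)
        skipped <- skipped + 1L
        next
      }
    }
    if (nrow(loc$spans) > 1)
      message("multi-exon CDS at ", f$location, " on ", contig_id,
              "; using minimal enclosing span")
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = sprintf("%s|%s|%d-%d|%s", genome_id, contig_id,
                        loc$start + 1L, loc$end,
                        if (loc$strand > 0) "+" else "-"),
      contig_id = contig_id, start = loc$start, end = loc$end,
      strand = loc$strand,
      locus_tag = if (is.null(f$qualifiers$locus_tag)) "" else f$qualifiers$locus_tag,
      product = if (is.null(f$qualifiers$product)) "" else f$qualifiers$product,
      protein_seq = prot, contig_edge = FALSE, stringsAsFactors = FALSE)
  }
  g <- if (length(genes)) do.call(rbind, genes) else gene_table()
  class(g) <- c("gator_genes", "data.frame")
  if (nrow(g) && anyDuplicated(g$gene_id))
    g$gene_id <- make.unique(g$gene_id, sep = "#")
  contig(contig_id, max(ct_len, if (nrow(g)) max(g$end) else 0L),
         genome_id, g, seq_str)
}

# Split a FEATURES block into features: key at column 6, qualifiers at 22.
parse_feature_block <- function(fl) {
  feats <- list(); cur <- NULL; curq <- NULL
  flush_q <- function() {
    if (!is.null(curq)) {
      val <- curq$value
      cur$qualifiers[[curq$name]] <<- val
    }
    curq <<- NULL
  }
  for (ln in fl) {
    if (grepl("^ {0,4}\\S", ln) && !grepl("^ {5}", ln)) break  # left margin: end of table
    if (grepl("^ {5}\\S", ln)) {                 # new feature
      flush_q()
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      key <- trimws(substr(ln, 1, 20))
      loc <- trimws(substr(ln, 21, nchar(ln)))
      cur <- list(key = key, location = loc, qualifiers = list())
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (!nzchar(txt)) next
      if (startsWith(txt, "/")) {                 # new qualifier
        flush_q()
        m <- regmatches(txt, regexec("^/([A-Za-z_0-9]+)(=(.*))?$", txt))[[1]]
        name <- m[2]
        val <- if (length(m) >= 4 && nzchar(m[3])) m[4] else TRUE
        if (is.character(val)) val <- gsub("^\"|\"$", "", val)
        curq <- list(name = name, value = val)
      } else if (!is.null(curq) && is.character(curq$value)) {
        txt <- gsub("\"$", "", txt)
        sep <- if (curq$name == "translation") "" else " "
        curq$value <- paste(curq$value, txt, sep = sep)
      } else if (is.null(curq)) {                 # continued location
        cur$location <- paste0(cur$location, txt)
      }
    }
  }
  flush_q()
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  feats
}

# GenBank location -> list(start 0-based, end, strand, spans matrix)
parse_location <- function(loc) {
  strand <- 1L
  s <- gsub("[<>]", "", loc)
  if (grepl("complement", s)) strand <- -1L
  s <- gsub("complement\\(|join\\(|order\\(|\\)", "", s)
  parts <- strsplit(s, ",")[[1]]
  sp <- lapply(parts, function(p) {
    nums <- suppressWarnings(as.integer(strsplit(p, "\\.\\.")[[1]]))
    if (any(is.na(nums))) return(NULL)
    if (length(nums) == 1) nums <- c(nums, nums)
    nums
  })
  if (any(vapply(sp, is.null, TRUE)) || !length(sp)) return(NULL)
  m <- do.call(rbind, sp)
  list(start = min(m[, 1]) - 1L, end = max(m[, 2]), strand = strand,
       spans = m)
}

# Translate a CDS span (exon-joined) with the bacterial code; NULL if the
# sequence is unavailable or an internal stop remains after trimming one
# trailing stop.
translate_cds <- function(seq_str, loc) {
  if (is.na(seq_str)) return(NULL)
  if (max(loc$spans[, 2]) > nchar(seq_str)) return(NULL)
  nt <- paste(apply(loc$spans, 1, function(sp)
    substr(seq_str, sp[1], sp[2])), collapse = "")
  if (loc$strand < 0)
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  nt <- substr(nt, 1, 3L * (nchar(nt) %/% 3L))
  if (!nchar(nt)) return(NULL)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode("11"), if.fuzzy.codon = "X"))
  aa <- sub("\\*$", "", aa)
  if (grepl("\\*", aa) || !nzchar(aa)) return(NULL)
  aa
}

#' Write an annotated GATOR window as a GenBank file
#'
#' One file per window under `out_dir` (conventionally `windows_genbanks/`).
#' Coordinates are re-based to the window start; each CDS carries the
#' qualifiers `gator_query` (required/optional/None), `gator_hit` (matched
#' query id; absent when there is no hit), `gator_nrps`, `gator_pks` and
#' `contig_edge`.
#'
#' @param window an annotated `gator_window` (see [annotate_window()]).
#' @param out_dir output directory, created if needed.
#' @return path of the written file, invisibly.
#' @export
write_window_genbank <- function(window, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  g <- window$genes
  w_len <- window$span_end - window$span_start
  name <- gsub("[^A-Za-z0-9._-]", "_", window$window_id)
  path <- file.path(out_dir, paste0(name, ".gbk"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   BCT %s",
                     name, w_len, "01-JAN-2000"), con)
  writeLines(sprintf("DEFINITION  GATOR window %s (%s:%d..%d, %s).",
                     window$window_id, window$contig_id,
                     window$span_start + 1L, window$span_end,
                     window$genome_id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", w_len), con)
  qline <- function(q, v) sprintf("                     /%s=%s", q, v)
  for (i in seq_len(nrow(g))) {
    s1 <- g$start[i] - window$span_start + 1L
    e1 <- g$end[i] - window$span_start
    s1 <- max(s1, 1L); e1 <- min(e1, w_len)
    loc <- sprintf("%d..%d", s1, e1)
    if (g$strand[i] < 0) loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    if (nzchar(g$locus_tag[i]))
      writeLines(qline("locus_tag", dquote(g$locus_tag[i])), con)
    if (nzchar(g$product[i]))
      writeLines(qline("product", dquote(g$product[i])), con)
    gq <- if (is.null(g$gator_query)) "None" else g$gator_query[i]
    writeLines(qline("gator_query", dquote(gq)), con)
    if (!is.null(g$gator_hit) && !is.na(g$gator_hit[i]))
      writeLines(qline("gator_hit", dquote(g$gator_hit[i])), con)
    writeLines(qline("gator_nrps",
                     dquote(tolower(isTRUE(g$gator_nrps[i])))), con)
    writeLines(qline("gator_pks",
                     dquote(tolower(isTRUE(g$gator_pks[i])))), con)
    writeLines(qline("contig_edge",
                     dquote(tolower(isTRUE(g$contig_edge[i])))), con)
    writeLines(wrap_qualifier("translation", g$protein_seq[i]), con)
  }
  nt <- window_sequence(window)
  writeLines("ORIGIN", con)
  writeLines(format_origin(nt), con)
  writeLines("//", con)
  invisible(path)
}

dquote <- function(x) paste0("\"", x, "\"")

wrap_qualifier <- function(name, value) {
  txt <- paste0("/", name, "=\"", value, "\"")
  chunks <- substring(txt, seq(1, nchar(txt), 58), pmin(seq(58, nchar(txt) + 57, 58), nchar(txt)))
  paste0(strrep(" ", 21), chunks)
}

window_sequence <- function(window) {
  w_len <- window$span_end - window$span_start
  if (!is.null(window$seq) && !is.na(window$seq)) return(window$seq)
  strrep("n", w_len)
}

format_origin <- function(nt) {
  n <- nchar(nt)
  starts <- seq(1, n, 60)
  vapply(starts, function(s) {
    line <- substr(nt, s, min(s + 59, n))
    blocks <- substring(line, seq(1, nchar(line), 10),
                        pmin(seq(10, nchar(line) + 9, 10), nchar(line)))
    sprintf("%9d %s", s, paste(tolower(blocks), collapse = " "))
  }, "")
}

#' Write the per-run query-hit summary table
#'
#' One row per query hit: window id, query id and role, NRPS/PKS flags,
#' gene coordinates (1-based inclusive), locus tag and contig. Rows are
#' sorted by window id, then gene start.
#'
#' @param windows list of annotated `gator_window`.
#' @param out_path CSV path.
#' @return the data.frame written, invisibly.
#' @export
write_summary_table <- function(windows, out_path) {
  rows <- lapply(windows, function(w) {
    g <- w$genes
    hit <- !is.null(g$gator_query) & if (is.null(g$gator_query)) FALSE else g$gator_query != "None"
    g <- g[hit, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    data.frame(window_id = w$window_id, query_id = g$gator_hit,
               query_type = g$gator_query,
               gator_nrps = g$gator_nrps, gator_pks = g$gator_pks,
               start = g$start + 1L, end = g$end,
               strand = ifelse(g$strand > 0, "+", "-"),
               locus_tag = g$locus_tag, contig_id = g$contig_id,
               contig_edge = g$contig_edge, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(window_id = character(), query_id = character(),
               query_type = character(), gator_nrps = logical(),
               gator_pks = logical(), start = integer(), end = integer(),
               strand = character(), locus_tag = character(),
               contig_id = character(), contig_edge = logical())
  df <- df[order(df$window_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, out_path, row.names = FALSE)
  invisible(df)
}
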