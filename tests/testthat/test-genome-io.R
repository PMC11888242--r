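# GenBank parsing, coordinate conventions, protein-db headers, window
# writing and the summary table.

write_gbk <- function(lines, path = tempfile(fileext = ".gbk")) {
  writeLines(lines, path)
  path
}

gbk_record <- function(contig_id, len, features, origin = NULL) {
  c(sprintf("LOCUS       %-16s %d bp    DNA     linear   BCT 01-JAN-2000",
            contig_id, len),
    "DEFINITION  test record.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", len),
    features,
    if (!is.null(origin)) c("ORIGIN", paste("        1", origin)),
    "//")
}

cds_feature <- function(loc, ...) {
  quals <- c(...)
  c(sprintf("     CDS             %s", loc),
    if (length(quals)) sprintf('                     /%s="%s"',
                               names(quals), quals))
}

test_that("GenBank 1-based inclusive coordinates map to 0-based half-open", {
  prot <- strrep("M", 100)
  p <- write_gbk(gbk_record("c1", 1000,
                            cds_feature("101..400", translation = prot)))
  ct <- parse_genbank(p)
  expect_length(ct, 1)
  g <- ct[[1]]$genes
  expect_equal(g$start, 100L)
  expect_equal(g$end, 400L)
  expect_equal(g$strand, 1L)
  expect_equal(nchar(g$protein_seq), 100L)
  # translation qualifier is stored verbatim, never re-translated
  expect_identical(g$protein_seq, prot)
})

test_that("missing /translation falls back to table-11 translation", {
  # 300 nt = ATG + 98 GCT codons + TAA stop -> 99 aa
  nt <- paste0("ATG", strrep("GCT", 98), "TAA")
  expect_equal(nchar(nt), 300L)
  p <- write_gbk(gbk_record("c1", 400, cds_feature("51..350"),
                            origin = tolower(paste0(strrep("a", 50), nt,
                                                    strrep("a", 50)))))
  ct <- parse_genbank(p)
  g <- ct[[1]]$genes
  expect_equal(nchar(g$protein_seq), 99L)
  expect_identical(g$protein_seq, paste0("M", strrep("A", 98)))
})

test_that("complement CDS translates from the reverse strand", {
  nt <- paste0("ATG", strrep("AAA", 5), "TAA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  p <- write_gbk(gbk_record("c1", 200,
                            cds_feature(sprintf("complement(11..%d)",
                                                10 + nchar(nt))),
                            origin = tolower(paste0(strrep("g", 10), rc,
                                                    strrep("g", 190 - 10 - nchar(nt))))))
  g <- parse_genbank(p)[[1]]$genes
  expect_equal(g$strand, -1L)
  expect_identical(g$protein_seq, paste0("M", strrep("K", 5)))
})

test_that("internal-stop CDS is skipped with a warning", {
  nt <- paste0("ATG", "TAA", "GCTGCT", "TAA")   # stop after 1 codon
  p <- write_gbk(gbk_record("c1", 200, cds_feature("11..25"),
                            origin = tolower(paste0(strrep("a", 10), nt,
                                                    strrep("a", 175 - nchar(nt))))))
  expect_warning(ct <- parse_genbank(p), "internal stop|cannot translate")
  expect_equal(nrow(ct[[1]]$genes), 0L)
})

test_that("multi-record files give one contig per record, genes sorted", {
  feats <- c(cds_feature("501..800", translation = strrep("A", 100)),
             cds_feature("101..400", translation = strrep("C", 100)),
             cds_feature("901..1200", translation = strrep("D", 100)))
  p <- write_gbk(c(gbk_record("c1", 2000, feats),
                   gbk_record("c2", 2000, feats)))
  ct <- parse_genbank(p, genome_id = "gX")
  expect_length(ct, 2)
  for (c_i in ct) {
    expect_equal(nrow(c_i$genes), 3L)
    expect_true(!is.unsorted(c_i$genes$start))
  }
  expect_identical(vapply(ct, `[[`, "", "contig_id"), c("c1", "c2"))
  expect_identical(unique(vapply(ct, `[[`, "", "genome_id")), "gX")
})

test_that("unreadable or non-GenBank input raises an input error", {
  expect_error(parse_genbank(tempfile()), "cannot read")
  p <- write_gbk(c("this is", "not genbank"))
  expect_error(parse_genbank(p), "LOCUS")
})

test_that("contig-edge flagging follows the 500 bp rule and is idempotent", {
  ct <- contig("c", 10000, "g", gene_table(
    gene_id = c("a", "b", "c"), contig_id = "c",
    start = c(0, 600, 9600), end = c(300, 900, 9900), strand = 1L,
    protein_seq = "M"))
  out <- flag_contig_edges(list(ct))[[1]]$genes
  expect_identical(out$contig_edge, c(TRUE, FALSE, TRUE))
  twice <- flag_contig_edges(flag_contig_edges(list(ct)))[[1]]$genes
  expect_identical(twice$contig_edge, out$contig_edge)
  # threshold is strict: distance exactly 500 is not flagged
  ct2 <- contig("c", 10000, "g", gene_table(
    gene_id = "d", contig_id = "c", start = 500, end = 9500, strand = 1L,
    protein_seq = "M"))
  expect_false(flag_contig_edges(list(ct2))[[1]]$genes$contig_edge)
})

test_that("protein-db headers round-trip all context fields", {
  set.seed(1)
  ct <- toy_contig(5)
  db <- build_protein_db(list(ct))
  expect_equal(nrow(db), 5L)
  back <- parse_db_header(db$header)
  expect_identical(back$contig_id, db$contig_id)
  expect_identical(back$start, db$start)
  expect_identical(back$end, db$end)
  expect_identical(back$strand, db$strand)
  expect_identical(back$locus_tag, db$locus_tag)
  expect_identical(back$product, db$product)
})

test_that("empty gene list yields an empty FASTA without error", {
  ct <- contig("c", 100, "g")
  f <- tempfile(fileext = ".faa")
  db <- build_protein_db(list(ct), f)
  expect_equal(nrow(db), 0L)
  expect_true(file.exists(f))
  expect_length(readLines(f), 0L)
})

test_that("pipes in product text are sanitized and the header still parses", {
  ct <- contig("c", 5000, "g", gene_table(
    gene_id = "x", contig_id = "c", start = 100, end = 400, strand = 1L,
    locus_tag = "L1", product = "weird|product|name", protein_seq = "MKLV"))
  expect_message(db <- build_protein_db(list(ct)), "sanitized")
  back <- parse_db_header(db$header)
  expect_identical(back$product, "weird_product_name")
  expect_identical(back$locus_tag, "L1")
  expect_equal(back$start, 100L)
})

test_that("db entry order is deterministic by (genome, contig, start)", {
  set.seed(2)
  c1 <- toy_contig(3, contig_id = "b", genome_id = "g2")
  c2 <- toy_contig(3, contig_id = "a", genome_id = "g1")
  db <- build_protein_db(list(c1, c2))
  expect_identical(db$genome_id, c(rep("g1", 3), rep("g2", 3)))
  expect_true(!is.unsorted(db$start[1:3]))
})

test_that("written window GenBank round-trips genes and qualifiers", {
  fix <- mined_fixture()
  w <- fix$res$windows[[1]]
  d <- tempfile()
  path <- write_window_genbank(w, d)
  back <- suppressMessages(parse_genbank(path))
  expect_length(back, 1)
  expect_equal(nrow(back[[1]]$genes), nrow(w$genes))
  txt <- readLines(path)
  # every CDS carries the annotation qualifiers
  n_cds <- sum(grepl("^     CDS ", txt))
  expect_equal(n_cds, nrow(w$genes))
  expect_equal(sum(grepl("/gator_query=", txt)), n_cds)
  expect_equal(sum(grepl("/gator_nrps=", txt)), n_cds)
  expect_equal(sum(grepl("/gator_pks=", txt)), n_cds)
  expect_equal(sum(grepl("/contig_edge=", txt)), n_cds)
  # gator_hit only on hit genes, with the query id as value
  hits <- regmatches(txt, regexec('/gator_hit="([^"]+)"', txt))
  hit_vals <- vapply(hits[lengths(hits) > 0], `[`, "", 2)
  expect_setequal(hit_vals, w$genes$gator_hit[!is.na(w$genes$gator_hit)])
  # required anchor is labelled required
  expect_true(any(grepl('/gator_query="required"', txt)))
  # re-based coordinates: first gene starts within the window span
  expect_true(all(back[[1]]$genes$end <= w$span_end - w$span_start))
})

test_that("summary table is sorted by window id then gene start", {
  fix <- mined_fixture()
  out <- tempfile(fileext = ".csv")
  df <- write_summary_table(fix$res$windows, out)
  expect_true(!is.unsorted(match(df$window_id, unique(df$window_id))))
  for (wid in unique(df$window_id))
    expect_true(!is.unsorted(df$start[df$window_id == wid]))
  expect_true(file.exists(out))
  # every row is a query hit
  expect_true(all(df$query_type %in% c("required", "optional")))
  # empty input -> header-only CSV
  empty <- write_summary_table(list(), out)
  expect_equal(nrow(empty), 0L)
  expect_equal(length(readLines(out)), 1L)
})
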