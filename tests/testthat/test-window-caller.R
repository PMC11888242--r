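# Distance estimation, window calling against a brute-force oracle, and
# window annotation.

test_that("distance percentile matches a sorted-array interpolation oracle", {
  # one 2-gene cluster per pooled distance value: gaps 0, 10, ..., 990
  gaps <- seq(0, 990, by = 10)
  clusters <- lapply(gaps, function(d)
    data.frame(start = c(0, 100 + d), end = c(100, 200 + d)))
  expect_equal(estimate_default_distance(clusters, 95), 940.5)
  # independent oracle on random pools
  set.seed(5)
  for (i in 1:5) {
    g <- sample(0:5000, 30)
    cl <- lapply(g, function(d)
      data.frame(start = c(0, 100 + d), end = c(100, 200 + d)))
    p <- sample(c(50, 90, 95, 99), 1)
    s <- sort(g)
    h <- (length(s) - 1) * p / 100 + 1
    oracle <- s[floor(h)] + (h - floor(h)) *
      (s[min(ceiling(h), length(s))] - s[floor(h)])
    expect_equal(estimate_default_distance(cl, p), oracle)
  }
})

test_that("constant distance pools return that distance; empty pools error", {
  cl <- list(data.frame(start = c(0, 350), end = c(100, 450)))
  expect_equal(estimate_default_distance(cl), 250)
  expect_error(estimate_default_distance(list()), "no gene pairs")
  expect_error(estimate_default_distance(
    list(data.frame(start = 0, end = 10))), "no gene pairs")
})

test_that("all within-cluster pairs are pooled, not only adjacent ones", {
  # 3 genes: gaps 100 (1-2), 200 (2-3), 400 (1-3 span gap)
  cl <- list(data.frame(start = c(0, 200, 500), end = c(100, 300, 600)))
  # pairwise gaps: (1,2)=100, (2,3)=200, (1,3)=400
  expect_equal(estimate_default_distance(cl, 100), 400)
  expect_equal(estimate_default_distance(cl, 50), 200)
})

two_hit_contig <- function(gap_bp, contig_id = "c1", genome_id = "g1") {
  # two 1 kb genes separated by gap_bp, plus margins
  starts <- c(20000, 21000 + gap_bp)
  ct <- contig(contig_id, 60000 + gap_bp, genome_id, gene_table(
    gene_id = paste0(genome_id, contig_id, c("A", "B")),
    contig_id = contig_id, start = starts, end = starts + 1000,
    strand = 1L, protein_seq = "M"))
  ct
}

test_that("two required hits chain within the cutoff and gain 10 kb flanks", {
  ct <- two_hit_contig(40000)
  dict <- list(qA = "g1c1A", qB = "g1c1B")
  w <- call_windows(list(ct), dict, c("qA", "qB"))
  expect_length(w, 1)
  expect_equal(w[[1]]$span_start, 20000 - 10000)
  expect_equal(w[[1]]$span_end, 21000 + 40000 + 1000 + 10000)
  expect_equal(nrow(w[[1]]$genes), 2L)
  # beyond the default cutoff: no window
  ct2 <- two_hit_contig(90000)
  expect_length(call_windows(list(ct2), dict, c("qA", "qB")), 0)
  # exactly at the cutoff: still one window
  ct3 <- two_hit_contig(85900)
  expect_length(call_windows(list(ct3), dict, c("qA", "qB")), 1)
})

test_that("required hits split across contigs never form a window", {
  c1 <- two_hit_contig(1000, contig_id = "c1")
  c2 <- two_hit_contig(1000, contig_id = "c2")
  dict <- list(qA = "g1c1A", qB = "g1c2B")
  expect_length(call_windows(list(c1, c2), dict, c("qA", "qB")), 0)
})

test_that("window extension changes spans but never window counts", {
  fix <- mined_fixture()
  syn <- fix$syn
  dict <- make_truth_dict(syn)
  req <- syn$queries$query_id[syn$queries$role == "required"]
  opt <- syn$queries$query_id[syn$queries$role == "optional"]
  w0 <- call_windows(syn$contigs, dict, req, opt,
                     window_params(window_extension = 0))
  w10 <- call_windows(syn$contigs, dict, req, opt,
                      window_params(window_extension = 10000))
  expect_equal(length(w0), length(w10))
  for (i in seq_along(w0)) {
    expect_lte(w10[[i]]$span_start, w0[[i]]$span_start)
    expect_gte(w10[[i]]$span_end, w0[[i]]$span_end)
  }
})

test_that("planted clusters are recovered; decoys are not", {
  fix <- mined_fixture()
  syn <- fix$syn
  dict <- make_truth_dict(syn)
  req <- syn$queries$query_id[syn$queries$role == "required"]
  w <- call_windows(syn$contigs, dict, req,
                    syn$queries$query_id[syn$queries$role == "optional"])
  expect_equal(length(w), sum(syn$truth$windows$is_window))
  # no window on the decoy genome
  decoy_g <- syn$truth$windows$genome_id[syn$truth$windows$locus_type == "decoy"]
  expect_false(any(vapply(w, `[[`, "", "genome_id") %in% decoy_g))
})

test_that("calling equals the brute-force oracle on random genomes", {
  set.seed(101)
  for (rep in 1:8) {
    n <- sample(20:60, 1)
    ct <- toy_contig(n, gene_len = 500, gap = sample(200:3000, 1))
    ids <- ct$genes$gene_id
    dict <- list(qA = sample(ids, sample(2:5, 1)),
                 qB = sample(ids, sample(2:5, 1)))
    cutoff <- sample(c(500, 2000, 5000, 20000), 1)
    called <- call_windows(list(ct), dict, c("qA", "qB"),
                           params = window_params(required_distance = cutoff,
                                                  window_extension = 0),
                           merge_overlapping = FALSE)
    got <- set_sort(called_core_sets(called, dict, c("qA", "qB")))
    want <- set_sort(brute_force_windows(list(ct), dict, c("qA", "qB"),
                                         cutoff))
    expect_equal(got, want)
  }
})

test_that("raising the distance cutoff only grows windows", {
  set.seed(33)
  ct <- toy_contig(40, gene_len = 500, gap = 1500)
  ids <- ct$genes$gene_id
  dict <- list(qA = sample(ids, 6), qB = sample(ids, 6))
  cover <- function(cutoff) {
    w <- call_windows(list(ct), dict, c("qA", "qB"),
                      params = window_params(required_distance = cutoff,
                                             window_extension = 0))
    unique(unlist(lapply(w, function(x) x$genes$gene_id)))
  }
  small <- cover(2000); big <- cover(10000)
  expect_true(all(small %in% big))
})

test_that("window calling is deterministic", {
  fix <- mined_fixture()
  syn <- fix$syn
  dict <- make_truth_dict(syn)
  req <- syn$queries$query_id[syn$queries$role == "required"]
  w1 <- call_windows(syn$contigs, dict, req)
  w2 <- call_windows(syn$contigs, dict, req)
  expect_identical(vapply(w1, `[[`, "", "window_id"),
                   vapply(w2, `[[`, "", "window_id"))
  expect_identical(lapply(w1, function(w) w$genes$gene_id),
                   lapply(w2, function(w) w$genes$gene_id))
})

test_that("overlapping extended spans merge into one window", {
  # two separate required pairs 30 kb apart; with a huge extension their
  # extended spans overlap and merge
  starts <- c(10000, 11500, 45000, 46500)
  ct <- contig("c1", 90000, "g1", gene_table(
    gene_id = paste0("G", 1:4), contig_id = "c1", start = starts,
    end = starts + 1000, strand = 1L, protein_seq = "M"))
  dict <- list(qA = c("G1", "G3"), qB = c("G2", "G4"))
  p <- window_params(required_distance = 5000, window_extension = 20000)
  merged <- call_windows(list(ct), dict, c("qA", "qB"), params = p)
  expect_length(merged, 1)
  apart <- call_windows(list(ct), dict, c("qA", "qB"), params = p,
                        merge_overlapping = FALSE)
  expect_length(apart, 2)
})

test_that("annotation resolves multi-query genes by precedence", {
  set.seed(8)
  ct <- toy_contig(5)
  ids <- ct$genes$gene_id
  dict <- list(r1 = ids[2], r2 = ids[4], o1 = c(ids[2], ids[5]),
               o2 = ids[5])
  hits <- data.frame(query_id = c("o1", "o2"), subject_id = ids[5],
                     pct_identity = 90, query_cover = 90, evalue = 1e-20,
                     bit_score = c(50, 120), q_start = 1, q_end = 50,
                     s_start = 1, s_end = 50, stringsAsFactors = FALSE)
  w <- call_windows(list(ct), dict, c("r1", "r2"), c("o1", "o2"),
                    window_params(required_distance = 1e6,
                                  window_extension = 1e6))[[1]]
  w <- suppressMessages(annotate_window(
    w, categories = c(stats::setNames("HYBRID", ids[2])),
    homology_hits = hits))
  g <- w$genes
  # required beats optional on gene 2
  expect_identical(g$gator_query[2], "required")
  expect_identical(g$gator_hit[2], "r1")
  # within-role tie on gene 5 broken by bit score (o2 has 120)
  expect_identical(g$gator_hit[5], "o2")
  expect_identical(g$gator_query[1], "None")
  expect_true(is.na(g$gator_hit[1]))
  # hybrid category sets both modular booleans
  expect_true(g$gator_nrps[2] && g$gator_pks[2])
  expect_false(g$gator_nrps[1] || g$gator_pks[1])
})
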