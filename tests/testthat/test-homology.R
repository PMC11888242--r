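# Hit-table ingestion, the built-in search oracle, modular-domain
# classification and the query dictionary.

tab_row <- function(q, s, pid, len = 100, qs = 1, qe = 100, ss = 1, se = 100,
                    ev = 1e-30, bit = 200, qcov = NULL) {
  f <- c(q, s, pid, len, 2, 0, qs, qe, ss, se, ev, bit)
  if (!is.null(qcov)) f <- c(f, qcov)
  paste(f, collapse = "\t")
}

test_that("tabular hits are filtered at the identity/coverage defaults", {
  p <- tempfile()
  writeLines(c(
    tab_row("q1", "s1", 34.9, qcov = 80),     # below identity default
    tab_row("q1", "s2", 100, qcov = 100),     # self-hit, retained
    tab_row("q1", "s3", 35, qcov = 70),       # exactly at both thresholds
    tab_row("q1", "s4", 80, qcov = 69.9),     # below coverage
    tab_row("q2", "s5", 50, qcov = 90),
    tab_row("q2", "s6", 20, qcov = 20),
    tab_row("q2", "s7", 90, qcov = 95),
    tab_row("q2", "s8", 36, qcov = 50),
    tab_row("q3", "s9", 40, qcov = 75),
    tab_row("q3", "s1", 99, qcov = 99)), p)
  h <- load_tabular_hits(p)
  expect_equal(nrow(h), 6L)   # 4 of 10 fail the defaults
  expect_false("s1" %in% h$subject_id[h$query_id == "q1"])
  expect_true("s2" %in% h$subject_id)
  expect_true("s3" %in% h$subject_id)   # thresholds are inclusive
  # raising thresholds never adds hits (monotonicity)
  for (thr in list(c(70, 50), c(90, 35), c(90, 50))) {
    h2 <- load_tabular_hits(p, min_qcov = thr[1], min_pid = thr[2])
    expect_true(all(paste(h2$query_id, h2$subject_id) %in%
                      paste(h$query_id, h$subject_id)))
    expect_lte(nrow(h2), nrow(h))
  }
})

test_that("coverage is derived from query lengths for 12-column tables", {
  p <- tempfile()
  writeLines(tab_row("q1", "s1", 80, qs = 1, qe = 80), p)
  h <- load_tabular_hits(p, query_lengths = c(q1 = 100))
  expect_equal(h$query_cover, 80)
  expect_error(load_tabular_hits(p), "query_lengths")
})

test_that("malformed tabular rows are skipped with a warning", {
  p <- tempfile()
  writeLines(c(tab_row("q1", "s1", 90, qcov = 90), "broken\trow"), p)
  expect_warning(h <- load_tabular_hits(p), "malformed")
  expect_equal(nrow(h), 1L)
})

domtbl_row <- function(prot, profile, ev, score = 100, es = 1, ee = 50) {
  paste(c(prot, "-", 500, profile, "-", 60, 1e-40, 300, 1, 1, 1,
          1e-40, ev, score, 0.5, 1, 60, 1, 50, es, ee, 0.9), collapse = " ")
}

test_that("domain hits respect the e-value threshold and profile map", {
  p <- tempfile()
  writeLines(c("# comment",
               domtbl_row("p1", "AMP-binding", 1e-3),      # above threshold
               domtbl_row("p1", "AMP-binding", 0.0),       # best case kept
               domtbl_row("p1", "Condensation", 1e-10),
               domtbl_row("p2", "PKS_AT", 1e-6),
               domtbl_row("p2", "ketoacyl-synt", 1e-9),
               domtbl_row("p3", "NotAProfile", 1e-9)), p)
  expect_message(d <- load_domain_hits(p), "NotAProfile")
  expect_equal(nrow(d), 4L)
  expect_setequal(d$domain[d$protein_id == "p1"], c("A", "C"))
  expect_setequal(d$domain[d$protein_id == "p2"], c("AT", "KS"))
  expect_false(any(d$evalue > 1e-4))
})

test_that("domain-count fixture yields one hit per qualifying row", {
  p <- tempfile()
  writeLines(c(domtbl_row("x1", "A", 1e-9), domtbl_row("x2", "A", 1e-9),
               domtbl_row("x3", "A", 1e-9), domtbl_row("x4", "C", 1e-9),
               domtbl_row("x5", "C", 1e-9), domtbl_row("x6", "AT", 1e-9)), p)
  d <- load_domain_hits(p)
  expect_equal(nrow(d), 6L)
  expect_equal(as.vector(table(d$domain)[c("A", "C", "AT")]), c(3L, 2L, 1L))
})

test_that("built-in search reports identity alignments at 100/100", {
  set.seed(42)
  db <- c(a = rand_prot(80), b = rand_prot(120), c = rand_prot(60))
  h <- builtin_search(db["a"], db)
  self <- h[h$subject_id == "a", ]
  expect_equal(nrow(self), 1L)
  expect_equal(self$pct_identity, 100)
  expect_equal(self$query_cover, 100)
  expect_equal(self$s_start, 1)
  expect_equal(self$s_end, 80)
})

test_that("a query matching half of a subject has full query coverage", {
  set.seed(7)
  subj <- rand_prot(200)
  q <- substr(subj, 1, 100)
  h <- builtin_search(c(q1 = q), c(s1 = subj))
  expect_equal(nrow(h), 1L)
  expect_equal(h$pct_identity, 100)
  expect_equal(h$query_cover, 100)
  expect_equal(h$s_start, 1)
  expect_equal(h$s_end, 100)
})

test_that("unrelated random proteins produce no passing hit", {
  set.seed(9)
  h <- builtin_search(c(q = rand_prot(100)), c(s = rand_prot(100)))
  expect_equal(nrow(h), 0L)
})

test_that("every database protein self-hits at 100/100", {
  set.seed(11)
  db <- stats::setNames(vapply(sample(50:120, 8, TRUE), rand_prot, ""),
                        paste0("p", 1:8))
  h <- builtin_search(db, db)
  for (id in names(db)) {
    self <- h[h$query_id == id & h$subject_id == id, ]
    expect_equal(nrow(self), 1L)
    expect_equal(self$pct_identity, 100)
    expect_equal(self$query_cover, 100)
  }
})

test_that("tabular serialization round-trips the built-in search output", {
  set.seed(3)
  base <- rand_prot(90)
  db <- c(p1 = base, p2 = mutate_protein(base, 60, seed = 1),
          p3 = rand_prot(90))
  h <- builtin_search(db, db, min_qcov = 50, min_pid = 30)
  p <- tempfile()
  write_tabular_hits(h, p)
  h2 <- load_tabular_hits(p, min_qcov = 50, min_pid = 30)
  expect_equal(nrow(h2), nrow(h))
  expect_identical(h2$query_id, h$query_id)
  expect_identical(h2$subject_id, h$subject_id)
  expect_equal(h2$pct_identity, h$pct_identity, tolerance = 1e-3)
  expect_equal(h2$query_cover, h$query_cover, tolerance = 1e-3)
  expect_equal(h2$bit_score, h$bit_score, tolerance = 1e-2)
})

test_that("modular classification matches the NRPS/PKS/hybrid rules", {
  domains <- c("A", "C", "AT", "KS")
  for (mask in 0:15) {
    present <- domains[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0]
    nrps <- all(c("A", "C") %in% present)
    pks <- all(c("AT", "KS") %in% present)
    want <- if (nrps && pks) "HYBRID" else if (nrps) "NRPS" else
      if (pks) "PKS" else "NONE"
    expect_identical(classify_modularity(present), want)
    # order independence and idempotence on duplicated evidence
    expect_identical(classify_modularity(rev(rep(present, 2))), want)
  }
})

test_that("query screening partitions modular from plain queries", {
  q <- data.frame(query_id = c("nrps1", "pks1", "plain1", "plain2"),
                  sequence = strrep("M", 50), role = "required",
                  stringsAsFactors = FALSE)
  dom <- data.frame(protein_id = c("nrps1", "nrps1", "pks1", "pks1"),
                    domain = c("A", "C", "AT", "KS"),
                    evalue = 1e-9, score = 100, env_start = 1L,
                    env_end = 40L, stringsAsFactors = FALSE)
  s <- screen_queries(q, dom)
  expect_equal(nrow(s$modular), 2L)
  expect_equal(nrow(s$non_modular), 2L)
  expect_identical(s$queries$category,
                   c("NRPS", "PKS", "NONE", "NONE"))
})

test_that("hit dictionary maps by similarity or by category membership", {
  q <- data.frame(query_id = c("nq", "pq", "hq", "plain"),
                  sequence = strrep("M", 50), role = "required",
                  category = c("NRPS", "PKS", "HYBRID", "NONE"),
                  stringsAsFactors = FALSE)
  cats <- c(g1 = "NRPS", g2 = "NRPS", g3 = "NRPS", g4 = "PKS", g5 = "PKS",
            g6 = "HYBRID", g7 = "NONE")
  hits <- data.frame(query_id = c("plain", "plain"),
                     subject_id = c("g7", "g1"),
                     pct_identity = 90, query_cover = 90, evalue = 1e-30,
                     bit_score = 100, q_start = 1, q_end = 50, s_start = 1,
                     s_end = 50, stringsAsFactors = FALSE)
  d <- build_hit_dictionary(q, hits, cats)
  expect_setequal(d$nq, c("g1", "g2", "g3", "g6"))   # NRPS + hybrid
  expect_setequal(d$pq, c("g4", "g5", "g6"))
  expect_setequal(d$hq, "g6")                        # hybrids only
  expect_setequal(d$plain, c("g7", "g1"))
  strict <- build_hit_dictionary(q, hits, cats, hybrid_mode = "strict")
  expect_setequal(strict$nq, c("g1", "g2", "g3"))
  # a query with zero subjects is allowed
  cats0 <- c(g1 = "NONE")
  d0 <- build_hit_dictionary(q[q$query_id == "nq", ], empty_hits_df(), cats0)
  expect_length(d0$nq, 0L)
})

empty_hits_df <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), query_cover = numeric(),
             evalue = numeric(), bit_score = numeric(), q_start = numeric(),
             q_end = numeric(), s_start = numeric(), s_end = numeric())
}

test_that("filter thresholds are monotone on the built-in search too", {
  set.seed(21)
  base <- rand_prot(100)
  db <- c(a = base, b = mutate_protein(base, 60, seed = 2),
          c = mutate_protein(base, 40, seed = 3), d = rand_prot(100))
  h_loose <- builtin_search(db, db, min_qcov = 50, min_pid = 30)
  h_tight <- builtin_search(db, db, min_qcov = 80, min_pid = 50)
  expect_lte(nrow(h_tight), nrow(h_loose))
  expect_true(all(paste(h_tight$query_id, h_tight$subject_id) %in%
                    paste(h_loose$query_id, h_loose$subject_id)))
})
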