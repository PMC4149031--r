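# Significance thresholds, all-vs-all search, reciprocal best hits, and
# ORFan classification.

mk_hit <- function(e_value, alignment_length, identity_pct = 90,
                   bit_score = 100, query_id = "q1", subject_id = "s1",
                   query_coverage = 1, subject_coverage = 1) {
  data.frame(query_id = query_id, subject_id = subject_id,
             e_value = e_value, alignment_length = alignment_length,
             identity_pct = identity_pct, bit_score = bit_score,
             query_coverage = query_coverage,
             subject_coverage = subject_coverage,
             stringsAsFactors = FALSE)
}

test_that("is_significant applies the two-tier E-value/length rule", {
  cases <- data.frame(
    e = c(1e-4, 1e-4, 1e-6, 1e-3, 1e-5, 9.9e-4, 9.9e-6, 1e-2),
    len = c(100L, 60L, 10L, 100L, 80L, 81L, 80L, 200L),
    want = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  for (i in seq_len(nrow(cases)))
    expect_equal(is_significant(mk_hit(cases$e[i], cases$len[i])),
                 cases$want[i], info = paste(cases$e[i], cases$len[i]))
  # vectorized over a table
  expect_equal(is_significant(mk_hit(cases$e, cases$len)), cases$want)
})

test_that("all_vs_all finds the perfect hit between identical genes", {
  set.seed(9)
  cds <- random_cds(300)
  a <- toy_geneset("ga", c(ga_1 = cds))
  b <- toy_geneset("gb", c(gb_1 = cds))
  for (mode in c("kmer", "exact")) {
    hits <- all_vs_all(a, b, mode = mode)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$identity_pct, 100)
    expect_equal(hits$query_coverage, 1)
    expect_equal(hits$subject_coverage, 1)
    expect_equal(hits$alignment_length, 100L)
    expect_lt(hits$e_value, 1e-5)
  }
})

test_that("k-mer prefilter reproduces exact-mode significant hits", {
  set.seed(19)
  for (rep in seq_len(5)) {
    sim <- simulate_pair(simulation_config(
      n_genes = 3L, gene_length_range = c(240L, 420L), p_sub = 0.15,
      seed = 1000L + rep))
    ex <- all_vs_all(sim$geneset_a, sim$geneset_b, mode = "exact",
                     min_evalue_keep = 1e-5)
    km <- all_vs_all(sim$geneset_a, sim$geneset_b, mode = "kmer",
                     min_evalue_keep = 1e-5)
    key <- function(h) sort(paste(h$query_id, h$subject_id))
    expect_equal(key(km), key(ex))
  }
  # unrelated random genes share no 5-mers at desk scale: no hits at all
  set.seed(29)
  a <- toy_geneset("ga", c(ga_1 = random_cds(300)))
  b <- toy_geneset("gb", c(gb_1 = random_cds(300)))
  expect_equal(nrow(all_vs_all(a, b, mode = "kmer")), 0L)
})

test_that("reciprocal_best_hits matches the brute-force oracle", {
  # deterministic elementary cases first
  mutual <- mk_hit(1e-8, 150)
  expect_equal(reciprocal_best_hits(mutual),
               data.frame(gene_a = "q1", gene_b = "s1",
                          stringsAsFactors = FALSE),
               ignore_attr = TRUE)
  none <- mk_hit(1e-2, 150)
  expect_equal(nrow(reciprocal_best_hits(none)), 0L)
  # a1's best is b1 but b1 prefers a2: nobody pairs with a1 or b1
  broken <- rbind(
    mk_hit(1e-8, 150, bit_score = 100, query_id = "a1", subject_id = "b1"),
    mk_hit(1e-9, 150, bit_score = 200, query_id = "a2", subject_id = "b1"),
    mk_hit(1e-9, 150, bit_score = 300, query_id = "a2", subject_id = "b2"))
  got <- reciprocal_best_hits(broken)
  expect_equal(got$gene_a, "a2")
  expect_equal(got$gene_b, "b2")

  set.seed(77)
  for (rep in seq_len(300)) {
    hits <- random_hit_table()
    got <- reciprocal_best_hits(hits)
    want <- oracle_rbh(hits)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("rep", rep))
  }
})

test_that("RBH output is symmetric, 1:1, and bounded by genome size", {
  set.seed(88)
  for (rep in seq_len(200)) {
    hits <- random_hit_table()
    fwd <- reciprocal_best_hits(hits)
    swapped <- hits
    names(swapped)[names(swapped) == "query_id"] <- "tmp"
    names(swapped)[names(swapped) == "subject_id"] <- "query_id"
    names(swapped)[names(swapped) == "tmp"] <- "subject_id"
    qc <- swapped$query_coverage
    swapped$query_coverage <- swapped$subject_coverage
    swapped$subject_coverage <- qc
    rev <- reciprocal_best_hits(swapped)
    expect_equal(sort(paste(fwd$gene_a, fwd$gene_b)),
                 sort(paste(rev$gene_b, rev$gene_a)))
    expect_false(any(duplicated(fwd$gene_a)))
    expect_false(any(duplicated(fwd$gene_b)))
    expect_lte(nrow(fwd), min(length(unique(hits$query_id)),
                              length(unique(hits$subject_id))))
  }
})

test_that("RBH recovers the full truth map at low divergence", {
  sim <- simulate_pair(simulation_config(
    n_genes = 25L, gene_length_range = c(300L, 600L), p_sub = 0.05,
    seed = 5L))
  hits <- all_vs_all(sim$geneset_a, sim$geneset_b)
  pairs <- reciprocal_best_hits(hits)
  expect_equal(nrow(pairs), 25L)
  truth <- sim$truth$ortholog_map
  expect_equal(sort(paste(pairs$gene_a, pairs$gene_b)),
               sort(paste(truth$gene_a, truth$gene_b)))
})

test_that("classify_orfans flags genes without significant hits", {
  set.seed(31)
  gs <- toy_geneset("g", c(g_1 = random_cds(300), g_2 = random_cds(300),
                           g_3 = random_cds(300)))
  hits <- rbind(
    mk_hit(1e-2, 200, query_id = "g_1", subject_id = "ref1"),  # weak
    mk_hit(1e-4, 100, query_id = "g_2", subject_id = "ref2"))  # strong
  # g_1 has only an insignificant hit, g_3 has none: both ORFans
  expect_equal(classify_orfans(gs, hits), c("g_1", "g_3"))
  expect_error(classify_orfans(gs, mk_hit(1e-4, 100, query_id = "zz")),
               "absent")
})
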