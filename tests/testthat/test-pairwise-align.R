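# Global/local alignment against enumeration oracles, alignment-result
# invariants, and Karlin-Altschul E-values.

nt <- scoring_scheme("nucleotide")

test_that("nw_align handles the elementary identity and mismatch cases", {
  a <- nw_align("ACGT", "ACGT", nt)
  expect_equal(a$identity_pct, 100)
  expect_equal(a$columns, 4L)
  expect_equal(a$score, 20)

  b <- nw_align("ACGT", "ACGA", nt)
  expect_equal(b$identities, 3L)
  expect_equal(b$columns, 4L)
  expect_equal(b$identity_pct, 75)
})

test_that("nw_align score equals the enumeration oracle on short pairs", {
  set.seed(101)
  schemes <- list(nt, scoring_scheme("nucleotide", match = 2,
                                     mismatch = -1, gap_open = 3,
                                     gap_extend = 1))
  n_cases <- 0L
  for (rep in seq_len(150)) {
    la <- sample.int(8L, 1L)
    lb <- sample.int(8L, 1L)
    a <- random_seq(la)
    b <- random_seq(lb)
    for (sch in schemes) {
      expect_equal(nw_align(a, b, sch)$score, oracle_nw_score(a, b, sch),
                   info = paste(a, b))
      n_cases <- n_cases + 1L
    }
  }
  expect_gte(n_cases, 300L)
})

test_that("sw_align matches the elementary cases and substring oracle", {
  s <- sw_align("AAATTTAAA", "TTT", nt)
  expect_equal(s$score, 15)
  expect_equal(s$aligned_a, "TTT")
  expect_equal(s$aligned_b, "TTT")

  s0 <- sw_align("AAAA", "GGGG",
                 scoring_scheme("nucleotide", match = 1, mismatch = -3))
  expect_equal(s0$score, 0)
  expect_equal(s0$columns, 0L)
  expect_true(is.na(s0$identity_pct))

  set.seed(202)
  for (rep in seq_len(40)) {
    a <- random_seq(sample.int(6L, 1L))
    b <- random_seq(sample.int(6L, 1L))
    expect_equal(sw_align(a, b, nt)$score, oracle_sw_score(a, b, nt),
                 info = paste(a, b))
  }
})

test_that("alignment results satisfy their structural invariants", {
  set.seed(303)
  for (rep in seq_len(50)) {
    a <- random_seq(sample(3:30, 1L), c("A", "C", "G", "T"))
    b <- random_seq(sample(3:30, 1L), c("A", "C", "G", "T"))
    for (aln in list(nw_align(a, b, nt), sw_align(a, b, nt))) {
      expect_equal(nchar(aln$aligned_a), aln$columns)
      expect_equal(nchar(aln$aligned_b), aln$columns)
      if (aln$type == "global") {
        expect_gte(aln$columns, max(nchar(a), nchar(b)))
        expect_equal(gsub("-", "", aln$aligned_a), a)
        expect_equal(gsub("-", "", aln$aligned_b), b)
      } else if (aln$columns > 0L) {
        expect_equal(gsub("-", "", aln$aligned_a),
                     substr(a, aln$a_start, aln$a_end))
        expect_equal(gsub("-", "", aln$aligned_b),
                     substr(b, aln$b_start, aln$b_end))
      }
      if (aln$columns > 0L) {
        ca <- strsplit(aln$aligned_a, "")[[1]]
        cb <- strsplit(aln$aligned_b, "")[[1]]
        expect_false(any(ca == "-" & cb == "-"))
        expect_gte(aln$identity_pct, 0)
        expect_lte(aln$identity_pct, 100)
        expect_equal(aln$identities, sum(ca == cb & ca != "-"))
      }
    }
  }
})

test_that("alignment scores are symmetric and local >= global", {
  set.seed(404)
  for (rep in seq_len(30)) {
    a <- random_seq(sample(2:20, 1L))
    b <- random_seq(sample(2:20, 1L))
    expect_equal(nw_align(a, b, nt)$score, nw_align(b, a, nt)$score)
    expect_equal(sw_align(a, b, nt)$score, sw_align(b, a, nt)$score)
    expect_gte(sw_align(a, b, nt)$score, nw_align(a, b, nt)$score)
  }
})

test_that("self-alignment is 100% identical; shared prefixes help", {
  set.seed(505)
  for (rep in seq_len(20)) {
    a <- random_seq(sample(1:25, 1L), c("A", "C", "G", "T"))
    expect_equal(nw_align(a, a, nt)$identity_pct, 100)
    b <- random_seq(sample(1:10, 1L))
    c <- random_seq(sample(1:10, 1L))
    pre <- random_seq(sample(1:8, 1L))
    expect_gte(nw_align(paste0(pre, b), paste0(pre, c), nt)$identities,
               nw_align(b, c, nt)$identities)
  }
})

test_that("mixed or invalid alphabets are rejected", {
  expect_error(nw_align("ACGT", "MKLV", nt), "outside the nucleotide")
  expect_error(nw_align("", "ACGT", nt), "empty")
  prot <- scoring_scheme("protein")
  expect_error(sw_align("MKLV", "ACGZ!", prot), "outside the protein")
  expect_silent(sw_align("MKLVMKLV", "MKLV", prot))
})

test_that("evalue follows the Karlin-Altschul closed form", {
  p1 <- karlin_altschul_params(m = 300, n = 1e5)
  p2 <- karlin_altschul_params(m = 300, n = 2e5)
  expect_equal(evalue(60, p2), 2 * evalue(60, p1))
  # fixed point: lambda * S = ln(K m n) gives E = 1
  s_star <- log(p1$K * p1$m * p1$n) / p1$lambda
  expect_equal(evalue(s_star, p1), 1)
  # frozen arbitrary-precision evaluation of K m n exp(-lambda S)
  expect_equal(evalue(60, p1), 0.1356773996209989, tolerance = 1e-12)
  # strictly decreasing in S
  ss <- seq(0, 100, by = 5)
  expect_true(all(diff(vapply(ss, evalue, numeric(1),
                              params = p1)) < 0))
})

test_that("identity denominator options differ only via gap columns", {
  aln <- nw_align("ACGTACGT", "ACGT", nt)
  expect_equal(alignment_identity(aln, "all"),
               100 * aln$identities / aln$columns)
  expect_equal(alignment_identity(aln, "aligned"),
               100 * aln$identities / aln$aligned_columns)
  expect_gte(alignment_identity(aln, "aligned"),
             alignment_identity(aln, "all"))
})
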