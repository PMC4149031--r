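# Genome summary statistics, 16S identity and delineation, COG tables.

test_that("genome_size sums contig lengths including N", {
  asm <- assembly("g", c(c1 = strrep("A", 100), c2 = strrep("N", 250)))
  expect_equal(genome_size(asm), 350L)
  expect_error(assembly("g", c(c1 = "")), "empty contig")
})

test_that("gc_content excludes ambiguity codes from both terms", {
  expect_equal(gc_content(assembly("g", c(c = "GGCC"))), 100)
  expect_equal(gc_content(assembly("g", c(c = "ATGC"))), 50)
  expect_equal(gc_content(assembly("g", c(c = "ATGCNN"))), 50)
  expect_error(gc_content(assembly("g", c(c = "NNNN"))),
               "no unambiguous")
})

test_that("gc_content is invariant under reverse complement", {
  set.seed(11)
  for (rep in seq_len(10)) {
    s <- random_seq(sample(50:500, 1), c("A", "C", "G", "T", "N"))
    rc <- chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]),
                                         collapse = ""))
    expect_equal(gc_content(assembly("g", c(c = s))),
                 gc_content(assembly("g", c(c = rc))))
  }
})

test_that("coding_density takes the union of CDS intervals", {
  asm <- assembly("g", c(c1 = strrep("A", 20)))
  gs <- gene_set("g", c(g1 = strrep("A", 9), g2 = strrep("A", 9)),
                 c(g1 = "KKK", g2 = "KKK"),
                 coords = data.frame(gene_id = c("g1", "g2"),
                                     contig = "c1", start = c(1L, 5L),
                                     end = c(10L, 14L),
                                     strand = c("+", "-")))
  cd <- coding_density(asm, gs)
  expect_equal(cd$coding_bp, 14L)
  expect_equal(cd$coding_pct, 70)

  # non-overlapping genes: sum of lengths
  gs2 <- gs
  gs2$coords$start <- c(1L, 15L)
  gs2$coords$end <- c(10L, 20L)
  expect_equal(coding_density(asm, gs2)$coding_bp, 16L)

  # no genes
  gs3 <- gs
  gs3$coords <- NULL
  expect_equal(coding_density(asm, gs3)$coding_bp, 0L)

  # out of bounds names the gene
  gs4 <- gs
  gs4$coords$end[2] <- 99L
  expect_error(coding_density(asm, gs4), "g2")
})

test_that("coding_bp equals a per-base membership oracle", {
  set.seed(21)
  for (rep in seq_len(10)) {
    clen <- sample(200:1000, 1)
    asm <- assembly("g", c(c1 = strrep("A", clen)))
    ng <- sample(1:12, 1)
    starts <- sample(seq_len(clen - 30L), ng, replace = TRUE)
    ends <- pmin(clen, starts + sample(10:200, ng, replace = TRUE))
    co <- data.frame(gene_id = sprintf("g%d", seq_len(ng)),
                     contig = "c1", start = starts, end = ends,
                     strand = "+")
    gs <- gene_set("g", setNames(rep(strrep("A", 9), ng), co$gene_id),
                   setNames(rep("KKK", ng), co$gene_id), coords = co)
    covered <- logical(clen)
    for (i in seq_len(ng)) covered[starts[i]:ends[i]] <- TRUE
    expect_equal(coding_density(asm, gs)$coding_bp, sum(covered))
  }
})

test_that("sixteen_s_identity reflects point divergence", {
  set.seed(31)
  s <- random_seq(1000, c("A", "C", "G", "T"))
  expect_equal(sixteen_s_identity(s, s), 100)
  chars <- strsplit(s, "")[[1]]
  chars[500] <- setdiff(c("A", "C", "G", "T"), chars[500])[1]
  expect_equal(sixteen_s_identity(s, paste(chars, collapse = "")), 99.9)
  expect_warning(sixteen_s_identity("ACGTACGT", "ACGTACGT"),
                 "shorter than 500")
  expect_error(sixteen_s_identity("", s), "empty")
})

test_that("delineate applies the 98.7% threshold with >= boundary", {
  expect_equal(delineate(95.0)$verdict,
               "below_threshold_candidate_new_species")
  expect_equal(delineate(98.7)$verdict,
               "above_threshold_same_species_not_excluded")
  expect_equal(delineate(100)$verdict,
               "above_threshold_same_species_not_excluded")
  expect_equal(delineate(98.69)$verdict,
               "below_threshold_candidate_new_species")
  expect_error(delineate(101))
})

test_that("summarize_cogs counts per letter with multi-letter genes", {
  tab <- summarize_cogs(c(g1 = "J", g2 = "J", g3 = "-"))
  expect_equal(tab$count[tab$code == "J"], 2L)
  expect_equal(tab$pct[tab$code == "J"], 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(tab$count[tab$code == "-"], 1L)

  multi <- summarize_cogs(c(g1 = "KT", g2 = "K"))
  expect_equal(multi$count[multi$code == "K"], 2L)
  expect_equal(multi$count[multi$code == "T"], 1L)
  # multi-letter genes can push summed percentages above 100
  expect_gt(sum(multi$pct), 100)

  empty <- summarize_cogs(data.frame(gene_id = character(),
                                     letters = character()))
  expect_true(all(empty$count == 0L))
  expect_error(summarize_cogs(c(g1 = "q")), "unknown COG")
})

test_that("published category counts reproduce printed percentages", {
  # J: 140 genes of 2,006 protein-coding -> 6.98%
  tab <- summarize_cogs(
    setNames(rep("J", 140), sprintf("g%d", 1:140)), n_total = 2006)
  expect_equal(round(tab$pct[tab$code == "J"], 2), 6.98)
  # G: 224 -> 11.16%, half-way rows of the published table
  tab2 <- summarize_cogs(
    setNames(rep("G", 224), sprintf("g%d", 1:224)), n_total = 2006)
  expect_equal(round(tab2$pct[tab2$code == "G"], 2), 11.17)
})

test_that("genome_stats assembles the summary fields", {
  asm <- assembly("g", c(c1 = strrep("ACGT", 50)))
  gs <- gene_set("g", c(g1 = strrep("A", 30)), c(g1 = translate_cds(strrep("A", 30))),
                 coords = data.frame(gene_id = "g1", contig = "c1",
                                     start = 1L, end = 30L, strand = "+"))
  st <- genome_stats(asm, gs, n_rna = 2L, orfans = "g1")
  expect_equal(st$size_bp, 200L)
  expect_equal(st$gc_pct, 50)
  expect_equal(st$coding_bp, 30L)
  expect_equal(st$n_genes, 3L)
  expect_equal(st$orfan_pct, 100)
})
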