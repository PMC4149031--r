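# Independent oracles used by the unit and acceptance tests. These are
# deliberately written as plain-R enumeration/recursion, sharing no code
# with the package's C++ dynamic program.

# Exhaustive affine-gap global alignment score by memoized recursion
# over (position in a, position in b, type of previous column). A gap
# run of length k costs open + (k - 1) * ext.
oracle_nw_score <- function(a, b, scheme) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  open <- scheme$gap_open
  ext <- scheme$gap_extend
  sc <- function(x, y) if (x == y) scheme$match else scheme$mismatch
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    key <- paste(i, j, last)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, sc(A[i], B[j]) + rec(i + 1L, j + 1L, "M"))
    if (i <= n)
      best <- max(best, -(if (last == "X") ext else open) +
                    rec(i + 1L, j, "X"))
    if (j <= m)
      best <- max(best, -(if (last == "Y") ext else open) +
                    rec(i, j + 1L, "Y"))
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, "start")
}

# Local score oracle: the best global score over every substring pair
# (local optima never carry terminal gaps), floored at the empty
# alignment.
oracle_sw_score <- function(a, b, scheme) {
  n <- nchar(a)
  m <- nchar(b)
  best <- 0
  for (i1 in seq_len(n)) for (i2 in i1:n) {
    sub_a <- substr(a, i1, i2)
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      best <- max(best, oracle_nw_score(sub_a, substr(b, j1, j2), scheme))
    }
  }
  best
}

random_seq <- function(len, alphabet = c("A", "C", "G")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Brute-force reciprocal-best-hit oracle: a pair survives iff no other
# filtered hit of either partner is preferred under the ordering
# (higher bit score, then lower E-value, then lexicographically smaller
# partner ID). Filtering re-states the significance rule inline.
oracle_rbh <- function(hits, e_long = 1e-3, e_short = 1e-5,
                       length_cut = 80, min_identity = 25,
                       min_coverage = 0.5) {
  keep <- logical(nrow(hits))
  for (r in seq_len(nrow(hits))) {
    h <- hits[r, ]
    sig <- (h$alignment_length > length_cut && h$e_value < e_long) ||
      (h$alignment_length <= length_cut && h$e_value < e_short)
    keep[r] <- sig && h$identity_pct >= min_identity &&
      h$query_coverage >= min_coverage &&
      h$subject_coverage >= min_coverage
  }
  sig <- hits[keep, , drop = FALSE]
  preferred <- function(h1, h2, partner) {
    # is h1 strictly preferred over h2?
    if (h1$bit_score != h2$bit_score) return(h1$bit_score > h2$bit_score)
    if (h1$e_value != h2$e_value) return(h1$e_value < h2$e_value)
    h1[[partner]] < h2[[partner]]
  }
  out <- list()
  for (r in seq_len(nrow(sig))) {
    h <- sig[r, ]
    ok <- TRUE
    for (r2 in seq_len(nrow(sig))) {
      if (r2 == r) next
      h2 <- sig[r2, ]
      if (h2$query_id == h$query_id &&
          !preferred(h, h2, "subject_id")) ok <- FALSE
      if (h2$subject_id == h$subject_id &&
          !preferred(h, h2, "query_id")) ok <- FALSE
      if (!ok) break
    }
    if (ok) out[[length(out) + 1L]] <-
        data.frame(gene_a = h$query_id, gene_b = h$subject_id,
                   stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$gene_a), , drop = FALSE]
}

# Random hit table between <= 4 x 4 gene sets with values straddling
# every filter threshold.
random_hit_table <- function() {
  na <- sample.int(4L, 1L)
  nb <- sample.int(4L, 1L)
  rows <- expand.grid(query_id = sprintf("a%d", seq_len(na)),
                      subject_id = sprintf("b%d", seq_len(nb)),
                      stringsAsFactors = FALSE)
  rows <- rows[runif(nrow(rows)) < 0.7, , drop = FALSE]
  n <- nrow(rows)
  if (n == 0L) return(cbind(rows, data.frame(
    bit_score = numeric(), e_value = numeric(),
    alignment_length = integer(), identity_pct = numeric(),
    query_coverage = numeric(), subject_coverage = numeric())))
  rows$bit_score <- sample(seq(20, 200, by = 20), n, replace = TRUE)
  rows$e_value <- ifelse(runif(n) < 0.5, 10^runif(n, -10, 0),
                         sample(c(1e-8, 1e-6, 1e-5, 1e-4, 1e-3, 1e-2),
                                n, TRUE))
  rows$alignment_length <- sample(c(40L, 80L, 81L, 150L), n, TRUE)
  rows$identity_pct <- sample(c(20, 25, 60, 95), n, TRUE)
  rows$query_coverage <- sample(c(0.3, 0.5, 0.9), n, TRUE)
  rows$subject_coverage <- sample(c(0.3, 0.5, 0.9), n, TRUE)
  rows
}

# Small gene set built from explicit CDS strings (proteins translated).
toy_geneset <- function(genome_id, cds) {
  prot <- vapply(cds, translate_cds, character(1))
  gene_set(genome_id, cds, prot)
}

# Random stop-free CDS of the given nt length (multiple of 3): each
# codon drawn uniformly from the 61 sense codons.
SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

random_cds <- function(len) {
  stopifnot(len %% 3 == 0)
  paste(sample(SENSE_CODONS, len / 3L, replace = TRUE), collapse = "")
}
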