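# Ortholog detection between two genomes: all-vs-all protein similarity
# (Smith-Waterman with Karlin-Altschul E-values), strict 1:1 reciprocal
# best hits, and ORFan classification under E-value/length thresholds.

#' Significance rule for protein homology hits
#'
#' A hit is significant when its E-value is below 1e-03 for alignment
#' lengths greater than 80 amino acids, or below 1e-05 for alignment
#' lengths of 80 amino acids or fewer.
#'
#' @param e_long E-value cutoff for long alignments (default 1e-03).
#' @param e_short E-value cutoff for short alignments (default 1e-05).
#' @param length_cut Alignment-length boundary in amino acids (default 80).
#' @return A `significance_rule` object.
#' @export
significance_rule <- function(e_long = 1e-3, e_short = 1e-5,
                              length_cut = 80L) {
  stopifnot(e_short < e_long, length_cut > 0)
  structure(list(e_long = e_long, e_short = e_short,
                 length_cut = length_cut), class = "significance_rule")
}

#' Is a homology hit significant?
#'
#' @param hit A one-row hit data frame, or a full hit table (vectorized).
#' @param rule A [significance_rule()].
#' @return Logical vector, one element per hit.
#' @export
is_significant <- function(hit, rule = significance_rule()) {
  (hit$alignment_length > rule$length_cut & hit$e_value < rule$e_long) |
    (hit$alignment_length <= rule$length_cut & hit$e_value < rule$e_short)
}

.protein_kmers <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
}

# Candidate pairs (index pairs into a and b) sharing at least one k-mer.
# Sequences shorter than k are candidates against everything.
.kmer_candidates <- function(seqs_a, seqs_b, k) {
  ka <- .protein_kmers(seqs_a, k)
  kb <- .protein_kmers(seqs_b, k)
  da <- data.frame(kmer = unlist(ka, use.names = FALSE),
                   ia = rep(seq_along(ka), lengths(ka)))
  db <- data.frame(kmer = unlist(kb, use.names = FALSE),
                   ib = rep(seq_along(kb), lengths(kb)))
  m <- merge(da, db, by = "kmer")
  pairs <- unique(m[, c("ia", "ib")])
  short_a <- which(nchar(seqs_a) < k)
  short_b <- which(nchar(seqs_b) < k)
  if (length(short_a) > 0L)
    pairs <- rbind(pairs, expand.grid(ia = short_a,
                                      ib = seq_along(seqs_b)))
  if (length(short_b) > 0L)
    pairs <- rbind(pairs, expand.grid(ia = seq_along(seqs_a),
                                      ib = short_b))
  unique(pairs)
}

#' All-vs-all protein similarity search between two gene sets
#'
#' Every candidate gene pair is aligned with affine-gap Smith-Waterman
#' and scored under the Karlin-Altschul model; hits passing the keep
#' threshold are returned as one row each. In `"kmer"` mode (the
#' default) pairs sharing no protein k-mer are skipped; `"exact"` mode
#' aligns every pair and is the reference behaviour the prefilter must
#' reproduce for significant hits.
#'
#' @param set_a,set_b `gene_set` objects (non-empty).
#' @param scheme Protein [scoring_scheme()].
#' @param ka [karlin_altschul_params()]; per-pair `m`, `n` are the raw
#'   protein lengths.
#' @param min_evalue_keep Keep threshold on the E-value (default 1e-05,
#'   the customary search cutoff for ortholog detection; raise to 1e-03
#'   when the table feeds ORFan calling).
#' @param mode `"kmer"` or `"exact"`.
#' @param k K-mer size for the prefilter (default 5).
#' @return A `data.frame` of hits (12 tabular-format columns plus
#'   `raw_score`, `query_coverage`, `subject_coverage`), with attributes
#'   `genome_a`/`genome_b`.
#' @export
all_vs_all <- function(set_a, set_b, scheme = scoring_scheme("protein"),
                       ka = karlin_altschul_params(),
                       min_evalue_keep = 1e-5,
                       mode = c("kmer", "exact"), k = 5L) {
  mode <- match.arg(mode)
  stopifnot(inherits(set_a, "gene_set"), inherits(set_b, "gene_set"))
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop("gene sets must be non-empty")
  pa <- set_a$protein
  pb <- set_b$protein
  cand <- if (mode == "exact")
    expand.grid(ia = seq_along(pa), ib = seq_along(pb))
  else .kmer_candidates(pa, pb, k)
  sub <- .scheme_submat(scheme)
  # score cutoff implied by the keep threshold at the largest search
  # space, used only to order work; the per-pair E-value decides.
  rows <- vector("list", nrow(cand))
  n_hit <- 0L
  for (r in seq_len(nrow(cand))) {
    ia <- cand$ia[r]; ib <- cand$ib[r]
    a <- pa[[ia]]; b <- pb[[ib]]
    raw <- align_affine_cpp(a, b, sub, scheme$gap_open,
                            scheme$gap_extend, TRUE)
    if (raw$columns == 0L) next
    pk <- karlin_altschul_params(ka$lambda, ka$K,
                                 m = nchar(a), n = nchar(b))
    ev <- evalue(raw$score, pk)
    if (ev > min_evalue_keep) next
    chars_a <- strsplit(raw$aligned_a, "")[[1]]
    chars_b <- strsplit(raw$aligned_b, "")[[1]]
    both <- chars_a != "-" & chars_b != "-"
    n_hit <- n_hit + 1L
    rows[[n_hit]] <- data.frame(
      query_id = set_a$gene_ids[ia], subject_id = set_b$gene_ids[ib],
      identity_pct = 100 * raw$identities / raw$columns,
      alignment_length = raw$columns,
      mismatches = sum(both) - raw$identities,
      gap_opens = sum(diff(c(FALSE, !both)) == 1L),
      q_start = raw$a_start, q_end = raw$a_end,
      s_start = raw$b_start, s_end = raw$b_end,
      e_value = ev, bit_score = bit_score(raw$score, pk),
      raw_score = raw$score,
      query_coverage = (raw$a_end - raw$a_start + 1) / nchar(a),
      subject_coverage = (raw$b_end - raw$b_start + 1) / nchar(b),
      stringsAsFactors = FALSE)
  }
  hits <- if (n_hit == 0L) {
    empty <- data.frame(query_id = character(), subject_id = character(),
                        identity_pct = numeric(),
                        alignment_length = integer(),
                        mismatches = integer(), gap_opens = integer(),
                        q_start = integer(), q_end = integer(),
                        s_start = integer(), s_end = integer(),
                        e_value = numeric(), bit_score = numeric(),
                        raw_score = numeric(), query_coverage = numeric(),
                        subject_coverage = numeric(),
                        stringsAsFactors = FALSE)
    empty
  } else do.call(rbind, rows[seq_len(n_hit)])
  attr(hits, "genome_a") <- set_a$genome_id
  attr(hits, "genome_b") <- set_b$genome_id
  hits
}

#' Reciprocal-best-hit ortholog pairing
#'
#' A pair `(a, b)` is returned iff `b` is `a`'s best significant hit in
#' genome B and `a` is `b`'s best significant hit in genome A, after
#' filtering hits by the significance rule, a minimum percent identity,
#' and a minimum coverage required on both sequences. "Best" is the
#' maximum bit score, with ties broken by lower E-value and then
#' lexicographic partner ID, so the pairing is deterministic and 1:1.
#'
#' @param hits Hit table between one ordered genome pair (A queries, B
#'   subjects), as from [all_vs_all()].
#' @param rule A [significance_rule()].
#' @param min_identity Minimum alignment percent identity (default 25).
#' @param min_coverage Minimum aligned fraction of both query and
#'   subject (default 0.5). Hits with `NA` coverage (external tables
#'   without sequence lengths) are not coverage-filtered.
#' @return A `data.frame` with columns `gene_a`, `gene_b`.
#' @export
reciprocal_best_hits <- function(hits, rule = significance_rule(),
                                 min_identity = 25, min_coverage = 0.5) {
  if (all(c("query_genome", "subject_genome") %in% names(hits))) {
    if (length(unique(hits$query_genome)) > 1L ||
        length(unique(hits$subject_genome)) > 1L)
      stop("hits span more than one genome pair")
  }
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  keep <- is_significant(hits, rule) & hits$identity_pct >= min_identity &
    (is.na(hits$query_coverage) | hits$query_coverage >= min_coverage) &
    (is.na(hits$subject_coverage) | hits$subject_coverage >= min_coverage)
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0L) return(empty)
  best_of <- function(df, by, partner) {
    ord <- order(df[[by]], -df$bit_score, df$e_value, df[[partner]],
                 method = "radix")
    df <- df[ord, , drop = FALSE]
    df[!duplicated(df[[by]]), c(by, partner), drop = FALSE]
  }
  best_a <- best_of(h, "query_id", "subject_id")   # a -> its best b
  best_b <- best_of(h, "subject_id", "query_id")   # b -> its best a
  merged <- merge(best_a, best_b, by = c("query_id", "subject_id"))
  out <- data.frame(gene_a = merged$query_id, gene_b = merged$subject_id,
                    stringsAsFactors = FALSE)
  out[order(out$gene_a), , drop = FALSE]
}

#' Classify ORFans in a gene set
#'
#' A gene is an ORFan when none of its hits against the reference
#' collection is significant under the rule (E-value below 1e-03 for
#' alignment lengths over 80 amino acids, below 1e-05 otherwise); genes
#' with no hits at all are ORFans. The reference hit table may come from
#' [all_vs_all()] against other genomes or from an external search read
#' with [read_hit_table()].
#'
#' @param geneset A `gene_set`.
#' @param hits_vs_reference Hit table whose `query_id`s belong to
#'   `geneset`.
#' @param rule A [significance_rule()].
#' @return Character vector of ORFan gene IDs (in gene-set order).
#' @export
classify_orfans <- function(geneset, hits_vs_reference,
                            rule = significance_rule()) {
  stopifnot(inherits(geneset, "gene_set"))
  if (nrow(hits_vs_reference) > 0L &&
      !all(hits_vs_reference$query_id %in% geneset$gene_ids))
    stop("hit table contains query IDs absent from the gene set")
  sig <- hits_vs_reference[is_significant(hits_vs_reference, rule), ,
                           drop = FALSE]
  setdiff(geneset$gene_ids, unique(sig$query_id))
}
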