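# The AGIOS statistic: mean Needleman-Wunsch nucleotide percent identity
# over reciprocal-best-hit orthologous gene pairs, computed genome pair
# by genome pair, and the multi-genome summary matrix.

#' Configuration for AGIOS comparisons
#'
#' Bundles the search and alignment parameters used by [compare_pair()]
#' and [build_matrix()]. Defaults: BLOSUM62 protein search with gap open
#' 11 / extend 1 and gapped-BLASTP Karlin-Altschul constants; EMBOSS-style
#' nucleotide alignment (match +5, mismatch -4, gap open 10, extend 0.5);
#' reciprocal-best-hit filters of E <= 1e-05, identity >= 25%, coverage
#' >= 0.5; identity denominator over all alignment columns.
#'
#' @param protein_scheme Protein [scoring_scheme()].
#' @param nt_scheme Nucleotide [scoring_scheme()].
#' @param ka [karlin_altschul_params()] constants.
#' @param rule [significance_rule()] applied to hits.
#' @param min_evalue_keep Search keep threshold.
#' @param min_identity,min_coverage Reciprocal-best-hit filters.
#' @param search_mode `"kmer"` or `"exact"` (see [all_vs_all()]).
#' @param kmer_k Prefilter k-mer size.
#' @param identity_denominator `"all"` (every alignment column, terminal
#'   gaps included) or `"aligned"` (both-residue columns only).
#' @param weighted If `TRUE`, weight each ortholog pair's identity by its
#'   alignment column count instead of averaging per-gene percentages.
#' @return An `agios_config` list.
#' @export
agios_config <- function(protein_scheme = scoring_scheme("protein"),
                         nt_scheme = scoring_scheme("nucleotide"),
                         ka = karlin_altschul_params(),
                         rule = significance_rule(),
                         min_evalue_keep = 1e-5,
                         min_identity = 25, min_coverage = 0.5,
                         search_mode = c("kmer", "exact"), kmer_k = 5L,
                         identity_denominator = c("all", "aligned"),
                         weighted = FALSE) {
  structure(list(protein_scheme = protein_scheme, nt_scheme = nt_scheme,
                 ka = ka, rule = rule, min_evalue_keep = min_evalue_keep,
                 min_identity = min_identity, min_coverage = min_coverage,
                 search_mode = match.arg(search_mode), kmer_k = kmer_k,
                 identity_denominator = match.arg(identity_denominator),
                 weighted = weighted),
            class = "agios_config")
}

#' Compare one genome pair: orthologs and mean nucleotide identity
#'
#' Runs the all-vs-all protein search, pairs orthologs by reciprocal
#' best hit, globally aligns each ortholog pair's CDS nucleotide
#' sequences, and averages the per-pair percent identities (unweighted
#' by default: the statistic is the mean of per-gene percentages, not a
#' pooled column count). With zero orthologs the AGIOS value is `NA`,
#' never 0.
#'
#' @param set_a,set_b `gene_set` objects.
#' @param config An [agios_config()].
#' @return A `pair_comparison`: `genome_a`, `genome_b`, `pairs`
#'   (data frame `gene_a`, `gene_b`, `nt_identity_pct`), `n_orthologs`,
#'   `agios_pct`.
#' @export
compare_pair <- function(set_a, set_b, config = agios_config()) {
  stopifnot(inherits(set_a, "gene_set"), inherits(set_b, "gene_set"))
  hits <- all_vs_all(set_a, set_b, scheme = config$protein_scheme,
                     ka = config$ka,
                     min_evalue_keep = config$min_evalue_keep,
                     mode = config$search_mode, k = config$kmer_k)
  pairs <- reciprocal_best_hits(hits, rule = config$rule,
                                min_identity = config$min_identity,
                                min_coverage = config$min_coverage)
  n <- nrow(pairs)
  if (n > 0L) {
    ids <- numeric(n)
    cols <- numeric(n)
    for (i in seq_len(n)) {
      aln <- nw_align(set_a$cds[[pairs$gene_a[i]]],
                      set_b$cds[[pairs$gene_b[i]]],
                      scheme = config$nt_scheme)
      ids[i] <- alignment_identity(aln, config$identity_denominator)
      cols[i] <- if (config$identity_denominator == "all")
        aln$columns else aln$aligned_columns
    }
    pairs$nt_identity_pct <- ids
    agios <- if (config$weighted)
      sum(ids * cols) / sum(cols) else mean(ids)
  } else {
    pairs$nt_identity_pct <- numeric(0)
    agios <- NA_real_
  }
  structure(list(genome_a = set_a$genome_id, genome_b = set_b$genome_id,
                 pairs = pairs, n_orthologs = n, agios_pct = agios),
            class = "pair_comparison")
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf("<pair_comparison> %s vs %s: %d orthologs, AGIOS %s\n",
              x$genome_a, x$genome_b, x$n_orthologs,
              if (is.na(x$agios_pct)) "NA" else
                sprintf("%.2f%%", x$agios_pct)))
  invisible(x)
}

#' Multi-genome AGIOS matrix
#'
#' Compares all `n * (n - 1) / 2` genome pairs. The result mirrors the
#' conventional published layout: diagonal = per-genome gene counts,
#' upper triangle = shared ortholog counts, lower triangle = mean
#' nucleotide identities.
#'
#' @param genesets List of at least two `gene_set` objects.
#' @param config An [agios_config()].
#' @return An `agios_matrix`: `genome_ids`, `gene_counts`,
#'   `ortholog_counts` (symmetric), `agios_pcts` (symmetric),
#'   `comparisons` (list of `pair_comparison`).
#' @export
build_matrix <- function(genesets, config = agios_config()) {
  if (length(genesets) < 2L)
    stop("need at least two genomes to build a comparison matrix")
  ids <- vapply(genesets, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome IDs")
  n <- length(ids)
  orth <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  agios <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  comps <- list()
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    cmp <- compare_pair(genesets[[i]], genesets[[j]], config)
    orth[i, j] <- orth[j, i] <- cmp$n_orthologs
    agios[i, j] <- agios[j, i] <- cmp$agios_pct
    comps[[paste(ids[i], ids[j], sep = "|")]] <- cmp
  }
  structure(list(genome_ids = ids,
                 gene_counts = setNames(
                   vapply(genesets, length, integer(1)), ids),
                 ortholog_counts = orth, agios_pcts = agios,
                 comparisons = comps),
            class = "agios_matrix")
}

#' @export
print.agios_matrix <- function(x, ...) {
  n <- length(x$genome_ids)
  cat(sprintf("<agios_matrix> %d genomes\n", n))
  cells <- matrix("", n, n, dimnames = list(x$genome_ids, x$genome_ids))
  for (i in seq_len(n)) {
    cells[i, i] <- format(x$gene_counts[i])
    if (i < n) for (j in seq((i + 1L), n)) {
      cells[i, j] <- format(x$ortholog_counts[i, j])
      cells[j, i] <- ifelse(is.na(x$agios_pcts[j, i]), "NA",
                            sprintf("%.2f", x$agios_pcts[j, i]))
    }
  }
  print(cells, quote = FALSE)
  invisible(x)
}

#' Range summary of an AGIOS matrix
#'
#' Reports the minimum and maximum mean identity over the filled lower
#' triangle, and optionally restricted to pairs involving a focal
#' genome. The two ranges are always reported separately because they
#' answer different questions (family-wide spread vs spread relative to
#' one organism).
#'
#' @param matrix An `agios_matrix`.
#' @param focal Optional focal genome ID.
#' @return A list with `overall = c(min, max)`, `n_pairs`, and when
#'   `focal` is given, `focal_genome` and `focal = c(min, max)`.
#' @export
agios_range_report <- function(matrix, focal = NULL) {
  stopifnot(inherits(matrix, "agios_matrix"))
  vals <- matrix$agios_pcts[lower.tri(matrix$agios_pcts)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("matrix has no defined AGIOS values")
  out <- list(overall = c(min = min(vals), max = max(vals)),
              n_pairs = length(vals))
  if (!is.null(focal)) {
    if (!focal %in% matrix$genome_ids)
      stop(sprintf("focal genome '%s' not in matrix", focal))
    fv <- matrix$agios_pcts[focal, ]
    fv <- fv[!is.na(fv)]
    out$focal_genome <- focal
    out$focal <- c(min = min(fv), max = max(fv))
  }
  out
}
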