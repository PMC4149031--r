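# Genome-level summary statistics, 16S identity with the 98.7%
# species-delineation threshold, and COG category table summaries.

#' Load an assembly from FASTA
#'
#' @param path Nucleotide FASTA of contigs.
#' @param genome_id Genome identifier token (default: file base name).
#' @return An `assembly`: list with `genome_id` and named character
#'   vector `contigs`.
#' @export
load_assembly <- function(path,
                          genome_id = tools::file_path_sans_ext(basename(path))) {
  recs <- read_fasta(path, "nucleotide")
  assembly(genome_id, setNames(recs$residues, recs$id))
}

#' Construct an assembly
#'
#' @param genome_id Genome identifier token.
#' @param contigs Named character vector of contig sequences (>= 1).
#' @return An `assembly` object.
#' @export
assembly <- function(genome_id, contigs) {
  stopifnot(is.character(contigs), length(contigs) >= 1L,
            !is.null(names(contigs)))
  if (any(nchar(contigs) == 0L)) stop("empty contig in assembly")
  structure(list(genome_id = genome_id, contigs = contigs),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %s: %d contig(s), %d bp\n", x$genome_id,
              length(x$contigs), genome_size(x)))
  invisible(x)
}

#' Total genome size in bp
#'
#' Sum of contig lengths, counting every residue including `N`.
#'
#' @param assembly An `assembly`.
#' @return Integer number of base pairs.
#' @export
genome_size <- function(assembly) {
  stopifnot(inherits(assembly, "assembly"))
  sum(nchar(assembly$contigs))
}

#' G+C content in percent
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguity codes and `N` are
#' excluded from both numerator and denominator.
#'
#' @param assembly An `assembly`.
#' @return Percent G+C.
#' @export
gc_content <- function(assembly) {
  stopifnot(inherits(assembly, "assembly"))
  freq <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(assembly$contigs), c("A", "C", "G", "T"))
  tot <- colSums(freq)
  denom <- sum(tot)
  if (denom == 0) stop("assembly contains no unambiguous A/C/G/T bases")
  100 * (tot[["G"]] + tot[["C"]]) / denom
}

#' Coding density from annotated CDS intervals
#'
#' The coding length is the size of the union of CDS intervals per
#' contig (overlapping genes counted once, strand-agnostic), so a base
#' covered by two genes contributes one bp.
#'
#' @param assembly An `assembly`.
#' @param geneset A `gene_set` whose `coords` are present and within
#'   contig bounds.
#' @return List with `coding_bp` and `coding_pct`.
#' @export
coding_density <- function(assembly, geneset) {
  stopifnot(inherits(assembly, "assembly"), inherits(geneset, "gene_set"))
  size <- genome_size(assembly)
  co <- geneset$coords
  if (is.null(co) || nrow(co) == 0L)
    return(list(coding_bp = 0L, coding_pct = 0))
  clen <- nchar(assembly$contigs)
  unknown <- setdiff(co$contig, names(clen))
  if (length(unknown) > 0L)
    stop(sprintf("gene(s) on unknown contig(s): %s",
                 paste(unknown, collapse = ", ")))
  oob <- co$end > clen[co$contig] | co$start < 1L
  if (any(oob))
    stop(sprintf("gene '%s' has coordinates outside contig '%s'",
                 co$gene_id[oob][1L], co$contig[oob][1L]))
  coding <- 0L
  for (ct in unique(co$contig)) {
    sel <- co$contig == ct
    red <- IRanges::reduce(IRanges::IRanges(start = co$start[sel],
                                            end = co$end[sel]))
    coding <- coding + sum(IRanges::width(red))
  }
  list(coding_bp = coding, coding_pct = 100 * coding / size)
}

#' 16S rRNA pairwise identity
#'
#' Global (Needleman-Wunsch) percent identity between two 16S rRNA gene
#' sequences, under the same denominator convention as the AGIOS
#' statistic. Sequences shorter than 500 bp trigger a warning (partial
#' 16S genes give unstable similarity values).
#'
#' @param seq1,seq2 Nucleotide sequences (strings or one-row records).
#' @param scheme Nucleotide [scoring_scheme()].
#' @param denominator `"all"` or `"aligned"` (see [alignment_identity()]).
#' @return Percent identity.
#' @export
sixteen_s_identity <- function(seq1, seq2,
                               scheme = scoring_scheme("nucleotide"),
                               denominator = c("all", "aligned")) {
  denominator <- match.arg(denominator)
  s1 <- .as_residues(seq1); s2 <- .as_residues(seq2)
  if (nchar(s1) == 0L || nchar(s2) == 0L) stop("empty 16S sequence")
  if (nchar(s1) < 500L || nchar(s2) < 500L)
    warning("16S sequence shorter than 500 bp; identity may be unstable")
  alignment_identity(nw_align(s1, s2, scheme), denominator)
}

#' Species delineation from 16S identity
#'
#' Applies the 98.7% 16S rRNA gene identity threshold below which a new
#' species can be proposed without DNA-DNA hybridization. The boundary
#' itself (exactly 98.7) is treated as "same species not excluded",
#' since the criterion requires being LOWER than the threshold.
#'
#' @param identity_pct Percent identity in `[0, 100]`.
#' @param threshold Threshold in percent (default 98.7).
#' @return A `delineation_result`: `identity_pct`, `threshold`, and
#'   `verdict` (`"below_threshold_candidate_new_species"` or
#'   `"above_threshold_same_species_not_excluded"`).
#' @export
delineate <- function(identity_pct, threshold = 98.7) {
  stopifnot(identity_pct >= 0, identity_pct <= 100)
  verdict <- if (identity_pct < threshold)
    "below_threshold_candidate_new_species"
  else "above_threshold_same_species_not_excluded"
  structure(list(identity_pct = identity_pct, threshold = threshold,
                 verdict = verdict), class = "delineation_result")
}

#' @export
print.delineation_result <- function(x, ...) {
  cat(sprintf("<delineation> %.2f%% vs %.1f%% threshold: %s\n",
              x$identity_pct, x$threshold, x$verdict))
  invisible(x)
}

COG_CODES <- c("J", "A", "K", "L", "B", "D", "Y", "V", "T", "M", "N",
               "Z", "W", "U", "O", "C", "G", "E", "F", "H", "I", "P",
               "Q", "R", "S")

COG_DESCRIPTIONS <- c(
  J = "Translation", A = "RNA processing and modification",
  K = "Transcription", L = "Replication, recombination and repair",
  B = "Chromatin structure and dynamics",
  D = "Cell cycle control, mitosis and meiosis", Y = "Nuclear structure",
  V = "Defense mechanisms", T = "Signal transduction mechanisms",
  M = "Cell wall/membrane biogenesis", N = "Cell motility",
  Z = "Cytoskeleton", W = "Extracellular structures",
  U = "Intracellular trafficking and secretion",
  O = "Posttranslational modification, protein turnover, chaperones",
  C = "Energy production and conversion",
  G = "Carbohydrate transport and metabolism",
  E = "Amino acid transport and metabolism",
  F = "Nucleotide transport and metabolism",
  H = "Coenzyme transport and metabolism",
  I = "Lipid transport and metabolism",
  P = "Inorganic ion transport and metabolism",
  Q = "Secondary metabolites biosynthesis, transport and catabolism",
  R = "General function prediction only", S = "Function unknown",
  `-` = "Not in COGs")

#' Summarize a COG category assignment table
#'
#' Assignments are user-supplied (no database search is performed): a
#' table mapping each gene to one or more of the 25 single-letter COG
#' functional categories, or `-` for unassigned. A gene carrying several
#' letters is counted once under each; percentages are therefore allowed
#' to sum above 100.
#'
#' @param assignments A `data.frame` with columns `gene_id` and
#'   `letters` (e.g. `"J"`, `"KT"`, `"-"`), or a named character vector.
#' @param n_total Total protein-coding genes used as the percentage
#'   denominator (default: number of rows in the table).
#' @return A `data.frame` with one row per category: `code`, `count`,
#'   `pct`, `description`.
#' @export
summarize_cogs <- function(assignments, n_total = NULL) {
  if (is.character(assignments))
    assignments <- data.frame(gene_id = names(assignments),
                              letters = unname(assignments),
                              stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "letters") %in% names(assignments)))
  if (is.null(n_total)) n_total <- nrow(assignments)
  codes <- c(COG_CODES, "-")
  counts <- setNames(integer(length(codes)), codes)
  if (nrow(assignments) > 0L) {
    letters <- strsplit(assignments$letters, "")
    for (i in seq_along(letters)) {
      ls <- unique(letters[[i]])
      bad <- setdiff(ls, codes)
      if (length(bad) > 0L)
        stop(sprintf("unknown COG category letter '%s' for gene '%s'",
                     bad[1L], assignments$gene_id[i]))
      counts[ls] <- counts[ls] + 1L
    }
  }
  data.frame(code = codes, count = unname(counts),
             pct = if (n_total > 0) 100 * unname(counts) / n_total else 0,
             description = unname(COG_DESCRIPTIONS[codes]),
             stringsAsFactors = FALSE)
}

#' Assemble per-genome summary statistics
#'
#' @param assembly An `assembly`.
#' @param geneset A `gene_set` (coordinates required for coding density;
#'   without them `coding_bp`/`coding_pct` are `NA`).
#' @param n_rna User-supplied RNA gene count (prediction is out of
#'   scope).
#' @param orfans Optional character vector of ORFan gene IDs from
#'   [classify_orfans()].
#' @return A `genome_stats` list: `genome_id`, `size_bp`, `gc_pct`,
#'   `coding_bp`, `coding_pct`, `n_genes`, `n_protein_coding`, `n_rna`,
#'   `n_orfans`, `orfan_pct`.
#' @export
genome_stats <- function(assembly, geneset, n_rna = NA_integer_,
                         orfans = NULL) {
  stopifnot(inherits(assembly, "assembly"), inherits(geneset, "gene_set"))
  cd <- if (is.null(geneset$coords))
    list(coding_bp = NA_integer_, coding_pct = NA_real_)
  else coding_density(assembly, geneset)
  n_pc <- length(geneset)
  n_orf <- if (is.null(orfans)) NA_integer_ else length(orfans)
  structure(list(
    genome_id = assembly$genome_id,
    size_bp = genome_size(assembly),
    gc_pct = gc_content(assembly),
    coding_bp = cd$coding_bp, coding_pct = cd$coding_pct,
    n_genes = n_pc + ifelse(is.na(n_rna), 0L, n_rna),
    n_protein_coding = n_pc, n_rna = n_rna,
    n_orfans = n_orf,
    orfan_pct = if (is.na(n_orf) || n_pc == 0L) NA_real_ else
      100 * n_orf / n_pc), class = "genome_stats")
}

#' @export
print.genome_stats <- function(x, ...) {
  cat(sprintf("<genome_stats> %s\n", x$genome_id))
  cat(sprintf("  size: %d bp, G+C: %.2f%%\n", x$size_bp, x$gc_pct))
  if (!is.na(x$coding_bp))
    cat(sprintf("  coding: %d bp (%.2f%%)\n", x$coding_bp, x$coding_pct))
  cat(sprintf("  genes: %d protein-coding, %s RNA\n",
              x$n_protein_coding,
              ifelse(is.na(x$n_rna), "?", x$n_rna)))
  if (!is.na(x$n_orfans))
    cat(sprintf("  ORFans: %d (%.2f%%)\n", x$n_orfans, x$orfan_pct))
  invisible(x)
}
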