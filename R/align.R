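# Pairwise alignment: affine-gap Needleman-Wunsch (global) and
# Smith-Waterman (local) with percent identity, plus Karlin-Altschul
# E-values. The DP itself lives in src/align.cpp; this file owns scoring
# schemes and the user-facing interface.

#' Scoring scheme for pairwise alignment
#'
#' Nucleotide defaults follow the EMBOSS-needle convention (match +5,
#' mismatch -4, gap open 10, gap extend 0.5); protein defaults follow
#' gapped BLASTP (BLOSUM62, gap open 11, gap extend 1). A gap of length
#' `k` costs `gap_open + (k - 1) * gap_extend`.
#'
#' @param kind `"nucleotide"` or `"protein"`.
#' @param match,mismatch Nucleotide match reward / mismatch penalty
#'   (penalty given as a negative score).
#' @param matrix Protein substitution matrix name (only `"BLOSUM62"`).
#' @param gap_open,gap_extend Positive gap costs, `gap_open >= gap_extend > 0`.
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(kind = c("nucleotide", "protein"),
                           match = 5, mismatch = -4,
                           matrix = "BLOSUM62",
                           gap_open = if (kind == "nucleotide") 10 else 11,
                           gap_extend = if (kind == "nucleotide") 0.5 else 1) {
  kind <- match.arg(kind)
  force(gap_open); force(gap_extend)
  if (!(gap_open >= gap_extend && gap_extend > 0))
    stop("gap costs must satisfy gap_open >= gap_extend > 0")
  if (kind == "nucleotide" && (match <= 0 || mismatch >= 0))
    stop("nucleotide scoring needs match > 0 and mismatch < 0")
  if (kind == "protein" && matrix != "BLOSUM62")
    stop("only BLOSUM62 is supported for protein scoring")
  structure(list(kind = kind, match = match, mismatch = mismatch,
                 matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

# 256x256 ASCII-indexed lookup used by the C++ DP.
.submat_cache <- new.env(parent = emptyenv())

.scheme_submat <- function(scheme) {
  key <- paste(scheme$kind, scheme$match, scheme$mismatch, scheme$matrix,
               sep = "|")
  cached <- .submat_cache[[key]]
  if (!is.null(cached)) return(cached)
  sub <- matrix(NA_real_, 256, 256)
  if (scheme$kind == "nucleotide") {
    chars <- strsplit(NUC_CHARS, "")[[1]]
    codes <- utf8ToInt(paste(chars, collapse = "")) + 1L
    sub[codes, codes] <- scheme$mismatch
    sub[cbind(codes, codes)] <- scheme$match
    # ambiguity codes never reward a match
    amb <- utf8ToInt(paste(setdiff(chars, c("A", "C", "G", "T")),
                           collapse = "")) + 1L
    sub[cbind(amb, amb)] <- scheme$mismatch
  } else {
    b62 <- get_blosum62()
    chars <- colnames(b62)
    codes <- utf8ToInt(paste(chars, collapse = "")) + 1L
    sub[codes, codes] <- b62
  }
  .submat_cache[[key]] <- sub
  sub
}

.b62_cache <- new.env(parent = emptyenv())

get_blosum62 <- function() {
  if (is.null(.b62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .b62_cache$m <- e$BLOSUM62
  }
  .b62_cache$m
}

.as_residues <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x$residues
  } else if (is.character(x) && length(x) == 1L) {
    toupper(x)
  } else stop("sequence must be a single string or one-row record")
}

.check_pair <- function(a, b, scheme) {
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("cannot align empty sequences")
  rex <- .alphabet_regex(scheme$kind)
  if (regexpr(rex, a) > 0L || regexpr(rex, b) > 0L)
    stop(sprintf("sequence contains residues outside the %s alphabet",
                 scheme$kind))
}

.alignment_result <- function(raw, a, b, local) {
  columns <- raw$columns
  aligned_cols <- if (columns == 0L) 0L else
    sum(strsplit(raw$aligned_a, "")[[1]] != "-" &
        strsplit(raw$aligned_b, "")[[1]] != "-")
  structure(list(
    aligned_a = raw$aligned_a, aligned_b = raw$aligned_b,
    score = raw$score, identities = raw$identities, columns = columns,
    aligned_columns = aligned_cols,
    identity_pct = if (columns == 0L) NA_real_ else
      100 * raw$identities / columns,
    a_start = raw$a_start, a_end = raw$a_end,
    b_start = raw$b_start, b_end = raw$b_end,
    type = if (local) "local" else "global"), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<%s alignment> score %.1f, %d/%d identical (%.2f%%)\n",
              x$type, x$score, x$identities, x$columns,
              x$identity_pct))
  invisible(x)
}

#' Global (Needleman-Wunsch) alignment with affine gaps
#'
#' Returns the optimal global alignment under the scheme's affine gap
#' model, with a deterministic traceback (ties resolved diagonal > up >
#' left). `identity_pct` counts identical residue columns over ALL
#' alignment columns, terminal gaps included; see
#' [alignment_identity()] for the alternative denominator.
#'
#' @param a,b Sequences: single strings or one-row record data frames.
#' @param scheme A [scoring_scheme()]; both sequences must match its
#'   alphabet.
#' @return An `alignment_result`.
#' @export
nw_align <- function(a, b, scheme = scoring_scheme("nucleotide")) {
  a <- .as_residues(a); b <- .as_residues(b)
  .check_pair(a, b, scheme)
  raw <- align_affine_cpp(a, b, .scheme_submat(scheme),
                          scheme$gap_open, scheme$gap_extend, FALSE)
  .alignment_result(raw, a, b, FALSE)
}

#' Local (Smith-Waterman) alignment with affine gaps
#'
#' The empty alignment (score 0) is allowed when no pair of substrings
#' scores positively.
#'
#' @inheritParams nw_align
#' @return An `alignment_result`; `columns` is the local alignment length.
#' @export
sw_align <- function(a, b, scheme = scoring_scheme("protein")) {
  a <- .as_residues(a); b <- .as_residues(b)
  .check_pair(a, b, scheme)
  raw <- align_affine_cpp(a, b, .scheme_submat(scheme),
                          scheme$gap_open, scheme$gap_extend, TRUE)
  .alignment_result(raw, a, b, TRUE)
}

#' Percent identity of an alignment under a chosen denominator
#'
#' `"all"` divides identical columns by every alignment column (internal
#' and terminal gaps included); `"aligned"` divides by columns where both
#' sequences have a residue.
#'
#' @param aln An `alignment_result`.
#' @param denominator `"all"` or `"aligned"`.
#' @return Percent identity in `[0, 100]` (`NA` for an empty alignment).
#' @export
alignment_identity <- function(aln, denominator = c("all", "aligned")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "all") aln$columns else aln$aligned_columns
  if (den == 0L) return(NA_real_)
  100 * aln$identities / den
}

#' Karlin-Altschul parameters
#'
#' Defaults are the standard gapped BLASTP constants (lambda 0.267,
#' K 0.041) so that internal E-values are comparable with the BLASTP
#' thresholds used for ORFan calling. Effective lengths are the raw
#' sequence lengths (no edge-effect correction).
#'
#' @param lambda Per-score scale, > 0.
#' @param K Search-space constant, > 0.
#' @param m,n Effective sequence lengths, >= 1.
#' @return A `karlin_altschul` parameter object.
#' @export
karlin_altschul_params <- function(lambda = 0.267, K = 0.041,
                                   m = 1L, n = 1L) {
  stopifnot(lambda > 0, K > 0, m >= 1, n >= 1)
  structure(list(lambda = lambda, K = K, m = m, n = n),
            class = "karlin_altschul")
}

#' Expected chance-hit count for an alignment score
#'
#' The Karlin-Altschul model `E = K * m * n * exp(-lambda * S)`.
#'
#' @param raw_score Raw alignment score.
#' @param params A [karlin_altschul_params()] object.
#' @return The E-value (> 0, strictly decreasing in `raw_score`, linear
#'   in `m` and in `n`).
#' @export
evalue <- function(raw_score, params) {
  stopifnot(is.finite(raw_score))
  params$K * params$m * params$n * exp(-params$lambda * raw_score)
}

#' Bit score from a raw score
#'
#' `S' = (lambda * S - ln K) / ln 2`.
#'
#' @inheritParams evalue
#' @return The bit score.
#' @export
bit_score <- function(raw_score, params) {
  (params$lambda * raw_score - log(params$K)) / log(2)
}
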