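# FASTA and tabular I/O. Parsing is delegated to Biostrings; validation,
# ID handling and the matrix/hit-table layouts are defined here.

NUC_CHARS <- "ACGTNRYSWKMBDHV"
PROT_CHARS <- "ACDEFGHIKLMNPQRSTVWYX*"

.alphabet_regex <- function(alphabet) {
  chars <- switch(alphabet,
    nucleotide = NUC_CHARS,
    protein    = PROT_CHARS,
    stop(sprintf("unknown alphabet '%s'", alphabet))
  )
  sprintf("[^%s]", gsub("\\*", "\\\\*", chars))
}

#' Read a FASTA file into a record table
#'
#' Records are returned in file order. Residues are uppercased and
#' whitespace-stripped; the record ID is the first whitespace-delimited
#' header token and the remainder of the header is kept as the
#' description. IDs must be unique within a file and residues must belong
#' to the stated alphabet (IUPAC nucleotide codes, or the 20 amino acids
#' plus `X` and `*`).
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A `data.frame` with columns `id`, `description`, `residues`
#'   and attribute `alphabet`.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop(sprintf("record with empty ID in %s", path))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop(sprintf("duplicate sequence ID(s) in %s: %s", path,
                 paste(unique(dup), collapse = ", ")))
  residues <- toupper(gsub("\\s", "", as.character(set)))
  if (any(nchar(residues) == 0L))
    stop(sprintf("zero-length sequence '%s' in %s",
                 ids[nchar(residues) == 0L][1L], path))
  bad <- regexpr(.alphabet_regex(alphabet), residues)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf(
      "invalid %s residue '%s' at position %d of sequence '%s' in %s",
      alphabet, substr(residues[i], bad[i], bad[i]), bad[i], ids[i], path))
  }
  out <- data.frame(id = ids, description = desc, residues = residues,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "alphabet") <- alphabet
  out
}

#' Write a record table to FASTA
#'
#' @param records A record `data.frame` as returned by [read_fasta()], or
#'   a named character vector of residues.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records))
    records <- data.frame(id = names(records), description = "",
                          residues = unname(records),
                          stringsAsFactors = FALSE)
  headers <- ifelse(records$description == "", records$id,
                    paste(records$id, records$description))
  set <- Biostrings::BStringSet(setNames(records$residues, headers))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Build a gene set from paired CDS and protein FASTA files
#'
#' Genes are matched on exact sequence ID; the output follows the order
#' of the nucleotide file. Genes present in only one of the two files are
#' dropped with a message. CDS/protein length consistency (protein length
#' equal to `cds_length/3`, allowing one terminal stop) is checked but
#' non-fatal: real annotations contain pseudogenes and frameshifts, and
#' downstream analysis only requires paired sequences.
#'
#' @param fna_path Nucleotide CDS FASTA.
#' @param faa_path Translated protein FASTA with matching IDs.
#' @param genome_id Genome identifier token.
#' @return A `gene_set` object.
#' @export
load_geneset <- function(fna_path, faa_path, genome_id) {
  fna <- read_fasta(fna_path, "nucleotide")
  faa <- read_fasta(faa_path, "protein")
  shared <- intersect(fna$id, faa$id)
  if (length(shared) == 0L)
    stop(sprintf("no gene IDs shared between %s and %s", fna_path, faa_path))
  n_drop <- (nrow(fna) - length(shared)) + (nrow(faa) - length(shared))
  if (n_drop > 0L)
    message(sprintf("load_geneset(%s): dropped %d unpaired gene(s)",
                    genome_id, n_drop))
  keep <- fna$id[fna$id %in% shared]
  cds <- setNames(fna$residues[match(keep, fna$id)], keep)
  prot <- setNames(faa$residues[match(keep, faa$id)], keep)
  gene_set(genome_id, cds, prot)
}

#' Construct a gene set
#'
#' @param genome_id Genome identifier token.
#' @param cds Named character vector of nucleotide CDS sequences.
#' @param protein Named character vector of protein sequences (same names).
#' @param coords Optional `data.frame` with columns `gene_id`, `contig`,
#'   `start`, `end`, `strand` (1-based inclusive, GenBank convention).
#' @return A `gene_set`: list with elements `genome_id`, `gene_ids`,
#'   `cds`, `protein`, `coords`.
#' @export
gene_set <- function(genome_id, cds, protein, coords = NULL) {
  stopifnot(is.character(cds), is.character(protein),
            !is.null(names(cds)), !is.null(names(protein)))
  if (anyDuplicated(names(cds)))
    stop("duplicate gene IDs in gene set")
  if (!setequal(names(cds), names(protein)))
    stop("cds and protein gene IDs differ")
  protein <- protein[names(cds)]
  if (any(nchar(cds) < 3L))
    stop("CDS shorter than 3 nt in gene set")
  plen <- nchar(protein)
  clen <- nchar(cds)
  inconsistent <- plen != clen %/% 3L & plen != clen %/% 3L - 1L
  if (any(inconsistent))
    warning(sprintf(
      "gene_set(%s): %d gene(s) with inconsistent CDS/protein lengths (kept)",
      genome_id, sum(inconsistent)))
  if (!is.null(coords)) {
    need <- c("gene_id", "contig", "start", "end", "strand")
    if (!all(need %in% names(coords)))
      stop("coords must have columns gene_id, contig, start, end, strand")
    if (any(coords$start < 1L) || any(coords$end < coords$start))
      stop("coords must satisfy 1 <= start <= end")
  }
  structure(list(genome_id = genome_id, gene_ids = names(cds),
                 cds = cds, protein = protein, coords = coords),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes%s\n", x$genome_id,
              length(x$gene_ids),
              if (is.null(x$coords)) "" else " (with coordinates)"))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$gene_ids)

#' Write an AGIOS matrix as a square TSV
#'
#' Layout: header row and column of genome IDs; diagonal cells hold
#' per-genome gene counts (integers), the upper triangle shared-ortholog
#' counts (integers), and the lower triangle mean nucleotide identities
#' printed with 2 decimal places. Tab separator, `.` decimal point, no
#' thousands separators.
#'
#' @param matrix An `agios_matrix` from [build_matrix()].
#' @param path Output path.
#' @export
write_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "agios_matrix"))
  ids <- matrix$genome_ids
  n <- length(ids)
  cells <- base::matrix("", n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    cells[i, i] <- sprintf("%d", matrix$gene_counts[i])
    if (i < n) for (j in seq((i + 1L), n)) {
      cells[i, j] <- sprintf("%d", matrix$ortholog_counts[i, j])
      v <- matrix$agios_pcts[j, i]
      cells[j, i] <- if (is.na(v)) "NA" else sprintf("%.2f", v)
    }
  }
  df <- data.frame(genome = ids, cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an AGIOS matrix TSV written by [write_matrix_tsv()]
#'
#' @param path Path to the TSV.
#' @return An `agios_matrix` (identities carry the serialized 2-decimal
#'   precision).
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df$genome
  n <- length(ids)
  cells <- as.matrix(df[, -1, drop = FALSE])
  gene_counts <- setNames(integer(n), ids)
  orth <- base::matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  agios <- base::matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    gene_counts[i] <- as.integer(cells[i, i])
    if (i < n) for (j in seq((i + 1L), n)) {
      orth[i, j] <- orth[j, i] <- as.integer(cells[i, j])
      v <- suppressWarnings(as.numeric(cells[j, i]))
      agios[i, j] <- agios[j, i] <- v
    }
  }
  structure(list(genome_ids = ids, gene_counts = gene_counts,
                 ortholog_counts = orth, agios_pcts = agios,
                 comparisons = NULL),
            class = "agios_matrix")
}

HIT_COLUMNS <- c("query_id", "subject_id", "identity_pct",
                 "alignment_length", "mismatches", "gap_opens",
                 "q_start", "q_end", "s_start", "s_end",
                 "e_value", "bit_score")

#' Read a 12-column tabular homology hit file
#'
#' The ubiquitous tab-separated search format (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query/subject
#' start/end, E-value, bit score), so externally produced searches can be
#' slotted into ORFan calling or reciprocal-best-hit pairing.
#'
#' @param path Path to a headerless 12-column TSV.
#' @param query_lengths,subject_lengths Optional named integer vectors of
#'   sequence lengths, used to fill alignment coverage columns.
#' @return A `data.frame` of hits.
#' @export
read_hit_table <- function(path, query_lengths = NULL,
                           subject_lengths = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12L)
    stop(sprintf("expected 12 columns in hit table %s, found %d",
                 path, ncol(df)))
  names(df) <- HIT_COLUMNS
  df$query_coverage <- if (is.null(query_lengths)) NA_real_ else
    (df$q_end - df$q_start + 1) / unname(query_lengths[df$query_id])
  df$subject_coverage <- if (is.null(subject_lengths)) NA_real_ else
    (df$s_end - df$s_start + 1) / unname(subject_lengths[df$subject_id])
  df
}

#' Write hits in the 12-column tabular format
#'
#' @param hits Hit `data.frame` from [all_vs_all()] or [read_hit_table()].
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  out <- hits[, HIT_COLUMNS]
  out$identity_pct <- sprintf("%.2f", out$identity_pct)
  out$e_value <- sprintf("%.3g", out$e_value)
  out$bit_score <- sprintf("%.1f", out$bit_score)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
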