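# Synthetic ancestor-descendant genome simulator. Two (or more) gene
# sets descend from one ancestral gene pool by independent per-site
# substitution down each lineage, with optional codon-length indels and
# per-lineage gene loss/gain, and carry full ground truth (orthology map,
# realized identities, lineage-specific genes).

.BASES <- c("A", "C", "G", "T")
.TS_MAP <- c(3L, 4L, 1L, 2L)   # A<->G, C<->T
.TV1 <- c(2L, 1L, 2L, 1L)
.TV2 <- c(4L, 3L, 4L, 3L)
.STOPS <- c("TAA", "TAG", "TGA")

# Probability that two independently substituted sites land on the same
# target base, under transition bias kappa (given substitution, the
# transition is chosen with probability kappa / (kappa + 2)).
.collision_prob <- function(kappa) {
  t <- kappa / (kappa + 2)
  v <- 1 / (kappa + 2)
  t^2 + 2 * v^2
}

# Per-lineage substitution rate q such that the expected per-site
# difference between the two descendants equals p:
#   1 - [(1-q)^2 + c q^2] = p  =>  q = (1 - sqrt(1 - (1+c) p)) / (1+c).
.lineage_rate <- function(p_sub, kappa) {
  cc <- .collision_prob(kappa)
  disc <- 1 - (1 + cc) * p_sub
  if (disc < 0)
    stop(sprintf("p_sub too large for this substitution model (max %.3f)",
                 1 / (1 + cc)))
  (1 - sqrt(disc)) / (1 + cc)
}

#' Simulation configuration
#'
#' `p_sub` parameterizes the expected pairwise per-site difference
#' between two descendant genomes, so the expected AGIOS of a simulated
#' pair is `100 * (1 - p_sub)`; each lineage receives the calibrated
#' per-lineage substitution rate that accounts for same-target
#' collisions (see the methods vignette). Gene lengths are uniform
#' integer multiples of 3 in `gene_length_range`.
#'
#' @param n_genes Number of ancestral genes (>= 1).
#' @param gene_length_range CDS length range in nt, multiples of 3
#'   (default 300 to 1500).
#' @param p_sub Expected pairwise per-site substitution divergence in
#'   `[0, 0.7]`.
#' @param ts_tv_ratio Transition/transversion bias kappa (default 2).
#' @param p_indel Per-gene, per-lineage probability of one codon-length
#'   indel (default 0).
#' @param loss_rate Per-gene, per-lineage loss probability (default 0).
#' @param gain_rate Expected number of novel (lineage-specific) genes
#'   gained per lineage, Poisson-distributed (default 0).
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_genes = 200L,
                              gene_length_range = c(300L, 1500L),
                              p_sub = 0.1, ts_tv_ratio = 2,
                              p_indel = 0, loss_rate = 0,
                              gain_rate = 0, seed = 1L) {
  stopifnot(n_genes >= 1, p_sub >= 0, p_indel >= 0, p_indel <= 1,
            loss_rate >= 0, loss_rate <= 1, gain_rate >= 0,
            ts_tv_ratio > 0, length(gene_length_range) == 2L,
            gene_length_range[1] >= 3L,
            gene_length_range[2] >= gene_length_range[1])
  .lineage_rate(p_sub, ts_tv_ratio)  # errors early if p_sub infeasible
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 p_sub = p_sub, ts_tv_ratio = ts_tv_ratio,
                 p_indel = p_indel, loss_rate = loss_rate,
                 gain_rate = gain_rate, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Expected AGIOS of a simulated pair
#'
#' By the rate calibration, `100 * (1 - p_sub)` (substitutions only; no
#' indels or turnover terms).
#'
#' @param config A [simulation_config()].
#' @return Expected mean percent identity.
#' @export
expected_pair_identity <- function(config) 100 * (1 - config$p_sub)

.random_gene_length <- function(range) {
  lo <- range[1] %/% 3L
  hi <- range[2] %/% 3L
  3L * (lo + sample.int(hi - lo + 1L, 1L) - 1L)
}

# Random CDS as integer codes 1..4, stop-free in frame.
.random_cds_codes <- function(len) {
  x <- sample.int(4L, len, replace = TRUE)
  .fix_stops(x, resample_all = TRUE)
}

.codon_strings <- function(codes) {
  ch <- .BASES[codes]
  nc <- length(ch) %/% 3L
  paste0(ch[seq(1L, by = 3L, length.out = nc)],
         ch[seq(2L, by = 3L, length.out = nc)],
         ch[seq(3L, by = 3L, length.out = nc)])
}

# Replace stop codons. With resample_all the whole codon is redrawn
# (used for ancestor/novel genes); otherwise `changed` flags the sites
# substituted this round and the first such site in the codon is
# redirected to a different target (used after lineage mutation).
.fix_stops <- function(codes, changed = NULL, anc = NULL,
                       resample_all = FALSE) {
  repeat {
    stops <- which(.codon_strings(codes) %in% .STOPS)
    if (length(stops) == 0L) return(codes)
    for (ci in stops) {
      idx <- (3L * (ci - 1L) + 1L):(3L * ci)
      if (resample_all) {
        codes[idx] <- sample.int(4L, 3L, replace = TRUE)
      } else {
        site <- idx[changed[idx]][1L]
        alt <- setdiff(seq_len(4L), c(anc[site], codes[site]))
        codes[site] <- alt[sample.int(length(alt), 1L)]
      }
    }
  }
}

# Per-site Bernoulli substitution with transition bias; returns codes
# plus the changed-site mask.
.mutate_codes <- function(anc, q, kappa) {
  n <- length(anc)
  hit <- runif(n) < q
  out <- anc
  if (any(hit)) {
    t <- kappa / (kappa + 2)
    v <- 1 / (kappa + 2)
    u <- runif(sum(hit))
    targ <- ifelse(u < t, .TS_MAP[anc[hit]],
                   ifelse(u < t + v, .TV1[anc[hit]], .TV2[anc[hit]]))
    out[hit] <- targ
    out <- .fix_stops(out, changed = hit, anc = anc)
  }
  out
}

# One lineage's version of a gene: mutated codes plus at most one
# codon-length indel event.
.evolve_gene <- function(anc, q, kappa, p_indel) {
  codes <- .mutate_codes(anc, q, kappa)
  event <- NULL
  if (p_indel > 0 && runif(1L) < p_indel) {
    nc <- length(anc) %/% 3L
    if (runif(1L) < 0.5 && nc > 1L) {
      event <- list(type = "del", codon = sample.int(nc, 1L))
    } else {
      ins <- .random_cds_codes(3L)
      event <- list(type = "ins", after = sample.int(nc + 1L, 1L) - 1L,
                    codon = ins)
    }
  }
  list(codes = codes, event = event)
}

# Assemble the true alignment of the two descendant versions of one
# ancestral gene, honouring at most one indel per lineage. Returns the
# realized sequences and the identity over all alignment columns.
.pair_gene_alignment <- function(anc, ga, gb) {
  nc <- length(anc) %/% 3L
  cols_a <- character(0)
  cols_b <- character(0)
  emit <- function(a3, b3) {
    cols_a <<- c(cols_a, a3)
    cols_b <<- c(cols_b, b3)
  }
  ins_at <- function(g, pos) {
    if (!is.null(g$event) && g$event$type == "ins" && g$event$after == pos)
      paste(.BASES[g$event$codon], collapse = "")
    else NULL
  }
  del_at <- function(g, ci) {
    !is.null(g$event) && g$event$type == "del" && g$event$codon == ci
  }
  for (ci in 0:nc) {
    if (ci > 0L) {
      da <- del_at(ga, ci); db <- del_at(gb, ci)
      if (!(da && db)) {
        idx <- (3L * (ci - 1L) + 1L):(3L * ci)
        emit(if (da) "---" else
               paste(.BASES[ga$codes[idx]], collapse = ""),
             if (db) "---" else
               paste(.BASES[gb$codes[idx]], collapse = ""))
      }
    }
    ia <- ins_at(ga, ci)
    if (!is.null(ia)) emit(ia, "---")
    ib <- ins_at(gb, ci)
    if (!is.null(ib)) emit("---", ib)
  }
  sa <- strsplit(paste(cols_a, collapse = ""), "")[[1]]
  sb <- strsplit(paste(cols_b, collapse = ""), "")[[1]]
  list(seq_a = paste(sa[sa != "-"], collapse = ""),
       seq_b = paste(sb[sb != "-"], collapse = ""),
       identity_pct = 100 * sum(sa == sb & sa != "-") / length(sa))
}

#' Translate a CDS with the standard genetic code
#'
#' @param cds Nucleotide CDS string, length a multiple of 3. Stop codons
#'   translate to `*`, unresolvable codons to `X`.
#' @return Protein string.
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length is not a multiple of 3")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.novel_genes <- function(n, prefix, range) {
  if (n == 0L) return(character(0))
  out <- setNames(character(n), sprintf("%s%04d", prefix, seq_len(n)))
  for (i in seq_len(n))
    out[i] <- paste(.BASES[.random_cds_codes(.random_gene_length(range))],
                    collapse = "")
  out
}

.geneset_from_cds <- function(genome_id, cds) {
  prot <- vapply(cds, translate_cds, character(1))
  gene_set(genome_id, cds, prot)
}

#' Simulate a descendant genome pair with ground truth
#'
#' Ancestral genes are drawn with uniform base composition (in-frame
#' stop codons resampled), then mutated independently down two lineages
#' with the calibrated per-lineage substitution rate, optional
#' codon-length indels, per-gene loss, and Poisson gains of novel random
#' genes (the ORFan analogues). Proteins are standard-table
#' translations.
#'
#' @param config A [simulation_config()].
#' @param genome_ids Two genome identifier tokens.
#' @return A `simulated_pair`: `geneset_a`, `geneset_b`, and `truth`
#'   with `ortholog_map` (`gene_a`, `gene_b`, `identity_pct`),
#'   `gained_a`/`gained_b` (novel gene IDs), `lineage_specific_a`/`_b`
#'   (novel plus sister-lost gene IDs), and the config.
#' @export
simulate_pair <- function(config = simulation_config(),
                          genome_ids = c("simA", "simB")) {
  stopifnot(inherits(config, "simulation_config"),
            length(genome_ids) == 2L)
  set.seed(config$seed)
  q <- .lineage_rate(config$p_sub, config$ts_tv_ratio)
  n <- config$n_genes
  anc <- vector("list", n)
  for (i in seq_len(n))
    anc[[i]] <- .random_cds_codes(.random_gene_length(config$gene_length_range))
  ga <- lapply(anc, .evolve_gene, q = q, kappa = config$ts_tv_ratio,
               p_indel = config$p_indel)
  gb <- lapply(anc, .evolve_gene, q = q, kappa = config$ts_tv_ratio,
               p_indel = config$p_indel)
  keep_a <- runif(n) >= config$loss_rate
  keep_b <- runif(n) >= config$loss_rate
  ids_a <- sprintf("%s_g%04d", genome_ids[1], seq_len(n))
  ids_b <- sprintf("%s_g%04d", genome_ids[2], seq_len(n))
  cds_a <- setNames(character(n), ids_a)
  cds_b <- setNames(character(n), ids_b)
  ident <- numeric(n)
  for (i in seq_len(n)) {
    al <- .pair_gene_alignment(anc[[i]], ga[[i]], gb[[i]])
    cds_a[i] <- al$seq_a
    cds_b[i] <- al$seq_b
    ident[i] <- al$identity_pct
  }
  gain_a <- .novel_genes(rpois(1L, config$gain_rate),
                         sprintf("%s_n", genome_ids[1]),
                         config$gene_length_range)
  gain_b <- .novel_genes(rpois(1L, config$gain_rate),
                         sprintf("%s_n", genome_ids[2]),
                         config$gene_length_range)
  set_a <- .geneset_from_cds(genome_ids[1], c(cds_a[keep_a], gain_a))
  set_b <- .geneset_from_cds(genome_ids[2], c(cds_b[keep_b], gain_b))
  both <- keep_a & keep_b
  truth <- list(
    ortholog_map = data.frame(gene_a = ids_a[both], gene_b = ids_b[both],
                              identity_pct = ident[both],
                              stringsAsFactors = FALSE),
    gained_a = names(gain_a), gained_b = names(gain_b),
    lineage_specific_a = c(ids_a[keep_a & !keep_b], names(gain_a)),
    lineage_specific_b = c(ids_b[keep_b & !keep_a], names(gain_b)),
    config = config)
  structure(list(geneset_a = set_a, geneset_b = set_b, truth = truth),
            class = "simulated_pair")
}

#' @export
print.simulated_pair <- function(x, ...) {
  cat(sprintf(
    "<simulated_pair> %s (%d genes) / %s (%d genes), %d true orthologs\n",
    x$geneset_a$genome_id, length(x$geneset_a),
    x$geneset_b$genome_id, length(x$geneset_b),
    nrow(x$truth$ortholog_map)))
  invisible(x)
}

#' Simulate a star clade of genomes from one ancestor
#'
#' Every lineage is mutated independently from the same ancestral gene
#' pool (star phylogeny), so all pairs are exchangeable and each pair's
#' expected divergence equals `p_sub`. Indels are not applied in clade
#' mode.
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param config A [simulation_config()].
#' @param genome_ids Optional identifier tokens (default `sim1..simN`).
#' @return A `simulated_clade`: `genesets` (list of `gene_set`) and
#'   `truth` with `presence` (ancestor-by-genome matrix of gene IDs,
#'   `NA` where lost), `gained` (per-genome novel gene IDs), and the
#'   config.
#' @export
simulate_clade <- function(n_genomes, config = simulation_config(),
                           genome_ids = sprintf("sim%d", seq_len(n_genomes))) {
  stopifnot(n_genomes >= 2L, length(genome_ids) == n_genomes)
  set.seed(config$seed)
  q <- .lineage_rate(config$p_sub, config$ts_tv_ratio)
  n <- config$n_genes
  anc <- vector("list", n)
  for (i in seq_len(n))
    anc[[i]] <- .random_cds_codes(.random_gene_length(config$gene_length_range))
  presence <- matrix(NA_character_, n, n_genomes,
                     dimnames = list(NULL, genome_ids))
  genesets <- vector("list", n_genomes)
  gained <- vector("list", n_genomes)
  names(gained) <- genome_ids
  for (g in seq_len(n_genomes)) {
    ids <- sprintf("%s_g%04d", genome_ids[g], seq_len(n))
    cds <- setNames(vapply(anc, function(a)
      paste(.BASES[.mutate_codes(a, q, config$ts_tv_ratio)],
            collapse = ""), character(1)), ids)
    keep <- runif(n) >= config$loss_rate
    presence[keep, g] <- ids[keep]
    gains <- .novel_genes(rpois(1L, config$gain_rate),
                          sprintf("%s_n", genome_ids[g]),
                          config$gene_length_range)
    gained[[g]] <- names(gains)
    genesets[[g]] <- .geneset_from_cds(genome_ids[g],
                                       c(cds[keep], gains))
  }
  structure(list(genesets = genesets,
                 truth = list(presence = presence, gained = gained,
                              config = config)),
            class = "simulated_clade")
}

#' Write a simulated pair to per-genome FASTA files plus truth JSON
#'
#' Writes `<genome>.fna` / `<genome>.faa` for both genomes and a
#' `truth.json` holding the orthology map, realized identities,
#' lineage-specific gene sets and the configuration.
#'
#' @param sim A `simulated_pair`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_simulated_pair <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_pair"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (gs in list(sim$geneset_a, sim$geneset_b)) {
    write_fasta(gs$cds, file.path(dir, paste0(gs$genome_id, ".fna")))
    write_fasta(gs$protein, file.path(dir, paste0(gs$genome_id, ".faa")))
  }
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
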