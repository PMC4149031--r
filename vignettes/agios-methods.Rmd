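---
title: "Genome relatedness from orthologous gene identity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome relatedness from orthologous gene identity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agioskit)
```

## The statistic

When a new bacterial isolate is described, its genome is compared with the
genomes of its closest relatives. One family of relatedness statistics
averages nucleotide identity over the genes two genomes share. `agioskit`
implements such a statistic — the average genomic identity of orthologous
gene sequences (AGIOS) — in three steps for each genome pair:

1. **Ortholog detection.** Every protein of genome A is compared with every
   protein of genome B by affine-gap Smith–Waterman alignment. Alignment
   scores are converted to expectation values with the Karlin–Altschul
   model \(E = K m n e^{-\lambda S}\). Gene pairs that are each other's
   best hit in both directions — after significance, identity, and
   coverage filters — are accepted as 1:1 orthologs.
2. **Gene alignment.** For each ortholog pair, the annotated nucleotide
   CDS sequences are aligned globally (Needleman–Wunsch, affine gaps) and
   the percent identity recorded.
3. **Averaging.** AGIOS is the unweighted mean of the per-pair percent
   identities. For a set of genomes the pairwise results are arranged in a
   square matrix: diagonal = gene counts, upper triangle = shared ortholog
   counts, lower triangle = AGIOS.

Alongside the statistic the package provides ORFan classification (genes
with no significant homolog in a reference collection), genome summary
statistics (size, G+C, coding density, COG category tables), and 16S rRNA
identity with the 98.7 % species-delineation threshold.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| nucleotide match / mismatch | +5 / −4 | EMBOSS-needle convention, the de-facto default for identity-style genome comparison |
| nucleotide gap open / extend | 10 / 0.5 | same convention; a gap of length *k* costs `open + (k−1)·extend` |
| protein matrix, gaps | BLOSUM62, 11 / 1 | standard gapped protein search scoring |
| Karlin–Altschul λ, K | 0.267, 0.041 | the standard gapped BLOSUM62 constants, so internal E-values are comparable with the BLASTP-style thresholds used for ORFan calling |
| effective lengths m, n | raw lengths | no edge-effect correction; any correction only shifts explicit thresholds |
| significance rule | E < 1e−3 if alignment > 80 aa, else E < 1e−5 | the two-tier threshold used for ORFan definition; short alignments need the stricter cutoff because short chance alignments are common |
| RBH filters | identity ≥ 25 %, coverage ≥ 0.5, keep E ≤ 1e−5 | customary ortholog-search filters; all configurable via `agios_config()` |
| identity denominator | all columns | see below |
| 16S threshold | 98.7 % | the accepted boundary below which a new species may be proposed without DNA–DNA hybridization; the boundary value itself counts as "same species not excluded" because the criterion is being *lower* than the threshold |

### The identity denominator

Percent identity of a global alignment can divide by all alignment columns
(terminal and internal gaps included) or only by columns where both
sequences have a residue. The method's original description does not fix
the convention. The package defaults to **all columns** — the most literal
reading of "percent identity of the global alignment" — and exposes
`identity_denominator = "aligned"` on `agios_config()` and
`alignment_identity()` for the other convention. For orthologous CDS pairs
of similar length the two differ by well under a percentage point.

### Mean vs weighted mean

AGIOS averages per-gene percentages without length weighting ("mean
percentage of identity among orthologous genes" is a mean over genes, not
over sites). A length-weighted variant is available behind
`agios_config(weighted = TRUE)` for sensitivity analysis.

## The simulator: what it emulates, and what it does not

`simulate_pair()` draws an ancestral gene pool (uniform base composition,
in-frame stop codons resampled; lengths uniform over multiples of 3 in
300–1500 nt — the typical bacterial CDS range) and evolves it down two
independent lineages:

* **Substitutions** are independent per-site Bernoulli draws with a
  transition bias of κ = 2 (given a substitution, a transition is chosen
  with probability κ/(κ+2)). A per-site Bernoulli process is not a
  continuous-time substitution model, but it has closed-form expectations,
  which is what a validation harness needs.
* **Calibration.** `p_sub` is defined as the *expected pairwise per-site
  difference* between the two descendants. Two lineages mutating at
  per-lineage rate *q* collide on the same target base with probability
  \(c = t^2 + 2v^2\) (t, v the transition/transversion target
  probabilities), giving pairwise identity \((1-q)^2 + cq^2\). The
  simulator therefore applies
  \(q = \frac{1 - \sqrt{1 - (1+c)\,p}}{1+c}\)
  per lineage, so the expected AGIOS of a simulated pair is exactly
  \(100(1 - p_\mathrm{sub})\) and parameter-recovery tests compare against
  that closed form directly. With κ = 2, c = 0.375 and the calibration is
  feasible for `p_sub` ≤ 0.727.
* **Indels** (optional) are single codon-length insertions or deletions,
  at most one per gene per lineage, keeping every CDS in frame. The true
  alignment is tracked through the event, so realized identities in the
  truth table remain exact.
* **Turnover.** Genes are lost per lineage with `loss_rate`; novel genes
  (uniform-composition random sequences, guaranteed non-homologous at
  desk scale) are gained Poisson(`gain_rate`) per lineage. Gained genes
  are the ground-truth ORFan analogues.
* **Stop handling.** Any in-frame stop codon created by mutation is
  re-targeted (the substituted site is redrawn among the remaining bases),
  so all proteins translate cleanly. This perturbs the per-site model at a
  few sites per genome — far below the resolution of any test tolerance.

What the simulator does **not** emulate: codon usage bias, selection,
rearrangement, recombination, co-orthology (gene families), horizontal
transfer, or assembly artefacts. A green parameter-recovery test therefore
establishes that the pipeline measures what it claims on exchangeable,
star-phylogeny data with known divergence — not that it reproduces every
property of real annotations. The published-genome comparisons that would
test the latter require downloading the deposited assemblies and are out
of desk scale.

## Numerical and algorithmic choices

* **Alignment DP.** Global and local affine-gap alignment are a single
  three-state (Gotoh) dynamic program in C++; tie-breaks are fixed
  (column state preferred in the order match > gap-in-b > gap-in-a, i.e.
  diagonal > up > left), so tracebacks are deterministic. Unit tests
  compare scores against an independent enumeration oracle written in
  plain R.
* **Search prefilter.** All-vs-all protein search skips pairs sharing no
  protein 5-mer (`mode = "kmer"`, the default); `mode = "exact"` aligns
  every pair. On test-scale data the prefilter reproduces exact-mode
  significant hits; at high divergence it can in principle miss a small
  tail of weak orthologs, which biases AGIOS upward by well under the
  test tolerances (measured ≪ 0.2 pp at 25 % divergence).
* **Best-hit ties** are broken by bit score, then E-value, then
  lexicographic partner ID. The ordering is arbitrary but fixed;
  reciprocal best hits are therefore deterministic and strictly 1:1.
* **Zero orthologs** yield `NA` AGIOS (never 0), so empty comparisons
  cannot corrupt range summaries.
* **Rounding** to 2 decimals happens only at TSV serialization; all
  internal values keep full precision.
* **Degenerate inputs.** Empty sequences, mixed alphabets, out-of-bounds
  coordinates and unknown COG letters are errors; CDS/protein length
  disagreement is a warning (real annotations contain pseudogenes and
  frameshifts, and the statistic only needs paired sequences).

## Design choices where the field is genuinely open

* **Ortholog criterion.** Published pipelines often build co-orthology
  groups; this package deliberately uses strict 1:1 reciprocal best hits,
  the deterministic core of those pipelines, because a pairwise mean
  identity is defined over 1:1 pairs. Co-ortholog expansion is a
  non-goal.
* **ORFan direction.** The two-tier threshold rule is stated in the
  literature as the condition a hit must meet; an ORFan is a gene none of
  whose hits meets it (genes with no hits at all are ORFans). ORFan
  calling accepts any externally produced 12-column hit table, so a
  search against a large reference database can be slotted in; the
  package does not search such databases itself.
* **Coding density** uses the union of CDS intervals (overlapping genes
  counted once). Published genome tables rarely state their convention;
  the union is the defensible one and is what the per-base oracle tests
  check.
* **Range reporting** always distinguishes the overall lower-triangle
  range from the range against a focal genome — published prose ranges
  are ambiguous between the two.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_genes = 60, p_sub = 0.10, seed = 42)
sim <- simulate_pair(cfg)
cmp <- compare_pair(sim$geneset_a, sim$geneset_b)
cmp$n_orthologs   # 60: every ancestral gene recovered
cmp$agios_pct     # ~90: matches 100 * (1 - p_sub)
mean(sim$truth$ortholog_map$identity_pct)  # ground truth, ~90
```

Every number this vignette claims is recomputed by the test suite
(`tests/testthat/`, in particular `test-acceptance.R`) or by
`scripts/acceptance.R`; the vignette states no empirical result beyond
those.

## Known limitations

* The Karlin–Altschul constants are applied to raw Smith–Waterman scores
  without edge-effect correction or composition adjustment; internal
  E-values are comparable with each other and adequate for thresholding,
  but are not BLAST replicas.
* The k-mer prefilter is a sensitivity/speed trade-off; for maximal
  fidelity on small inputs use `agios_config(search_mode = "exact")`.
* AGIOS is only defined over detected orthologs; two genomes sharing few
  genes produce a mean over a small, non-random sample of their gene
  content.
* The simulator's star phylogeny cannot produce topology-dependent
  effects; it validates a pairwise statistic only.
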