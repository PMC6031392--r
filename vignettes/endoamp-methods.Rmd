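---
title: "Detecting Endozoicomonas in amplicon surveys: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Endozoicomonas in amplicon surveys: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoamp)
```

# The problem

*Endozoicomonas* (Gammaproteobacteria: Hahellaceae) is a widespread,
putatively symbiotic associate of reef-building corals. General-purpose
16S rRNA surveys dilute it among the whole bacterial community, so a
taxon-specific assay pairs the universal forward primer 27F with a
genus-specific reverse primer, En771R, that carries a *deliberate*
single-base mismatch. The engineered base breaks annealing on the
CAG-repeat region of the nearest non-target relative (a *Simiduia*-like
lineage) — which the un-engineered "matched" consensus would still
amplify — while every target sequence remains within the tolerated
mismatch budget. This package implements the full computational side of
that assay: primer design and in-silico evaluation, read QC, naive-Bayes
classification with multi-database rescue, ribotype/OTU/diversity
analysis, and K2P-based divergence, all exercisable on a synthetic
community generator with complete ground truth.

# In-silico PCR model

`iupac_mismatches()` uses set semantics: a primer code matches a target
base iff their expansion sets intersect; `N` in a reference never
matches (conservative against database ambiguity). `predict_amplicon()`
declares a product iff both primers find a site with

* total mismatches ≤ 1 (`max_mm`), and
* zero mismatches in the 3′-terminal 4 nt (`three_prime_protect`).

There is no melting-temperature model; this qualitative rule is the
simplest one that reproduces the matched/mismatched discrimination
behaviour of the wet assay (one engineered mismatch on top of one
natural mismatch blocks extension; a single natural mismatch does not).
It is calibrated only on the synthetic CAG fixture, which is the honest
statement of its scope. When several site pairs exist the shortest
product is reported; coordinates are 0-based half-open with reverse
sites on the forward strand.

`design_discriminative_primer()` slides a window over a
target/outgroup alignment, forms the degenerate target consensus
(most-frequent bases added until the conservation fraction is covered),
and — if the consensus does not already separate the outgroups — tries
every single-base substitution outside the 3′-protected zone, keeping
the one that maximizes the minimum outgroup mismatch count subject to
the per-target budget. A candidate is only emitted when every outgroup
mismatches it *strictly more* than the worst-matching target does;
without this margin a degenerate "engineered" base that mismatches
everything equally would count as discriminative. Ranking is
lexicographic (min outgroup mismatches desc, target mismatch sum asc,
position asc) for determinism.

# Read QC

The quality filters mirror the published processing rules: the
universal-primer dataset keeps reads of 280–350 nt, mean Phred > 20,
homopolymer < 8 nt and no `N`; the specific-primer dataset keeps reads
≥ 380 nt with no upper bound. Criteria are checked in that order and
the first violation is the reported reason, so filter reports are
stable. Mean quality is the arithmetic mean of raw Phred scores
(Phred+33), not error probabilities.

Demultiplexing is exact on the 4-nt tag — 4-nt tags leave no safe
mismatch margin — and tolerates one degenerate-aware mismatch in the
primer prefix so that a sequencing error in the primer region does not
discard the read. Reads whose primer prefix exceeds that tolerance go
to the unassigned bin (stripping an unrecognizable primer would be
guesswork), which keeps the assigned/unassigned partition exact.

The bimera screen tests each unique sequence against pairs of
more-abundant candidates (parent abundance ≥ 2× query). A query is
chimeric iff some single-crossover model reconstructs it with at most 1
residual mismatch per side, beats the best single parent, and wins the
two-parent vote by ≥ 2 mismatches per side. The model is positional
(no alignment), which makes it brute-force verifiable; the trade-off is
that homopolymer indel errors shift the frame and mask chimeras in
erroneous reads, so on raw 454-style reads the screen mainly removes
error-free chimeric ribotypes. Full UCHIME scoring is out of scope.

# Classification and rescue

`train_classifier()` is the standard naive-Bayes formulation on 8-mer
presence: word prior $P_w = (n_w + 0.5)/(N + 1)$ and genus-conditional
$P(w\mid g) = (m_{wg} + P_w)/(M_g + 1)$. A read is scored by the sum of
log conditional probabilities of its distinct words; bootstrap
confidence draws $\lceil k/8\rceil$ of the $k$ words per trial (100
trials). Per-rank confidence is the fraction of trials whose winner
shares the assigned lineage *down to that rank*, which makes confidence
non-increasing from domain to genus by construction; assignment is
truncated at the deepest rank reaching the 0.8 cutoff. Ties between
equal-scoring genera break lexicographically and deterministically.

`rescue_classify()` reproduces the survey's multi-database procedure:
reads unclassified at the trigger rank (default genus) are reclassified
against each secondary reference set, and a read counts toward the
combined target if any database applies a target label (the label set
may name a genus in one database and a family in another). Reads
primary-assigned to the target but not target-labelled by any secondary
database are set aside as "distantly related" and excluded from
target-specific analyses. The published criterion for that discard is
not stated; cross-database agreement is this package's stand-in, and
the reads are counted separately in the summary so the rule is
auditable. Percentages are rounded half-away-from-zero to one decimal,
matching the printed arithmetic (e.g. 65,305/75,551 → 86.4%, plus
6,948 rescued → 95.6%).

# Ribotypes, OTUs and diversity

Dereplication keeps singletons (`-minsize 1` behaviour) and profiles
each unique sequence as a percentage of its sample. Greedy centroid
clustering at 3% divergence is UPARSE-style: abundance-sorted uniques
either join the highest-identity centroid at ≥ 97% or seed a new OTU.
Identity is matches/columns of a global alignment with free terminal
gaps (match +1, mismatch −1, gap −2), each internal gap column counting
as one difference. A shared-8-mer prescreen skips centroids that cannot
plausibly reach the threshold — the same class of word-count heuristic
greedy clustering tools use; UPARSE's exact internals are deliberately
not reproduced. On every instance of ≤ 12 uniques the result is
property-tested against a brute-force reimplementation.

Rarefying subsamples without replacement to an even depth (500 by
default; the published sensitivity comparison used 2,496), dropping and
logging samples below depth; the empirical expectation is tested
against the hypergeometric closed form
$E[S] = \sum_i 1 - \binom{N-n_i}{d}/\binom{N}{d}$. Whether the printed
tables used one subsample draw or an average is unstated; the default
here is a single seeded draw.

Diversity indices follow the tables: Shannon $H$ with natural log,
Gini-Simpson $1-\sum p_i^2$, evenness $E = H/\ln S_{obs}$ (the
natural-log convention back-calculates from the printed values:
$2.20/\ln 88 = 0.491$ and $2.61/\ln 54 = 0.65$), and a richness
statistic defined as $S/(N+1)$ with $S$ the singleton-OTU count and $N$
the OTU count. That definition is a singleton ratio rather than a
richness estimator; it is implemented verbatim because it is what the
tables print, and it is documented as such. The specific-vs-universal
comparison rarefies both co-clustered tables, removes OTUs whose total
count is exactly 1 (in that order), then counts shared and private
OTUs.

# Divergence and trees

`k2p_distance()` implements
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$ with explicit $P$
(transition) and $Q$ (transversion) fractions and per-pair saturation
flags; saturated pairs are excluded from group means with a warning
rather than propagating infinities. The matrix is cross-checked against
an independent reference implementation in the tests. Complete deletion
removes every column containing a gap, `N` or ambiguity code before
distance estimation. Group divergence reports the mean over the
relevant pairs with a standard error from 500 site-bootstrap
replicates (the convention of the original analysis tool).

Trees are canonical neighbor-joining on the K2P matrix with negative
branch lengths clamped to zero and bipartition support from
site-resampled replicates. The original study's maximum-likelihood
Tamura–Nei tree is deliberately replaced: NJ on K2P is deterministic,
desk-scale, and the quantitative claims rest on distances rather than
on a specific topology. The published 28-accession GenBank panel
analysis (`reference_panel_divergence()`) needs network access and an
aligner and is therefore isolated in its own driver; everything else
runs offline.

# The synthetic community generator

`default_panel()` encodes the study conditions once: a 900 nt root with
the 27F site at position 100, a universal reverse site near 450, and
the specific site ending at 850 — giving the assay's ~750 bp product —
over five clades: the target genus (10 taxa, depth 0.05
substitutions/site), a sister genus within the family (6 taxa), a
near-neighbor carrying 2 mismatches at the specific site (the
*S. agarivorans* analogue), and two distant outgroups with 4
mismatches. Substitutions are per-site independent with transition
probability $\kappa/(\kappa+2)$ ($\kappa = 2$), which is exactly the
process K2P estimates, so distance recovery is testable
(depth 0.025 per lineage recovers a within-clade mean of ≈ 0.05).

`simulate_amplicon_reads()` emits `barcode + forward primer + amplicon`
reads with per-base substitution errors (0.005), homopolymer run
±1 indels (0.01 per run ≥ 3 nt — the 454-characteristic error),
single-crossover bimeras (5% of reads, crossover uniform in the middle
50%), up to 30 nt of 3′ length jitter, and Q30/Q10 quality strings.
Default library size is 600 reads per sample across four samples
(three target-dominated 85/15 coral-like samples, one even
seawater-like sample), chosen so rarefying at depth 500 retains the
coral samples; tests use smaller sizes of the same design. Barcodes are
synthesized error-free so the demultiplexing round-trip against ground
truth is exact; real tag errors would only move reads to the unassigned
bin.

What the generator does *not* emulate: flowgram-level 454 noise,
PCR-efficiency bias between templates, indel variation between
reference taxa (so template-guided alignment degeneracies are exercised
with constructed indels rather than evolved ones), and realistic
chimera breakpoint hotspots. Passing tests therefore demonstrate
algorithmic correctness under a controlled error model, not end-to-end
performance on real pyrosequencing data.

# Numerical and reproducibility choices

* One global seed fans out to stage-name-derived child seeds
  (`child_seed()`), so any stage can be rerun independently with
  identical results; per-read bootstrap seeds derive from read ids,
  making classification order-independent.
* All reported percentages round half-away-from-zero at one decimal;
  internal computation is full precision.
* Ties everywhere (classifier genera, clustering centroids, design
  ranking) break lexicographically or by abundance, never by input
  order alone.
* The K2P-to-p-distance convergence tolerance follows the Taylor
  remainder, which is $O((P+Q)^2)$: agreement is ~$10^{-4}$ at
  $P+Q = 0.01$ and ~$10^{-6}$ at $P+Q = 0.001$.
* Problem sizes in the tests (hundreds of reads, ≤ 12-unique oracle
  instances, 100-replicate bootstraps) are chosen as the smallest sizes
  at which every property is informative; the analysis drivers use the
  full default conditions.

# Known limitations

* The in-silico amplification rule is qualitative; primers with
  marginal thermodynamics may behave differently in vitro.
* The positional bimera model misses chimeras in reads that carry
  homopolymer indels upstream of the crossover.
* The "distantly related" discard is a cross-database-agreement
  stand-in for an unstated published criterion and is flagged in the
  rescue summary.
* Template-guided alignment discards query insertions relative to the
  template (NAST-style), so insertion-rich novel ribotypes lose
  information by design.

# A minimal session

```{r example, eval = FALSE}
library(endoamp)

panel <- default_panel(seed = 101)
ev <- evaluate_primer_pair(primer_27f(), primer_en771r(), panel,
                           "Endozoicomonas")
ev$sensitivity; ev$specificity

report <- run_pipeline(pipeline_config(seed = 1))
report$specificity
report$diversity
```

The numbered scripts under `analysis/` run the same stages as a
narrative workflow and write their tables under `results/`.
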