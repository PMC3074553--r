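---
title: "Methods: gene-centric Alu distribution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-centric Alu distribution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aludist)
```

## Scope and units

`aludist` measures where Alu retrotransposons sit relative to genes and what
that placement associates with. The measurement unit throughout is the gene
(more precisely, the reference transcript), never a fixed-length sliding
window: an Alu burden of 1 per Knt means something different inside a 3 Knt
gene than spread over a megabase bin, and the downstream questions (mutation
classes of cancer genes) are gene-level questions.

Every density in the package is a count divided by an *Alu-adjusted* length
in Knt (kilo-nucleotides). Adjusting means excluding the nucleotides covered
by Alu elements themselves from the denominator, so that a gene packed with
Alus is not mechanically diluted by the very sequence those Alus contribute.
For one transcript:

* `Si = (span - exons - clipped intron-Alu nt) / 1000`, the adjusted intron
  length;
* `Se = (exons - clipped exon-Alu nt) / 1000`, the adjusted exon length;
* `Di = Ni / Si` and `De = Ne / Se`, the intron and exon Alu densities.

An Alu overlapping the transcript span by at least one nucleotide counts
toward the transcript total `Nt`; it is an exon Alu if it overlaps any exon
by at least one nucleotide (this covers both exonic and exonized insertions),
otherwise an intron Alu, so `Ni = Nt - Ne` by construction. Genes annotated
with several multi-exon transcripts on one chromosome and strand get the
arithmetic mean over transcripts. Single-exon transcripts carry no intron
and are dropped; a gene is excluded only when all its transcripts are
single-exon.

Two tie-breaks deserve notice because the definitions do not force them:

* an Alu straddling an exon/intron boundary is an **exon** Alu (the 1-nt
  exon-overlap rule), consistent with counting `Ne` first and obtaining `Ni`
  by subtraction;
* Alu length is clipped to the region the Alu is assigned to (and to the
  span), so a boundary-straddling exon Alu removes only its exonic
  nucleotides from `Se` and leaves its intronic overhang in `Si`. This keeps
  both adjusted lengths local and non-negative.

Motif densities (`Mi`, `Me`, default motif `TTAAAA`, the preferred
L1-endonuclease cleavage signal that initiates Alu integration) use the same
geometry and the same denominators. Motif occurrences overlapping an
assigned Alu are by default **not** counted: the denominator already
excludes Alu nucleotides, and counting motif copies carried inside Alu
sequence would correlate the numerator with Alu content mechanically. The
source definitions are explicit only about the denominator; the numerator
exclusion is this package's choice, reversible with
`count_motifs_in_alus = TRUE`.

Two composite features proxy Alu/Alu recombination potential: the
**Alu-pair density** counts consecutive intron Alus whose gap
(next start − previous end) is strictly below 300 nt, divided by `Si`; the
**Alu-exon-Alu triplet count** counts exons flanked on both sides by an Alu
within a sub-300-nt gap. Gaps are inter-interval distances (not midpoint
distances) — the only reading under which a "distance less than 300 bases"
is meaningful for elements that are themselves ~300 nt. Triplets are counted
per exon, so one Alu sitting between two close exons can serve both. The
transcript-averaged triplet count may be fractional and is kept so.
GC content is computed on the gene span after masking all Alu-covered
nucleotides (ambiguous bases excluded from numerator and denominator), so it
reflects the genomic environment Alus integrated into rather than the
elements' own base composition.

Chromosome-level densities pool counts over pooled adjusted lengths (never a
mean of gene-level densities). Intergenic regions are the complement of the
merged transcript spans; an Alu is intergenic when it overlaps no span.

Internally all coordinates are 0-based half-open; BED enters unchanged, GTF
(1-based closed) and RepeatMasker `.out` (1-based closed) are converted at
the I/O boundary only. Repeat strand is read but ignored downstream — no
quantity here conditions on element orientation.

## The zero-inflated Gamma mixture

Roughly 30% of multi-exon genes carry no intron Alu at all, at every gene
size, so neither a mean/SD summary nor a log transform is adequate.
`fit_mixture()` models gene-level intron Alu density as a point mass at zero
with weight `p0` plus `(1 - p0)` times a Gamma density on the positive
values:

* `p0` is estimated by `r`, the observed fraction of exact zeros. "Zero"
  means exactly zero — `Ni` is an integer count, so no epsilon threshold is
  involved;
* the Gamma shape and scale are fitted by maximum likelihood on the strictly
  positive subset.

The ML fit (`fit_gamma_ml()`) profiles the scale out (`scale = mean/shape`)
and solves the score equation `log(k) - digamma(k) = log(mean) - mean(log)`
by Newton iteration, started from the moment estimator `mean^2/var`,
converged when successive shape iterates differ by less than 1e-10
(relative), failing after 200 iterations. A step that would leave the
parameter space is halved. Degenerate input (fewer than two distinct
positive values) is an error, and a fit with no positive values is flagged
rather than fabricated.

The fitted object is a classed model (`"zig_fit"`) with `print`, `summary`,
`coef`, `logLik`, `simulate` and `plot` methods. `mixture_density()`
evaluates the adjusted curve `(1 - r) * dgamma(x; shape, scale)` — the zero
mass plus the area under this curve is one, a property the tests verify to
1e-6 for all 24 published chromosome parameter sets — and returns the Gamma
moments (`mean = shape * scale`, `variance = shape * scale^2`).
`qq_points()` uses midpoint plotting positions `(i - 0.5)/n`; the
published analyses do not state their plotting convention, and the midpoint
rule is the standard default.

A note on naming: the published per-chromosome table
(`hg18_intron_alu_params()`) is reproduced with `shape` ≈ 0.615 and `scale`
≈ 1.303 for chromosome 1. The source text swaps the Greek letters for shape
and scale internally; this package follows the numbers (the moments
`E = shape * scale` ≈ 0.80 only make sense that way) and avoids the Greek
names entirely. Where two printed values conflict (1.303 vs 1.313 for the
chromosome-1 scale), the table value 1.303 is used.

## Two-step motif regression

A single linear model cannot express the motif effect when a third of the
responses are exact zeros. `two_step_motif_analysis()` therefore fits, per
chromosome:

* **Model-1** — logistic: `[Di > 0] ~ Mi + log10_size` over all multi-exon
  genes (does the motif density predict whether a gene holds any intron Alu
  at all?);
* **Model-2** — ordinary least squares: `Di ~ Mi + log10_size` over the
  genes with `Di > 0` (does it predict how much?).

`log10_size` is the log10 of the Alu-adjusted gene length in nt; gene size
enters both models because it affects Alu presence strongly. Model-2 uses
the **raw** density as response, exactly as the model equation is written in
the source, even though the surrounding motivation discusses log
transformation; `log_response = TRUE` offers the alternative reading.
Per-term p-values are Wald tests (the source does not name its test;
for the single linear term the t and F tests coincide). The motif-term
p-values are Benjamini–Hochberg adjusted across chromosomes separately
within each model, matching the two axes of the published scatter.
Contributions are reported as the increase in Nagelkerke pseudo-R²
(Model-1) or plain R² (Model-2) from adding the motif term to the size-only
reduced model, clipped at zero. Logistic fits go through `stats::glm`
(IRLS, log-likelihood tolerance 1e-10); the test suite checks them against
a hand-rolled IRLS oracle to 1e-8, and perfect separation is surfaced as a
warning with finite capped estimates. Chromosomes with fewer than 10 genes
(configurable), constant presence, or fewer than four Alu-containing genes
are skipped with a diagnostic rather than fitted badly.

## Class associations, clustering, enrichment

`class_association()` is a logistic regression of a binary gene class
(recessive vs dominant, germline vs somatic, non-translocation vs
translocation) on intron Alu density and log10 gene size, optionally
adding exon Alu density or the distance to the nearest fragile-site
midpoint (`nearest_site_distance()`, measured from the gene-span midpoint).
Records with ambiguous dominance ("Rec?") are excluded from the
dominant/recessive comparison only; genes mutated in both cell compartments
from the somatic/germline comparison only.

`cluster_genes()` performs complete-linkage agglomerative clustering with
Euclidean distance on five features: `Di`, `De`, pair density, triplet
count, GC content. Features enter **unscaled** by default. The source never
states whether it standardized; unscaled is inferred from its absolute cut
height (4.5) and from the fact that a single gene is isolated by its raw
triplet count — neither is coherent after z-scoring. `scale = "zscore"`
is available. The cut height is a parameter (default 4.5, a value the
source itself calls heuristic); `cut_dendrogram()` returns the connected
components below the cut, singletons allowed.
`cluster_class_enrichment()` pools the focus clusters against the remaining
non-singleton clusters — singletons belong to neither pool, mirroring the
published 48-vs-302 comparison that sets a singleton gene aside — and tests
the 2×2 table with `fisher_exact_2x2()`: exact two-sided p by the
point-probability rule (the sum of hypergeometric probabilities not
exceeding the observed table's), odds ratio reported as the sample
`ad/(bc)`. On the published table `[[22, 26], [53, 249]]` the two-sided p is
4.0e-5 and the one-sided 3.6e-5; the printed 3.8e-5 lies between the two,
so the conventional two-sided default is kept and the worked-example test
asserts at printed precision.

## What the synthetic genome emulates — and what it does not

`simulate_genome()` exists so every pipeline stage is testable offline with
known ground truth. Per chromosome it draws, for each gene:

* a span length `10^N(4.4, 0.5)` nt — annotation-scale, log-normal, matching
  the shape and center of real multi-exon gene-length distributions;
* an exon count `2 + Geom(0.12)` (about 10 exons on average, multi-exon by
  construction) with log-normal exon lengths (median 140 nt, floored at
  30 nt), intron lengths split by a symmetric stick-breaking rule;
* a target intron Alu density from the chromosome's zero-inflated Gamma
  mixture; the default four chromosomes use the published parameter sets of
  chr1, chr7, chr19 and chrY — the densest, an intermediate, the
  Alu-richest and the extreme zero-inflated case — at 200 genes each;
* the number of inserted Alus as `round(d * Si)` where `Si` is the
  *post-placement* adjusted intron length, i.e. the self-consistent count
  `n = d * L_intron / (1000 + 300 d)`. Using the pre-placement length
  instead would inflate realized densities by `1/(1 - 0.3 d)`, badly
  distorting the upper tail. Realized density therefore differs from the
  target only by integer rounding, and the truth table records both;
* uniform non-overlapping placement of 300-nt Alu tags within introns
  (a fixed synthetic tag of configurable GC, not a real Alu consensus —
  every feature except GC depends on coordinates only, and the tag contains
  no TTAAAA);
* motif copies planted in Alu-free intron sequence at a per-gene rate
  (mean 1.0 per Knt, CV 0.5), on top of the ~0.24 per Knt that uniform
  i.i.d. background sequence contains by chance (4^-6 per position);
* optional couplings: `beta_presence` shifts the presence logit and
  `beta_intensity` the positive density linearly in the (centred) motif
  rate — the generative twins of Model-1 and Model-2;
* intergenic gaps U(1000, 5000) nt carrying background Alus at 0.2 per Knt.

Everything is a pure function of `(spec, seed)`; the emitted FASTA, BED12
and BED6 parse with the package readers, and feature extraction reproduces
the recorded realized densities *exactly* — this round-trip is the
generator's defining invariant and is asserted in the tests.

What it does **not** emulate: real Alu sequence (subfamilies, divergence,
poly-A structure), exonic/exonized Alus (the simulator inserts into introns
only, so synthetic `De` is zero), GC isochores, selection, overlapping gene
models, or any coupling between gene size and Alu density beyond what the
mixture induces. Passing tests on synthetic data therefore demonstrate the
correctness of the measurement and inference machinery, not that real
genomes satisfy the model.

**A granularity limitation worth understanding.** A gene with adjusted
intron length `Si` can only realize densities `0, 1/Si, 2/Si, ...`; values
below `1/Si` do not exist at the coordinate level. For small Gamma shapes
(chrY's published shape is 0.217) the continuous mixture puts substantial
mass below that floor, so an ML Gamma fit to realized densities is biased
upward in shape relative to the latent generating value — at any feasible
gene size, and equally for a fit to real annotation-derived densities. The
full-loop test therefore checks the zero fraction against the generating
`r` (rounding never moves a gene across zero) and checks shape/scale
against the *granularity-matched law*: the same discretized density
distribution sampled directly, without coordinates or files. Recovery of
the latent parameters themselves is demonstrated on the continuous
sampling route (`simulate_density_sample()`), where the chromosome-1
conditions (N = 1928, r = 0.281, shape 0.615, scale 1.303) are recovered
within Monte-Carlo tolerance over 20 seeds — that computation is what
`scripts/acceptance.R` reruns.

## Numerical choices and problem sizes

* Gamma ML: relative tolerance 1e-10 on the shape, 200-iteration cap,
  moment-estimator start, step-halving into the positive half-line.
* Logistic IRLS: `glm` with epsilon 1e-10, 100 iterations.
* BH adjustment: `stats::p.adjust`, input order preserved.
* Fisher two-sided: point-probability rule with a 1 + 1e-7 relative slack
  on the probability comparison, the standard guard against ties lost to
  floating point.
* Complete linkage: `stats::hclust`; merge heights are non-decreasing, and
  tests verify them against a brute-force agglomerator for n ≤ 12.
* Dendrogram cut: `stats::cutree` at a height, singletons permitted.
* Test problem sizes were chosen to keep the full suite within a few
  minutes on one core: the default synthetic genome is 4 chromosomes × 200
  genes (~50 Mnt), machinery tests use 25–40 genes per chromosome with
  shrunken gene lengths, brute-force property suites run 1000 randomized
  toys, the type-I-error study runs 1000 replicates of n = 300, and
  exhaustive Fisher enumeration covers all tables with total ≤ 24 plus 500
  randomized tables up to total 40.

## Known limitations

* Symbol reconciliation between annotation sources is out of scope: input
  gene symbols are taken as authoritative, and the same symbol on two
  chromosomes or strands is analysed as two genes.
* Motif scanning is exact-match, forward-strand; single-base-substitution
  motif variants are not expanded (the motif string itself is a parameter,
  so e.g. the recombination-associated `CCTCCCT` can be scanned).
* Multi-isoform exon-Alu clipping uses per-transcript exons; whether the
  original analysis used transcript unions is not recoverable from the
  source.
* The Weibull alternative to the Gamma component and joint EM over the
  mixture are deliberately not implemented: the plug-in `r` (observed zero
  fraction) is the documented estimator.
```{r example}
# worked micro-example: fit the mixture at the published chr1 conditions
x <- simulate_density_sample(0.281, 0.615, 1.303, n = 1928, seed = 1)
fit <- fit_mixture(x, group = "chr1-like")
fit
summary(fit)
```
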