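# aludist

Gene-centric analysis of Alu retrotransposon distribution and its
association with the mutation classes of cancer genes.

Alu elements are ~300 nt SINE retrotransposons — the most abundant mobile
element in the human genome — and a recurring source of genetic instability
through insertional mutagenesis and Alu/Alu non-allelic recombination.
`aludist` is for genome scientists who want to quantify Alu burden **per
gene** rather than per fixed-length window, and relate it to gene
properties such as dominant/recessive mutation classes of cancer genes.

## What it computes

**Densities on Alu-adjusted lengths.** For each multi-exon transcript, with
`Nt` Alus overlapping the span, `Ne` of them touching an exon and
`Ni = Nt − Ne` intronic:

```
Si = (span − exons − intron-Alu nt) / 1000 Knt     Di = Ni / Si
Se = (exons − exon-Alu nt) / 1000 Knt              De = Ne / Se
```

plus motif densities (`Mi`, `Me`; default motif `TTAAAA`, the
L1-endonuclease cleavage signal), adjacent Alu-pair density (gap < 300 nt),
Alu-exon-Alu triplet counts, Alu-masked GC content, and pooled
chromosome-level intron/exon/intergenic densities. Gene values average over
the gene's multi-exon transcripts.

**Zero-inflated Gamma mixture.** Gene-level intron Alu density within a
chromosome is modelled as

```
f(x) = r · 1{x = 0} + (1 − r) · Gamma(x; shape, scale)
```

with `r` the observed zero fraction and (shape, scale) fitted by maximum
likelihood (profile-likelihood Newton). `fit_mixture()` returns a classed
model with `print`, `summary`, `coef`, `logLik`, `simulate`, `plot`,
`mixture_density()` and `qq_points()` support.

**Inference.** A two-step regression of motif density on Alu presence
(logistic) and on positive Alu density (linear) per chromosome, with
Benjamini–Hochberg adjustment across chromosomes and Nagelkerke pseudo-R²
contributions; logistic class-association models; complete-linkage
clustering on the five Alu features with Fisher's exact enrichment of gene
classes in clusters.

**Synthetic genomes.** `simulate_genome()` emits FASTA + BED12 + BED6 with
per-gene ground truth so the entire pipeline runs and is tested without any
external genome resource.

## Worked example

```r
library(aludist)

# densities at the published chromosome-1 conditions, then refit
x <- simulate_density_sample(r = 0.281, shape = 0.615, scale = 1.303,
                             n = 1928, seed = 1)
fit <- fit_mixture(x, group = "chr1-like")
fit
#> Zero-inflated Gamma mixture fit [chr1-like]
#>   n = 1928  zeros = 544  (r = 0.2822)
#>   Gamma component: shape = 0.585, scale = 1.396 (logLik -937.9 on 1384 positive values)
```

The zero fraction 0.2822 estimates the probability that a multi-exon gene
carries no intron Alu; the Gamma component (mean `shape × scale` ≈ 0.82
Alus per Knt) describes the Alu-containing genes, recovering the generating
parameters within sampling error at n = 1928.

```r
# the cluster-enrichment worked example: 22/48 recessive genes in the focus
# clusters vs 53/302 elsewhere
res <- fisher_exact_2x2(matrix(c(22, 26, 53, 249), 2, 2, byrow = TRUE))
sprintf("p = %.3g, OR = %.3g", res$p_value, res$odds_ratio)
#> "p = 4e-05, OR = 3.98"
```

End-to-end on a synthetic genome:

```r
sim <- simulate_genome(synthetic_genome_spec(), seed = 1)
cfg <- pipeline_config(genes = sim$paths$genes, repeats = sim$paths$repeats,
                       fasta = sim$paths$fasta, outdir = "out")
report <- run_pipeline(cfg)     # features, densities, mixture fits, regressions
render_report(report)           # markdown summary + plot-ready TSVs
```

A thin CLI over the same functions ships in
`inst/scripts/alu-pipeline.R` (subcommands `simulate`, `extract`,
`fit-mixture`, `motif-regression`, `class-assoc`, `cluster`, `run-all`).

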