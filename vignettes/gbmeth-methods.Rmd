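---
title: "Methods and design notes for gbmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for gbmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind each stage of the
package, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the design decisions taken
where the methodology left genuine choices open. It states no numbers
that the test suite and `scripts/acceptance.R` do not themselves
compute.

## The site-calling model

A bisulfite experiment converts unmethylated cytosines to uracil (read
as T) while methylated cytosines remain C. A truly unmethylated site
can still read as methylated when conversion fails; the per-read
failure probability ε is estimated from an unmethylated spike-in
(classically λ phage DNA) as the pooled methylated-read fraction over
all control cytosines,

$$\hat\varepsilon = \frac{\sum_i m_i}{\sum_i (m_i + u_i)},$$

pooling across sites because conversion failure is a property of the
chemistry, not of genomic position. A site with $m$ methylated reads
out of $n$ is then tested with the one-sided upper-tail binomial
p-value $P(X \ge m)$, $X \sim \mathrm{Bin}(n, \hat\varepsilon)$: the
alternative of interest is always "more methylated reads than
conversion failure explains", which is why the test is one-sided.
$m = 0$ gives $p = 1$ by construction.

Depth filtering precedes testing: sites with fewer than 5 or more
than 30 reads are removed (both bounds inclusive in the retained set,
i.e. depths 5 and 30 are kept — the literal reading of "lower than 5"
and "higher than 30" being excluded). Shallow sites are uninformative;
very deep sites flag collapsed repeats and PCR stacks.

P-values are converted to q-values by the Benjamini–Hochberg step-up
procedure over all retained sites as a single genome-wide family,
across chromosomes and sequence contexts alike; a per-context option
exists but is off by default, since a single genome-wide procedure is
the conventional analysis. BH handles tied p-values through the
step-up minimum with shared ranks; no randomisation is involved, and
calls are invariant to input row order. Sites with q below the
threshold (default 0.01) are called methylated.

Beta-binomial overdispersion, single-site differential methylation and
smoothing are deliberately out of scope: the analyses downstream
operate on aggregated feature levels where overdispersion matters far
less.

## Weighted methylation and feature aggregation

The level of a region is the weighted methylation level
$W = \sum m_i / \sum (m_i + u_i)$, a read-weighted quantity: a site
covered by 20 reads carries twenty times the weight of a site covered
once. This differs from the mean of per-site fractions and is
associative under partitioning of the site list — a property the test
suite asserts exactly. $W$ is computed from raw counts of *all*
retained CpG sites in the feature regardless of call status; calls
feed only the companion metric `frac_sites_called`. An empty site list
gives a missing value, never 0.

A gene body means exons plus introns; UTRs inside the gene span count
as gene body. Genes with 10 or fewer covered CpG sites are dropped
from gene-level analyses (keep requires ≥ 11 — the strict reading of
"no more than 10 ... removed"). Transposable elements are `genic` when
fully contained in a gene span (TEs nested in introns are genic:
context is defined by gene overlap, not exon overlap), `intergenic`
when they overlap no gene, and `boundary` otherwise.

## Methylation and expression

Three analyses connect methylation to expression:

1. **Level.** Genes are binned by $W$ into low [0, 0.2], medium
   (0.2, 0.7] and high (0.7, 1] classes and their FPKM distributions
   compared by two-sided Wilcoxon rank-sum tests for every class pair.
   The published bin brackets overlap at 0.2 and 0.7; boundaries are
   assigned to the lower class, a deterministic and documented rule
   whose sensitivity is directly testable.
2. **Differential coupling.** Between two populations, per-gene
   differential methylation is $\Delta W = W_A - W_B$ (first argument
   minus second, stated everywhere it is printed) and differential
   expression is $\log_2((\bar F_A + c)/(\bar F_B + c))$ over
   replicate-mean FPKM, with pseudocount $c = 0.01$ FPKM — the source
   methodology is silent on zero handling, and a small constant
   preserves ordering while keeping silent genes finite. Because most
   genes barely differ in methylation, only the top 5% of $|\Delta W|$
   (after the ≥ 11-CpG rule in both populations) enter the Spearman
   correlation; $\lceil 0.05 n \rceil$ genes are flagged and ties at
   the cutoff are all kept rather than arbitrarily dropped.
3. **Stability.** The sample standard deviation (n − 1 denominator,
   conventional for a ten-individual panel) of $\log_2(\mathrm{FPKM})$
   across a designated set of individuals, paired with the gene's $W$.
   By default only genes expressed in every individual enter; an
   alternate mode admits genes expressed in at least one individual
   using the pseudocount. Because the published stability figure's
   x-axis metric is ambiguous between $W$ and the fraction of sites
   called methylated, the table carries both columns and the plot
   helper can draw either.

Wilcoxon and Spearman use the exact small-sample methods where
applicable and the usual tie-corrected approximations otherwise; both
are validated against full enumeration oracles in the tests.

## CpG O/E and mixture decomposition

CpG O/E is $(L \cdot \#CpG)/(\#C \cdot \#G)$ with overlapping
dinucleotide counting in single-base steps; GpC O/E is the same
formula on GC counts and serves as the control unaffected by
CpG-specific deamination. Positions with non-ACGT symbols are excluded
from base counts, and any dinucleotide touching one is excluded from
dinucleotide counts. Genome-wide scans tile contigs with 1000-bp
non-overlapping fragments from position 0, dropping the short trailing
fragment so the length term is constant across values.

Density estimation uses a Gaussian kernel with Silverman's
rule-of-thumb bandwidth. Exact zeroes are removed before both KDE and
mixture fitting: in gene sets they arise from very short genes, not
real depletion.

The mixture model is a k-component univariate Gaussian mixture fitted
by EM with responsibilities. Numerical choices: the E-step runs in log
space with a per-observation max subtraction; component standard
deviations are floored at $10^{-4}$ of the sample SD to prevent
collapse onto single points; convergence is declared when the relative
log-likelihood change falls below $10^{-8}$ (default), capped at 2000
iterations; the fit restarts from 10 random initialisations
(k-quantiles of the data plus jitter; the first start is the plain
quantile start) and keeps the best log-likelihood. The EM monotonicity
guarantee is asserted on every iteration of every run — a decrease
beyond float noise aborts the fit rather than silently continuing.
Components are reported sorted by ascending mean. The component count
k is a user decision, as it was in the source analyses (two peaks for
one species, three for the other); `mixture_bic_report()` provides BIC
across candidate k as information, not automation. The fitter is
cross-checked in the tests against an independent implementation
(mclust, unequal-variance univariate model) to three decimals in
means, SDs and log-likelihood.

## Comparative analyses

Ortholog pairs are reciprocal best hits: a pair forms only when each
gene is the other's unique top-scoring hit; a score tie at the top of
either list disqualifies that query. Scores are abstracted to "higher
is better"; e-value tie-breaking is not modelled.

Codon alignments are filtered by local identity: a codon is kept
exactly when it lies fully inside at least one 60-bp window with at
most 10 non-identical positions, where mismatches and gap positions
both count as non-identical. Windows are codon-aligned and slide in
3-bp steps — the unit being kept is the codon, so windows must respect
frame, and sliding (rather than tiling) windows are the more
permissive reading of a "60 bp stretches" rule whose overlap behaviour
was unspecified. Partially covered codons are not kept. The filtered
alignment is retained only when strictly longer than 180 bp, measured
after codon filtering (the retention sentence follows the codon-keeping
sentence). The filter is idempotent and preserves frame, both asserted
in tests.

Cross-species and rate correlations are Pearson's r with Fisher-z 95%
intervals; the "average CpG O/E of the two species" is the per-pair
mean of the two species' values. dN, dS and dN/dS are consumed as an
externally computed table — alignment construction and rate estimation
are upstream tools' jobs, not this package's.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume,
with every quantity traceable to ground truth:

- **Genome and annotation**: one contig of i.i.d. sequence at GC
  content 0.33 (the assembly-level GC content of the study system);
  non-overlapping genes of 2–4 exons (exons 120–300 bp, introns
  60–150 bp) separated by intergenic spacers of at least 200 bp; TEs
  placed in all three genomic contexts. Gene structures are far
  shorter than real spider genes (mean intron lengths in kilobases
  would make desk-scale simulation pointless); what matters for the
  analyses is CpG counts per feature, not physical length.
- **Methylation**: 45% of genes methylated (a clearly bimodal gene
  population), per-site methylation probability 0.8 inside methylated
  genes and 0 in unmethylated ones, 5% for intergenic CpGs. The true
  within-gene per-site probability is not published anywhere; 0.8 is
  this package's calibration choice, made once. CHG/CHH cytosines are
  simulated as pure conversion noise, matching the near-zero
  non-CpG methylation of the study system.
- **Reads**: depth is negative binomial (mean 15, dispersion 5)
  truncated to ≥ 1, so the 5–30 depth band produces realistic
  attrition; observed methylated counts are Binomial(depth, 1 − ε)
  at truly methylated sites and Binomial(depth, ε) otherwise, with
  conversion failure ε = 0.01 (99% conversion, the spike-in value).
- **Expression**: log-normal FPKM; methylated genes have 4× the mean
  and 0.5× the coefficient of variation of unmethylated genes
  (defaults chosen to give the observed qualitative contrasts at
  comfortable but not overwhelming effect sizes). A configurable
  coupling adds a log2-scale group shift proportional to a gene's
  between-population methylation difference; the acceptance analyses
  use coupling 2 (log2 units per unit ΔW), which yields a clearly
  positive but far-from-deterministic ΔW–log2FC correlation.
- **Sequences**: per-gene CpG O/E targets are drawn from a prescribed
  normal mixture truncated at 0; a sequence of fixed base composition
  is built by random placement followed by targeted swaps until the CG
  count equals the target exactly (realised O/E within ±0.03 of
  target, enforced). Swaps that would change the GC dinucleotide count
  are rejected: conditioning on a low CG count alone drags GC down
  with it through shared CGC/GCG triples, and holding GC fixed keeps
  the GpC O/E control centred on 1 — the point of the control.

What the generator does **not** emulate: read-level artefacts (no
FASTQ, mapping bias, M-bias or trimming — the package consumes
coverage files, as the analyses do), PCR duplication structure,
spatially correlated methylation along genes, partial methylation
within a gene class, annotation error, or real codon evolution.
Passing tests on synthetic data therefore validate the statistical
machinery and its calibration, not robustness to upstream
artefacts in real libraries.

## Validation problem sizes

The test suite runs fully from code: mixture recovery uses 20,000
draws per fit (the published decompositions are refit to within ±0.03
in means and SDs); FDR calibration uses twenty null methylomes of
10⁵ CpG sites; the oracle-equivalence suites run 200 randomised
instances per statistic against brute-force enumeration; the
methylation–expression triad is checked on twenty simulations of
2,000 genes each. These sizes make every distributional claim a
measured result rather than an asymptotic hope while keeping the whole
suite runnable on a laptop in a few minutes.

## Interface decisions

The package is tidyverse-shaped: data frames in, tibbles out, so every
stage composes with pipes; fitted mixtures have `tidy()`, `glance()`
and `autoplot()` methods; figures are ggplot2. There is no shell
executable: the audience is R analysts, and `run_pipeline()` plus the
exported stage functions cover orchestration, with a JSON config and
manifest serialized into every output directory for provenance.
Coordinates are 0-based half-open internally, converted only at the
I/O boundary (GFF3 and the 1-based coverage dialect), which confines
the classic off-by-one hazards to two well-tested functions. CpG
sites are kept per strand throughout and never collapsed onto the
symmetric dinucleotide, matching the per-cytosine records of the
coverage format.

## Known limitations

- ε is one genome-wide scalar; no per-context or per-strand error
  rates.
- BH is exchangeable across sites; spatial correlation of methylation
  is ignored (conservative for FDR on aggregated features, but not
  modelled).
- The binomial model ignores within-site overdispersion across
  individuals in pooled libraries.
- The mixture fitter assumes Gaussian components on the O/E scale;
  truncation at 0 is handled in sampling but not in the likelihood,
  which slightly biases components near 0 — visible only for
  components with large σ relative to their mean.
- `sim_mixture_sequences()` holds base composition constant across
  genes, so it cannot emulate GC-content gradients.
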