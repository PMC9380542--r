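---
title: "Methods: mapping a bacterial SOS regulon with sosmap"
author: "sosmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a bacterial SOS regulon with sosmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sosmap)
```

# Overview

`sosmap` re-implements, as tested and reusable R code, the computational
route from ChIP-seq and RNA-seq signal to the LexA-controlled DNA-damage
(SOS) regulon of a bacterium such as *Streptomyces venezuelae*.  LexA is
the transcriptional repressor of the SOS response: it sits on palindromic
operator motifs ("SOS boxes") in target promoters and is degraded after
DNA damage, derepressing its regulon.  The pipeline has six stages, each
usable on its own:

1. **Sliding-window local-enrichment peak calling** on ChIP coverage with
   control subtraction (`makeWindows`, `countInWindows`,
   `localEnrichment`, `subtractControl`, `callPeaks`).
2. **Peak-to-gene association**: strand-aware assignment of peaks to the
   promoters of transcriptional units, and classification of intragenic
   sites (`associatePromoters`, `classifyIntragenic`).
3. **Differential expression**: an in-house negative-binomial Wald test
   with median-of-ratios normalisation and BH-FDR (`runDE`).
4. **Regulon integration** and a three-way classification of each binding
   site's dissociation under DNA damage (`integrateRegulon`,
   `classifyDissociation`).
5. **SOS-box motif discovery and scanning** by ZOOPS EM and bidirectional
   PWM scoring (`discoverMotif`, `scanMotif`).
6. **SPR kinetics**: closed-form 1:1 Langmuir modelling and nonlinear
   least-squares fitting of single-cycle sensorgrams (`modelResponse`,
   `fitSingleCycle`).

A synthetic-data module (`generateGenome`, `plantSites`,
`simulateChipCoverage`, `simulateCounts`, `simulateSummitSequences`,
`simulateSensorgram`, `simulateSosExperiment`) generates every input with
recorded ground truth, so all stages are testable without sequencing data.

# The local-enrichment peak statistic

Each contig is tiled into 30-bp sections overlapping by 15 bp (defaults in
`sosConfig()`), and every section $w$ is scored by its read density
relative to its local neighbourhood:

$$E_w \;=\; \log_2\!\frac{d_w + \varepsilon}{d_{\mathrm{flank}} + \varepsilon},$$

where $d_w$ is window mass divided by window width, and
$d_{\mathrm{flank}}$ is the density of the 3,000 bp centred on the
section, *excluding the section itself* and truncated at contig ends
(densities are always over the bases actually available).  Excluding the
section keeps its own signal from diluting its background.  The
pseudocount $\varepsilon$ defaults to the density equivalent of one read
per flank, $1/(3000-30)$, which bounds the statistic on sparse tracks and
makes all-zero coverage score exactly 0; with $\varepsilon = 0$ the
statistic is exactly invariant to multiplying the track by any constant.
Control tracks are scored identically and subtracted on the log2 scale
(a ratio of ratios on the linear scale).

Peak calling selects windows with subtracted $E_w \ge \log_2 2$ and merges
runs of *consecutive* selected windows.  There is deliberately no gap
bridging: one sub-threshold window splits a run even though, with
half-overlapping windows, the flanking runs still abut as intervals.  The
summit is the midpoint of the window with maximal enrichment; ties resolve
to the leftmost window for determinism.  Contigs are treated as linear
(the *Streptomyces* chromosome is linear) and windows never wrap.

# Peak-to-gene association

Offsets follow the convention of published SOS-box tables: position 0 is
the first base of the start codon, negative values are upstream *on the
gene's strand*.  A peak is assigned to the promoter of a transcriptional
unit when (a) the unit's first gene's start codon lies within 300 bp of
the peak interval and (b) the summit's offset falls inside the regulatory
window $[-200, +100]$.  The summit is the reference point for the window
test and the peak edges for the distance test, mirroring the two distinct
phrasings these rules usually carry.  "Right orientation" is subsumed by
the window test: a summit inside $[-200, +100]$ of a start codon is by
construction on the regulatory side of the gene.  One association is made
per (peak, unit) pair, so a peak between divergent units may legitimately
be assigned to both.

A peak is intragenic for gene $g$ when its summit lies more than 100 bp
past the start codon inside $g$ and is *not* inside any unit's promoter
window — promoter assignment always wins, which also guarantees that no
peak is simultaneously promoter-associated with a unit and intragenic for
that unit's first gene.  TSS proximity of intragenic sites uses a 50-bp
radius; no number is standard here, so it is a visible `sosConfig()`
parameter.

# Differential expression

Counts are normalised with median-of-ratios size factors (reference genes
are those with all counts positive; factors are rescaled to geometric mean
1; an all-zero corner case falls back to total-count ratios with a
warning).  Per-gene NB dispersions come from the method of moments on the
pooled within-condition variance, floored at $10^{-8}$ and shrunk toward
the 10%-trimmed-mean common dispersion.

Two numerical choices were calibrated on null simulations (NB counts, no
effect, triplicates per condition) rather than taken on faith, because the
per-gene moment estimator has only $n_1+n_2-2 = 4$ degrees of freedom at
the triplicate design:

* the shrinkage weight defaults to **0.8** toward the common value — with
  thousands of genes the common dispersion is estimated far more precisely
  than any per-gene value, and an 80/20 blend stabilises the Wald standard
  error while letting strong per-gene signal through;
* the Wald statistic is referred to a **t distribution with
  $(n_1+n_2-2)/(1-w)$ degrees of freedom** (t(20) at the defaults), a
  small-sample correction reflecting the precision of the blended
  dispersion.  On 2,000-gene null simulations this holds the empirical
  type-I error at 0.04–0.06 for a nominal 0.05, where a plug-in normal
  reference is anticonservative (~0.09) and t(4) overcorrects (~0.03).

The log2 fold change uses pseudocounted group means
($\log_2\frac{\bar y_T + 0.5}{\bar y_U + 0.5}$) so genes with zero counts
stay finite.  BH adjustment runs across testable genes only (genes with
zero total count get $p = \mathrm{FDR} = 1$), and a gene is a DEG when
$|\log_2 FC| \ge 1$ and $\mathrm{FDR} \le 0.05$, both inclusive.

# Dissociation classification

Each promoter-associated peak of a differentially expressed unit is
classified by two peak-level log2 comparisons: $e$, the MMC-treated ChIP
enrichment over its control, and $\Delta$, the drop from untreated to
treated ChIP.  The criteria are: *complete* dissociation when $e < 0.25$;
otherwise *none* when $\Delta \le 0.2$; otherwise *partial*.  The second
criterion is stated in the literature as a treated/untreated ratio being
"greater than 0.2" for partial dissociation, which taken literally would
contradict dissociation (the treated signal should be *lower*); it is
implemented here as the drop $\Delta = E_{\mathrm{untreated}} -
E_{\mathrm{treated}} > 0.2$, the only reading consistent with the
no-dissociation criterion.  Boundary values resolve to the
less-dissociated class (none over partial over complete), making the three
predicates exhaustive and mutually exclusive.

# ZOOPS motif discovery

The SOS box is found by expectation-maximisation under the
zero-or-one-occurrence-per-sequence (ZOOPS) model: a sequence carries,
with probability $\gamma$, exactly one motif occurrence at a uniformly
chosen position and strand, and is otherwise 0-order background.  The
E-step computes the exact posterior over \{absent\} $\cup$ \{every
(position, strand)\}; the M-step re-estimates the PWM with a Dirichlet
pseudocount of 0.25 per base and $\gamma$ from the posterior occurrence
mass.  Because the M-step is MAP rather than ML, the quantity EM provably
never decreases is the *penalised* likelihood (observed log-likelihood
plus the Dirichlet log-prior); that is what the model's `llHistory`
records and what the tests assert, since the raw likelihood can dip by
$\sim 10^{-8}$ relative near convergence.

For each width, several random starts (PWMs seeded from actual
subsequences, MEME-style) are run briefly, the best is refined to
convergence, and one-column *shift moves* are then attempted: EM at the
true width frequently converges to an optimum aligned one column off, and
sliding the PWM left/right with short re-runs repairs the alignment phase
— the same device MEME uses.

**Width selection** across the search range (default 6–30 bp) maximises
the BIC-penalised log-likelihood ratio,
$\mathrm{LLR}(w) - \tfrac{3w}{2}\log n$.  A per-free-parameter criterion
($\mathrm{LLR}/3w$) was considered and rejected: the SOS box is a
palindromic pair of strongly conserved half-sites separated by degenerate
positions, so per-parameter likelihood density is *maximised by the 6-bp
half-site alone*, while the BIC penalty (a few nats per extra column)
is easily paid by the second half-site's information and correctly stops
at the full 16-bp box.  The motif is reported once; scanning (not
discovery) handles promoters with multiple boxes, and masking found sites
to N and re-running reproduces a multi-motif search.

The consensus string uses the conventional casing: uppercase where the top
base reaches probability 0.9, lowercase at 0.5, N below.  Scanning scores
both strands at every offset with the log2-odds of the PWM against the
background and reports all hits above an absolute (bits) or
fraction-of-max threshold, without masking overlaps.  Note that on a GC
0.72 background a fraction-of-max threshold implicitly penalises instances
whose degenerate positions happen to be G/C (each such column can sit
$\log_2(0.36/0.14) \approx 1.4$ bits below the column maximum); absolute
thresholds are the safer choice on skewed backgrounds.

# SPR kinetics

Single-cycle sensorgrams are modelled with the closed-form 1:1 Langmuir
solution: within a segment at analyte concentration $C$,

$$R(t) = R_{eq} + (R_0 - R_{eq})\,e^{-(k_a C + k_d)(t - t_0)},
\qquad R_{eq} = \frac{k_a C\,R_{max}}{k_a C + k_d},$$

continuous across segment boundaries, with $C=0$ giving pure exponential
dissociation.  Fitting minimises least squares over $(k_a, k_d, R_{max})$
in log10 space (bounds $k_a \in [10^2, 10^9]$ M$^{-1}$s$^{-1}$,
$k_d \in [10^{-6}, 1]$ s$^{-1}$ — positivity plus conditioning) with
Levenberg–Marquardt from a log-grid of 8 starts; the fit is flagged
unconverged when the optimiser fails or a parameter lands on a bound.
$K_D$ is always the derived ratio $k_d/k_a$, never independently fitted.
Mass-transport limitation, bulk refractive-index jumps and drift are not
modelled (blank-cell subtraction is assumed done upstream); the
bookkeeping formulas $R_{max} = \frac{MW_{protein}}{MW_{DNA}} \times RU
\times n \times 0.78$ and $\%R_{max} = 100\,RU_{bound}/R_{max}$ are
evaluated directly.

# What the synthetic data emulate — and what they do not

The generators reproduce the *structure* of the study design at desk
scale: a high-GC (0.72) linear genome of 100 kb; non-overlapping genes, a
fraction grouped into 2–4-gene same-strand operons with a TSS at each
unit's first start codon; 16-bp SOS boxes
(`TCGAACNNNNGNNCGA`, Ns drawn uniformly, 0–2 mismatches) planted at
promoter offsets; matched ChIP/control coverage with and without DNA
damage; NB triplicate counts; and stepped sensorgrams over the doubling
concentration series 0.78125–25 nM (120 s per step, 1,200 s dissociation).

Deliberate simplifications, and hence limits on what passing tests show
about real data:

* **Coverage is per-base Poisson depth, not reads**: the enrichment
  statistic only consumes densities.  A planted site multiplies the mean
  depth over a flat fragment-length (200 bp) window.  Real fragment
  pileups are peaked, not flat, so real summits localise better than
  simulated ones; under the flat plateau the called summit is uniform
  within roughly half a fragment of the site.  For that reason the default
  planted promoter offsets are drawn from $[-150, -20]$ — the typical
  placement of a repressor operator upstream of the start codon — rather
  than hugging the $[-200, +100]$ window boundaries, where no method
  relying on summit offsets could recover them at this resolution.
  Arbitrary offsets remain available (`plantSites(offsets = ...)`).
* Dissociation classes are planted with margin: treated occupancy is
  background for *complete*, halved for *partial*, unchanged for *none*.
  Real intermediate sites near the 0.25/0.2 boundaries will classify less
  cleanly.
* No sequencing error, GC bias, PCR duplication, or multi-mapping;
  library size factors default to 1 and are a free parameter for testing
  normalisation.
* The DE recovery fixtures plant $|\log_2 FC| = 2$ on 20% of 2,000 genes
  (a DNA-damage response is a broad perturbation); BH sensitivity depends
  on that fraction, so sparser regulons yield lower sensitivity at the
  same effect size.
* The occupancy scale (8-fold over background at depth 20) is a free
  parameter of the generator, not an estimate from any real dataset.

Problem sizes used throughout the test suite — 100-kb genomes, 30 planted
sites, 2,000-gene count matrices, 175 summit sequences, widths 6–30 with
10 EM starts — were chosen as the smallest sizes at which the statistical
properties under test (recovery rates, error calibration, width
selection) are stable across seeds.

# Degenerate inputs and tie-breaks

* All-zero coverage: enrichment 0 everywhere (pseudocount over
  pseudocount); empty peak lists are legal everywhere downstream.
* Summit ties: leftmost maximal window.  Dissociation boundaries: the
  less-dissociated class.  DEG cutoffs: inclusive.
* Genes with zero counts in all samples: untestable, $p = FDR = 1$,
  excluded from the BH denominator.
* Sequences shorter than the motif width: an error in discovery, an empty
  result in scanning.  N bases score as background in both.
* Pure-noise sensorgrams: the fit returns `converged = FALSE` (optimiser
  failure or a parameter at its bound) rather than raising.

# Coordinates

Internally everything is 1-based closed, the Bioconductor (`GRanges`)
convention.  BED/BedGraph files are converted from and to their native
0-based half-open form at the I/O boundary only; GFF3 is natively 1-based.
Offsets relative to start codons are convention-free (the same in either
system).
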