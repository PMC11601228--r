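---
title: "Scoring pooled CRISPRi FACS-sort phagocytosis screens"
author: "phagoScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pooled CRISPRi FACS-sort phagocytosis screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagoScreen)
```

# The experimental design being modelled

A pooled CRISPR-interference screen read out by cell sorting asks, for every
gene in a compact library, whether knocking it down changes a quantitative
cellular phenotype — here, how much fluorescently labelled substrate
(beads, synaptosomes, or live synaptic material) a microglial cell ingests.
The design this package is built around is a compact arrayed-oligo library:
102 target genes with two sgRNAs each plus 28 non-targeting controls
(NTCs), delivered by lentivirus at low multiplicity of infection
(MOI < 0.15, so most transduced cells carry a single guide), with the cell
population sorted into the bottom 25% and top 25% of the fluorescence
distribution and each sorted bin sequenced to count sgRNA abundances across
three replicates.

Alongside the screen itself, the same experimental programme produces
several bespoke quantifications that this package also implements:
transcriptomic cluster occupancy of perturbed cells (CROP-seq style),
a time-lapse surveillance-area metric for microglial motility,
pixel colocalization coefficients, viability and dot-array quantification,
flow-cytometry uptake readouts with in-well paired controls, and
delta-delta-Ct knockdown validation.

# The generative model behind the simulator

Every stage of the screen has a synthetic counterpart with known ground
truth, so the scoring pipeline can be validated end to end without any
external data.

**Infection.** Each plated cell receives $k \sim \mathrm{Poisson}(\lambda)$
guides, $\lambda$ = MOI, drawn uniformly from the library; cells with
$k = 0$ are removed, modelling antibiotic selection. At the default
$\lambda = 0.15$ the surviving population carries more than one guide with
probability $1 - \lambda e^{-\lambda}/(1 - e^{-\lambda}) \approx 0.073$.

**Phenotype.** Cell fluorescence is log-normal:
$\log_2 F = \mu_0 + \bar\gamma + \varepsilon$, where $\bar\gamma$ is the
mean of the per-gene log2 shifts $\gamma$ over the cell's guides (zero for
NTCs and unperturbed genes) and $\varepsilon \sim N(0, \sigma^2)$. Defaults
$\mu_0 = 10$, $\sigma = 1$: a $|\gamma| = 2$ hit shifts a cell two
population standard deviations, a strong but realistic knockdown phenotype;
$\gamma = \pm 0.5$ sits well inside the noise and is only detectable
through guide-level averaging over many cells. Multi-guide cells average
their guides' effects, a simple bounded-bias choice appropriate at low MOI.

**Sorting.** Cells are ranked by fluorescence; the bottom and top
$\lfloor qn \rfloor$ cells ($q = 0.25$) form the low and high bins, the
middle half is discarded, and ties are broken by stable input order so the
operation is fully deterministic.

**Sequencing.** Each bin's guide tally is sequenced to a fixed depth $R$
(default $10^6$) with Dirichlet-multinomial noise: read proportions
$\sim \mathrm{Dirichlet}(\alpha_g = \mathrm{tally}_g/\varphi)$, counts
$\sim \mathrm{Multinomial}(R, p)$. This gives negative-binomial-like
marginal overdispersion while conserving depth exactly — every sample sums
to $R$ by construction, a property the tests rely on. $\varphi = 0$
degenerates to pure multinomial sampling. The default $\varphi = 0.01$ is
deliberately mild: at screen-scale tallies (thousands of cells per guide)
the extra dispersion is a few percent, and it grows as tallies shrink,
which is how library-preparation noise behaves in practice. Neither depth
nor coverage is a published quantity for this design; the defaults
(500 cells/guide, $10^6$ reads/bin) are ordinary desk-scale choices for a
232-guide library and are exposed in `screenConfig()`.

**Determinism.** Each replicate and stage draws its own sub-seed,
`master * 1000 + stage index`, so any stage can be reproduced in isolation
and results do not depend on iteration order.

What the simulator does *not* model: PCR jackpotting, index hopping, sort
impurity, guide-activity differences within a gene, or chromatin-dependent
CRISPRi efficacy. Passing tests therefore demonstrate that the *scoring
machinery* is correct and calibrated under a clean generative null — not
that any particular wet-lab screen is free of those artefacts.

# From counts to gene calls

1. **Normalisation.** Reads per million with a pseudocount (default 0.5)
   added before scaling. The pseudocount keeps log fold changes finite for
   guides that drop out of one bin while perturbing well-covered guides
   negligibly; with pseudocount 0, LFCs are exactly invariant to rescaling
   any sample's depth.
2. **Guide statistics.** Per replicate,
   $\mathrm{LFC}_r = \log_2(\mathrm{RPM}_{\mathrm{high},r} /
   \mathrm{RPM}_{\mathrm{low},r})$, averaged across replicates (averaging
   per-replicate LFCs rather than pooling counts is robust to unequal
   depths; a pooled mode exists behind `pooled = TRUE`). Each guide gets a
   robust z-score against the NTC guides,
   $z = (\mathrm{LFC} - \mathrm{median}_{NTC}) / (1.4826 \cdot
   \mathrm{MAD}_{NTC})$.
3. **Gene test.** A two-sided Mann–Whitney U test compares the gene's guide
   LFCs with the NTC guide LFCs — exact by enumeration for up to 3 guides
   and 40 NTCs without ties (the 2-guide design always takes this path;
   its most extreme attainable p is $2/\binom{30}{2} = 2/435$), otherwise
   the normal approximation with continuity correction. Note the
   approximation is coarse at $n_1 = 2$: enumeration shows deviations up
   to 0.033, which is why the exact path matters for this design.
4. **Gene phenotype.** A weighted geometric mean of the guides' fold
   changes: $\mathrm{LFC}_{gene} = \sum_i w_i \,\mathrm{LFC}_i$ in log
   space with $w_i \propto \max(|z_i|, 0.25)$ (floor so no guide is zeroed
   out), or equal weights on request. Whether guide weights should derive
   from significance, variance or expression is genuinely open; |z|
   weighting favours guides that behave unlike controls while the floor
   bounds its influence, and the equal-weight mode is the plain geometric
   mean.
5. **Score and empirical FDR.** Each gene's score is
   $\mathrm{LFC}_{gene} \cdot (-\log_{10} p)$. All $\binom{28}{2} = 378$
   pairs of NTC guides are scored identically as pseudogenes, and the
   positive-tail FDR at threshold $t$ is
   $\widehat{\mathrm{FDR}}(t) = \frac{\#\{pseudo \ge t\}/N_{pseudo}}
   {\#\{gene \ge t\}/N_{gene}}$, clipped to $[0,1]$, with the q-value the
   minimum over all thresholds that include the gene; the negative tail
   mirrors. Benjamini–Hochberg adjusted Mann–Whitney p-values are reported
   alongside, but the empirical q gates the hit calls (how the two would be
   combined into a single aggregated gene FDR is not a settled question;
   reporting both and gating on the decoy-based quantity is the
   transparent option).
6. **Hit calling.** `increase` if the phenotype LFC is positive and the
   positive-tail q is below $\alpha = 0.01$; `decrease` mirrored; the tails
   partition by phenotype sign so no gene is called twice.

## Numerical and design choices worth knowing about

**Exchangeable nulls.** A pseudogene is never tested against its own
guides, and each real gene excludes a rotating, data-independent NTC
subset of the same size, so every scored unit faces an identically sized
null with identical attainable p-values. Without the first exclusion,
decoy p-values are biased toward 1 and the empirical FDR is
anticonservative; without the second, real genes have slightly finer
p-granularity than decoys. With both, null gene and pseudogene score
distributions agree to about one percent in spread and tail quantiles.

**Behaviour of the plain-ratio FDR estimator.** The estimator above
reports exactly 0 whenever a gene's score exceeds every pseudogene score.
With only 28 NTC guides the 378 decoy pairs are highly dependent
(effectively far fewer independent decoys), so under a complete null a
screen still produces occasional q = 0 genes, arriving in small clumps.
Across many all-null simulated screens at the full design the mean
falsely-called fraction is about 0.0075 — inside the 0.01 hit threshold —
but individual 20-screen batches range from about 0.003 to 0.012. This is
a property of the estimator at this decoy-set size, not of the
implementation; the conservative variant used elsewhere in target–decoy
statistics (adding one pseudo count to the numerator) would remove the
q = 0 events at the cost of a floor of $1/N_{pseudo}$ on every q.

**Problem sizes.** The validation suites simulate at the full screen
design (102 × 2 + 28 guides, 3 replicates, 500 cells/guide, $10^6$
reads/bin) for calibration and recovery checks — roughly 770,000 plated
cells per replicate — and at reduced designs (tens of genes, $10^4$–$10^5$
reads) where only mechanics are being exercised. At the full design one
simulated-and-scored screen takes well under a second of compute.

# The companion quantifications

**Cluster occupancy.** From per-cell (perturbation, cluster) assignments:
occupancy fractions per perturbation (rows sum to 1), additive occupancy
change relative to the NTC reference (rows sum to 0; an additive difference
matches how occupancy-change bar plots are read, with a log-ratio view
possible downstream), and Pearson correlation between two states' changes
across perturbations, which quantifies trade-offs such as anti-correlated
interferon and chemokine state shifts. Perturbations under 10 cells are
excluded with a warning rather than an error — occupancy estimates below
that size are sampling noise. No significance test is attached to
occupancy deltas by default; a bootstrap CI utility
(`deltaBootstrapCI()`) provides uncertainty without inventing a testing
procedure the analysis does not define.

**Surveillance area.** For a single cell's stabilised binary mask stack,
the metric is the area of the maximum projection (logical OR over frames)
divided by the frame-0 area: exactly 1 for a stationary cell, and for a
disk of radius $r$ translated a total distance $d$ it approaches the
stadium value $1 + 2d/(\pi r)$ as step size shrinks — the analytic oracle
used in the tests. Stabilisation is integer-pixel translation registration
to frame 0 by maximising binary overlap, bounded by `max_shift` (the
search erroring out on a boundary solution rather than silently
under-correcting). Registration must be driven by a stationary field
reference; registering on the moving cell itself would cancel the motion
being measured. The original analysis stabilised with an interactive
image-processing tool whose algorithm is unspecified; bounded
integer-translation registration is this package's declared substitute.
Segmentation is Otsu (or fixed) thresholding plus connected components
with a minimum-size filter — a deliberate, testable simplification of an
interactive pipeline's object identification.

**Colocalization.** Pearson correlation over in-mask pixels plus Manders
overlap coefficients $M_1 = \sum_i A_i [B_i > t_B] / \sum_i A_i$ (and
symmetrically $M_2$), thresholds defaulting to per-channel Otsu within the
mask and overridable for determinism. A constant channel yields an NA
correlation sentinel while the Manders coefficients remain defined.

**Flow uptake.** Events are gated on $\log_{10}(x + 1)$ of the marker
channel — cytometry convention, with the offset stabilising the mixture
fit near zero — using either a fixed threshold or the boundary of a
two-component Gaussian mixture (the valley between marker-negative and
marker-positive populations; manual gate placement in the original assay
is not numerically specified, so the mixture valley is the declared
default). The uptake readout is the median green intensity of gated
events; knockdown wells are compared with their in-well controls by a
two-sided paired t-test, reported unadjusted (an optional BH flag is
available downstream since multiple genes are typically compared).
Degenerate cases are made explicit: identical pairs give $t = 0, p = 1$,
and constant nonzero differences give the $p \to 0$ sentinel. The paired
design is calibrated: over 100 simulated null experiments of 6 wells, 5%
were significant at $\alpha = 0.05$.

**Dot arrays and qPCR.** Replicate dots are averaged before subtracting
the mean negative-control intensity, without clipping, and knockdown
validation uses $2^{-\Delta\Delta Ct}$ against a housekeeping gene.

# Known limitations

* The read counter handles anchored or sliding protospacer extraction with
  at most one mismatch; no adapter trimming, UMIs, or reverse-complement
  search (amplicon reads are stranded; an RC flag could be added).
* The empirical FDR inherits the granularity of its decoy set: with 28
  NTCs in pairs, q-values move in steps of 1/378 and the plain-ratio
  estimator can return exactly 0 (see above).
* Cluster assignments and per-cell perturbation identities are consumed as
  given; demultiplexing, clustering and differential expression belong to
  the upstream single-cell toolchain.
* The imaging module assumes one cell per (cropped) field in single-cell
  mode and binary masks; no sub-pixel registration, morphology features or
  deconvolution.
* FCS binary parsing is out of scope; flow events are consumed as CSV-style
  tables.

# A worked miniature

```{r example, eval = FALSE}
lib <- simulateGuideLibrary(n_genes = 102, guides_per_gene = 2, n_ntc = 28,
                            seed = 1)
cfg <- screenConfig(lib, effects = c(G0001 = 2, G0002 = -2), seed = 1)
sim <- simulateScreen(cfg)
res <- scoreScreen(sim$counts, alpha = 0.01)
head(res$genes[order(res$genes$p_value), ])
plotVolcano(res$genes)
```
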