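---
title: "Linking host genomic and gut-microbiome dissimilarity in common-garden designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking host genomic and gut-microbiome dissimilarity in common-garden designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gardenscan)
```

## The scientific problem

A central question in host-microbe biology is whether hosts that are more
similar genetically also carry more similar microbial communities, and
whether particular regions of the host genome drive that relationship.
Common-garden experiments address the main confound — shared environment —
by rearing genetically distinct families together. The design gardenscan
targets is a fish cross experiment: families from two differentiated
populations (a freshwater population, "Bt", and an anadromous population,
"RS") plus F1 hybrids ("Hy"), reared germ-free-derived and co-housed in two
replicate tanks, with each fish yielding a genome-wide SNP dosage profile
(RAD-seq markers on 21 chromosomes), a gut 16S ASV count profile, and
morphometrics (standard length, SL).

All inference in the package runs on pairwise dissimilarity matrices:

* **genetic** — the fraction of allelic differences between two fish,
  $d_{ij} = \sum_m |g_{im} - g_{jm}| / (2\,n_{ij})$, over dosages
  $g \in \{0, 1, 2\}$ with pairwise deletion of missing genotypes
  ($n_{ij}$ counts the markers compared);
* **Bray-Curtis** — $\sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})$
  on normalized ASV abundances;
* **weighted UniFrac** — $\sum_b l_b\,|P_{ib} - P_{jb}|$ over tree branches
  $b$ with length $l_b$ and descendant-abundance proportions $P$, optionally
  normalized by the abundance-weighted root-to-tip sum so values lie in
  $[0, 1]$;
* **size** — $|SL_i - SL_j|$ in millimeters.

## Inference machinery

**Mantel and partial Mantel tests.** The association between two distance
matrices is the Pearson correlation $r$ of their strict upper-triangle
vectors; significance comes from randomly relabeling the rows and columns of
the first matrix. The partial statistic controlling for a third matrix $C$
is the first-order partial correlation
$r_{AB\cdot C} = (r_{AB} - r_{AC} r_{BC}) / \sqrt{(1-r_{AC}^2)(1-r_{BC}^2)}$,
recomputed per permutation (relabeling $A$ only). Tests are one-tailed
(upper) because the scientific hypothesis is directional: greater genetic
dissimilarity accompanying greater community dissimilarity. With the
default 999 permutations and the $(1 + \#\{r^\ast \ge r\})/(n_{perm}+1)$
convention the smallest attainable p-value is 0.001; ties count toward the
null (conservative). The hot permutation loop runs in C++; the
permutation-invariant moments of the permuted matrix are computed once, so
each permutation costs one pass over the pair triangle.

**Genome scan.** Windows of 5 consecutive markers (maximally overlapping,
step 1) slide along each chromosome. Each window's genetic dissimilarity is
tested against the community matrix by a partial Mantel test whose control
is, by default, the genome-wide genetic dissimilarity — this absorbs family
structure and overall relatedness, so a window must carry signal beyond its
correlation with genome-wide kinship. `control = "size"` substitutes the SL
distance matrix, and `control = "both-sequential"` residualizes on
genome-wide relatedness first and size second (we default to genome-wide
only; the sequential variant is provided because body size itself covaries
with both genotype and community composition, and users may wish to remove
it too). Each window derives its permutation stream from (master seed,
window ordinal), so results are independent of execution order and of how
many chromosomes are scanned.

Raw permutation p-values are reported next to Benjamini-Hochberg q-values;
peak calling uses the raw p at `alpha = 0.001` (the permutation floor)
together with the requirement $r > 0$. Significant windows merge into
blocks when they share a marker or abut; with several scans (e.g.
Bray-Curtis and weighted UniFrac), a peak is a region where blocks from
every scan overlap on the bp axis — "consistently significant across
metrics" — reported as the span of the contributing windows. Lowess
smoothing of $\log_{10} p$ against window midpoint is display-only and
never feeds peak calling.

**PERMANOVA, PCoA, dispersion.** These are implemented from first
principles on the Gower-centered inner-product matrix
$G = -\tfrac12 J D^2 J$. PERMANOVA uses sequential (order-dependent) sums
of squares via nested hat matrices, so the model
`~ population * standard_length_mm + tank * population` attributes variance
in the order written; p-values come from free permutation of sample labels.
Interactions are assembled by `model.matrix`; since the spanned column
space equals that of products of centered main-effect columns, the
sequential sums of squares are identical either way. PCoA keeps negative
eigenvalues visible (no Cailliez/Lingoes correction), matching how
practitioners usually inspect Bray-Curtis ordinations; axis proportions are
taken over positive eigenvalues only. The dispersion test embeds samples on
all PCoA axes and combines real and imaginary parts as
$z_i = \sqrt{\max(0, d_+^2 - d_-^2)}$ before a one-way ANOVA F with a
label-permutation null.

**Random-forest population classifier.** Three splits mirror the
experimental design: train tank 1 / test tank 2, the reverse, and a random
80-versus-rest split. Training uses stratified equal-size bootstrap
sampling per class (the minimum class size) so the most common population
cannot dominate; test accuracy is the plain proportion correct, left
uncorrected for test-set imbalance. Statistical significance comes from
refitting with shuffled *training* labels (999 by default):
$p = (1 + \#\{acc^\ast \ge acc\})/(n_{null}+1)$. The forest itself is the
randomForest package — the contribution here is the harness, not the
learner. Consensus importance ranks features by how many splits place them
in the top-k (ties by mean rank).

## The synthetic common-garden generator

`simulate_dataset()` emulates the processed products of the experiment so
every stage runs with known ground truth and no downloads:

* **founders** — per marker, an ancestral frequency uniform on
  [0.05, 0.95] (respecting a 5% minor-allele-frequency genotyping filter);
  population frequencies drawn Balding-Nichols style around it with the
  `differentiation` knob (default 0.3, strong marine-freshwater
  divergence); Boot Lake founders drawn with excess homozygosity
  (`inbreeding_bt = 0.15`) to reflect their more inbred history;
* **crosses** — 3 Bt, 3 RS and 2 hybrid (RS mother x Bt father) families,
  40 offspring each, Mendelian transmission with independent markers (no
  recombination map — the analyses consume dissimilarities, not linkage,
  and the genome-wide control still captures family structure; a documented
  limitation);
* **phenotypes** — SL = population mean + family effect + noise, with
  defaults 17.368 / 18.524 / 16.753 mm for Bt / RS / Hy, family SD 0.5 mm
  and residual SD 1.5 mm; 20/20 tank allocation per family; one Bt family
  lost entirely; per-fish survival 0.53, leaving ~134 typed fish;
* **counts** — for ASV $k$ and fish $i$,
  $\mu_{ik} = \beta_{0k} + pop_k + tank_k + \gamma_k SL_i + gxe_k +
  \sum_w \delta_w s_{iw}$ with $s_{iw}$ the centered mean dosage across
  planted window $w$; counts are zero-inflated negative binomial with
  per-ASV dispersion $\theta_k \sim \log N(\log 2, 0.7)$ and zero-inflation
  $\pi_k \sim U(0, 0.7)$, scaled so each fish's expected total equals its
  drawn library size ($\log$-normal, mean 238,706 reads). The defaults
  yield a zero-fraction spectrum spanning the 5-80% window relevant for
  downstream differential-abundance model selection;
* **tree** — a random coalescent topology over the ASVs (the real analysis
  would estimate one from sequences; tree estimation is out of scope here).

Planted causal windows are made *maximally informative*: their markers get
intermediate ancestral frequencies and heterozygous founders, so the window
segregates within every family. Without this, a draw of founder genotypes
can leave a "causal" window monomorphic within families, in which case no
scan controlling for relatedness could possibly localize it — the planted
truth would not be well-defined.

What the generator does **not** emulate: sequence-level artifacts
(chimeras, contamination), taxonomic structure in abundances, linkage
disequilibrium decay along chromosomes, multi-generation pedigrees, or
selection. Tests passing on synthetic data therefore demonstrate the
statistical machinery — calibration, power against the planted model,
determinism — not robustness to upstream bioinformatic noise.

## Reference configurations and problem sizes

Two documented configurations drive the test suite and the acceptance
script:

* the **study-shaped default** (21 chromosomes x 115 markers, 8 crosses,
  ~134 fish, 2 tanks) exercises the full design, including
  population/tank/SL/GxE effects on counts (log-scale SDs 0.4 / 0.3 / 0.03
  per mm / 0.2; the power test for the population-by-tank interaction uses
  a documented reference value of 0.4, at which the PERMANOVA interaction
  term is detected in >= 80% of replicates);
* the **scan-reference configuration**
  (`sim_config_scan_reference()`: 8 chromosomes x 50 markers, ~120-130
  fish, 300 ASVs) isolates parameter recovery: background design effects
  off, mild zero-inflation ($\pi \sim U(0, 0.1)$) and moderate
  overdispersion ($\theta \sim \log N(\log 20, 0.3)$), one planted 5-marker
  window with log-scale effect $\delta = 3$ on 150 of 300 ASVs. The effect
  size is a power-oriented reference value chosen once, at design time, so
  that the planted window is the chromosome-maximum statistic in ~19 of 20
  seeds for both community metrics; it is labeled as such and is not a
  biological estimate. With heavier noise, background design effects, or
  smaller $\delta$, recovery degrades gracefully — the same attenuation
  argument that explains why real sliding-window effects are subtle
  ($r \approx 0.04$ genome-wide is typical in data of this shape).

Scaled-down sizes keep the suite fast: permutation-null calibrations use
99 permutations and 200 replicates at 12-36 samples; scan calibration uses
the scan-reference shape. These sizes were chosen as the smallest at which
the binomial acceptance bands are meaningful.

## Numerical choices and degenerate inputs

* Distance matrices are validated (symmetry to 1e-12, zero diagonal) and
  symmetrized once on construction; all downstream code assumes exactness.
* Permutation p-values count ties as exceedances (conservative), with a
  1e-12 relative guard against floating-point ties.
* Monomorphic windows (zero variance in window distances) are flagged with
  missing statistics rather than aborting a scan; degenerate full matrices
  (zero variance) are hard errors, as is a control matrix collinear with
  the tested matrix (|r| = 1).
* Missing genotypes use pairwise deletion; a pair sharing no markers is an
  error naming the pair.
* Log-CPM uses the library-scaled prior $p_i = p\,L_i/\bar L$; a plain
  constant prior would re-rank zero counts across libraries of unequal
  depth. Bray-Curtis on log-CPM asserts non-negativity and refuses
  negative values (possible for very deep libraries) rather than returning
  out-of-range dissimilarities.
* The child-seed scheme (`derive_seed(master, index)`) draws the index-th
  integer from a master-seeded stream, keeping every permutation stream
  reproducible and order-independent; all seeds stay below $2^{31}$.

## Known limitations

* No restricted (within-family) permutation: family non-independence is
  controlled only through the genome-wide control matrix, as in the
  analysis the package reimplements; a nested PERMANOVA is out of scope.
* Independent-marker inheritance means the generator cannot produce
  realistic LD decay around planted windows; peak widths on synthetic data
  are therefore narrower than in real genomes.
* The weighted UniFrac variant (normalized vs raw) is exposed because
  published wrappers differ in their defaults; results on strongly
  depth-skewed data can differ between the two.
* Peak counts depend on `alpha` and the metric set; they are
  configuration-dependent summaries, not calibrated estimates.
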