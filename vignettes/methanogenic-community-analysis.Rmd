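---
title: "Diversity, co-occurrence networks and methane accounting for enrichment cultures"
author: "SyntrophNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity, co-occurrence networks and methane accounting for enrichment cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SyntrophNet)
```

# The analysis problem

Methanogenic enrichment cultures — small panels of related anaerobic
communities fed long-chain fatty acids or *n*-alkanes — are typically
profiled with 16S rRNA amplicon sequencing and monitored for methane.
Three computational questions recur:

1. **Diversity**: how rich and even is each culture, and how do the
   communities relate to one another?
2. **Co-occurrence**: which OTUs co-vary in abundance across the panel,
   suggesting syntrophic partnerships between fermenting/syntrophic
   bacteria and methanogenic archaea?
3. **Methane accounting**: does the measured methane actually demand
   degradation of the amended substrate, or could it come from the medium's
   reductant?

`SyntrophNet` implements these three stages over a shared `OtuTable`
container (a `SummarizedExperiment` holding an integer `counts` assay and
optional lineage annotations), plus a seeded community simulator that
provides ground truth for benchmarking the network stage.

# Alpha and beta diversity

For a sample with counts $n_i$, $N = \sum_i n_i$:

* Shannon $H = -\sum_i p_i \ln p_i$ with $p_i = n_i/N$, in nats by default
  (`base` is an argument).
* Simpson is reported as the finite-sample **dominance**
  $D = \sum_i n_i(n_i-1) / (N(N-1))$ — the probability that two reads
  drawn without replacement are the same OTU, so *low* values mean *high*
  diversity, matching the convention of culture-panel reports where the
  most diverse sample carries the smallest Simpson value.  The complement
  $1-D$ is available via `complement = TRUE`.
* Chao1 uses the bias-corrected form
  $S_{obs} + n_1(n_1-1)/(2(n_2+1))$ so it stays defined when no
  doubletons exist.
* Expected rarefied richness is the hypergeometric expectation
  $E[S_m] = \sum_i \left(1 - \binom{N-n_i}{m}\big/\binom{N}{m}\right)$,
  evaluated with `lchoose` in log space so realistic read depths do not
  overflow.  Rarefaction curves default to 20 evenly spaced depths.
* Bray–Curtis dissimilarity
  $1 - 2\sum_i \min(a_i,b_i)/(\sum a + \sum b)$ feeds UPGMA
  (average-linkage) sample clustering; the tree is returned as an `ape`
  `phylo` whose cophenetic distances equal the merge dissimilarities.

**Singleton handling.** The compositional and network stages exclude OTUs
with a single read across the whole panel (likely sequencing artifacts).
Diversity estimation keeps them by default: Chao1 is driven by singleton
and doubleton counts, and removing singletons would force
$\widehat{S}_{Chao1} = S_{obs}$, defeating the estimator.  A
`dropGlobalSingletons` flag applies the exclusion to diversity as well for
users who want one uniform rule.

# Co-occurrence network inference

The network stage follows a fixed order: global singleton removal →
candidate filtering → profile correlation → thresholded edge construction
→ connected components.

* **Candidate filters** (`FilterCriteria`): an OTU must occur (count ≥ 1)
  in at least 3 samples and carry at least 50 reads in total — the
  classical rules for a five-culture panel; both thresholds are
  configurable and retention is monotone in each.
* **Correlation**: Pearson's $r$ between OTU abundance profiles across
  samples.  The default basis is per-sample *relative* abundance, which
  removes sequencing-depth artifacts; raw counts are retained as an option
  for exact reproduction of count-based analyses.  The two bases coincide
  only when all sample depths are equal, and the chosen basis is recorded
  in the network object and its exports.  Zero-variance profiles have
  undefined $r$; they are excluded from edge formation with a warning
  rather than an error, because constant profiles can legitimately pass
  the abundance filters.
* **Edges**: $r \ge 0.75$, *inclusive* (the threshold is a "at least"
  rule), and positive-only by default; negative-association support is a
  flag.  With only $n$ samples $r$ has $n-2$ degrees of freedom, so the
  module reports a two-sided $t$-based p-value per edge for transparency
  but does not filter on it.
* **Components**: connected components are the "distinct networks" of the
  analysis, ordered by decreasing size with ties broken by smallest member
  OTU id; isolated nodes are reported separately and never counted as
  networks.

Exports: GraphML (with node abundance/prevalence/taxonomy/component and
edge $r$/p attributes), a tab-separated edge list, and a component
membership table.

```{r network-example}
fix <- fixtureCommunity(seed = 42)
net <- cooccurrenceNetwork(fix$table)
networkSummary(net)$component_sizes
```

# Methanogenic stoichiometry

Complete anaerobic mineralization of a substrate
$\mathrm{C}_c\mathrm{H}_h\mathrm{O}_o\mathrm{N}_n\mathrm{S}_s$ to methane
and carbon dioxide follows the generalized Symons–Buswell balance,
extended with nitrogen and sulfur terms:

$$\mathrm{CH_4} = \frac{c}{2} + \frac{h}{8} - \frac{o}{4} - \frac{3n}{8}
  - \frac{s}{4}, \qquad
  \mathrm{H_2O} = c - \frac{h}{4} - \frac{o}{2} + \frac{3n}{4} +
  \frac{s}{2},$$

with $\mathrm{CO_2} = c - \mathrm{CH_4}$, nitrogen leaving as
$\mathrm{NH_4^+}$ (consuming one proton per N, tracked so the hydrogen
balance closes) and sulfur as $\mathrm{H_2S}$.  All coefficients are exact
rationals (every denominator divides 8), and the class validity method
re-asserts the elemental balance in integer arithmetic before an object
can exist.  Formulas whose CH4 or CO2 coefficient would be negative are
outside the model's validity and are rejected.

```{r stoich-example}
buswellCoefficients("palmitate")
buswellCoefficients("cysteine")
```

Derived quantities:

* `theoreticalMethane(f, amount)` — linear in the amount.
* `percentConversion(measured, f, amount)` — reported unrounded and
  rounded half-up to an integer (the "approximately NN%" convention);
  values above 100% warn rather than error, since headspace carry-over and
  background production can exceed the theoretical yield.
* `reductantCeiling(cysteine_umol)` — cultures reduced with cysteine
  sulfide can make methane from the reductant itself at 5 mol CH4 per
  4 mol cysteine; the coefficient is always computed from the element
  balance, never hard-coded.  The cysteine amount (or the ceiling
  directly) is user input: it depends on medium volume and stock
  concentration, which are not part of the model.
* `attributeMethaneSource(measured, ceiling)` — substrate degradation is
  *supported* only when measured methane strictly exceeds the ceiling;
  equality or less is *inconclusive*.

# Marker-fragment identity

`globalAlignment` wraps a Needleman–Wunsch global alignment (via
`Biostrings`) under linear gap scoring (+1/−1/−2 by default; near-identical
fragments are insensitive to reasonable scoring choices) and computes
percent identity over aligned columns.  Terminal-gap overhangs are
excluded from the denominator by default — appropriate for end-trimmed
amplicons of slightly different lengths — with a flag to include them.
`meanPairwiseIdentity` reports each pairwise identity and the arithmetic
mean over all pairs, the summary usually quoted for a set of amplicons;
which pair drives the mean is always visible in the per-pair table.

# The community simulator

`simulateCommunity` generates OTU tables with the structure the network
analysis assumes, plus the ground-truth edge set for scoring:

$$e_{ij} = \text{base}_i \cdot \exp(f_{b(i),j} + \varepsilon_{ij}),\qquad
  \text{counts}_{\cdot j} \sim \text{Multinomial}(\text{depth}_j,\,
  e_{\cdot j}/\textstyle\sum_i e_{ij})$$

where $f_{b,j} \sim N(0, \sigma_{signal}^2)$ is a latent factor shared by
all members of block $b$ in sample $j$ (background OTUs draw independent
factors) and $\varepsilon \sim N(0, \sigma_{noise}^2)$ is per-OTU
deviation.  An optional Dirichlet layer adds overdispersion.  The spec plus
seed determines the output byte-for-byte, and per-sample totals equal the
drawn depths exactly.

Defaults mirror a five-culture enrichment panel:

* 5 samples with depths drawn uniformly from 5,000–20,000 reads;
* planted blocks of 18, 15 and 4 OTUs (three co-varying guilds);
* one dominant OTU at an expected 40% relative abundance, given its own
  *stable* latent factor (sd 0.25): dominant genera in such panels hold a
  consistent 30–60% share across related cultures, which a variance-1
  factor would violate by an order of magnitude.  The dominant OTU is its
  own stratum, outside the planted blocks and the ground-truth edge set.
* block members draw baselines from a moderate log-normal (sdlog 0.7) and
  jointly hold the large remainder of the community — planted blocks play
  the role of the abundant, detectable guild members, which in real panels
  sit above the read-count detection threshold;
* 260 background OTUs form the heavy-tailed rare tail
  (log-normal, sdlog 1.5) and hold 5% of expected reads — in deeply
  enriched cultures the named abundant taxa account for roughly 87–99% of
  reads, leaving a few percent for the tail;
* block signal sd 1.0 and within-block noise sd 0.1 — a strong shared
  signal with small member-level deviation, the regime in which a
  correlation-threshold method should work.

**What the simulator does not emulate**: PCR/primer bias, chimeras, 16S
copy-number variation, overdispersion beyond the optional Dirichlet layer,
and genuine compositional closure effects among strongly anti-correlated
guilds.  Passing recovery benchmarks on these simulations therefore shows
the inference machinery is correct under its own assumptions, not that a
five-sample Pearson network on real data is reliable.

**Benchmark scale.** The packaged recovery benchmark uses 30 replicates at
20 samples and depth 10,000 (where mean edge precision and recall both
exceed 0.8) and 30 replicates per noise level for the monotonicity check —
sizes chosen to make the Monte-Carlo means stable at interactive run
times.  At the realistic panel size of 5 samples the same procedure is
*unstable*: with 3 degrees of freedom, $|r| \ge 0.75$ occurs by chance in
roughly 7% of independent pairs, and a dedicated test documents that
precision collapses relative to the 20-sample benchmark.  This is the
statistical caveat to keep in mind when interpreting small-panel
co-occurrence networks.

**Fixture mode.** `fixtureCommunity` is the deterministic variant for
exact-valued tests: counts are expected abundances rounded to integers
(within-block $r$ essentially 1), and background OTUs are constructed
sparse — present in exactly 2 samples — so the three-of-five prevalence
rule removes them by construction and the recovered components equal the
planted blocks of 18, 15 and 4 exactly.

# Numerical and design notes

* Counts are integers end to end; fractional input is rejected at the
  container boundary.  Taxonomic collapse (`collapseByTaxonomy`) uses
  integer row sums, so per-sample totals are conserved exactly.
* Rational arithmetic in the stoichiometry module is integer
  numerator/denominator with gcd reduction; nothing passes through
  floating point before the balance assertion.
* UPGMA uses `stats::hclust(method = "average")`; ties between merge
  candidates follow `hclust`'s deterministic order.  Trees are ultrametric
  with cophenetic distance equal to merge dissimilarity.
* The correlation threshold comparison is inclusive (`>= 0.75`), the
  reading consistent with an "at least" rule; the threshold, prevalence
  and abundance cut-offs are all `FilterCriteria` fields.
* `runPipeline` executes diversity → singleton removal → filtering →
  correlation → network → stoichiometry from one YAML config, writes all
  artifacts under an output directory and records an MD5 checksum per file
  in `manifest.yaml`; identical config and inputs give bit-identical
  outputs.  Stage failures abort with the stage name.  The package's
  interface is its functions; the config-driven runner covers scripted
  end-to-end use.

# Known limitations

* Pearson co-occurrence on relative abundances is not
  compositionally aware; spurious associations induced by closure are
  mitigated (stable dominant, depth normalization) but not eliminated.
  Compositional methods (SparCC-family) are out of scope by design.
* The "Simpson" reported by historical pipelines can be dominance or its
  complement; both are exposed, dominance is the default.
* Percent conversion does not correct for biomass yield, gas-phase
  partitioning or thermodynamics; it is a pure stoichiometric ceiling
  comparison.
* Identity of real marker fragments depends on the aligner's gap placement
  in low-complexity regions; for the near-identical fragments this module
  targets the effect is negligible.
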