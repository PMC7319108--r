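---
title: "Methods: plastome marker screening and chloroplast phylogeography"
author: "plastomark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastome marker screening and chloroplast phylogeography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomark)
```

This vignette documents the statistical models, the algorithmic and
numerical choices, and the limits of what the package's tests demonstrate.
It is the companion to the function reference: where a design was genuinely
open, the choice made and its rationale are recorded here.

## The problem

Chloroplast genomes evolve slowly and unevenly: most of the molecule is
nearly invariant within a species, while a minority of short regions —
typically AT-rich, intergenic, and enriched for microsatellites — carry a
disproportionate share of SNPs and indels. Phylogeographic studies of plants
with very small populations need exactly those regions. The package
implements the two-stage strategy: (1) compare a few complete plastomes to
*screen* hotspot regions and polymorphic cpSSRs; (2) genotype a population
sample at the screened markers and analyze haplotype diversity, population
differentiation, network genealogy and admixture structure.

## Marker screening

**Trimming.** Columns containing any character outside `{A, C, G, T, -}` in
any sequence are removed before analysis (ambiguity codes and `N` carry no
usable signal at this scale). The removed-column report maps retained
columns back to original coordinates so loci can be reported against the
input alignment. All coordinates in outputs are 1-based closed intervals
over alignment columns.

**Binning.** The trimmed alignment is tiled into consecutive bins of 400 bp
(configurable). The final short bin is retained rather than dropped: this
preserves the conservation invariants (bin SNP counts sum to the total
number of segregating sites; every indel event is counted exactly once, in
the bin containing its leftmost column) that the tests assert.

**SNP counting.** A bin's SNP count is its number of *segregating sites*
among the ingroup — columns where two or more distinct non-gap bases occur.
With only three ingroup sequences, pairwise-difference counting and
segregating-site counting nearly coincide; segregating sites are
well-defined for any sample size, so that definition is used throughout and
an outgroup (used only as an alignment anchor) is excluded via the
`ingroup` argument.

**Indel events.** An indel event is a maximal run of `-` in one sequence;
runs with identical extent shared by several sequences are a single
mutational event. This mirrors the one-indel-one-mutation convention used
for haplotyping (below), keeping the scan and the downstream statistics
consistent.

**cpSSR detection.** Perfect tandem repeats with motif length 1–6 bp are
reported when they reach 8 units (mononucleotide) or 5 units
(multinucleotide) — the conventional GMATo-style thresholds. Two rules keep
the report canonical: motifs that are themselves periodic (e.g. `AA`,
`ATAT`) are never reported, so each locus appears once at its smallest
period; overlapping candidates are resolved leftmost-longest. Compound and
imperfect repeats are out of scope. Polymorphism screening detects SSRs per
ungapped sequence, maps them to alignment columns, clusters loci sharing a
canonical (rotation-minimal) motif and overlapping span, then *recounts*
the tandem unit number of every sample over the cluster span — so a sample
whose repeat dropped below the detection threshold still contributes its
allele.

**Hotspot ranking.** Bins are scored by `snp_count + indel_count`; ties
break by higher SNP count, then lower start coordinate (fully
deterministic). Adjacent selected bins fuse into regions, and selection
continues until the requested number of regions (default 27) exists or
variable bins run out, with a warning in the latter case.

**Correlations.** Spearman's rank correlation uses average ranks for ties
and a two-sided p-value from the t approximation on n − 2 degrees of
freedom. A constant vector yields `NA` with a warning — an undefined
correlation, deliberately distinct from zero.

## Haplotypes and diversity

Haplotyping follows the conventions of chloroplast marker studies:

* terminal (5′/3′) gaps are missing data — the sample does not vote at
  those columns and its state is undefined for characters there;
* alignment columns inside mononucleotide runs of ≥ 8 bp in any sample are
  excluded (cpSSR stutter is screened separately, not counted as sequence
  variation); the 8-bp cutoff deliberately equals the mono-SSR detection
  threshold and is a configurable knob;
* each maximal internal gap run (identical extent across carriers) becomes
  one binary presence/absence character — an indel is a single mutation
  event regardless of length;
* a haplotype is a distinct joint state over substitution columns plus
  indel characters; inter-haplotype distance is the count of differing
  characters where both states are defined.

Haplotype ids are assigned H1, H2, … by decreasing global count with ties by
first occurrence among samples sorted by id, which makes the numbering
invariant to input order. If no characters survive filtering, all samples
form one haplotype and a warning (not an error) is emitted.

Diversity uses Nei's unbiased estimators. Nucleotide diversity uses
substitution characters only and divides by the number of retained,
gap-free, fully resolved columns — indel characters contribute to neither
numerator nor denominator.

## Differentiation

**Pons–Petit estimators.** With unweighted population means and the
harmonic-mean sample-size correction:
$h_k = \frac{n_k}{n_k-1}(1 - \sum_i p_{ki}^2)$,
$H_S = \frac1P \sum_k h_k$,
$H_T = 1 - \sum_i \bar p_i^2 + H_S/(\tilde n P)$, and
$G_{ST} = 1 - H_S/H_T$. The ordered (distance-weighted) analogues replace
$1-\sum p^2$ with $\sum_{i \ne j} p_i p_j d_{ij}$, giving $v_S$, $v_T$ and
$N_{ST}$. The correctness anchor, asserted to machine precision in the
tests, is the identity $N_{ST} = G_{ST}$ whenever all inter-haplotype
distances are equal. Note the unbiased corrections leave an $O(1/n)$
remainder: a population duplicated as two yields $G_{ST}$ near, but not
exactly, zero for small $n$. Populations with fewer than two samples are
excluded (with a warning) since $h_k$ is undefined for them.

The $N_{ST} > G_{ST}$ test permutes haplotype identities on the distance
matrix (rows and columns jointly), preserving frequencies while destroying
the association between genealogical distance and geography; the p-value is
$(1 + \#\{N_{ST}-G_{ST} \ge \text{obs}\})/(1 + n_{perm})$, never exactly
zero.

**AMOVA.** The Excoffier decomposition of squared inter-sample distances,
with the standard unbalanced-design coefficients for one (population) or
two (group/population) levels. Squared mutational step counts are the
default distance ($\delta^2 = d^2$); `squared = FALSE` uses the supplied
values as-is for sensitivity analysis. Negative variance components are
reported as computed, and percentages are computed from the raw components.
Permutation schemes follow the stratum being tested: samples among
populations for $\Phi_{ST}$ (group labels following the permuted population
assignment), samples among populations within groups for $\Phi_{SC}$, and
whole populations among groups for $\Phi_{CT}$. A grouped design with one
group reduces exactly to the one-level decomposition. One master seed
drives the three tests through derived streams (seed + 1, 2, 3), recorded
in output headers.

The test suite validates the components against an independent oracle that
embeds samples as Euclidean points, computes sums of squares from projection
quadratic forms, and solves the expected-mean-square system with
trace-derived coefficients — a route that never touches the closed-form
coefficient formulas used by the implementation.

A note on printed-table arithmetic: published five-population haplotype
count tables for this system reproduce their one-level AMOVA exactly under
haplotype-frequency (0/1) distances only if the fourth Funiushan haplotype
is read as H11 rather than a second H1 — the reading consistent with the
accompanying statement that eleven haplotypes exist and that H9–H11 are
restricted to that population. The tests freeze that reading. The grouped
AMOVA block is not recoverable from the printed counts under the stated
grouping and is left unasserted.

## Median-joining networks

The minimum spanning network (MSN) is computed by the single-linkage
characterization: an edge $(i,j)$ belongs to the $\varepsilon$-relaxed MSN
iff $d_{ij} \le t_{ij} + \varepsilon$, where $t_{ij}$ is the single-linkage
merge threshold (the min-max path distance). With $\varepsilon = 0$ this is
exactly the union of all minimum spanning trees — ties are retained, and a
unique MST is returned unchanged. $\varepsilon$ defaults to 0, the common
default of network software; it is surfaced as a flag because the source
studies rarely state it.

Median joining iterates: build the MSN over the current node set; for every
triplet connected in the MSN, form the per-character majority median (all
three states distinct falls back to the state of the lowest-ordered node —
a documented, deterministic tie-break); add the candidate that most reduces
the minimum-spanning cost of the node set (ties broken lexicographically on
the state string); stop at a fixpoint or after 10,000 medians. Finally,
median vectors that lie on no shortest path between observed haplotypes are
removed, iterating until stable. Substitution and indel characters carry
equal weight, consistent with the one-indel-one-step convention. The
Steiner-tree test case (three pairwise-distance-2 haplotypes whose median
reduces the network from cost 4 to cost 3) is verified against exhaustive
enumeration in the tests.

## Haploid admixture clustering and ΔK

The STRUCTURE-style model for haploid multilocus genotypes: sample $i$'s
allele at locus $l$ originates from cluster $z_{il} \sim
\mathrm{Cat}(Q_{i\cdot})$ and is drawn from that cluster's allele
frequencies $P_{z,l,\cdot}$. The Gibbs sweep updates
$P \mid z \sim \mathrm{Dir}(\lambda + \text{counts})$,
$Q_i \mid z \sim \mathrm{Dir}(\alpha_0 + \text{counts})$, and
$z \mid P, Q$ categorically. Defaults: $\lambda = 1$, $\alpha_0 = 1$,
burn-in 5,000 and 20,000 retained sweeps — desk-scale settings chosen so a
full ΔK scan runs in minutes; production-scale sweep counts are plain
arguments. Missing alleles (NA or −9) are simply skipped. The model
log-probability is the STRUCTURE-style estimator
$\widehat{\ln P(D)} = \overline{\ln L} - \mathrm{var}(\ln L)/2$ with
$\ln L = \sum_{il} \ln \sum_k q_{ik} p_{kl,a}$.

Three deliberate choices:

* **Independent allele-frequency prior.** The correlated-frequency F-model
  adds a hierarchy that six haploid loci cannot support; the independent
  Dirichlet prior is the documented default lineage of the method. The
  choice is recorded in the result's `model` field.
* **Fixed $\alpha_0$.** The admixture hyper-parameter is not sampled. With
  $L$ loci the posterior mean membership is bounded by
  $(\alpha_0 + L)/(K\alpha_0 + L)$, so recovery analyses of strongly
  diverged clusters should pass a small `alpha0` (e.g. 0.1) — the tests do.
* **K = 1 uses the same estimator.** For one cluster Q is analytically a
  column of ones and P's posterior is a fixed Dirichlet; `lnpd` is still
  computed by the mean − var/2 sweep estimator so that values are
  comparable across K (mixing an exact marginal at K = 1 with the sweep
  estimator elsewhere would bias every ΔK and model-choice comparison,
  because the sweep estimator sits a posterior-KL offset above the true
  marginal). The K = 1 sampler is validated against exact
  digamma/trigamma moments of the log-Dirichlet in the tests.

Evanno's ΔK is $|L(K{+}1) - 2L(K) + L(K{-}1)| / \mathrm{sd}(L(K))$ over
replicate runs; it is undefined (flagged NA, never infinite) where the
across-run sd is zero, and at the ends of the K range. Label switching
across runs is resolved by greedy column matching to the first run —
adequate for the small K of cpSSR work, and checked against brute-force
permutation for K ≤ 4; a full CLUMPP-style consensus is out of scope.

## The synthetic-data generator

The generator emulates the features the analyses rely on, and only those:

* **Quadripartite structure**: LSC | IRA | SSC | IRB with IRB the exact
  reverse complement of IRA; defaults reproduce a Dendrobium-scale genome
  (84,719 + 25,984 + 12,099 + 25,984 = 148,786 bp) at background GC 0.375.
* **AT-biased hotspots**: 27 intervals of ~400 bp by default, at local GC
  0.25 with per-site SNP rate 0.02 and indel rate 0.008; the background
  rate is one tenth of the smallest hotspot rate, and the IRs are kept
  mutation-free (they are strongly conserved in real plastomes, and
  mutating IRA would silently break the mirror invariant).
* **cpSSR seeds** planted verbatim inside hotspots, with repeat numbers
  varied among lineages by a stepwise (birth–death) process.
* **Population structure**: a two-tier star genealogy — deme founders
  diverge from the ancestral sequence by Poisson(`divergenceSteps`)
  mutational events (default 3, matching the few-step haplotype networks
  typical of intraspecific plastome data), within-deme satellites diverge
  from their founder by Poisson(`localSteps`) (default 1). A one-tier star
  would make all haplotypes equidistant, which forces
  $N_{ST} \approx G_{ST}$ and would make phylogeographic structure
  undetectable by construction; the two-tier process creates the
  within-deme-closer-than-between pattern the $N_{ST}$ test needs while
  preserving the star-like, ancestor-centred network shape. Each sample
  carries a haplotype from its deme's pool, or with probability
  `admixture` (default 0.1) from another deme.
* **Alignment-frame mutation**: deletions become 1–10-column gap runs in
  the carrier; SSR expansions become inserted columns (gaps in all
  non-carriers). Mutations are placed directly in alignment coordinates —
  the analyses consume alignments, and alignment inference is explicitly
  out of scope, so no re-alignment step exists to disturb the truth
  tables. Indel lengths are uniform on 1–10 columns (small indels dominate
  intraspecific plastome variation; the exact law is not critical and is
  not asserted anywhere).
* The default demography mirrors a five-population design of 9/7/2/6/4
  samples in three groups with an 11-lineage pool.

What the generator does **not** emulate: coalescent genealogies with
recombination (plastomes do not recombine, but neither does the generator
draw genealogies from a coalescent), selection, heteroplasmy, sequencing
error, or alignment error. Consequently, passing tests demonstrate the
*estimators and algorithms* are correct on data satisfying their
assumptions — they do not validate robustness to misalignment or to
assembly artifacts in real data.

Per-sample truth tables (haplotype lineage, source deme, cpSSR unit counts)
are returned alongside every simulated alignment, which is what the
truth-table tests compare against.

## Numerical conventions and problem sizes

* All stochastic functions take an explicit `seed`; RNG state is restored
  afterwards, so seeded calls never perturb a surrounding stream. Fixed
  seed + fixed inputs ⇒ bit-identical outputs (asserted for the CLI).
* Permutation p-values use the add-one convention and therefore lie in
  (0, 1].
* Floating-point identities (Nst = Gst under equal distances; grouped
  AMOVA with one group equals the one-level design) are asserted at
  10⁻¹²; oracle agreements at 10⁻⁸.
* The test suite runs its Monte-Carlo properties at reduced problem sizes
  chosen to keep the full suite in a few minutes while leaving the
  assertions sharp: 8.7-kb plastomes with 8 hotspots and 15–21 samples for
  the scan/differentiation properties (20 replicates), 10-locus,
  20-sample genotype matrices for clustering recovery (10 seeds), and
  3-run ΔK scans over K = 1…5. The statistical conditions (rate contrasts,
  divergence steps, admixture settings) are the ones stated above, not
  scaled.

## Known limitations

* Hotspot region fusion is adjacency-based on bins; the published 27-region
  lists of real studies involve manual curation that no algorithm can
  reproduce exactly.
* Pairwise-deletion handling of missing states in haplotype distances can
  make step distances non-metric in pathological missingness patterns;
  terminal gaps are the only missingness source produced by this pipeline.
* The MJ implementation targets the small haplotype sets of intraspecific
  studies (tens of nodes); its exhaustive triplet scan is quadratic in the
  MSN degree and not intended for hundreds of haplotypes.
* `Hs`/`Ht` from marker-level data and `Hd` from collapsed haplotypes are
  different estimators of related quantities and will not agree numerically
  on real data; both are reported so users can compare.
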