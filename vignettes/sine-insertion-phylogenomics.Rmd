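---
title: "SINE insertion phylogenomics: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SINE insertion phylogenomics: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinephylo)
```

sinephylo implements a complete retroposon-insertion phylogenomics workflow
for a 16-taxon cetacean system (15 cetaceans plus the hippopotamus
outgroup): discovery of candidate SINEs by target-site-duplication
scanning, presence/absence coding and filtering, irreversible-character
parsimony with branch-mapped synapomorphies, rule-based classification of
anomalous loci, and fossil-calibrated relaxed-clock dating of the
element-free flanking sequence. This vignette records the scientific model
behind each stage, the tunable parameters with their defaults and why, and
the design decisions taken where more than one reasonable construction
exists.

## Element discovery by TSD scanning

When a SINE integrates, the target site is duplicated, leaving identical
direct repeats (target-site duplications, TSDs) immediately flanking the
element. `scan_tsd_candidates()` searches for every interval of
100–500 nt (defaults, configurable) whose immediate flanks are perfect
direct repeats of 8–25 nt. Conventions:

* **Element length is measured between the repeats**, excluding both TSD
  copies. The window bounds are configurable because the field sometimes
  quotes lengths inclusive of repeats.
* Repeats must be **exactly adjacent** to the element, **exact matches**,
  case-insensitive; any window containing a non-ACGT code (including N)
  never matches — N is an unknown base, not a wildcard.
* **Maximality**: for a fixed element interval only the longest flanking
  repeat (capped at `max_tsd`) is reported. Overlapping candidates are then
  resolved greedily — longer TSD first, then longer element, then leftmost
  start — and losers are dropped. This mirrors "perfect repeat" extraction
  while making the output deterministic and testable.
* Scanning is single-strand: TSDs are direct repeats and read identically
  on both strands. Consensus annotation (`classify_candidates()`) searches
  both strands via Smith–Waterman local alignment and reports the
  best-scoring family above identity and coverage thresholds (defaults
  0.8/0.8), with deterministic tie-breaking by library order.

The production scanner indexes k-mer positions per repeat length (near
linear expected time); an O(n²k) enumeration of all (position, repeat
length, spacing) triples exists solely as a test oracle and the two are
compared exactly on hundreds of random sequences.

A note on chance matches: on random background the expected number of raw
8-nt TSD pairs is about `n × 401 × 4⁻⁸ × 4/3` — dozens per 10 kb. Short-TSD
candidates in real or simulated scans are therefore not all retroposons;
the test suite checks the scanner *against this expectation* rather than
against zero, and planted-element fixtures use TSDs of ≥ 14 nt so that
chance candidates cannot displace planted ones during overlap resolution.

## Presence/absence coding and informativeness filtering

`code_matrix()` converts per-taxon PCR observations into a `{0, 1, ?}`
matrix: long amplicon → presence (1), short amplicon → absence (0), no
interpretable amplification → missing (?). A taxon exhibiting both allele
classes — a heterozygous two-band profile, or presence and absence in
different individuals — is coded 1 (the insertion allele is demonstrably
present) and retained in per-locus polymorphism metadata that the anomaly
classifier consumes. Present and absent records for one (locus, taxon)
without such supporting evidence are a hard conflict error.

`filter_informative()` removes loci that failed in all taxa, loci flagged
undecipherable (an input flag: it cannot be derived from states), and loci
present in all taxa. Two design choices:

* "Present in all taxa" is evaluated over non-missing entries by default: a
  locus that is 1 in every amplifying taxon carries no grouping signal for
  the sampled taxa even if some reactions failed. A strict mode requires 1
  in literally every taxon; both are provided because published tallies
  rarely state which rule was used.
* Species-specific insertions (autapomorphies) are retained as informative:
  they document terminal branches in the insertion tree.

## Camin–Sokal irreversible parsimony

Retroposon integration is effectively irreversible: no mechanism of precise
excision is known. Characters are therefore scored under Camin–Sokal
parsimony: only 0 → 1 changes are allowed and the root (the outgroup
attachment) is fixed at state 0. With missing entries assigned freely, the
minimum number of origins equals the number of maximal subtrees whose
determinate leaves are all 1, computed by a single postorder pass over
(has-1, has-0) flags. Two boundary conventions matter:

* Changes live on branches. If even the root subtree is 0-free, the origins
  fall on the root's child branches (there is no branch above the root); a
  character scored 1 across the ingroup with a missing outgroup maps to the
  ingroup stem with a single origin.
* `origin_branches` reports the stem of each maximal all-1 subtree, and
  branches are identified by their subtended leaf sets, never by figure
  labels — published clade letters are not stable identifiers.

The postorder scorer is verified against a brute force that minimises over
all subsets of branches receiving a change (≤ 2^|E| subsets), and
cross-checked against an independent Sankoff implementation with an
asymmetric cost matrix.

Compatibility of two irreversible binary characters reduces to the laminar
condition (determinate 1-sets nested or disjoint), and a conflict-free
matrix yields a perfect phylogeny whose clades are exactly the distinct
1-sets (`build_perfect_phylogeny()`), with polytomies where unresolved.
Tree search (`search_mp_trees()`) offers exhaustive enumeration (≤ 9
ingroup taxa), an exact branch-and-bound (partial-tree scores only grow as
taxa are added, so the incumbent prunes safely), and a heuristic
(random-addition starts, NNI to convergence alternating with SPR sweeps
until neither improves; all randomness behind a seed). `strict_consensus()`
keeps exactly the clades common to all optimal trees. Polytomies are
retained rather than arbitrarily resolved.

## Anomaly classification

Three biological processes can make one presence/absence column conflict
with the species tree, and the classifier is deliberately rule-based:

* **Near-parallel insertion** (`detect_near_parallel()`): two independent
  elements at nearby but distinct sites mimic a shared insertion on a gel.
  Insertion points are compared on the ungapped coordinate frame of an
  element-free sequence; any offset ≥ 1 nt, or element identity below 0.8
  at a shared point, is called near-parallel. Offsets of 1–5 nt are
  additionally flagged for manual review because alignment slippage can
  fabricate small offsets. Splitting such a locus into site-specific
  characters (`split_near_parallel()`) removes the homoplasy: each split
  character scores a single origin again.
* **Polymorphism** (`detect_polymorphic_loci()`): both allele classes
  within a species, from a heterozygous profile or a mixture across
  individuals.
* **Candidate explanations** (`classify_conflict()`): a locus fixed in one
  group and polymorphic in related taxa keeps *all three* candidate
  explanations — incomplete lineage sorting, introgression, and paralogous
  insertion — because presence/absence data alone cannot adjudicate among
  them; the output is always a candidate set, never a single verdict.
  Remaining multi-origin characters without sequence evidence are reported
  as unresolved homoplasy with the same non-empty candidate set.

Quantitative hemiplasy expectations live in the simulator, not in the
classifier.

## Relaxed-clock dating of element-free flanks

`concatenate_flanks()` removes every alignment column touched by an
element, plus columns above a gap-fraction threshold (default 0.5), and
concatenates the rest with partition bookkeeping and a removal log, so that
dating is fully independent of the insertions themselves. The package
always reports its own retained-site count; published per-study site counts
are typically irreproducible to the digit because alignment filtering is
operator-dependent.

The dating model: on a fixed rooted topology, branch length in expected
substitutions per site is (parent age − child age) × μ × m<sub>e</sub>,
with m<sub>e</sub> i.i.d. lognormal with mean 1 and log-SD σ — the
uncorrelated lognormal relaxed clock. The likelihood is Felsenstein pruning
over compressed site patterns under a reversible substitution model
(JC/K80/HKY/GTR; `select_model()` ranks them by AIC with substitution
parameters ML-fitted on a fixed neighbour-joining tree — branch lengths are
shared across candidates and cancel from the comparison). Gaps and N are
fully ambiguous.

**Priors.** Four fossil calibrations enter as lognormal densities on node
age with offset at the younger bound, log-SD as published, and the median
of the lognormal part placed at the geometric mean of the bounds (the
common convention when a study quotes an interval plus an "SD" without
stating the parameterisation; fully configurable). The tree prior is
uniform on node ages given the root. One point deserves emphasis because
getting it wrong is both easy and quietly catastrophic: "uniform given the
root" means the conditional density of the non-root ages is
1/Vol(order polytope), and that volume scales as R^(n−1) with the root age
R. The sampler therefore includes a −(n−1)·log R term. Without it the
polytope volume acts as a polynomial pro-older bias that overwhelms the
calibration densities, and the nominal prior has most of its mass at
absurd ages. A side effect of the *correct* construction is still worth
knowing: free nodes trade volume against calibrated brackets, so the
marginal prior of an internally calibrated node (e.g. crown Odontoceti) is
tilted within its bracket relative to its raw calibration density; only
nodes bracketed from a single side (the Phocoenidae–Monodontidae split
here) reproduce their calibration density exactly in prior-only runs, and
the test suite checks exactly that plus the stronger invariant that an
empty alignment returns the joint prior unchanged. The published analysis
used a birth–death tree prior; uniform-given-root is simpler and the target
here is dating, not diversification inference.

**Sampler.** Metropolis–Hastings sweeps over node ages (sliding windows
reflected at order constraints, per-node widths scaled to node depth),
per-branch rate multipliers, μ, κ (for K80/HKY), and σ, plus three
likelihood-invariant moves that traverse the posterior's stiff directions:
an age-rate exchange (slide one node age while rescaling adjacent
multipliers so branch lengths are unchanged), a global age-versus-μ scale,
and a μ-versus-multipliers trade. Partial likelihoods are cached per node
and only the path to the root is recomputed after a proposal. Defaults
(4000 sweeps ≈ 190k proposals, 10% burn-in, sampling every 2 sweeps) are a
desk-scale stand-in for the published 20-million-generation runs; the
sampler reports acceptance rates and effective sample sizes so longer runs
can be requested when they matter. Substitution-model parameters beyond κ
(GTR exchangeabilities, gamma shape) are fixed at their `select_model()`
estimates rather than sampled; for low-divergence noncoding flanks their
posterior uncertainty is negligible relative to rate-time confounding.

**What the coverage simulations do and do not show.** The acceptance suite
draws true timetrees and rates from the sampler's own prior, simulates 4 kb
alignments under the relaxed clock (σ = 0.3), and checks that true node
ages fall inside 95% HPD intervals at close to the nominal rate over 100
replicates. This is simulation-based calibration: it validates the prior,
likelihood, and sampler jointly, under the model's own assumptions. It does
not validate those assumptions against real flanking data — alignment
error, selection on flanks, and model misspecification are outside its
reach. Finite chains also bite: with desk-scale chain lengths the shortest
HPD interval from a few hundred effective samples undercovers by roughly
2–3% (measured against long-chain prior-vs-prior calibration), so the test
accepts coverage down to 0.87 rather than demanding 0.95 exactly.

## The synthetic-data generator

The generator defines the study conditions every stage is tested under:

* `cetacean_timetree()` — the 16-taxon dated species tree (flank-sequence
  topology; published posterior mean ages; root at 52.08 Ma, the median of
  its fossil calibration, since no root age is published).
* `simulate_insertions()` — insertion origins as a Poisson process along
  branches (default rate 0.6 per lineage per Ma, chosen so the expected
  locus count over the ~358 Ma of total tree length matches the ~219-locus
  scale of the survey) with genealogies from a multispecies coalescent
  (constant Ne, default 0.5 Ma of pairwise coalescence time, two sampled
  alleles per species). Presence follows the gene lineage carrying the
  insertion, so short internodes yield hemiplasy and unfixed insertions
  yield polymorphism; as Ne → 0 every locus is concordant. An optional
  post-hoc allele-transfer event emulates introgression; it is off by
  default.
* `simulate_flank_alignment()` / `simulate_flanks()` — sites evolve
  independently down the timetree with one lognormal multiplier per branch
  shared across loci (matching the single-alignment clock model); flank
  loci carry an element block only in presence taxa. Element sequences are
  a per-locus consensus with 2% per-taxon mutations — adequate because
  element columns are removed before dating and only element identity
  (same/different) matters to the anomaly rules.
* `plant_genome()` — plants elements by duplicating the k-mer at the
  insertion site (the biological TSD mechanism), with boundary characters
  guarded so the repeat cannot extend by chance and planted coordinates are
  exact; TSD k-mers are rejection-sampled to occur exactly twice so recall
  is well defined.
* `simulate_pcr()` — independent per-reaction failure (default 5%), long
  and short amplicon classes, both classes for polymorphic taxa.
* `synthetic_survey_matrix()` — a synthetic reconstruction of the published
  219-locus survey structure: 118 all-failed loci, 1 undecipherable, 36
  present-in-all, and 64 informative loci whose synapomorphies fall on the
  insertion-tree branches with the published multiplicities (8 Cetacea
  stem, 1 Odontoceti, 4, 10, 13, 11, 4, plus 13 species-specific). The
  locus-to-branch assignment beyond those counts is synthetic; the matrix
  stands in for the unavailable supplementary data file and is labelled
  accordingly.

## Numerical choices and degenerate inputs

Ties in overlap resolution, library annotation and heuristic search are
broken deterministically (seeded where random). Empty sequences, empty
libraries, zero-length alignments, all-missing characters and zero-locus
matrices return empty results or defined conventions (a zero-length
alignment has log-likelihood 0, with a warning) rather than errors, except
where the spec of the operation demands an error (invalid bounds,
conflicting observations, unmappable calibrations, non-overlapping
calibration constraints). Discrete-gamma rates use equal-probability
categories represented by conditional means. The HPD interval is the
shortest window containing ⌈0.95 n⌉ sorted samples.

## Known limitations

* The annotator is a local-alignment stand-in for RepeatMasker-style
  screening: no defragmentation, no family-specific scoring matrices.
* Dating assumes the topology; tree-space MCMC is out of scope, and the
  uniform-given-root prior tilts internally calibrated nodes within their
  brackets (see above) — estimated ages for such nodes sit a little above
  a birth–death-prior analysis of the same data.
* The coalescent insertion simulator uses one constant Ne; per-branch Ne
  variation and gene conversion are not modelled.
* Heuristic tree search is exact only in expectation; for ≤ 9 ingroup taxa
  use branch-and-bound, which is exact.
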