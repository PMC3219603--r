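# sinephylo

Phylogenetic analysis with SINE retroposon insertion markers, end to end:
from raw genomic sequence to a dated species tree.

SINEs (short interspersed elements) integrate into genomes essentially
irreversibly and at nearly random sites, so a SINE shared at an orthologous
locus by several taxa is close to an ideal synapomorphy. This package
implements the full marker workflow for a 16-taxon cetacean system
(15 whales, dolphins and porpoises plus the hippopotamus outgroup), and a
synthetic-data generator that makes every stage testable without any
external downloads:

* **Element discovery** — scan genomic sequence for candidate retroposed
  elements of 100–500 nt flanked by 8–25 nt perfect direct repeats
  (target-site duplications), and annotate candidates against a consensus
  library by local alignment on both strands.
* **Character coding** — code per-taxon PCR presence/absence observations
  into a `{0, 1, ?}` matrix (heterozygous profiles become presence plus a
  polymorphism flag) and filter to phylogenetically informative loci.
* **Irreversible parsimony** — score characters under the Camin–Sokal
  criterion (only 0 → 1 changes, ancestral state 0): the minimum number of
  insertion origins for a character is the number of maximal subtrees whose
  determinate leaves all carry the insertion. Includes pairwise character
  compatibility (the laminar condition on 1-sets), perfect-phylogeny
  construction, exhaustive / branch-and-bound / heuristic searches for
  minimum-change trees, strict consensus, and per-branch synapomorphy
  mapping.
* **Anomaly classification** — near-parallel insertions (two independent
  elements at sites an offset apart in the ancestral coordinate frame),
  within-species insertion polymorphism, and rule-based candidate sets
  (incomplete lineage sorting / introgression / paralogous insertion) for
  loci that conflict with the species tree.
* **Divergence dating** — concatenate element-free flanking sequence,
  choose a substitution model by AIC, and sample node ages under a
  fossil-calibrated uncorrelated lognormal relaxed clock: branch length
  = duration × μ × m<sub>e</sub> with m<sub>e</sub> ~ LogNormal(−σ²/2, σ),
  four lognormal fossil calibrations, a uniform-given-root tree prior, and
  a Metropolis–Hastings sampler (C++ core) with 95% HPD summaries.

Everything tabular goes in and out as tibbles; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` displays.

## Worked example

```r
library(sinephylo)

## 1. plant three elements with TSDs into a random genome and re-find them
pg <- plant_genome(3, background_length = 8000, seed = 7)
cand <- scan_tsd_candidates(pg$genome)
dplyr::filter(cand, tsd_length >= 14)
#>   source_id        left_tsd_start left_tsd_end element_start element_end
#> 1 synthetic_genome           4108         4125          4125        4397
#> 2 synthetic_genome           5601         5616          5616        6001
#> 3 synthetic_genome           7328         7347          7347        7651
#>   ... tsd_length tsd_sequence
#>             17   AAGTAACCAATGCCAGC
#>             15   GCCGCCCCTCTTGCC
#>             19   ACGTTTTATAGCAGGTATT
```

All three planted elements are recovered with exact coordinates (0-based,
half-open) and their duplicated target sites.

```r
## 2. filter the 219-locus synthetic survey and map synapomorphies
flt <- filter_informative(synthetic_survey_matrix())
flt$report
#>   category           n
#> 1 failed_all       118
#> 2 undecipherable     1
#> 3 present_all       36
#> 4 informative       64

ms <- map_synapomorphies(cetacean_insertion_tree(), flt$matrix)
head(dplyr::select(ms$branches, clade_label, n_loci), 7)
#>   clade_label                                  n_loci
#> 1 Balaenoptera_acutorostrata|Balaenoptera_omur      8   # Cetacea stem
#> 2 Delphinapterus_leucas|Delphinus_capensis|Gra      1   # Odontoceti
#> 3 Delphinapterus_leucas|Delphinus_capensis|Gra      4
#> 4 Delphinapterus_leucas|Delphinus_capensis|Gra     10
#> 5 Delphinapterus_leucas|Delphinus_capensis|Gra     13
#> 6 Delphinapterus_leucas|Delphinus_capensis|Gra     11   # Delphinoidea
#> 7 Delphinus_capensis|Grampus_griseus|Sousa_chi      4   # Delphinidae
```

Of 219 loci, 118 failed in all taxa, 1 is undecipherable, 36 are present in
every taxon, and 64 are informative; the informative loci map onto the
insertion tree with 8 supporting the monophyly of Cetacea, 11 supporting
Delphinoidea, 4 supporting Delphinidae, and so on — branches are identified
by their subtended taxa.

```r
## 3. date nodes from element-free flanking sequence
tt <- cetacean_timetree()
aln <- simulate_flank_alignment(tt, 4000, mu = 0.002, sigma = 0.3, seed = 1)
fit <- mcmc_date(aln, tt, cetacean_calibrations(), model = sub_model("JC"),
                 clock = clock_prior(sigma = 0.3, sample_sigma = FALSE),
                 seed = 1)
node_age(fit, c("Neophocaena_phocaenoides", "Delphinapterus_leucas"))
#>   mean  median hpd_lower hpd_upper   ess
#>   11.0    10.7      10.0      13.1  424.
glance(fit)
#>   n_samples acceptance ess_logpost model prior_only
#>        1800      0.365        412. JC    FALSE
```

The porpoise–beluga (Phocoenidae–Monodontidae) split, simulated at
11.39 Ma, is re-estimated at 11.0 Ma with a 95% HPD of [10.0, 13.1] —
the truth sits comfortably inside the interval.

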