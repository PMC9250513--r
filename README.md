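# emsco

Genome-wide detection of meiotic crossovers (COs) in crossing designs that
use **sparse EMS-induced mutations as markers**, plus the statistics needed
to compare megabase-scale recombination landscapes.

Mapping COs normally requires a hybrid, where dense natural polymorphism
makes recombinant haplotypes visible — but then the measured landscape is
entangled with the polymorphism landscape.  An alternative design crosses
two independently EMS-mutagenized plants into an F1\* that is heterozygous
for a few hundred induced G→A / C→T mutations split between two *phases*
(its two homologues).  In F1 progeny of two reciprocally crossed F1\*s,
each CO of the F1\* meiosis appears as a consistent switch of marker phase
along a chromosome, separately observable for female and male meiosis.
The catch: markers are ~100–300 kb apart and progeny are sequenced at ~5×,
where a heterozygous marker shows *no* mutant read ~8% of the time, so
naive genotype tracks flip constantly.

`emsco` provides, for this design and its hybrid companion:

* **Marker filtering** — heterozygous candidates with alt-allele frequency
  in [0.4, 0.6], private to one F1\*, EMS-type (G→A/C→T), outside repeat/SV
  masks (`filterEmsMarkers()`); syntenic-block liftover between assemblies
  (`liftoverPositions()`).
* **Phasing** — a sliding window of 10 markers (step 1) is clustered into
  the two local haplotype groups (average-linkage on mismatch fractions);
  overlapping windows *vote* on every call, with support-rate thresholds
  0.9 near chromosome ends and 0.8 internally gating imputation and
  correction (`phaseMarkers()`).
* **Inbred CO calling** — consistent phase switches (≥ 2 markers), noise
  masking, read-level border refinement, and terminus validation (accept a
  terminal switch on ≥ 3 mutant reads or a > 10-read consecutive wild-type
  observation) (`callCrossovers()`, `validateTerminalCO()`).
* **Hybrid CO calling** — sliding-window genotyping of dense SNPs with a
  0.95 allelic-ratio homozygosity threshold, design-legal transition
  calling (BC1/F2), binomial-likelihood breakpoint refinement, terminal
  rescue, and sample QC (`genotypeWindows()`, `callCrossoversHybrid()`,
  `qcSamples()`).
* **Landscapes** — CO-frequency tracks (2 Mb windows / 50 kb step) with
  bootstrap confidence bands, per-chromosome normalization + 40-window
  moving-average smoothing + z-scoring, peak/valley detection, Spearman and
  segmented non-linear correlation, permutation overlap tests against
  region sets, and coefficient-of-coincidence interference curves.
* **A forward simulator** — gamma-renewal meiosis (interference shape ν,
  obligate-CO option, heterozygous-inversion suppression, piecewise
  intensity tracks) with a Poisson-depth binomial read model, providing
  exact ground truth for every stage (`simulateMeiosis()`,
  `simulateInbredPopulation()`, `simulateHybridPopulation()`).

Containers are Bioconductor-style S4 (`GenomeLayout`, `MarkerSet`,
`AlleleDepthMatrix` on `SummarizedExperiment`, `PhaseMatrix`,
`CrossoverSet`, `LandscapeTrack` on `GRanges`).  A thin command-line
wrapper lives in `inst/scripts/emsco`.

## Worked example

Simulate an inbred F1 population on an Arabidopsis-sized genome, phase one
parent's markers, and call its female-meiosis crossovers:

```r
library(emsco)

lay <- arabidopsisLayout()
cfg <- SimConfig(nSamples = 100, markerCount = 450, seed = 42)
pop <- simulateInbredPopulation(cfg, lay)

adm <- pop$depths$P1          # 450 markers x 100 samples, ref/alt reads
pm  <- phaseMarkers(adm)
pm
#> PhaseMatrix: 450 markers x 100 samples
#> calls: 44954 ( observed 42741, imputed 262, corrected 1951 )

cos <- callCrossovers(pm, adm, parent = "P1", sex = "female")
cos
#> CrossoverSet with 370 crossovers in 98 sample(s)
#> median resolution: 1194996 bp

head(coCalls(cos), 3)
#>   sample parent    sex chrom     left    right from to resolution
#> 1 F1_001     P1 female  Chr1 15291654 18644720    A  B    3353066
#> 2 F1_002     P1 female  Chr1  8290457  9305055    A  B    1014598
#> 3 F1_007     P1 female  Chr1 24450712 26166066    B  A    1715354
```

The phase matrix shows how the voting behaves at 5×: ~95% of calls are
direct observations, ~4% are observed genotypes corrected by the window
vote (mostly allele dropouts), and a few hundred missing sites are imputed.
The caller reports 370 crossover intervals (the simulation planted 410;
the difference is COs without two informative flanking markers, which are
not callable at this marker density).  Each interval is bounded by genuine
marker positions; `resolution` is the interval width in bp — ~1.2 Mb
median at 450 markers/parent, shrinking with marker count.

Downstream, `coFrequencyTrack()` + `normalizeAndSmooth()` turn pooled
calls into the 50-kb landscape grid, `coCountSummary()` compares female
vs male CO counts with a two-sided Mann–Whitney test, and
`permutationOverlapTest()` / `interferenceCoc()` quantify regional
depletion and interference.

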