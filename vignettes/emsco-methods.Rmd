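---
title: "Detecting meiotic crossovers from EMS-induced markers: models and methods"
author: "emsco package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting meiotic crossovers from EMS-induced markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsco)
library(GenomicRanges)
```

# The problem

Meiotic crossovers (COs) are usually mapped in hybrids, where dense natural
polymorphism makes every recombinant haplotype visible.  That confounds the
CO landscape with the polymorphism landscape.  An alternative design
measures recombination in essentially isogenic material: two independently
EMS-mutagenized plants are crossed to make an F1\* that is heterozygous for
a few hundred induced G->A / C->T point mutations, split between its two
homologues (two *phases*).  F1 progeny of two reciprocally crossed F1\*s
each carry one recombinant haplotype from the female and one from the male
meiosis, and a CO appears as a consistent switch of marker phase along a
chromosome.  The markers are sparse (~one per 100-300 kb) and the progeny
are sequenced at low coverage (~5x), so individual genotype observations
are unreliable and the method has to lean on population structure.

`emsco` implements this inbred-line CO caller (sliding-window
hierarchical-clustering phasing with voting, phase-switch calling with
read-level border refinement and chromosome-terminus validation), the
companion caller for hybrid backcross/F2 progeny genotyped at dense SNPs,
and the downstream landscape statistics (windowed frequency tracks with
bootstrap confidence bands, per-chromosome normalization and
moving-average smoothing, peak/valley detection, rank and segmented
non-linear correlation, permutation overlap tests, coefficient-of-
coincidence interference curves).  A forward simulator of both crossing
designs supplies ground truth for every stage.

# The simulator

`simulateMeiosis()` places COs on each bivalent by a stationary gamma
renewal process on the genetic axis.  Inter-event distances are
Gamma(shape = nu, rate = nu) in units of the mean spacing, so `nu = 1` is a
Poisson process (no interference) and larger `nu` suppresses nearby double
COs; `nu = 10` gives an inter-CO coefficient of variation of
1/sqrt(10) ~ 0.32.  Stationarity is obtained by starting the process 20
mean inter-arrivals upstream of the chromosome.  `intensity` is the
expected CO count per **bivalent**; each CO is transmitted to the sampled
chromatid independently with probability 1/2, so a gamete carries
`intensity / 2` COs on average — the arithmetic behind "one obligate CO
per bivalent = 0.5 per chromatid".  `obligateCo` enforces at least one CO
per bivalent by rejection (capped at 10,000 draws); COs falling inside a
heterozygous inversion are discarded after that acceptance, so a fully
inverted chromosome yields zero COs rather than an endless loop.  A
piecewise-constant `intensityTrack` maps the genetic axis to base pairs
through its inverse cumulative intensity, which is how structured
landscapes are simulated; otherwise the genetic map is uniform.

`simulateInbredPopulation()` and `simulateHybridPopulation()` layer the
read model on top: per-site depth is Poisson(`meanDepth`), the mutant or
parent-2 allele count is Binomial(depth, 1/2) at heterozygous sites and
Binomial(depth, `errorRate`) otherwise, and depth 0 is missing.  Defaults
are the study conditions the package is designed around: 300 progeny, 450
EMS markers per F1\* parent (~900 segregating per population), 5x depth,
0.5% per-read error, per-bivalent intensities `female = 1.6`,
`male = 2.45` per chromosome (scaled so that a gamete carries ~4 female /
~6 male COs across the five Arabidopsis-sized chromosomes of
`arabidopsisLayout()`, with male above female as observed in Arabidopsis),
`nu = 5`, obligate CO on.  The simulator emulates marker sparsity, allele
dropout, sequencing error, interference and inversion suppression; it does
**not** emulate alignment artifacts, non-allelic (paralogous) read
mapping, segmental coverage biases, contamination or gene conversion, so
passing tests demonstrate statistical correctness of the method under the
stated noise model, not robustness to every failure mode of real
sequencing data (non-allelic signal is instead handled upstream by the
marker filters, and contamination by the hybrid QC rules).

The two numbers worth remembering at 5x: a heterozygous site shows **no**
alt read with probability E[2^-D] = e^(-2.5) ~ 8% (allele dropout), and at
a 0.5% per-read error rate a non-carrier site shows >= 1 spurious alt read
with probability ~2.5%.  Almost every design choice below exists to make
the caller immune to one of these two events.

# Marker filtering and coordinate transfer

`filterEmsMarkers()` keeps a candidate variant iff (i) it is heterozygous
with an alternative-allele frequency in [0.4, 0.6] (inclusive at both
ends) in the F1\* that carries it, (ii) it is present in exactly one of
the two F1\*s (presence = heterozygous call with at least one alt read),
(iii) it is an EMS-type substitution (G->A or C->T), and (iv) it lies
outside the supplied mask intervals (tandem repeats, structural variants).
Duplicated surviving positions are treated as non-allelic signal and
rejected.  Masks are consumed as BED; the upstream repeat/SV detection is
out of scope.

`liftoverPositions()` transfers coordinates between assemblies through a
table of syntenic blocks: affine within `+` blocks, reflected
(`tgt_end - 1 - offset`, 0-based) within `-` blocks, proportionally scaled
when block lengths differ, and *unmapped* (never clamped) outside all
blocks.  Reflection is an involution, so inverting the block table
round-trips every mappable position exactly.

# Phasing by sliding-window clustering with voting

For one F1\* parent's marker set, the observable per (marker, sample) is a
derived genotype call: mutant (>= 1 alt read), wild-type (ref only) or
missing.  A window of 10 consecutive markers (step 1) is clustered into
two sample groups — the two locally inherited haplotypes — by average-
linkage hierarchical clustering on the pairwise mismatch fraction over
co-observed markers; pairs sharing fewer than 3 observed markers get the
uninformative distance 0.5.  Windows without any disagreement are
*degenerate* and abstain.  Group labels are chained left to right by
majority agreement of shared samples with the previous informative window
(ties keep the labels), which prevents arbitrary label flips mid-
chromosome.

Every (sample, marker) call is then decided by **voting** over the <= 10
windows covering the marker: the support rate of a call is its winning-
vote fraction.  The vote decides the call — imputing missing sites and
correcting contradicted observed ones — wherever support reaches the
positional threshold: 0.9 for markers at ordinal positions 5-9 from
either chromosome end, 0.8 in the interior.  The outermost four markers
rely on observed calls only: a handful of windows, all dominated by
interior markers, cannot out-vote a genuine terminal phase switch.  Where
the vote falls below its threshold (typically the few markers straddling
a true CO, where window assignments genuinely disagree), the observed
genotype read through the marker's phase label stands.  Per-marker phase
labels are the majority vote among samples observed as mutant there (or
the complement of the wild-type majority when no mutant was seen).
Chromosomes with fewer markers than one window are phased in a flagged,
degraded single-window mode.

Why vote-first?  At 5x, 8% of a sample's own-phase markers *look*
wild-type.  A raw-genotype phase track therefore flips constantly, while
the cluster assignment — driven by ten markers at once — is stable, and
its vote fraction along a chromosome is near-monotone across a CO, giving
a single clean switch.  An alternative rule that let high-support votes
override well-covered observed calls everywhere was evaluated and
rejected: near a true CO the window majority systematically overrides
genuine boundary observations and displaces the switch by one to two
markers.

On fully observed instances small enough for exhaustive search (<= 10
markers x <= 8 samples), the clustering-plus-voting assignment coincides
with the global agreement-maximizing phasing (up to the global A/B swap,
and up to genuinely tied marker labels), which the acceptance suite
verifies over 50 random instances.

# Crossover calling in inbred lines

A CO is a consistent phase switch: at least `minRun = 2` consecutive
non-missing markers of the new phase ("consistent switches" is not
quantified upstream; 2 is the weakest consistent reading and is exposed as
an argument).  Three safeguards shape the call structure:

* **Isolated internal flips** are masked as noise, weakest first: when
  adjacent short runs compete (a genuine boundary marker next to an error-
  read flip), the run with the least direct read evidence is removed
  first, so the noise call is masked rather than the boundary.
* **Run strength**: every surviving run must contain strong evidence for
  its own phase somewhere — >= 2 alt reads at a marker of that phase, or a
  ref-only observation deeper than 10 reads at a marker of the other
  phase.  Two adjacent allele dropouts (probability ~0.6% per marker
  pair) otherwise fabricate a `minRun`-long run of weak calls; requiring
  strength reduced the measured false-discovery rate from several percent
  to ~0.3% without touching recovery.
* **Terminal validation**: a switch reaching a chromosome end with fewer
  than `minRun` markers is accepted only on a well-supported mutant allele
  (>= 3 alt reads) or a consecutive wild-type observation carrying more
  than 10 reads — a deeply covered ref-only site at an old-phase marker
  demonstrates the sample lacks that phase's mutation.

Interval borders are refined by examining the read evidence across the
transition region (EMS markers are dominant-presence evidence, so a
shallow wild-type observation is compatible with either phase): the right
bound is the first marker with strong new-phase evidence, the left bound
the last marker before it with strong old-phase evidence, with the cut
between them chosen to maximize the number of strong observations on
their consistent sides (robust to a stray strong observation deep inside
a run).  Thresholds: >= 2 alt reads (a single alt read is a sequencing
error with probability ~2.5% per site and would misplace the bound), or
ref-only above 10 reads (dropout probability < 2^-11).  The 10-read
threshold reuses the terminal-validation constant.

At the default study scale (300 samples, 900 markers over five
chromosomes, 5x, 0.5% error), the acceptance suite measures >= 95%
recovery of true COs flanked by two informative markers per side, with the
true position inside the reported interval, at an FDR well under 2%.

# Crossover calling in hybrids

BC1/F2 progeny are genotyped at dense SNPs (default one per 5 kb) in
sliding windows of `winSnps = 50` SNPs, step 25 (the window is
parameterized in SNPs, not bp; a final window is anchored at each
chromosome end).  A window with fewer than 10 reads is missing; otherwise
the allelic ratio max(reads)/total calls homozygosity at >= 0.95
(inclusive) and heterozygosity below.  COs are sustained window-genotype
transitions (>= 2 windows per internal state; terminal runs may be a
single window, since a false whole-window homozygosity call over ~250
summed reads is essentially impossible) that are legal for the design —
hom-Col <-> het in BC1, plus het <-> hom-Ler in F2.  Direct hom <-> hom
transitions are impossible in a single meiosis and are flagged, not
called.  `qcSamples()` drops samples with > 50% missing windows
(coverage) and BC1 samples with > 5% hom-Ler windows (a genotype
impossible under the backcross design: contamination).

The breakpoint is then refined at SNP resolution with a binomial
likelihood changepoint: under hom-Col, het, hom-Ler the parent-2 read
count at a SNP of depth d is Binomial(d, e), Binomial(d, 1/2),
Binomial(d, 1 - e) with e the per-read error rate.  The reported interval
runs from the last SNP with error-robust evidence for the left state to
the first with such evidence for the right state, scanned outward from
the maximum-likelihood cut: on a heterozygous side the first SNP with
>= 2 reads of the allele the flanking homozygote lacks, on a homozygous
side the **third** consecutive hom-consistent SNP, because one or two
hom-looking SNPs in a row are routinely heterozygous sites with allele
dropout.  Crossovers closer to a chromosome end than window genotyping
can see (about half a window) are rescued by a dedicated terminal
changepoint test that accepts a terminal state only when it improves the
log-likelihood by >= 21 — roughly six average-depth informative SNPs, a
bar that a run of dropout artifacts cannot clear (zero false calls in
10,000 simulated non-recombinant chromosomes).

This coverage-first refinement has a deliberate cost.  At one SNP per
5 kb the gap *containing* a breakpoint is already ~8 kb in the median
(uniformly placed breakpoints land in length-biased gaps), and the
dropout slack adds about two more spacings, so reported intervals have a
~15-20 kb median.  Tighter intervals are possible only by surrendering
the guarantee that the true breakpoint lies inside the interval ~99% of
the time; the package chooses the guarantee.  Interval width scales with
the inverse SNP density, as the tests verify.

# Landscape statistics

`coFrequencyTrack()` assigns each CO to windows by its interval midpoint
and reports per-gamete frequencies; the display track uses 2-Mb windows
sliding by 50 kb, the analysis grid 50-kb tiles (then the per-window
counts sum exactly to the CO total).  Confidence bands (default 90%) are
percentile bootstrap over gametes, 1,000 replicates under a fixed seed —
resampling gametes, not COs, so the band reflects between-gamete
variation.  `normalizeAndSmooth()` divides each window count by the
chromosome's CO total, applies a centered 40-window moving average
(`stats::filter`; positions whose window is incomplete at chromosome ends
are missing, with no shrinking-window fallback), and z-scores over the
genome by default (`base::scale`; zero variance yields zeros with a
warning).  `detectPeaksValleys()` reports local extrema by topographic
prominence with a user-set threshold, since no canonical detector or
threshold exists for these tracks.

`correlateTracks()` offers Spearman correlation and a segmented
non-linear coefficient (`nlcorCoefficient()`), an independent
implementation of the segmented-correlation idea: points ordered by x are
split into s equal-size contiguous segments for each s up to ceiling(n/20);
per-segment Pearson p-values are Benjamini-Hochberg screened at 0.05 (a
failing segment contributes zero); the score of a segmentation is the
size-weighted mean of |r|, and the reported value is the maximum over
segmentations, in [0, 1].  A symmetric V-shaped relation — invisible to
Spearman — scores ~1; independent noise stays near 0 because random
segments rarely pass the screen.  Compartment scopes (arms /
pericentromere) restrict the correlated windows through the layout's
partition.

`permutationOverlapTest()` compares the observed count of CO midpoints
inside a region set (or inside flanks of configurable width, in adjacency
mode) against re-placements drawn uniformly per chromosome, preserving
per-chromosome CO counts; both one-sided empirical p-values are reported
with the floor 1/(nPerm + 1), i.e. 0.0002 at the default 4,999
permutations.

`interferenceCoc()` partitions a chromosome into fixed intervals and, for
every pair separation, divides the pooled frequency of gametes with COs in
both intervals by the product of single-interval frequencies.  Defaults
used in the acceptance analyses: a 30-Mb chromosome at bivalent intensity
4, 1.5-Mb intervals, separations up to half the chromosome.  Those three
numbers balance two failure modes: intervals much wider than the
interference distance dilute the short-range suppression (at `nu = 10`
the renewal process only suppresses pairs closer than ~3 Mb when the mean
spacing is 7.5 Mb), while long separations leave so few interval pairs
that the CoC ratio becomes noisy — hence the half-chromosome cap.

# Numerical and degenerate-input conventions

Marker positions are 1-based (VCF convention); BED/bedGraph input and
output are 0-based half-open.  CO intervals report marker/SNP positions,
`resolution = right - left`.  Empty CO sets give all-zero tracks but are
errors for the permutation test; a chromosome with zero COs normalizes to
missing with a warning; sd = 0 z-scores become zeros with a warning; ties
in clustering orientation keep the previous labels; fully tied
Mann-Whitney comparisons report p = 1.  All simulators and bootstrap/
permutation routines take explicit seeds and restore the caller's RNG
state; identical (configuration, seed) pairs give identical output.

# Problem sizes and limitations

The test and acceptance analyses run at the design scales: 300 progeny x
900 markers (inbred), 300 progeny x ~24,000 SNPs (BC1), 5,000 gametes for
landscape recovery, 10,000 gametes per interference curve, 10,000
chromosome trials for the false-positive check — each a minute or two of
compute.  Known limitations: the inbred caller's resolution is bounded by
marker sparsity (~1 Mb median intervals at 450 markers/parent, improving
with marker count); double COs closer than `minRun` markers are
unresolvable by construction; the hybrid caller assumes exactly the three
genotype states of a single meiosis (no aneuploidy or double reduction);
the phasing assumes two and only two haplotype groups per window, so
sample contamination must be removed upstream (hybrids) or will surface
as low-support calls (inbreds); and the simulator's noise model is
binomial-uniform, so systematic, locus-specific biases of real libraries
are outside what the recovery guarantees certify.
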