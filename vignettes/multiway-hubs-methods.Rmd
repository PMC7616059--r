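---
title: "Models and methods: multiway hubs, intermingling and bursting kinetics from single-cell Hi-C"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models behind `schichubs`, the
tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design
choices a maintainer would want on record. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The data and coordinate conventions

The primary input is one cell's Hi-C contact list: records
`(chromA, posA, chromB, posB)` with 0-based bp positions,
canonicalised so the genomically earlier end comes first. Coordinates
are uniformly 0-based and half-open; bead `i` of a chromosome covers
`[(i-1)*bin_size, i*bin_size)` and a position maps to bead
`floor(pos / bin_size) + 1`. Structure coordinates are in bead-radius
units (one bead = one genomic bin). Parsers reject malformed input
with file and line rather than coercing.

## Multiway hub detection

A multiway hub is a small anchor region contacting several distal loci
within one cell. The caller slides a 40 kb window at a 20 kb step
(half the window, so any true 40 kb cluster overlaps some window by at
least half; the step is a package choice, the window width and the
50 kb long-range threshold are the conventional values). Both ends of
every intra-chromosomal contact with separation above 50 kb are
counted; a window needs at least `min_count = 4` such ends to become a
candidate — this floor only bounds compute, significance comes from
the permutation test. Overlapping candidates are resolved greedily,
keeping the larger count (leftmost on ties).

The null preserves everything about a cell's contact list except
anchor clustering: each long-range contact is relocated uniformly on
`[0, L - separation)` with its separation kept exactly, so per-cell
depth and the distance-decay profile are untouched. The identical scan
runs on each of `n_perm = 400` permuted maps, pseudo-anchor counts are
pooled per chromosome, and each observed candidate gets
`p = (1 + #\{null >= observed\}) / (1 + n_null)` — the add-one
estimator avoids zero p-values before FDR. Benjamini-Hochberg runs
across the candidates of one cell (the search is per cell, so the
multiplicity being controlled is per cell); hubs with `q < 0.05` are
retained. Short-range contacts are left in place by the permutation
and trans contacts are excluded from the statistic on both the
observed and the null side, so the two sides stay exactly comparable.
Hub span is `"short"` when every intra-chromosomal contact site lies
within 1 Mb of the anchor centre and `"long"` otherwise (1 Mb itself
is long, matching the half-open convention everywhere else).

Two facts about the empirical p-values are worth knowing. First, they
are discrete: with sparse cells the attainable counts are few, so the
p distribution is uniform only on its support; the calibration check
in the acceptance suite therefore uses cells dense enough (about 2,500
contacts on a 10 Mb chromosome, matching the per-window end density of
a ~10^5-contact genome-wide cell) for the support to be fine. Second,
spatially sampled background is *not* null — contacts drawn from a 3D
conformation cluster around genuinely proximal bead pairs, and the
caller reports those windows as hubs because they are ones.

## Restraint-based structure calculation

Contacts become distance restraints: one flat-bottom harmonic per
distinct contacted bead pair (duplicates collapse; a contact between
sequence-adjacent beads folds into the backbone restraint), with
bounds 0.8-1.2 bead diameters (1.6/2.4 radii) around a 1-diameter
target, plus backbone restraints between adjacent beads. The
flat-bottom shape tolerates the ambiguity of a capture radius; the
restraint force is linear within half a radius of a bound and constant
beyond, so a handful of unsatisfiable restraints cannot dominate the
fold.

Annealing is hierarchical: restraints are coarse-grained onto a ladder
of 8x, 4x, 2x, 1x the target bin size (the ladder is forced to end at
1x), and at each rung the polymer runs overdamped Langevin dynamics
through a geometric temperature ladder (14 stages from T = 25, factor
0.6, 800 steps each, dt = 0.002 with a 0.4-radius step cap) followed
by a 3,000-step zero-temperature descent. Excluded volume is a soft
quadratic repulsion below 2 radii evaluated on a uniform spatial grid.
Between rungs, beads subdivide by linear interpolation along the chain
with 0.1-radius Gaussian jitter, and coordinates rescale by the cube
root of the subdivision factor (bead radius tracks the cube root of
its sequence content). Two numerical choices matter and were made for
stated reasons:

* *Force-evaluation margin.* Forces drive restrained pairs a small
  margin (0.08 radii) inside the flat bottom. Without it, the balance
  between restraint pull and excluded-volume pressure settles pairs
  exactly on the bound, and reporting then counts hairline excesses of
  order 10^-3 radii as violations.
* *Replica count.* `anneal()` defaults to 10 models — the ensemble
  size the downstream precision filter refers to — while the demo
  pipeline uses 3 replicas as its desk-scale setting.

Ensembles are aligned by least-squares superposition onto the first
model, testing both chiralities and keeping the better one: global
chirality is not determinable from distance data, which is a
documented limitation, not a bug. Per-bead RMSD is the deviation from
the across-model mean position. Violation reports give per-model
fractions outside the bounds (with a 10^-6 numerical slack) and
per-restraint worst-case distances.

Noise contacts are removed in two complementary ways. The
isolated-contact support filter drops contacts with no second contact
joining bins within 2 bins of both of its ends — genuine spatial
proximity drags chain neighbours along, uniform noise does not — and
is applied before annealing. The structural-consistency filter drops
contacts whose bead pair exceeds a distance cutoff in every model of a
preliminary ensemble, the "likely close in space" cleanup.

## Chromosome intermingling

A bead's proximal set contains every bead within 2 radii of it
(centre-centre) in *all* replica models, both beads having per-bead
RMSD below 1.5 radii; its intermingling score is the trans fraction of
that set (with uniform bins, summed genomic length reduces to bead
counting). Beads failing the precision filter, or with empty sets,
are `NA`. Per-cell score tracks are quantile-normalised to the mean of
the sorted per-cell distributions, the per-locus median across cells
is taken, and non-`NA` loci are cut into 5 or 10 equal-size ordered
groups. Feature enrichment compares the top 30% vs bottom 30% strata
(log2 fold change of feature density, capped with a flag when a
stratum is empty) or runs Fisher's exact test on the highest vs lowest
group. The trans density of a bead is the mean over models of the
summed reciprocal centre-centre distances to all beads of other
chromosomes; the track is scaled so the all-bead background median is
exactly 1.00, and coincident beads are excluded with a warning.

## Compartments and saddle analysis

Intra-chromosomal matrices are distance-normalised by dividing each
entry by its diagonal's mean (zeros stay zero), which is idempotent
and scale-free. The per-bin compartment score is the leading
eigenvector of the bin-bin Pearson correlation matrix of the
observed/expected matrix — the standard eigenvector method; the
likelihood-based population tool it stands in for is external — with
the sign oriented by a supplied track (planted A-density in synthetic
work), positive = A. Saddle analysis orders bins by score, cuts them
into equal groups, averages observed/expected between group pairs, and
summarises the outer 20% x 20% corner blocks (the corner box size is a
package choice); both the corner contact enrichments and the corner
mean scores are reported, since either may be the quantity of
interest. Scaling curves are log-binned contact probabilities
normalised to sum to one; separation fractions use the half-open
classes <10 kb, 10-100 kb, 100 kb-1 Mb, 1-5 Mb, >5 Mb and trans.
Bootstrap error bars are SDs over subsamples without replacement
(200 draws of 20% for saddle summaries, 2,000 of 30% for hub
abundance).

## Regulatory elements and contact enrichment

Element classes per time point (naive, 24h, 48h/primed): active
enhancer = H3K27ac with no H3K4me3 or H3K27me3 (H3K27ac peaks longer
than 1 kb trimmed to 1 kb about their centre); active promoter = TSS
with H3K4me3 and H3K27ac, no H3K27me3; bivalent promoter = TSS with
H3K4me3 and H3K27me3; emerging enhancer = H3K27ac absent at naive,
present at 48h with at least a 3x intensity increase; weakening = the
mirror. "Absent" means no called peak; the 3x ratio substitutes a
pseudo-intensity floor of 1% of the genome-wide median for the missing
peak so it is always defined. Replicate intensities are averaged.

Hub contacts are typed by the element classes whose midpoint lies
within 20 kb (inclusive) of the anchor centre or the contact site;
anchors additionally carry the gene group of any TSS strictly closer
than 5 kb — the inclusive/exclusive split follows the two conventions
as stated. Enrichment of each (anchor category, contact class) total
is tested against a null that re-pairs each anchor with another hub's
intact contact set drawn from the same A/B compartment (the anchor's
compartment is the majority label over its window, ties to A), so
per-compartment hub counts and each set's composition are preserved
exactly and only the anchor-contact association is broken. Two
one-sided add-one empirical p-values are computed and BH applied to
the two-sided `min(2p, 1)` across category pairs; log2 fold changes
against the null mean are capped at ±10 with a flag when a zero is
involved. The inter-chromosomal variant first keeps only trans
contacts whose beads come within 3.5 radii in the cell's structure
(minimum over models), pools filtered contacts across cells, and
shuffles promoter and enhancer identities within compartments.
Per-hub chromatin-state profiles (mean mark intensity over contact
sites) are clustered with Ward linkage, and the anchor-profile matrix
keeps the contact-matrix row order so the two heatmaps stay aligned
hub-for-hub.

## H3K27me3 promoter trajectories

Per gene and replicate, the changes (24h − naive) and (primed − 24h)
are divided by the gene's maximum intensity across time points, making
features scale-free; replicates contribute separate dimensions rather
than being averaged. Ward (ward.D2) clustering on Euclidean distances
is cut by descending the dendrogram and splitting a branch only while
both children keep at least 100 members — a conservative analogue of a
dynamic hybrid cut at its shallowest setting which, by construction,
never produces an undersized cluster (so the reassign-or-drop question
for undersized branches does not arise). Ties break by input order,
making the labels deterministic. Bivalency trajectories classify each
promoter's (naive, 24h, primed) H3K4me3/H3K27me3 pattern into
always-bivalent, formed-at-24h-and-maintained, bivalent-only-naive,
bivalent-only-primed, never-bivalent, or other transition.

## Poisson-beta bursting kinetics

The two-state promoter model in Poisson-beta form: each cell draws an
active-state occupancy `p ~ Beta(k_on, k_off)` and a count
`~ Poisson(s * p)`; `k_on/(k_on + k_off)` is the mean active fraction.
The sampler is random-walk Metropolis on the logs of the three rates
against the *marginal* likelihood, evaluated by quantile quadrature:
the Beta mixing density is represented by its 200 midpoint quantiles,
so each count's marginal probability is a plain average of Poisson
densities (computed in C++). A data-augmented Gibbs sampler with
per-cell latent occupancies was implemented first and abandoned: its
posterior intervals were a fraction of the width of a brute-force grid
posterior on the same data even at several times the default chain
length, because the latent block moves the rates only in tiny steps.
The marginal sampler matches the grid oracle.

Moves per iteration: a joint random walk on `(log k_on, log k_off)`, a
scale move multiplying both rates (active fraction fixed), a ridge
move multiplying `k_off` and `s` together (in the bursty regime the
likelihood is nearly flat along that direction — burst size `s/k_off`
and frequency fixed — and axis-aligned moves alone mix poorly there),
and a walk on `log s`. Defaults: 500 burn-in plus 2,000 kept
iterations thinned by 3. Priors are truncated log-normals — rates
centred at 1 with sdlog 2.5 on [10^-3, 10^3], `s` centred at the data
scale `log(max(2*mean, max count))` with sdlog 1.5 on [10^-2, 10^6].
The truncation keeps the chain off the unidentifiable
negative-binomial ridge (`k_off → ∞` with `s → ∞`), and the
data-anchored `s` centre is an empirical-Bayes choice that matters
only through weak shrinkage. Genes with all-zero counts are excluded
before fitting; fits with posterior-median `k_off > 10` are removed as
unreliable (parameter estimation is poor there), and a split-half
stability ratio on `log s` is reported per fit. In the constitutive
limit (pure Poisson data) the total rate `k_on + k_off` is
unidentified, so the posterior of the active fraction retains some
prior mass below 1; the median still sits far above any bursty regime.
Condition comparisons report per-gene log2 ratios of the posterior
medians with two-sided paired Wilcoxon tests.

## The synthetic-data generator

The generator defines the study conditions for every test; the
systems it emulates are experimental, so all generative choices are
stand-ins, made once:

* *Conformations.* Chromosomes grow as discrete random walks with
  2-radius bonds and excluded volume (best-of-60 candidate steps with a
  1.6-radius clearance target; residual overlaps are rare and shallow),
  confined in a nucleus sized for ~25% bead volume fraction.
  Territories are denser sub-spheres (~45% volume fraction) with
  centres on a shell; the `intermingle_level` dial inflates each
  sub-sphere toward the shared central sphere and pulls the centres
  together, so level 0 gives separated territories and level 1 one
  co-occupied volume. The densities are melt-like so that beads have
  realistic numbers of spatial neighbours — sparser packings leave too
  few proximal pairs to support restraint-based recovery at all.
* *Contacts.* Background contacts sample uniformly over bead pairs
  within the capture radius (default 2 radii, mirroring the proximity
  threshold; no distance weighting, for analyzability), with bp
  offsets uniform within beads; a noise fraction samples arbitrary
  pairs. Planted hubs add `k` contacts from a 40 kb anchor to sites at
  chosen separations (log-uniform 100 kb-3 Mb when unspecified).
  Optional compartment labels up-weight same-compartment pairs.
  The structure-recovery experiments sample at capture radius 2.4 —
  the restraint upper bound — so the truth satisfies its own restraint
  set by construction.
* *Population matrices.* Checkerboard compartments are planted
  directly: expected counts combine a power-law distance decay with a
  same-compartment enrichment factor, Poisson-sampled. Spatially
  sampled single-cell contacts cannot express a checkerboard that the
  conformation does not contain, which is why compartment scoring runs
  on this population input.
* *Tracks and counts.* Mark tracks place peaks so the element rules
  recover the planted classes, with log-normal intensities and
  multiplicative replicate noise (CV 0.2). Promoter trajectories follow
  four archetypes (gain-maintained, transient gain, progressive gain,
  loss). Expression counts come from the Poisson-beta model itself.

What the generator does not emulate — restriction-fragment bias,
ligation artefacts, diploid homologs, cell-cycle structure variation,
mappability — bounds what green tests mean: they demonstrate that the
statistics are calibrated and powerful under the stated model, not
that any particular biological dataset will behave identically.

## Problem sizes and defaults

The demo pipeline (`default_run_config()`) runs 3 chromosomes x 200
bins at 100 kb, 8 cells of ~3,000 contacts with 5% noise and two
planted 12-contact hubs each, 3 structure replicas per cell, 400 hub
permutations, 5,000 enrichment permutations, and 10 genes x 300 cells
of kinetics — a configuration chosen so a complete, deterministic run
stays in the minutes range on a single core while every stage has
enough signal to measure. Thresholds default to the reference values
collected in one place (40 kb/20 kb window and step, 50 kb separation,
2 and 1.5 radii proximity and precision, 3.5 radii trans support,
20 kb/5 kb flanks, FDR 0.05, minimum cluster size 100, `k_off` cutoff
10); every run writes its resolved configuration into the report.
Per-stage seeds derive from one master seed by a fixed affine hash, so
stages can be re-run in isolation and whole runs are byte-identical
per seed.

## Known limitations

* Global chirality of reconstructed structures is undetermined;
  alignment and truth comparisons are chirality-matched by design.
* Empirical p-values are discrete at low contact depth; treat their
  uniformity (and KS-based checks) accordingly.
* The compartment score is the standard correlation-eigenvector
  method, not a likelihood model; on weak checkerboards the sign
  orientation depends on the supplied track.
* Poisson-beta parameters beyond the active fraction are weakly
  identified in the constitutive and extreme-`k_off` regimes; that is
  exactly why the `k_off > 10` exclusion exists.
* The hub caller reports any anchor whose long-range contact count is
  inconsistent with the separation-preserving null — including
  spatial hotspots of a genuine 3D conformation that were not
  explicitly "planted"; on synthetic territorial genomes such calls
  are correct behaviour, not false positives.
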