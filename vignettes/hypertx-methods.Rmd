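---
title: "Models and methods behind hypertx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hypertx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypertx)
```

# The problem: measuring global transcription output

Standard RNA-seq normalisation assumes that samples contain the same total
amount of RNA, so any *global* change in transcription — hypertranscription,
where a cell synthesises uniformly more RNA per cell — is divided away and
rendered invisible. The experiments this package models break that
assumption deliberately: exogenous spike-ins added in fixed per-cell
amounts (purified RNA mixes for RNA-seq, a fixed number of foreign cells
for nascent run-on sequencing) anchor the normalisation to absolute
per-cell quantities. hypertx implements the downstream computational
stages of such a study as testable, desk-scale components, each paired
with a seeded synthetic-data generator that reproduces the statistical
structure the stage assumes.

# Spike-in anchored differential expression

## Model

Counts for gene $g$ in sample $j$ are modelled as negative binomial,

$$K_{gj} \sim \mathrm{NB}\!\left(\mu_{gj},\, \alpha_g\right), \qquad
\mu_{gj} = q_{g,c(j)}\, s_j, \qquad
\mathrm{Var}(K_{gj}) = \mu_{gj} + \alpha_g \mu_{gj}^2,$$

where $c(j)$ is the condition of sample $j$, $q_{g,c}$ is the
condition-specific expression level, and $s_j$ a per-sample size factor.

Size factors use the median-of-ratios estimator restricted to a reference
row set: each usable reference row is divided by its geometric mean across
samples and $s_j$ is the median of those ratios. Rows containing any zero
are excluded (the geometric mean would otherwise vanish), and factors are
re-centred to geometric mean 1 — a pure convention making factors
comparable across runs. With `reference = "spikein"` the factors equalise
spike-in abundance and preserve genuine global shifts of the endogenous
transcriptome; with `reference = "all"` they implement the conventional
equal-totals assumption. The `"all"` reference excludes the spike-in rows:
in a real library spike-ins are a negligible fraction of features, whereas
in a compact simulation (92 spike-ins among 2,000 genes) keeping constant
rows inside the reference would visibly bias the comparator that is meant
to represent "normalise on the transcriptome".

## Testing

Each gene is fitted by maximum likelihood: group means are profiled from
the score equation at fixed dispersion, and the dispersion maximises the
Cox–Reid adjusted profile likelihood, penalised by half the log
determinant of the information of the two estimated means. This is the
standard small-sample correction for plug-in group means; it remains a
*per-gene* estimate with no information sharing across genes — a
documented simplification relative to empirical-Bayes shrinkage used by
popular packages, chosen because the direction-bias phenomenon the
package demonstrates does not depend on shrinkage and because a per-gene
estimator is directly checkable against simulation truth. The dispersion
is floored at $10^{-8}$.

The Wald statistic is $\log_2\!\mathrm{FC} / \mathrm{SE}$ with the SE from
the Fisher information of the two group means at the fitted dispersion,
and a two-sided p-value from the standard normal reference. Genes with
all-zero counts get $\log_2\mathrm{FC} = 0$ and $p = p_{\mathrm{adj}} = 1$;
a failed fit flags the gene and removes it from testing. With a normal
reference the test is asymptotic: it is close to nominal at ten replicates
per group (the size used for the null-calibration checks, where the
realised type-I error at $p < 0.05$ is required to sit in $0.05 \pm 0.02$)
and remains anti-conservative at three replicates per group, which is why
a handful of false discoveries survive BH correction in the 3 + 3 designs
below.

Multiple testing uses the Benjamini–Hochberg step-up,
$p^{\mathrm{adj}}_{(i)} = \min_{j \ge i} \min\!\big(1, \tfrac{m}{j} p_{(j)}\big)$,
delegated to `stats::p.adjust` and verified in the test suite against an
independently coded brute-force step-up on random vectors.

Differential genes are classified with a strict fold-change bound and an
inclusive adjusted-p bound: *up* iff $\mathrm{FC} > f$ and
$p_{\mathrm{adj}} \le a$, *down* iff $\mathrm{FC} < 1/f$ with the same
$p_{\mathrm{adj}}$ rule. Two presets are provided: $(f, a) = (2, 0.01)$
and $(1.5, 0.05)$, matching the two cell systems the pipeline is designed
around.

## The direction-bias contrast

The methodological heart of the package is
`spikein_direction_contrast()`: simulate a design in which *every*
endogenous gene is amplified 1.5-fold (2,000 genes, 92 spike-ins, 3 + 3
replicates, dispersion 0.05), then analyse it twice. Spike-in anchoring
reads the amplification as a near-unanimous block of upregulated genes;
all-gene normalisation absorbs it, leaving only calibration false
positives with no consistent direction. Because those number only tens of
genes, their direction split in a single simulation is dominated by
binomial noise; the contrast therefore pools differential-gene counts
over three replicate simulations (independent seed streams derived from
one root seed) before forming the up-fraction, and reports 0.5 — balanced
— when no differential genes exist at all.

# Dominant-TSS refinement of nascent 3'-end signal

Nascent run-on sequencing records, at single-base resolution, the 3' end
of each nascent RNA; the package stores such signal as strand-separated
per-base count tracks (bedGraph semantics, 0-based coordinates). Tracks
from multiple samples are summed before activity calling.

For each annotated transcript, reads are counted in the strand-aware
proximal window from the TSS to 150 nt downstream; both endpoints are
included (an explicit convention applied identically in the brute-force
test oracle). A transcript with at most 9 proximal counts is inactive;
with 10 or more it is active. Each gene's active transcripts collapse to
one dominant TSS by a total tie-break cascade:

1. highest proximal count;
2. ties: the TSS furthest upstream, strand-aware (smallest coordinate on
   `+`, largest on `-`);
3. transcripts sharing that start: the longest annotated transcript;
4. still tied: the lowest numerical portion of the transcript identifier.

Because the cascade is total, the result is independent of the input
order of transcripts. Collapse operates within genes; distinct genes
whose dominant TSSs coincide are reported via a message and left
unresolved, since merging across genes would change gene-level counting.
Gene-body counts for differential expression then sum same-strand 3'-end
signal over the closed interval from the dominant TSS to the TES of the
dominant transcript; inactive genes are omitted.

The synthetic annotation generator places non-overlapping genes on both
strands and deterministically includes the situations that exercise the
cascade: two-TSS genes given exactly tied proximal counts, transcripts
sharing a start with different lengths (both strands), and genes within
5 kb of chromosome ends. The whole pipeline is validated against a
per-base enumeration oracle on a 200-gene annotation containing all of
these cases.

# Intergenic-background calibration of ChIP-seq coverage

When a protein's binding changes globally, normalising ChIP-seq libraries
to equal depth hides the change, exactly as equal-totals RNA
normalisation hides hypertranscription. The package calibrates instead on
non-specific background: every gene is padded by 5 kb upstream of the TSS
and 5 kb downstream of the TES, the padded spans are merged regardless of
strand, and the complement of the merged set defines intergenic regions
(the two sets partition each chromosome exactly — verified per-base in the
tests). Reads whose 5' end falls in an intergenic interval are counted
per sample, and sample $j$ is scaled by
$\mathrm{geomean}(C) / C_j$. The 5' end is used as the membership point
because it is single and unambiguous — midpoint or any-overlap rules
differ at interval boundaries; the geometric-mean reference is symmetric
in the samples. Both choices are conventions of this implementation.

Coverage is computed on fixed 20-bp bins after extending single-end reads
to 200 bp in their orientation (paired fragments are used as given); the
bin value is the number of overlapping fragments, and calibration is
elementwise multiplication by the sample's factor. On synthetic data with
a programmed two-fold binding difference at equal background, the
calibrated gene-body coverage ratio recovers the truth within ±10%, and
calibrated tracks are invariant to a doubled sequencing depth to within a
5% mean absolute relative deviation on intergenic bins. Those checks use
a 200-kb chromosome, six 1–4-kb genes, and a background of 4,000 reads
per kb — sized so that per-bin Poisson noise (the dominant term in the
depth-invariance deviation, roughly $1/\sqrt{\lambda}$ with
$\lambda \approx 900$ fragments per bin) sits well inside the bound while
the simulation still runs in seconds.

Expression classes for metagene stratification are assigned from mean
FPKM ($\mathrm{count} \times 10^9 / (\mathrm{length} \times
\mathrm{total})$): zero-FPKM genes are *silent*; for expressed genes the
5th and 95th quantiles (linear-interpolation definition, R type 7) split
*low* (strictly below q5), *high* (strictly above q95) and *medium*.
Metagene matrices follow scale-regions semantics: each gene body is
mean-pooled to a fixed number of columns, flanks are appended at native
bin width, and minus-strand genes are reversed so the TSS is always
leftmost; bodies shorter than the requested column count fall back to
linear interpolation and are reported.

# Worm-like-chain analysis of magnetic-tweezer force scans

A DNA tether of contour length $L_0$ under force $F$ follows the
Marko–Siggia interpolation,

$$F = \frac{k_B T}{L_p}\left(\frac{1}{4\,(1 - x/L_0)^2} - \frac14 +
\frac{x}{L_0}\right),$$

inverted numerically by bracketed root finding to $10^{-6}$ nm. The
simulated experiment holds each force for a 20-s dwell (10 Hz sampling,
2 nm Gaussian height noise — matching the ~2 nm spatial resolution of
such setups), scanning forces downward then upward. A protein-bound,
compacted state sequesters a fraction $c$ of the contour (effective
contour $(1-c)L_0$); it can form stochastically during low-force dwells
($\le$ 1 pN) of the decrease branch and persists into the increase branch
until the force exceeds an unbinding threshold (4 pN). Defaults
($L_0 = 2000$ nm, $L_p = 50$ nm, $k_BT = 4.114$ pN·nm, $c = 0.5$) are
round, realistic values for a several-kb tether at room temperature.

Dwells are summarised by mean and $n-1$ standard deviation. The
compaction ratio divides the protein-incubated tether's mean height
during the *force-increase* branch by the naked-DNA height at the same
force; force grids must match exactly — the scan protocol guarantees it,
and interpolation would invent smoothing the data does not contain.
Because fractional extension depends only on force, the ratio in the
bound state equals $(1-c)$ up to noise, giving a closed-form check.
Hysteresis subtracts the decrease-branch extension from the
increase-branch extension at each force; a persistent compacted state
appears as a large negative hysteresis at intermediate forces. Adding a
constant offset to both scans leaves hysteresis unchanged but not the
ratio — both directions are asserted in the tests.

Group comparisons use the Mann–Whitney U test: exact by enumeration of
all group assignments whenever $\min(n_a, n_b) \le 8$ and
$n_a + n_b \le 20$ (ties handled naturally by permuting the pooled
values), otherwise a normal approximation with tie correction and
continuity correction. The two-tailed p doubles the smaller one-tailed
tail, capped at 1. Contingency comparisons use the Pearson chi-squared
statistic with the upper-tail chi-squared p-value; `chi_square_sf()`
exposes the survival function directly.

# Hydrogen-bond occupancy over trajectory frames

A donor–hydrogen–acceptor triple is hydrogen bonded in a frame when the
donor–acceptor heavy-atom distance is at most 3.5 Å *and* the bond angle
is at least 135°, both comparisons inclusive. The angle criterion as
commonly phrased ("between the donor and acceptor heavy atoms") is
geometrically incomplete; hypertx implements the conventional D–H···A
angle measured at the hydrogen, with a switch (`angle_at = "donor"`) for
a donor-centred variant. Occupancy is the percentage of analysed frames
in which the bond is present, the analysis window being the trailing
fraction of frames (trajectory analyses typically restrict to the
equilibrated tail; the window is specified in frames because the
time-per-frame mapping belongs to the trajectory, not the criteria).
Reported tables keep only bonds present in strictly more than 5% of
analysed frames. `unbinding_time()` gives the first frame index from
which a contact count stays zero, as a descriptive unbinding statistic.

The frame generator programs each pair's occupancy exactly: bonded frames
draw distances in [2.7, 3.3] Å and angles in [155, 180]°, and non-bonded
frames violate the distance criterion by at least 0.2 Å or the angle
criterion by at least 10°, so boundary behaviour is never left to
sampling accident. Detection is checked to be invariant under rigid
rotation and translation, and occupancy is verified against brute-force
per-frame arithmetic. Frames round-trip through multi-model PDB (3
decimal places; the programmed geometric margins are far larger than that
precision).

# Randomness, determinism and problem sizes

All generators draw from streams derived from a single root seed by a
deterministic hash of the generator name (and an optional index), so
adding a generator to a workflow never perturbs the data produced by
existing ones, and identical configurations yield identical output bytes.

The test-suite and acceptance problem sizes — 2,000-gene count matrices,
a 200-gene annotation for the TSS pipeline, a 200-kb chromosome for ChIP
calibration, 2,000 trajectory frames, three pooled replicates for the
direction contrast — were chosen as the smallest sizes at which each
check's sampling noise is comfortably inside its tolerance, and they run
in seconds to tens of seconds each.

# What the generators do and do not emulate

The synthetic data reproduce the statistical structure each stage
assumes: NB counts with constant spike-ins and a global amplification
factor; gene-anchored 3'-end signal with a promoter-proximal component
(the proximal peak is a modelling choice of this package — its precise
shape is not taken from any experimental claim); expression-proportional
gene-body ChIP enrichment over a uniform intergenic background; WLC
mechanics with binding-induced compaction and scan-direction hysteresis;
and geometric frames with programmed bond occupancies. They do not
emulate read-level artefacts (sequencing errors, UMI duplication, GC or
mappability bias), non-uniform background, correlated dispersion between
genes, bead-tracking drift, or true polymer dynamics. Passing tests
therefore demonstrate correctness of the implemented computations under
their stated assumptions, not robustness to every artefact of real data.

# Known limitations

* The Wald test with per-gene dispersion is anti-conservative for designs
  with two or three replicates per group; interpret small-n results
  accordingly (the package reports, it does not shrink).
* Cross-gene dominant-TSS collisions are reported but not resolved.
* Intergenic read counting uses read 5' ends, not extended fragments;
  the choice is documented and consistently applied, but other tools may
  differ at region boundaries.
* The compaction model is a two-state effective-contour description; it
  does not model gradual protein loading or force-dependent binding
  kinetics.
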