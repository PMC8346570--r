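---
title: "Methods: multi-lesion evolution analysis of gallbladder carcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-lesion evolution analysis of gallbladder carcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The setting

Gallbladder carcinoma (GBC) frequently co-occurs with its putative
precursor lesions: adenoma with low-grade dysplasia (LG-BilIN) and
high-grade dysplasia / carcinoma in situ (HG-BilIN).  When all three
lesions are resected together with matched normal mucosa, the somatic
alterations of the four samples let one reconstruct, per patient, how the
carcinoma arose: either along the classical adenoma–carcinoma sequence
(the carcinoma lineage splits *after* the common ancestor of the two
BilIN lesions — *BilIN-dependent*), or as an early-diverging lineage that
splits *before* that ancestor (*BilIN-independent*).

`bilinevo` implements the full analysis chain from filtered somatic
calls and allele-specific copy-number segments to per-patient
phylogenies, path classification, ancestral loss-of-heterozygosity (LOH)
reconstruction, clone clustering and seeding inference, together with a
seeded synthetic-data generator that stands in for the controlled-access
patient data.

# Mutation processing

Calls are kept when the site has depth ≥ 10 in both tumor and normal,
at least two callers support the variant, and the site lies in the
targeted regions (`filter_calls()`).  The *rescue* rule then revisits
the patient's other tumor samples: a variant that passed anywhere is
accepted elsewhere with only a single supporting caller
(`rescue_across_samples()`).  Two choices here were genuinely open:

* whether rescue also waives the depth filter — we keep a symmetric
  depth ≥ 10 requirement in the rescued sample (exposed as
  `min_depth_rescue`), because a rescue at an uncovered site is
  indistinguishable from noise;
* whether rescue needs alternate reads beyond caller support — we
  default `rescue_min_alt = 0`, since a supporting caller implies
  alternate evidence upstream.

A variant passing filters in the *normal* sample aborts the patient
with a germline-contamination error rather than silently propagating.

Tumor mutation burden divides the missense/nonsense/ORF-shift count by
the targeted territory in Mb.  Driver tabulation restricts to a bundled
pan-cancer driver list and to protein-affecting classes.

# Mutational signatures

Per-sample SNV spectra are tallied over the 96 pyrimidine-centered
trinucleotide channels (purine-reference calls are strand-collapsed).
`decompose_signatures()` fits the normalized spectrum by non-negative
least squares against a 30-signature catalog, prunes signatures below
6% of the fitted exposure, re-fits until stable and renormalizes.  This
replaces the forward-selection heuristic of the classic refitting tool
with the same objective in a simpler form; the 6% cutoff is that tool's
documented default.  No trinucleotide-frequency renormalization is
applied: spectra and catalog live in the same exome count space, so an
extra normalization layer would only add a degree of freedom we cannot
validate here.

The bundled catalog is **synthetic** (see
`?load_signature_catalog`): the published reference probabilities are
not redistributable, so the package ships a deterministic stand-in with
the structural features the analysis relies on (a CpG C>T aging-like
Sig1, APOBEC-like Sig2/Sig13, a T>C clock-like Sig5, …).  Any catalog
file with the same layout — including the real v2 or v3 references —
can be passed instead; the catalog file is the single source of truth
for channel order.

# Phylogenies

With three tumor leaves the rooted topology space is tiny: three
resolved trees plus the star.  `infer_tree()` scores all of them
exhaustively.  The score of a topology is the sum over binary
presence/absence characters of the minimum number of 0↔1 changes on the
tree, computed by unit-cost dynamic programming with the root fixed at
the matched normal's all-absent state.  Back-mutation is allowed — we
deliberately do not impose an infinite-sites constraint, matching
standard maximum-parsimony semantics.  A tie between resolved
topologies returns the star with the per-topology scores as
diagnostics; real cohorts resolve such patients with additional
(off-target) mutations, which corresponds to adding rows to the matrix.

Bootstrap support resamples matrix rows with replacement (default
B = 1000; the appropriate B is not well constrained, and supports
stabilise well below this) and reports the fraction of replicates whose
best resolved topology reproduces the observed sister pair; score ties
within a replicate are broken uniformly at random under the run seed.

Branch assignment places each character on the branch subtending
exactly its presence set; characters whose pair pattern is off-tree are
homoplasic and excluded from branch lengths, so branch lengths plus the
homoplasy count always equal the number of rows.

As a robustness check, `infer_tree_nonloh()` rebuilds the tree from
mutations outside every tumor's LOH regions, guarding against allele
loss masquerading as phylogenetic signal.

# Path classification and consensus

`classify_topology()` maps `((LG,HG),GBC)` to BilIN-independent and a
GBC-containing sister pair to the corresponding BilIN-dependent
sublabel.  Corroborating layers are built from gene-level copy-number
profiles (sister pair = minimal Manhattan distance; Euclidean available
— the original layer-tree method is not specified, so a transparent
distance criterion is used) and from large-scale LOH binned at 10 Mb
(a bin is LOH when ≥ 50% covered; "large-scale" is not quantified
anywhere, and 10 Mb is the scale at which arm-level events dominate).
The consensus votes at the coarse independent-vs-dependent level only,
because the coarser layers cannot always resolve which BilIN lesion the
carcinoma pairs with; ties fall back to the mutation layer, which is
also where the dependent sublabel always comes from.

# LOH analysis

Segments follow the SEG dialect: 1-based inclusive coordinates, lengths
`end − start + 1`.  A segment is LOH when its minor copy number is 0 —
copy-neutral LOH, deletion LOH and homozygous deletion all qualify,
matching minor-allele semantics of allele-specific CN callers.  Genome
fractions default to the covered (segmented) length as denominator; the
published "LOH percentage" denominator is unstated, and the covered
length is the only denominator that is well-defined for partial
profiles (`denominator = "autosome_total"` switches to the bundled
GRCh37 autosome total).  Ancestral LOH is the base-pair three-way
intersection of the tumors' LOH intervals (GenomicRanges); chromosome-
level profiles report per-autosome LOH *fractions* rather than binary
chromosome status — the fraction carries strictly more information and
a binary view is recoverable by thresholding.  Cohort clustering is
average-linkage on Euclidean distances between the 22-vectors.

# Clonality and seeding

For each mutation, multiplicity and cancer cell fraction follow

$$m = \mathrm{clamp}\!\left(\mathrm{round}\!\left(\frac{\mathrm{VAF}\,(\rho c_t + 2(1-\rho))}{\rho}\right),\, 1,\, \max(1, c_t - c_m)\right),
\qquad
\mathrm{CCF} = \min\!\left(1,\ \frac{\mathrm{VAF}}{\rho m}\left(\rho c_t + 2(1-\rho)\right)\right)$$

with purity $\rho$ and local total/minor copy numbers $c_t, c_m$.
Sites with $c_t = 0$ are flagged and excluded from clustering.

Clone clustering is a seeded finite mixture with binomial read-count
emissions: cluster $k$ carries a per-sample CCF vector
$\phi_k$, a mutation's expected VAF in sample $s$ is
$\phi_{ks}\,\rho_s m / (\rho_s c_t + 2(1-\rho_s))$, and $K$ is chosen by
BIC over $1..K_{max}$ ($K_{max}=8$).  This is a deliberate,
documented methodological stand-in for Dirichlet-process Beta-binomial
clustering: the finite mixture with BIC is transparent, fast and
seed-deterministic, and the quantity the downstream analysis consumes —
the number of clusters with ≥ 10 member mutations (`n_clones`) — is
preserved exactly, including the ≥ 10 counting rule.  EM is initialised
three ways per $K$ (thresholded presence-pattern grouping, k-means on
naive CCFs, and random restarts); the pattern initialisation matters,
because multi-region clones differ mainly in *which* samples carry
them, and generic initialisations readily merge a small shared cluster
into a private one.  Per-cluster per-sample CCFs are updated by bounded
1-D likelihood maximisation; empty clusters decay via their mixing
weight and are dropped at reporting time.

Seeding classification grades every clustered mutation per sample from
its cluster mean CCF — absent below 0.05, clonal at ≥ 0.6, subclonal
between (both cutoffs exposed, since the cited construction fixes the
idea but not the numbers) — and computes, for a sample pair,
$\mathrm{JSI} = s/(p_A + p_B + s)$ over shared-subclonal and private
mutations, excluding mutations clonal in both.  JSI ≥ 0.3 calls
polyclonal seeding.  Which sample pairs to evaluate is not pinned down
by the source description; all three tumor pairs are computed and
reported.

# Group statistics

`group_compare()` implements the two tests the cohort figures use:
two-sided equal-variance Student's t (the captions say Student, not
Welch) and the two-sided Wilcoxon rank-sum test, exact for combined
n ≤ 20 without ties.  Raw p-values are reported without multiplicity
correction, as in the source figures.

# The synthetic generator

`simulate_patient()` emulates the statistical structure the analysis
assumes — it is the package's study-condition definition, not a tuning
knob:

* **Clone tree.** One rooted tree per patient with the mode-determined
  sister pair; trunk, internal-branch and per-tumor private mutation
  counts are Poisson with means 150/25/40 (independent mode) or
  36/100/70 (dependent modes).  Trunk means are the published group
  means; the internal/private split is not published per branch, so the
  defaults were chosen once to reproduce the published ~214 SNVs per
  sample and held fixed.
* **Depths and read support.** Per-sample depths are Poisson with means
  107× (normal), 171× (GBC), 188× (LG), 206× (HG); alternate reads are
  binomial at the expected VAF implied by purity, local copy number and
  multiplicity.  Mutations co-located with LOH are modelled on the
  retained allele (multiplicity = local total copy number) — a
  simplification that avoids tracking haplotypes.
* **Caller behaviour.** Detected mutations draw support 2–5; with
  probability 0.05 a sample sees support 1 (recoverable only through
  rescue) and with probability 0.01 support 0 (a false negative).
* **LOH.** Trunk LOH covers 13% (independent) or 2% (dependent) of the
  GRCh37 autosomes, with 7%/3% additional private LOH per tumor;
  segments (5–30 Mb) are placed uniformly without overlap within a
  lineage, half copy-neutral (2+0) and half deletions (1+0).  Each
  patient's fraction target gets unit-mean gamma jitter (CV 0.15) so
  cohort-level comparisons see biological-scale variance while the
  cohort mean stays at the preset.
* **Purity** is uniform on (0.4, 0.8) — typical for microdissected
  FFPE material — and is passed downstream as the "estimated" purity,
  since purity estimation itself is an input, not part of this
  pipeline.
* **Signatures.** Contexts are multinomial draws from the catalog
  mixture with weights Sig1 = 0.78, Sig5 = 0.12, Sig2 = 0.10, matching
  an aging-dominated (> 75% Sig1) spectrum.
* **Indels** are carried as a count only (mean 9); trees are built from
  SNVs.

What the generator does *not* emulate: sequencing error reads at
absent sites, subclonal mutations below clone resolution, germline
variation, mappability/FFPE artifacts, kataegis, or genuinely
homoplasic mutations.  Passing recovery tests therefore demonstrate
correctness of the inference machinery under the assumed generative
structure, not robustness to every artifact of real exomes.

# Verification scale and numerical choices

The test suite verifies parsimony against brute-force ancestral-state
enumeration (100 random matrices), interval intersections against a
per-base oracle on a 10 kb toy genome, NNLS refitting against exact
mixtures (within 0.02), the CCF closed form, the JSI formula, and
seeded determinism of every stochastic component.  Recovery checks run
50 simulated patients per mode at the default settings: mode
classification accuracy ≥ 90%, cohort-mean trunk counts and ancestral
LOH fractions within 10% of the generative parameters, and counted
clone number recovered in ≥ 85% of replicates; a paper-scale 6 + 5
cohort must separate the groups at p < 0.05 under the stated tests.
These problem sizes keep the default suite in the minutes range while
leaving the estimators enough data to converge.

Degenerate inputs are defined rather than accidental: empty matrices
give a star tree with a warning; an all-zero spectrum, a zero-variance
t-test and an empty JSI denominator are errors/NA with explicit
messages; segment profiles reject overlaps and minor > major states.

# Known limitations

* The clone model is a finite mixture, not a posterior over partitions;
  cluster-number uncertainty is summarised only through BIC.
* Parsimony trees are exhaustive only up to 6 tumor samples.
* The SCNA/LOH layer trees use simple distance/parsimony criteria; the
  original per-layer tree methods were not described and may differ.
* The bundled signature catalog is synthetic; analyses of real cohorts
  must supply a real catalog file.
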