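---
title: "Methods: dynamics, co-evolution, and the four-category classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamics, co-evolution, and the four-category classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdc)
```

# The problem

Positions that control a protein's function are not confined to its
active or binding site. Distal residues can modulate catalysis or
ligand affinity through the network of contacts that couples their
local fluctuations to the functional site — dynamic allostery. Such
positions leave two independent signatures: a *dynamic* one (they are
rigid communication hubs whose perturbation propagates to the
functional site) and an *evolutionary* one (their identity covaries
with functional-site composition across homologs). This package scores
both signatures per position and intersects them, producing a small,
ranked candidate list for mutagenesis, together with the
alignment-supported amino acid substitutions at each candidate.

# The dynamics arm

## Elastic-network kernel

The protein is coarse-grained to its C&alpha; trace and modeled as an
anisotropic elastic network: residues $i,j$ with
$d_{ij} \le r_c$ are joined by a Hookean spring. The off-diagonal
$3\times3$ superblock of the Hessian $\mathbf{H}$ for a contacting
pair is

$$
\mathbf{H}_{ij} \;=\; -\frac{\gamma}{d_{ij}^2}\,
(\mathbf{r}_j-\mathbf{r}_i)(\mathbf{r}_j-\mathbf{r}_i)^{\mathsf T},
$$

i.e. a uniform spring constant $\gamma$ acting along the unit
inter-residue vector; diagonal superblocks are the negated row sums,
which enforces translation invariance exactly. The default cutoff
$r_c = 13$ Å is the usual C&alpha;-network radius that captures
second-shell contacts; $\gamma$ only scales the spectrum and cancels
from every normalized profile.

The linear-response kernel is the Moore–Penrose pseudo-inverse
$\mathbf{H}^{-1}$, computed by eigendecomposition after discarding the
`null_modes` smallest-magnitude eigenvalues. For a generic
three-dimensional structure there are exactly six rigid-body null
modes, and six is the default. Two degenerate geometries matter in
practice and are handled explicitly rather than silently:

* **Planar structures** (all springs in one plane, as in the `ring`
  and `square` fixtures) have *no* out-of-plane restoring force, so
  all $N$ out-of-plane degrees of freedom are null in addition to the
  three in-plane rigid motions: $N+3$ null modes. Tests on planar
  fixtures pass `null_modes = N + 3`.
* **Two-point bridges**: if two sub-domains interact *only* through
  two anchor residues, rigid rotation of one sub-domain about the line
  through the anchors stretches no spring — an exact torsional null
  mode. The dumbbell generator therefore spaces the lobe faces 11.4 Å
  apart, inside the default cutoff, so weak direct lobe–lobe springs
  lift this mode.

If the retained spectrum still contains an eigenvalue below
$10^{-10}\lambda_{\max}$, inversion refuses with a count of
near-singular modes instead of returning a garbage kernel. A dense
$3N\times3N$ covariance matrix from molecular dynamics can be supplied
in place of the network pseudo-inverse (`load_covariance()`); every
profile downstream is agnostic to the kernel's origin.

## Perturbation response scanning, DFI and DCI

A unit force $\mathbf{F}$ applied at residue $j$ produces the
linear-response displacement $\Delta\mathbf{R} = \mathbf{H}^{-1}
\mathbf{F}$. Scanning all residues with a fixed set of force
directions and recording the norm of each residue's 3-vector response
gives the $N \times N$ response matrix with entries
$|\Delta\mathbf{R}_j|_i$ (response *of* $i$ *to* a perturbation at
$j$). Two per-residue indices summarize it:

$$
\mathrm{DFI}_i =
\frac{\sum_j |\Delta\mathbf{R}_j|_i}{\sum_i\sum_j |\Delta\mathbf{R}_j|_i},
\qquad
\mathrm{DCI}_i =
\frac{\sum_{j\in F} |\Delta\mathbf{R}_j|_i \,/\, |F|}
     {\sum_{j=1}^{N} |\Delta\mathbf{R}_j|_i \,/\, N},
$$

where $F$ is the functional-site set. DFI is each residue's share of
the total displacement response (it sums to 1); the low tail marks
hinges. DCI compares a residue's mean response to functional-site
perturbations against its mean response to perturbations anywhere;
values above 1 mean above-average coupling. Both are converted to
within-protein percentile ranks (`%DFI`, `%DCI`) using mid-rank ties,
so thresholds are scale-free and stable under duplicated values.

**Direction handling.** The default force set is deterministic: the
three Cartesian axes plus the four normalized diagonals, averaged as
the arithmetic mean of the response norms. This is the conventional
choice, but no finite fixed direction set makes the *mean of norms*
exactly isotropic — profiles of a perfectly symmetric structure come
out slightly unequal (about 6% spread on a regular hexagon). Where
exact rotation invariance matters, `scan_responses(..., average =
"rms")` with a tight-frame direction set (any set with $\sum_k
\mathbf{d}_k\mathbf{d}_k^{\mathsf T} \propto \mathbf{I}$, e.g. the
three axes) computes the root-mean-square response
$\sqrt{\mathrm{tr}(\mathbf{A}\mathbf{A}^{\mathsf T})/3}$, which equals
the infinite-direction RMS limit and is exactly invariant. The
symmetric-ring regression test runs in that mode; pipeline defaults
keep the conventional mean-of-norms.

# The co-evolution arm

Columns of a multiple sequence alignment are scored pairwise with
sequence-weighted mutual information plus average-product correction:

1. **Weights.** Sequence $s$ gets weight $1/n_s$, where $n_s$ counts
   sequences (including $s$) within 80% pairwise identity over
   columns where both are ungapped. $M_\mathrm{eff} = \sum_s w_s$ is
   the effective family size. Duplicating every sequence $k$ times
   leaves all downstream scores unchanged.
2. **MI.** For each column pair, joint frequencies are accumulated
   over sequences ungapped at *both* columns (pairwise-complete gap
   policy; gaps are never a 21st symbol, which avoids gap-driven
   spurious MI in sparse families), with a total pseudocount
   $\lambda = 0.5$ spread uniformly over the $20\times20$ table. MI is
   reported in bits. Pairs retaining less than `min_effective = 5`
   total weight are flagged invalid.
3. **APC.** $\mathrm{corrected}(a,b) = \mathrm{MI}(a,b) - \bar m_a
   \bar m_b / \bar m$, with $\bar m_a$ the mean MI of column $a$ over
   valid partners and $\bar m$ the overall mean — the standard
   background term absorbing shared phylogenetic and entropic signal.
4. **Rank normalization.** Corrected scores are percentile-ranked over
   valid pairs into $(0,1]$. The published co-evolution threshold
   (0.6) is defined on heterogeneous webserver score scales; rank
   normalization is the one convention that makes a fixed threshold
   well-defined for a self-contained scorer. It is not guaranteed to
   reproduce any particular external scale.

A position's coupling *to the binding site* is the maximum normalized
score between its column and any binding-site column (a single strong
co-evolutionary link suffices); a mean-over-site mode is available.
Externally computed $L\times L$ score matrices can be dropped in via
the dense-matrix reader.

# The classifier

Each non-binding-site position receives two bits:

* **dynamics bit** = 1 if `%DFI` $\le$ 0.2 *and* `%DCI` $\ge$ 0.7
  (rigid and strongly coupled); = 0 if `%DFI` $\ge$ 0.7 *and* `%DCI`
  $<$ 0.7 (flexible and weakly coupled); *undefined* otherwise;
* **co-evolution bit** = 1 if the position's binding-site coupling
  score $\ge$ 0.6.

All cuts are inclusive at the threshold. Category (1,1) — rigid,
dynamically coupled, co-evolved — is the high-impact candidate set;
(0,0) is the neutral control. Positions whose `%DFI` falls strictly
between the rigid and flexible cuts, or whose rigidity and coupling
disagree, are labeled `unclassified` rather than forced into a bin:
the category definitions only cover the extremes, and binning
intermediate positions would contaminate downstream category
statistics. A `mode = "nearest"` switch assigns those positions the
dynamics bit of the nearer extreme for users who want an exhaustive
partition.

Candidate substitutions at a position are read off the alignment:
sequences are first filtered to those whose binding-site columns match
the reference composition (exact match by default; a conservative-class
mode groups {ILVM}, {FYW}, {KR}, {DE}, {ST}, {NQ}), then every
non-wild-type amino acid with weighted frequency $\ge$ 0.05 at the
position's column is proposed, most frequent first. The frequency
floor keeps singleton alignment noise out of the proposal list.

# Fitness stratification

Per-mutation fitness (or docking-score) tables are joined to the
classification and summarized per category: counts, median, mean, IQR,
and the fractions above/below a user-supplied neutral band (default
$[-0.1, 0.1]$ on a relative-fitness scale; the band is
dataset-specific and deliberately not hard-coded). Records pool one
value per substitution; a per-position-mean option exists because
published distributions do not always state which convention they use.
Two categories are compared with a two-sided Mann–Whitney U test —
exact enumeration for tie-free samples of at most 20 per group,
tie-corrected normal approximation otherwise — chosen because fitness
distributions are non-normal and often heavy-tailed; the rank-biserial
correlation $2U/(n_1 n_2) - 1$ is reported as the effect size. The
signature expected of high-impact categories is *dispersion* (both
enhancing and deleterious tails) rather than a location shift, so
comparisons can run on absolute deviations from the neutral-band
midpoint (`on = "dispersion"`). Docking-score tables use the
lower-is-better direction.

# Hydrogen-bond pathways

Multi-model PDB ensembles (e.g. snapshots exported from a trajectory)
are scanned per model: a residue pair is bonded when any
template-donor heavy atom of one and template-acceptor of the other
(backbone N/O plus standard side-chain chemistry) lie within 3.5 Å;
when the file contains hydrogens, the donor–H···acceptor angle must
also reach 120°. Covalently adjacent backbone pairs are excluded. Edge
*occupancy* is the fraction of models containing the bond. Pathways
between two residues are all simple paths of at most 6 edges over
edges above an occupancy floor (default 0.1); each path reports both
its *bottleneck* (minimum edge occupancy) and its *support* (fraction
of models containing every edge simultaneously). Support never exceeds
the bottleneck; both are reported because "how often a pathway is
sampled" is ambiguous between the two readings, and the distinction is
informative — a path of individually frequent but anti-correlated
bonds has high bottleneck and low support.

# Synthetic study conditions

The generators in this package define the conditions under which the
method is validated:

* `make_structure()`: chains (3.8 Å C&alpha; spacing, 0.3 Å off-axis
  jitter), exact rings, unit squares, and dumbbells (two lobes on a
  3.8 Å grid bridged by a 2-residue linker) — geometries with known
  spectra, symmetries, or hinge locations.
* `make_msa()`: background columns draw the consensus with
  probability 0.7 (a typical protein-family conservation level),
  otherwise uniform; planted pairs draw one of two covarying symbol
  combinations with the stated strength. At strength 1 the pair's MI
  approaches exactly 1 bit.
* `make_fitness_table()`: per-category Gaussians; two-tailed
  categories flip the sign of the mean per record, widening the
  distribution without moving its center — the planted analogue of a
  function-altering site. Validation plants a two-tailed effect (mean
  0.5, sd 0.15) in (1,1) against a null (sd 0.05) in (0,0), 100
  records per category.
* `make_hbond_ensemble()`: minimal heavy-atom models in which each
  requested edge is bonded in exactly `round(occupancy * n_models)`
  seeded models.

Every generator is a pure function of its arguments including the
seed (via an isolated RNG scope), so fixtures are reproducible and
never serialized.

**What passing these conditions does and does not show.** The
synthetic structures have clean spectra and planted symmetries; real
proteins add missing residues, heterogeneous packing, and kernel noise
from finite sampling. The synthetic alignments are phylogenetically
unstructured — sequence weighting faces none of the clade correlation
that real families carry, so planted-pair recovery rates here are an
upper bound on real-data contact precision. The fitness generator
plants exactly the dispersion signature the stratification is designed
to detect. Green tests certify the machinery — formulas, rankings,
thresholds, invariances, determinism — not the biological effect
sizes, which depend on external data the package does not ship.

Problem sizes used throughout validation: structures of 4–60 residues,
alignments of 150–2000 sequences over 8–30 columns ($M_\mathrm{eff}
\ge 200$ for recovery runs, 20 seeds), 100 fitness records per
category (20 seeds), 10-model ensembles.

# Numerical choices and edge cases

* Percentile ranks use mid-rank ties: `(#smaller + 0.5·#equal-excl-self
  + 1)/N`; strictly increasing input maps to `(1/N, …, 1)`.
* Substitution proposals break frequency ties alphabetically; pathway
  sorting breaks support ties by length, then lexicographic path.
* Coincident C&alpha; atoms, ragged alignments, asymmetric covariance
  input (relative asymmetry above $10^{-6}$), non-finite fitness
  values, and duplicate mutation records are hard errors; residues
  lacking a C&alpha; and alignment-unmapped positions degrade softly
  with logged warnings (the latter score zero coupling).
* Translation invariance of the Hessian holds to floating-point
  round-off (coordinate differences of translated inputs re-round);
  it is asserted at $10^{-13}$, not bitwise.
* All randomness flows through explicit seeds; identical inputs and
  configuration give byte-identical output files, which the CLI
  verifies by emitting its fully resolved configuration with input
  checksums alongside every run.

# Limitations

* The elastic-network functional form (distance-weighted anisotropic
  springs, uniform $\gamma$) is one standard choice; no
  Gaussian-network mode, mass weighting, or B-factor calibration is
  provided.
* The co-evolution scorer is MI+APC only — no direct-coupling
  analysis, pseudolikelihood, or deep-learning contact prediction;
  external score matrices can be imported instead.
* The rank-normalized 0.6 co-evolution threshold is a convention, not
  a reproduction of any webserver's scale.
* Hydrogen-bond detection is geometric and template-based: no
  energetic scoring, water bridges, or trajectory-format readers
  (convert snapshots to multi-model PDB upstream).
* Binding-affinity prediction for proposed variants (docking, free
  energy) is out of scope; the package ends at ranked candidates and
  their distributional statistics.
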