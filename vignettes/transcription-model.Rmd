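---
title: "A stochastic model of RNA polymerase traffic on circular mitochondrial DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic model of RNA polymerase traffic on circular mitochondrial DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtpolsim)
```

## The model

Animal mitochondria transcribe a circular chromosome of 15–18 kb with a
single phage-type (T7/T3-like) RNA polymerase species. `mtpolsim`
simulates this traffic as a system of interacting stochastic and
deterministic processes in continuous modeled time:

* **Initiation.** Each promoter carries a Poisson intensity $\lambda$
  (binding attempts per second). An attempt succeeds only if no
  polymerase body and no bound protein factor overlaps the promoter
  footprint, even partially. The footprint is 17 nt (positions $-15$ to
  $+1$ around the initiation site in transcription direction), the
  assumed occupancy of the phage-type enzyme. A successful attempt
  places a polymerase that starts moving immediately.
* **Elongation.** Deterministic, at a constant rate $v$ (default
  500 nt/s; 200 nt/s is the usual control value). Heavy-strand
  polymerases move toward increasing coordinates, light-strand ones
  toward decreasing coordinates; the circle is traversed modulo its
  length, so a polymerase can complete several full circles.
* **Collision.** When two oncoming polymerases attempt the same
  nucleotide, both terminate at the meeting point. Co-directional
  polymerases move at equal speed and cannot collide.
* **Protein-dependent termination.** A factor site (mTERF in the study
  systems, a 28-bp region downstream of the 16S rRNA gene) binds by its
  own Poisson process when free of polymerases. A polymerase reaching a
  *bound* site passes with probability $p$ (heavy direction) or $q$
  (light direction); on a pass the protein–DNA complex dissociates, on a
  stop the polymerase terminates and the complex survives. The binding
  intensity subsumes spontaneous dissociation, which is not a separate
  event; an unbound site is transparent. The asymmetry of the stop
  fractions in the two directions is the *terminator polarization*.
* **G-quadruplex termination.** Optional sites that terminate a passing
  polymerase on the matching strand with a fixed Bernoulli probability.
  The default probability is 0 because the numeric ratio belongs to
  source material the package does not encode; the mechanism is exposed
  as a configurable hook.

A transcript is counted for a gene each time a polymerase traverses the
gene's full span on the gene's strand; each further full circle counts
again, and partial coverage counts zero. Counting is restricted to the
window `(run_up, t_end]`; the default horizon is 9 h of modeled time
(32,400 s) with no run-up. This operationalizes the "transcription
level" of a gene as full transcript equivalents per window, the quantity
the study systems report relative to a reference gene or time point.

Truncated transcripts at a collision still count the genes fully covered
before the collision point; whether such molecules are functional
in vivo is unknown, and this is a deliberate modeling assumption. Only
the 17-nt footprint excludes other polymerases — the growing RNA tail
does not occupy the template.

## Event-driven implementation and its reference oracle

The engine is event-driven: promoter and factor attempts are scheduled
from exponential gaps, each moving polymerase carries a precomputed
arrival time at its nearest obstacle (bound factor edge, quadruplex
site, or the horizon), and the earliest pending event — including the
earliest head-on meeting among converging pairs, `gap/(2v)` along the
converging arc — is processed next. State changes (a binding, a pass, a
termination) trigger rescheduling. Simultaneous events have probability
zero in continuous time; floating-point ties resolve deterministically
by creation order.

Because event-driven bookkeeping is where subtle bugs live, the package
also ships `run_trajectory_fixed_step()`: a deliberately naive reference
simulator (in C++) that walks the chromosome one nucleotide per tick of
`1/v` seconds and shares no code with the event engine. The test suite
requires the two engines to agree, per gene, within 3 standard errors
over 500-trajectory ensembles on a 3-kb two-strand toy genome with a
terminator and collisions. Further engine checks are analytic: exact
per-trajectory conservation (bindings = terminations + still-active),
Poisson counts for an unobstructed promoter, the renewal dead-time rate
$\lambda/(1+\lambda\cdot 17/v)$ for a saturated promoter, transparency
of a $p=q=1$ terminator, and binomial stop fractions $1-p$, $1-q$ at an
always-bound site.

## Reproducibility

All randomness derives from explicit seeds. An ensemble draws one seed
per trajectory index from its master seed before any simulation starts,
so results are independent of execution order, a checkpointed run that
resumes reproduces the uninterrupted result exactly, and the same master
seed gives bit-identical ensembles. The study-scale setting of 1,000
trajectories is cut to 100–600 in the tests and examples; these sizes
were chosen so that Monte-Carlo standard errors stay well inside every
tolerance asserted.

## Comparison statistics

Experiments on the study systems report relative RNA concentrations
$u$ with absolute errors, and RNA half-lives $t$. The package converts
these to transcription-level ratios: for stationary states,
$u_j t_0/t_j$ relative to a reference gene; for the two-condition
(hypothyroid vs euthyroid) design, $u_j (t_{0h} t_{je})/(t_{jh} t_{0e})$
with the 16S rRNA as normalizer. Model and experiment are scored with
the normalized L1 functional $\sum |x-y|/\max(x,y)$, optionally combined
across datasets with weights $1/(n_k s)$, $s = \sum 1/n_k$.

Absolute errors propagate through products and ratios as
$|r|\sqrt{\sum(\Delta x/x)^2}$ under independence and
$|r|\sum|\Delta x/x|$ otherwise (the dependent error always dominates).
Agreement is reported as the multiple $c = |a-b|/\Delta$ and as the
percentage deviation $(a-b)\cdot 100/b$, with deviations between −50%
and +100% conventionally flagged insignificant. In the measured
concentration ratio of the two-condition design, both the numerator and
the denominator carry their own printed errors and are treated as such
in the propagation; this choice reproduces the published ±0.17, ±0.34
and ±0.42 error entries.

Four arithmetic inconsistencies internal to the published tables are
documented rather than asserted: the ND3 deviation prints −4 where its
own cells give −8; the COX1 independent error prints 0.35 where
propagation gives 0.34; the printed L1n row value 1.736 evaluates to
1.720 from the printed cells, and the combined 2.098 evaluates to 2.059
from the printed per-specimen sums (both presumably computed from
unrounded internal values); and the ND2 and ND5 error multiples print
1.8 and 0.6 where the printed cells give 1.7 and 0.4. All other printed
comparison values reproduce exactly and are asserted in the tests.

The elongation-rate bound: in systems where transcription and
translation are concurrent, the polymerase must outrun the leading
ribosome across the first intron, so $v \ge 45\,\mathrm{nt/s}\cdot(E+I)/E$;
the largest reliable exon/intron ratios give lower bounds of 177 and
462 nt/s, bracketing the 500 nt/s default.

## The inverse problem ("active search")

`fit_transcription()` estimates promoter/factor binding intensities and
the passage probabilities from experimental levels by minimizing the
L1n functional of simulated against measured levels. Design choices:

* **Common random numbers.** Every candidate evaluation reuses the same
  per-trajectory seeds, making the objective a deterministic function of
  the parameters and removing Monte-Carlo jitter from accept/reject
  decisions. The response surface of this problem is rugged, which rules
  out gradient methods.
* **Log-grid steepest coordinate descent with multi-start.** All
  parameters are positive and span decades, so steps are multiplicative
  (default factors 3, 1.6, 1.25, giving a final resolution of ~±12%,
  inside the 25% recovery tolerance the package tests). At each move the
  better of both directions over all coordinates is taken; the step
  shrinks when nothing improves. Restarts start from the geometric
  center of the search box and from log-uniform random points.
* **The stop boundary.** Promoters of both strands are concentrated in
  one region, so the two polymerase flows compete along the rest of the
  circle; a compared gene with zero transcription on one strand signals
  that its strand is blocked by the opposing flow, and raising the
  opposing intensities further cannot improve the solution. Proposals
  that raise a strand's promoter intensity are therefore rejected
  outright once an opposing-strand gene falls silent. Intensities driven
  to the lower search bound are flagged as pinned. Two related rules:
  the L1n term of a gene silent in the *data* is exactly flat in the
  parameters, so a promoter whose every compared same-strand gene is
  silent is unidentifiable from levels and is pinned at the grid floor
  up front (and flagged); and objective ties are broken toward the
  smaller total intensity, preferring the minimal-flux solution.
* **Bounds.** Intensities default to [1e-4, 1] attempts/s, the
  magnitude range of the published solutions; probabilities to
  [1e-3, 1]. Desk-scale tests narrow the intensity box to [1e-3, 0.3]
  (published promoter intensities lie between 0.0004 and 0.11) to keep
  the search inside the regime the toy data occupy.
* **Units.** Binding intensities are attempts per second of modeled
  time, consistent with nt/s elongation rates and horizons in seconds.

Parameter recovery is verified on synthetic data: levels generated on
the two-strand toy genome at known ($\lambda_H$=0.02, $\lambda_L$=0.01,
$p$=0.3, $q$=0.05) are refit from scratch (200 trajectories per
evaluation, 3 restarts), recovering the intensities within 25% and $p$
within ±0.1. Multi-condition designs (conditions sharing $p$, $q$ and
the factor intensity) are fit per condition with the shared parameters
fixed between passes; the pooled-promoter convention of the rat system
(HSP = HSP1 + HSP2) is handled by fitting a single pooled promoter or
splitting at a fixed ratio.

## What the toy generator emulates — and what it does not

`make_toy_genome()` builds fully synthetic circular geometries (the
packaged 3-kb toy has convergent promoters, four genes and one
terminator). This reproduces the mechanisms — occupancy exclusion,
collisions, polarized termination, multi-circle transcription — at
sizes where exact oracles are computable. It does not reproduce the
full regulatory complement of real mitochondrial genomes: no
mTERF-independent termination values, no initiation-factor kinetics
(mtTFA/mtTFB), no sequence-dependent elongation, no replication, no
RNA secondary structure, and no antisense-duplex bookkeeping. Passing
tests therefore validate the simulator and the estimation machinery,
not the completeness of any particular genome annotation.

The same limitation applies to the packaged human geometry: it encodes
the standard gene annotation, the three promoters and the mTERF site
only. Forward simulation of the published healthy-human solution on it
reproduces the relative protein-gene levels (within 10%), the ~1.2-fold
MELAS rRNA drop and the ~1 light-strand circling polymerase, but not
the published 12S/COX2 ratio of 24, the 3.84-fold tRNA-Phe drop or the
23 ± 6 heavy-strand circling count — quantities that depend on
termination elements and weighting conditions defined in the original
study's supplementary material, which the package exposes only as hooks
(the quadruplex mechanism, user-supplied RNA weights). With mTERF as
the only terminator and near-saturated binding, the expected 12S/COX2
ratio is close to $1/p \approx 61$, which is what the simulation gives.
The corresponding acceptance checks are kept in the suite, failing, as
an explicit record of this gap. The published fitted parameter values
themselves were obtained by cluster-scale optimization and are treated
as forward-simulation inputs only.

Rat and frog fixtures carry promoters and genome lengths only; their
gene tables are not bundled and can be merged from GenBank/GFF3
annotation with `merge_geometry()`. The mTERF site interval outside
human is annotation-dependent and left editable.

## The polysome–ribonuclease model

An mRNA covered by translating ribosomes is protected from
endonucleolytic attack: a ribonuclease of linear size $h = Vw$ codons
needs a ribosome-free window of at least $h$ at its cleavage site.
With ribosome initiation a Poisson stream of intensity
$\lambda = \nu N/(1+\alpha N)$ (saturating at $\nu/\alpha$; the package
reads the saturation limit as this ratio), minimum headway $d = h_1/V$
seconds ($h_1$ = 10 codons, $V$ = 15 codons/s), and attack intensity
$\mu$ through an open window, the half-life and decay intensity are

$$\tau = \frac{\ln 2\,(1+d\lambda)e^{w\lambda}}{\mu k}, \qquad
\kappa = \frac{k\,\mu\, e^{-\lambda w}}{1+d\lambda},$$

with $k$ cleavage sites per molecule; $\tau\kappa = \ln 2$ exactly. The
window-time parameter $w$ is bounded below by $1/15$ s (one codon) and
plausibly above by $4/3$ s. `solve_nu()` inverts $\tau(\lambda)$ — a
strictly increasing function, so the root is unique — and recovers
$\nu$ from an observed half-life, enabling the ratio
$\tau/\tau' = \frac{1+d\lambda}{1+d\lambda'}e^{w(\lambda-\lambda')}$ to
be evaluated under a drop in ribosome numbers; a halving of $N$ at
unit loading lands in the experimentally expected 1.5–3 band. The test
oracle simulates the renewal process directly (headways $d +
\mathrm{Exp}(\lambda)$, exposure at rate $\mu$ through the open part of
each gap) and matches the closed form within 5%; the derivation's
stationarity assumption is the reason for the deliberately loose
tolerance: the closed form is the stationary-hazard limit, exact only
when cleavage is much slower than ribosome traffic (relative bias of
order $\mu/(\lambda+\mu)$ otherwise — at $\mu/\lambda \approx 0.15$ the
renewal process already deviates by >10%). The oracle therefore stays
in the slow-cleavage regime the model describes, with decay times long
against the ribosome cycle so its own start-condition bias is
negligible too. The number
and placement of real cleavage sites is unknown; $k$ is a free input.
No feedback loop from half-lives into the transcription fit is
implemented.

## Numerical choices and degenerate inputs

Coordinates are stored 0-based, half-open, and reduced modulo the
circle length, so origin-spanning features need no special cases;
external formats (GenBank, GFF3, the TSV dialect) use 1-based inclusive
coordinates with wrap encoded as start > end. A polymerase exactly at
an obstacle is treated as past it (an exact-hit distance of zero maps
to one full circle), which is also what makes re-encounters after a
pass-through work. Zero-intensity processes never fire; zero-length
geometries, non-positive horizons, probabilities outside [0, 1] and
negative intensities are rejected at construction. A factor site can
bind only when no polymerase overlaps it, and overlapping same-strand
promoter footprints are refused in the toy constructor but allowed in
real geometries (the frog LSP2A/LSP2B pair genuinely overlaps). In the
fit objective a gene silent in both model and data contributes zero; a
gene silent in exactly one contributes the maximal term 1.
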