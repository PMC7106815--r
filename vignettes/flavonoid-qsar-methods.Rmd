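---
title: "Methods: QSAR modelling of flavonoid activity on CaV channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QSAR modelling of flavonoid activity on CaV channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavoqsar)
```

## The problem

Flavonoids — polyphenolic plant compounds of the flavonol, flavone, flavanone
and isoflavone subclasses — modulate the L-type voltage-gated calcium (CaV)
channel of osteoblasts, a gateway of osteogenic signalling. A quantitative
structure–activity relationship (QSAR) maps numeric molecular descriptors
$X_1, \dots, X_p$ to the activity response

$$\mathrm{pIC_{50}} = \beta_0 + \beta_1 X_1 + \cdots + \beta_p X_p + \varepsilon,$$

where pIC50 is $-\log_{10}$ of the half-maximal (in)activating concentration
in µM. This package implements the full pipeline around two published linear
models for this system — Model A (channel activation, built on topological
descriptors) and Model B (channel inhibition, built on quantum-chemical and
steric descriptors) — together with the descriptor computations, the
principal-components regression (PCR) estimator, genetic-algorithm (GA)
descriptor selection, and the validation-metric suite those models were
assessed with. The published activity tables ship as checksummed plain-text
fixtures so every recomputable statistic is recomputed, not transcribed.

## Molecular graphs and descriptors

Structures are parsed (via ChemmineR/Open Babel) into hydrogen-suppressed
heavy-atom graphs: vertices carry an element symbol and a hybridization tag
(`sp3`, `sp2`, `sp`, `aromatic`), edges a bond order. Hydrogen suppression is
the convention of the Kier topological-index literature; an explicit-hydrogen
graph can always be built by hand through `mol_graph()` for sensitivity
checks. Aromaticity is taken only from the input's own flags (bond order 4 in
MOL blocks, lowercase atoms in SMILES) — the package performs no aromaticity
perception of its own, so what you feed in is what the descriptors see.

### Kier second-order kappa-alpha shape index

With $A$ heavy atoms, $P$ paths of length two, and the alpha correction
$\alpha = \sum_i (r_i / r_{C_{sp^3}} - 1)$ from Kier's covalent-radius
ratios (embedded as a versioned table: C sp3 = 0, C sp2/aromatic = −0.13,
O sp3 = −0.04, O sp2/aromatic = −0.20, …),

$$^2\kappa_\alpha = \frac{(A + \alpha - 1)(A + \alpha - 2)^2}{(P + \alpha)^2}.$$

Two variants are exposed. `kier_standard` (the default) is the formula above;
`literal_printed` replaces the middle factor with $(A+\alpha-1)^2$, the form
the source tables were typeset with. The printed form is almost certainly a
typographical slip — on an $n$-carbon sp3 chain the standard form gives the
textbook value $n-1$, the literal form does not — but silently "fixing" a
published equation is worse than exposing both, so the audit variant stays
selectable. $P$ is the count of length-two paths, the standard reading of the
second-order index; it satisfies the closed form
$P = \sum_v \deg(v)(\deg(v)-1)/2$, which the tests exploit as an oracle.

### Information content on distance equality

Let $K = A(A-1)/2$ pairwise graph distances (strict upper triangle of the
distance matrix $D$) fall into $G$ equality classes of sizes $f_g$. Then

$$\mathrm{Id} = K \log_2 K - \sum_{g=1}^{G} f_g \log_2 f_g, \qquad
\mathrm{IdwAverage} = -\sum_{g=1}^{G} \frac{2 f_g}{A(A-1)}
  \log_2 \frac{2 f_g}{A(A-1)},$$

in bits. The identity $\mathrm{Id} = K \cdot \mathrm{IdwAverage}$ is an exact
algebraic consequence of the two definitions and is enforced as a property
test on hundreds of random graphs. Both the integer bond-count distance
matrix and the reciprocal-square weighting ($1/d^2$ off the diagonal) are
first-class; note that because $d \mapsto 1/d^2$ is strictly monotone, the
equality classes — and therefore Id and IdwAverage — coincide between the two
modes. They differ only when distances are continuous (e.g. geometric), which
is where the equality *tolerance* matters: grouping is deterministic
(sort, then split where the gap exceeds the tolerance), exact for integer
distances and 1e-9 relative for weighted ones.

### Moment of inertia; supplied descriptors

`MomInertiaY` is $\sum_i m_i (x_i^2 + z_i^2)$ after translation to the center
of mass, in amu·Å². Coordinates are taken as-is from the input record (no
re-embedding); 2D records yield planar values flagged `derived_2d`. The
quantum-chemical descriptors `Most+vePotential` and `DeltaEpsilonC` are never
computed here — electronic-structure theory is out of scope — and enter only
as user-supplied table columns, with per-cell provenance (`computed` /
`supplied` / `missing`) recorded on every descriptor table so the two kinds
of value are never confounded.

## Principal-components regression

Descriptors are standardized (centered, unit variance) before decomposition —
the source data mixes scales across orders of magnitude (Id ≈ 800
vs IdwAverage ≈ 7.7), so unstandardized PCA would be dominated by a single
column. The SVD gives $X_{std} = T P^{\mathsf T}$ with orthonormal loadings
$P$ and orthogonal scores $T$; component signs are fixed by making the
largest-magnitude loading in each column positive. The response is regressed
on the first $p'$ scores plus an intercept, and the fit is back-transformed
to descriptor space, so every PCR model is also an ordinary linear equation
`predict()`-able on raw descriptor tables. With `p_prime = "auto"` the
package picks the $p'$ maximizing adjusted $r^2$, breaking ties toward fewer
components; at $p' = \mathrm{rank}(X)$ PCR reproduces ordinary least squares
exactly, which the tests verify against a normal-equations oracle at 1e-10.

## Genetic-algorithm descriptor selection

The published models were found by screening descriptor subsets with a GA
whose settings were never published, so the search here is this package's
own: a fixed-size population of descriptor bitmasks under tournament
selection (size 3), uniform crossover (rate 0.8), per-bit mutation (0.02) and
elitism (1), defaults of 50 individuals × 100 generations. Fitness is the
adjusted $r^2$ or leave-one-out $q^2$ of the least-squares model on the
selected subset (identical to full-rank PCR on that subset; LOO uses the
exact hat-matrix identity rather than refits). All-zero masks are repaired by
activating one random bit. Seeds are explicit arguments everywhere and the
random state is restored on exit — nothing in the package touches global RNG
state.

One property of these fitness functions matters for interpreting "recovery"
experiments: a pure-noise descriptor *increases* adjusted $r^2$ whenever its
partial $F$ exceeds 1, which for Gaussian noise happens about a third of the
time. The best-fitness subset is therefore expected to be a slight superset
of the truly active descriptors, and recovery of a planted model is judged by
whether every active descriptor is selected — the GA's job is to not miss
signal; pruning marginal extras is the analyst's. The test suite plants a
3-of-8 active model ($n = 40$, $\sigma = 0.05$, inter-descriptor correlation
0.3) and requires the active trio to be identified in at least 90% of 50
replicates; it also checks the GA's best fitness equals exhaustive search
over all 255 subsets on a reference dataset. These sweeps use a reduced GA
(24 × 30), ample for an 8-descriptor space at this signal-to-noise ratio.

## Validation metrics

All statistics are pure functions of observed/predicted vectors:

* $r^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$; adjusted
  $r_a^2 = ((N-1)r^2 - p)/(N-1-p)$;
  $F = [\sum(\hat y - \bar y_{obs})^2/p] \,/\, [\mathrm{RSS}/(N-p-1)]$.
* Standard error $s = \sqrt{\mathrm{RSS}/df}$ with **both** df conventions
  exposed: the default $N-p-1$ (the regression textbook convention and the
  printed formula) and $N-p$, because the published Model A value 0.0933
  reproduces only with $df = N - p = 17$. The reproduction path says which
  one it used.
* Leave-one-out: $\mathrm{PRESS} = \sum_i (y_i - \hat y_{(-i)})^2$,
  $\mathrm{SDEP} = \sqrt{\mathrm{PRESS}/n}$, and
  $q^2 = 1 - \mathrm{PRESS}/\sum(y - \bar y)^2$ with the mean over the full
  training set (not fold-local).
* Roy's $r_m^2$ family: after min-max scaling by the observed range,
  $r_m^2 = r^2(1 - \sqrt{r^2 - r_0^2})$ and the primed analogue, where
  $r_0^2$ / $r_0'^2$ are the determination coefficients of least-squares
  fits through the origin (predicted-on-observed and observed-on-predicted;
  the source leaves them undefined, so Roy's standard definition is used).
  Negative radicands — possible with anticorrelated predictions — are clamped
  to zero and flagged rather than erroring.
* External: $r^2_{pred} = 1 - \sum(y_{test} - \hat y_{test})^2 /
  \sum(y_{test} - \bar y_{train})^2$ and RMSEP; plus a k-subset scheme
  (6 subsets of 4 for the published 24-compound set) that trains on each
  complement, with the mandated-size path refusing uneven partitions.

Every metric is additionally pinned, at 1e-12, against independent one-line
transliterations of the defining formulas in the test helpers.

## The published fixtures and what recomputes

Loading a published dataset validates cardinalities (Model A: 20 train +
4 test; Model B: 20 + 3 — Naringenin has no inhibition record) and the
residual convention residual = predicted − observed, which holds for all 43
rows at the 3-decimal rounding tolerance 0.0005. The recomputable Model A
statistics come out as: training $r^2 = 0.3183$ (printed 0.3182), external
$r^2_{pred} = 0.9579$ (printed 0.9586), $s = 0.0933$ with $df = 17$ (printed
0.0933), RMSEP = 0.0178. The remaining printed summary values — Model A's
$F = 3.9664$ and $q^2 = 0.0693$, and all four Model B summary statistics —
are *not* recoverable from the printed activity pairs (e.g. the Model B
training pairs give $r^2 = 0.116$, not 0.0845); they are stored with status
`printed_unreproduced` and reported as reference metadata, never asserted.
$q^2$ additionally requires refitting on the unpublished descriptor pool, so
it is unreproducible in principle, not merely numerically.

Applying the printed Model A equation to the printed descriptor triples does
not regenerate the printed predictions either (scutellarein: equation gives
0.660, table prints 0.534); `apply_printed_equation()` quantifies and flags
this divergence per compound instead of hiding it.

### An audit observation on the descriptor table

The printed training-set descriptor table is internally puzzling: its Id and
IdwAverage columns violate the exact identity
$\mathrm{Id} = K \cdot \mathrm{IdwAverage}$ for any plausible atom count.
Recomputing descriptors from structures clarifies part of this. The Id of the
packaged scutellarein structure (21 heavy atoms) computes to exactly 660.411
— which the printed table lists, to every printed decimal, under
*Tamarixetin* (a 23-heavy-atom molecule that could not produce it):

```{r scutellarein-audit}
g <- read_structure(system.file("extdata", "scutellarein_2d_synthetic.mol",
                                package = "flavoqsar"))
total_info_distance(topological_distance_matrix(g))
kappa2_alpha(g)
paper_descriptors()[paper_descriptors()$flavonoid == "Tamarixetin",
                    c("flavonoid", "k2alpha", "Id")]
```

The same pattern — printed Id values exactly matching this package's
topological-distance Id for *some other* compound in the study set — recurs
across the table when the remaining structures are parsed from their SMILES.
The printed Id column is thus fully consistent with the conventions
implemented here (hydrogen-suppressed graph, integer bond-count distances,
exact equality classes); the compound *labels* appear permuted relative to
the structures the values imply, and the IdwAverage column (values near
$\log_2 K$) evidently derives from a different, continuous distance matrix.
Because the original label assignment is unrecoverable, the printed table
stays fixture data: no test maps printed rows to structures beyond the single
frozen scutellarein regression check above.

### Ranking

Compounds are ranked by descending predicted activity with alphabetical
tie-breaks. On the printed Model A training predictions the top compound is
Myricetin (0.630); the published ranking narrative (scutellarein first) does
not follow from any printed column and is not reproduced.

## The synthetic-data generator

The generator emulates the statistical structure the published study assumes,
with defaults fixed at the study conditions: 24 compounds split 20/4,
correlated Gaussian descriptors (compound-symmetric correlation, default
$\rho = 0.3$ — a single interpretable collinearity knob, the condition that
motivates PCR over plain least squares), a planted linear response, and
Gaussian noise (default $\sigma = 0.05$, small relative to the ~0.4-wide
pIC50 range of the real data). Random molecule-like graphs are spanning trees
plus optional ring closures, degree-capped at 4, over {C, O} — chemically
plausible but not valence-exact, since the descriptor machinery needs
labelled graphs, not chemistry. What passing synthetic tests show is that the
estimators recover known ground truth under the assumed model; they do not
show that real flavonoid activity is linear in these descriptors, that
descriptor errors are Gaussian, or anything about activity cliffs and
scaffold effects real sets exhibit.

## Numerical choices and problem sizes

Tolerances: PCR-vs-OLS equivalence 1e-10; metric transliterations 1e-12;
information-identity checks 1e-12 relative; distance-class grouping exact
(integer) / 1e-9 relative (continuous). Degenerate inputs error early and by
name: zero-variance columns under standardization, $P + \alpha \le 0$ kappa
denominators, single-atom reciprocal distances, constant observed vectors,
empty split halves. The test and acceptance sweeps use desk-scale sizes
chosen once — 200 random graphs for the information identity, 20 random
datasets each for the PCR and LOO oracles, 50 GA replicates at 24 × 30 — all
comfortably discriminating at these noise levels.

## Known limitations

* The published Model A/B coefficients cannot be re-derived: the candidate
  descriptor pool ("thousands" of descriptors) and GA configuration were
  never published. The coefficients are carried at printed precision only.
* Quantum-chemical descriptors are accepted, never computed.
* SMILES input depends on Open Babel (ChemmineOB); kekulization on MOL export
  means aromatic tags for SMILES come from the input text's own lowercase
  flags.
* How the observed pIC50 values were derived from the underlying patch-clamp
  measurements is not computable from any published formula; observed
  activity is taken as given.
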