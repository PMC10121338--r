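---
title: "Methods: individual-specific co-expression networks and discriminative pattern mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-specific co-expression networks and discriminative pattern mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wigamine)
```

# The problem

Case–control expression studies usually compare two populations through one
co-expression network per population, losing whatever is specific to single
individuals.  wigamine instead represents *every individual* by their own
weighted gene association network, built from that individual's expression
tuple alone, and then searches the two resulting network collections for
connected graph patterns whose presence-with-weight profile separates the
populations.  The output is a compact, ranked set of maximal discriminative
patterns plus summaries of the genes they intercept.

# Per-individual association: strength and relevance

For genes $i, j$ with pooled mean $\mu$ and standard deviation $\sigma$,
an individual's expression pair is standardized to $(z_i, z_j)$.  The
**strength** $\tilde\rho(z_i,z_j)$ is the correlation maximizing the
standard bivariate normal density at that single observation — a
one-observation maximum-likelihood estimate of the correlation.  Setting the
derivative of the log-density to zero gives the stationarity cubic

$$\rho^3 - z_i z_j\,\rho^2 + (z_i^2 + z_j^2 - 1)\,\rho - z_i z_j = 0,$$

whose real roots in $(-1,1)$ are compared by density.  On the diagonal the
density grows without bound toward the boundary, so $z_i = z_j \ne 0$ yields
$1$ and $z_i=-z_j\ne 0$ yields $-1$; the origin is a symmetric degenerate
point and returns $0$ by convention.  When one coordinate is exactly zero
and the other lies in $(-1,1)$ the density ties at $\pm\sqrt{1-z^2}$ and the
non-negative root is returned.  Strengths are evaluated canonically on the
positive quadrant with sorted margins, which makes the symmetry identities
$\tilde\rho(z_i,z_j)=\tilde\rho(z_j,z_i)=\tilde\rho(-z_i,-z_j)
=-\tilde\rho(z_i,-z_j)$ hold exactly in floating point.

The **relevance** of a pair is a per-edge significance under the null model
that the free coordinate is a standard normal draw while the observed margin
is held fixed:

$$r(z_i,z_j) = \min_{m \in \{i,j\}}
  P\!\left(\tilde\rho(z_m, Z) < \tilde\rho(z_i,z_j)\right),\qquad
  Z \sim \mathcal N(0,1).$$

The default `root_inversion` computation is closed-form: for a level
$r\in(0,1)$ the set $\{z : \tilde\rho(z_f,z)\ge r\}$ is an interval whose
endpoints solve the stationarity cubic read as a quadratic in the free
coordinate, $r z^2 - z_f(1+r^2) z + r(r^2+z_f^2-1)=0$, so the tail reduces
to differences of normal CDFs.  The interval structure (sign of the strength
matches the sign of $z_f z$, unimodality on each half-line) is validated
once per session on a dense grid against direct numerical integration; were
validation ever to fail, the function would fall back to Monte Carlo
(10{,}000 seeded draws by default, refused below 100).  Tests additionally
compare the closed form against an independent $10^5$-draw Monte-Carlo
oracle at three standard errors.

**Choice of moments.** Means and standard deviations are estimated on the
pooled population (both classes), so the two network collections live on one
common standardization and are comparable; per-class moments are available
via `by_class_stats = TRUE`.  Zero-variance genes cannot be standardized and
are excluded with a message.

# Networks, patterns, incidence

`build_networks()` scores every unordered candidate-gene pair in every
individual and keeps an edge when its relevance **strictly exceeds**
$\tau_r$ (default 0.9).  Edge weights $\eta(e)\in[0,1]$ are the normalized
strength; the default map is $\max(\tilde\rho,0)$, which is inert in
filtered networks because relevance above $0.5$ already forces a positive
strength ($P(\tilde\rho < r)\le 0.5$ whenever $r \le 0$).  The alternatives
$|\tilde\rho|$ and $(\tilde\rho+1)/2$ are selectable.  All-pairs
construction is quadratic in the gene count; `genes` and `top_variance`
pre-filters are the supported way to scale.

A **pattern** is a connected edge set over the shared node universe; it
*occurs* in a network iff all of its edges are present (node identities are
gene names, so each network admits at most one match).  The value of a match
is the mean weight of the pattern's edges there; the **incidence** is the
sum of match values over occurring networks, hence bounded by the support.
The **incidence at $x\%$** keeps the $n_x=\lceil x/100\cdot|N|\rceil$
largest match values and is *null* (reported as 0 with a flag) when the
support is below $n_x$.  Ceiling rounding guarantees $n_x \ge 1$; when the
two populations are profiled separately, $n_x$ is taken of each population
size separately.  Ties among equal match values are broken by sample
identifier; this fixes the reported match set without affecting the sum.

# Discriminative power

With class sizes $n_1, n_2$ and per-class incidences at $x\%$
$(\hat s_1, \hat s_2)$, the population entropy is
$H(N)=-\sum_p \frac{n_p}{n}\log\frac{n_p}{n}$ and the entropy given a
pattern is

$$H(N\mid P) = H(N_P)\,q + H(N_{\bar P})(1-q), \quad
q=\frac{\hat s_1+\hat s_2}{n},\;
q_1=\frac{\hat s_1}{\hat s_1+\hat s_2},\;
q_2=\frac{n_1-\hat s_1}{(n_1-\hat s_1)+(n_2-\hat s_2)},$$

with $0\log 0=0$ and the $H(N_P)$ term zero when $\hat s_1+\hat s_2=0$.
The **discriminative power** is the gain $\mathrm{pow}(P)=H(N)-H(N\mid P)$.
The definition is asymmetric — class 1 is the *guiding* population — and the
reverse analysis is obtained by swapping the classes (`direction`).
Logarithms default to base 2; rankings are base-invariant, so the choice is
cosmetic.  A pattern is **discriminative** when its power strictly exceeds
that of every proper connected subpattern, with equality (tolerance
$10^{-12}$, a floating-point guard) resolved by a larger total incidence at
$x\%$; single edges are vacuously discriminative.  Subpatterns are
enumerated exhaustively up to 12 edges (`exhaustive_limit`), beyond which
only one-edge-removed subpatterns are checked, with a warning — at the sizes
the method is designed for (about ten genes per pattern) the exhaustive
scope is always active.

**Which patterns are recorded.** A pattern enters the result set only when
its incidence at $x\%$ in the guiding population is non-null.  This is the
"compact descriptor" reading: the result set describes what recurs in at
least $x\%$ of the guiding population, contrasted against the other one.
Without this rule, patterns entirely absent from the guiding population but
frequent in the other would acquire positive entropy gain and dominate the
reverse-direction ranking, which contradicts the role of the guiding
population in the extraction.  The rule also yields an exact search prune:
support is anti-monotone under extension, so a subtree whose guiding support
falls below $n_x$ can never be recorded and is abandoned.

# The search

Seeds are all single edges occurring in at least one guiding-population
network, in canonical order.  Each pattern is extended one edge at a time —
an extension either closes a path between two pattern nodes or attaches one
external node, must itself occur in at least one guiding network, and must
respect the node cap (`max_nodes`, default 10).  Extensions are processed in
decreasing raw incidence over all networks (configurable to incidence at
$x\%$ or guiding-only incidence), ties by canonical key, which makes the
search fully deterministic.  Each extension is scored, recorded if
discriminative, and *expanded* only when its upper bound reaches its
parent's power.  A global visited set guarantees no canonical key is
expanded twice; expansion is parent-independent (children are gated against
the expanded pattern's own power), so deduplication cannot lose results.

**Upper bound.** The bound must dominate the power of every superpattern.
Supports shrink under extension and match values lie in $[0,1]$, so any
superpattern's incidences at $x\%$ are confined to the box
$[0,c_1]\times[0,c_2]$ with $c_p=n_{x_p}$ when the pattern's support in
population $p$ reaches $n_{x_p}$ and $c_p=0$ otherwise.  The bound is
$H(N)$ minus the minimum of the conditional entropy over that box, found on
a $101\times101$ grid refined by L-BFGS-B from the best grid point.  Since
$c_p$ takes only two values per population, the four possible minima are
precomputed per run and the gate costs a table lookup.  Admissibility is not
assumed: it is verified in the tests by exhaustive superpattern enumeration,
and pruned mining is required to equal unpruned mining.

`cascade_prune` (off by default) additionally skips the *expansion* of all
extensions ranked after the first bound-gate failure.  The original
justification — the bound grows with the incidence that orders the list —
is not proven for this replacement bound, so the flag is opt-in and covered
by the oracle equivalence tests; later extensions are still evaluated and
recorded.

After the search, non-maximal patterns (those with a strict superpattern in
the result set) are removed and the survivors are ranked by power, then
total incidence at $x\%$, then canonical key; the top $k$ are returned.
Single-edge seeds may appear in the final ranking, subject to maximality.

**Reference miner.** `brute_force_mine()` enumerates every connected edge
subset of the guiding population's union edge set (bitmask enumeration,
refused above 16 edges), scores it through the public incidence/entropy
operations — a route disjoint from the miner's matrix index — and applies
the same predicate and ranking with no pruning.  The equivalence of the two
routes on 100+ random instances, with pruning on and off, is the package's
central correctness test.

# Synthetic data

`simulate_expression()` draws each sample from a multivariate normal whose
correlation matrix is block-structured: planted modules receive a
population-specific within-module correlation, everything else the
background correlation (default 0).  Per-gene means are uniform on
$[6, 10]$ and standard deviations on $[0.5, 2]$ — scales typical of
log-intensity expression data.  Positive definiteness is checked at build
time and violations name the module layout.  The master seed draws the gene
parameters and spawns one substream per population, so enlarging one
population leaves the other unchanged.

The standard benchmark scenario is 30 genes, one 4-gene module at
correlation 0.9 in population 1 versus 0.0 in population 2, and $40+40$
samples, mined at $\tau_r=0.9$, $x=20$, $k=20$.  Under these conditions a
planted pair passes the relevance filter in roughly a third of
population-1 samples, comfortably above the $n_x=8$ support threshold,
while an independent pair passes in under a tenth — which is why recovery
(`planted_recovery_score()`: the fraction of differential planted pairs
appearing in a top-$k$ pattern) is expected near 1 in the guiding direction
and near 0 in reverse.  What the generator does *not* emulate: count noise,
batch effects, heavy tails, correlated backgrounds, probe-level artifacts.
Passing the recovery tests therefore demonstrates the machinery end to end,
not robustness on real microarray or RNA-seq data.

# Numerical choices

* Cubic roots by vectorized Cardano/trigonometric formulas plus two Newton
  polish steps; boundary-grazing roots are clamped one machine epsilon
  inside $\pm 1$ rather than discarded, because near-diagonal pairs have
  their genuine maximizer there.  Degenerate inputs fall back to direct
  log-density maximization.
* Power comparisons use an absolute tolerance of $10^{-12}$; incidence
  bound assertions use $10^{-9}$.
* Serialized numbers: expression matrices at 17 significant digits (exact
  binary round-trip, parsed back with strtod); JSON at 12 significant
  digits.
* All containers are kept in canonical order (endpoint-sorted edges,
  lexicographic edge lists, manifest-sorted samples), so identical inputs
  give byte-identical outputs.

# Problem sizes used in the test-suite

Unit and acceptance tests run on synthetic instances: association oracles
on 300–1000 random pairs (grid step $10^{-4}$), tail oracles on 20–100
pairs against $2\times10^4$–$10^5$ Monte-Carlo draws, miner-oracle
equivalence on 100+ random instances of at most 8 nodes, 10 union edges and
10 networks at `max_nodes = 4`, and the recovery benchmark over 10 seeds of
the standard scenario.  These sizes make the exhaustive oracles exact while
keeping the whole suite a few minutes long.

# Known limitations

* Two populations only; the entropy machinery has no multi-class extension
  here.
* Exact subgraph matching on a fixed node universe — no isomorphism, no
  approximate matches.
* All-pairs network construction is $O(|V|^2)$ per sample; thousands of
  genes require the variance pre-filter or an explicit gene list.
* The upper bound is a verified replacement for an unavailable closed form;
  it is admissible on every tested instance but carries no general proof,
  which is why unpruned equivalence is part of the acceptance suite.
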