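---
title: "Distilling temporal contact networks: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distilling temporal contact networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdistill)
```

This vignette is the package's account of the science it implements: the
data model, the three static representations, the SIR dynamics and their
boundary conventions, the evaluation protocol, the synthetic generator,
and the places where the design was genuinely open and we had to choose.

## The data model

A contact sequence is a multiset of triples $(i, j, t)$: individuals $i$
and $j$ had a potentially contagious contact at discrete time $t$.
Contacts are undirected, self-contacts are rejected, and real-valued times
are rejected rather than rounded — the dynamics below are defined on a
discrete clock, and silently rounding would change tie structure, which
matters (see the SIR tie rule). On construction the sequence is shifted so
the first contact sits at $t = 0$; $T$ denotes the time of the last
contact. $N$, $L$ and $M$ are the numbers of vertices, contacts, and
distinct contacted pairs. Duplicate rows are retained: two contacts of the
same pair in one timestep are two transmission opportunities.

**Burstiness.** Pooling, over all pairs with at least two contacts, the
gaps between a pair's successive contacts gives one long interevent
series. We summarize its dispersion with the normalized form
$B = (\sigma - m)/(\sigma + m)$, bounded in $[-1, 1]$: $0$ for
exponential (Poissonian) gaps, $-1$ for periodic ones, $\to 1$ for
extreme burstiness. We made this the default rather than the raw
coefficient of variation $\sigma/m$ because the raw ratio is unbounded
above for the heavy-tailed series typical of human contact data, while
empirically reported burstiness indices for such data lie well inside
$[0, 1]$; the raw ratio remains available via `normalized = FALSE`. The
standard deviation uses the $n - 1$ denominator; for the pooled series
(thousands of gaps) the distinction is far below any decision threshold.

## The three representations

All three reduce a contact sequence to a *simple* undirected graph whose
vertices are the individuals with at least one qualifying contact.

* **Time slice** — edge iff a contact falls in the *closed* window
  $t_{start} \le t \le t_{stop}$. The full window $[0, T]$ is the
  accumulated network.
* **Ongoing** — edge iff the pair has a contact *strictly* before
  $t_{start}$ and another *strictly* after $t_{stop}$. The closed/strict
  asymmetry between the two window representations is deliberate and
  follows each definition's natural reading; we document it because the
  two differ.
* **Exponential threshold** — pair weight
  $w_{ij} = \sum_{(i,j,t)} e^{-t/\tau}$, edge iff $w_{ij} > \Omega$.
  The comparison is strict ("exceeds"). In the $\tau \to \infty$ limit
  every contact weighs 1 and $w_{ij}$ approaches the contact count, so
  thresholds at half-integers $\Omega = n - \tfrac12$ reproduce the
  aggregated-threshold network of pairs with $\ge n$ contacts without
  float-equality fragility. That is also how the package's own tests pin
  the limit.

Parameters of dimension time are fractions of $T$ at the scan and CLI
level (the natural unit for comparing data sets) and native timesteps at
the function level; conversion happens once on entry.

## SIR dynamics on the contact sequence

The ground truth for "who is an important spreader" is simulated directly
on the temporal data. The rules, including the boundary conventions that
any implementation must fix:

* All vertices start susceptible. The seed becomes infective **at the
  time of its own first contact, and that contact can transmit.** The
  alternative (activation just after the first contact) would make every
  vertex whose only contact is its first a guaranteed dead end and
  degenerate the importance landscape, so we adopted the transmitting
  convention.
* Contacts are processed in time order; contacts sharing a timestep are
  processed in a fresh uniformly random order each run. A vertex infected
  mid-timestep can transmit at contacts later in that sampled order —
  processing is strictly sequential.
* At a contact between an infective and a susceptible, transmission
  occurs with probability $\lambda$. A vertex infected at $t_0$ is
  infective on the half-open interval $[t_0, t_0 + \delta)$: a contact at
  exactly $t_0 + \delta$ does not transmit. Half-open avoids
  double-counting the boundary; any convention is defensible, one must
  just be stated.
* Removed vertices are never reinfected. The infective period is a fixed
  duration, not exponentially distributed — fixed durations are both more
  realistic for most diseases and more parsimonious in an event-driven
  simulation.

$\Sigma_i$ is the Monte-Carlo mean outbreak size over `n_runs`
independent runs seeded at $i$ (default 1,000; the reference protocol
uses 1,000–10,000). The simulation core is compiled (Rcpp) but draws from
R's RNG, so everything is reproducible from a single `set.seed()`.

**Calibration.** Epidemiologically interesting dynamics sit at
intermediate outbreak sizes, where important and unimportant spreaders
separate. `calibrate_lambda()` fixes $\delta = T/5$ and finds $\lambda$
such that the seed-averaged mean outbreak size is one fifth of its
$\lambda = 1$ value, by bisection on $[0, 1]$ (the mean size is
non-decreasing in $\lambda$). Each bisection evaluation uses a fixed run
count and a matched RNG stream, which suppresses most Monte-Carlo noise
in the comparisons; the tolerance is 0.01 on the achieved fraction. The
reference size is averaged over **all** seeds (the alternative — random
seeds per run — is statistically equivalent at the default run counts but
noisier). An unreachable target (the mean size cannot drop below 1, so
fractions below $1/\langle s\rangle_{\lambda=1}$ are infeasible) raises a
calibration error reporting the bracket.

## Evaluation protocol

`performance()` computes the Spearman rank correlation between
$\Sigma_i$ and a static predictor (degree or coreness) over **all
vertices of the original data**: vertices absent from a derived network
enter with predictor 0. The alternative — dropping them — would make
$\rho$ values across representations incomparable, since each
representation keeps a different vertex subset; every vertex of the data
has $\Sigma_i \ge 1$ and a defensible static score of 0 when the
representation discards it.

`scan_representation()` evaluates $\rho$ over a parameter grid: a
triangular $t_{start} \le t_{stop}$ grid (default $21 \times 21$
fractions of $T$) for the window representations, a log-spaced
$\tau/T \in [10^{-2}, 10]$ by $\Omega \in [10^{-2}, 10]$ grid (16 points
per axis) for the exponential-threshold family. Degenerate grid points —
an edgeless network, or a constant predictor — are recorded as missing
and excluded from the argmax, never silently dropped. Standard errors on
$\rho$ come from a nonparametric bootstrap over the per-seed run-level
outbreak sizes (default 200 resamples, requiring
`importance_table(..., keep_runs = TRUE)`); we chose run-level
resampling because the Monte-Carlo error in $\Sigma_i$ is the dominant
stochastic ingredient of $\rho$ at fixed data.

Two structural guarantees are worth knowing: any time-slice grid that
contains the full window scores at least as high as the accumulated
network (it *is* a grid point), and widening a window can only grow the
time-slice edge set and shrink the ongoing one.

## Network diagnostics and the null model

`network_summary()` reports $N$, $M$, the largest-component fraction $S$
(denominator: the constructed network's own vertex set), and the mean
shortest-path distance $d$ within the largest component (unordered
pairs). Reference values $S_0, d_0$ come from a degree-preserving
rewiring null model: sequentially for each edge $(i, j)$, draw a random
partner edge $(i', j')$ and with equal probability rewire to
$(i, j')(i', j)$ or $(i, i')(j, j')$, redrawing the partner if a self- or
multi-edge would result, with a bounded retry count ($10^4$) before
declaring the graph rigid. Identity swaps are legal, which is why rigid
graphs (complete graphs) cycle through equivalent wirings instead of
hanging. The default number of randomizations is $10^4$, matching the
reference analyses; desk-scale work should pass something far smaller.

## The synthetic generator

The generator emulates the gross features of empirical contact data —
broad degree distributions, bursty edge dynamics, and tunable concurrency
— while staying free of topology–time correlations:

1. **Degrees** from a truncated power law with exponent $\gamma = 2.2$ on
   $[1, N-1]$, $N = 5{,}000$ by default. Two readings of "truncated
   power-law degrees" exist: a discrete Zipf pmf $p(k) \propto k^{-\gamma}$,
   or a continuous density $\propto x^{-\gamma}$ discretized by flooring.
   They differ materially: at these settings the discrete Zipf has mean
   degree $\approx 3.14$, the floored continuous law $\approx 4.5$. We
   use the floored continuous law (inverse-CDF draw on
   $[k_{min}, k_{max}+1)$, then floor), the standard recipe in the
   generative-model literature, which at the default settings yields on
   average about $10{,}600$ edges after stub matching — the scale this
   generator is meant to operate at. The implied pmf has the closed form
   $p(k) \propto k^{1-\gamma} - (k+1)^{1-\gamma}$, which the tests use as
   an independent oracle.
2. **Topology** by uniform stub matching, rejecting self- and
   multi-edges; after $10^4$ consecutive failed draws the remaining stubs
   are deleted (the counter resets on every success). With a heavy tail
   this deletion is not rare: a vertex drawing a near-maximal degree
   cannot place all its stubs as simple edges, and a few percent of stubs
   typically die. Realized degrees are therefore $\le$ requested ones,
   exactly accounted: $\sum_v k_v - \text{leftover} = 2M$.
3. **Activity intervals**: each edge is active on one interval of
   duration exactly $\mu T$, start uniform on $[0, (1-\mu)T]$. The
   overlap parameter $\mu \in (0, 1]$ tunes the prevalence of concurrent
   partnerships; $\mu = 1$ makes all partnerships concurrent. Interval
   durations are deliberately not skewed — with durations as broadly
   distributed as the degrees, the overlap would no longer be
   controllable by a single parameter.
4. **Contact times**: the total budget is $L = 10M$ contacts (the
   `contacts_per_edge` default). How to split one global bursty time
   series over the edges is genuinely under-specified; we allocate
   near-equal counts — one guaranteed contact per edge plus an
   equal-weight multinomial for the remainder, so every realized edge
   appears in the output and the per-edge mean is exactly 10 — then give
   each edge its own truncated power-law gaps ($\beta = 2$ on
   $[1, 10^4]$), cumulative-summed and mapped affinely onto the edge's
   interval, rounded to integer timesteps (coincident rounded times stay
   distinct contacts). The affine map preserves each edge's gap profile
   (hence burstiness) while enforcing interval confinement and the exact
   contact budget; the cost is that the *absolute* gap scale is rescaled
   per edge. A sequential-blocks reading of the same step would preserve
   absolute scales but violate either the interval confinement or the
   per-edge budget, which is why we did not adopt it.

The default sampling span $T = 10^5$ gives the full interval at
$\mu = 1$ room for the expected total gap of ten draws from the
interevent law. What the generator does **not** emulate: skewed interval
durations, degree–activity correlations, and community structure. Tests
passing on this generator therefore say nothing about data where those
features drive the dynamics — that is exactly why the evaluation
machinery takes arbitrary contact lists.

## Numerical and testing choices

* Strict threshold comparisons ($w > \Omega$) with half-integer
  thresholds in limit identities, as above.
* The configuration-space and oracle tests run at desk scale (tens to
  hundreds of vertices, 100–3,000 SIR runs), sizes chosen so the whole
  suite completes in well under a minute while keeping Monte-Carlo
  acceptance bands at $3\sigma$.
* The planted-recovery fixture is a "staircase" graph (edge iff
  $i + j \ge N + 1$, so degree $\approx$ vertex index and nearly all
  degrees distinct) with all informative contacts in $[0, T/2]$ and
  unstructured noise after. Distinct degrees matter: large tie blocks
  would cap the attainable Spearman $\rho$ well below 1 regardless of
  method. The fixture is run at $\lambda$ in the intermediate-outbreak
  regime (mean $\Sigma$ near $N/5$, the same regime the calibration
  protocol targets); at saturating $\lambda$ every seed reaches the dense
  core and the rank signal collapses — an instructive failure mode, not a
  bug. The scan's optimum typically lies at an *early* sub-window of the
  planted half, because outbreaks are seeded at first contacts and early
  structure predicts them best; the recovery assertion is therefore that
  the argmax lies inside the signal half and that the planted window
  itself scores $\rho \ge 0.95$.

## Known limitations

* The SIR engine holds the whole contact sequence in memory; it is
  comfortable to millions of contacts but not engineered beyond that.
* Importance tables cost $N \times$ `n_runs` simulations; for large $N$
  with 10,000 runs per seed, expect hours, and plan seeds/runs
  accordingly.
* Only undirected, unweighted contacts are modeled; directed or weighted
  data must be symmetrized or thresholded upstream.
* The bootstrap standard error on $\rho$ captures Monte-Carlo error in
  $\Sigma_i$ only, not sampling error of the underlying contact data.
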