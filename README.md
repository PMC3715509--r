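# netdistill

Distilling temporal contact networks into static graphs for epidemiology.

## The problem

Network epidemiology mostly runs on static graphs, but real contact data —
who met whom, and when — is temporal: a sequence of contacts *(i, j, t)*.
Collapsing the time dimension throws information away, and *how* you
collapse it matters. `netdistill` implements and evaluates three
conceptually simple, two-parameter ways of reducing a contact sequence to a
simple undirected graph:

- **time-slice network** — edge iff the pair has a contact with
  *t*<sub>start</sub> ≤ *t* ≤ *t*<sub>stop</sub>;
- **ongoing (concurrent-partnership) network** — edge iff the pair has
  contacts both strictly before *t*<sub>start</sub> and strictly after
  *t*<sub>stop</sub>, i.e. the relationship straddles the window;
- **exponential-threshold network** — every contact adds weight
  *e*<sup>−*t*/τ</sup> to its pair (time counted from the data's first
  contact) and an edge exists when the pair's total weight exceeds Ω.

Limit cases recover the familiar constructions: the full-window time slice
is the **accumulated** (aggregated) network, and τ → ∞ with Ω = *n* − ½
gives the network of pairs with at least *n* contacts.

A representation is scored by how well it predicts influential spreaders.
The ground truth is Σ<sub>*i*</sub>, the expected outbreak size of an SIR
epidemic simulated **on the temporal data itself**, seeded at vertex *i*'s
first contact (per-contact transmission probability λ, fixed infective
duration δ). The score is the Spearman rank correlation ρ between
Σ<sub>*i*</sub> and a static predictor — degree *k*<sub>*i*</sub> or
coreness *c*<sub>*i*</sub> — and each representation is optimized over its
two parameters to find ρ<sub>max</sub>. The package also ships the
supporting apparatus: λ calibration to intermediate outbreak sizes,
burstiness and network diagnostics with a degree-preserving rewiring null
model, and a synthetic temporal-network generator (configuration model with
truncated power-law degrees, per-edge activity intervals of duration μT,
bursty interevent times) so the whole pipeline runs without external data.

## Worked example

```r
library(netdistill)

# 1. generate a synthetic temporal network
cfg <- synthetic_config(N = 300, k_max = 299, mu = 0.5, T_total = 30000)
cs  <- generate_contacts(cfg, rng_seed = 1)
cs
#> Contact sequence: N = 300 vertices, L = 4300 contacts, M = 430 pairs, T = 29885
burstiness(cs)
#> [1] 0.1218257

# 2. calibrate lambda so the mean outbreak is 1/5 of the lambda = 1 size
lam <- calibrate_lambda(cs, n_runs = 100, rng_seed = 2)
round(c(lambda = as.numeric(lam), achieved = attr(lam, "achieved")), 3)
#>   lambda achieved
#>    0.156    0.200

# 3. per-seed expected outbreak sizes on the temporal data
imp <- importance_table(cs, lambda = as.numeric(lam),
                        delta = sampling_time(cs) / 5,
                        n_runs = 200, rng_seed = 3, keep_runs = TRUE)

# 4. optimize each representation's parameters
acc <- scan_representation(cs, imp, "accumulated")
ts  <- scan_representation(cs, imp, "time_slice", window_grid(11))
on  <- scan_representation(cs, imp, "ongoing",    window_grid(11))
et  <- scan_representation(cs, imp, "exp_threshold",
                           expthresh_grid(8, 8, c(0.01, 10), c(0.01, 5)))
round(c(accumulated = acc$rho_max, time_slice = ts$rho_max,
        ongoing = on$rho_max, exp_threshold = et$rho_max), 3)
#>   accumulated    time_slice       ongoing exp_threshold
#>         0.426         0.470         0.470         0.497
ts$best
#>    t_start t_stop       rho se
#> 46     0.1    0.4 0.4697342 NA
```

Reading the numbers: ρ<sub>max</sub> is how well static degree ranks the
true spreading importance under each representation; here the
exponential-threshold network carries the most epidemiologically relevant
information (ρ = 0.50), an optimized time window comes close (0.47, best
window [0.1 T, 0.4 T]), and naively accumulating all contacts is clearly
worse (0.43) — the qualitative ordering this methodology was built to
expose. Window times are fractions of the sampling time T; τ is a multiple
of T.

There is also a command-line driver over the same functions
(`generate`, `represent`, `simulate`, `calibrate`, `scan`, `stats`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/netdistill.R", package = "netdistill"))')" \
    generate --N 300 --mu 0.5 --T_total 30000 --seed 1 --out contacts.txt
```

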