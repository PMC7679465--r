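# hyperprox

Hyperbolic geometry of temporal human proximity networks.

Human proximity networks record who was within close range of whom in a
physical space (a hospital ward, a school, an office), as a sequence of
network snapshots, one per observation slot of a few seconds to minutes.
Individual snapshots are extremely sparse — a handful of contacts among
hundreds of people — yet the *time-aggregated* network over a sufficiently
long window (two nodes linked if they were ever in contact) is dense enough
to carry geometry. `hyperprox` implements a complete pipeline built on that
observation, for epidemiologists and network scientists who work with
SocioPatterns-style contact data:

- **dynamic-S¹ generation.** Every snapshot is an independent realization of
  the S¹ latent-space model: node *i* carries a hidden degree κᵢ and an
  angle θᵢ on a circle of radius R = N/2π, and pairs connect with the
  Fermi–Dirac probability p(χ) = 1/(1 + χ^{1/T}), where
  χᵢⱼ = RΔθᵢⱼ/(μκᵢκⱼ) is the effective distance and the temperature
  T ∈ (0,1) sets clustering and the contact/intercontact duration exponents
  2 + T and 2 − T.
- **aggregation theory.** Over τ slots the aggregated connection probability
  is P(χ) = 1 − (1 − p(χ))^τ, which in the rescaled distance χ̃ = χ/α with
  α = τ^T/Γ(1+T) again resembles a Fermi–Dirac curve — so the aggregated
  graph of a temporal network can be embedded with static S¹ machinery, and
  per-slot hidden degrees recovered as κ = κ̃/α.
- **embedding.** Temperature estimation by clustering matching, hidden-degree
  inference by an expected-degree fixed point, Laplacian-Eigenmaps angular
  initialization, and coordinate-ascent likelihood refinement, with an
  optional exact finite-τ (aggregated) likelihood; hidden degrees convert to
  hyperbolic radii rᵢ = R̂ − 2 ln(κᵢ/κ₀).
- **applications.** Greedy (H2H-GR) and random (H2H-RR) packet routing on
  the temporal network with success ratio and stretch against shortest
  time-respecting paths; geometric (s = 1/χ̃) and common-neighbor link
  prediction with AUROC/AUPR; discrete-time SI epidemics and the Spearman
  correlation between arrival slot and hyperbolic distance from the source.

## Worked example

```r
library(hyperprox)

# 1. simulate a face-to-face-style temporal network (two "days")
coords <- sample_latent(s1_params(100, 0.3, temperature = 0.6, seed = 1))
tn <- generate_dynamic_s1(coords, rep(0.3, 1200), seed = 2)

# 2. embed the first day's time-aggregated network
g1 <- aggregate_network(tn, 1:600)
emb <- embed_graph(g1, seed = 3)
#> embedding: 100/100 nodes, mode fermi_dirac, T_hat = 0.58, logL = -1126.6

# 3. coordinate recovery against the generating truth
ids <- emb$node_ids
d_kappa(per_slot_kappa(emb$kappa_agg, 600, 0.6), coords$kappa[ids])
d_theta(emb$theta, coords$theta[ids])
#> D_kappa = 0.067, D_theta = 0.121 rad

# 4. greedy vs random routing on the second day's temporal network
act <- intersect(active_nodes(tn, 601:1200), emb$node_ids)
set.seed(4)
src <- sample(act, 200, replace = TRUE)
pairs <- cbind(src, vapply(src, function(s) sample(setdiff(act, s), 1), 0L))
evaluate_routing(tn, emb, pairs, window = 601:1200, strategy = "greedy")
evaluate_routing(tn, NULL, pairs, window = 601:1200, strategy = "random",
                 seed = 5)
#> H2H-GR: p_s = 0.48, stretch = 2.6 | H2H-RR: p_s = 0.31, stretch = 10.2

# 5. geometric link prediction of day-2 edges from day-1 coordinates
predict_links(aggregate_network(tn, 601:1200), emb_prev = emb, g_prev = g1)
#> scored_pairs (geometric): 4950 pairs, prevalence 0.134,
#> AUROC 0.867, AUPR 0.671

# 6. SI epidemics: arrival time vs hyperbolic distance from the source
epidemic_experiment(tn, embedding_from_truth(coords, 1200),
                    beta = 0.05, n_sources = 10, seed = 6)
#> mean Spearman rho over 8 runs: 0.65
```

The numbers read as follows: after embedding one simulated "day", the mean
absolute error of the recovered per-slot hidden degrees is 0.067 and of the
angular coordinates 0.12 rad; greedy routing with those coordinates delivers
48% of packets at mean stretch 2.6 where coordinate-free random forwarding
delivers 31% at stretch 10.2; day-1 distances predict day-2 links at AUROC
0.87 against a 0.13 prevalence; and SI arrival times correlate with
hyperbolic distance from the source at mean Spearman ρ = 0.65.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/hyperprox` (subcommands `fixture`, `embed`, `evaluate`,
`route`, `predict-links`, `epidemic`).

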