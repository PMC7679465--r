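# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

## small static S1 snapshot with known coordinates
fix_static <- function() cached("static", function() {
  coords <- sample_latent(s1_params(150, 10, 0.5, seed = 41))
  edges <- with_seed(42, generate_s1_snapshot(coords))
  list(coords = coords, g = aggregated_graph(edges, 150))
})

## small dynamic-S1 temporal network with known coordinates
fix_temporal <- function() cached("temporal", function() {
  coords <- sample_latent(s1_params(100, 0.3, 0.6, seed = 81))
  tn <- generate_dynamic_s1(coords, rep(0.3, 600), seed = 82)
  list(coords = coords, tn = tn)
})

## hand-built three-slot toy network used across modules:
## slot 1 {(1,2)}, slot 2 {(2,3)}, slot 3 {(1,2)}
fix_toy3 <- function() {
  temporal_network(list(cbind(1L, 2L), cbind(2L, 3L), cbind(1L, 2L)), 3L)
}

## chain network: edges (1,2)@1, (2,3)@2, (3,4)@3 over equal-kappa nodes at
## angles 0,1,2,3
fix_chain <- function() {
  tn <- temporal_network(list(cbind(1L, 2L), cbind(2L, 3L), cbind(3L, 4L)), 4L)
  coords <- latent_coords(rep(1, 4), c(0, 1, 2, 3), mean_degree = 1,
                          temperature = 0.5)
  emb <- embedding_from_truth(coords, tau = 3)
  list(tn = tn, emb = emb)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
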