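#' Latent-degree laws for the S1 model
#'
#' A latent-degree law specifies the distribution rho(kappa) from which the
#' hidden degrees kappa are drawn when sampling S1 coordinates.  Three laws
#' are supported: a degenerate (delta) law giving every node the same kappa
#' (Poisson-like snapshot degrees), a Pareto-type power law with density
#' proportional to kappa^-gamma above kappa0 (scale-free snapshots), and an
#' empirical law that assigns a fixed list of values (used for synthetic
#' counterparts of observed networks, where kappa_i is a node's average
#' degree per slot).
#'
#' @param kappa,values positive real(s): the common hidden degree for the
#'   delta law, or one value per node for the empirical law.  Empirical
#'   values may be zero (nodes that were never active); such nodes generate
#'   no edges.
#' @param gamma power-law exponent, must exceed 2 so the mean exists.
#' @param kappa0 lower cutoff of the power law, positive.
#' @return An object of class `kappa_law`.
#' @examples
#' kappa_delta(2)
#' kappa_powerlaw(2.5, 1)
#' @export
kappa_delta <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    stop_invalid("delta law needs a single positive `kappa`")
  structure(list(type = "delta", kappa = kappa), class = "kappa_law")
}

#' @rdname kappa_delta
#' @export
kappa_powerlaw <- function(gamma, kappa0) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 2)
    stop_invalid("power-law exponent `gamma` must exceed 2")
  if (!is.numeric(kappa0) || length(kappa0) != 1L || kappa0 <= 0)
    stop_invalid("`kappa0` must be positive")
  structure(list(type = "powerlaw", gamma = gamma, kappa0 = kappa0),
            class = "kappa_law")
}

#' @rdname kappa_delta
#' @export
kappa_empirical <- function(values) {
  if (!is.numeric(values) || length(values) < 1L || any(!is.finite(values)) ||
      any(values < 0))
    stop_invalid("empirical law needs nonnegative finite `values`")
  structure(list(type = "empirical", values = as.numeric(values)),
            class = "kappa_law")
}

## analytic mean of the law (empirical: sample mean), used to calibrate mu
kappa_law_mean <- function(law) {
  switch(law$type,
         delta     = law$kappa,
         powerlaw  = law$kappa0 * (law$gamma - 1) / (law$gamma - 2),
         empirical = mean(law$values),
         stop_invalid("unknown kappa law"))
}

sample_kappa <- function(law, n) {
  switch(law$type,
         delta     = rep.int(law$kappa, n),
         powerlaw  = law$kappa0 * runif(n)^(-1 / (law$gamma - 1)),
         empirical = {
           if (length(law$values) != n)
             stop_invalid("empirical kappa list length must equal n_nodes")
           law$values
         })
}

#' S1 model parameters
#'
#' Bundles the parameters of a static S1 snapshot ensemble: the number of
#' nodes N, the target per-snapshot mean degree, the temperature T in (0,1)
#' that controls clustering and the distance decay of connections, and the
#' latent-degree law.
#'
#' @param n_nodes number of nodes N (>= 2).
#' @param mean_degree target expected mean degree per snapshot, positive.
#' @param temperature temperature T, in (0, 1).
#' @param kappa_law a [kappa_delta()], [kappa_powerlaw()] or
#'   [kappa_empirical()] law; defaults to the delta law at `mean_degree`.
#' @param seed optional integer; [sample_latent()] uses it for reproducible
#'   coordinate draws without disturbing the caller's RNG stream.
#' @return An object of class `s1_params`.
#' @export
s1_params <- function(n_nodes, mean_degree, temperature,
                      kappa_law = kappa_delta(mean_degree), seed = NULL) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 2)
    stop_invalid("`n_nodes` must be an integer >= 2")
  if (!is.numeric(mean_degree) || length(mean_degree) != 1L || mean_degree <= 0)
    stop_invalid("`mean_degree` must be positive")
  check_temperature(temperature)
  if (!inherits(kappa_law, "kappa_law"))
    stop_invalid("`kappa_law` must be built with kappa_delta/kappa_powerlaw/kappa_empirical")
  if (identical(kappa_law$type, "empirical") &&
      length(kappa_law$values) != as.integer(n_nodes))
    stop_invalid("empirical kappa list length must equal `n_nodes`")
  structure(list(n_nodes = as.integer(n_nodes), mean_degree = mean_degree,
                 temperature = temperature, kappa_law = kappa_law,
                 seed = seed),
            class = "s1_params")
}

#' Angular (similarity) distance on the circle
#'
#' Distance between two angles after reduction modulo 2*pi:
#' `pi - |pi - |theta_i - theta_j||`, in `[0, pi]`.  Vectorized and symmetric.
#'
#' @param theta_i,theta_j angles in radians (any finite reals).
#' @return Numeric vector of distances in `[0, pi]`.
#' @examples
#' angular_distance(0, pi)
#' angular_distance(0.5, 2 * pi - 0.5)
#' @export
angular_distance <- function(theta_i, theta_j) {
  check_finite(theta_i, "theta_i"); check_finite(theta_j, "theta_j")
  d <- abs(theta_i - theta_j) %% (2 * pi)
  pi - abs(pi - d)
}

## unchecked internal version
circ_dist <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pi - abs(pi - d)
}

#' Degree-calibration constant mu of the S1 model
#'
#' `mu = mean_degree * sin(T*pi) / (2 * kappa_bar^2 * T * pi)`, the constant
#' that makes the expected snapshot mean degree equal `mean_degree` when the
#' hidden-degree law has mean `kappa_bar`.
#'
#' @param mean_degree target mean degree, positive.
#' @param kappa_bar mean of the latent-degree law, positive.
#' @param temperature temperature T in (0, 1).
#' @return The positive scalar mu.
#' @examples
#' compute_mu(10, 10, 0.5)
#' @export
compute_mu <- function(mean_degree, kappa_bar, temperature) {
  if (any(mean_degree <= 0)) stop_invalid("`mean_degree` must be positive")
  if (any(kappa_bar <= 0)) stop_invalid("`kappa_bar` must be positive")
  check_temperature(temperature)
  mean_degree * sin(temperature * pi) / (2 * kappa_bar^2 * temperature * pi)
}

#' Effective distance between two nodes
#'
#' `chi_ij = R * dtheta_ij / (mu * kappa_i * kappa_j)` with `R = N / (2*pi)`:
#' the model's distance combining angular similarity and hidden degrees.
#'
#' @param i,j node indices (vectors allowed, elementwise; `i != j`).
#' @param coords a `latent_coords` object from [sample_latent()].
#' @return Numeric vector of effective distances.
#' @export
effective_distance <- function(i, j, coords) {
  stopifnot(inherits(coords, "latent_coords"))
  if (any(i == j)) stop_invalid("self-distance (i == j) is undefined")
  n <- coords$n_nodes
  if (any(i < 1L | i > n | j < 1L | j > n)) stop_invalid("node index out of range")
  chi_from_parts(circ_dist(coords$theta[i], coords$theta[j]),
                 coords$kappa[i] * coords$kappa[j], coords$mu, coords$radius)
}

## chi = R * dtheta / (mu * kprod); kprod = 0 maps to chi = Inf (never connect)
chi_from_parts <- function(dtheta, kprod, mu, radius) {
  chi <- radius * dtheta / (mu * kprod)
  chi[!is.finite(chi) | kprod == 0] <- Inf
  chi[dtheta == 0 & kprod > 0] <- 0
  chi
}

#' Fermi-Dirac connection probability
#'
#' `p(chi) = 1 / (1 + chi^(1/T))`: equals 1 at chi = 0, 1/2 at chi = 1, and
#' decays as chi^(-1/T) at large distances.
#'
#' @param chi nonnegative effective distance(s); `Inf` allowed (probability 0).
#' @param temperature temperature T in (0, 1).
#' @return Probabilities in `[0, 1]`.
#' @examples
#' connection_probability(4, 0.5)
#' @export
connection_probability <- function(chi, temperature) {
  if (any(is.nan(chi)) || any(chi < 0, na.rm = TRUE))
    stop_invalid("`chi` must be nonnegative")
  check_temperature(temperature)
  1 / (1 + chi^(1 / temperature))
}

#' Sample latent S1 coordinates
#'
#' Draws angular coordinates theta i.i.d. uniform on `[0, 2*pi)` and hidden
#' degrees kappa from the configured law, and records mu (degree
#' calibration), the circle radius `R = N/(2*pi)`, and the law mean
#' kappa_bar.
#'
#' @param params an [s1_params()] object.
#' @return An object of class `latent_coords` with fields `kappa`, `theta`,
#'   `mu`, `radius`, `kappa_bar`, `mean_degree`, `temperature`, `n_nodes`.
#' @export
sample_latent <- function(params) {
  stopifnot(inherits(params, "s1_params"))
  n <- params$n_nodes
  with_local_seed(params$seed, {
    theta <- runif(n, 0, 2 * pi) %% (2 * pi)
    kappa <- sample_kappa(params$kappa_law, n)
    latent_coords(kappa, theta, params$mean_degree, params$temperature,
                  kappa_bar = kappa_law_mean(params$kappa_law))
  })
}

#' Construct latent coordinates from explicit values
#'
#' @param kappa nonnegative hidden degrees (one per node).
#' @param theta angles in radians; reduced modulo 2*pi.
#' @param mean_degree per-snapshot mean degree used to calibrate mu.
#' @param temperature temperature T in (0, 1).
#' @param kappa_bar mean of the generating law; defaults to `mean(kappa)`.
#' @return A `latent_coords` object.
#' @export
latent_coords <- function(kappa, theta, mean_degree, temperature,
                          kappa_bar = mean(kappa)) {
  n <- length(kappa)
  if (length(theta) != n) stop_invalid("`kappa` and `theta` lengths differ")
  if (any(!is.finite(kappa)) || any(kappa < 0))
    stop_invalid("`kappa` must be nonnegative and finite")
  check_finite(theta, "theta")
  check_temperature(temperature)
  structure(list(kappa = as.numeric(kappa), theta = theta %% (2 * pi),
                 mu = compute_mu(mean_degree, kappa_bar, temperature),
                 radius = n / (2 * pi), kappa_bar = kappa_bar,
                 mean_degree = mean_degree, temperature = temperature,
                 n_nodes = n),
            class = "latent_coords")
}

## per-pair connection probabilities for one snapshot
s1_edge_probs <- function(coords, mu, temperature,
                          pairs = pair_indices(coords$n_nodes)) {
  dth <- circ_dist(coords$theta[pairs[, 1L]], coords$theta[pairs[, 2L]])
  kprod <- coords$kappa[pairs[, 1L]] * coords$kappa[pairs[, 2L]]
  chi <- chi_from_parts(dth, kprod, mu, coords$radius)
  connection_probability(chi, temperature)
}

#' Generate one S1 snapshot
#'
#' Connects every unordered pair independently with the Fermi-Dirac
#' probability at its effective distance.  When `mean_degree` differs from
#' the one recorded in `coords`, mu is recalibrated (holding kappa_bar
#' fixed), which is how the dynamic model varies per-slot mean degrees over
#' fixed coordinates.  Pairwise O(N^2) exact Bernoulli sampling.
#'
#' @param coords a `latent_coords` object.
#' @param mean_degree per-snapshot mean degree; default: the one in `coords`.
#' @param temperature temperature; default: the one in `coords`.
#' @return Integer edge matrix with columns `i`, `j` (i < j).
#' @export
generate_s1_snapshot <- function(coords, mean_degree = NULL,
                                 temperature = NULL) {
  stopifnot(inherits(coords, "latent_coords"))
  temperature <- temperature %||% coords$temperature
  mu <- if (is.null(mean_degree) || mean_degree == coords$mean_degree)
    coords$mu else compute_mu(mean_degree, coords$kappa_bar, temperature)
  pairs <- pair_indices(coords$n_nodes)
  p <- s1_edge_probs(coords, mu, temperature, pairs)
  pairs[runif(length(p)) < p, , drop = FALSE]
}

#' Convert hidden degrees to hyperbolic radial coordinates
#'
#' The S1 model is equivalent to a random hyperbolic graph in a disk of
#' radius `R_hat = 2*log(N / (pi * mu * kappa0^2))` after the change of
#' variables `r_i = R_hat - 2*log(kappa_i / kappa0)`, with kappa0 the
#' smallest hidden degree.  Under this map the effective distance satisfies
#' `chi_ij = exp((x_ij - R_hat)/2)` with
#' `x_ij = r_i + r_j + 2*log(dtheta_ij/2)` (approximately the hyperbolic
#' distance).
#'
#' @param coords a `latent_coords` object (all kappa strictly positive), or
#'   any list carrying `kappa`, `mu`, `n_nodes`.
#' @return An object of class `hyperbolic_coords`: list with radial
#'   coordinates `r` and `disk_radius` R_hat.
#' @export
to_hyperbolic <- function(coords) {
  kappa <- coords$kappa
  if (any(kappa <= 0))
    stop_invalid("all `kappa` must be positive for the radial map")
  kappa0 <- min(kappa)
  rhat <- 2 * log(coords$n_nodes / (pi * coords$mu * kappa0^2))
  structure(list(r = rhat - 2 * log(kappa / kappa0), disk_radius = rhat,
                 kappa0 = kappa0),
            class = "hyperbolic_coords")
}
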