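#' Emergent threshold distributions from network cascades
#'
#' When contingent individuals activate once strictly more than a share
#' `rho` of their network neighbours is active, the macroscopically observed
#' ("emergent") threshold distribution `F` is not a primitive but follows
#' from the degree structure. For an Erdos-Renyi network with linking
#' probability `ell`, the number of active neighbours `a_i ~ Binomial(R, ell)`
#' and inactive neighbours `b_i ~ Binomial(P', ell)` of a node are
#' independent, with `P' = N - 1 - R` the inactive pool excluding the node
#' itself. `F_exact()` evaluates the resulting activation probability
#'
#' `F(R) = P( a_i > rho * (a_i + b_i) )`
#'
#' by summing over `b_i` (truncated where the binomial tail mass falls below
#' `1e-13`) the probability that `a_i` strictly exceeds
#' `floor(rho * b_i / (1 - rho))`.
#'
#' `F_poisson()` is the large-`N` limit at fixed mean degree `K = ell*(N-1)`:
#' both binomials become Poisson with rates `K*r` and `K - K*r`, giving
#'
#' `F(r) = 1 - exp(-K) * sum_b ((K - K*r)^b / b!) * sum_(a=0)^(floor(rho*b/(1-rho))) (K*r)^a / a!`
#'
#' evaluated here in complement form (so `F(0) = 0` exactly and truncation
#' only underestimates). `F_gamma()` replaces the inner truncated
#' exponential sum by the regularised incomplete gamma function
#' `Q(m + 1, K*r)`; the Poisson-CDF/gamma identity is exact, so it agrees
#' with `F_poisson()` to numerical precision.
#'
#' Conventions: activation is strict (`>`), so an exactly integer
#' `rho * b / (1 - rho)` counts as non-activating, matching the cascade
#' simulator; at `rho = 0` any node with at least one active neighbour
#' activates; at `rho = 1` activation is impossible and `F` is identically 0.
#' All forms are bounded by `1 - exp(-K)`, the deficit being the mass of
#' isolated nodes, which never activate.
#'
#' @param R active count(s), `0 <= R <= N - 1` (vectorised).
#' @param N population size.
#' @param ell Erdos-Renyi linking probability, in `(0, 1]`.
#' @param rho threshold fraction in `[0, 1]`.
#' @param r active share(s) in `[0, 1]` (vectorised).
#' @param K mean degree, `K > 0`.
#' @return activation probabilities in `[0, 1]`.
#' @examples
#' F_poisson(c(0, 0.5, 1), K = 10, rho = 0.5)
#' F_exact(50, N = 100, ell = 0.1, rho = 0.5)
#' @export
F_exact <- function(R, N, ell, rho) {
  stopifnot(N >= 2, ell > 0, ell <= 1)
  check_rho(rho)
  vapply(R, function(Ri) {
    if (Ri < 0 || Ri > N - 1)
      stop_tip("R must lie in [0, N - 1]", "parameter_error")
    if (rho >= 1) return(0)
    Pp <- N - 1 - Ri
    bmax <- if (Pp > 0) stats::qbinom(1e-13, Pp, ell, lower.tail = FALSE) else 0
    b <- 0:bmax
    m <- guarded_floor(rho * b / (1 - rho))
    sum(stats::dbinom(b, Pp, ell) *
          stats::pbinom(m, Ri, ell, lower.tail = FALSE))
  }, numeric(1))
}

#' @rdname F_exact
#' @export
F_poisson <- function(r, K, rho) {
  check_share(r); check_rho(rho)
  stopifnot(K > 0)
  if (rho >= 1) return(numeric(length(r)))
  bmax <- max(stats::qpois(1e-13, K, lower.tail = FALSE), 5)
  out <- numeric(length(r))
  for (b in 0:bmax) {
    m <- guarded_floor(rho * b / (1 - rho))
    out <- out + stats::dpois(b, K - K * r) *
      stats::ppois(m, K * r, lower.tail = FALSE)
  }
  out
}

#' @rdname F_exact
#' @export
F_gamma <- function(r, K, rho) {
  check_share(r); check_rho(rho)
  stopifnot(K > 0)
  if (rho >= 1) return(numeric(length(r)))
  bmax <- max(stats::qpois(1e-13, K, lower.tail = FALSE), 5)
  out <- numeric(length(r))
  for (b in 0:bmax) {
    m <- guarded_floor(rho * b / (1 - rho))
    # P(Pois(K r) > m) = P(Gamma(m + 1) < K r), the regularised lower
    # incomplete gamma function evaluated at K r
    out <- out + stats::dpois(b, K - K * r) * stats::pgamma(K * r, m + 1)
  }
  out
}

check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1)
    stop_tip("rho must be a single number in [0, 1]", "parameter_error")
}

check_share <- function(r) {
  if (any(r < 0 | r > 1))
    stop_tip("active shares must lie in [0, 1]", "parameter_error")
}

#' @rdname F_exact
#' @export
cdf_poisson <- function(K, rho) {
  force(K); force(rho)
  threshold_cdf(function(r) F_poisson(r, K, rho),
                kind = "analytic-poisson", params = list(K = K, rho = rho),
                scale = "fraction")
}

#' @rdname F_exact
#' @export
cdf_gamma <- function(K, rho) {
  force(K); force(rho)
  threshold_cdf(function(r) F_gamma(r, K, rho),
                kind = "analytic-gamma", params = list(K = K, rho = rho),
                scale = "fraction")
}

#' @rdname F_exact
#' @export
cdf_exact <- function(N, ell, rho) {
  force(N); force(ell); force(rho)
  threshold_cdf(function(R) F_exact(pmin(R, N - 1), N, ell, rho),
                kind = "analytic-exact",
                params = list(N = N, ell = ell, rho = rho), scale = "count")
}

#' Measure the emergent threshold distribution from a cascade trajectory
#'
#' Rearranging the refined recursion, each simulated step yields one point
#' on the emergent threshold distribution: plotting `r(t) = R(t)/N` against
#' `(r(t+1) - a) / c` recovers `F(r(t))` up to sampling noise. The
#' mean-field form is only exact at equilibrium, so by default the points
#' are restricted to `t` in `{0, t_max - 1}` (the initial state and the last
#' step before the cascade stops); set `near_equilibrium_only = FALSE` to
#' keep the transient points as well, where clustering of active nodes
#' degrades the approximation.
#'
#' @param traj a [cascade_trajectory][run_cascade] or
#'   [recursion_trajectory][iterate] (any data frame with columns `t`, `R`).
#' @param part the [population_partition] of the run; must have `c > 0`.
#' @param near_equilibrium_only keep only `t` in `{0, t_max - 1}`.
#' @return a data frame of class `"emergent_threshold_curve"` with columns
#'   `t`, `r` (the abscissa `r(t)`) and `F_emp` (the ordinate).
#' @export
empirical_threshold_curve <- function(traj, part, near_equilibrium_only = TRUE) {
  stopifnot(inherits(part, "population_partition"))
  if (part$c == 0)
    stop_tip("empirical threshold curve undefined when c = 0",
             "undefined_curve")
  R <- traj$R
  t_max <- length(R) - 1L
  if (t_max < 1L)
    stop_tip("trajectory must contain at least one step", "parameter_error")
  ts <- 0:(t_max - 1L)
  if (near_equilibrium_only) ts <- unique(c(0L, t_max - 1L))
  out <- data.frame(
    t = ts,
    r = R[ts + 1L] / part$N,
    F_emp = (R[ts + 2L] / part$N - part$a) / part$c)
  class(out) <- c("emergent_threshold_curve", "data.frame")
  out
}

#' @rdname empirical_threshold_curve
#' @param curves one or more curves (row-bound data frames as returned by
#'   `empirical_threshold_curve()`).
#' @return `cdf_empirical()` pools the points, enforces monotonicity by
#'   cumulative maxima over sorted abscissae, and returns a tabulated
#'   [threshold_cdf] on the fraction scale.
#' @export
cdf_empirical <- function(curves) {
  o <- order(curves$r)
  r <- curves$r[o]
  Fv <- pmin(pmax(cummax(curves$F_emp[o]), 0), 1)
  keep <- !duplicated(r)
  if (sum(keep) < 2L) {
    r <- c(r[1L], r[1L] + 1e-9)
    Fv <- rep(Fv[1L], 2L)
    keep <- c(TRUE, TRUE)
  }
  F <- cdf_tabulated(r[keep], Fv[keep], scale = "fraction")
  F$kind <- "empirical"
  F
}
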