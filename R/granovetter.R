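#' The refined Granovetter threshold model
#'
#' Constructs the macroscopic threshold model of collective behaviour. In the
#' classic formulation the number of active individuals follows
#' `R(t+1) = N * F(R(t))`, where `F` is the cumulative distribution of
#' activation thresholds. The refinement partitions the population into `A`
#' certainly acting, `C = P - A` contingent and `N - P` never-acting
#' individuals and iterates
#'
#' `R(t+1) = A + C * F(R(t))`
#'
#' so that all equilibria lie in `[A, P]` and are generally non-trivial.
#' With `A = 0`, `P = N` the refinement degenerates exactly to the original
#' recursion. Graphically, equilibria are the intersections of `F` with the
#' diagonal through `(A, 0)` and `(P, 1)`; intersections where `F` crosses
#' the diagonal from above are stable.
#'
#' @param F a [threshold_cdf].
#' @param N population size; use `N = 1` for a purely fractional model (then
#'   `A` and `P` are the fractions `a` and `p`).
#' @param A,P sizes of the certainly and potentially acting groups,
#'   `0 <= A <= P <= N`.
#' @param validate check `F` for monotonicity and range on `[0, N]`.
#' @return an object of class `"granovetter"` with elements `F` and
#'   `partition` (a [population_partition]).
#' @examples
#' m <- granovetter(cdf_gaussian(25, 13), N = 100)
#' iterate(m, R0 = 1)
#' equilibria(m)
#' @seealso [iterate()], [equilibria()], [critical_sigma()], [fixed_points()]
#' @export
granovetter <- function(F, N = 1, A = 0, P = N, validate = TRUE) {
  part <- population_partition(N, A = A, P = P)
  if (validate) validate_threshold_cdf(F, N)
  structure(list(F = F, partition = part), class = "granovetter")
}

#' @export
print.granovetter <- function(x, ...) {
  p <- x$partition
  if (p$A == 0 && p$P == p$N)
    cat(sprintf("Granovetter threshold model: R(t+1) = %g F(R(t))\n", p$N))
  else
    cat(sprintf("Refined threshold model: R(t+1) = %g + %g F(R(t))\n",
                p$A, p$C))
  print(x$F)
  print(p)
  invisible(x)
}

#' @export
summary.granovetter <- function(object, ...) {
  eq <- equilibria(object, ...)
  structure(list(model = object, equilibria = eq),
            class = "summary.granovetter")
}

#' @export
print.summary.granovetter <- function(x, ...) {
  print(x$model)
  cat("\nEquilibria:\n")
  print(x$equilibria)
  invisible(x)
}

#' Iterate the threshold recursion to its fixed point
#'
#' Runs `R(t+1) = A + C * F(R(t))` from `R0` until successive iterates agree
#' to within `tol` or `max_steps` is reached. Iteration is carried out in
#' real numbers (the analytic treatment of the model is continuous even
#' though `R` counts individuals).
#'
#' For monotone `F` the map is monotone, so iterates started at `R0 = A`
#' form a nondecreasing sequence bounded by `P`.
#'
#' @param model a [granovetter] model.
#' @param R0 starting count; defaults to `A` (the certainly acting group).
#' @param max_steps iteration cap.
#' @param tol fixed-point tolerance; defaults to `1e-6 * N`.
#' @return an object of class `"recursion_trajectory"`: a data frame with
#'   columns `t` and `R`, and attributes `converged`, `t_max`, `N`.
#' @export
iterate <- function(model, R0 = NULL, max_steps = 10000L, tol = NULL) {
  stopifnot(inherits(model, "granovetter"))
  p <- model$partition
  if (is.null(R0)) R0 <- p$A
  if (is.null(tol)) tol <- 1e-6 * p$N
  if (R0 < 0 || R0 > p$N)
    stop_tip("R0 must lie in [0, N]", "parameter_error")
  traj <- numeric(max_steps + 1L)
  traj[1L] <- R0
  converged <- FALSE
  R <- R0
  n_t <- 1L
  for (s in seq_len(max_steps)) {
    Rn <- p$A + p$C * cdf_eval(model$F, R, p$N)
    n_t <- n_t + 1L
    traj[n_t] <- Rn
    if (abs(Rn - R) < tol) {
      converged <- TRUE
      break
    }
    R <- Rn
  }
  out <- data.frame(t = 0:(n_t - 1L), R = traj[seq_len(n_t)])
  structure(out, converged = converged, t_max = n_t - 1L, N = p$N,
            class = c("recursion_trajectory", "data.frame"))
}

#' @export
print.recursion_trajectory <- function(x, ...) {
  cat(sprintf("Threshold recursion: %d step(s), %s, final R = %.6g\n",
              attr(x, "t_max"),
              if (attr(x, "converged")) "converged" else "not converged",
              x$R[nrow(x)]))
  invisible(x)
}

#' Locate and classify the equilibria of the refined recursion
#'
#' Finds all solutions of `R = A + C * F(R)` on `[A, P]` by a dense grid scan
#' of `g(R) = A + C * F(R) - R` followed by bisection on sign changes
#' (a pure Newton iteration would be unsafe where `F` is flat). Each root is
#' labelled by the crossing direction: `g > 0` immediately left and `g < 0`
#' immediately right of the root means the map crosses the diagonal from
#' above, hence a stable equilibrium; the reverse is unstable; tangencies
#' (same sign on both sides, as at a saddle-node point) are labelled
#' `semi-stable`. Flat-zero segments of `g` are collapsed to one
#' representative root.
#'
#' @param model a [granovetter] model.
#' @param n_grid number of scan points on `[A, P]`.
#' @param rel_tol relative bisection tolerance (in units of `P - A`).
#' @param ... unused.
#' @return an object of class `"equilibrium_set"`: a data frame with columns
#'   `R_star`, `r_star` and `stability`.
#' @export
equilibria <- function(model, n_grid = 10001L, rel_tol = 1e-8, ...) {
  stopifnot(inherits(model, "granovetter"))
  p <- model$partition
  if (p$C == 0)
    return(equilibrium_set(p$A, "stable", p))
  g_of <- function(R) p$A + p$C * cdf_eval(model$F, R, p$N) - R
  grid <- seq(p$A, p$P, length.out = n_grid)
  g <- g_of(grid)
  span <- p$P - p$A
  zero_tol <- 1e-12 * max(1, span)

  # indices opening a root interval: exact zeros and sign changes
  hits <- which(abs(g) <= zero_tol)
  ch <- which(g[-n_grid] * g[-1L] < 0)
  idx <- sort(unique(c(hits, ch)))
  if (!length(idx)) return(equilibrium_set(numeric(0), character(0), p))

  # merge adjacent indices into clusters (flat-zero runs, double hits)
  cluster <- cumsum(c(1L, diff(idx) > 1L))
  roots <- vapply(split(idx, cluster), function(ii) {
    i0 <- ii[1L]; i1 <- ii[length(ii)]
    if (abs(g[i0]) <= zero_tol && abs(g[min(i1 + 1L, n_grid)]) <= zero_tol)
      return(mean(grid[c(i0, min(i1 + 1L, n_grid))]))  # flat segment
    lo <- grid[i0]; hi <- grid[min(i1 + 1L, n_grid)]
    glo <- g[i0]
    if (abs(glo) <= zero_tol) return(lo)
    for (k in 1:100) {
      if (hi - lo < rel_tol * span) break
      mid <- (lo + hi) / 2
      gm <- g_of(mid)
      if (abs(gm) <= zero_tol) return(mid)
      if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  roots <- sort(unique(pmin(pmax(roots, p$A), p$P)))

  delta <- max(1e-5 * span, 10 * rel_tol * span)
  stab <- vapply(roots, function(r0) {
    gl <- if (r0 - delta >= p$A) g_of(r0 - delta) else NA_real_
    gr <- if (r0 + delta <= p$P) g_of(r0 + delta) else NA_real_
    if (is.na(gl)) return(if (gr < 0) "stable" else "unstable")
    if (is.na(gr)) return(if (gl > 0) "stable" else "unstable")
    if (gl > 0 && gr < 0) "stable"
    else if (gl < 0 && gr > 0) "unstable"
    else "semi-stable"
  }, character(1))
  equilibrium_set(roots, stab, p)
}

equilibrium_set <- function(R_star, stability, part) {
  out <- data.frame(R_star = R_star, r_star = R_star / part$N,
                    stability = stability, stringsAsFactors = FALSE)
  structure(out, partition = part,
            class = c("equilibrium_set", "data.frame"))
}

#' @export
print.equilibrium_set <- function(x, ...) {
  part <- attr(x, "partition")
  cat(sprintf("%d equilibrium point(s) on [A, P] = [%g, %g]:\n",
              nrow(x), part$A, part$P))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
plot.granovetter <- function(x, n_grid = 401L, ...) {
  p <- x$partition
  R <- seq(0, p$N, length.out = n_grid)
  Fv <- cdf_eval(x$F, R, p$N)
  plot(R, Fv, type = "l", lwd = 2, col = "purple4", ylim = c(0, 1),
       xlab = "active count R", ylab = "F(R)  /  rescaled diagonal", ...)
  # diagonal through (A, 0) and (P, 1): the fixed-point condition (R-A)/C = F
  if (p$C > 0) lines(c(p$A, p$P), c(0, 1), col = "darkgreen")
  eq <- equilibria(x)
  if (nrow(eq)) {
    stable <- eq$stability == "stable"
    points(eq$R_star, (eq$R_star - p$A) / max(p$C, 1e-12),
           pch = ifelse(stable, 19, 21), bg = "white")
  }
  invisible(x)
}

#' Critical spread of a cut-off Gaussian threshold distribution
#'
#' For the classic worked example of the original threshold model: with
#' population `N` and Gaussian thresholds of mean `mu`, find the critical
#' standard deviation above which a single instigator (or `R0` initial
#' actors) triggers the whole population. The Gaussian CDF is evaluated
#' directly on `[0, N]` (a censored cut-off: probability mass below 0 acts
#' as threshold-0 individuals, mass above `N` as individuals who never act),
#' and a run counts as a full cascade when the equilibrium reaches at least
#' `N - 1`. The cascade/no-cascade boundary in `sigma` is located by
#' bisection and reported rounded to `resolution`.
#'
#' For `N = 100`, `mu = 25`, `R0 = 1` the critical value at resolution 0.1
#' is 12.2.
#'
#' @param N population size.
#' @param mu mean threshold (individuals), `0 < mu < N`.
#' @param R0 initial number of actors, at least 1.
#' @param resolution reporting resolution for `sigma`.
#' @param sigma_range search interval; the boundary must lie inside it.
#' @param max_steps,tol iteration controls for the inner recursion.
#' @return the critical standard deviation (individuals), rounded to
#'   `resolution`; `NA` with a warning if no `sigma` in `sigma_range`
#'   achieves a full cascade.
#' @export
critical_sigma <- function(N = 100, mu = 25, R0 = 1, resolution = 0.1,
                           sigma_range = c(resolution, max(2 * mu, 10 * resolution)),
                           max_steps = 100000L, tol = 1e-9 * N) {
  stopifnot(mu > 0, mu < N, R0 >= 1)
  full_cascade <- function(sigma) {
    m <- granovetter(cdf_gaussian(mu, sigma), N = N, validate = FALSE)
    tr <- iterate(m, R0 = R0, max_steps = max_steps, tol = tol)
    tr$R[nrow(tr)] >= N - 1
  }
  # the full-cascade region in sigma is an interval (very diffuse
  # distributions put too much mass above N), so locate its lower edge by
  # an upward scan at `resolution` followed by bisection of the boundary
  sigmas <- seq(sigma_range[1L], sigma_range[2L], by = resolution)
  hit <- NA_integer_
  for (i in seq_along(sigmas)) {
    if (full_cascade(sigmas[i])) { hit <- i; break }
  }
  if (is.na(hit)) {
    warning("no sigma in sigma_range achieves a full cascade")
    return(NA_real_)
  }
  if (hit == 1L) return(sigmas[1L])
  lo <- sigmas[hit - 1L]; hi <- sigmas[hit]
  while (hi - lo > resolution / 100) {
    mid <- (lo + hi) / 2
    if (full_cascade(mid)) hi <- mid else lo <- mid
  }
  round(hi / resolution) * resolution
}
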