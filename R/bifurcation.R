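#' Fixed points of the analytic refined threshold model
#'
#' Solves `(r - a) / c = F(r)` -- equivalently `r = a + c * F(r)` with
#' `c = p - a` -- on `[a, p]` for the analytic Poisson emergent threshold
#' distribution with mean degree `K` and threshold fraction `rho`
#' ([F_poisson()]). Generically the model has one globally stable fixed
#' point or two stable points separated by an unstable one; roots are found
#' by dense grid scan plus bisection and classified by the
#' crossing-direction rule (see [equilibria()]).
#'
#' @param a share of certainly acting individuals, `0 <= a <= p`.
#' @param p share of potentially acting individuals, `p <= 1`.
#' @param rho threshold fraction in `[0, 1]`.
#' @param K mean degree of the underlying network.
#' @param n_grid scan resolution on `[a, p]`.
#' @param F optional [threshold_cdf] overriding the Poisson form.
#' @return an object of class `c("fixed_point_set", "equilibrium_set")`:
#'   a data frame with columns `R_star`, `r_star`, `stability` and a
#'   `params` attribute.
#' @examples
#' fixed_points(a = 0.16, p = 0.67, rho = 0.4, K = 10)
#' @export
fixed_points <- function(a, p, rho, K = 10, n_grid = 10001L, F = NULL) {
  if (is.null(F)) F <- cdf_poisson(K, rho)
  m <- granovetter(F, N = 1, A = a, P = p, validate = FALSE)
  eq <- equilibria(m, n_grid = n_grid)
  attr(eq, "params") <- list(a = a, p = p, rho = rho, K = K)
  class(eq) <- c("fixed_point_set", class(eq))
  eq
}

n_stable <- function(fps) sum(fps$stability == "stable")

#' Smallest stable fixed point over a grid of (a, p) cells
#'
#' Computes `min(r*)` over the stable fixed points of the analytic refined
#' model for every combination of `a_values` and `p_values`; cells with
#' `a > p` are masked with `NA`. The sharp jumps of this surface trace the
#' saddle-node (fold) curves, and the point where the bistable window
#' collapses is the cusp.
#'
#' @param a_values,p_values grids of shares.
#' @inheritParams fixed_points
#' @return a matrix with rows indexed by `a_values` and columns by
#'   `p_values`, with `dimnames` set accordingly.
#' @export
min_stable_surface <- function(a_values, p_values, rho, K = 10,
                               n_grid = 2001L) {
  out <- matrix(NA_real_, length(a_values), length(p_values),
                dimnames = list(a = format(a_values), p = format(p_values)))
  for (j in seq_along(p_values)) {
    F <- cdf_poisson(K, rho)
    for (i in seq_along(a_values)) {
      if (a_values[i] > p_values[j]) next
      fps <- fixed_points(a_values[i], p_values[j], rho, K,
                          n_grid = n_grid, F = F)
      st <- fps$r_star[fps$stability == "stable"]
      out[i, j] <- if (length(st)) min(st) else NA_real_
    }
  }
  out
}

scan_fixed_points <- function(scan, value, fixed, n_grid) {
  pars <- fixed
  pars[[scan]] <- value
  fixed_points(pars$a, pars$p, pars$rho, pars$K, n_grid = n_grid)
}

#' Detect saddle-node (fold) bifurcations along a parameter scan
#'
#' Scans one of the parameters `a`, `p` or `rho` of the analytic refined
#' model and locates the parameter values where the number of stable fixed
#' points changes (1 to 2 or back, i.e. where a stable/unstable pair is
#' created or destroyed), refining each change point by bisection to `tol`.
#' Returns an empty set when the branch is monotone.
#'
#' @param scan which parameter to scan: `"a"`, `"p"` or `"rho"`.
#' @param range length-2 numeric scan interval.
#' @param a,p,rho,K model parameters; the scanned one may be left `NULL`.
#' @param n_scan number of initial scan points.
#' @param tol bisection tolerance on the fold location.
#' @param n_grid fixed-point scan resolution per parameter value.
#' @return an object of class `"fold_points"`: a data frame with columns
#'   `location`, `stable_below`, `stable_above` (stable fixed-point counts
#'   on either side of the fold).
#' @examples
#' saddle_node("a", c(0.01, 0.4), p = 0.67, rho = 0.4, K = 10)
#' @export
saddle_node <- function(scan = c("a", "p", "rho"), range,
                        a = NULL, p = NULL, rho = NULL, K = 10,
                        n_scan = 61L, tol = 1e-4, n_grid = 4001L) {
  scan <- match.arg(scan)
  fixed <- list(a = a, p = p, rho = rho, K = K)
  vals <- seq(range[1L], range[2L], length.out = n_scan)
  counts <- vapply(vals, function(v)
    n_stable(scan_fixed_points(scan, v, fixed, n_grid)), numeric(1))
  idx <- which(diff(counts) != 0)
  folds <- lapply(idx, function(i) {
    lo <- vals[i]; hi <- vals[i + 1L]
    clo <- counts[i]; chi <- counts[i + 1L]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      cm <- n_stable(scan_fixed_points(scan, mid, fixed, n_grid))
      if (cm == clo) lo <- mid else { hi <- mid; chi <- cm }
    }
    data.frame(location = (lo + hi) / 2, stable_below = clo,
               stable_above = chi)
  })
  out <- if (length(folds)) do.call(rbind, folds)
  else data.frame(location = numeric(0), stable_below = numeric(0),
                  stable_above = numeric(0))
  structure(out, scan = scan, fixed = fixed,
            class = c("fold_points", "data.frame"))
}

#' @export
print.fold_points <- function(x, ...) {
  if (!nrow(x)) {
    cat(sprintf("No fold in %s over the scanned range\n", attr(x, "scan")))
  } else {
    cat(sprintf("%d fold(s) in %s:\n", nrow(x), attr(x, "scan")))
    print.data.frame(x, row.names = FALSE, digits = 5)
  }
  invisible(x)
}

#' Locate the cusp point of the refined model in the (a, p) plane
#'
#' At fixed `rho` and `K` the saddle-node folds in `a` form two curves in
#' the `(a, p)` plane that meet at the cusp, below which the bistable
#' `a`-window has collapsed and the smallest stable fixed point varies
#' smoothly. `bistable_window()` returns the interval of `a` over which the
#' analytic model has at least two stable fixed points (boundaries refined
#' to `tol`; `NULL` if there is none wider than `win_tol`). `cusp_point()`
#' scans `p_values` upward for the first bistable `p`, then bisects `p`
#' against the last monostable value; the cusp estimate is that `p`
#' together with the midpoint of its (collapsing) `a`-window.
#'
#' @param p_values ascending grid of `p` values to scan.
#' @inheritParams saddle_node
#' @param win_tol minimal window width that counts as bistability.
#' @param p_tol bisection tolerance on the cusp `p`.
#' @return an object of class `"cusp_point"`: a list with `p_c`, `a_c` and
#'   the bistable `window` at `p_c`; `NA` entries with a warning if no
#'   bistability is found on the grid.
#' @export
cusp_point <- function(p_values, rho, K = 10, n_scan = 41L, tol = 1e-4,
                       n_grid = 2001L, win_tol = 1e-4, p_tol = 1e-3) {
  p_values <- sort(p_values)
  win <- NULL
  for (i in seq_along(p_values)) {
    win <- bistable_window(p_values[i], rho, K, n_scan, tol, n_grid, win_tol)
    if (!is.null(win)) break
  }
  if (is.null(win)) {
    warning("no bistable window found on the supplied p grid")
    return(structure(list(p_c = NA_real_, a_c = NA_real_,
                          window = c(NA_real_, NA_real_), rho = rho, K = K),
                     class = "cusp_point"))
  }
  p_hi <- p_values[i]
  if (i > 1L) {
    p_lo <- p_values[i - 1L]
    while (p_hi - p_lo > p_tol) {
      mid <- (p_lo + p_hi) / 2
      w <- bistable_window(mid, rho, K, n_scan, tol, n_grid, win_tol)
      if (is.null(w)) p_lo <- mid else { p_hi <- mid; win <- w }
    }
  }
  structure(list(p_c = p_hi, a_c = mean(win), window = win,
                 rho = rho, K = K),
            class = "cusp_point")
}

#' @rdname cusp_point
#' @param p share of potentially acting individuals.
#' @export
bistable_window <- function(p, rho, K = 10, n_scan = 41L, tol = 1e-4,
                            n_grid = 2001L, win_tol = 1e-4) {
  eps <- 1e-4 * p
  vals <- seq(eps, p - eps, length.out = n_scan)
  fixed <- list(a = NULL, p = p, rho = rho, K = K)
  counts <- vapply(vals, function(v)
    n_stable(scan_fixed_points("a", v, fixed, n_grid)), numeric(1))
  bi <- which(counts >= 2L)
  if (!length(bi)) return(NULL)
  refine <- function(in_idx, out_idx) {
    # bisect the bistability boundary between a bistable and a monostable a
    lo <- vals[out_idx]; hi <- vals[in_idx]
    while (abs(hi - lo) > tol) {
      mid <- (lo + hi) / 2
      if (n_stable(scan_fixed_points("a", mid, fixed, n_grid)) >= 2L)
        hi <- mid
      else lo <- mid
    }
    (lo + hi) / 2
  }
  lo <- if (bi[1L] > 1L) refine(bi[1L], bi[1L] - 1L) else vals[1L]
  last <- bi[length(bi)]
  hi <- if (last < n_scan) refine(last, last + 1L) else vals[n_scan]
  if (hi - lo <= win_tol) return(NULL)
  c(lo, hi)
}

#' @export
print.cusp_point <- function(x, ...) {
  if (is.na(x$p_c)) cat("No cusp found\n")
  else cat(sprintf(
    "Cusp estimate at rho = %g, K = %g: p_c ~ %.4g, a_c ~ %.4g (window [%.4g, %.4g])\n",
    x$rho, x$K, x$p_c, x$a_c, x$window[1L], x$window[2L]))
  invisible(x)
}

#' Hysteresis loop of the refined model under a parameter sweep
#'
#' Sweeps one parameter forward and backward across a (possibly) bistable
#' region, following the stable branch by warm-started continuation: at each
#' step the stable fixed point nearest to the previous one is selected, so
#' the state jumps only where its branch disappears at a fold. The forward
#' trace starts from the smallest stable fixed point at the start of the
#' range, the backward trace from the largest stable fixed point at its end.
#' The enclosed area (trapezoidal integral of `|r_up - r_down|`) is 0
#' exactly when the up and down traces coincide, i.e. when there is no
#' bistability in the swept range.
#'
#' @inheritParams saddle_node
#' @param steps number of sweep steps.
#' @return an object of class `"hysteresis_loop"`: a data frame with columns
#'   `value`, `r_up`, `r_down`, and attribute `area`.
#' @examples
#' hysteresis("a", c(0.02, 0.4), p = 0.67, rho = 0.4, K = 10, steps = 41)
#' @export
hysteresis <- function(scan = c("a", "p", "rho"), range,
                       a = NULL, p = NULL, rho = NULL, K = 10,
                       steps = 101L, n_grid = 4001L) {
  scan <- match.arg(scan)
  fixed <- list(a = a, p = p, rho = rho, K = K)
  vals <- seq(range[1L], range[2L], length.out = steps)
  stable_roots <- lapply(vals, function(v) {
    fps <- scan_fixed_points(scan, v, fixed, n_grid)
    sort(fps$r_star[fps$stability == "stable"])
  })
  follow <- function(order_idx, start_low) {
    r <- numeric(length(vals))
    prev <- NULL
    for (k in order_idx) {
      st <- stable_roots[[k]]
      if (!length(st)) { r[k] <- NA_real_; next }
      prev <- if (is.null(prev)) {
        if (start_low) st[1L] else st[length(st)]
      } else st[which.min(abs(st - prev))]
      r[k] <- prev
    }
    r
  }
  r_up <- follow(seq_along(vals), start_low = TRUE)
  r_down <- follow(rev(seq_along(vals)), start_low = FALSE)
  gap <- abs(r_up - r_down)
  area <- sum((gap[-1L] + gap[-length(gap)]) / 2 * diff(vals))
  structure(data.frame(value = vals, r_up = r_up, r_down = r_down),
            scan = scan, fixed = fixed, area = area,
            class = c("hysteresis_loop", "data.frame"))
}

#' @export
print.hysteresis_loop <- function(x, ...) {
  cat(sprintf("Hysteresis sweep in %s over [%g, %g]: loop area = %.6g\n",
              attr(x, "scan"), x$value[1L], x$value[nrow(x)],
              attr(x, "area")))
  invisible(x)
}

#' @export
plot.hysteresis_loop <- function(x, ...) {
  plot(x$value, x$r_up, type = "l", col = "firebrick", lwd = 2,
       xlab = attr(x, "scan"), ylab = "stable fixed point r*",
       ylim = range(c(x$r_up, x$r_down), na.rm = TRUE), ...)
  lines(x$value, x$r_down, col = "steelblue", lwd = 2, lty = 2)
  legend("topleft", c("sweep up", "sweep down"),
         col = c("firebrick", "steelblue"), lty = c(1, 2), bty = "n")
  invisible(x)
}
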