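#' Cumulative emergent-threshold distributions
#'
#' A `threshold_cdf` wraps the cumulative distribution function `F` that maps
#' the current number (or share) of active individuals to the fraction of the
#' population whose activation threshold is met. It is the single ingredient
#' of the macroscopic recursion and can come from several sources:
#'
#' * [cdf_gaussian()] -- the classic cut-off Gaussian assumption: a normal
#'   CDF with mean `mean` and standard deviation `sd` on the count scale,
#'   evaluated directly on `[0, N]` so that probability mass below 0 acts as
#'   threshold-0 individuals and mass above `N` as individuals who never act.
#' * [cdf_uniform()] -- thresholds uniform over the population (the identity
#'   on the fraction scale); every point of the original recursion is then a
#'   fixed point.
#' * [cdf_step()] -- a single common threshold (0 below `at`, 1 at/above).
#' * [cdf_tabulated()] -- a tabulated CDF, linearly interpolated with
#'   constant extrapolation; see [read_threshold_cdf()].
#' * [cdf_poisson()], [cdf_gamma()], [cdf_exact()] -- the analytic emergent
#'   threshold distributions arising from network cascades (see
#'   [F_poisson()], [F_gamma()], [F_exact()]).
#' * [cdf_empirical()] -- an isotonic fit to points measured from cascade
#'   simulations ([empirical_threshold_curve()]).
#'
#' @param fun vectorised function of the active count (scale `"count"`) or
#'   active share (scale `"fraction"`), returning values in `[0, 1]`.
#' @param kind provenance tag, e.g. `"gaussian"` or `"analytic-poisson"`.
#' @param params named list of the rule's parameters.
#' @param scale `"count"` or `"fraction"`: the native argument scale of `fun`.
#' @return an object of class `"threshold_cdf"`.
#' @seealso [granovetter()], [equilibria()]
#' @export
threshold_cdf <- function(fun, kind = "custom", params = list(),
                          scale = c("fraction", "count")) {
  scale <- match.arg(scale)
  stopifnot(is.function(fun))
  structure(list(fun = fun, kind = kind, params = params, scale = scale),
            class = "threshold_cdf")
}

#' @rdname threshold_cdf
#' @param mean,sd mean and standard deviation of the Gaussian threshold
#'   distribution, in individuals (count scale).
#' @export
cdf_gaussian <- function(mean, sd) {
  force(mean); force(sd)
  threshold_cdf(function(R) stats::pnorm(R, mean, sd),
                kind = "gaussian", params = list(mean = mean, sd = sd),
                scale = "count")
}

#' @rdname threshold_cdf
#' @export
cdf_uniform <- function() {
  threshold_cdf(function(r) pmin(pmax(r, 0), 1), kind = "uniform")
}

#' @rdname threshold_cdf
#' @param at threshold location: `F` jumps from 0 to 1 at `x >= at`.
#' @export
cdf_step <- function(at, scale = c("count", "fraction")) {
  scale <- match.arg(scale)
  force(at)
  threshold_cdf(function(x) as.numeric(x >= at),
                kind = "step", params = list(at = at), scale = scale)
}

#' @rdname threshold_cdf
#' @param x,prob tabulated threshold values and cumulative probabilities;
#'   `prob` must be nondecreasing and inside `[0, 1]`.
#' @export
cdf_tabulated <- function(x, prob, scale = c("count", "fraction")) {
  scale <- match.arg(scale)
  if (length(x) != length(prob) || length(x) < 2L)
    stop_tip("need at least two (x, prob) pairs", "invalid_distribution")
  o <- order(x)
  x <- x[o]; prob <- prob[o]
  if (any(diff(prob) < 0) || any(prob < 0) || any(prob > 1))
    stop_tip("tabulated CDF must be nondecreasing with values in [0, 1]",
             "invalid_distribution")
  f <- stats::approxfun(x, prob, rule = 2, ties = "ordered")
  threshold_cdf(f, kind = "tabulated", params = list(x = x, prob = prob),
                scale = scale)
}

#' Evaluate a threshold CDF on the count scale
#'
#' Converts between the object's native scale and counts via `N`, so every
#' model layer can work with counts `R` in `[0, N]` regardless of how `F`
#' was specified. Use `N = 1` for a purely fractional model.
#'
#' @param F a [threshold_cdf].
#' @param R active counts (vectorised).
#' @param N population size used for scale conversion.
#' @return cumulative probabilities in `[0, 1]`.
#' @export
cdf_eval <- function(F, R, N) {
  stopifnot(inherits(F, "threshold_cdf"))
  if (F$scale == "count") F$fun(R) else F$fun(R / N)
}

#' Check that a threshold CDF is monotone with values in [0, 1]
#'
#' Samples `F` on a regular grid over `[0, N]` and signals an
#' `invalid_distribution` error if it decreases (beyond a tiny numerical
#' tolerance) or leaves `[0, 1]`.
#'
#' @inheritParams cdf_eval
#' @param n_grid number of sample points.
#' @return `F`, invisibly.
#' @export
validate_threshold_cdf <- function(F, N, n_grid = 201L) {
  v <- cdf_eval(F, seq(0, N, length.out = n_grid), N)
  if (anyNA(v) || any(v < -1e-9) || any(v > 1 + 1e-9))
    stop_tip("threshold CDF takes values outside [0, 1]",
             "invalid_distribution")
  if (any(diff(v) < -1e-9))
    stop_tip("threshold CDF is not monotone nondecreasing",
             "invalid_distribution")
  invisible(F)
}

#' @export
print.threshold_cdf <- function(x, ...) {
  ps <- x$params[!vapply(x$params, function(p) length(p) > 4, logical(1))]
  cat(sprintf("Threshold CDF <%s> on the %s scale", x$kind, x$scale))
  if (length(ps))
    cat(" (", paste(names(ps), vapply(ps, format, ""), sep = "=",
                    collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
as.function.threshold_cdf <- function(x, ...) x$fun

#' Read and write tabulated threshold CDFs
#'
#' Tabulated CDFs are exchanged as two-column CSV files with a header row:
#' the threshold value and the cumulative probability.
#'
#' @param path file path.
#' @inheritParams cdf_tabulated
#' @return `read_threshold_cdf()` returns a [threshold_cdf];
#'   `write_threshold_cdf()` returns `path`, invisibly.
#' @export
read_threshold_cdf <- function(path, scale = c("count", "fraction")) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L)
    stop_tip("expected a two-column CSV (threshold, cumulative probability)",
             "invalid_distribution")
  cdf_tabulated(d[[1L]], d[[2L]], scale = match.arg(scale))
}

#' @rdname read_threshold_cdf
#' @param F a tabulated [threshold_cdf].
#' @export
write_threshold_cdf <- function(F, path) {
  stopifnot(inherits(F, "threshold_cdf"), F$kind == "tabulated")
  utils::write.csv(
    data.frame(threshold = F$params$x, cumulative_probability = F$params$prob),
    path, row.names = FALSE)
  invisible(path)
}
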