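#' Partition a population into certain, contingent and never-acting groups
#'
#' The refined threshold model splits a population of size `N` into `A`
#' certainly acting individuals (active from the outset), `C = P - A`
#' contingent individuals (activate when enough others have), and `N - P`
#' certainly inactive individuals who never act. `P = A + C` is the
#' potentially acting group. Fractions `a = A/N`, `p = P/N`, `c = p - a`.
#'
#' Either counts (`A`, `P`) or fractions (`a`, `p`) may be supplied;
#' fractions are converted with `round(x * N)`.
#'
#' @param N total population size (positive count, or 1 for a purely
#'   fractional model).
#' @param A number of certainly acting individuals, `0 <= A <= P`.
#' @param P number of potentially acting individuals, `A <= P <= N`.
#' @param a,p fractional alternatives to `A` and `P`.
#' @return an object of class `"population_partition"` with fields
#'   `N`, `A`, `C`, `P` and the fractions `a`, `c`, `p`.
#' @examples
#' population_partition(100, A = 10, P = 60)
#' population_partition(1e4, a = 0.05, p = 0.56)
#' @export
population_partition <- function(N, A = NULL, P = NULL, a = NULL, p = NULL) {
  if (!is.numeric(N) || length(N) != 1L || N <= 0)
    stop_tip("N must be a single positive number", "partition_error")
  if (is.null(A)) {
    if (is.null(a)) stop_tip("supply A or a", "partition_error")
    A <- if (N == 1) a else round(a * N)
  }
  if (is.null(P)) {
    if (is.null(p)) stop_tip("supply P or p", "partition_error")
    P <- if (N == 1) p else round(p * N)
  }
  if (A < 0 || A > P || P > N)
    stop_tip(sprintf("need 0 <= A <= P <= N, got A=%g, P=%g, N=%g", A, P, N),
             "partition_error")
  structure(list(N = N, A = A, C = P - A, P = P,
                 a = A / N, c = (P - A) / N, p = P / N),
            class = "population_partition")
}

#' @export
print.population_partition <- function(x, ...) {
  cat(sprintf(
    "Population partition: N = %g\n  certainly acting  A = %g (a = %.4g)\n  contingent        C = %g (c = %.4g)\n  never acting    N-P = %g (p = %.4g)\n",
    x$N, x$A, x$a, x$C, x$c, x$N - x$P, x$p))
  invisible(x)
}

#' @export
format.population_partition <- function(x, ...) {
  sprintf("partition(N=%g, A=%g, P=%g)", x$N, x$A, x$P)
}
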