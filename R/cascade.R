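#' Assign certain, contingent and never-acting roles to network nodes
#'
#' Draws a uniform random subset of `P` nodes as potentially active, and
#' within it a uniform random subset of `A` nodes as certainly acting; the
#' remaining `P - A` potentially active nodes are contingent and all others
#' never act. Group sizes match the partition exactly in every draw.
#'
#' @param net a [social_network][er_network].
#' @param part a [population_partition] with `part$N == net$N`.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return an object of class `"group_assignment"`: a list with `labels`
#'   (factor with levels certain/contingent/never), `part` and `seed`.
#' @export
assign_groups <- function(net, part, seed = NULL) {
  stopifnot(inherits(net, "social_network"),
            inherits(part, "population_partition"))
  if (part$N != net$N)
    stop_tip("partition and network sizes differ", "partition_error")
  labels <- rep("never", net$N)
  with_seed(seed, {
    potential <- sample.int(net$N, part$P)
    certain <- if (part$A > 0) sample(potential, part$A) else integer(0)
    labels[potential] <- "contingent"
    labels[certain] <- "certain"
  })
  structure(list(labels = factor(labels,
                                 levels = c("certain", "contingent", "never")),
                 part = part, seed = seed),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  print(table(x$labels))
  invisible(x)
}

#' Run a synchronous threshold cascade on a network
#'
#' Starts with exactly the certainly acting nodes active (`R(0) = A`). In
#' each discrete time step, every contingent inactive node whose share of
#' active neighbours strictly exceeds the threshold fraction `rho` becomes
#' active; all nodes update synchronously; activation is irreversible.
#' Zero-degree contingent nodes never activate (their active share is 0 and
#' `0 > rho * 0` fails). The simulation stops when no node activates, i.e.
#' when `R(t) = R(t - 1)`, and that repeated value closes the trajectory.
#'
#' Ties never activate: at `rho = 0.5` a node with exactly half of its
#' neighbours active stays inactive, making 0.5 a true majority rule on even
#' degrees.
#'
#' @param net a [social_network][er_network].
#' @param groups a [group_assignment][assign_groups] for `net`.
#' @param rho threshold fraction in `[0, 1]`.
#' @param record_sets also store the per-step active-node index sets.
#' @return an object of class `"cascade_trajectory"`: a data frame with
#'   columns `t`, `R`, and attributes `t_max`, `r_star` (final active
#'   share), `N`, `part`, `rho`, `active` (final logical vector) and,
#'   if requested, `active_sets`.
#' @examples
#' net <- er_network(500, K = 8, seed = 3)
#' grp <- assign_groups(net, population_partition(500, a = 0.05, p = 0.6),
#'                      seed = 4)
#' run_cascade(net, grp, rho = 0.2)
#' @export
run_cascade <- function(net, groups, rho, record_sets = FALSE) {
  stopifnot(inherits(net, "social_network"),
            inherits(groups, "group_assignment"))
  check_rho(rho)
  if (length(groups$labels) != net$N)
    stop_tip("assignment and network sizes differ", "partition_error")
  active <- groups$labels == "certain"
  contingent <- groups$labels == "contingent"
  deg <- net$degree
  traj <- sum(active)
  sets <- if (record_sets) list(which(active))
  repeat {
    counts <- as.vector(net$adj %*% active)
    newly <- contingent & !active & strictly_exceeds(counts, rho * deg)
    active <- active | newly
    traj <- c(traj, sum(active))
    if (record_sets) sets <- c(sets, list(which(active)))
    if (!any(newly)) break
  }
  t_max <- length(traj) - 1L
  out <- data.frame(t = 0:t_max, R = traj)
  structure(out, t_max = t_max, r_star = traj[t_max + 1L] / net$N,
            N = net$N, part = groups$part, rho = rho, active = active,
            active_sets = sets,
            class = c("cascade_trajectory", "data.frame"))
}

#' @export
print.cascade_trajectory <- function(x, ...) {
  cat(sprintf(
    "Cascade: N = %d, rho = %g, stopped at t_max = %d, final share r* = %.4g\n",
    attr(x, "N"), attr(x, "rho"), attr(x, "t_max"), attr(x, "r_star")))
  invisible(x)
}

#' Ensemble sweep of final cascade sizes
#'
#' For every combination of certainly acting share `a`, potentially acting
#' share `p` (cells with `a > p` are dropped) and threshold fraction `rho`,
#' runs `n` independent replicates -- each with a freshly generated
#' Erdos-Renyi network and a fresh random group assignment -- and records
#' the final active share `r*`. Replicate seeds are derived deterministically
#' from the master seed via [replicate_seed()] (the group-assignment seed
#' uses master + 524287), so any single replicate can be rerun in isolation.
#'
#' @param N number of nodes per network.
#' @param K target mean degree (or supply `ell`).
#' @param rho_values threshold fractions to sweep.
#' @param a_values,p_values shares of certainly / potentially acting nodes.
#' @param n ensemble size per cell.
#' @param seed master seed.
#' @param ell linking probability alternative to `K`.
#' @param verbose report per-cell progress via `message()`.
#' @return an object of class `"cascade_sweep"`: a data frame with columns
#'   `a`, `p`, `rho`, `replicate`, `seed`, `r_star`, `t_max`.
#' @seealso [tipping_share()] for locating the transition in `a`.
#' @export
sweep_final_share <- function(N, K = NULL, rho_values, a_values, p_values,
                              n = 100L, seed = 1L, ell = NULL,
                              verbose = FALSE) {
  cells <- expand.grid(a = a_values, p = p_values, rho = rho_values,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[cells$a <= cells$p, , drop = FALSE]
  if (!nrow(cells)) stop_tip("no cells with a <= p", "parameter_error")
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    a <- cells$a[i]; p <- cells$p[i]; rho <- cells$rho[i]
    part <- population_partition(N, a = a, p = p)
    if (verbose)
      message(sprintf("cell %d/%d: a = %.4g, p = %.4g, rho = %.2g",
                      i, nrow(cells), a, p, rho))
    res <- vapply(seq_len(n), function(rep) {
      s_net <- replicate_seed(seed, i, rep)
      s_grp <- replicate_seed(seed + 524287, i, rep)
      net <- er_network(N, K = K, ell = ell, seed = s_net)
      grp <- assign_groups(net, part, seed = s_grp)
      tr <- run_cascade(net, grp, rho)
      c(s_net, attr(tr, "r_star"), attr(tr, "t_max"))
    }, numeric(3))
    rows[[i]] <- data.frame(a = a, p = p, rho = rho,
                            replicate = seq_len(n), seed = res[1L, ],
                            r_star = res[2L, ], t_max = res[3L, ])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, N = N, K = K, ell = ell, master_seed = seed,
            class = c("cascade_sweep", "data.frame"))
}

#' @export
summary.cascade_sweep <- function(object, ...) {
  agg <- stats::aggregate(r_star ~ a + p + rho, data = object,
                          FUN = function(x)
                            c(median = stats::median(x), mean = mean(x),
                              sd = stats::sd(x)))
  out <- cbind(agg[c("a", "p", "rho")], as.data.frame(agg$r_star))
  names(out) <- c("a", "p", "rho", "median_r_star", "mean_r_star",
                  "sd_r_star")
  out[order(out$rho, out$p, out$a), ]
}

#' Locate the microscopic tipping point in the certainly acting share
#'
#' From an ensemble sweep, finds for each `(p, rho)` cell the smallest `a`
#' at which the ensemble-median final share first exceeds `frac * p`,
#' i.e. the point at which the system tips from `r* ~ a` to a global
#' cascade `r* -> p`.
#'
#' @param sweep a [cascade_sweep][sweep_final_share].
#' @param frac fraction of `p` that counts as a global cascade.
#' @return a data frame with columns `p`, `rho`, `a_tip` (`NA` when no `a`
#'   in the sweep tips).
#' @export
tipping_share <- function(sweep, frac = 0.9) {
  s <- summary(sweep)
  cells <- unique(s[c("p", "rho")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- s[s$p == cells$p[i] & s$rho == cells$rho[i], ]
    sub <- sub[order(sub$a), ]
    hit <- which(sub$median_r_star > frac * sub$p)
    data.frame(p = cells$p[i], rho = cells$rho[i],
               a_tip = if (length(hit)) sub$a[hit[1L]] else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
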