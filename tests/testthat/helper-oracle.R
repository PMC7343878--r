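# Brute-force cascade reference: recomputes every node's active-neighbour
# share from the raw edge list at every step. Deliberately independent of
# the package's sparse-matrix implementation.
brute_cascade <- function(N, edges, labels, rho) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  active <- labels == "certain"
  traj <- sum(active)
  repeat {
    nxt <- active
    for (i in seq_len(N)) {
      if (labels[i] != "contingent" || active[i]) next
      nbr <- c(edges[edges[, 1L] == i, 2L], edges[edges[, 2L] == i, 1L])
      k <- length(nbr)
      if (k > 0L && sum(active[nbr]) / k > rho + 1e-12) nxt[i] <- TRUE
    }
    traj <- c(traj, sum(nxt))
    if (all(nxt == active)) break
    active <- nxt
  }
  list(R = traj, active = active)
}

# edge lists of the miniature test graphs (1-based ids)
tiny_graphs <- function() {
  list(
    star = list(N = 5L, edges = cbind(1L, 2:5),
                labels = c("certain", rep("contingent", 4L))),
    path = list(N = 3L, edges = rbind(c(1L, 2L), c(2L, 3L)),
                labels = c("certain", "contingent", "never")),
    complete = list(N = 4L, edges = t(combn(4L, 2L)),
                    labels = c("certain", rep("contingent", 3L))),
    two_cliques = list(
      N = 8L,
      edges = rbind(t(combn(1:4, 2L)), t(combn(5:8, 2L)), c(4L, 5L)),
      labels = c("certain", "certain", rep("contingent", 6L))),
    isolated = list(N = 2L, edges = matrix(integer(0), 0L, 2L),
                    labels = c("certain", "contingent")))
}

random_tiny_graph <- function(N, seed) {
  set.seed(seed)
  pairs <- t(combn(N, 2L))
  edges <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
  labels <- sample(c("certain", "contingent", "never"), N, replace = TRUE)
  if (!any(labels == "certain")) labels[1L] <- "certain"
  list(N = N, edges = edges, labels = labels)
}

# random monotone tabulated threshold CDF on [0, N]
random_tabulated_cdf <- function(N, seed) {
  set.seed(seed)
  x <- seq(0, N, length.out = 12L)
  p <- cumsum(runif(12L))
  p <- (p - p[1L]) / (p[12L] - p[1L])
  cdf_tabulated(x, p, scale = "count")
}
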