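#' Build a group assignment from explicit labels
#'
#' Deterministic alternative to [assign_groups()] for hand-built fixtures
#' and for labels read from file: takes a vector of `"certain"` /
#' `"contingent"` / `"never"` labels and derives the matching
#' [population_partition] from the counts.
#'
#' @param labels character vector (or factor) of per-node labels.
#' @return a [group_assignment][assign_groups].
#' @export
as_group_assignment <- function(labels) {
  labels <- factor(as.character(labels),
                   levels = c("certain", "contingent", "never"))
  if (anyNA(labels))
    stop_tip("labels must be 'certain', 'contingent' or 'never'",
             "partition_error")
  n <- tabulate(labels, 3L)
  part <- population_partition(length(labels), A = n[1L],
                               P = n[1L] + n[2L])
  structure(list(labels = labels, part = part, seed = NULL),
            class = "group_assignment")
}

config_defaults <- list(N = 1e5, K = 10, n = 100L, seed = 1L)

config_keys <- c("kind", "N", "K", "ell", "n", "seed", "rho", "rho_values",
                 "a", "p", "a_values", "p_values", "method", "grid_points",
                 "scan", "from", "to", "steps", "out_dir")

experiment_kinds <- c("simulate", "threshold-dist", "fixedpoints",
                      "bifurcation", "hysteresis", "figure2", "figure3",
                      "figure4")

#' Experiment configuration files
#'
#' Experiments are described by a small YAML mapping with a `kind` key
#' (`r paste(tipcascade:::experiment_kinds, collapse = ", ")`) plus model
#' parameters. Missing `N`, `K`, `n` and `seed` default to the reference
#' study conditions `N = 1e5`, `K = 10`, `n = 100`, `seed = 1`; unknown keys
#' are rejected by name, as is `a > p`. Configurations round-trip losslessly
#' through [save_config()] / [load_config()].
#'
#' @param path path of a YAML configuration file.
#' @return `load_config()` returns a validated named list of class
#'   `"experiment_config"`.
#' @examples
#' cfg <- as_experiment_config(list(kind = "fixedpoints", a = 0.16,
#'                                  p = 0.67, rho = 0.4))
#' @export
load_config <- function(path) {
  as_experiment_config(yaml::read_yaml(path))
}

#' @rdname load_config
#' @param config a named list of configuration values.
#' @export
as_experiment_config <- function(config) {
  if (is.null(config$kind) || !config$kind %in% experiment_kinds)
    stop_tip(paste0("config key 'kind' must be one of: ",
                    paste(experiment_kinds, collapse = ", ")),
             "config_error")
  unknown <- setdiff(names(config), config_keys)
  if (length(unknown))
    stop_tip(paste0("unknown config key(s): ",
                    paste(unknown, collapse = ", ")), "config_error")
  for (k in names(config_defaults))
    if (is.null(config[[k]])) config[[k]] <- config_defaults[[k]]
  if (!is.null(config$a) && !is.null(config$p) && any(config$a > config$p))
    stop_tip("config has a > p", "config_error")
  if (!is.null(config$rho)) check_rho(config$rho)
  structure(config, class = "experiment_config")
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run a configured experiment and write its outputs
#'
#' Dispatches a validated configuration to the matching model layer and
#' writes tidy CSV results, a JSON run manifest (parameters, master seed,
#' package version, wall time, output files) and a plain-text log into
#' `out_dir`. Reruns with the same configuration and seed produce
#' byte-identical result files.
#'
#' Kinds: `simulate` sweeps final cascade shares over `a_values` /
#' `p_values` / `rho_values`; `threshold-dist` tabulates an analytic
#' emergent threshold distribution (`method` of `poisson`, `gamma` or
#' `exact`); `fixedpoints` solves the analytic refined model at one
#' parameter set; `bifurcation` scans one parameter and reports branches
#' plus fold locations; `hysteresis` sweeps a parameter up and down;
#' `figure2`, `figure3` and `figure4` are scaled study presets built on the
#' same primitives (log-spaced `a` grids, near-equilibrium threshold
#' scatter, min-stable-fixed-point surface).
#'
#' @param config an [experiment_config][load_config] (or plain list).
#' @param out_dir output directory, created if missing.
#' @return the manifest, invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  config <- as_experiment_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat(sprintf("tipcascade experiment '%s'\n", config$kind), file = log_path)
  files <- switch(config$kind,
    "simulate" = , "figure2" = exp_sweep(config, out_dir, logf),
    "threshold-dist" = exp_threshold_dist(config, out_dir, logf),
    "fixedpoints" = exp_fixedpoints(config, out_dir, logf),
    "bifurcation" = exp_bifurcation(config, out_dir, logf),
    "hysteresis" = exp_hysteresis(config, out_dir, logf),
    "figure3" = exp_figure3(config, out_dir, logf),
    "figure4" = exp_figure4(config, out_dir, logf))
  manifest <- list(
    kind = config$kind,
    parameters = unclass(config),
    master_seed = config$seed,
    package_version = as.character(utils::packageVersion("tipcascade")),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_tidy_csv <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  basename(path)
}

exp_sweep <- function(cfg, out_dir, logf) {
  a_values <- cfg$a_values
  if (is.null(a_values)) {
    # study default: A log-spaced between 1 and N (30 points), as shares
    gp <- if (is.null(cfg$grid_points)) 30L else cfg$grid_points
    a_values <- exp(seq(log(1 / cfg$N), log(1), length.out = gp))
  }
  p_values <- if (!is.null(cfg$p_values)) cfg$p_values
              else if (!is.null(cfg$p)) cfg$p else 0.56
  rho_values <- if (!is.null(cfg$rho_values)) cfg$rho_values else cfg$rho
  sw <- sweep_final_share(cfg$N, K = cfg$K, ell = cfg$ell,
                          rho_values = rho_values,
                          a_values = a_values, p_values = p_values,
                          n = cfg$n, seed = cfg$seed)
  logf("sweep: %d runs over %d cell(s)", nrow(sw),
       nrow(unique(sw[c("a", "p", "rho")])))
  write_tidy_csv(sw, file.path(out_dir, "sweep.csv"))
}

exp_threshold_dist <- function(cfg, out_dir, logf) {
  method <- if (is.null(cfg$method)) "poisson" else cfg$method
  gp <- if (is.null(cfg$grid_points)) 101L else cfg$grid_points
  r <- seq(0, 1, length.out = gp)
  Fv <- switch(method,
    poisson = F_poisson(r, cfg$K, cfg$rho),
    gamma = F_gamma(r, cfg$K, cfg$rho),
    exact = F_exact(pmin(floor(r * cfg$N), cfg$N - 1), cfg$N,
                    if (is.null(cfg$ell)) cfg$K / (cfg$N - 1) else cfg$ell,
                    cfg$rho),
    stop_tip("method must be poisson, gamma or exact", "config_error"))
  logf("threshold-dist: method %s, %d grid points", method, gp)
  write_tidy_csv(
    data.frame(r = r, F = Fv, method = method, K = cfg$K, rho = cfg$rho),
    file.path(out_dir, "threshold_dist.csv"))
}

exp_fixedpoints <- function(cfg, out_dir, logf) {
  fps <- fixed_points(cfg$a, cfg$p, cfg$rho, cfg$K)
  logf("fixedpoints: %d root(s) at a=%g p=%g rho=%g K=%g", nrow(fps),
       cfg$a, cfg$p, cfg$rho, cfg$K)
  write_tidy_csv(as.data.frame(fps),
                 file.path(out_dir, "fixedpoints.csv"))
}

exp_bifurcation <- function(cfg, out_dir, logf) {
  vals <- seq(cfg$from, cfg$to, length.out = cfg$steps)
  fixed <- list(a = cfg$a, p = cfg$p, rho = cfg$rho, K = cfg$K)
  branches <- do.call(rbind, lapply(vals, function(v) {
    fps <- scan_fixed_points(cfg$scan, v, fixed, n_grid = 4001L)
    if (!nrow(fps)) return(NULL)
    data.frame(scan_value = v, r_star = fps$r_star,
               stability = fps$stability)
  }))
  folds <- saddle_node(cfg$scan, c(cfg$from, cfg$to), a = cfg$a, p = cfg$p,
                       rho = cfg$rho, K = cfg$K)
  logf("bifurcation in %s: %d fold(s)", cfg$scan, nrow(folds))
  f1 <- write_tidy_csv(branches, file.path(out_dir, "branches.csv"))
  jsonlite::write_json(as.data.frame(folds),
                       file.path(out_dir, "folds.json"),
                       auto_unbox = TRUE, digits = NA)
  c(f1, "folds.json")
}

exp_hysteresis <- function(cfg, out_dir, logf) {
  h <- hysteresis(cfg$scan, c(cfg$from, cfg$to), a = cfg$a, p = cfg$p,
                  rho = cfg$rho, K = cfg$K, steps = cfg$steps)
  logf("hysteresis in %s: loop area %.6g", cfg$scan, attr(h, "area"))
  write_tidy_csv(as.data.frame(h), file.path(out_dir, "hysteresis.csv"))
}

exp_figure3 <- function(cfg, out_dir, logf) {
  rho_values <- if (!is.null(cfg$rho_values)) cfg$rho_values
                else c(0.2, 0.5, 0.8)
  p_values <- if (!is.null(cfg$p_values)) cfg$p_values else c(0.56, 1)
  scatter <- list(); curves <- list(); cell <- 0L
  for (rho in rho_values) for (p in p_values)
    for (a in c(0.02, 0.05, 0.1, 0.2, 0.4) * p) {
      cell <- cell + 1L
      part <- population_partition(cfg$N, a = a, p = p)
      net <- er_network(cfg$N, K = cfg$K,
                        seed = replicate_seed(cfg$seed, cell, 1L))
      grp <- assign_groups(net, part,
                           seed = replicate_seed(cfg$seed + 524287, cell, 1L))
      tr <- run_cascade(net, grp, rho)
      pts <- empirical_threshold_curve(tr, part)
      scatter[[cell]] <- cbind(pts, a = a, p = p, rho = rho)
    }
  for (rho in rho_values) {
    r <- seq(0, 1, length.out = 101L)
    curves[[length(curves) + 1L]] <-
      data.frame(r = r, F = F_poisson(r, cfg$K, rho), rho = rho)
  }
  logf("figure3: %d scatter point(s), rho in {%s}",
       sum(vapply(scatter, nrow, integer(1))),
       paste(rho_values, collapse = ", "))
  c(write_tidy_csv(do.call(rbind, scatter),
                   file.path(out_dir, "empirical_thresholds.csv")),
    write_tidy_csv(do.call(rbind, curves),
                   file.path(out_dir, "analytic_thresholds.csv")))
}

exp_figure4 <- function(cfg, out_dir, logf) {
  a_values <- if (!is.null(cfg$a_values)) cfg$a_values
              else seq(0.01, 0.4, length.out = 40L)
  p_values <- if (!is.null(cfg$p_values)) cfg$p_values
              else seq(0.3, 1, length.out = 36L)
  s <- min_stable_surface(a_values, p_values, cfg$rho, cfg$K)
  tidy <- expand.grid(a = a_values, p = p_values, KEEP.OUT.ATTRS = FALSE)
  tidy$min_r_star <- as.vector(s)
  logf("figure4: %d x %d surface at rho=%g K=%g", length(a_values),
       length(p_values), cfg$rho, cfg$K)
  write_tidy_csv(tidy, file.path(out_dir, "min_stable_surface.csv"))
}

#' Write tiny hand-checkable cascade fixtures
#'
#' Generates a set of named miniature networks with group labels and a JSON
#' record of their hand-enumerated cascade outcomes: a 5-node star (one
#' certain centre, contingent leaves), a 3-node path probing the strict
#' tie rule, a 4-node complete graph, two 4-cliques joined by a single
#' bridge (two certain nodes seed one clique; at `rho = 0.6` the cascade
#' stays confined to it), and a 2-node edgeless graph whose zero-degree
#' contingent node can never activate. Each network is written as a
#' plain-text edge list (see [write_network()]) with a per-node label CSV.
#'
#' @param out_dir directory to write into (created if missing).
#' @return a named list of fixtures, invisibly; each has `net`, `labels`
#'   and `expected` (a list of `rho`, `r_star`, `t_max`).
#' @export
generate_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fx <- fixture_set()
  for (nm in names(fx)) {
    write_network(fx[[nm]]$net, file.path(out_dir, paste0(nm, ".edges")))
    utils::write.csv(
      data.frame(node = seq_len(fx[[nm]]$net$N) - 1L,
                 label = fx[[nm]]$labels),
      file.path(out_dir, paste0(nm, ".labels.csv")), row.names = FALSE,
      quote = FALSE)
  }
  jsonlite::write_json(lapply(fx, `[[`, "expected"),
                       file.path(out_dir, "expected.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fx)
}

# hand-enumerated miniature cascades; the expected entries are the oracle
fixture_set <- function() {
  fixture <- function(N, edges, labels, expected)
    list(net = network_from_edges(N, edges), labels = labels,
         expected = expected)
  list(
    star = fixture(
      5L, cbind(1L, 2:5),
      c("certain", rep("contingent", 4L)),
      list(list(rho = 0.5, r_star = 1, t_max = 2),
           list(rho = 0.99, r_star = 1, t_max = 2))),
    path = fixture(
      3L, rbind(c(1L, 2L), c(2L, 3L)),
      c("certain", "contingent", "never"),
      # the middle node's active share is exactly 1/2: a tie, no activation
      list(list(rho = 0.5, r_star = 1 / 3, t_max = 1),
           list(rho = 0.4, r_star = 2 / 3, t_max = 2))),
    complete = fixture(
      4L, t(utils::combn(4L, 2L)),
      c("certain", rep("contingent", 3L)),
      list(list(rho = 0.5, r_star = 1 / 4, t_max = 1),
           list(rho = 0.2, r_star = 1, t_max = 2))),
    two_cliques = fixture(
      8L, rbind(t(utils::combn(1:4, 2L)), t(utils::combn(5:8, 2L)),
                c(4L, 5L)),
      c("certain", "certain", rep("contingent", 6L)),
      # rho = 0.6: node 3 (share 2/3) then node 4 (3/4; its bridge edge
      # dilutes the first wave to 2/4) activate; the bridge head sees 1/4
      # and the cascade stays confined to the seeded clique
      list(list(rho = 0.6, r_star = 1 / 2, t_max = 3),
           list(rho = 0.8, r_star = 1 / 4, t_max = 1))),
    isolated = fixture(
      2L, matrix(integer(0), 0L, 2L),
      c("certain", "contingent"),
      # a zero-degree contingent node never activates, even at rho = 0
      list(list(rho = 0, r_star = 1 / 2, t_max = 1))))
}

#' @rdname generate_fixtures
#' @param path a `.labels.csv` file written by `generate_fixtures()`.
#' @export
read_groups <- function(path) {
  d <- utils::read.csv(path)
  as_group_assignment(d$label[order(d$node)])
}
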