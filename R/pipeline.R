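#' Seeded Fruchterman-Reingold layout
#'
#' Force-directed 2-D coordinates for a signed weighted network (attraction
#' along edges, repulsion between all node pairs, with a cooling
#' schedule), computed by igraph's Fruchterman-Reingold implementation on
#' the absolute edge weights and rescaled to the unit square. Deterministic
#' given `seed`. Layout is cosmetic: it never enters any statistic.
#'
#' @param weights Symmetric weight matrix (an `ising_network` is also
#'   accepted).
#' @param seed Integer seed.
#' @param iterations Number of force iterations.
#' @return Matrix of node coordinates in \[0, 1\]^2, one row per node.
#' @export
fruchterman_reingold <- function(weights, seed = 1L, iterations = 500L) {
  if (inherits(weights, "ising_network")) weights <- weights$weights
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) >= 1)
  if (is.null(rownames(weights)))
    dimnames(weights) <- list(paste0("V", seq_len(nrow(weights))),
                              paste0("V", seq_len(nrow(weights))))
  g <- igraph::graph_from_adjacency_matrix(abs(weights), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(as.integer(seed))
  if (nrow(weights) == 1L) {
    xy <- matrix(0.5, 1, 2)
  } else {
    xy <- igraph::layout_with_fr(g, niter = as.integer(iterations))
    rng <- apply(xy, 2L, function(c) diff(range(c)))
    for (k in 1:2)
      xy[, k] <- if (rng[k] > 0) (xy[, k] - min(xy[, k])) / rng[k] else 0.5
  }
  dimnames(xy) <- list(rownames(weights), c("x", "y"))
  xy
}

write_matrix_csv <- function(m, path) {
  df <- data.frame(node = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

write_edge_list <- function(weights, path) {
  idx <- which(upper.tri(weights) & weights != 0, arr.ind = TRUE)
  df <- data.frame(node_i = rownames(weights)[idx[, 1]],
                   node_j = colnames(weights)[idx[, 2]],
                   weight = weights[idx])
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full capital-violence network pipeline
#'
#' Orchestrates every stage — synthetic survey generation (or a supplied
#' binary dataset), Ising estimation, optional bootstrap, the sign split
#' into protection and risk networks, two-mode centralities and a seeded
#' layout — and writes every intermediate artifact plus a checksummed JSON
#' manifest to `out_dir`. Alternatively, when `weights` is supplied the
#' estimation stages are skipped and the mode-2 analysis runs directly on
#' that coefficient block (the published-table route).
#'
#' @param out_dir Output directory (created if needed).
#' @param data Optional `binary_dataset` to estimate from. If neither
#'   `data` nor `weights` is given, a planted-model dataset of `n` rows is
#'   simulated.
#' @param weights Optional factor x outcome coefficient matrix; skips
#'   estimation.
#' @param n Simulated sample size when no data is supplied.
#' @param seed Master seed for every stochastic stage.
#' @param gamma,rule Estimator settings, see [fit_nodewise()].
#' @param B Bootstrap replicates; 0 skips the bootstrap stage.
#' @param layout_iterations Force-layout iterations.
#' @return The manifest (named list), invisibly; written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(out_dir, data = NULL, weights = NULL, n = 1665L,
                         seed = 1L, gamma = 0.25, rule = "and", B = 0L,
                         layout_iterations = 500L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
  }
  if (is.null(weights)) {
    if (is.null(data)) {
      log_stage("simulate", "planted model, n = ", n, ", seed = ", seed)
      model <- make_planted_model(planted_design(), seed = seed)
      data <- sample_ising(model, n = n, seed = seed + 1L)
    }
    utils::write.csv(as.data.frame(data$values),
                     f <- file.path(out_dir, "binary_data.csv"),
                     row.names = FALSE)
    files <- c(files, f)
    log_stage("estimate", "gamma = ", gamma, ", rule = ", rule)
    net <- fit_nodewise(data, gamma = gamma, rule = rule)
    files <- c(files,
               write_matrix_csv(net$weights,
                                file.path(out_dir, "network_adjacency.csv")),
               write_edge_list(net$weights,
                               file.path(out_dir, "network_edges.csv")))
    if (B > 0) {
      log_stage("bootstrap", "B = ", B)
      bs <- bootstrap_networks(data, B = B, seed = seed + 2L,
                               gamma = gamma, rule = rule)
      utils::write.csv(stability_report(bs)$table,
                       f <- file.path(out_dir, "bootstrap_summary.csv"),
                       row.names = FALSE)
      files <- c(files, f)
    }
    weights <- extract_bipartite(net)
    layout_net <- net$weights
  } else {
    weights <- as.matrix(weights)
    layout_net <- rbind(cbind(matrix(0, nrow(weights), nrow(weights),
                                     dimnames = list(rownames(weights),
                                                     rownames(weights))),
                              weights),
                        cbind(t(weights),
                              matrix(0, ncol(weights), ncol(weights),
                                     dimnames = list(colnames(weights),
                                                     colnames(weights)))))
  }
  files <- c(files, write_matrix_csv(weights,
                                     file.path(out_dir, "bipartite_block.csv")))
  log_stage("mode2", "sign split + centrality")
  nets <- split_by_sign(weights)
  for (pol in c("protection", "risk")) {
    utils::write.csv(nets[[pol]]$edges,
                     f <- file.path(out_dir, paste0(pol, "_edges.csv")),
                     row.names = FALSE)
    files <- c(files, f)
    utils::write.csv(centrality_table(nets[[pol]]),
                     f <- file.path(out_dir, paste0("centrality_", pol,
                                                    ".csv")),
                     row.names = FALSE)
    files <- c(files, f)
  }
  log_stage("layout", "Fruchterman-Reingold, seed = ", seed)
  xy <- fruchterman_reingold(layout_net, seed = seed,
                             iterations = layout_iterations)
  files <- c(files, write_matrix_csv(xy, file.path(out_dir, "layout.csv")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("capnet")),
    seed = seed, gamma = gamma, rule = rule, B = B,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
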