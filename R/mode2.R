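#' Load a factor-by-outcome coefficient matrix
#'
#' Reads a CSV whose first column names the factors and whose remaining
#' columns are outcomes. With no arguments it loads the published 11 x 4
#' capital-by-violence coefficient table shipped with the package.
#'
#' @param path CSV path; default is the packaged coefficient table.
#' @return Numeric matrix, factors x outcomes, with dimnames.
#' @export
load_coefficient_matrix <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "capital_violence_coefficients.csv",
                        package = "capnet", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("coefficient matrix contains missing cells",
                     call. = FALSE)
  m
}

new_mode_two_network <- function(factors, outcomes, edges, polarity) {
  stopifnot(is.matrix(edges) || is.data.frame(edges))
  structure(list(mode_a = factors, mode_b = outcomes,
                 edges = edges, polarity = polarity),
            class = "mode_two_network")
}

#' @export
print.mode_two_network <- function(x, ...) {
  cat(sprintf("Two-mode %s network: %d factors, %d outcomes, %d edges\n",
              x$polarity, length(x$mode_a), length(x$mode_b),
              nrow(x$edges)))
  invisible(x)
}

#' Split a signed coefficient block into protection and risk networks
#'
#' Every strictly negative cell becomes an (unweighted) edge of the
#' protection network — a higher factor level accompanies a lower outcome
#' prevalence; every strictly positive cell becomes an edge of the risk
#' network. Zero cells create no edge in either. Weight magnitudes play no
#' further role after the split: the two-mode centralities below are
#' defined on the unweighted bipartite graphs.
#'
#' @param bipartite_weights Numeric factors x outcomes matrix with
#'   dimnames (e.g. from [extract_bipartite()] or
#'   [load_coefficient_matrix()]).
#' @return List with elements `protection` and `risk`, each a
#'   `mode_two_network` over all factors and outcomes.
#' @export
split_by_sign <- function(bipartite_weights) {
  w <- as.matrix(bipartite_weights)
  if (!all(is.finite(w))) stop("weights must be finite", call. = FALSE)
  if (is.null(rownames(w))) rownames(w) <- paste0("F", seq_len(nrow(w)))
  if (is.null(colnames(w))) colnames(w) <- paste0("O", seq_len(ncol(w)))
  edge_df <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    data.frame(factor = rownames(w)[idx[, 1]],
               outcome = colnames(w)[idx[, 2]],
               stringsAsFactors = FALSE)
  }
  list(protection = new_mode_two_network(rownames(w), colnames(w),
                                         edge_df(w < 0), "protection"),
       risk = new_mode_two_network(rownames(w), colnames(w),
                                   edge_df(w > 0), "risk"))
}

#' Geodesic distances on a two-mode network
#'
#' Breadth-first shortest-path distances over all factor and outcome nodes
#' of the bipartite graph. Unreachable pairs get a finite stand-in
#' distance: by default the maximum finite geodesic in the network plus
#' one (`unreachable = "diameter_plus_one"`), the convention that
#' reproduces the published centrality tables including isolated nodes;
#' alternatively the node count (`"order"`). A network with no edges at
#' all has no finite off-diagonal distance; by convention all off-diagonal
#' distances are then set to 1 (with a message).
#'
#' @param network A `mode_two_network`.
#' @param unreachable `"diameter_plus_one"` (default) or `"order"`.
#' @return Symmetric integer-valued distance matrix over all nodes,
#'   zero diagonal.
#' @export
geodesics <- function(network,
                      unreachable = c("diameter_plus_one", "order")) {
  stopifnot(inherits(network, "mode_two_network"))
  unreachable <- match.arg(unreachable)
  nodes <- c(network$mode_a, network$mode_b)
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(network$edges) > 0)
    g <- igraph::add_edges(g, rbind(network$edges$factor,
                                    network$edges$outcome))
  d <- igraph::distances(g)
  d <- d[nodes, nodes]
  off <- row(d) != col(d)
  finite <- is.finite(d) & off
  if (!any(finite)) {
    message("geodesics: network has no edges; ",
            "all off-diagonal distances set to 1 by convention")
    d[off] <- 1
    return(d)
  }
  fill <- if (unreachable == "diameter_plus_one") max(d[finite]) + 1
          else length(nodes)
  d[!is.finite(d)] <- fill
  d
}

#' Two-mode normalized degree
#'
#' A node's direct-tie count divided by the size of the opposite mode (the
#' maximum possible in a bipartite graph): factor degree / number of
#' outcomes, outcome degree / number of factors.
#'
#' @param network A `mode_two_network`.
#' @return Named numeric vector over all nodes (factors first), in
#'   \[0, 1\].
#' @export
two_mode_degree <- function(network) {
  stopifnot(inherits(network, "mode_two_network"))
  fc <- table(factor(network$edges$factor, levels = network$mode_a))
  oc <- table(factor(network$edges$outcome, levels = network$mode_b))
  stats::setNames(c(as.numeric(fc) / length(network$mode_b),
                    as.numeric(oc) / length(network$mode_a)),
                  c(network$mode_a, network$mode_b))
}

#' Two-mode normalized closeness
#'
#' Minimum-possible farness divided by actual farness. In a bipartite
#' graph the nearest a node can be to the rest is distance 1 to every
#' opposite-mode node and distance 2 to every same-mode node, so for a
#' node whose mode has `n_same` members and the other mode `n_other`, the
#' numerator is `n_other + 2 * (n_same - 1)`; the denominator is the sum
#' of its geodesic distances ([geodesics()], including the
#' unreachable-pair convention) to all other nodes.
#'
#' @param network A `mode_two_network`.
#' @param unreachable Passed to [geodesics()].
#' @return Named numeric vector over all nodes (factors first).
#' @export
two_mode_closeness <- function(network,
                               unreachable = "diameter_plus_one") {
  stopifnot(inherits(network, "mode_two_network"))
  d <- geodesics(network, unreachable = unreachable)
  n1 <- length(network$mode_a); n2 <- length(network$mode_b)
  numer <- c(rep(n2 + 2 * (n1 - 1), n1), rep(n1 + 2 * (n2 - 1), n2))
  farness <- rowSums(d)
  stats::setNames(numer / farness, rownames(d))
}

#' Centrality table of a two-mode network
#'
#' Degree and closeness for every node, laid out as in the published
#' tables: factors sorted by decreasing degree (ties by closeness, then
#' name), outcomes listed after the factors in the same order.
#'
#' @param network A `mode_two_network`.
#' @param unreachable Passed to [geodesics()].
#' @param digits Rounding for the `degree` / `closeness` display columns;
#'   full-precision values are kept in `degree_raw` / `closeness_raw`.
#' @return Data frame of class `centrality_table` with columns `node`,
#'   `mode`, `degree`, `closeness`, `degree_raw`, `closeness_raw`.
#' @export
centrality_table <- function(network, unreachable = "diameter_plus_one",
                             digits = 2L) {
  stopifnot(inherits(network, "mode_two_network"))
  deg <- two_mode_degree(network)
  clo <- two_mode_closeness(network, unreachable = unreachable)
  mode <- c(rep("factor", length(network$mode_a)),
            rep("outcome", length(network$mode_b)))
  df <- data.frame(node = names(deg), mode = mode,
                   degree = round(deg, digits),
                   closeness = round(clo, digits),
                   degree_raw = as.numeric(deg),
                   closeness_raw = as.numeric(clo),
                   stringsAsFactors = FALSE)
  f <- df[df$mode == "factor", ]
  o <- df[df$mode == "outcome", ]
  f <- f[order(-f$degree_raw, -f$closeness_raw, f$node), ]
  o <- o[order(-o$degree_raw, -o$closeness_raw, o$node), ]
  out <- rbind(f, o)
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}
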