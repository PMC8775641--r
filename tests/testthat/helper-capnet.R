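# Shared fixtures and independent oracles for the test suite.

# Small codebook: two yes/no violence items, one contact-frequency factor,
# two likert items (one egalitarian / reverse-coded).
toy_codebook <- function() {
  codebook(
    variable_spec("p1", "item", "binary"),
    variable_spec("p2", "item", "binary"),
    variable_spec("contact", "factor", "ordinal",
                  c("never", "yearly", "monthly", "weekly")),
    variable_spec("st1", "item", "likert"),
    variable_spec("st2", "item", "likert", reverse_coded = TRUE))
}

toy_survey <- function(values) {
  cb <- toy_codebook()
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(values, path, row.names = FALSE, na = "")
  read_survey(path, cb)
}

# Independent all-pairs shortest-path oracle: Floyd-Warshall on the
# bipartite adjacency, same unreachable convention as geodesics().
fw_distances <- function(network) {
  nodes <- c(network$mode_a, network$mode_b)
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(network$edges))) {
    a <- network$edges$factor[i]; b <- network$edges$outcome[i]
    d[a, b] <- d[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  off <- row(d) != col(d)
  finite <- is.finite(d) & off
  if (!any(finite)) { d[off] <- 1; return(d) }
  d[!is.finite(d)] <- max(d[finite]) + 1
  d
}

# Random bipartite mode-two network with n1 factors, n2 outcomes.
random_mode_two <- function(n1, n2, p_edge = 0.3) {
  f <- paste0("f", seq_len(n1)); o <- paste0("o", seq_len(n2))
  grid <- expand.grid(factor = f, outcome = o, stringsAsFactors = FALSE)
  edges <- grid[stats::runif(nrow(grid)) < p_edge, , drop = FALSE]
  w <- matrix(0, n1, n2, dimnames = list(f, o))
  for (i in seq_len(nrow(edges))) w[edges$factor[i], edges$outcome[i]] <- -1
  split_by_sign(w)$protection
}

# Tiny deterministic binary dataset with an x1-x2 association.
toy_binary_data <- function(n = 400, seed = 11) {
  set.seed(seed)
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rbinom(n, 1, plogis(-1 + 2 * x1))
  x3 <- rbinom(n, 1, 0.4)
  m <- cbind(a = x1, b = x2, c = x3)
  structure(list(values = m,
                 roles = c(a = "factor", b = "factor", c = "factor"),
                 names = colnames(m)),
            class = "binary_dataset")
}
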