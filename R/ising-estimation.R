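#' L1-penalized logistic regression path
#'
#' Fits, for each penalty value, the lasso-penalized logistic regression of
#' one node on the remaining nodes: maximize
#' `loglik/n - lambda * sum(|beta|)` with an unpenalized intercept and no
#' predictor standardization (predictors are already 0/1). The default grid
#' is 50 log-spaced values from `lambda_max` (the smallest penalty that
#' zeroes every slope, `max |x_k'(y - mean(y))| / n`) down to
#' `0.01 * lambda_max`. Fitting is delegated to glmnet with convergence
#' tolerance 1e-7 and an iteration cap of 1e4; results are deterministic
#' for fixed input.
#'
#' @param y Binary 0/1 response (non-constant).
#' @param X Binary predictor matrix (columns non-constant).
#' @param lambdas Optional explicit grid, strictly decreasing and positive.
#' @param nlambda,lambda_min_ratio Grid size and lower endpoint relative to
#'   `lambda_max` (used when `lambdas` is NULL).
#' @return List with `lambdas`, `coefficients` (grid x ncol(X)),
#'   `intercepts`, `loglik` (per-lambda Bernoulli log-likelihood) and
#'   `lambda_max`.
#' @export
logistic_lasso_path <- function(y, X, lambdas = NULL, nlambda = 50L,
                                lambda_min_ratio = 0.01) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("response is constant; cannot fit", call. = FALSE)
  const <- which(apply(X, 2L, function(c) length(unique(c)) < 2L))
  if (length(const))
    stop("constant predictor column(s): ",
         paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  n <- length(y)
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
  if (is.null(lambdas)) {
    lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                       length.out = nlambda))
  } else {
    if (any(lambdas <= 0) || any(diff(lambdas) >= 0))
      stop("'lambdas' must be positive and strictly decreasing",
           call. = FALSE)
  }
  if (ncol(X) == 1L) {
    sol <- vapply(lambdas, function(l) lasso_logistic_1d(y, X[, 1], l),
                  numeric(2))
    a0 <- sol[1, ]
    beta <- matrix(sol[2, ], ncol = 1, dimnames = list(NULL, colnames(X)))
    fit <- list(lambda = lambdas)
  } else {
    fit <- glmnet::glmnet(X, y, family = "binomial", lambda = lambdas,
                          standardize = FALSE, thresh = 1e-7, maxit = 1e4)
    beta <- t(as.matrix(fit$beta))      # grid x p
    a0 <- as.numeric(fit$a0)
  }
  beta[abs(beta) < 1e-10] <- 0          # numerical zeros at the KKT boundary
  eta <- sweep(X %*% t(beta), 2L, a0, `+`)   # n x grid
  ll <- colSums(y * eta - log1p(exp(eta)))
  list(lambdas = fit$lambda, coefficients = beta, intercepts = a0,
       loglik = as.numeric(ll), lambda_max = lambda_max)
}

# Exact penalized MLE for logistic regression on one binary predictor
# (glmnet requires >= 2 columns). With x in {0,1} the fit depends on the
# 2x2 table only: stationarity gives fitted group-1 success probability
# p1 = (k1 - n*lambda*s)/n1 (shrunk toward the pooled rate) and total
# fitted successes equal to observed, where s is the sign of the
# unpenalized slope; the slope is 0 whenever lambda >= |x'(y - ybar)|/n.
lasso_logistic_1d <- function(y, x, lambda) {
  if (!all(x %in% c(0, 1)))
    stop("single-predictor path requires a binary predictor", call. = FALSE)
  n <- length(y)
  n1 <- sum(x == 1); n0 <- n - n1
  k1 <- sum(y[x == 1]); k0 <- sum(y) - k1
  ybar <- (k0 + k1) / n
  if (abs(k1 - n1 * ybar) / n <= lambda + 1e-15)
    return(c(stats::qlogis(min(max(ybar, 1e-12), 1 - 1e-12)), 0))
  s <- sign(k1 / n1 - k0 / n0)
  clamp <- function(p) min(max(p, 1e-12), 1 - 1e-12)
  p1 <- clamp((k1 - n * lambda * s) / n1)
  p0 <- clamp((k0 + k1 - n1 * p1) / n0)
  a <- stats::qlogis(p0)
  b <- stats::qlogis(p1) - a
  if (sign(b) != s) return(c(stats::qlogis(clamp(ybar)), 0))
  c(a, b)
}

#' Extended Bayesian Information Criterion
#'
#' `-2 * loglik + k * log(n) + 2 * gamma * k * log(p_neighbors)`, where k
#' counts nonzero slopes and `p_neighbors` the candidate predictors. With
#' `gamma = 0` this reduces to the ordinary BIC.
#'
#' @param loglik Model log-likelihood.
#' @param k Nonzero slope count.
#' @param n Sample size.
#' @param p_neighbors Number of candidate predictors.
#' @param gamma EBIC hyperparameter (sparsity vs fit).
#' @return Scalar EBIC (vectorized over `loglik`/`k`).
#' @export
ebic <- function(loglik, k, n, p_neighbors, gamma = 0.25) {
  stopifnot(n >= 1, all(k >= 0))
  -2 * loglik + k * log(n) + 2 * gamma * k * log(p_neighbors)
}

#' Estimate a signed Ising network (eLasso)
#'
#' Regresses every node on all others by [logistic_lasso_path()], selects
#' each node's penalty by minimum [ebic()] (ties broken toward the first
#' index in descending-lambda order, i.e. the sparser end of the path), and
#' symmetrizes the directed slope estimates: under the AND rule an edge
#' exists only if both directed slopes are nonzero, under OR if either is.
#' Edge weights are the average of the two directed slopes. Setting
#' `gamma = 0` (BIC selection) or lowering `lambda_min_ratio` approximates
#' the denser fits some published applications appear to use.
#'
#' @param data A `binary_dataset` (no constant columns).
#' @param gamma EBIC hyperparameter, default 0.25.
#' @param rule `"and"` (default) or `"or"` symmetrization.
#' @param nlambda,lambda_min_ratio Passed to [logistic_lasso_path()].
#' @return An `ising_network`: symmetric zero-diagonal `weights` matrix,
#'   node `names` and `roles`, the `rule` and `gamma` used, and the
#'   per-node selected lambda.
#' @export
fit_nodewise <- function(data, gamma = 0.25, rule = c("and", "or"),
                         nlambda = 50L, lambda_min_ratio = 0.01) {
  rule <- match.arg(rule)
  stopifnot(inherits(data, "binary_dataset"))
  m <- data$values
  p <- ncol(m)
  if (p < 2L) stop("need at least 2 columns", call. = FALSE)
  const <- colnames(m)[apply(m, 2L, function(c) length(unique(c)) < 2L)]
  if (length(const))
    stop("constant column(s): ", paste(const, collapse = ", "),
         call. = FALSE)
  if (nrow(m) <= p)
    warning("fewer rows than variables; estimates will be unstable")
  directed <- matrix(0, p, p, dimnames = list(colnames(m), colnames(m)))
  sel_lambda <- numeric(p)
  for (j in seq_len(p)) {
    path <- logistic_lasso_path(m[, j], m[, -j, drop = FALSE],
                                nlambda = nlambda,
                                lambda_min_ratio = lambda_min_ratio)
    k <- rowSums(path$coefficients != 0)
    crit <- ebic(path$loglik, k, nrow(m), p - 1L, gamma)
    pick <- which.min(crit)   # first index on ties (descending lambda)
    directed[j, -j] <- path$coefficients[pick, ]
    sel_lambda[j] <- path$lambdas[pick]
  }
  avg <- (directed + t(directed)) / 2
  present <- if (rule == "and") directed != 0 & t(directed) != 0
             else directed != 0 | t(directed) != 0
  weights <- ifelse(present, avg, 0)
  diag(weights) <- 0
  structure(list(names = colnames(m),
                 roles = data$roles,
                 weights = weights,
                 directed = directed,
                 rule = rule, gamma = gamma,
                 selected_lambda = stats::setNames(sel_lambda, colnames(m))),
            class = "ising_network")
}

#' @export
print.ising_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("Ising network:", length(x$names), "nodes,", ne, "edges (",
      toupper(x$rule), "rule, gamma =", x$gamma, ")\n")
  invisible(x)
}

#' Factor-by-outcome coefficient block
#'
#' Extracts the submatrix of network weights between factor nodes (rows)
#' and outcome nodes (columns) — the analogue of the published
#' capital-by-violence coefficient table. Factor-factor and
#' outcome-outcome edges stay in the parent network but are excluded here.
#'
#' @param network An `ising_network` with node roles assigned.
#' @return Numeric matrix, factors x outcomes.
#' @export
extract_bipartite <- function(network) {
  stopifnot(inherits(network, "ising_network"))
  roles <- network$roles
  if (is.null(roles)) stop("network has no node roles", call. = FALSE)
  f <- network$names[roles == "factor"]
  o <- network$names[roles == "outcome"]
  if (!length(f) || !length(o))
    stop("need at least one factor and one outcome node", call. = FALSE)
  network$weights[f, o, drop = FALSE]
}
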