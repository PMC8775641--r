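#' Nonparametric bootstrap of the network estimator
#'
#' Resamples respondents (rows) with replacement B times, refits the full
#' nodewise estimator on every replicate, and summarizes per-edge weight
#' stability. Replicates in which any column becomes constant cannot be
#' estimated; they are dropped and counted, not redrawn. Replicate b draws
#' its resample indices under seed `seed + b`, so runs are reproducible and
#' replicates could be recomputed independently.
#'
#' @param data A `binary_dataset` valid for [fit_nodewise()].
#' @param B Number of bootstrap replicates (the motivating analysis used
#'   1000).
#' @param seed Master integer seed.
#' @param gamma,rule,... Passed to [fit_nodewise()].
#' @param indices Optional list of explicit row-index vectors (length-B),
#'   overriding random resampling — used for diagnostics such as the
#'   identity resample, where the summary must reproduce the sample
#'   estimate exactly.
#' @return A `bootstrap_summary`: per-edge table (`edges`) with sample
#'   weight, bootstrap mean, 2.5%/97.5% quantiles and inclusion proportion
#'   over retained replicates, plus counts `B`, `B_retained`, `B_dropped`.
#' @export
bootstrap_networks <- function(data, B = 1000L, seed = 1L, gamma = 0.25,
                               rule = c("and", "or"), indices = NULL, ...) {
  rule <- match.arg(rule)
  stopifnot(inherits(data, "binary_dataset"), B >= 1)
  sample_net <- fit_nodewise(data, gamma = gamma, rule = rule, ...)
  p <- length(sample_net$names)
  pair_idx <- which(upper.tri(sample_net$weights), arr.ind = TRUE)
  n <- nrow(data$values)
  boot_w <- matrix(NA_real_, B, nrow(pair_idx))
  retained <- logical(B)
  for (b in seq_len(B)) {
    idx <- if (!is.null(indices)) indices[[b]] else {
      set.seed(as.integer(seed) + b)
      sample.int(n, n, replace = TRUE)
    }
    rep_data <- structure(list(values = data$values[idx, , drop = FALSE],
                               roles = data$roles, names = data$names),
                          class = "binary_dataset")
    net_b <- tryCatch(
      suppressWarnings(fit_nodewise(rep_data, gamma = gamma, rule = rule,
                                    ...)),
      error = function(e) NULL)
    if (is.null(net_b)) next
    retained[b] <- TRUE
    boot_w[b, ] <- net_b$weights[pair_idx]
  }
  if (!any(retained))
    stop("all ", B, " bootstrap replicates were degenerate ",
         "(a column became constant in every resample)", call. = FALSE)
  w <- boot_w[retained, , drop = FALSE]
  qs <- apply(w, 2L, stats::quantile, probs = c(0.025, 0.975))
  edges <- data.frame(
    node_i = sample_net$names[pair_idx[, 1]],
    node_j = sample_net$names[pair_idx[, 2]],
    sample_weight = sample_net$weights[pair_idx],
    boot_mean = colMeans(w),
    boot_q025 = qs[1, ],
    boot_q975 = qs[2, ],
    inclusion_proportion = colMeans(w != 0),
    stringsAsFactors = FALSE)
  structure(list(edges = edges, B = as.integer(B),
                 B_retained = sum(retained),
                 B_dropped = sum(!retained),
                 network = sample_net, seed = as.integer(seed)),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("Bootstrap summary:", x$B_retained, "of", x$B, "replicates retained",
      sprintf("(%d dropped as degenerate)\n", x$B_dropped))
  nz <- x$edges[x$edges$sample_weight != 0, ]
  cat("  ", nrow(nz), "sample edges; mean |boot - sample| =",
      signif(mean(abs(nz$boot_mean - nz$sample_weight)), 3), "\n")
  invisible(x)
}

#' Edge-stability report
#'
#' Tabulates the bootstrap summary sorted by decreasing absolute sample
#' weight and returns the paired sample-vs-bootstrap-mean series used for
#' the classic stability overlay (sample estimate as one line, bootstrap
#' mean as the other).
#'
#' @param summary A `bootstrap_summary`.
#' @return List with `table` (sorted per-edge data frame) and `overlay`
#'   (data frame of rank, sample weight, bootstrap mean).
#' @export
stability_report <- function(summary) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  tab <- summary$edges[order(-abs(summary$edges$sample_weight)), ]
  rownames(tab) <- NULL
  overlay <- data.frame(rank = seq_len(nrow(tab)),
                        sample = tab$sample_weight,
                        boot_mean = tab$boot_mean)
  list(table = tab, overlay = overlay)
}
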