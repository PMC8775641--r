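#' Ising model parameters
#'
#' Container for a binary ({0,1}-state) Markov random field: per-node
#' thresholds tau and a symmetric zero-diagonal coupling matrix omega. The
#' unnormalized log-probability of a state x is
#' `sum(tau * x) + sum_{i<j} omega[i,j] x_i x_j`, which matches the
#' logistic-regression parameterization used by the nodewise estimator
#' (each slope estimates the corresponding coupling directly). The
#' {-1,+1}-domain equivalent has couplings omega/4 and thresholds
#' `tau/2 + rowSums(omega)/4`.
#'
#' @param thresholds Numeric vector tau, length p.
#' @param couplings p x p symmetric numeric matrix, zero diagonal.
#' @param names Node identifiers (default V1..Vp).
#' @param roles Optional per-node roles (`"factor"`/`"outcome"`).
#' @return An object of class `ising_params`.
#' @export
ising_parameters <- function(thresholds, couplings, names = NULL,
                             roles = NULL) {
  couplings <- as.matrix(couplings)
  p <- length(thresholds)
  stopifnot(nrow(couplings) == p, ncol(couplings) == p)
  if (max(abs(couplings - t(couplings))) > 1e-10)
    stop("coupling matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(couplings)) > 0))
    stop("coupling matrix must have zero diagonal", call. = FALSE)
  if (is.null(names)) names <- paste0("V", seq_len(p))
  dimnames(couplings) <- list(names, names)
  structure(list(names = names, thresholds = stats::setNames(thresholds, names),
                 couplings = couplings, roles = roles),
            class = "ising_params")
}

#' @export
print.ising_params <- function(x, ...) {
  cat("Ising parameters:", length(x$names), "nodes,",
      sum(x$couplings[upper.tri(x$couplings)] != 0), "nonzero couplings\n")
  invisible(x)
}

#' Exact state distribution of a small Ising model
#'
#' Enumerates all 2^p states and returns their Boltzmann probabilities
#' `P(x) = exp(sum(tau x) + sum_{i<j} omega_ij x_i x_j) / Z`. Intended as an
#' exactness oracle for the Gibbs sampler; refuses p > 15.
#'
#' @param params An [ising_parameters()] object.
#' @return Data frame with one row per state: the p state columns and `prob`.
#' @export
enumerate_distribution <- function(params) {
  stopifnot(inherits(params, "ising_params"))
  p <- length(params$names)
  if (p > 15L)
    stop("enumeration limited to p <= 15 (2^p states); got p = ", p,
         call. = FALSE)
  states <- as.matrix(expand.grid(rep(list(0:1), p), KEEP.OUT.ATTRS = FALSE))
  colnames(states) <- params$names
  logw <- states %*% params$thresholds +
    rowSums((states %*% params$couplings) * states) / 2
  w <- exp(logw - max(logw))
  out <- as.data.frame(states)
  out$prob <- as.numeric(w / sum(w))
  out
}

#' Gibbs-sample an Ising model
#'
#' Draws n rows from the model by sequential-scan Gibbs sampling with full
#' conditionals `P(x_j = 1 | rest) = plogis(tau_j + sum_k omega_jk x_k)`.
#' The defaults (200 burn-in sweeps, one retained row per 10 sweeps) mix
#' well at the coupling magnitudes used here and are verified against
#' [enumerate_distribution()] in the test suite.
#'
#' @param params An [ising_parameters()] object.
#' @param n Number of rows to retain.
#' @param seed Integer RNG seed.
#' @param burn_in Burn-in sweeps before the first retained row.
#' @param thin Sweeps between retained rows.
#' @return A `binary_dataset`; roles taken from `params$roles` (default all
#'   `"factor"`). Columns may be constant for extreme parameters — checked
#'   downstream by the estimator, not here.
#' @export
sample_ising <- function(params, n, seed, burn_in = 200L, thin = 10L) {
  stopifnot(inherits(params, "ising_params"), n >= 1, burn_in >= 1, thin >= 1)
  set.seed(as.integer(seed))
  m <- .gibbs_sample(as.numeric(params$thresholds), params$couplings,
                     as.integer(n), as.integer(burn_in), as.integer(thin))
  colnames(m) <- params$names
  roles <- if (is.null(params$roles))
    rep("factor", length(params$names)) else params$roles
  structure(list(values = m, roles = stats::setNames(roles, params$names),
                 names = params$names), class = "binary_dataset")
}

#' Reference sign pattern for the planted factor-outcome block
#'
#' Signs of the published 11 x 4 capital-by-violence coefficient matrix
#' shipped with the package (21 negative, 23 positive cells).
#'
#' @return Integer matrix in \{-1, 0, +1\}, factors x outcomes.
#' @export
reference_sign_pattern <- function() {
  w <- load_coefficient_matrix()
  sign(w)
}

#' Planted bipartite Ising design
#'
#' Describes a ground-truth model for estimator validation: `n_factors`
#' factor nodes, `n_outcomes` outcome nodes, a signed factor x outcome
#' coupling pattern of magnitude `effect_size`, and optionally a fraction
#' of nonzero factor-factor couplings (magnitude `effect_size / 2`,
#' random sign).
#'
#' @param n_factors,n_outcomes Node counts (defaults 11 and 4).
#' @param bipartite_signs `n_factors x n_outcomes` matrix in \{-1,0,+1\};
#'   defaults to [reference_sign_pattern()].
#' @param effect_size Positive coupling magnitude.
#' @param within_block_density Fraction of factor-factor pairs coupled
#'   (default 0: the bipartite block is the object under study).
#' @param outcome_prevalence Target marginal probabilities for the outcome
#'   nodes, used for threshold calibration; defaults to the study
#'   prevalences of the four violence spheres.
#' @return An object of class `planted_design`.
#' @export
planted_design <- function(n_factors = 11L, n_outcomes = 4L,
                           bipartite_signs = NULL, effect_size = 0.5,
                           within_block_density = 0,
                           outcome_prevalence = c(0.17, 0.059, 0.12, 0.064)) {
  stopifnot(n_factors >= 1, n_outcomes >= 1, effect_size >= 0,
            within_block_density >= 0, within_block_density <= 1)
  if (is.null(bipartite_signs)) {
    bipartite_signs <- reference_sign_pattern()
    if (n_factors != nrow(bipartite_signs) ||
        n_outcomes != ncol(bipartite_signs))
      stop("give 'bipartite_signs' explicitly for non-default dimensions",
           call. = FALSE)
  }
  bipartite_signs <- as.matrix(bipartite_signs)
  stopifnot(nrow(bipartite_signs) == n_factors,
            ncol(bipartite_signs) == n_outcomes,
            all(bipartite_signs %in% c(-1, 0, 1)))
  outcome_prevalence <- rep_len(outcome_prevalence, n_outcomes)
  structure(list(n_factors = as.integer(n_factors),
                 n_outcomes = as.integer(n_outcomes),
                 bipartite_signs = bipartite_signs,
                 effect_size = effect_size,
                 within_block_density = within_block_density,
                 outcome_prevalence = outcome_prevalence),
            class = "planted_design")
}

#' Build a planted Ising model from a design
#'
#' Assembles the coupling matrix (bipartite block = signs * effect_size;
#' optional random factor-factor couplings) and calibrates thresholds so
#' that factor nodes have marginal prevalence near 0.5 and outcome nodes
#' near their target prevalences. Calibration starts from the mean-field
#' solution `tau_j = logit(p_j) - sum_k omega_jk p_k` and refines it with a
#' few short pilot Gibbs runs.
#'
#' @param design A [planted_design()].
#' @param seed Integer seed (drives factor-factor placement and pilots).
#' @param calibrate Number of pilot refinement rounds (0 = mean-field only).
#' @return An [ising_parameters()] object with roles assigned.
#' @export
make_planted_model <- function(design, seed, calibrate = 4L) {
  stopifnot(inherits(design, "planted_design"))
  nf <- design$n_factors; no <- design$n_outcomes
  p <- nf + no
  names <- c(paste0("F", seq_len(nf)), paste0("O", seq_len(no)))
  if (!is.null(rownames(design$bipartite_signs)))
    names[seq_len(nf)] <- rownames(design$bipartite_signs)
  if (!is.null(colnames(design$bipartite_signs)))
    names[nf + seq_len(no)] <- colnames(design$bipartite_signs)
  omega <- matrix(0, p, p)
  omega[seq_len(nf), nf + seq_len(no)] <-
    design$bipartite_signs * design$effect_size
  set.seed(as.integer(seed))
  if (design$within_block_density > 0 && nf > 1) {
    pairs <- which(upper.tri(matrix(0, nf, nf)), arr.ind = TRUE)
    on <- stats::runif(nrow(pairs)) < design$within_block_density
    sgn <- sample(c(-1, 1), nrow(pairs), replace = TRUE)
    for (i in which(on))
      omega[pairs[i, 1], pairs[i, 2]] <- sgn[i] * design$effect_size / 2
  }
  omega <- omega + t(omega)
  target <- c(rep(0.5, nf), design$outcome_prevalence)
  tau <- stats::qlogis(target) - omega %*% target
  params <- ising_parameters(as.numeric(tau), omega, names,
                             roles = c(rep("factor", nf), rep("outcome", no)))
  for (r in seq_len(calibrate)) {
    pilot <- sample_ising(params, n = 2000L, seed = seed + r,
                          burn_in = 100L, thin = 2L)
    phat <- pmin(pmax(colMeans(pilot$values), 0.01), 0.99)
    params$thresholds <- params$thresholds +
      stats::qlogis(target) - stats::qlogis(phat)
  }
  params
}

#' Default marginal specification for the survey-like generator
#'
#' Per-variable category probabilities emulating the study sample: the four
#' sphere indicators at their reported prevalences (17%, 5.9%, 12%, 6.4%),
#' six network-contact frequencies and thirteen stereotype items at their
#' published category frequencies (renormalized where rows of the source
#' tables do not sum to 100%), socio-economic level and educational levels
#' at their published distribution, and package-chosen distributions for
#' the two marginals the source does not print (economic dependence,
#' partner education).
#'
#' Contact frequencies are coded in increasing order never < yearly <
#' monthly < weekly, so that a median split reads as "more frequent
#' contact".
#'
#' @return A named list; each element has `role`, `level`, `categories`,
#'   `probs` and (likert items) `reverse_coded`.
#' @export
default_survey_margins <- function() {
  freq_cats <- c("never", "once per year", "once per month", "once per week")
  # published contact frequencies, reordered to never/year/month/week
  contact <- list(
    family         = c(1.9, 2.4, 5.3, 90.2),
    family_similar = c(7.7, 2.1, 12.1, 77.7),
    friends        = c(6.6, 2.8, 16.5, 73.8),
    neighbors      = c(24.1, 4.9, 15.6, 55.3),
    religious      = c(69.0, 9.6, 6.6, 14.4),
    others         = c(75.7, 1.2, 3.5, 9.3))
  likert_cats <- c("strongly disagree", "disagree", "indifferent",
                   "agree", "strongly agree")
  stereo <- list(
    st01 = c(29.2, 48.8, 6.8, 12.2, 2.9),
    st02 = c(25.0, 43.0, 6.4, 19.7, 6.0),
    st03 = c(30.1, 51.9, 5.4, 9.9, 2.7),
    st04 = c(36.4, 51.3, 4.5, 5.9, 1.9),
    st05 = c(39.9, 49.4, 3.4, 5.8, 1.4),
    st06 = c(5.5, 11.7, 2.2, 43.3, 37.3),   # egalitarian wording
    st07 = c(3.9, 7.6, 1.8, 44.7, 42.0),    # egalitarian wording
    st08 = c(38.8, 52.5, 2.6, 4.5, 1.6),
    st09 = c(52.4, 45.5, 1.0, 1.0, 0.2),
    st10 = c(37.1, 48.2, 3.5, 8.5, 2.8),
    st11 = c(53.6, 44.6, 0.8, 0.9, 0.1),
    st12 = c(35.3, 40.2, 3.4, 17.5, 3.7),
    st13 = c(55.4, 43.3, 0.8, 0.4, 0.2))
  edu_cats <- c("no studies", "grade school", "secondary school",
                "technical professional", "university", "postgraduate")
  edu_probs <- c(0.1, 5.0, 47.6, 16.4, 30.4, 0.4)
  spec <- list()
  outc <- c(sv_public = 0.17, sv_work = 0.059, sv_partner = 0.12,
            sv_educational = 0.064)
  for (nm in names(outc))
    spec[[nm]] <- list(role = "outcome", level = "binary",
                       categories = c("no", "yes"),
                       probs = c(1 - outc[[nm]], outc[[nm]]))
  for (nm in names(contact))
    spec[[paste0("net_", nm)]] <- list(role = "factor", level = "ordinal",
                                       categories = freq_cats,
                                       probs = contact[[nm]] / sum(contact[[nm]]))
  spec$ses <- list(role = "factor", level = "ordinal",
                   categories = c("low", "medium", "high"),
                   probs = c(51.0, 41.3, 7.7) / 100)
  spec$econ_dependence <- list(role = "factor", level = "ordinal",
                               categories = c("low", "medium", "high"),
                               probs = c(0.4, 0.35, 0.25))
  spec$education <- list(role = "factor", level = "ordinal",
                         categories = edu_cats,
                         probs = edu_probs / sum(edu_probs))
  spec$partner_education <- list(role = "factor", level = "ordinal",
                                 categories = edu_cats,
                                 probs = edu_probs / sum(edu_probs))
  for (nm in names(stereo))
    spec[[nm]] <- list(role = "item", level = "likert",
                       categories = likert_cats,
                       probs = stereo[[nm]] / sum(stereo[[nm]]),
                       reverse_coded = nm %in% c("st06", "st07"))
  spec
}

#' Generate a survey-like table with given marginals
#'
#' Draws each variable independently from its specified category
#' probabilities. This generator exercises the data-handling pipeline
#' (loading, validation, outcome construction, scoring, binarization); it
#' deliberately carries no dependence structure — dependence recovery is
#' tested with [sample_ising()].
#'
#' @param n Respondent count (the study analyzed 1665).
#' @param seed Integer RNG seed.
#' @param margins Marginal spec as from [default_survey_margins()].
#' @return A `survey_table` whose codebook mirrors the margins.
#' @export
generate_survey_like <- function(n = 1665L, seed = 1L,
                                 margins = default_survey_margins()) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  for (nm in names(margins)) {
    pr <- margins[[nm]]$probs
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-8)
      stop("malformed marginal spec for '", nm,
           "': probabilities must be nonnegative and sum to 1", call. = FALSE)
    if (length(pr) != length(margins[[nm]]$categories))
      stop("marginal spec for '", nm,
           "': one probability per category required", call. = FALSE)
  }
  set.seed(as.integer(seed))
  vals <- matrix(NA_integer_, n, length(margins),
                 dimnames = list(NULL, names(margins)))
  specs <- vector("list", length(margins))
  for (i in seq_along(margins)) {
    m <- margins[[i]]
    vals[, i] <- sample.int(length(m$probs), n, replace = TRUE,
                            prob = m$probs)
    specs[[i]] <- variable_spec(names(margins)[i], m$role, m$level,
                                m$categories,
                                isTRUE(m$reverse_coded))
  }
  new_survey_table(vals, codebook(specs))
}
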