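#' Factorial model specification
#'
#' Condition differences are partitioned into three subsets: intrinsic gain
#' changes in extrastriate sources (V2, V3, V5), intrinsic gain changes in
#' parietal sources (PC), and changes in extrinsic backward modulation. A
#' model is a combination of flags saying which subsets may differ between
#' valid and invalid trials; labels follow the positional convention
#' `"1 0 1"` = extrastriate gain + modulation, no parietal gain.
#'
#' @param extrastriate_gain,parietal_gain,modulation 0/1 flags.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(extrastriate_gain, parietal_gain, modulation) {
  flags <- c(extrastriate_gain, parietal_gain, modulation)
  stopifnot(all(flags %in% c(0, 1)))
  structure(list(extrastriate_gain = extrastriate_gain == 1,
                 parietal_gain = parietal_gain == 1,
                 modulation = modulation == 1,
                 label = paste(flags, collapse = " ")),
            class = "model_spec")
}

#' Enumerate the factorial model space
#'
#' All eight combinations of the three condition-difference subsets, ordered
#' from the null model `"0 0 0"` to the full model `"1 1 1"`.
#'
#' @return list of eight [model_spec()] objects.
#' @export
enumerate_model_space <- function() {
  grid <- expand.grid(modulation = 0:1, parietal_gain = 0:1,
                      extrastriate_gain = 0:1)
  grid <- grid[order(grid$extrastriate_gain, grid$parietal_gain,
                     grid$modulation), ]
  lapply(seq_len(nrow(grid)), function(k)
    model_spec(grid$extrastriate_gain[k], grid$parietal_gain[k],
               grid$modulation[k]))
}

#' Provisional model over backward condition effects
#'
#' The provisional comparison asks whether the validity effect is carried by
#' condition differences in top-down *driving* connections, in top-down
#' *modulatory* connections, both, or neither. Intrinsic gain differences
#' remain free in all four models; only the backward condition effects vary.
#'
#' @param driving,modulation 0/1 flags for condition effects on backward
#'   driving strengths and on modulatory strengths.
#' @return object of class `provisional_model`.
#' @export
provisional_model <- function(driving, modulation) {
  stopifnot(driving %in% c(0, 1), modulation %in% c(0, 1))
  lab <- c("null", "driving", "modulatory", "both")[1 + driving + 2 * modulation]
  structure(list(driving = driving == 1, modulation = modulation == 1,
                 label = lab),
            class = "provisional_model")
}

#' @rdname provisional_model
#' @return `provisional_space()`: list of the four provisional models
#'   (null, driving-only, modulatory-only, both).
#' @export
provisional_space <- function() {
  list(provisional_model(0, 0), provisional_model(1, 0),
       provisional_model(0, 1), provisional_model(1, 1))
}

#' Evidence for a reduced model by Bayesian model reduction
#'
#' Computes the free energy of a model whose priors are a shrunk version of
#' the full model's priors (smaller or zero variances) analytically from the
#' full model's Gaussian posterior, without refitting. With unchanged priors
#' the full free energy is returned exactly.
#'
#' @param full_fit a `dcm_fit` of the full model.
#' @param full_priors the [default_priors()] used for the full fit (defaults
#'   to the priors stored in the fit).
#' @param reduced_priors a priors table differing from `full_priors` only by
#'   reduced variances (possibly 0) and possibly shifted means on fixed
#'   parameters.
#' @return list with `free_energy` (the reduced model's evidence
#'   approximation), `delta_f` (change from the full model) and `posterior`
#'   (the reduced posterior mean/covariance).
#' @export
reduce_evidence <- function(full_fit, full_priors = NULL, reduced_priors) {
  full_priors <- full_priors %||% full_fit$priors
  if (!identical(full_priors$name, reduced_priors$name))
    stop("full and reduced priors must describe the same parameters",
         call. = FALSE)
  if (any(reduced_priors$var > full_priors$var + 1e-12))
    stop("reduced prior variances must not exceed the full priors",
         call. = FALSE)

  free <- full_fit$posterior$free
  mu <- full_fit$posterior$mean[free]
  Sigma <- full_fit$posterior$cov
  mu0 <- full_priors$mean[free]
  v0 <- full_priors$var[free]
  vr <- reduced_priors$var[free]
  mr <- reduced_priors$mean[free]

  p <- length(mu)
  P <- chol_solve(Sigma)
  Pmu <- as.numeric(P %*% mu)
  X <- vr == 0
  Fr <- !X

  ld_P <- -determinant_chol(Sigma)
  const <- -p / 2 * log(2 * pi) + 0.5 * ld_P - 0.5 * sum(mu * Pmu) +
    p / 2 * log(2 * pi) + 0.5 * sum(log(v0)) +
    0.5 * sum((mr[X] - mu0[X])^2 / v0[X]) + 0.5 * sum(mu0[Fr]^2 / v0[Fr])
  if (any(X)) {
    mX <- mr[X]
    PXX <- P[X, X, drop = FALSE]
    const <- const - 0.5 * sum(mX * (PXX %*% mX)) + sum(mX * Pmu[X])
  }

  mean_red <- full_fit$posterior$mean
  mean_red[free][X] <- mr[X]
  if (any(Fr)) {
    nf <- sum(Fr)
    A <- P[Fr, Fr, drop = FALSE] + diag(1 / vr[Fr], nf) - diag(1 / v0[Fr], nf)
    b <- Pmu[Fr] - (if (any(X)) as.numeric(P[Fr, X, drop = FALSE] %*% mr[X]) else 0) +
      mr[Fr] / vr[Fr] - mu0[Fr] / v0[Fr]
    const <- const - nf / 2 * log(2 * pi) - 0.5 * sum(log(vr[Fr])) -
      0.5 * sum(mr[Fr]^2 / vr[Fr])
    Ainv <- chol_solve(A)
    delta_f <- const + 0.5 * sum(b * (Ainv %*% b)) +
      nf / 2 * log(2 * pi) - 0.5 * determinant_chol(A)
    mu_r <- as.numeric(Ainv %*% b)
    mean_red[free][Fr] <- mu_r
    cov_red <- Ainv
    dimnames(cov_red) <- list(reduced_priors$name[free][Fr],
                              reduced_priors$name[free][Fr])
  } else {
    delta_f <- const
    cov_red <- matrix(0, 0, 0)
  }
  list(free_energy = full_fit$free_energy + delta_f, delta_f = delta_f,
       posterior = list(mean = mean_red, cov = cov_red, free_in_reduced = Fr))
}

#' Posterior model probabilities from free energies
#'
#' Softmax of the free energies weighted by the model prior: adding a common
#' constant to every free energy leaves the probabilities unchanged.
#'
#' @param free_energies numeric vector (nats), optionally named.
#' @param model_prior prior probabilities (default uniform).
#' @return probabilities summing to 1.
#' @export
posterior_probs <- function(free_energies, model_prior = NULL) {
  if (length(free_energies) < 2)
    stop("need at least two models to compare", call. = FALSE)
  stopifnot_finite(free_energies, "free energies")
  prior <- model_prior %||% rep(1 / length(free_energies),
                                length(free_energies))
  w <- exp(free_energies - max(free_energies)) * prior
  setNames(w / sum(w), names(free_energies))
}

#' Bayesian model comparison over a declared space
#'
#' Scores every model in a space against a fitted full model, by analytic
#' Bayesian model reduction (default) or by independent refitting, and
#' converts the free energies to posterior model probabilities under a
#' uniform model prior. Ties in free energy are broken toward the model with
#' fewer free parameters.
#'
#' @param full_fit a `dcm_fit` whose priors subsume every model in the space.
#' @param space list of [model_spec()] or [provisional_model()] objects.
#' @param refit if `TRUE`, refit each model by [variational_laplace()]
#'   instead of reducing (requires `data`).
#' @param data `mode_dataset`, needed when `refit = TRUE`.
#' @return object of class `bmc_result`: data frame `table` (label, free
#'   energy, relative free energy, probability, n free effect parameters),
#'   `winner` (label), `posteriors` (per-model reduced posteriors).
#' @export
bmc_from_fit <- function(full_fit, space = enumerate_model_space(),
                         refit = FALSE, data = NULL) {
  network <- full_fit$network
  labels <- vapply(space, `[[`, character(1), "label")
  res <- lapply(space, function(m) {
    pri <- default_priors(network, m)
    if (refit) {
      if (is.null(data)) stop("refit = TRUE needs the data", call. = FALSE)
      fit <- variational_laplace(data, network, pri, full_fit$opts)
      list(free_energy = fit$free_energy,
           posterior = fit$posterior, trace = fit$trace)
    } else reduce_evidence(full_fit, full_fit$priors, pri)
  })
  Fs <- setNames(vapply(res, `[[`, numeric(1), "free_energy"), labels)
  n_free <- vapply(space, function(m)
    sum(default_priors(network, m)$var[grepl("^(dgamma|dm|db)\\[",
                                             full_fit$priors$name)] > 0),
    numeric(1))
  best <- which(Fs == max(Fs))
  winner <- labels[best[which.min(n_free[best])]]
  tab <- data.frame(model = labels, free_energy = Fs,
                    relative_f = Fs - min(Fs),
                    probability = posterior_probs(Fs),
                    n_free_effects = n_free, row.names = NULL)
  structure(list(table = tab, winner = winner,
                 posteriors = setNames(lapply(res, `[[`, "posterior"), labels)),
            class = "bmc_result")
}

#' Time-resolved gain trajectories
#'
#' Integrates the network per condition and returns the log gain (negative
#' instantaneous log self-inhibition, i.e. log precision) of every source
#' over peristimulus time, evaluated with the same afferent deep-pyramidal
#' firing rates the integrator uses. With all modulatory strengths zero the
#' trajectories are flat at \eqn{-(\gamma_0 + [invalid]\Delta\gamma)}.
#'
#' @param fit_or_params a `dcm_fit` (posterior-mean parameters are applied to
#'   its network) or a `dcm_network`.
#' @param conditions conditions to evaluate.
#' @param window peristimulus window (ms).
#' @param dt integration step (ms).
#' @return object of class `gain_trajectory`: list with `time` and `gain`
#'   (named list of sources x time matrices of log gain per condition).
#' @export
gain_timecourse <- function(fit_or_params, conditions = c("valid", "invalid"),
                            window = c(-50, 400), dt = 1) {
  net <- if (inherits(fit_or_params, "dcm_fit"))
    apply_parameters(fit_or_params$network, fit_or_params$posterior$mean,
                     fit_or_params$priors)$network
  else if (inherits(fit_or_params, "dcm_network")) fit_or_params
  else stop("expected a dcm_fit or dcm_network", call. = FALSE)
  gain <- lapply(setNames(conditions, conditions), function(cond) {
    act <- integrate_network(net, cond, window, dt)
    -act$gamma
  })
  structure(list(time = seq(window[1], window[2], by = dt), gain = gain,
                 sources = net$sources$label),
            class = "gain_trajectory")
}

#' Posterior mean parameters of a reduced model as a network
#'
#' @param full_fit the full-model `dcm_fit`.
#' @param reduced a posterior entry from [bmc_from_fit()] (or
#'   [reduce_evidence()]).
#' @return a `dcm_network` with the reduced posterior-mean parameters applied.
#' @export
network_from_posterior <- function(full_fit, reduced) {
  apply_parameters(full_fit$network, reduced$mean, full_fit$priors)$network
}
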