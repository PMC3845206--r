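# shared fixtures; heavy scenario fits are cached across test files

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# full-model inversion of a generated scenario dataset (the expensive path)
scenario_fit <- function(kind = c("default", "null"), seed) {
  kind <- match.arg(kind)
  cached(sprintf("fit_%s_%d", kind, seed), {
    sc <- if (kind == "default") default_validity_scenario(seed = seed)
          else null_scenario(seed = seed)
    gd <- generate_dataset(sc)
    basis <- canonical_modes(gd$dataset, gd$dataset$lead, 8)
    modes <- reduce_to_modes(gd$dataset, basis)
    net <- build_posner_network()
    fit <- variational_laplace(modes, net,
                               default_priors(net, model_spec(1, 1, 1)))
    list(fit = fit, truth = gd$truth, modes = modes, scenario = sc)
  })
}

# ground-truth condition-effect vector (delta_gamma then delta_M, edge order)
truth_effect_vector <- function(network) {
  edges <- dcmgain:::hierarchy_edges()
  dm <- mapply(function(t, s) network$effects$delta_M[s, t],
               edges$target, edges$source)
  c(network$effects$delta_gamma, dm)
}

fitted_effect_vector <- function(fit) {
  eff <- grepl("^(dgamma|dm)\\[", fit$priors$name)
  fit$posterior$mean[eff]
}

# linear-Gaussian test model with conjugate closed-form posterior/evidence
linear_gaussian_fixture <- function(p = 10, n = 40, sigma = 0.5, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta_true <- rnorm(p)
  y <- as.numeric(X %*% beta_true + rnorm(n, 0, sigma))
  priors <- prior_spec(sprintf("b%02d", seq_len(p)), mean = 0, var = 1)
  list(X = X, y = y, sigma = sigma, priors = priors,
       data = list(Y = list(y = matrix(y, 1))),
       opts = list(gfun = function(th) X %*% th,
                   lambda0 = log(1 / sigma^2), fix_lambda = TRUE,
                   conditions = "y"))
}

# conjugate posterior and log evidence for the fixture (independent oracle)
linear_gaussian_oracle <- function(fx, prior_var = rep(1, ncol(fx$X)),
                                   prior_mean = rep(0, ncol(fx$X))) {
  X <- fx$X
  keep <- prior_var > 0
  yadj <- fx$y - X[, !keep, drop = FALSE] %*% prior_mean[!keep]
  Xk <- X[, keep, drop = FALSE]
  beta <- 1 / fx$sigma^2
  S0 <- diag(prior_var[keep], sum(keep))
  Spost <- solve(beta * crossprod(Xk) + solve(S0))
  mpost <- Spost %*% (beta * crossprod(Xk, yadj) + solve(S0, prior_mean[keep]))
  C <- fx$sigma^2 * diag(length(fx$y)) + Xk %*% S0 %*% t(Xk)
  R <- chol(C)
  resid <- as.numeric(yadj - Xk %*% prior_mean[keep])
  z <- backsolve(R, forwardsolve(t(R), resid))
  logev <- -0.5 * (length(fx$y) * log(2 * pi) + 2 * sum(log(diag(R))) +
                     sum(resid * z))
  mean_full <- prior_mean
  mean_full[keep] <- as.numeric(mpost)
  list(mean = mean_full, cov = Spost, log_evidence = logev)
}
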