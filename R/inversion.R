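#' Prior specification over model parameters
#'
#' All positive structural quantities (extrinsic strengths, modulatory
#' strengths, rate constants, stimulus width/amplitude, lead-field gain) are
#' estimated as log-scalings of their network defaults, so Gaussian priors
#' give automatic positivity. Baseline log self-inhibition and the condition
#' effects are additive on the log scale. A prior variance of zero fixes the
#' parameter at its prior mean and removes it from the optimization.
#'
#' `default_priors()` builds the prior table for a given model: structural
#' log-scalings have mean 0 and variance 1/16; the stimulus peak has mean
#' 120 ms and standard deviation 16 ms; condition effects included by the
#' model have mean 0 and variance 1/4, excluded effects are fixed at 0.
#'
#' @param network a `dcm_network` (supplies labels and edges).
#' @param model a [model_spec()] (factorial space) or
#'   [provisional_model()] (backward driving vs modulatory space).
#' @return object of class `prior_spec`: data frame with columns `name`,
#'   `slot`, `i`, `j`, `mean`, `var` and attribute `model`.
#' @export
default_priors <- function(network, model = model_spec(1, 1, 1)) {
  lab <- network$sources$label
  edges <- hierarchy_edges()
  v_struct <- 1 / 16
  v_effect <- 1 / 4

  rows <- list()
  add <- function(name, slot, i = NA, j = NA, mean = 0, var = v_struct)
    rows[[length(rows) + 1]] <<- data.frame(name = name, slot = slot,
                                            i = i, j = j, mean = mean,
                                            var = var,
                                            stringsAsFactors = FALSE)
  for (k in seq_len(nrow(edges))) {
    add(sprintf("afwd[%s<-%s]", edges$target[k], edges$source[k]),
        "A_forward", edges$target[k], edges$source[k])
    add(sprintf("abwd[%s<-%s]", edges$source[k], edges$target[k]),
        "A_backward", edges$source[k], edges$target[k])
    add(sprintf("m[%s<-%s]", edges$source[k], edges$target[k]),
        "M", edges$source[k], edges$target[k])
  }
  for (l in lab) add(sprintf("g0[%s]", l), "gamma0", l)
  add("kappa_e", "kappa_e")
  add("kappa_dp", "kappa_dp")
  add("stim_peak", "stim_peak", mean = 120, var = 16^2)
  add("stim_logwidth", "stim_logwidth")
  add("stim_logamp", "stim_logamp")
  add("lf_loggain", "lf_loggain")

  if (inherits(model, "model_spec")) {
    free_g <- function(l) {
      nm <- sub("\\..*$", "", l)
      if (nm == "PC") model$parietal_gain else model$extrastriate_gain
    }
    for (l in lab)
      add(sprintf("dgamma[%s]", l), "delta_gamma", l,
          var = if (free_g(l)) v_effect else 0)
    for (k in seq_len(nrow(edges)))
      add(sprintf("dm[%s<-%s]", edges$source[k], edges$target[k]),
          "delta_M", edges$source[k], edges$target[k],
          var = if (model$modulation) v_effect else 0)
    for (k in seq_len(nrow(edges)))
      add(sprintf("db[%s<-%s]", edges$source[k], edges$target[k]),
          "delta_B", edges$source[k], edges$target[k], var = 0)
  } else if (inherits(model, "provisional_model")) {
    for (l in lab)
      add(sprintf("dgamma[%s]", l), "delta_gamma", l, var = v_effect)
    for (k in seq_len(nrow(edges)))
      add(sprintf("dm[%s<-%s]", edges$source[k], edges$target[k]),
          "delta_M", edges$source[k], edges$target[k],
          var = if (model$modulation) v_effect else 0)
    for (k in seq_len(nrow(edges)))
      add(sprintf("db[%s<-%s]", edges$source[k], edges$target[k]),
          "delta_B", edges$source[k], edges$target[k],
          var = if (model$driving) v_effect else 0)
  } else stop("model must be a model_spec or provisional_model", call. = FALSE)

  out <- do.call(rbind, rows)
  if (any(out$var < 0)) stop("prior variances must be >= 0", call. = FALSE)
  attr(out, "model") <- model
  class(out) <- c("prior_spec", class(out))
  out
}

# apply a full-length named parameter vector to a network; returns the
# modified network plus the lead-field log gain
apply_parameters <- function(network, theta, priors) {
  net <- network
  net$effects <- condition_effects(nrow(net$sources), net$sources$label)
  lf_loggain <- 0
  for (r in seq_len(nrow(priors))) {
    th <- theta[[r]]
    slot <- priors$slot[r]
    i <- priors$i[r]; j <- priors$j[r]
    switch(slot,
      A_forward  = net$A_forward[i, j] <- net$A_forward[i, j] * exp(th),
      A_backward = net$A_backward[i, j] <- net$A_backward[i, j] * exp(th),
      M          = net$M[i, j] <- net$M[i, j] * exp(th),
      gamma0     = net$intrinsics[[i]]$gamma0 <- net$intrinsics[[i]]$gamma0 + th,
      kappa_e    = for (l in seq_along(net$intrinsics))
                     net$intrinsics[[l]]$kappa[1:3] <-
                       net$intrinsics[[l]]$kappa[1:3] * exp(th),
      kappa_dp   = for (l in seq_along(net$intrinsics))
                     net$intrinsics[[l]]$kappa[4] <-
                       net$intrinsics[[l]]$kappa[4] * exp(th),
      stim_peak  = net$stimulus$peak_time <- th,
      stim_logwidth = net$stimulus$width <- network$stimulus$width * exp(th),
      stim_logamp   = net$stimulus$amplitude <-
                        network$stimulus$amplitude * exp(th),
      lf_loggain = lf_loggain <- th,
      delta_gamma = net$effects$delta_gamma[i] <- th,
      delta_M     = net$effects$delta_M[i, j] <- th,
      delta_B     = net$effects$delta_B[i, j] <- th,
      stop("unknown parameter slot: ", slot))
  }
  list(network = net, lf_loggain = lf_loggain)
}

# fast mode-space forward prediction used by the optimizer.
# UtL = t(U) %*% L precomputed; returns n_modes x n_times x n_conditions.
mode_prediction <- function(theta, network, priors, UtL, times, conditions,
                            weights = contribution_weights(), dt = 1) {
  ap <- apply_parameters(network, theta, priors)
  window <- range(times)
  tt <- seq(window[1], window[2], by = dt)
  idx <- 1 + round((times - window[1]) / dt)
  out <- array(0, c(nrow(UtL), length(times), length(conditions)),
               dimnames = list(NULL, NULL, conditions))
  for (ci in seq_along(conditions)) {
    act <- integrate_network(ap$network, conditions[ci], window, dt)
    src <- matrix(as.numeric(weights) %*% matrix(act$v, 4), ncol = length(tt))
    out[, , ci] <- exp(ap$lf_loggain) * (UtL %*% src[, idx, drop = FALSE])
  }
  out
}

#' Predicted mode-space responses for a parameter vector
#'
#' Deterministic composition of network integration, sensor projection and
#' mode reduction: the forward model that the variational scheme fits.
#'
#' @param theta full-length named parameter vector ordered as in `priors`
#'   (use `priors$mean` for the prior expectation).
#' @param network a `dcm_network` (structural scaffold; condition effects are
#'   taken from `theta`, not from the network).
#' @param priors a [default_priors()] table defining the parameterization.
#' @param lead a [make_lead_field()] object.
#' @param basis a [canonical_modes()] basis.
#' @param times sample times (ms) at which to evaluate.
#' @param conditions conditions to predict.
#' @param weights population contribution weights.
#' @param dt integration step (ms).
#' @return n_modes x time x condition array.
#' @export
predict_response <- function(theta, network, priors, lead, basis, times,
                             conditions = c("valid", "invalid"),
                             weights = contribution_weights(), dt = 1) {
  mode_prediction(theta, network, priors, t(basis$U) %*% lead$L, times,
                  conditions, weights, dt)
}

# Laplace free energy for given residuals and linearization
# F = -beta/2 e'e + n/2 log beta - n/2 log 2pi
#     - 1/2 (mu-mu0)' P0 (mu-mu0) + 1/2 (logdet Sigma + logdet P0)
vl_free_energy <- function(eps, beta, mu, mu0, P0, Sigma) {
  n <- length(eps)
  e0 <- mu - mu0
  ld_S <- determinant_chol(Sigma)
  ld_P0 <- sum(log(diag(P0)))
  -beta / 2 * sum(eps^2) + n / 2 * log(beta) - n / 2 * log(2 * pi) -
    0.5 * sum(e0 * (P0 %*% e0)) + 0.5 * (ld_S + ld_P0)
}

determinant_chol <- function(S) {
  2 * sum(log(diag(chol((S + t(S)) / 2))))
}

#' Construct a bare prior table
#'
#' Builds a `prior_spec` for a custom forward model (for instance the linear
#' test models used to validate the optimizer against conjugate closed
#' forms). For the network model use [default_priors()].
#'
#' @param name parameter names.
#' @param mean,var prior means and variances (variance 0 fixes a parameter).
#' @return a `prior_spec` data frame.
#' @export
prior_spec <- function(name, mean = 0, var = 1) {
  out <- data.frame(name = name, slot = "custom", i = NA, j = NA,
                    mean = rep_len(mean, length(name)),
                    var = rep_len(var, length(name)),
                    stringsAsFactors = FALSE)
  if (any(out$var < 0)) stop("prior variances must be >= 0", call. = FALSE)
  class(out) <- c("prior_spec", class(out))
  out
}

#' Fit the network model by variational Laplace
#'
#' Gaussian fixed-form variational inference on the mode-space evoked
#' responses: Gauss-Newton ascent with Levenberg-Marquardt regularization on
#' the free-energy objective (accuracy minus complexity), Jacobians by
#' central finite differences in parameter space, and a closed-form update of
#' a single noise log-precision hyperparameter between parameter steps.
#' Optimization starts at the prior mean; the trace of accepted free-energy
#' values is non-decreasing by construction.
#'
#' @param data a `mode_dataset` from [reduce_to_modes()] (carries the mode
#'   basis and lead-field reference).
#' @param network a `dcm_network` structural scaffold.
#' @param priors a [default_priors()] table. Parameters with zero prior
#'   variance are fixed at their prior mean.
#' @param opts list of options: `max_iter` (default 64), `tol` (0.01),
#'   `tol_count` (3 successive small improvements), `fd_step` (1e-3),
#'   `lambda0` (initial noise log precision), `fix_lambda` (logical),
#'   `dt` (integration step, 1 ms), `weights`, `conditions`, `verbose`;
#'   `gfun` replaces the network forward model by a custom prediction
#'   function of the full parameter vector (used with [prior_spec()] to
#'   validate the optimizer on models with known closed-form evidence).
#' @return object of class `dcm_fit`: posterior mean/covariance, noise
#'   log-precision posterior, free energy, predicted responses, iteration
#'   trace and a convergence flag.
#' @export
variational_laplace <- function(data, network, priors, opts = list()) {
  o <- modifyList(list(max_iter = 64L, tol = 0.01, tol_count = 3L,
                       fd_step = 1e-3, lambda0 = NULL, fix_lambda = FALSE,
                       dt = 1, weights = contribution_weights(),
                       conditions = names(data$Y), verbose = FALSE,
                       gfun = NULL), opts)
  stopifnot(inherits(priors, "prior_spec"))
  if (is.null(o$gfun)) {
    stopifnot(inherits(data, "mode_dataset"))
    if (is.null(data$lead))
      stop("mode dataset carries no lead field", call. = FALSE)
    UtL <- t(data$basis$U) %*% data$lead$L
  }

  y <- as.numeric(unlist(data$Y[o$conditions]))
  stopifnot_finite(y, "data")
  n <- length(y)

  free <- priors$var > 0
  if (!any(free)) stop("model has no free parameters", call. = FALSE)
  p <- sum(free)
  mu0 <- priors$mean[free]
  P0 <- diag(1 / priors$var[free], p)
  theta_full <- setNames(priors$mean, priors$name)

  gfun <- function(mu) {
    theta_full[free] <- mu
    if (!is.null(o$gfun)) as.numeric(o$gfun(theta_full))
    else as.numeric(mode_prediction(theta_full, network, priors, UtL,
                                    data$times, o$conditions, o$weights, o$dt))
  }
  jac <- function(mu) {
    J <- matrix(0, n, p)
    for (k in seq_len(p)) {
      dp <- dm <- mu
      dp[k] <- dp[k] + o$fd_step
      dm[k] <- dm[k] - o$fd_step
      J[, k] <- (gfun(dp) - gfun(dm)) / (2 * o$fd_step)
    }
    J
  }

  mu <- mu0
  g <- gfun(mu)
  eps <- y - g
  lambda <- o$lambda0 %||% log(1 / max(var(y), .Machine$double.eps))

  update_lambda <- function(lambda, eps, JtJ) {
    if (isTRUE(o$fix_lambda)) return(lambda)
    for (it in 1:8) {
      Sigma <- chol_solve(exp(lambda) * JtJ + P0)
      S_eff <- sum(eps^2) + sum(JtJ * Sigma)
      lambda_new <- log(n / S_eff)
      if (abs(lambda_new - lambda) < 1e-8) break
      lambda <- lambda_new
    }
    lambda
  }

  J <- jac(mu)
  JtJ <- crossprod(J)
  lambda <- update_lambda(lambda, eps, JtJ)
  Sigma <- chol_solve(exp(lambda) * JtJ + P0)
  F_best <- vl_free_energy(eps, exp(lambda), mu, mu0, P0, Sigma)
  trace <- F_best
  mu_best <- mu; Sigma_best <- Sigma; lambda_best <- lambda; eps_best <- eps
  g_best <- g; J_best <- J; JtJ_best <- JtJ
  small_steps <- 0L
  bad <- 0L
  rho <- 1e-6
  converged <- FALSE

  for (iter in seq_len(o$max_iter)) {
    beta <- exp(lambda)
    H <- beta * JtJ + P0
    grad <- beta * crossprod(J, eps) - P0 %*% (mu - mu0)
    accepted <- FALSE
    rho_try <- rho
    for (try in 1:12) {
      step <- tryCatch(chol_solve(H + rho_try * diag(diag(H), p), grad),
                       error = function(e) NULL)
      if (!is.null(step)) {
        mu_c <- mu + as.numeric(step)
        g_c <- tryCatch(gfun(mu_c), error = function(e) NULL)
        if (!is.null(g_c) && all(is.finite(g_c))) {
          eps_c <- y - g_c
          F_c <- vl_free_energy(eps_c, beta, mu_c, mu0, P0, Sigma)
          if (is.finite(F_c) && F_c > F_best) {
            mu <- mu_c; eps <- eps_c; g <- g_c
            rho <- rho_try
            accepted <- TRUE
            break
          }
        }
      }
      rho_try <- rho_try * 16
    }
    if (!accepted) {
      # no improving parameter step: a noise-precision update alone may still
      # raise the objective; otherwise we are at a (local) optimum
      lambda_c <- update_lambda(lambda, eps, JtJ)
      Sigma_c <- chol_solve(exp(lambda_c) * JtJ + P0)
      F_new <- vl_free_energy(eps, exp(lambda_c), mu, mu0, P0, Sigma_c)
      if (F_new > F_best) {
        dF <- F_new - F_best
        F_best <- F_new; Sigma_best <- Sigma_c; lambda_best <- lambda_c
        lambda <- lambda_c; Sigma <- Sigma_c
        trace <- c(trace, F_best)
        small_steps <- if (dF < o$tol) small_steps + 1L else 0L
        if (small_steps >= o$tol_count) { converged <- TRUE; break }
        next
      }
      break
    }

    # re-linearize at the accepted point and update the noise hyperparameter;
    # commit only if the re-linearized objective still improves on the best
    J <- jac(mu)
    JtJ <- crossprod(J)
    lambda_c <- update_lambda(lambda, eps, JtJ)
    Sigma_c <- chol_solve(exp(lambda_c) * JtJ + P0)
    F_new <- vl_free_energy(eps, exp(lambda_c), mu, mu0, P0, Sigma_c)
    if (F_new < F_best && !isTRUE(all.equal(lambda, lambda_c))) {
      Sigma_alt <- chol_solve(exp(lambda) * JtJ + P0)
      F_alt <- vl_free_energy(eps, exp(lambda), mu, mu0, P0, Sigma_alt)
      if (F_alt > F_new) { F_new <- F_alt; Sigma_c <- Sigma_alt; lambda_c <- lambda }
    }
    if (F_new > F_best) {
      dF <- F_new - F_best
      F_best <- F_new; mu_best <- mu; Sigma_best <- Sigma_c
      lambda_best <- lambda_c; eps_best <- eps; g_best <- g
      J_best <- J; JtJ_best <- JtJ
      lambda <- lambda_c; Sigma <- Sigma_c
      trace <- c(trace, F_best)
      rho <- max(rho / 4, 1e-8)
      bad <- 0L
      small_steps <- if (dF < o$tol) small_steps + 1L else 0L
      if (o$verbose)
        message(sprintf("iter %d: F = %.4f (dF = %.4g)", iter, F_best, dF))
      if (small_steps >= o$tol_count) { converged <- TRUE; break }
    } else {
      # revert to the best point and retry under stronger regularization
      mu <- mu_best; eps <- eps_best; g <- g_best
      J <- J_best; JtJ <- JtJ_best
      lambda <- lambda_best; Sigma <- Sigma_best
      rho <- rho * 64
      bad <- bad + 1L
      if (bad >= 3L) break
    }
  }
  # non-convergence means failure to improve on the prior mean at all;
  # stopping at a stationary point after improvement counts as converged
  if (!converged) converged <- length(trace) > 1L

  theta_full[free] <- mu_best
  post_mean <- theta_full
  dimnames(Sigma_best) <- list(priors$name[free], priors$name[free])
  pred <- if (!is.null(o$gfun)) o$gfun(post_mean)
          else mode_prediction(post_mean, network, priors, UtL, data$times,
                               o$conditions, o$weights, o$dt)
  beta_best <- exp(lambda_best)
  accuracy <- -beta_best / 2 * sum(eps_best^2) + n / 2 * log(beta_best) -
    n / 2 * log(2 * pi)
  structure(list(
    posterior = list(mean = post_mean, cov = Sigma_best, free = free),
    noise = list(lambda = lambda_best, var = 2 / n),
    free_energy = F_best,
    accuracy = accuracy,
    predicted = pred,
    trace = trace,
    converged = converged,
    priors = priors,
    network = network,
    opts = o,
    n_data = n),
    class = "dcm_fit")
}

chol_solve <- function(A, b = NULL) {
  R <- chol((A + t(A)) / 2)
  if (is.null(b)) chol2inv(R)
  else backsolve(R, forwardsolve(t(R), b))
}

#' Free energy of a fit
#'
#' Returns the converged free-energy objective (the approximation to log
#' model evidence). If `data` is supplied, the accuracy term is re-evaluated
#' for those data at the fitted parameters and noise precision (the
#' complexity terms are unchanged) — useful for asking how the objective
#' responds to noisier data at fixed parameters.
#'
#' @param fit a `dcm_fit`.
#' @param data optional `mode_dataset` to re-evaluate accuracy on.
#' @return scalar free energy (nats).
#' @export
free_energy <- function(fit, data = NULL) {
  if (is.null(data)) return(fit$free_energy)
  y <- as.numeric(unlist(data$Y[fit$opts$conditions]))
  if (length(y) != fit$n_data)
    stop("data dimensions do not match the fit", call. = FALSE)
  eps <- y - as.numeric(fit$predicted)
  beta <- exp(fit$noise$lambda)
  accuracy_new <- -beta / 2 * sum(eps^2) + length(y) / 2 * log(beta) -
    length(y) / 2 * log(2 * pi)
  fit$free_energy - fit$accuracy + accuracy_new
}
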