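test_that("default priors gate condition effects by model flags", {
  net <- build_posner_network()
  full <- default_priors(net, model_spec(1, 1, 1))
  expect_true(all(full$var[grepl("^dgamma", full$name)] == 1 / 4))
  expect_true(all(full$var[grepl("^dm", full$name)] == 1 / 4))
  expect_true(all(full$var[grepl("^db", full$name)] == 0))
  expect_equal(full$mean[full$name == "stim_peak"], 120)
  expect_equal(full$var[full$name == "stim_peak"], 256)

  null <- default_priors(net, model_spec(0, 0, 0))
  eff <- grepl("^(dgamma|dm|db)", null$name)
  expect_true(all(null$var[eff] == 0))
  expect_true(all(null$mean[eff] == 0))

  m101 <- default_priors(net, model_spec(1, 0, 1))
  expect_true(all(m101$var[grepl("^dgamma\\[PC", m101$name)] == 0))
  expect_true(all(m101$var[grepl("^dgamma\\[V", m101$name)] == 1 / 4))
  expect_true(all(m101$var[grepl("^dm", m101$name)] == 1 / 4))

  drv <- default_priors(net, provisional_model(1, 0))
  expect_true(all(drv$var[grepl("^db", drv$name)] == 1 / 4))
  expect_true(all(drv$var[grepl("^dm", drv$name)] == 0))
  expect_true(all(drv$var[grepl("^dgamma", drv$name)] == 1 / 4))
})

test_that("variational Laplace matches the conjugate linear-Gaussian solution", {
  fx <- linear_gaussian_fixture()
  fit <- variational_laplace(fx$data, NULL, fx$priors, fx$opts)
  oracle <- linear_gaussian_oracle(fx)
  expect_lt(max(abs(fit$posterior$mean - oracle$mean)), 1e-6)
  expect_lt(max(abs(fit$posterior$cov - oracle$cov)), 1e-6)
  expect_lt(abs(fit$free_energy - oracle$log_evidence), 1e-6)
  expect_true(all(diff(fit$trace) >= 0))
  expect_true(fit$converged)
})

test_that("zero-variance parameters stay fixed at their prior mean", {
  fx <- linear_gaussian_fixture()
  fx$priors$var[3] <- 0
  fx$priors$mean[3] <- 0.7
  fit <- variational_laplace(fx$data, NULL, fx$priors, fx$opts)
  expect_equal(unname(fit$posterior$mean[3]), 0.7)
  expect_false("b03" %in% rownames(fit$posterior$cov))
  oracle <- linear_gaussian_oracle(fx, prior_var = fx$priors$var,
                                   prior_mean = fx$priors$mean)
  expect_lt(max(abs(fit$posterior$mean - oracle$mean)), 1e-6)
  expect_lt(abs(fit$free_energy - oracle$log_evidence), 1e-6)
})

test_that("the forward prediction matches the generator at truth parameters", {
  sc <- default_validity_scenario(snr_db = Inf)
  gd <- generate_dataset(sc)
  basis <- canonical_modes(gd$dataset, gd$dataset$lead, 8)
  modes <- reduce_to_modes(gd$dataset, basis)
  net <- build_posner_network()
  pri <- default_priors(net, model_spec(1, 1, 1))
  th <- setNames(pri$mean, pri$name)
  for (l in names(sc$network$effects$delta_gamma))
    th[sprintf("dgamma[%s]", l)] <- sc$network$effects$delta_gamma[[l]]
  edges <- dcmgain:::hierarchy_edges()
  for (k in seq_len(nrow(edges)))
    th[sprintf("dm[%s<-%s]", edges$source[k], edges$target[k])] <-
      sc$network$effects$delta_M[edges$source[k], edges$target[k]]
  pred <- predict_response(th, net, pri, gd$dataset$lead, basis, modes$times)
  expect_equal(pred[, , "valid"], unname(modes$Y$valid), tolerance = 1e-8)
  expect_equal(pred[, , "invalid"], unname(modes$Y$invalid), tolerance = 1e-8)

  # with all effects zero the prediction is condition-identical
  pred0 <- predict_response(setNames(pri$mean, pri$name), net, pri,
                            gd$dataset$lead, basis, modes$times)
  expect_identical(pred0[, , "valid"], pred0[, , "invalid"])
})

test_that("free energy falls when noise is added to the data at fixed fit", {
  fx <- linear_gaussian_fixture()
  fit <- variational_laplace(fx$data, NULL, fx$priors, fx$opts)
  expect_equal(free_energy(fit), fit$trace[length(fit$trace)])
  set.seed(1)
  noisy <- fx$data
  noisy$Y$y <- noisy$Y$y + matrix(rnorm(length(fx$y), 0, 1), 1)
  expect_lt(free_energy(fit, noisy), free_energy(fit))
})

test_that("numerical directional derivatives agree with the internal gradient", {
  fx <- linear_gaussian_fixture()
  beta <- 1 / fx$sigma^2
  mu <- rep(0.2, 10)   # a non-stationary point
  P0 <- diag(10)
  eps <- fx$y - as.numeric(fx$X %*% mu)
  grad <- beta * crossprod(fx$X, eps) - P0 %*% mu
  Sigma <- solve(beta * crossprod(fx$X) + P0)
  Fof <- function(m) {
    e <- fx$y - as.numeric(fx$X %*% m)
    dcmgain:::vl_free_energy(e, beta, m, rep(0, 10), P0, Sigma)
  }
  set.seed(2)
  for (k in 1:5) {
    d <- rnorm(10); d <- d / sqrt(sum(d^2))
    h <- 1e-5
    num <- (Fof(mu + h * d) - Fof(mu - h * d)) / (2 * h)
    expect_lt(abs(num - sum(grad * d)) / abs(num), 0.01)
  }
})

test_that("null data at high SNR keep effect estimates near zero", {
  # pooled 90% credible-interval coverage across seeded runs; the pooled
  # threshold allows for binomial variation around the nominal rate
  covered <- total <- 0L
  for (s in 6:8) {
    sc <- null_scenario(seed = s, snr_db = 20)
    gd <- generate_dataset(sc)
    basis <- canonical_modes(gd$dataset, gd$dataset$lead, 8)
    modes <- reduce_to_modes(gd$dataset, basis)
    net <- build_posner_network()
    pri <- default_priors(net, model_spec(1, 1, 1))
    fit <- variational_laplace(modes, net, pri)
    eff_idx <- which(grepl("^(dgamma|dm)\\[", pri$name))
    est <- fit$posterior$mean[eff_idx]
    sds <- sqrt(diag(fit$posterior$cov))[pri$name[eff_idx]]
    covered <- covered + sum(abs(est) <= qnorm(0.95) * sds)
    total <- total + length(est)
    expect_lt(max(abs(est)), 0.5)    # no spurious effect beyond the prior sd
    expect_true(all(diff(fit$trace) >= 0))
  }
  expect_gte(covered / total, 0.8)
})
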