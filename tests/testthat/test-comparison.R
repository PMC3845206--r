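test_that("the factorial space enumerates all eight flag combinations", {
  space <- enumerate_model_space()
  expect_length(space, 8)
  labels <- vapply(space, `[[`, character(1), "label")
  expect_equal(length(unique(labels)), 8)
  expect_equal(labels[1], "0 0 0")
  expect_equal(labels[8], "1 1 1")
  expect_true("1 0 1" %in% labels)
})

test_that("the provisional space spans driving-by-modulatory combinations", {
  space <- provisional_space()
  expect_length(space, 4)
  labels <- vapply(space, `[[`, character(1), "label")
  expect_setequal(labels, c("null", "driving", "modulatory", "both"))
  net <- build_posner_network()
  null_pri <- default_priors(net, space[[which(labels == "null")]])
  expect_true(all(null_pri$var[grepl("^(db|dm)", null_pri$name)] == 0))
  drv_pri <- default_priors(net, space[[which(labels == "driving")]])
  expect_true(all(drv_pri$var[grepl("^db", drv_pri$name)] > 0))
  expect_true(all(drv_pri$var[grepl("^dm", drv_pri$name)] == 0))
})

test_that("model reduction is exact against the conjugate oracle", {
  fx <- linear_gaussian_fixture()
  fit <- variational_laplace(fx$data, NULL, fx$priors, fx$opts)

  # unchanged priors: delta F is exactly zero
  same <- reduce_evidence(fit, fx$priors, fx$priors)
  expect_lt(abs(same$delta_f), 1e-9)

  # fix three parameters at zero, shrink two others
  red <- fx$priors
  red$var[c(2, 5, 9)] <- 0
  red$var[c(1, 10)] <- 0.25
  bmr <- reduce_evidence(fit, fx$priors, red)
  refit <- variational_laplace(fx$data, NULL, red, fx$opts)
  expect_lt(abs(bmr$free_energy - refit$free_energy), 1e-6)
  expect_lt(max(abs(bmr$posterior$mean - refit$posterior$mean)), 1e-6)

  # growing a prior variance is not a reduction
  grown <- fx$priors
  grown$var[1] <- 4
  expect_error(reduce_evidence(fit, fx$priors, grown), "exceed")
})

test_that("fixing a parameter the posterior finds unnecessary raises evidence", {
  set.seed(3)
  n <- 60
  X <- cbind(matrix(rnorm(n * 3), n, 3), rnorm(n))
  theta <- c(1, -0.5, 0.8, 0)       # last regressor is irrelevant
  y <- as.numeric(X %*% theta + rnorm(n, 0, 0.3))
  pri <- prior_spec(paste0("b", 1:4), var = 1)
  opts <- list(gfun = function(th) X %*% th, lambda0 = log(1 / 0.09),
               fix_lambda = TRUE, conditions = "y")
  fit <- variational_laplace(list(Y = list(y = matrix(y, 1))), NULL, pri, opts)
  red <- pri
  red$var[4] <- 0
  out <- reduce_evidence(fit, pri, red)
  expect_gt(out$delta_f, 0)   # complexity saving
})

test_that("posterior model probabilities behave like a softmax", {
  expect_equal(unname(posterior_probs(rep(1.3, 8))), rep(1 / 8, 8))
  p <- posterior_probs(c(a = 0, b = 3))
  expect_equal(unname(p), c(1 / (1 + exp(3)), exp(3) / (1 + exp(3))),
               tolerance = 1e-12)
  expect_equal(round(unname(p), 3), c(0.047, 0.953))
  expect_equal(sum(posterior_probs(rnorm(5))), 1, tolerance = 1e-12)
  shifted <- posterior_probs(c(0, 3) + 100)
  expect_equal(shifted, p, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(posterior_probs(c(1, NA)), "free energies")
  expect_error(posterior_probs(3), "at least two")
})

test_that("gain trajectories reduce to baselines without modulation", {
  net <- build_posner_network(
    list(modulatory_strength = 1e-12,
         effects = list(delta_gamma = c("V2.L" = -0.4))))
  net$M[] <- 0
  g <- gain_timecourse(net)
  for (cond in c("valid", "invalid")) {
    gm <- g$gain[[cond]]
    base <- -(vapply(net$intrinsics, `[[`, numeric(1), "gamma0") +
                (cond == "invalid") * net$effects$delta_gamma)
    expect_equal(gm, matrix(base, 8, ncol(gm),
                            dimnames = dimnames(gm)), tolerance = 1e-12)
  }
})

test_that("pre-stimulus gain equals the condition baseline", {
  sc <- default_validity_scenario()
  g <- gain_timecourse(sc$network)
  pre <- g$time < 0
  g0 <- vapply(sc$network$intrinsics, `[[`, numeric(1), "gamma0")
  base_valid <- -g0
  base_invalid <- -(g0 + sc$network$effects$delta_gamma)
  expect_equal(as.numeric(g$gain$valid[, pre][, 1]), base_valid,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(max(abs(g$gain$invalid[, pre][, 1] - base_invalid)), 1e-6)
  # and rises after the input arrives in the invalid left V2 source
  gl <- g$gain$invalid["V2.L", ]
  expect_gt(max(gl) - gl[1], 0.5)
  expect_gt(g$time[which.max(gl)], 120)
  expect_lt(g$time[which.max(gl)], 200)
})

test_that("the full analysis report has the declared structure", {
  res <- scenario_fit("default", 0)
  gd <- generate_dataset(res$scenario)
  out_dir <- file.path(tempdir(), "dcmgain-report-test")
  report <- run_full_analysis(gd$dataset,
                              config = list(out_dir = out_dir, seed = 0))
  expect_s3_class(report, "dcm_report")
  expect_equal(nrow(report$factorial$table), 8)
  expect_equal(nrow(report$provisional$table), 4)
  expect_equal(sum(report$factorial$table$probability), 1, tolerance = 1e-9)
  expect_true(report$winner %in% report$factorial$table$model)
  expect_true(all(diff(report$fit$trace) >= 0))
  expect_s3_class(report$gain, "gain_trajectory")
  # provenance reproduces the config verbatim
  prov <- jsonlite::read_json(file.path(out_dir, "provenance.json"),
                              simplifyVector = TRUE)
  expect_equal(prov$config$seed, 0)
  expect_true(file.exists(file.path(out_dir, "factorial_bmc.json")))
  expect_true(file.exists(file.path(out_dir, "effect_estimates.csv")))
  unlink(out_dir, recursive = TRUE)
})
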