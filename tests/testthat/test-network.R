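test_that("the default hierarchy has the declared edge structure", {
  net <- build_posner_network()
  expect_equal(nrow(net$sources), 8)
  expect_equal(length(unique(net$sources$label)), 8)
  expect_equal(sum(net$A_forward != 0), 8)
  expect_equal(sum(net$A_backward != 0), 8)
  expect_equal(sum(net$M != 0), 8)
  # every modulatory edge coincides with a backward driving edge
  expect_true(all((net$M != 0) == (net$A_backward != 0)))
  expect_true(all(diag(net$A_forward) == 0))
  expect_true(all(diag(net$A_backward) == 0))
  # forward edges ascend exactly one level within hemisphere
  lv <- setNames(net$sources$level, net$sources$label)
  hemi <- setNames(net$sources$hemisphere, net$sources$label)
  nz <- which(net$A_forward != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(nz))) {
    tgt <- rownames(net$A_forward)[nz[k, 1]]
    src <- colnames(net$A_forward)[nz[k, 2]]
    expect_equal(lv[[tgt]], lv[[src]] + 1L)
    expect_equal(hemi[[tgt]], hemi[[src]])
  }
  # backward/modulatory edges are the reciprocals
  expect_true(all(t(net$A_forward != 0) == (net$A_backward != 0)))
})

test_that("overrides are validated against the structure", {
  expect_error(build_posner_network(list(nonsense = 1)), "unknown override")
  expect_error(build_posner_network(list(A_forward = list("PC.L<-V2.L" = 1))),
               "structurally absent")
  expect_error(build_posner_network(
    list(effects = list(delta_M = list("V2.L<-PC.L" = 0.1)))),
    "structurally absent")
  net <- build_posner_network(list(A_forward = list("V3.L<-V2.L" = 5)))
  expect_equal(net$A_forward["V3.L", "V2.L"], 5)
})

test_that("the stimulus is a Gaussian bump with the canonical prior timing", {
  spec <- stimulus_spec()
  expect_equal(spec$peak_time, 120)
  expect_equal(spec$width, 16)
  expect_equal(gaussian_input(spec$peak_time, spec), spec$amplitude)
  expect_equal(gaussian_input(spec$peak_time + spec$width, spec),
               spec$amplitude * exp(-0.5))
  expect_equal(gaussian_input(spec$peak_time - spec$width, spec),
               spec$amplitude * exp(-0.5))
  expect_error(stimulus_spec(width = 0), "width")
  expect_error(stimulus_spec(target_source = "PC.L"), "V2")
})

test_that("integration respects condition symmetry and rest", {
  net <- build_posner_network()   # zero effects by default
  va <- integrate_network(net, "valid")
  iv <- integrate_network(net, "invalid")
  expect_identical(va$v, iv$v)
  expect_identical(va$gamma, iv$gamma)

  quiet <- build_posner_network(list(stimulus = list(amplitude = 0)))
  act <- integrate_network(quiet, "valid")
  expect_true(all(act$v == 0))
  g0 <- vapply(quiet$intrinsics, `[[`, numeric(1), "gamma0")
  expect_true(all(act$gamma == g0))
})

test_that("mirroring the hemispheres mirrors the output exactly", {
  sc <- default_validity_scenario()
  act <- integrate_network(sc$network, "invalid")
  mir <- mirror_hemispheres(sc$network)
  act_m <- integrate_network(mir, "invalid")
  perm <- c(5:8, 1:4)
  expect_identical(unname(act$v), unname(act_m$v[, perm, ]))
  expect_identical(unname(act$gamma), unname(act_m$gamma[perm, ]))
})

test_that("halving the step changes traces by less than 1 percent sup-norm", {
  sc <- default_validity_scenario()
  a1 <- integrate_network(sc$network, "invalid", dt = 1)
  a2 <- integrate_network(sc$network, "invalid", dt = 0.5)
  idx2 <- seq(1, dim(a2$v)[3], by = 2)
  rel <- max(abs(a1$v - a2$v[, , idx2])) / max(abs(a2$v))
  expect_lt(rel, 0.01)
})

test_that("integration error decreases under step refinement", {
  sc <- default_validity_scenario()
  ref <- integrate_network(sc$network, "invalid", dt = 0.25)
  a1 <- integrate_network(sc$network, "invalid", dt = 1)
  a2 <- integrate_network(sc$network, "invalid", dt = 0.5)
  e1 <- max(abs(a1$v - ref$v[, , seq(1, dim(ref$v)[3], by = 4)]))
  e2 <- max(abs(a2$v - ref$v[, , seq(1, dim(ref$v)[3], by = 2)]))
  expect_lt(e2, e1)
})

test_that("more invalid-condition self-inhibition never raises the peak response", {
  peaks <- vapply(c(0, 0.3, 0.7, 1.2), function(dg) {
    net <- build_posner_network(
      list(effects = list(delta_gamma = c("V2.R" = dg))))
    act <- integrate_network(net, "invalid")
    max(act$v["sp", "V2.R", ])
  }, numeric(1))
  expect_true(all(diff(peaks) <= 1e-10))
})

test_that("the all-zero state is a stable resting fixed point", {
  net <- build_posner_network()
  rs <- resting_state(net)
  expect_lt(rs$max_derivative, 1e-9)
  expect_true(all(rs$v == 0))

  # numeric Jacobian of the vector field at rest has eigenvalues in the
  # left half plane
  n <- nrow(net$sources)
  dim_s <- 4 * n
  J <- matrix(0, 2 * dim_s, 2 * dim_s)
  h <- 1e-6
  base_v <- matrix(0, 4, n); base_i <- matrix(0, 4, n)
  for (k in seq_len(dim_s)) {
    dv <- base_v; dv[k] <- h
    dp <- dcmgain:::network_vfield(net, dv, base_i)
    dm <- dcmgain:::network_vfield(net, -dv, base_i)
    J[, k] <- c(as.vector(dp$dv - dm$dv), as.vector(dp$di - dm$di)) / (2 * h)
    di <- base_i; di[k] <- h
    dp <- dcmgain:::network_vfield(net, base_v, di)
    dm <- dcmgain:::network_vfield(net, base_v, -di)
    J[, k + dim_s] <- c(as.vector(dp$dv - dm$dv),
                        as.vector(dp$di - dm$di)) / (2 * h)
  }
  expect_lt(max(Re(eigen(J, only.values = TRUE)$values)), 0)

  # a perturbed state relaxes back to rest
  v0 <- matrix(0.5, 4, n)
  rs2 <- resting_state(net, v0 = v0, i0 = matrix(0, 4, n))
  expect_lt(rs2$max_derivative, 1e-9)
  expect_lt(max(abs(rs2$v)), 1e-4)
})

test_that("compiled and reference vector fields agree", {
  sc <- default_validity_scenario()
  act <- integrate_network(sc$network, "invalid")
  # recompute gamma from the R-side field at a mid-response state
  k <- which(act$time == 150)
  d <- dcmgain:::network_vfield(sc$network, act$v[, , k],
                                act$v[, , k] * 0, "invalid",
                                ut = gaussian_input(150, sc$network$stimulus) /
                                  sc$network$stimulus$amplitude)
  expect_equal(as.numeric(d$gamma), as.numeric(act$gamma[, k]),
               tolerance = 1e-10)
})

test_that("source activity exports to a tidy table", {
  net <- build_posner_network()
  act <- integrate_network(net, "valid", window = c(-50, 0))
  df <- activity_to_df(act)
  expect_equal(nrow(df), 4 * 8 * length(act$time))
  expect_setequal(unique(df$population), c("ss", "sp", "ii", "dp"))
  expect_setequal(unique(df$hemisphere), c("L", "R"))
})
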