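#' Exogenous stimulus specification
#'
#' The visual target is modeled as a Gaussian bump of drive delivered to the
#' spiny stellate population of a V2 source, with prior peak 120 ms after
#' target onset and prior width 16 ms. A configurable fraction of the input is
#' delivered to the mirror V2 source, reflecting the ipsilateral spread of
#' early visual responses; the network itself has no interhemispheric edges.
#'
#' @param peak_time input peak (ms after target onset).
#' @param width Gaussian standard deviation (ms); must be positive.
#' @param amplitude input strength (a.u.).
#' @param target_source label of the stimulated source; must be a V2 source.
#' @param contralateral_fraction fraction of `amplitude` delivered to the
#'   mirror-hemisphere V2 source (default 0.5, the upper end of reported
#'   ipsilateral/contralateral early visual response ratios).
#' @return object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(peak_time = 120, width = 16, amplitude = 3,
                          target_source = "V2.R", contralateral_fraction = 0.5) {
  if (!is.finite(width) || width <= 0) stop("width must be > 0", call. = FALSE)
  if (!grepl("^V2\\.[LR]$", target_source))
    stop("target_source must be a V2 source ('V2.L' or 'V2.R')", call. = FALSE)
  stopifnot(contralateral_fraction >= 0, contralateral_fraction <= 1)
  structure(list(peak_time = peak_time, width = width, amplitude = amplitude,
                 target_source = target_source,
                 contralateral_fraction = contralateral_fraction),
            class = "stimulus_spec")
}

#' Gaussian exogenous input
#'
#' @param t time (ms after target onset); vectorized.
#' @param spec a [stimulus_spec()].
#' @return drive value(s) `amplitude * exp(-(t - peak)^2 / (2 width^2))`.
#' @export
gaussian_input <- function(t, spec = stimulus_spec()) {
  if (!is.finite(spec$width) || spec$width <= 0)
    stop("width must be > 0", call. = FALSE)
  spec$amplitude * exp(-(t - spec$peak_time)^2 / (2 * spec$width^2))
}

#' Source table of the two-hemisphere visual hierarchy
#'
#' Eight sources: bilateral early visual (V2, level 1), bilateral dorsal (V3)
#' and occipitotemporal (V5) extrastriate sources (level 2) and bilateral
#' superior parietal sources (PC, level 3). Labels are `name.hemisphere`,
#' ordered left hemisphere first.
#'
#' @return data frame with columns `label`, `name`, `hemisphere`, `level`.
#' @export
source_table <- function() {
  df <- expand.grid(name = SOURCE_NAMES, hemisphere = HEMISPHERES,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$level <- c(1L, 2L, 2L, 3L)[match(df$name, SOURCE_NAMES)]
  df$label <- paste(df$name, df$hemisphere, sep = ".")
  df[, c("label", "name", "hemisphere", "level")]
}

# within-hemisphere forward edges as (target, source) label pairs
hierarchy_edges <- function() {
  e <- rbind(c("V3", "V2"), c("V5", "V2"), c("PC", "V3"), c("PC", "V5"))
  do.call(rbind, lapply(HEMISPHERES, function(h)
    data.frame(target = paste(e[, 1], h, sep = "."),
               source = paste(e[, 2], h, sep = "."),
               stringsAsFactors = FALSE)))
}

#' Assemble the eight-source Posner hierarchy
#'
#' Builds the default network: within each hemisphere V2 sends forward
#' connections to V3 and V5, which send forward connections to PC; every
#' forward edge is reciprocated by a backward driving edge and a backward
#' modulatory edge (deep pyramidal afferents acting on the superficial
#' pyramidal self-inhibition of the lower source). Hemispheres are not
#' interconnected.
#'
#' @param overrides named list of overrides. Scalars `forward_strength`,
#'   `backward_strength`, `modulatory_strength`, `gamma0`, `mod_coef`,
#'   `bwd_ii_weight`; lists `stimulus`, `sigmoid`, `kappa`; per-edge lists
#'   `A_forward`, `A_backward`, `M` with entries named `"target<-source"`;
#'   `effects` with `delta_gamma` (named by source label), `delta_M`,
#'   `delta_B` (per-edge lists). Referencing a structurally absent edge or an
#'   unknown key is an error.
#' @return object of class `dcm_network`.
#' @export
build_posner_network <- function(overrides = list()) {
  known <- c("forward_strength", "backward_strength", "modulatory_strength",
             "gamma0", "mod_coef", "bwd_ii_weight", "stimulus", "sigmoid",
             "kappa", "A_forward", "A_backward", "M", "effects")
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown override keys: ", paste(bad, collapse = ", "), call. = FALSE)

  src <- source_table()
  n <- nrow(src)
  lab <- src$label
  edges <- hierarchy_edges()

  fwd <- overrides$forward_strength %||% 2
  bwd <- overrides$backward_strength %||% 1
  mod <- overrides$modulatory_strength %||% 3

  zero <- matrix(0, n, n, dimnames = list(lab, lab))
  A_forward <- A_backward <- M <- zero
  for (k in seq_len(nrow(edges))) {
    A_forward[edges$target[k], edges$source[k]] <- fwd
    A_backward[edges$source[k], edges$target[k]] <- bwd
    M[edges$source[k], edges$target[k]] <- mod
  }

  sig_args <- overrides$sigmoid %||% list()
  sigmoid <- do.call(sigmoid_spec, sig_args)
  kap_args <- overrides$kappa %||% list()
  kappa <- c(0.25, 0.25, 0.25, 0.0625)
  if (length(kap_args)) {
    stopifnot(is.numeric(unlist(kap_args)), length(unlist(kap_args)) == 4)
    kappa <- as.numeric(unlist(kap_args))
  }
  g0 <- overrides$gamma0 %||% 0.4
  gamma0 <- if (length(g0) == 1) setNames(rep(as.numeric(g0), n), lab)
            else {
              stopifnot(all(names(g0) %in% lab))
              out <- setNames(rep(0, n), lab); out[names(g0)] <- g0; out
            }
  intr <- lapply(seq_len(n), function(i)
    source_intrinsics(kappa = kappa, gamma0 = gamma0[[i]], sigmoid = sigmoid))
  names(intr) <- lab

  apply_edge_overrides <- function(mat, ov, what) {
    for (nm in names(ov)) {
      ts <- strsplit(nm, "<-", fixed = TRUE)[[1]]
      if (length(ts) != 2 || !all(ts %in% lab))
        stop(sprintf("malformed %s edge override '%s'", what, nm), call. = FALSE)
      if (mat[ts[1], ts[2]] == 0)
        stop(sprintf("%s edge %s is structurally absent", what, nm), call. = FALSE)
      mat[ts[1], ts[2]] <- ov[[nm]]
    }
    mat
  }
  A_forward <- apply_edge_overrides(A_forward, overrides$A_forward, "forward")
  A_backward <- apply_edge_overrides(A_backward, overrides$A_backward, "backward")
  M <- apply_edge_overrides(M, overrides$M, "modulatory")

  apply_effect_overrides <- function(delta, ov, structure, what) {
    for (nm in names(ov)) {
      ts <- strsplit(nm, "<-", fixed = TRUE)[[1]]
      if (length(ts) != 2 || !all(ts %in% lab))
        stop(sprintf("malformed %s effect override '%s'", what, nm), call. = FALSE)
      if (structure[ts[1], ts[2]] == 0)
        stop(sprintf("%s edge %s is structurally absent", what, nm), call. = FALSE)
      delta[ts[1], ts[2]] <- ov[[nm]]
    }
    delta
  }
  effects <- condition_effects(n_sources = n, labels = lab)
  if (!is.null(overrides$effects)) {
    ov <- overrides$effects
    if (!is.null(ov$delta_gamma)) {
      stopifnot(all(names(ov$delta_gamma) %in% lab))
      effects$delta_gamma[names(ov$delta_gamma)] <- ov$delta_gamma
    }
    effects$delta_M <- apply_effect_overrides(effects$delta_M, ov$delta_M,
                                              M, "modulatory")
    effects$delta_B <- apply_effect_overrides(effects$delta_B, ov$delta_B,
                                              A_backward, "backward")
  }

  stim_args <- overrides$stimulus %||% list()
  stimulus <- do.call(stimulus_spec, stim_args)

  structure(list(sources = src, intrinsics = intr,
                 A_forward = A_forward, A_backward = A_backward, M = M,
                 bwd_ii_weight = overrides$bwd_ii_weight %||% 0.5,
                 mod_coef = overrides$mod_coef %||% 1.5,
                 effects = effects, stimulus = stimulus),
            class = "dcm_network")
}

#' Condition-specific effect parameters
#'
#' The valid condition is the baseline; all effects apply only in the invalid
#' condition. `delta_gamma` is an additive increment to the baseline log
#' self-inhibition per source; `delta_M` and `delta_B` scale the modulatory
#' and backward driving connections in log space
#' (\eqn{M_{invalid} = M e^{\Delta M}}).
#'
#' @param n_sources number of sources.
#' @param labels source labels.
#' @return list of class `condition_effects`.
#' @export
condition_effects <- function(n_sources = 8, labels = source_table()$label) {
  zero <- matrix(0, n_sources, n_sources, dimnames = list(labels, labels))
  structure(list(delta_gamma = setNames(rep(0, n_sources), labels),
                 delta_M = zero, delta_B = zero),
            class = "condition_effects")
}

# condition-effective quantities fed to the integrator
condition_params <- function(network, condition = c("valid", "invalid")) {
  condition <- match.arg(condition)
  inv <- condition == "invalid"
  eff <- network$effects
  gamma_base <- vapply(network$intrinsics, `[[`, numeric(1), "gamma0")
  if (inv) gamma_base <- gamma_base + eff$delta_gamma
  M_eff <- network$M * if (inv) exp(eff$delta_M) else 1
  B_eff <- network$A_backward * if (inv) exp(eff$delta_B) else 1
  stim <- network$stimulus
  lab <- network$sources$label
  stimgain <- setNames(rep(0, length(lab)), lab)
  stimgain[stim$target_source] <- stim$amplitude
  mirror <- mirror_label(stim$target_source)
  stimgain[mirror] <- stim$amplitude * stim$contralateral_fraction
  list(gamma_base = gamma_base, M_eff = M_eff, B_eff = B_eff,
       stimgain = stimgain)
}

mirror_label <- function(label) {
  parts <- strsplit(label, ".", fixed = TRUE)[[1]]
  paste(parts[1], setdiff(HEMISPHERES, parts[2]), sep = ".")
}

#' Integrate the coupled network dynamics
#'
#' Fixed-step fourth-order Runge-Kutta integration of the eight coupled
#' microcircuits over the peristimulus window. At every step the superficial
#' pyramidal self-inhibition of each source is \eqn{e^{\gamma_{eff}}} with
#' \eqn{\gamma_{eff}} computed from the instantaneous deep-pyramidal firing of
#' its modulatory afferents (see [effective_gamma()]).
#'
#' @param params a `dcm_network` from [build_posner_network()].
#' @param condition `"valid"` or `"invalid"`.
#' @param window peristimulus window in ms (default `c(-50, 400)`).
#' @param dt integration step (ms), default 1.
#' @return object of class `source_activity`: list with `time` (ms), `v`
#'   (4 populations x 8 sources x time depolarization array, mV), `gamma`
#'   (8 x time instantaneous log self-inhibition) and metadata.
#' @export
integrate_network <- function(params, condition = c("valid", "invalid"),
                              window = c(-50, 400), dt = 1) {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "dcm_network"), dt > 0, window[2] > window[1])
  cp <- condition_params(params, condition)
  n <- nrow(params$sources)
  C <- array(0, c(4, 4, n))
  kap <- matrix(0, 4, n)
  slope <- thresh <- numeric(n)
  for (i in seq_len(n)) {
    intr <- params$intrinsics[[i]]
    C[, , i] <- intr$intrinsic_coupling
    kap[, i] <- intr$kappa
    slope[i] <- intr$sigmoid$slope
    thresh[i] <- intr$sigmoid$threshold
  }
  tt <- seq(window[1], window[2], by = dt)
  out <- cmc_integrate(C, kap, cp$gamma_base,
                       params$A_forward, cp$B_eff, cp$M_eff,
                       params$bwd_ii_weight, params$mod_coef,
                       slope, thresh, cp$stimgain,
                       params$stimulus$peak_time, params$stimulus$width,
                       window[1], dt, length(tt))
  lab <- params$sources$label
  dimnames(out$v) <- list(POP_SHORT, lab, NULL)
  dimnames(out$gamma) <- list(lab, NULL)
  structure(list(time = tt, v = out$v, gamma = out$gamma,
                 condition = condition, sources = lab, dt = dt),
            class = "source_activity")
}

# R-side evaluation of the full network vector field (reference/diagnostics;
# the production path is the compiled integrator)
network_vfield <- function(params, v, cur, condition = "valid", ut = 0) {
  cp <- condition_params(params, condition)
  n <- nrow(params$sources)
  sig0 <- vapply(params$intrinsics, function(i) i$sigmoid$sigma0, numeric(1))
  r <- vapply(seq_len(n), function(i)
    sigmoid_rate(v[, i], params$intrinsics[[i]]$sigmoid) - sig0[i],
    numeric(4))
  gam <- cp$gamma_base - params$mod_coef * as.vector(cp$M_eff %*% r[4, ])
  inp <- vapply(seq_len(n), function(i)
    as.vector(params$intrinsics[[i]]$intrinsic_coupling %*% r[, i]),
    numeric(4))
  bdrv <- as.vector(cp$B_eff %*% r[4, ])
  inp[1, ] <- inp[1, ] + as.vector(params$A_forward %*% r[2, ]) + cp$stimgain * ut
  inp[2, ] <- inp[2, ] + bdrv - exp(gam) * r[2, ]
  inp[3, ] <- inp[3, ] + params$bwd_ii_weight * bdrv
  kap <- vapply(params$intrinsics, `[[`, numeric(4), "kappa")
  list(dv = cur, di = kap * inp - 2 * kap * cur - kap^2 * v, gamma = gam)
}

#' Resting fixed point of the network
#'
#' With drives expressed as firing-rate deviations from baseline, the all-zero
#' state is the resting fixed point by construction. This function verifies
#' that the derivatives vanish there (and, if an initial state is supplied,
#' relaxes it toward rest by input-free integration).
#'
#' @param params a `dcm_network`.
#' @param v0,i0 optional initial state matrices (4 x sources).
#' @param tol derivative tolerance (default 1e-9).
#' @param max_time relaxation budget (ms).
#' @return list with `v`, `i` (the fixed point) and `max_derivative`.
#' @export
resting_state <- function(params, v0 = NULL, i0 = NULL, tol = 1e-9,
                          max_time = 20000) {
  n <- nrow(params$sources)
  v <- v0 %||% matrix(0, 4, n)
  cur <- i0 %||% matrix(0, 4, n)
  d <- network_vfield(params, v, cur)
  md <- max(abs(d$dv), abs(d$di))
  if (md >= tol) {
    # relax by integrating the input-free dynamics in chunks
    quiet <- params
    quiet$stimulus$amplitude <- 0
    elapsed <- 0
    dt <- 1
    while (md >= tol && elapsed < max_time) {
      for (k in 1:500) {
        d1 <- network_vfield(quiet, v, cur)
        d2 <- network_vfield(quiet, v + dt / 2 * d1$dv, cur + dt / 2 * d1$di)
        d3 <- network_vfield(quiet, v + dt / 2 * d2$dv, cur + dt / 2 * d2$di)
        d4 <- network_vfield(quiet, v + dt * d3$dv, cur + dt * d3$di)
        v <- v + dt / 6 * (d1$dv + 2 * d2$dv + 2 * d3$dv + d4$dv)
        cur <- cur + dt / 6 * (d1$di + 2 * d2$di + 2 * d3$di + d4$di)
      }
      elapsed <- elapsed + 500
      d <- network_vfield(params, v, cur)
      md <- max(abs(d$dv), abs(d$di))
    }
    if (md >= tol)
      stop("no fixed point found within the relaxation budget", call. = FALSE)
  }
  list(v = v, i = cur, max_derivative = md)
}

#' Mirror the network across hemispheres
#'
#' Swaps the left and right hemisphere blocks of every parameter, including
#' condition effects and the stimulated source. Because the hierarchy contains
#' no interhemispheric edges, integrating a mirrored network yields exactly
#' the mirrored source activity.
#'
#' @param network a `dcm_network`.
#' @return the mirrored `dcm_network`.
#' @export
mirror_hemispheres <- function(network) {
  n <- nrow(network$sources)
  half <- n / 2
  p <- c(seq_len(half) + half, seq_len(half))
  lab <- network$sources$label
  out <- network
  out$intrinsics <- network$intrinsics[p]
  names(out$intrinsics) <- lab
  relab <- function(m) {
    m <- m[p, p, drop = FALSE]
    dimnames(m) <- list(lab, lab)
    m
  }
  out$A_forward <- relab(network$A_forward)
  out$A_backward <- relab(network$A_backward)
  out$M <- relab(network$M)
  out$effects$delta_gamma <- setNames(network$effects$delta_gamma[p], lab)
  out$effects$delta_M <- relab(network$effects$delta_M)
  out$effects$delta_B <- relab(network$effects$delta_B)
  out$stimulus$target_source <- mirror_label(network$stimulus$target_source)
  out
}

#' Tidy export of source activity
#'
#' @param activity a `source_activity` from [integrate_network()].
#' @return data frame with columns `time_ms`, `source`, `hemisphere`,
#'   `population`, `v`.
#' @export
activity_to_df <- function(activity) {
  lab <- activity$sources
  hemi <- sub("^.*\\.", "", lab)
  grid <- expand.grid(population = POP_SHORT, source = lab,
                      time_ms = activity$time,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$hemisphere <- sub("^.*\\.", "", grid$source)
  grid$v <- as.vector(activity$v)
  grid[, c("time_ms", "source", "hemisphere", "population", "v")]
}
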