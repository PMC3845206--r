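#' Sigmoid specification for population firing rates
#'
#' Firing rates are a logistic function of depolarization,
#' \eqn{\sigma(v) = 1 / (1 + e^{-slope (v - threshold)})}, bounded in
#' \eqn{[0, 1]}. The baseline rate \eqn{\sigma_0 = \sigma(0)} plays a special
#' role: all synaptic drives in the network are expressed as deviations
#' \eqn{\sigma(v) - \sigma_0}, so the all-zero state is a fixed point and the
#' top-down modulation of gain vanishes when afferents fire at baseline.
#'
#' @param slope sigmoid steepness (1/mV); default 0.56.
#' @param threshold depolarization at half-maximum rate (mV); default 0,
#'   which centres the sigmoid so \eqn{\sigma_0 = 0.5}.
#' @return an object of class `sigmoid_spec` with fields `slope`, `threshold`
#'   and the implied baseline rate `sigma0`.
#' @export
sigmoid_spec <- function(slope = 0.56, threshold = 0) {
  stopifnot(is.finite(slope), slope > 0, is.finite(threshold))
  structure(list(slope = slope, threshold = threshold,
                 sigma0 = 1 / (1 + exp(slope * threshold))),
            class = "sigmoid_spec")
}

#' Population firing rate
#'
#' @param v depolarization (mV); may be a vector.
#' @param spec a [sigmoid_spec()].
#' @return firing rate(s) in \eqn{[0, 1]}; `spec$sigma0` at `v = 0`.
#' @export
sigmoid_rate <- function(v, spec = sigmoid_spec()) {
  stopifnot_finite(v, "depolarization")
  1 / (1 + exp(-spec$slope * (v - spec$threshold)))
}

#' Precision encoded by self-inhibition
#'
#' The log self-inhibition \eqn{\gamma} of superficial pyramidal cells is the
#' negative log precision of the prediction errors they report:
#' \eqn{\Pi = e^{-\gamma}}. Lower self-inhibition means higher gain and higher
#' expected precision.
#'
#' @param gamma log self-inhibition (dimensionless); vectorized.
#' @return precision \eqn{\Pi > 0}.
#' @seealso [precision_inverse()] for the reverse map.
#' @export
precision_of <- function(gamma) {
  stopifnot_finite(gamma, "gamma")
  exp(-gamma)
}

#' @rdname precision_of
#' @param pi_ precision \eqn{\Pi > 0}.
#' @return `precision_inverse`: the log self-inhibition \eqn{\gamma = -\ln\Pi}.
#' @export
precision_inverse <- function(pi_) {
  stopifnot_finite(pi_, "precision")
  if (any(pi_ <= 0)) stop("precision must be positive", call. = FALSE)
  -log(pi_)
}

#' Intrinsic parameters of one cortical source
#'
#' A source is a four-population canonical microcircuit: spiny stellate (ss),
#' superficial pyramidal (sp), inhibitory interneuron (ii) and deep pyramidal
#' (dp) cells. `intrinsic_coupling` holds the signed within-source synaptic
#' strengths (rows = target population, columns = afferent population);
#' excitatory entries are nonnegative and inhibitory entries nonpositive. The
#' sp self-connection is *not* stored here: superficial pyramidal
#' self-inhibition is always \eqn{e^{\gamma}} with \eqn{\gamma} the (possibly
#' state- and condition-dependent) log self-inhibition built on `gamma0`.
#'
#' @param intrinsic_coupling 4x4 signed coupling matrix; the default realizes
#'   an excitatory ss -> sp -> dp chain with interneuron inhibition of ss, sp
#'   and dp, and fixed ss/ii self-inhibition.
#' @param kappa per-population rate constants (1/ms); defaults 1/4 for the
#'   three fast populations and 1/16 for deep pyramidal cells.
#' @param gamma0 baseline log self-inhibition of superficial pyramidal cells.
#' @param sigmoid a [sigmoid_spec()].
#' @return object of class `source_intrinsics`.
#' @export
source_intrinsics <- function(intrinsic_coupling = default_intrinsic_coupling(),
                              kappa = c(0.25, 0.25, 0.25, 0.0625),
                              gamma0 = 0,
                              sigmoid = sigmoid_spec()) {
  stopifnot(is.matrix(intrinsic_coupling),
            all(dim(intrinsic_coupling) == c(4, 4)),
            length(kappa) == 4, all(kappa > 0),
            is.finite(gamma0),
            inherits(sigmoid, "sigmoid_spec"))
  if (intrinsic_coupling[2, 2] != 0)
    stop("the sp->sp entry must be zero: sp self-inhibition is derived from gamma",
         call. = FALSE)
  ex <- excitatory_mask()
  if (any(intrinsic_coupling[ex] < 0) || any(intrinsic_coupling[!ex] > 0))
    stop("excitatory couplings must be >= 0 and inhibitory couplings <= 0",
         call. = FALSE)
  dimnames(intrinsic_coupling) <- list(POP_SHORT, POP_SHORT)
  structure(list(intrinsic_coupling = intrinsic_coupling,
                 kappa = setNames(as.numeric(kappa), POP_SHORT),
                 gamma0 = gamma0, sigmoid = sigmoid),
            class = "source_intrinsics")
}

#' @rdname source_intrinsics
#' @export
default_intrinsic_coupling <- function() {
  m <- rbind(c(-1, 0, -2, 0),   # ss <- ss(self), ii
             c( 4, 0, -2, 0),   # sp <- ss, ii (self via gamma only)
             c( 2, 2, -1, 0),   # ii <- ss, sp, self
             c( 0, 3, -1, 0))   # dp <- sp, ii
  dimnames(m) <- list(POP_SHORT, POP_SHORT)
  m
}

# TRUE where population q -> population p is excitatory (ss and pyramidal
# afferents excite; interneuron afferents and self-inhibition terms inhibit)
excitatory_mask <- function() {
  ex_from <- c(TRUE, TRUE, FALSE, TRUE)         # ss, sp, ii, dp afferents
  m <- matrix(rep(ex_from, each = 4), 4, 4)
  diag(m) <- FALSE                              # self-connections are inhibitory
  m
}

#' Instantaneous log self-inhibition under top-down modulation
#'
#' Computes \eqn{\gamma = \gamma_0 + [invalid]\,\Delta\gamma - c \sum_k M_k
#' (\sigma_k - \sigma_0)}: the baseline log self-inhibition plus a
#' condition-specific increment, minus the modulatory influence of afferent
#' deep-pyramidal firing. When all afferents fire at baseline rate
#' \eqn{\sigma_0} the modulatory term vanishes and \eqn{\gamma} reduces to the
#' condition baseline.
#'
#' @param gamma0 baseline log self-inhibition.
#' @param delta_gamma condition increment, applied only when
#'   `condition == "invalid"`.
#' @param condition `"valid"` (baseline) or `"invalid"`.
#' @param mod_row modulatory in-strengths from afferent sources.
#' @param afferent_rates firing rates of the modulatory afferents, in
#'   \eqn{[0, 1]}; same length as `mod_row`.
#' @param spec [sigmoid_spec()] supplying the baseline rate \eqn{\sigma_0}.
#' @param c_mod modulation coefficient (default 3/2).
#' @return the instantaneous log self-inhibition (scalar).
#' @export
effective_gamma <- function(gamma0, delta_gamma = 0,
                            condition = c("valid", "invalid"),
                            mod_row = numeric(0), afferent_rates = numeric(0),
                            spec = sigmoid_spec(), c_mod = 1.5) {
  condition <- match.arg(condition)
  if (length(mod_row) != length(afferent_rates))
    stop("mod_row and afferent_rates must have the same length", call. = FALSE)
  if (length(afferent_rates) && (any(afferent_rates < 0) || any(afferent_rates > 1)))
    stop("afferent rates must lie in [0, 1]", call. = FALSE)
  gamma0 + (condition == "invalid") * delta_gamma -
    c_mod * sum(mod_row * (afferent_rates - spec$sigma0))
}

#' Derivative of one population's convolution kinetics
#'
#' Second-order (alpha-kernel) dynamics: \eqn{\dot v = i}, \eqn{\dot i =
#' \kappa u - 2\kappa i - \kappa^2 v}. A constant drive \eqn{u} settles at
#' \eqn{v = u / \kappa}; the impulse response \eqn{\kappa t e^{-\kappa t}}
#' peaks at \eqn{t = 1/\kappa}.
#'
#' @param state numeric `c(v, i)`: depolarization (mV) and current (mV/ms).
#' @param presynaptic_input summed synaptic drive.
#' @param kappa rate constant (1/ms), must be positive.
#' @return numeric `c(dv, di)`.
#' @export
population_derivative <- function(state, presynaptic_input, kappa) {
  stopifnot_finite(c(state, presynaptic_input), "population state or input")
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  c(dv = state[[2]],
    di = kappa * presynaptic_input - 2 * kappa * state[[2]] - kappa^2 * state[[1]])
}

#' Didactic error-unit integrator
#'
#' Integrates \eqn{\dot\xi = \mu - f - e^{\gamma}\xi} for constant expectation
#' \eqn{\mu}, top-down prediction \eqn{f} and log self-inhibition
#' \eqn{\gamma}. At steady state the error unit reports the precision-weighted
#' prediction error \eqn{\xi = e^{-\gamma}(\mu - f) = \Pi(\mu - f)}.
#'
#' @param unit list with fields `mu`, `prediction`, `gamma` and optionally
#'   `xi` (initial error state, default 0); see [error_unit()].
#' @param duration integration time; defaults to 40 time constants
#'   \eqn{40 e^{-\gamma}}.
#' @param dt step size; must satisfy the explicit-Euler stability bound
#'   `dt * exp(gamma) < 2`. Defaults to a tenth of the time constant.
#' @return list with `time`, `xi` (the trajectory) and `steady_state`
#'   (the analytic fixed point \eqn{\Pi(\mu - f)}).
#' @export
error_unit_trajectory <- function(unit, duration = NULL, dt = NULL) {
  tau <- exp(-unit$gamma)
  duration <- duration %||% (40 * tau)
  dt <- dt %||% (tau / 10)
  if (dt * exp(unit$gamma) >= 2)
    stop("unstable step size: need dt * exp(gamma) < 2", call. = FALSE)
  n <- max(2L, ceiling(duration / dt) + 1L)
  xi <- numeric(n)
  xi[1] <- unit$xi %||% 0
  drive <- unit$mu - unit$prediction
  decay <- exp(unit$gamma)
  for (k in seq_len(n - 1L)) xi[k + 1L] <- xi[k] + dt * (drive - decay * xi[k])
  list(time = (seq_len(n) - 1) * dt, xi = xi,
       steady_state = precision_of(unit$gamma) * drive)
}

#' @rdname error_unit_trajectory
#' @param mu expectation signal.
#' @param prediction top-down prediction of the expectation.
#' @param gamma log self-inhibition (negative log precision) of the unit.
#' @param xi initial error state.
#' @export
error_unit <- function(mu, prediction, gamma, xi = 0) {
  stopifnot_finite(c(mu, prediction, gamma, xi), "error-unit fields")
  structure(list(mu = mu, prediction = prediction, gamma = gamma, xi = xi),
            class = "error_unit")
}
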