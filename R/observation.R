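#' Synthetic lead field
#'
#' Generates smooth random channel topographies per source, with a
#' configurable between-source topography correlation emulating MEG field
#' spread. Smoothness is imposed by averaging spatially adjacent channel
#' loadings; correlation by mixing each source topography with a shared
#' component. Columns are scaled to unit root-mean-square.
#'
#' @param n_channels number of sensors (default 64).
#' @param sources source labels (columns), default the eight-source hierarchy.
#' @param rho between-source topography correlation (default 0.3).
#' @param seed RNG seed; the lead field is deterministic given the seed.
#' @return object of class `lead_field`: list with `L` (channels x sources),
#'   `channels`, `sources`.
#' @export
make_lead_field <- function(n_channels = 64, sources = source_table()$label,
                            rho = 0.3, seed = 101) {
  stopifnot(n_channels >= length(sources), rho >= 0, rho < 1)
  L <- with_seed(seed, {
    smooth <- function(x) stats::filter(c(x[1], x, x[length(x)]),
                                        rep(1 / 3, 3))[2:(length(x) + 1)]
    shared <- smooth(rnorm(n_channels))
    vapply(seq_along(sources), function(s) {
      topo <- sqrt(1 - rho) * smooth(rnorm(n_channels)) + sqrt(rho) * shared
      topo / sqrt(mean(topo^2))
    }, numeric(n_channels))
  })
  colnames(L) <- sources
  channels <- sprintf("MEG%03d", seq_len(n_channels))
  rownames(L) <- channels
  if (any(colSums(abs(L)) == 0)) stop("lead field has an all-zero source column")
  structure(list(L = L, channels = channels, sources = sources),
            class = "lead_field")
}

#' Population contribution weights
#'
#' Relative contribution of the three excitatory populations to the measured
#' signal. Superficial pyramidal cells dominate; inhibitory interneurons
#' contribute nothing.
#'
#' @param ss,sp,dp weights for spiny stellate, superficial pyramidal and deep
#'   pyramidal depolarization. `sp` must be strictly the largest.
#' @return named numeric vector over all four populations (ii = 0).
#' @export
contribution_weights <- function(ss = 0.2, sp = 1.0, dp = 0.5) {
  if (!(sp > ss && sp > dp))
    stop("superficial pyramidal weight must be strictly greatest", call. = FALSE)
  if (any(c(ss, sp, dp) < 0)) stop("weights must be nonnegative", call. = FALSE)
  c(ss = ss, sp = sp, ii = 0, dp = dp)
}

#' Condition-labelled sensor dataset
#'
#' @param data named list of channels x time matrices (one per condition).
#' @param sfreq sampling rate (Hz).
#' @param window peristimulus window in ms (target onset at 0).
#' @param lead the generating [make_lead_field()] object.
#' @return object of class `sensor_dataset`.
#' @export
sensor_dataset <- function(data, sfreq = 200, window = c(-50, 400),
                           lead = NULL) {
  stopifnot(is.list(data), length(data) >= 1)
  nt <- unique(vapply(data, ncol, integer(1)))
  nc <- unique(vapply(data, nrow, integer(1)))
  if (length(nt) != 1 || length(nc) != 1)
    stop("all conditions must share channel and time dimensions", call. = FALSE)
  times <- seq(window[1], window[2], length.out = nt)
  structure(list(data = data, sfreq = sfreq, window = window, times = times,
                 channels = rownames(data[[1]]), lead = lead),
            class = "sensor_dataset")
}

#' Project source activity to sensors
#'
#' The sensor signal is the lead field applied to the weighted sum of
#' excitatory population depolarizations,
#' \eqn{y(t) = L \sum_p w_p v_p(t)}; the map is linear in the activity.
#'
#' @param activity a `source_activity` from [integrate_network()].
#' @param lead a [make_lead_field()] object with sources aligned to the
#'   activity's source order.
#' @param weights population weights from [contribution_weights()].
#' @return channels x time matrix.
#' @export
project_to_sensors <- function(activity, lead, weights = contribution_weights()) {
  if (!identical(lead$sources, activity$sources))
    stop("lead field source order does not match activity", call. = FALSE)
  nt <- length(activity$time)
  src_signal <- vapply(seq_len(nt), function(k)
    as.vector(weights %*% activity$v[, , k]), numeric(length(lead$sources)))
  lead$L %*% src_signal
}

#' Canonical modes of the scalp data
#'
#' The first `n` principal components of the condition-concatenated sensor
#' data after projection onto the column space of the lead field: the
#' orthonormal sensor-space directions of maximal variance that source
#' activity can explain.
#'
#' @param data a [sensor_dataset()] (all conditions are used).
#' @param lead a [make_lead_field()] object.
#' @param n number of modes (default 8); must not exceed the lead-field rank.
#' @return object of class `mode_basis`: list with `U` (channels x n,
#'   orthonormal), `var_explained`, `n`.
#' @export
canonical_modes <- function(data, lead, n = 8) {
  stopifnot(inherits(data, "sensor_dataset"))
  if (n > length(lead$channels))
    stop("more modes requested than channels", call. = FALSE)
  qrL <- qr(lead$L)
  if (qrL$rank < n)
    stop(sprintf("lead field rank (%d) is below the requested %d modes",
                 qrL$rank, n), call. = FALSE)
  Y <- do.call(cbind, data$data)
  Q <- qr.Q(qrL)[, seq_len(qrL$rank), drop = FALSE]
  Yp <- Q %*% (t(Q) %*% Y)
  sv <- svd(Yp, nu = n, nv = 0)
  U <- sv$u
  rownames(U) <- rownames(lead$L)
  structure(list(U = U, var_explained = sv$d[seq_len(n)]^2 / sum(sv$d^2),
                 n = n), class = "mode_basis")
}

#' Reduce sensor data to mode space
#'
#' @param data a [sensor_dataset()].
#' @param basis a [canonical_modes()] basis.
#' @return object of class `mode_dataset`: list with `Y` (named list of
#'   n_modes x time matrices), `times`, `sfreq`, `basis`.
#' @export
reduce_to_modes <- function(data, basis) {
  stopifnot(inherits(basis, "mode_basis"))
  if (nrow(basis$U) != nrow(data$data[[1]]))
    stop("mode basis and data channel dimensions do not match", call. = FALSE)
  Y <- lapply(data$data, function(d) t(basis$U) %*% d)
  structure(list(Y = Y, times = data$times, sfreq = data$sfreq, basis = basis,
                 lead = data$lead),
            class = "mode_dataset")
}

#' @rdname reduce_to_modes
#' @param modes a `mode_dataset`.
#' @return `expand_from_modes`: a [sensor_dataset()] reconstructed from the
#'   retained modes.
#' @export
expand_from_modes <- function(modes) {
  data <- lapply(modes$Y, function(y) modes$basis$U %*% y)
  sensor_dataset(data, sfreq = modes$sfreq,
                 window = range(modes$times))
}

#' Add white sensor noise at a target signal-to-noise ratio
#'
#' Gaussian noise with a common variance across channels, scaled so that
#' \eqn{10 \log_{10}(P_{signal}/P_{noise})} equals `snr_db`, where signal
#' power is the mean square over all conditions, channels and samples.
#'
#' @param data a [sensor_dataset()].
#' @param snr_db target SNR in dB (use `Inf` for no noise).
#' @param seed RNG seed; identical seeds give identical noise.
#' @return the noisy `sensor_dataset`.
#' @export
add_sensor_noise <- function(data, snr_db, seed = 1) {
  stopifnot(inherits(data, "sensor_dataset"))
  if (is.infinite(snr_db) && snr_db > 0) return(data)
  if (!is.finite(snr_db)) stop("snr_db must be finite or +Inf", call. = FALSE)
  p_sig <- mean(unlist(lapply(data$data, function(d) d^2)))
  if (p_sig == 0)
    stop("cannot scale noise to zero-power signal", call. = FALSE)
  sd_noise <- sqrt(p_sig / 10^(snr_db / 10))
  data$data <- with_seed(seed, lapply(data$data, function(d)
    d + matrix(rnorm(length(d), sd = sd_noise), nrow(d), ncol(d))))
  data
}
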