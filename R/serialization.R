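#' Flat key/value serialization of network parameters
#'
#' Exports a network's parameters as a flat named list with keys namespaced
#' `source.population.parameter` (intrinsics) or `type.target<-source`
#' (extrinsic strengths and effects), suitable for YAML or JSON round trips.
#'
#' @param network a `dcm_network`.
#' @return named list of scalars.
#' @export
network_to_config <- function(network) {
  out <- list()
  for (l in names(network$intrinsics)) {
    intr <- network$intrinsics[[l]]
    for (p in POP_SHORT)
      out[[paste(l, p, "kappa", sep = ".")]] <- unname(intr$kappa[[p]])
    out[[paste(l, "sp", "gamma0", sep = ".")]] <- intr$gamma0
    for (p in POP_SHORT) for (q in POP_SHORT)
      if (intr$intrinsic_coupling[p, q] != 0)
        out[[paste(l, p, paste0("from_", q), sep = ".")]] <-
          intr$intrinsic_coupling[p, q]
  }
  mats <- list(forward = network$A_forward, backward = network$A_backward,
               modulatory = network$M, delta_M = network$effects$delta_M,
               delta_B = network$effects$delta_B)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    nz <- which(m != 0, arr.ind = TRUE)
    for (k in seq_len(nrow(nz)))
      out[[sprintf("%s.%s<-%s", nm, rownames(m)[nz[k, 1]],
                   colnames(m)[nz[k, 2]])]] <- m[nz[k, 1], nz[k, 2]]
  }
  dg <- network$effects$delta_gamma
  for (l in names(dg)[dg != 0]) out[[paste0("delta_gamma.", l)]] <- dg[[l]]
  out$mod_coef <- network$mod_coef
  out$bwd_ii_weight <- network$bwd_ii_weight
  for (f in c("peak_time", "width", "amplitude", "target_source",
              "contralateral_fraction"))
    out[[paste0("stimulus.", f)]] <- network$stimulus[[f]]
  out
}

#' @rdname network_to_config
#' @param path file path; written as YAML.
#' @export
write_network_config <- function(network, path) {
  yaml::write_yaml(network_to_config(network), path)
  invisible(path)
}

#' Write / read a sensor dataset as CSV + JSON sidecar
#'
#' The container is plain text: one `<condition>.csv` per condition
#' (channels x time, with channel names as the first column), a
#' `leadfield.csv` (channels x sources with a source-name header) and a
#' `meta.json` holding the sampling rate and window.
#'
#' @param data a [sensor_dataset()].
#' @param dir container directory (created if needed).
#' @return `dir` (write) or the restored `sensor_dataset` (read).
#' @export
write_sensor_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in names(data$data)) {
    df <- data.frame(channel = rownames(data$data[[cond]]) %||%
                       sprintf("MEG%03d", seq_len(nrow(data$data[[cond]]))),
                     data$data[[cond]], check.names = FALSE)
    colnames(df)[-1] <- sprintf("t%d", seq_len(ncol(data$data[[cond]])))
    write.csv(df, file.path(dir, paste0(cond, ".csv")), row.names = FALSE)
  }
  if (!is.null(data$lead)) {
    lf <- data.frame(channel = data$lead$channels, data$lead$L,
                     check.names = FALSE)
    colnames(lf)[-1] <- data$lead$sources
    write.csv(lf, file.path(dir, "leadfield.csv"), row.names = FALSE)
  }
  jsonlite::write_json(list(sfreq = data$sfreq, window = data$window,
                            conditions = names(data$data)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_sensor_dataset
#' @export
read_sensor_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  dat <- lapply(setNames(meta$conditions, meta$conditions), function(cond) {
    df <- read.csv(file.path(dir, paste0(cond, ".csv")), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    colnames(m) <- NULL
    m
  })
  lead <- NULL
  lf_path <- file.path(dir, "leadfield.csv")
  if (file.exists(lf_path)) {
    lf <- read.csv(lf_path, check.names = FALSE)
    L <- as.matrix(lf[, -1, drop = FALSE])
    rownames(L) <- lf[[1]]
    lead <- structure(list(L = L, channels = lf[[1]], sources = colnames(L)),
                      class = "lead_field")
  }
  sensor_dataset(dat, sfreq = meta$sfreq, window = meta$window, lead = lead)
}

#' Serialize a fit result to JSON
#'
#' Posterior mean, covariance, noise hyperposterior, free energy and the
#' iteration trace, as a single JSON file.
#'
#' @param fit a `dcm_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(posterior_mean = as.list(fit$posterior$mean),
         posterior_cov = fit$posterior$cov,
         free = fit$posterior$free,
         noise = fit$noise,
         free_energy = fit$free_energy,
         trace = fit$trace,
         converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
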