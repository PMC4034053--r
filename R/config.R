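#' Output weight matrices for the two classifier cells
#'
#' Cell 1 reads the even-`j` sub-channels (vertical contrast), cell 2 the
#' odd ones (horizontal contrast).  Within each cell, the `F = 1` row
#' carries the large constant `A` and the `F = 2` row the small constant
#' `B`; `B < A` is required, because the strongest figure-ground-reversal
#' signal travels through the `F = 2` channel and must yield the weakest
#' output.
#'
#' @param A weight on the F = 1 row, model current units (default 100).
#' @param B weight on the F = 2 row (default 5); must satisfy `B < A`.
#' @return List of two 2 x 4 matrices `w5_1`, `w5_2` (rows F, columns j).
#' @export
default_w5 <- function(A = 100, B = 5) {
  if (!(B < A))
    stop("B must be smaller than A (B = ", B, ", A = ", A,
         "); otherwise figure-ground-reversed responses are not suppressed")
  w5_1 <- rbind(c(0, A, 0, A), c(0, B, 0, B))
  w5_2 <- rbind(c(A, 0, A, 0), c(B, 0, B, 0))
  dimnames(w5_1) <- dimnames(w5_2) <- list(F = c("F1", "F2"),
                                           j = paste0("j", 1:4))
  list(w5_1 = w5_1, w5_2 = w5_2)
}

#' Network configuration
#'
#' Collects every constant of the five-area model.  The drive weights
#' reproduce the reference operating point: `w1 = 10` (retina-like input),
#' `w2e = 400` / `w2i = -750` (local excitation and global inhibition on
#' area 2), `w3 = 500` (edge-detection drive), `w4 = 5.0` (spatial
#' integration), and the output weights built from `A = 100`, `B = 5`,
#' all in model current units.
#'
#' Plumbing constants that the drive equations leave open:
#' * `tau_syn` (ms): spike maps enter the drive equations as exponentially
#'   filtered traces with this time constant (a very small value reproduces
#'   a literal instantaneous reading of the maps).  The input relay stage
#'   (area 1 to area 2) uses its own, faster constant `tau_syn_input`, so
#'   the global inhibition arrives as sharp pulses whose pauses are what
#'   permits post-inhibitory rebound, while the later stages integrate
#'   sustained currents.
#' * `theta_b`, `trace_sat`: area-2 activity is re-binarized before edge
#'   filtering; a site counts as active when its trace reaches
#'   `theta_b * trace_sat`.  `trace_sat` is calibrated to the steady-state
#'   trace peak of a strongly driven area-2 cell, so the product sits above
#'   the trace peak of weakly driven sites (single spikes per input cycle)
#'   and below that of strongly driven sites (multi-spike bursts): weakly
#'   driven regions still spike -- and therefore still count as segregated
#'   -- but do not propagate to the feature stages.
#' * `v0_area2` (mV): area-2 cells start slightly depolarized relative to
#'   rest, i.e. with an elevated recovery variable, which suppresses a
#'   spurious rebound wave at stimulus onset.
#' * `kappa4`: gain on the area-4 drive.  The literal spatial mean of a
#'   border map over `N^2` sites is a few parts in a thousand, far below
#'   spiking threshold, so the shipped configuration rescales it
#'   (`kappa4 = 250`); `kappa4 = 1` restores the literal equation.  The
#'   rescaling multiplies every sub-channel equally and so preserves all
#'   response orderings.
#'
#' @param w1,w2e,w2i,w3,w4 drive weights; `w2i` is stored signed and its
#'   magnitude is used in the inhibition term.
#' @param A,B output weight constants, `B < A`.
#' @param kappa4 area-4 drive gain.
#' @param theta_b binarization threshold fraction in (0, 1].
#' @param trace_sat reference trace saturation level.
#' @param tau_syn trace time constant of the feature stages, ms.
#' @param tau_syn_input trace time constant of the input relay stage, ms.
#' @param dt integration step, ms. @param duration simulated time, ms.
#' @param params_area1,params_area2,params_area3,params_area4,params_area5
#'   [izh_params] per area; area 1 defaults to a tonic relay, areas 3-5 to
#'   regular-spiking cells, area 2 to rebound-capable cells.
#' @param v0 initial membrane potential, mV; `NULL` (default) starts every
#'   area at its own stable resting point so the network is exactly silent
#'   until the stimulus drives it.
#' @param v0_area2 initial potential of area-2 cells (see above); `NULL`
#'   falls back to `v0`.
#' @param jitter_mv half-width of optional uniform initial-voltage jitter
#'   (default 0: fully deterministic).
#' @param jitter_seed integer seed used when `jitter_mv > 0`.
#' @return An object of class `network_config`.
#' @export
network_config <- function(w1 = 10, w2e = 400, w2i = -750, w3 = 500,
                           w4 = 5.0, A = 100, B = 5, kappa4 = 250,
                           theta_b = 0.9, trace_sat = 2.5, tau_syn = 5,
                           tau_syn_input = 1, dt = 0.25, duration = 100,
                           params_area1 = izh_tonic_relay(),
                           params_area2 = izh_rebound(),
                           params_area3 = izh_regular_spiking(),
                           params_area4 = izh_regular_spiking(),
                           params_area5 = izh_regular_spiking(),
                           v0 = NULL, v0_area2 = -55,
                           jitter_mv = 0, jitter_seed = NULL) {
  stopifnot(theta_b > 0, theta_b <= 1, trace_sat > 0, tau_syn > 0,
            tau_syn_input > 0, dt > 0, dt <= 1, duration > 0, kappa4 > 0,
            jitter_mv >= 0)
  w5 <- default_w5(A, B)     # validates B < A
  cfg <- list(w1 = w1, w2e = w2e, w2i = w2i, w3 = w3, w4 = w4,
              A = A, B = B, w5 = w5, kappa4 = kappa4,
              theta_b = theta_b, trace_sat = trace_sat, tau_syn = tau_syn,
              tau_syn_input = tau_syn_input, dt = dt, duration = duration,
              params = list(area1 = params_area1, area2 = params_area2,
                            area3 = params_area3, area4 = params_area4,
                            area5 = params_area5),
              filters = filter_bank(),
              v0 = v0, v0_area2 = v0_area2,
              jitter_mv = jitter_mv, jitter_seed = jitter_seed)
  structure(cfg, class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(paste0("<network_config: w1=%g w2e=%g w2i=%g w3=%g w4=%g ",
                     "A=%g B=%g kappa4=%g | dt=%g ms, %g ms, tau_syn=%g>\n"),
              x$w1, x$w2e, x$w2i, x$w3, x$w4, x$A, x$B, x$kappa4,
              x$dt, x$duration, x$tau_syn))
  invisible(x)
}

#' Stable hash of a configuration
#'
#' A short hex digest of the serialized configuration, carried in
#' experiment reports so a result can be traced to the exact constants
#' that produced it.
#'
#' @param config a [network_config].
#' @return A character scalar.
#' @export
config_hash <- function(config) {
  json <- config_to_json(config)
  bytes <- utf8ToInt(json)
  acc <- 5381
  for (b in bytes) acc <- (acc * 33 + b) %% 4294967291
  sprintf("%08x", as.integer(acc %% 2147483647))
}

config_to_json <- function(config) {
  ser <- unclass(config)
  ser$params <- lapply(ser$params, unclass)
  ser$filters <- NULL                 # fixed bank, not configurable by file
  ser$w5 <- NULL                      # derived from A, B
  jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Write a configuration to a JSON file
#' @param config a [network_config]. @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  writeLines(config_to_json(config), path)
  invisible(path)
}

#' Load a configuration from a JSON file
#'
#' Unspecified fields keep the shipped defaults; unknown keys and invariant
#' violations (such as `B >= A`) are rejected with the offending names.
#'
#' @param path JSON file; an empty file or empty object yields the full
#'   default configuration.
#' @return A [network_config].
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  raw <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt, simplifyVector = TRUE)
         else list()
  config_from_list(raw)
}

#' Build a configuration from a plain list of overrides
#' @param raw named list of fields to override (possibly nested `params`).
#' @return A [network_config].
#' @export
config_from_list <- function(raw) {
  scalar_keys <- c("w1", "w2e", "w2i", "w3", "w4", "A", "B", "kappa4",
                   "theta_b", "trace_sat", "tau_syn", "tau_syn_input",
                   "dt", "duration", "v0", "v0_area2",
                   "jitter_mv", "jitter_seed")
  known <- c(scalar_keys, "params")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  args <- raw[intersect(names(raw), scalar_keys)]
  if (!is.null(raw$params)) {
    areas <- paste0("area", 1:5)
    badp <- setdiff(names(raw$params), areas)
    if (length(badp))
      stop("unknown params keys: ", paste(badp, collapse = ", "))
    for (ar in names(raw$params)) {
      p <- raw$params[[ar]]
      args[[paste0("params_", ar)]] <-
        izh_params(p$a, p$b, p$c, p$d,
                   if (is.null(p$v_peak)) 30 else p$v_peak)
    }
  }
  do.call(network_config, args)
}
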