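#' Build the two contrast-polarity input channels
#'
#' Channel `F = 1` carries the stimulus itself, channel `F = 2` its full
#' contrast reversal, so whichever polarity the figure is drawn in, one
#' channel sees it white.
#'
#' @param img a [binary_image].
#' @return List with [binary_image] members `T1`, `T2`.
#' @export
make_channels <- function(img) {
  stopifnot(inherits(img, "binary_image"))
  list(T1 = img, T2 = contrast_reverse(img))
}

#' Area-1 drive: retinotopic copy of the input
#'
#' `I1 = w1 * T`, so only units at white pixels receive current.
#'
#' @param TF 0/1 matrix (or vector) of one input channel.
#' @param w1 input weight.
#' @return Numeric drive of the same shape.
#' @export
area1_drive <- function(TF, w1) w1 * TF

#' Area-2 drive: local excitation and global inhibition
#'
#' Each unit receives `w2e` times the activity of the area-1 unit at its
#' own site, minus `|w2i|` times the area-wide mean activity, identical at
#' every site.  Units inside the smaller (figure) region keep a positive
#' balance and fire directly; units whose only input is the global term
#' are hyperpolarized and can fire only by post-inhibitory rebound.
#'
#' @param x1 non-negative activity of area 1 (matrix or vector).
#' @param w2e excitatory weight. @param w2i inhibitory weight (its
#'   magnitude is used).
#' @return Numeric drive of the same shape.
#' @export
area2_drive <- function(x1, w2e, w2i) {
  stopifnot(all(x1 >= 0))
  w2e * x1 - abs(w2i) * mean(x1)
}

#' Re-binarize a filtered activity map
#'
#' A site counts as active when its trace reaches `theta_b * trace_sat`.
#' This stabilizes the spike map that is fed to the edge filters: the
#' filters then see the segregated region as a solid block rather than a
#' per-step scatter of coincident spikes.
#'
#' @param x trace map. @param theta_b threshold fraction in (0, 1].
#' @param trace_sat reference saturation level of the trace.
#' @return Integer 0/1 map of the same shape.
#' @export
binarize_map <- function(x, theta_b, trace_sat = 1.0) {
  stopifnot(theta_b > 0, theta_b <= 1)
  out <- as.integer(x >= theta_b * trace_sat)
  if (is.matrix(x)) out <- matrix(out, nrow(x), ncol(x))
  out
}

#' Area-3 drive: edge-detection current
#'
#' `w3` at every detection site of the feature map, zero elsewhere.
#'
#' @param detection 0/1 matrix from [feature_map].
#' @param w3 detection weight.
#' @return Numeric drive of the same shape.
#' @export
area3_drive <- function(detection, w3) w3 * detection

#' Area-4 drive: spatial integration of one sub-channel
#'
#' The literal drive is `w4` times the mean of the sub-channel's activity
#' map over all `N^2` sites; `kappa4` rescales that mean into the spiking
#' range (see [network_config]).
#'
#' @param x3 activity map of one area-3 sub-channel.
#' @param w4 integration weight. @param kappa4 gain.
#' @return Scalar drive.
#' @export
area4_drive <- function(x3, w4, kappa4 = 1) kappa4 * w4 * mean(x3)

#' Area-5 drive: weighted read-out of the eight sub-channels
#'
#' @param x4 2 x 4 matrix of area-4 activities (rows F, columns j).
#' @param w5_i 2 x 4 weight matrix of one output cell.
#' @return Scalar drive.
#' @export
area5_drive <- function(x4, w5_i) sum(w5_i * x4)

#' Run the five-area network on one stimulus
#'
#' Synchronous simulation: at every step each area's drive is computed
#' from the previous step's filtered presynaptic activity (a one-step
#' feed-forward delay), then all areas advance by one Euler step and the
#' activity traces are updated.  Channel `F = 2` processes the
#' contrast-reversed stimulus, so areas 1-3 hold two full grids each,
#' area 3 further split into the four filter sub-channels; area 4 has one
#' cell per channel and sub-channel (8 in total) and area 5 the two
#' output cells.
#'
#' @param img a [binary_image] whose array size matches no constraint
#'   other than squareness; the default stimuli are 76 x 76.
#' @param config a [network_config].
#' @param keep_drives record the per-step area-4/5 drives? (default TRUE;
#'   they are 10 scalars per step).
#' @return An object of class `network_run`: list with `stimulus`,
#'   `channels`, `rasters` (`area1`/`area2`: lists of two
#'   [spike_raster]s; `area3`: nested `[[F]][[j]]`; `area4`: 8 units
#'   ordered F1j1..F1j4, F2j1..F2j4; `area5`: 2 units), `drive_log`, and
#'   the `config_hash`.
#' @export
run_network <- function(img, config, keep_drives = TRUE) {
  stopifnot(inherits(img, "binary_image"), inherits(config, "network_config"))
  N <- nrow(img$pixels)
  if (N != ncol(img$pixels)) stop("stimulus must be square")
  n_pix <- N * N
  n_steps <- check_steps(config$duration, config$dt)
  dt <- config$dt
  decay <- exp(-dt / config$tau_syn)
  decay_in <- exp(-dt / config$tau_syn_input)   # relay (area-1) traces
  thresh <- config$theta_b * config$trace_sat

  channels <- make_channels(img)
  Tmat <- list(channels$T1$pixels, channels$T2$pixels)
  I1 <- lapply(Tmat, function(Tm) area1_drive(as.numeric(Tm), config$w1))

  init <- function(params, n, v0 = config$v0) {
    st <- izh_init(n, params, v0)
    if (config$jitter_mv > 0) {
      # RNG state is active across all init() calls; see with_seed below
      st$v <- st$v + stats::runif(n, -config$jitter_mv, config$jitter_mv)
      st$u <- params$b * st$v
    }
    st
  }
  make_states <- function() {
    v0_a2 <- if (is.null(config$v0_area2)) config$v0 else config$v0_area2
    list(a1 = lapply(1:2, function(F) init(config$params$area1, n_pix)),
         a2 = lapply(1:2, function(F) init(config$params$area2, n_pix, v0_a2)),
         a3 = lapply(1:2, function(F)
           lapply(1:4, function(j) init(config$params$area3, n_pix))),
         a4 = init(config$params$area4, 8L),
         a5 = init(config$params$area5, 2L))
  }
  states <- if (config$jitter_mv > 0) {
    if (is.null(config$jitter_seed))
      stop("jitter_mv > 0 requires jitter_seed")
    with_seed(config$jitter_seed, make_states())
  } else make_states()
  a1 <- states$a1; a2 <- states$a2; a3 <- states$a3
  a4 <- states$a4; a5 <- states$a5

  sp1 <- lapply(1:2, function(F) vector("list", n_steps))
  sp2 <- lapply(1:2, function(F) vector("list", n_steps))
  sp3 <- lapply(1:2, function(F)
    lapply(1:4, function(j) vector("list", n_steps)))
  sp4 <- vector("list", n_steps)
  sp5 <- vector("list", n_steps)
  log4 <- if (keep_drives) matrix(0, n_steps, 8L) else NULL
  log5 <- if (keep_drives) matrix(0, n_steps, 2L) else NULL

  w5 <- list(config$w5$w5_1, config$w5$w5_2)
  p <- config$params

  for (s in seq_len(n_steps)) {
    # ---- drives from the previous step's traces (one-step delay) ----
    I2 <- lapply(1:2, function(F)
      area2_drive(a1[[F]]$trace, config$w2e, config$w2i))
    I3 <- vector("list", 2L)
    x4 <- matrix(0, 2L, 4L)
    for (F in 1:2) {
      S2bin <- matrix(a2[[F]]$trace >= thresh, N, N)
      I3[[F]] <- lapply(config$filters, function(k)
        config$w3 * as.numeric(feature_map(S2bin, k)))
      for (j in 1:4) x4[F, j] <- mean(a3[[F]][[j]]$trace)
    }
    I4 <- config$kappa4 * config$w4 * as.numeric(t(x4))   # F1j1..F2j4
    tr4 <- matrix(a4$trace[c(1:4, 5:8)], 2L, 4L, byrow = TRUE)
    I5 <- c(area5_drive(tr4, w5[[1L]]), area5_drive(tr4, w5[[2L]]))
    if (keep_drives) { log4[s, ] <- I4; log5[s, ] <- I5 }

    # ---- advance every area one step, then refresh the traces ----
    for (F in 1:2) {
      a1[[F]] <- izh_step(a1[[F]], I1[[F]], p$area1, dt)
      sp1[[F]][[s]] <- which(a1[[F]]$spiked == 1L)
      a1[[F]]$trace <- a1[[F]]$trace * decay_in + a1[[F]]$spiked
      a2[[F]] <- izh_step(a2[[F]], I2[[F]], p$area2, dt)
      sp2[[F]][[s]] <- which(a2[[F]]$spiked == 1L)
      a2[[F]]$trace <- a2[[F]]$trace * decay + a2[[F]]$spiked
      for (j in 1:4) {
        a3[[F]][[j]] <- izh_step(a3[[F]][[j]], I3[[F]][[j]], p$area3, dt)
        sp3[[F]][[j]][[s]] <- which(a3[[F]][[j]]$spiked == 1L)
        a3[[F]][[j]]$trace <- a3[[F]][[j]]$trace * decay + a3[[F]][[j]]$spiked
      }
    }
    a4 <- izh_step(a4, I4, p$area4, dt)
    sp4[[s]] <- which(a4$spiked == 1L)
    a4$trace <- a4$trace * decay + a4$spiked
    a5 <- izh_step(a5, I5, p$area5, dt)
    sp5[[s]] <- which(a5$spiked == 1L)
    a5$trace <- a5$trace * decay + a5$spiked
  }

  mk <- function(spk, n, dims = c(N, N))
    spike_raster(spk, n, dt, config$duration, dim = dims)
  structure(list(
    stimulus = img,
    channels = channels,
    rasters = list(
      area1 = lapply(1:2, function(F) mk(sp1[[F]], n_pix)),
      area2 = lapply(1:2, function(F) mk(sp2[[F]], n_pix)),
      area3 = lapply(1:2, function(F)
        lapply(1:4, function(j) mk(sp3[[F]][[j]], n_pix))),
      area4 = mk(sp4, 8L, dims = NULL),
      area5 = mk(sp5, 2L, dims = NULL)),
    drive_log = list(I4 = log4, I5 = log5),
    config = config,
    config_hash = config_hash(config)),
    class = "network_run")
}

#' @export
print.network_run <- function(x, ...) {
  c5 <- spike_counts(x$rasters$area5)
  o5 <- first_spike_times(x$rasters$area5)
  cat(sprintf(paste0("<network_run on %s: area-5 counts (%d, %d), ",
                     "onsets (%s, %s) ms>\n"),
              if (is.null(x$stimulus$label)) "stimulus" else x$stimulus$label,
              c5[1L], c5[2L], format(o5[1L]), format(o5[2L])))
  invisible(x)
}

# evaluate expr with a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
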