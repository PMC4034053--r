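#' Izhikevich neuron parameters
#'
#' The two-variable model `v' = 0.04 v^2 + 5 v + 140 - u + I`,
#' `u' = a (b v - u)`, with a spike emitted when `v` reaches `v_peak`,
#' after which `v <- c` and `u <- u + d`.
#'
#' @param a recovery rate, 1/ms. @param b recovery coupling, dimensionless.
#' @param c reset potential, mV. @param d recovery increment per spike.
#' @param v_peak spike cutoff, mV (30 in the published model).
#' @return An object of class `izh_params`.
#' @export
izh_params <- function(a, b, c, d, v_peak = 30) {
  stopifnot(a > 0, v_peak > c)
  structure(list(a = a, b = b, c = c, d = d, v_peak = v_peak),
            class = "izh_params")
}

#' Regular-spiking parameters (a = 0.02, b = 0.2, c = -65, d = 8)
#' @return An [izh_params] object.
#' @export
izh_regular_spiking <- function() izh_params(0.02, 0.2, -65, 8)

#' Tonic relay parameters (a = 0.1, b = 0.2, c = -65, d = 8)
#'
#' A fast-recovering cell that fires regularly and without the strong
#' spike-frequency adaptation of the regular-spiking set.  Used for the
#' input area, which acts as a retina-like relay: under the constant
#' stimulus drive it emits an evenly spaced spike train (about 70 Hz at
#' the default input current), giving the downstream excitation-inhibition
#' balance a steady rhythm.
#' @return An [izh_params] object.
#' @export
izh_tonic_relay <- function() izh_params(0.1, 0.2, -65, 8)

#' Rebound-capable low-threshold parameters (a = 0.06, b = 0.25, c = -57, d = 1)
#'
#' With `b = 0.25` the resting recovery value sits at the edge of the
#' spiking regime, so pulsed hyperpolarization that ratchets `u` below its
#' resting value lets the cell fire in the pauses of the inhibitory
#' rhythm, even without any excitatory input -- post-inhibitory rebound.
#' The moderately fast recovery rate and small reset increment keep that
#' rebound periodic, while graded burst sizes under direct excitation
#' (more spikes per input cycle for stronger drive) let a downstream
#' threshold on the filtered trace separate strongly from weakly driven
#' sites.
#' @return An [izh_params] object.
#' @export
izh_rebound <- function() izh_params(0.06, 0.25, -57, 1)

#' Resting potential of an Izhikevich cell
#'
#' The stable zero-drive fixed point: the more negative root of
#' `0.04 v^2 + (5 - b) v + 140 = 0`.  For regular-spiking parameters this
#' is -70 mV; for the rebound parameters about -64.4 mV.  Cells whose
#' parameters admit no resting point (discriminant < 0) are
#' intrinsically active and have no rest; `NA` is returned.
#'
#' @param params an [izh_params].
#' @return Resting potential, mV, or `NA`.
#' @export
izh_rest <- function(params) {
  disc <- (5 - params$b)^2 - 4 * 0.04 * 140
  if (disc < 0) return(NA_real_)
  (-(5 - params$b) - sqrt(disc)) / (2 * 0.04)
}

#' Initialize a grid of neurons
#'
#' Units start at the cell's stable resting point (`u = b * v`), so a grid
#' under zero drive stays exactly silent.  An explicit `v0` overrides the
#' resting potential.
#'
#' @param n_units number of units.
#' @param params an [izh_params].
#' @param v0 initial membrane potential, mV; `NULL` (default) uses
#'   [izh_rest], falling back to -65 for parameters without a rest point.
#' @return A `grid_state` list with numeric vectors `v`, `u`, `trace`.
#' @export
izh_init <- function(n_units, params, v0 = NULL) {
  if (is.null(v0)) {
    v0 <- izh_rest(params)
    if (is.na(v0)) v0 <- -65
  }
  v <- rep(as.numeric(v0), length.out = n_units)
  structure(list(v = v, u = params$b * v, trace = numeric(n_units)),
            class = "grid_state")
}

#' Advance a grid of Izhikevich neurons by one time step
#'
#' Forward Euler with the membrane potential advanced in two half-steps of
#' `dt/2` (the integration scheme published with the model) and one full
#' step for the recovery variable, evaluated at the pre-reset potential.
#' Units whose potential reaches `v_peak` emit a spike and are reset.
#'
#' @param state a `grid_state` from [izh_init].
#' @param I drive per unit (scalar or vector), model current units.
#' @param params an [izh_params]. @param dt time step, ms, in (0, 1].
#' @return The updated state, with an integer attribute-free component
#'   `spiked` (0/1 per unit) added to the returned list.
#' @export
izh_step <- function(state, I, params, dt) {
  stopifnot(dt > 0, dt <= 1)
  v <- state$v; u <- state$u
  h <- dt / 2
  v <- v + h * (0.04 * v * v + 5 * v + 140 - u + I)
  v <- v + h * (0.04 * v * v + 5 * v + 140 - u + I)
  u <- u + dt * params$a * (params$b * v - u)
  spiked <- v >= params$v_peak
  if (anyNA(v) || any(!is.finite(v)) || any(!is.finite(u)))
    stop("non-finite membrane state at unit(s) ",
         paste(utils::head(which(!is.finite(v) | !is.finite(u)), 5L),
               collapse = ", "),
         "; integration unstable, reduce dt")
  if (any(spiked)) {
    v[spiked] <- params$c
    u[spiked] <- u[spiked] + params$d
  }
  state$v <- v; state$u <- u
  state$spiked <- as.integer(spiked)
  state
}

#' Exponentially filtered spike trace
#'
#' `trace <- trace * exp(-dt / tau_syn) + spiked`.  The traces stand in for
#' sustained synaptic activity when spike maps enter the drive equations;
#' a unit firing periodically with interval `D` saturates at a peak of
#' `1 / (1 - exp(-D / tau_syn))`.
#'
#' @param trace current trace vector. @param spiked 0/1 vector.
#' @param dt time step, ms. @param tau_syn trace time constant, ms (> 0).
#' @return The updated trace vector.
#' @export
update_trace <- function(trace, spiked, dt, tau_syn) {
  stopifnot(tau_syn > 0)
  trace * exp(-dt / tau_syn) + spiked
}

#' Simulate an isolated grid of neurons under a drive schedule
#'
#' @param n_units number of units. @param params an [izh_params].
#' @param drive_provider function(step, time_ms) returning the drive
#'   (scalar or per-unit vector) for that step.
#' @param duration total simulated time, ms (multiple of `dt`).
#' @param dt time step, ms. @param v0 initial potential, mV.
#' @return A [spike_raster].
#' @export
simulate_grid <- function(n_units, params, drive_provider, duration, dt,
                          v0 = -65) {
  n_steps <- check_steps(duration, dt)
  state <- izh_init(n_units, params, v0)
  spikes <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    I <- drive_provider(s, (s - 1) * dt)
    state <- izh_step(state, I, params, dt)
    spikes[[s]] <- which(state$spiked == 1L)
  }
  spike_raster(spikes, n_units, dt, duration)
}

check_steps <- function(duration, dt) {
  n_steps <- round(duration / dt)
  if (abs(n_steps * dt - duration) > 1e-9)
    stop("duration must be a multiple of dt")
  as.integer(n_steps)
}

#' Spike raster
#'
#' Records, for every simulation step, which units spiked.  Spike times are
#' reported as the end of the step in which the potential crossed the
#' cutoff, i.e. `step * dt` ms.
#'
#' @param spikes list of integer vectors, one per step: indices of units
#'   that spiked in that step.
#' @param n_units number of units. @param dt step, ms.
#' @param duration total time, ms.
#' @param dim optional c(rows, cols) grid shape of the unit layout.
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(spikes, n_units, dt, duration, dim = NULL) {
  structure(list(spikes = spikes, n_units = as.integer(n_units),
                 dt = dt, duration = duration, dim = dim),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster: %d units, %g ms @ dt=%g, %d spikes>\n",
              x$n_units, x$duration, x$dt, sum(lengths(x$spikes))))
  invisible(x)
}

#' Per-unit spike counts of a raster
#' @param raster a [spike_raster].
#' @return Integer vector of length `n_units`.
#' @export
spike_counts <- function(raster) {
  idx <- unlist(raster$spikes, use.names = FALSE)
  if (is.null(idx)) idx <- integer(0)
  tabulate(idx, nbins = raster$n_units)
}

#' Per-unit first spike times of a raster
#' @param raster a [spike_raster].
#' @return Numeric vector, ms; `NA` for silent units.
#' @export
first_spike_times <- function(raster) {
  first <- rep(NA_real_, raster$n_units)
  for (s in seq_along(raster$spikes)) {
    units <- raster$spikes[[s]]
    fresh <- units[is.na(first[units])]
    if (length(fresh)) first[fresh] <- s * raster$dt
    if (!anyNA(first)) break
  }
  first
}

#' Spike times of one unit
#' @param raster a [spike_raster]. @param unit unit index.
#' @return Increasing numeric vector of spike times, ms.
#' @export
unit_spike_times <- function(raster, unit) {
  steps <- which(vapply(raster$spikes, function(s) unit %in% s, logical(1)))
  steps * raster$dt
}

#' Raster as an event table
#' @param x a [spike_raster]. @param ... unused.
#' @return data.frame with columns `unit`, `row`, `col`, `time_ms`.
#' @export
as.data.frame.spike_raster <- function(x, ...) {
  units <- unlist(x$spikes, use.names = FALSE)
  if (is.null(units)) units <- integer(0)
  times <- rep(seq_along(x$spikes) * x$dt, lengths(x$spikes))
  if (!is.null(x$dim)) {
    nr <- x$dim[1L]
    df <- data.frame(unit = units,
                     row = (units - 1L) %% nr + 1L,
                     col = (units - 1L) %/% nr + 1L,
                     time_ms = times)
  } else {
    df <- data.frame(unit = units, row = NA_integer_, col = NA_integer_,
                     time_ms = times)
  }
  df[order(df$unit, df$time_ms), , drop = FALSE]
}
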