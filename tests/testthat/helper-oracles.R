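# Independent reference implementations used as oracles.  These stay
# deliberately naive (plain loops, fine time steps) and never call the
# package's own integration or filtering code paths.

# Fine-step reference integration of the published two-variable model.
# drive_fn(t_ms) -> current; returns spike times (ms).
oracle_izhikevich <- function(params, drive_fn, duration, dt = 0.01,
                              v0 = NULL) {
  if (is.null(v0)) {
    disc <- (5 - params$b)^2 - 4 * 0.04 * 140
    v0 <- if (disc >= 0) (-(5 - params$b) - sqrt(disc)) / 0.08 else -65
  }
  v <- v0; u <- params$b * v0
  spikes <- numeric(0)
  n <- round(duration / dt)
  for (s in seq_len(n)) {
    t <- (s - 1) * dt
    I <- drive_fn(t)
    v <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
    u <- u + dt * params$a * (params$b * v - u)
    if (v >= params$v_peak) {
      spikes <- c(spikes, s * dt)
      v <- params$c
      u <- u + params$d
    }
  }
  spikes
}

# Brute-force two-pixel correlation + step threshold, double loop.
oracle_feature_map <- function(x, kernel) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0L, nr, nc)
  dr <- if (kernel$orientation == "along-column") 1L else 0L
  dc <- if (kernel$orientation == "along-row") 1L else 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    second <- if (r + dr <= nr && c + dc <= nc) x[r + dr, c + dc] else 0L
    corr <- kernel$k1 * x[r, c] + kernel$k2 * second
    if (corr - 1L >= 0L) out[r, c] <- 1L
  }
  out
}

# Brute-force border counting by explicit neighbour enumeration.
oracle_border_length <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  Bh <- 0L; Bv <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (r < nr && px[r, c] != px[r + 1L, c]) Bh <- Bh + 1L
    if (c < nc && px[r, c] != px[r, c + 1L]) Bv <- Bv + 1L
  }
  list(Bh = Bh, Bv = Bv, total = Bh + Bv)
}

dice_coefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

random_binary_image <- function(side, p = 0.5) {
  matrix(as.integer(stats::runif(side * side) < p), side, side)
}
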