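#' Profile specification for framed polygon stimuli
#'
#' A framed polygon display is a white region bounded by straight frame
#' edges at the top, bottom and along one side of the inner square, and by
#' a "profile" line on the other side.  The profile is single-valued in the
#' row coordinate: `p[r]` gives the number of white columns in inner row
#' `r` (equivalently the 0-based column index at which the ground starts
#' when the frame side is the left).  Both profile endpoints are pinned at
#' the mid-points of the top and bottom inner edges (`p = n/2`), which is
#' what makes the total border length identical across the original and its
#' mirror-, contrast- and figure-ground-reversed versions.
#'
#' @param p integer vector of length `n`; `p[r]` in `[1, n-1]`, with
#'   `p[1] == p[n] == n/2`.
#' @param frame_side `"left"` or `"right"`: which side carries the straight
#'   frame edge (the white region sits against that side).
#' @return An object of class `profile_spec`.
#' @export
profile_spec <- function(p, frame_side = c("left", "right")) {
  frame_side <- match.arg(frame_side)
  p <- as.integer(p)
  n <- length(p)
  if (n < 4L || n %% 2L != 0L) stop("profile length n must be even and >= 4")
  if (p[1L] != n %/% 2L || p[n] != n %/% 2L)
    stop("profile endpoints must sit at the mid-points: p[1] = p[n] = n/2")
  if (any(p < 1L) || any(p > n - 1L))
    stop("profile values must lie in [1, n-1]")
  structure(list(p = p, frame_side = frame_side), class = "profile_spec")
}

#' Generate a framed polygon stimulus
#'
#' Rasterizes a [profile_spec] into a framed-on-black [binary_image] and
#' deterministically adjusts the interior profile columns (never the pinned
#' endpoints) so that the white pixel count equals `target_white` exactly.
#' The adjustment spreads single-pixel increments or decrements over the
#' interior rows, starting from the rows farthest from the endpoints, so
#' identical inputs always yield bit-identical images.
#'
#' @param spec a [profile_spec].
#' @param n inner square side (must equal `length(spec$p)`).
#' @param m margin width, pixels.
#' @param target_white required number of white pixels; `NULL` keeps the
#'   profile as given.
#' @param label optional label.
#' @return A framed-on-black [binary_image] with exactly `target_white`
#'   white pixels.
#' @export
generate_polygon_stimulus <- function(spec, n, m, target_white = NULL,
                                      label = NULL) {
  stopifnot(inherits(spec, "profile_spec"))
  n <- as.integer(n); m <- as.integer(m)
  if (length(spec$p) != n) stop("length(spec$p) must equal n")
  width <- if (spec$frame_side == "left") spec$p else n - spec$p
  if (!is.null(target_white)) {
    lo <- n + (n - 2L)            # endpoints fixed at n/2, interior >= 1
    hi <- n + (n - 2L) * (n - 1L) # interior <= n - 1
    if (target_white < lo || target_white > hi)
      stop("target_white = ", target_white, " unreachable; achievable range is [",
           lo, ", ", hi, "] for n = ", n)
    width <- adjust_widths(width, as.integer(target_white), n)
  }
  px <- matrix(0L, n + 2L * m, n + 2L * m)
  for (r in seq_len(n)) {
    if (width[r] > 0L) {
      cols <- if (spec$frame_side == "left") seq_len(width[r])
              else seq.int(n - width[r] + 1L, n)
      px[m + r, m + cols] <- 1L
    }
  }
  binary_image(px, n, m, "framed-on-black", label)
}

# Deterministic +/-1 sweeps over interior rows, middle rows first.
adjust_widths <- function(width, target, n) {
  interior <- 2:(n - 1L)
  # fixed visiting order: decreasing distance from the nearer endpoint
  ord <- interior[order(-pmin(interior - 1L, n - interior), interior)]
  delta <- target - sum(width)
  step <- if (delta > 0L) 1L else -1L
  while (delta != 0L) {
    moved <- FALSE
    for (r in ord) {
      if (delta == 0L) break
      w <- width[r] + step
      if (w >= 1L && w <= n - 1L) {
        width[r] <- w
        delta <- delta - step
        moved <- TRUE
      }
    }
    if (!moved) stop("cannot reach target white count under profile constraints")
  }
  width
}

#' Generate a circle stimulus
#'
#' A filled white disc centred in the inner square (centre between pixels,
#' so the display is exactly mirror-symmetric).  With `connected = TRUE`
#' the disc is joined to the mid-points of the top and bottom inner edges
#' by 1-pixel-wide white bridges along the vertical midline, so the figure
#' touches the frame the way a polygon profile does.
#'
#' @param radius disc radius in pixels, `0 < radius < n/2`.
#' @param connected join the disc to the top/bottom inner-edge mid-points?
#' @param n inner square side. @param m margin width.
#' @param label optional label.
#' @return A framed-on-black [binary_image].
#' @export
generate_circle_stimulus <- function(radius, connected = FALSE, n = 64L,
                                     m = 6L, label = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  if (!(radius > 0 && radius < n / 2))
    stop("radius must satisfy 0 < radius < n/2, got ", radius)
  ctr <- (n + 1) / 2            # between the two central pixels
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  disc <- (rr - ctr)^2 + (cc - ctr)^2 <= radius^2
  if (connected) disc[, n %/% 2L] <- TRUE    # vertical midline bridge
  px <- matrix(0L, n + 2L * m, n + 2L * m)
  idx <- inner_index(n, m)
  px[idx, idx] <- as.integer(disc)
  binary_image(px, n, m, "framed-on-black", label)
}

#' Solve for the disc radius matching a target area ratio
#'
#' Scans radii on a fine deterministic grid and returns the one whose
#' rasterized disc area is closest to `ratio * n^2` (smallest radius wins
#' ties).
#'
#' @param n inner square side.
#' @param ratio target inner white-area ratio (default 0.42, the ratio of
#'   the default polygon fixtures).
#' @return The radius, pixels.
#' @export
default_circle_radius <- function(n = 64L, ratio = 0.42) {
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  d2 <- (rr - ctr)^2 + (cc - ctr)^2
  radii <- seq(1, n / 2 - 0.01, by = 0.01)
  target <- ratio * n^2
  err <- vapply(radii, function(r) abs(sum(d2 <= r^2) - target), numeric(1))
  radii[which.min(err)]
}

#' Bundle a stimulus with its three transforms
#'
#' Builds the original plus its mirror-, contrast- and figure-ground
#' reversals.  For polygon sets the total border length is asserted to be
#' identical across all four members (a consequence of the mid-point
#' anchoring of the profile); circle sets instead record whether the
#' equality holds in `border_equal`, since a disconnected disc does not
#' preserve it.
#'
#' @param original a framed-on-black [binary_image].
#' @param label one of `"set1"`, `"set2"`, `"circle-disconnected"`,
#'   `"circle-connected"`, or any other tag; border equality is enforced
#'   unless the label starts with `"circle"`.
#' @return An object of class `image_set`: list with members `original`,
#'   `mirror`, `contrast`, `fg`, plus `label` and `border_equal`.
#' @export
make_image_set <- function(original, label = "set") {
  stopifnot(inherits(original, "binary_image"))
  members <- list(original = original,
                  mirror   = mirror_reverse(original),
                  contrast = contrast_reverse(original),
                  fg       = fg_reverse(original))
  totals <- vapply(members, function(im) border_length(im)$total, integer(1))
  equal <- length(unique(totals)) == 1L
  if (!equal && !startsWith(label, "circle"))
    stop("border length not conserved across transforms: ",
         paste(names(totals), totals, sep = "=", collapse = ", "))
  structure(list(original = members$original, mirror = members$mirror,
                 contrast = members$contrast, fg = members$fg,
                 label = label, border_equal = equal,
                 border_totals = totals),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set '%s': 4 members %dx%d, border totals %s>\n",
              x$label, nrow(x$original$pixels), ncol(x$original$pixels),
              paste(x$border_totals, collapse = "/")))
  invisible(x)
}

#' Default polygon fixtures
#'
#' Two deterministic framed polygon image sets emulating the study
#' displays: inner side `n = 64`, margin `m = 6` (`N = 76`), both originals
#' with exactly 1720 white pixels (inner area ratio 0.42, 0.30 including
#' the frame).  Set 1 uses a shallow trapezoidal profile, so its borders
#' are dominated by vertical segments (`Bv > Bh`); set 2 uses a square-wave
#' profile, dominated by horizontal segments (`Bh > Bv`).  Within each set
#' the total border length is identical across all four members.
#'
#' @param n inner side (default 64). @param m margin (default 6).
#' @param target_white white pixel count of each original (default 1720).
#' @return A list with components `set1` and `set2`, each an [image_set].
#' @export
default_fixtures <- function(n = 64L, m = 6L, target_white = 1720L) {
  n <- as.integer(n); m <- as.integer(m)
  half <- n %/% 2L
  set1 <- make_image_set(
    generate_polygon_stimulus(profile_spec(default_profile1(n), "left"),
                              n, m, target_white, label = "set1"),
    label = "set1")
  set2 <- make_image_set(
    generate_polygon_stimulus(profile_spec(default_profile2(n), "left"),
                              n, m, target_white, label = "set2"),
    label = "set2")
  b1 <- border_length(set1$original); b2 <- border_length(set2$original)
  stopifnot(sum(set1$original$pixels) == sum(set2$original$pixels),
            b1$Bv > b1$Bh, b2$Bh > b2$Bv)
  list(set1 = set1, set2 = set2)
}

# Shallow trapezoid: ramp in, plateau, ramp out.  Scaled from the n = 64
# reference (depth n/8, plateau n/2 rows); the generator's target
# adjustment absorbs any rounding.
default_profile1 <- function(n) {
  half <- n %/% 2L
  depth <- max(1L, n %/% 8L)
  p <- rep(half, n)
  ramp_rows <- seq_len(depth)
  p[1L + ramp_rows] <- half - ramp_rows
  plateau <- seq.int(2L + depth, min(n - 1L - depth, 1L + depth + n %/% 2L))
  p[plateau] <- half - depth
  down <- seq.int(max(plateau) + 1L, max(plateau) + depth)
  down <- down[down <= n - 1L]
  p[down] <- half - depth + seq_along(down)
  p
}

# Square wave: alternating wide/narrow blocks of 4 rows.
default_profile2 <- function(n) {
  half <- n %/% 2L
  p <- rep(half, n)
  hi <- half + max(1L, n %/% 11L)      # 38 for n = 64
  lo <- half - max(1L, n %/% 4L)       # 16 for n = 64
  r <- 2L
  phase <- 0L
  while (r + 3L <= n - 1L - max(1L, n %/% 10L)) {
    p[r:(r + 3L)] <- if (phase %% 2L == 0L) hi else lo
    phase <- phase + 1L
    r <- r + 4L
  }
  if (r <= n - 1L) p[r:(n - 1L)] <- half - n %/% 8L
  p
}
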