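#' Binary stimulus images
#'
#' A `binary_image` is an N x N grid of 0/1 pixels (1 = white) together with
#' the geometry that produced it: the inner square side `n` and the margin
#' width `m`, with `N = n + 2 m`.  Row 1 of the pixel matrix is the top of
#' the display.  The `polarity` tag records whether the display is a white
#' figure framed on black (`"framed-on-black"`, all margin pixels 0) or a
#' full contrast reversal of such a display (`"inverted"`).
#'
#' @param pixels integer or logical N x N matrix of 0/1 values (1 = white).
#' @param n inner square side, pixels.
#' @param m margin width, pixels.
#' @param polarity `"framed-on-black"` or `"inverted"`.
#' @param label optional character tag carried through transforms.
#' @return An object of class `binary_image`.
#' @export
binary_image <- function(pixels, n, m, polarity = "framed-on-black",
                         label = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  N <- n + 2L * m
  if (nrow(pixels) != N || ncol(pixels) != N)
    stop("pixels must be ", N, " x ", N, " (n + 2m), got ",
         nrow(pixels), " x ", ncol(pixels))
  if (!all(pixels %in% c(0L, 1L)))
    stop("pixels must contain only 0 and 1")
  polarity <- match.arg(polarity, c("framed-on-black", "inverted"))
  if (polarity == "framed-on-black" && m > 0L) {
    inner <- inner_index(n, m)
    margin <- pixels
    margin[inner, inner] <- 0L
    if (any(margin == 1L))
      stop("framed-on-black image has white pixels in the margin")
  }
  structure(list(pixels = pixels, n = as.integer(n), m = as.integer(m),
                 polarity = polarity, label = label),
            class = "binary_image")
}

# rows/cols (1-based) of the inner square
inner_index <- function(n, m) seq.int(m + 1L, m + n)

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image %dx%d (n=%d, m=%d, %s)%s: %d white (%.4f)>\n",
              nrow(x$pixels), ncol(x$pixels), x$n, x$m, x$polarity,
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              sum(x$pixels), mean(x$pixels)))
  invisible(x)
}

#' @export
dim.binary_image <- function(x) dim(x$pixels)

#' Mirror reversal (horizontal flip)
#'
#' Flips the full array left-right.  White count and border metrics are
#' preserved exactly.
#'
#' @param img a [binary_image].
#' @return The mirrored [binary_image].
#' @export
mirror_reverse <- function(img) {
  stopifnot(inherits(img, "binary_image"))
  out <- img
  out$pixels <- img$pixels[, rev(seq_len(ncol(img$pixels))), drop = FALSE]
  out$label <- transform_label(img$label, "mirror")
  out
}

#' Contrast reversal (full-array polarity inversion)
#'
#' Bitwise NOT of every pixel, margins included, so the margin of a framed
#' display becomes white.  This is the only polarity inversion that leaves
#' the border structure exactly unchanged, and it is also how the second
#' input channel of the network is built from the first.
#'
#' @param img a [binary_image].
#' @return The contrast-reversed [binary_image] with its polarity toggled.
#' @export
contrast_reverse <- function(img) {
  stopifnot(inherits(img, "binary_image"))
  out <- img
  out$pixels <- 1L - img$pixels
  out$polarity <- if (img$polarity == "framed-on-black") "inverted"
                  else "framed-on-black"
  out$label <- transform_label(img$label, "contrast")
  out
}

#' Figure-ground reversal
#'
#' Keeps the same dividing contour but presents the complementary inner
#' region as the white figure: white pixels become exactly the inner-square
#' pixels that were black, and the margins stay black, so the result is
#' again a white figure on a black background rather than a polarity change.
#'
#' @param img a framed-on-black [binary_image].
#' @return The figure-ground-reversed [binary_image].
#' @export
fg_reverse <- function(img) {
  stopifnot(inherits(img, "binary_image"))
  if (img$polarity != "framed-on-black")
    stop("fg_reverse is defined for framed-on-black images")
  inner <- inner_index(img$n, img$m)
  out <- img
  px <- matrix(0L, nrow(img$pixels), ncol(img$pixels))
  px[inner, inner] <- 1L - img$pixels[inner, inner]
  out$pixels <- px
  out$label <- transform_label(img$label, "fg")
  out
}

#' Quarter-turn rotation
#'
#' Rotates the array 90 degrees clockwise.  Horizontal and vertical border
#' lengths are exchanged exactly.
#'
#' @param img a [binary_image].
#' @return The rotated [binary_image].
#' @export
rotate90 <- function(img) {
  stopifnot(inherits(img, "binary_image"))
  out <- img
  out$pixels <- rotate90_matrix(img$pixels)
  out$label <- transform_label(img$label, "rot90")
  out
}

# clockwise quarter turn of a matrix
rotate90_matrix <- function(x) t(x[rev(seq_len(nrow(x))), , drop = FALSE])

transform_label <- function(label, tag) {
  if (is.null(label)) tag else paste(label, tag, sep = "-")
}

#' Border lengths of a binary image
#'
#' Counts 4-adjacent pixel pairs with differing values.  `Bh` counts
#' vertically adjacent differing pairs (horizontal border segments) and
#' `Bv` horizontally adjacent differing pairs (vertical border segments);
#' `total = Bh + Bv`.  The total is zero exactly for uniform images, is
#' preserved by mirror and contrast reversal, and `Bh`/`Bv` are swapped by
#' a quarter turn.
#'
#' @param img a [binary_image] (or a plain 0/1 matrix).
#' @return A list with integer components `Bh`, `Bv`, `total`.
#' @export
border_length <- function(img) {
  px <- if (inherits(img, "binary_image")) img$pixels else img
  nr <- nrow(px); nc <- ncol(px)
  Bh <- if (nr > 1L) sum(px[-1L, , drop = FALSE] != px[-nr, , drop = FALSE]) else 0L
  Bv <- if (nc > 1L) sum(px[, -1L, drop = FALSE] != px[, -nc, drop = FALSE]) else 0L
  list(Bh = as.integer(Bh), Bv = as.integer(Bv), total = as.integer(Bh + Bv))
}

#' White-area ratio of a stimulus
#'
#' @param img a [binary_image].
#' @param include_margin if `TRUE`, white count over the full array (`N^2`);
#'   otherwise white count over the inner square only (`n^2`).
#' @return A fraction in `[0, 1]` (can exceed 1 only if an inverted image is
#'   measured without its margin, which is disallowed).
#' @export
white_area_ratio <- function(img, include_margin = FALSE) {
  stopifnot(inherits(img, "binary_image"))
  if (include_margin) {
    sum(img$pixels) / length(img$pixels)
  } else {
    inner <- inner_index(img$n, img$m)
    sum(img$pixels[inner, inner]) / (img$n^2)
  }
}

#' Figure region of a display
#'
#' The region the network is expected to segregate: the smaller of the white
#' and black pixel sets (area measured over the full array).  For a framed
#' original this is the white polygon; for its contrast reversal it is the
#' same polygon, now black.  Ties go to white.
#'
#' @param img a [binary_image].
#' @return A logical N x N matrix, `TRUE` on the figure region.
#' @export
figure_mask <- function(img) {
  stopifnot(inherits(img, "binary_image"))
  white <- img$pixels == 1L
  if (sum(white) <= sum(!white)) white else !white
}
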