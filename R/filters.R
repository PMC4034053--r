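#' The two-pixel edge filter bank
#'
#' Four difference kernels, one +1 and one -1 coefficient each, covering
#' the two orientations times the two contrast polarities.  Along-row
#' kernels pair a pixel with its right neighbour and therefore detect
#' vertical borders; along-column kernels pair a pixel with the one below
#' and detect horizontal borders.  The shipped index assignment puts the
#' along-column kernels at odd `j` and the along-row kernels at even `j`,
#' matching the output weight matrices that read vertical contrast from
#' even columns and horizontal contrast from odd columns.
#'
#' @return A list of four `filter_kernel` objects, `j = 1..4`:
#'   j=1 along-column (-1 over +1): top edges of white regions;
#'   j=2 along-row (-1, +1): left edges;
#'   j=3 along-column (+1 over -1): bottom edges;
#'   j=4 along-row (+1, -1): right edges.
#' @export
filter_bank <- function() {
  k <- function(j, orientation, k1, k2, detects)
    structure(list(j = j, orientation = orientation, k1 = k1, k2 = k2,
                   polarity = if (k1 < 0) "+" else "-", detects = detects),
              class = "filter_kernel")
  list(k(1L, "along-column", -1, 1, "top-edge"),
       k(2L, "along-row",    -1, 1, "left-edge"),
       k(3L, "along-column",  1, -1, "bottom-edge"),
       k(4L, "along-row",     1, -1, "right-edge"))
}

#' @export
print.filter_kernel <- function(x, ...) {
  cat(sprintf("<filter_kernel j=%d %s (%+d,%+d) detects %s>\n",
              x$j, x$orientation, x$k1, x$k2, x$detects))
  invisible(x)
}

#' Edge detection by a two-pixel filter
#'
#' Cross-correlates a binary map with a two-pixel difference kernel (zero
#' padding outside the array, output anchored at the first pixel of the
#' pair) and thresholds with the step function: a site is a detection when
#' the correlation reaches 1, i.e. exactly where the kernel's -1 pixel is 0
#' and its +1 pixel is 1.
#'
#' @param x binary (0/1 or logical) matrix.
#' @param kernel one element of [filter_bank].
#' @return Integer 0/1 matrix of the same shape.
#' @export
feature_map <- function(x, kernel) {
  x <- matrix(as.integer(x), nrow(x), ncol(x))
  nr <- nrow(x); nc <- ncol(x)
  shifted <- matrix(0L, nr, nc)    # value of the second pixel of the pair
  if (kernel$orientation == "along-row") {
    if (nc > 1L) shifted[, -nc] <- x[, -1L, drop = FALSE]
  } else {
    if (nr > 1L) shifted[-nr, ] <- x[-1L, , drop = FALSE]
  }
  corr <- kernel$k1 * x + kernel$k2 * shifted
  matrix(as.integer(corr >= 1L), nr, nc)
}
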