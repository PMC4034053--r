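#' Write a binary image to PGM or PNG
#'
#' PGM files are written as plain text (P2, maxval 255, white = 255) so
#' every artifact stays human-readable; PNG files are 8-bit grayscale.
#' The geometry metadata (`n`, `m`, `polarity`, `label`) goes to a JSON
#' sidecar `<path>.json`, so a written image reloads to an identical
#' in-memory value.
#'
#' @param img a [binary_image].
#' @param path output file ending in `.pgm` or `.png`.
#' @param sidecar write the metadata sidecar? (default TRUE)
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, sidecar = TRUE) {
  stopifnot(inherits(img, "binary_image"))
  ext <- tolower(tools::file_ext(path))
  px <- img$pixels
  if (ext == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(px), nrow(px)), "255"), con)
    # one image row per line, 0/255 coding
    writeLines(apply(px * 255L, 1L, paste, collapse = " "), con)
  } else if (ext == "png") {
    png::writePNG(matrix(as.double(px), nrow(px), ncol(px)), path)
  } else stop("unsupported image format: .", ext)
  if (sidecar) {
    meta <- list(n = img$n, m = img$m, polarity = img$polarity,
                 label = img$label)
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null"),
               paste0(path, ".json"))
  }
  invisible(path)
}

#' Read a binary image from PGM or PNG
#'
#' Accepts plain (P2) and raw (P5) PGM with any maxval, and 8-bit or
#' 1-bit PNG; any nonzero sample maps to white.  Geometry comes from the
#' JSON sidecar when present, otherwise from the `n`/`m` arguments.
#'
#' @param path image file.
#' @param n,m inner size and margin when no sidecar exists; default
#'   margin 0 and `n` the full image side.
#' @return A [binary_image].
#' @export
read_image <- function(path, n = NULL, m = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    pgm = read_pgm(path),
    png = {
      arr <- png::readPNG(path)
      if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
      matrix(as.integer(arr > 0), nrow(arr), ncol(arr))
    },
    stop("unsupported image format: .", ext))
  meta_path <- paste0(path, ".json")
  label <- NULL; polarity <- "framed-on-black"
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    n <- meta$n; m <- meta$m
    polarity <- meta$polarity
    label <- meta$label
  }
  if (nrow(px) != ncol(px)) stop("image must be square, got ",
                                 nrow(px), " x ", ncol(px))
  if (is.null(m)) m <- 0L
  if (is.null(n)) n <- nrow(px) - 2L * m
  if (n + 2L * m != nrow(px))
    stop("inconsistent geometry: n + 2m = ", n + 2L * m,
         " but image side is ", nrow(px))
  binary_image(px, n, m, polarity, label)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  # header tokens: width, height, maxval (comments allowed)
  tokens <- integer(0)
  buf <- ""
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L)
    if (length(ch) == 0L || ch == "") stop("truncated PGM header")
    if (ch == "#") {                     # skip comment to end of line
      repeat {
        ch <- readChar(con, 1L)
        if (length(ch) == 0L || ch %in% c("\n", "")) break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) buf <- paste0(buf, ch)
    else if (nzchar(buf)) { tokens <- c(tokens, as.integer(buf)); buf <- "" }
  }
  w <- tokens[1L]; h <- tokens[2L]; maxval <- tokens[3L]
  vals <- if (magic == "P2") {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else {
    if (maxval > 255L) stop("16-bit P5 not supported")
    as.integer(readBin(con, "raw", n = w * h))
  }
  if (length(vals) != w * h) stop("truncated PGM data")
  matrix(as.integer(vals > 0L), nrow = h, ncol = w, byrow = TRUE)
}

#' Write a spike raster as CSV
#'
#' Columns `area`, `channel_F`, `subchannel_j`, `cell_i`, `row`, `col`,
#' `time_ms`; one line per spike event.
#'
#' @param run a `network_run`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(run, path) {
  stopifnot(inherits(run, "network_run"))
  rows <- list()
  add <- function(raster, area, F = NA, j = NA, cell = NA) {
    df <- as.data.frame(raster)
    if (nrow(df) == 0L) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      area = area, channel_F = F, subchannel_j = j,
      cell_i = if (is.na(cell)) df$unit else df$unit,
      row = df$row, col = df$col, time_ms = df$time_ms)
  }
  for (F in 1:2) {
    add(run$rasters$area1[[F]], 1L, F)
    add(run$rasters$area2[[F]], 2L, F)
    for (j in 1:4) add(run$rasters$area3[[F]][[j]], 3L, F, j)
  }
  a4 <- as.data.frame(run$rasters$area4)
  if (nrow(a4)) rows[[length(rows) + 1L]] <- data.frame(
    area = 4L, channel_F = (a4$unit - 1L) %/% 4L + 1L,
    subchannel_j = (a4$unit - 1L) %% 4L + 1L, cell_i = a4$unit,
    row = NA_integer_, col = NA_integer_, time_ms = a4$time_ms)
  a5 <- as.data.frame(run$rasters$area5)
  if (nrow(a5)) rows[[length(rows) + 1L]] <- data.frame(
    area = 5L, channel_F = NA_integer_, subchannel_j = NA_integer_,
    cell_i = a5$unit, row = NA_integer_, col = NA_integer_,
    time_ms = a5$time_ms)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(area = integer(0), channel_F = integer(0),
               subchannel_j = integer(0), cell_i = integer(0),
               row = integer(0), col = integer(0), time_ms = numeric(0))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialize an experiment report to JSON
#' @param report an `experiment_report`, `rotation_report` or
#'   `circle_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  writeLines(jsonlite::toJSON(strip_class(report), auto_unbox = TRUE,
                              digits = NA, null = "null", na = "null",
                              pretty = TRUE),
             path)
  invisible(path)
}

strip_class <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_class)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Write the summary table of an experiment report as CSV
#' @param report an `experiment_report`. @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
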