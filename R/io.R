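#' Read a grayscale TIFF detector image
#'
#' Minimal baseline-TIFF reader for single-plane grayscale detector frames:
#' uncompressed data, little- or big-endian byte order, 16-bit unsigned,
#' 32-bit signed integer or 32-bit float samples, one or more strips.  This
#' covers the output of standard detector pipelines and of common image
#' tools writing uncompressed TIFF.
#'
#' @param path file path.
#' @return numeric matrix indexed `[ix, iy]` (x along rows), matching the
#'   `image_shape` convention of [detector_geometry()].
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(magic, charToRaw("II"))) "little"
            else if (identical(magic, charToRaw("MM"))) "big"
            else stop("not a TIFF file (bad byte-order mark): ", path)
  u16 <- function() readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
  u32 <- function() readBin(con, "integer", 1, 4, endian = endian)
  if (u16() != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd_off <- u32()
  seek(con, ifd_off)
  n_entries <- u16()
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- u16(); type <- u16(); count <- u32()
    field <- readBin(con, "raw", 4)
    tags[[as.character(tag)]] <- list(type = type, count = count, field = field)
  }
  val <- function(tag, default = NULL) {
    e <- tags[[as.character(tag)]]
    if (is.null(e)) return(default)
    size <- switch(as.character(e$type), `3` = 2L, `4` = 4L,
                   stop("unsupported TIFF tag type ", e$type, " in ", path))
    total <- size * e$count
    raw <- if (total <= 4) e$field[seq_len(total)] else {
      seek(con, readBin(e$field, "integer", 1, 4, endian = endian))
      readBin(con, "raw", total)
    }
    readBin(raw, "integer", e$count, size, signed = size > 2, endian = endian)
  }
  width <- val(256); height <- val(257)
  if (is.null(width) || is.null(height)) stop("TIFF missing dimensions: ", path)
  bits <- val(258, 1L)[1]
  if (val(259, 1L) != 1L) stop("compressed TIFF not supported: ", path)
  fmt <- val(339, 1L)[1]
  offsets <- val(273); counts <- val(279)
  if (is.null(offsets)) stop("TIFF missing strip offsets: ", path)
  if (is.null(counts)) counts <- rep(width * height * bits / 8, length(offsets))

  npix <- width * height
  read_strip <- function(off, nbytes) {
    seek(con, off)
    n <- nbytes / (bits / 8)
    if (bits == 16 && fmt == 1) {
      readBin(con, "integer", n, 2, signed = FALSE, endian = endian)
    } else if (bits == 32 && fmt == 3) {
      readBin(con, "double", n, 4, endian = endian)
    } else if (bits == 32 && fmt == 2) {
      readBin(con, "integer", n, 4, endian = endian)
    } else stop("unsupported TIFF sample layout (bits = ", bits,
                ", format = ", fmt, "): ", path)
  }
  v <- as.numeric(unlist(mapply(read_strip, offsets, counts, SIMPLIFY = FALSE)))
  if (length(v) != npix) stop("TIFF pixel count mismatch in ", path)
  matrix(v, nrow = width)   # TIFF rows are contiguous x runs
}

#' Write a grayscale TIFF detector image
#'
#' Writes a single-strip uncompressed little-endian TIFF.  `type "float32"`
#' preserves arbitrary numeric data; `"uint16"` requires values in
#' `[0, 65535]` (rounded).
#'
#' @param image numeric matrix indexed `[ix, iy]`.
#' @param path output path.
#' @param type `"float32"` (default) or `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(image, path, type = c("float32", "uint16")) {
  type <- match.arg(type)
  stopifnot(is.matrix(image))
  width <- nrow(image); height <- ncol(image)
  con <- file(path, "wb"); on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, 4, endian = "little")
  bits <- if (type == "uint16") 16L else 32L
  fmt <- if (type == "uint16") 1L else 3L
  nbytes <- width * height * bits / 8
  data_off <- 8L
  ifd_off <- data_off + nbytes

  writeBin(charToRaw("II"), con); w16(42L); w32(ifd_off)
  if (type == "uint16") {
    v <- round(as.vector(image))
    if (any(v < 0 | v > 65535)) stop("uint16 TIFF needs values in [0, 65535]")
    v[v > 32767] <- v[v > 32767] - 65536     # two's complement for writeBin
    writeBin(as.integer(v), con, 2, endian = "little")
  } else {
    writeBin(as.numeric(as.vector(image)), con, 4, endian = "little")
  }
  entries <- list(
    c(256L, 4L, 1L, width), c(257L, 4L, 1L, height),
    c(258L, 3L, 1L, bits),  c(259L, 3L, 1L, 1L),
    c(262L, 3L, 1L, 1L),    c(273L, 4L, 1L, data_off),
    c(277L, 3L, 1L, 1L),    c(278L, 4L, 1L, height),
    c(279L, 4L, 1L, nbytes), c(339L, 3L, 1L, fmt))
  w16(length(entries))
  for (e in entries) {
    w16(e[1]); w16(e[2]); w32(e[3])
    if (e[2] == 3L) { w16(e[4]); w16(0L) } else w32(e[4])
  }
  w32(0L)                                     # no next IFD
  invisible(path)
}

#' Write / read a polar pattern stack
#'
#' Stores an ensemble of polar patterns with its axes, masks, metadata and
#' (for synthetic data) ground truth in a single self-describing container.
#' The container is an RDS file holding named components `intensity`
#' (`n_d x n_q x n_phi`), `mask`, `q`, `phi`, `meta`, and optionally `truth`
#' and `orientations`; round trips are bitwise lossless.  (An HDF5 layout
#' with the same component names is the natural exchange format; RDS is used
#' here so the package has no compiled I/O dependencies.)
#'
#' @param patterns list of [polar_pattern()]s on a shared grid.
#' @param path output path.
#' @param truth optional ground-truth data frame.
#' @param orientations optional list of per-exposure orientations.
#' @param meta named list of run metadata.
#' @return `path`, invisibly.
#' @export
write_polar_stack <- function(patterns, path, truth = NULL,
                              orientations = NULL, meta = list()) {
  if (length(patterns) < 1) stop("empty stack")
  grid <- patterns[[1]]$grid
  n_d <- length(patterns)
  I <- array(0, c(n_d, grid$n_q, grid$n_phi))
  M <- array(TRUE, c(n_d, grid$n_q, grid$n_phi))
  for (k in seq_len(n_d)) {
    p <- patterns[[k]]
    if (!identical(p$grid$q, grid$q) || p$grid$n_phi != grid$n_phi)
      stop("patterns must share one polar grid")
    I[k, , ] <- p$intensity; M[k, , ] <- p$mask
  }
  obj <- list(format = "padftex-polar-stack", version = 1L,
              intensity = I, mask = M, q = grid$q, phi = grid$phi,
              mean_subtracted = patterns[[1]]$mean_subtracted,
              meta = meta, truth = truth, orientations = orientations)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_polar_stack
#' @return for `read_polar_stack`: list with `patterns`, `grid`, `truth`,
#'   `orientations`, `meta`.
#' @export
read_polar_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot parse polar stack ", path, ": ", conditionMessage(e)))
  if (!identical(obj$format, "padftex-polar-stack"))
    stop("not a padftex polar stack: ", path)
  grid <- polar_grid(obj$q, length(obj$phi))
  patterns <- lapply(seq_len(dim(obj$intensity)[1]), function(k)
    polar_pattern(obj$intensity[k, , , drop = TRUE], grid,
                  mask = obj$mask[k, , , drop = TRUE],
                  meta = list(exposure = k),
                  mean_subtracted = isTRUE(obj$mean_subtracted)))
  list(patterns = patterns, grid = grid, truth = obj$truth,
       orientations = obj$orientations, meta = obj$meta)
}

#' Write / read a detector geometry config
#'
#' Plain-text `key = value` format with units fixed by convention
#' (wavelength angstrom, distance metres, pixel size micrometres).
#'
#' @param geom a [detector_geometry()].
#' @param path file path.
#' @return `path` / a [detector_geometry()].
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "detector_geometry"))
  lines <- c(
    sprintf("wavelength = %.10g", geom$wavelength),
    sprintf("distance = %.10g", geom$distance),
    sprintf("pixel_size = %.10g", geom$pixel_size),
    sprintf("beam_centre_x = %.10g", geom$beam_centre[1]),
    sprintf("beam_centre_y = %.10g", geom$beam_centre[2]),
    sprintf("image_nx = %d", geom$image_shape[1]),
    sprintf("image_ny = %d", geom$image_shape[2]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 0L) != 2
  if (any(bad)) stop("malformed geometry config ", path, ": line '",
                     lines[which(bad)[1]], "'")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2))))
  need <- c("wavelength", "distance", "pixel_size", "beam_centre_x",
            "beam_centre_y", "image_nx", "image_ny")
  if (!all(need %in% keys) || anyNA(vals[match(need, keys)]))
    stop("malformed geometry config ", path, ": missing or non-numeric keys")
  g <- as.list(vals[match(need, keys)])
  detector_geometry(g[[1]], g[[2]], g[[3]], c(g[[4]], g[[5]]),
                    c(g[[6]], g[[7]]))
}
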