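#' Write a frame sequence as numbered image files with a manifest
#'
#' Frames are written as `frame_0001.png`, ... plus a `manifest.json`
#' recording frame order, bit depth, instrument parameters and seed.
#' 8-bit frames are PNG; higher bit depths use binary 16-bit PPM (P6,
#' two-byte big-endian samples), since no available PNG writer emits
#' 16-bit samples. Raw DN values are preserved exactly either way.
#'
#' @param frames list of `rows x cols x 3` integer arrays, or a
#'   `scan_result` from [render_scan()].
#' @param dir output directory (created if needed).
#' @param bit_depth DN bit depth of the frames; taken from the
#'   `scan_result`'s model when available.
#' @param metadata extra fields stored in the manifest.
#' @return the directory path, invisibly.
#' @export
write_frames <- function(frames, dir, bit_depth = 8, metadata = list()) {
  if (inherits(frames, "scan_result")) {
    bit_depth <- frames$model$bit_depth
    metadata <- c(metadata, list(
      seed = frames$seed,
      dispersion_coefficients = frames$model$dispersion$coefficients,
      sensor = c(frames$model$sensor_rows, frames$model$sensor_cols)))
    frames <- frames$frames
  }
  if (!length(frames)) stop("write_frames: no frames")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (bit_depth > 8) "ppm" else "png"
  files <- sprintf("frame_%04d.%s", seq_along(frames), ext)
  for (i in seq_along(frames)) {
    if (bit_depth > 8)
      .write_ppm16(frames[[i]], file.path(dir, files[i]), bit_depth)
    else png::writePNG(frames[[i]] / 255, file.path(dir, files[i]))
  }
  manifest <- c(list(frames = files, bit_depth = bit_depth,
                     n_frames = length(frames)), metadata)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a push-broom frame sequence from a directory
#'
#' If `manifest.json` is present its frame order and bit depth are used
#' (manifest order overrides filename order); otherwise PNG files are read
#' in lexicographic order and assumed 8-bit. All frames must share
#' dimensions.
#'
#' @param dir directory of numbered PNG frames.
#' @return an object of class `frame_sequence`: `frames` (list of integer
#'   `rows x cols x 3` arrays), `bit_depth`, `manifest` (or `NULL`).
#' @export
read_frames <- function(dir) {
  if (!dir.exists(dir)) stop("read_frames: no such directory: ", dir)
  manifest <- NULL
  mpath <- file.path(dir, "manifest.json")
  if (file.exists(mpath)) {
    manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    files <- manifest$frames
    bit_depth <- manifest$bit_depth
  } else {
    files <- sort(list.files(dir, pattern = "\\.(png|ppm)$", ignore.case = TRUE))
    bit_depth <- 8
  }
  if (!length(files)) stop("read_frames: no frames found in ", dir)
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    path <- file.path(dir, files[i])
    dn <- tryCatch({
      if (grepl("\\.ppm$", files[i], ignore.case = TRUE)) .read_ppm16(path)
      else {
        img <- png::readPNG(path)
        if (length(dim(img)) == 2L)
          img <- array(rep(img, 3), dim = c(dim(img), 3))
        if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
        array(as.integer(round(img * 255)), dim = dim(img))
      }
    }, error = function(e)
      stop("read_frames: cannot read frame '", files[i], "': ",
           conditionMessage(e), call. = FALSE))
    if (i > 1L && !identical(dim(dn), dim(frames[[1]])))
      stop("read_frames: frame '", files[i], "' has dimensions ",
           paste(dim(dn), collapse = "x"), " but '", files[1], "' has ",
           paste(dim(frames[[1]]), collapse = "x"))
    frames[[i]] <- dn
  }
  structure(list(frames = frames, bit_depth = bit_depth, manifest = manifest,
                 dir = dir),
            class = "frame_sequence")
}

# binary PPM (P6) with two-byte big-endian samples; maxval = 2^bit_depth - 1
.write_ppm16 <- function(frame, path, bit_depth) {
  d <- dim(frame)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0("P6\n", d[2], " ", d[1], "\n",
                            2^bit_depth - 1, "\n")), con)
  # sample order: per pixel R,G,B; pixels left-to-right, rows top-to-bottom
  px <- aperm(frame, c(3, 2, 1))
  writeBin(as.integer(px), con, size = 2, endian = "big")
}

.read_ppm16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  next_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readBin(con, "raw", n = 1)
      if (!length(ch)) stop("unexpected end of PPM header")
      c2 <- rawToChar(ch)
      if (c2 %in% c(" ", "\t", "\r", "\n")) {
        if (length(tok)) return(paste(tok, collapse = ""))
      } else tok <- c(tok, c2)
    }
  }
  if (!identical(next_token(), "P6")) stop("not a binary PPM file")
  w <- as.integer(next_token()); h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(w) || is.na(h) || is.na(maxval)) stop("malformed PPM header")
  if (maxval <= 255) stop("8-bit PPM not expected here")
  n <- w * h * 3
  raw2 <- readBin(con, integer(), n = n, size = 2, endian = "big",
                  signed = FALSE)
  if (length(raw2) < n) stop("truncated PPM payload")
  aperm(array(as.integer(raw2), dim = c(3, w, h)), c(3, 2, 1))
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat("Frame sequence:", length(x$frames), "frames of", d[1], "x", d[2],
      "x", d[3], paste0("(", x$bit_depth, "-bit)"),
      if (!is.null(x$manifest)) "with manifest" else "", "\n")
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Write a spectrum to CSV
#'
#' Two-column CSV `(wavelength_nm, intensity)` with one header line, the
#' interchange format for line tables and measured spectra.
#'
#' @param spectrum data.frame with wavelength and intensity columns.
#' @param path output path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  sp <- .as_spectrum_df(spectrum, "spectrum")
  utils::write.csv(sp, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum (or reference line table) from CSV
#'
#' @param path 2-column CSV `(wavelength_nm, intensity)` with a header line.
#' @return data.frame `(wavelength_nm, intensity)`.
#' @export
read_spectrum_csv <- function(path) {
  x <- utils::read.csv(path)
  if (ncol(x) < 2L) stop("read_spectrum_csv: expected two columns in ", path)
  out <- suppressWarnings(data.frame(wavelength_nm = as.numeric(x[[1]]),
                                     intensity = as.numeric(x[[2]])))
  if (any(!is.finite(out$wavelength_nm)))
    stop("read_spectrum_csv: non-numeric wavelengths in ", path)
  out
}
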