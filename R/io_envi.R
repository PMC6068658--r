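#' Write a hypercube in ENVI format
#'
#' Flat binary cube (BSQ interleave, little-endian IEEE doubles, ENVI data
#' type 5) plus a text `.hdr` carrying dimensions, interleave and the
#' wavelength axis at full precision. Double storage makes the round trip
#' bit-exact for both integer and floating cubes.
#'
#' ENVI axis convention: `lines` = scan lines, `samples` = slit rows,
#' `bands` = spectral bands.
#'
#' @param cube a `hypercube`.
#' @param path output path without extension; writes `path.img` and
#'   `path.hdr`.
#' @return `path`, invisibly.
#' @export
write_cube_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  img <- paste0(path, ".img"); hdr <- paste0(path, ".hdr")
  con <- file(img, "wb")
  on.exit(close(con), add = TRUE)
  # BSQ: per band, all lines; per line, all samples (samples vary fastest)
  for (b in seq_len(d[3])) {
    plane <- cube$data[, , b]
    writeBin(as.numeric(t(plane)), con, size = 8, endian = "little")
  }
  wl_txt <- paste(vapply(cube$wavelength_nm,
                         function(w) format(w, digits = 17), character(1)),
                  collapse = ", ")
  valid_txt <- paste(as.integer(cube$valid), collapse = ", ")
  writeLines(c(
    "ENVI",
    "description = {pushbroomr hypercube}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {", wl_txt, "}"),
    paste0("band validity = {", valid_txt, "}")
  ), hdr)
  invisible(path)
}

#' Read a hypercube written by [write_cube_envi()]
#'
#' @param path path without extension (expects `path.img` and `path.hdr`).
#' @return a `hypercube`.
#' @export
read_cube_envi <- function(path) {
  img <- paste0(path, ".img"); hdr <- paste0(path, ".hdr")
  if (!file.exists(hdr)) stop("read_cube_envi: missing header ", hdr)
  if (!file.exists(img)) stop("read_cube_envi: missing binary ", img)
  lines <- readLines(hdr, warn = FALSE)
  field <- function(name) {
    hit <- grep(paste0("^", name, "\\s*="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^", name, "\\s*=\\s*"), "", hit[1])
  }
  ns <- as.integer(field("samples")); nl <- as.integer(field("lines"))
  nb <- as.integer(field("bands")); dt <- as.integer(field("data type"))
  il <- field("interleave")
  if (is.na(ns) || is.na(nl) || is.na(nb))
    stop("read_cube_envi: header lacks dimensions")
  if (!identical(dt, 5L)) stop("read_cube_envi: unsupported data type ", dt)
  if (!identical(tolower(il), "bsq"))
    stop("read_cube_envi: unsupported interleave ", il)
  brace_list <- function(name) {
    # value may span lines; rejoin and pull the {...} body
    txt <- paste(lines, collapse = " ")
    m <- regmatches(txt, regexpr(paste0(name, "\\s*=\\s*\\{[^}]*\\}"), txt))
    if (!length(m)) return(NULL)
    body <- sub(".*\\{", "", sub("\\}$", "", m))
    as.numeric(strsplit(body, ",")[[1]])
  }
  wl <- brace_list("wavelength")
  if (is.null(wl) || length(wl) != nb)
    stop("read_cube_envi: wavelength list missing or wrong length")
  valid <- brace_list("band validity")

  expected <- as.numeric(ns) * nl * nb * 8
  actual <- file.size(img)
  if (actual != expected)
    stop("read_cube_envi: binary size ", actual, " bytes does not match the ",
         "header (expected ", expected, ")")
  con <- file(img, "rb")
  on.exit(close(con), add = TRUE)
  data <- array(NA_real_, dim = c(nl, ns, nb))
  for (b in seq_len(nb)) {
    plane <- readBin(con, numeric(), n = ns * nl, size = 8, endian = "little")
    data[, , b] <- matrix(plane, nl, ns, byrow = TRUE)
  }
  hypercube(data, wl,
            valid = if (!is.null(valid)) as.logical(valid),
            provenance = list(source = "read_cube_envi", path = path))
}
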