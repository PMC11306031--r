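#' Read a point cloud
#'
#' Reads a 3D point cloud into a tibble with columns `x`, `y`, `z` (meters)
#' plus any extra per-point channels the file carries (e.g. `red`, `green`,
#' `blue` from PLY). Point order is preserved from the file. Supported
#' formats: ASCII or binary-little-endian PLY, whitespace-delimited XYZ text
#' (extra columns beyond the first three are kept as `v4`, `v5`, ...), and
#' LAS 1.2 point format 0.
#'
#' @param path file path.
#' @param format one of `"ply"`, `"xyz"`, `"las"`; guessed from the file
#'   extension when `NULL`.
#' @return a tibble with one row per point.
#' @seealso [write_point_cloud()]
#' @export
read_point_cloud <- function(path, format = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("ply", "xyz", "las"))
  pc <- switch(format,
    ply = read_ply(path),
    xyz = read_xyz(path),
    las = read_las(path)
  )
  if (nrow(pc) == 0) abort(paste0("empty point cloud in ", path))
  as_cloud(pc)
}

#' Write a point cloud
#'
#' Writes a cloud to PLY (ASCII by default, for diff-able files), XYZ text,
#' or LAS 1.2 point format 0. LAS coordinates are quantized with a scale of
#' 0.0001 m (0.1 mm) and an offset at the floor of the lower box corner, so
#' millimeter-scale structure survives the integer encoding.
#'
#' @param data a data frame with columns `x`, `y`, `z` in meters.
#' @param path output file path.
#' @param format one of `"ply"`, `"xyz"`, `"las"`; guessed from the extension
#'   when `NULL`.
#' @param binary write binary-little-endian PLY instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(data, path, format = NULL, binary = FALSE) {
  data <- as_cloud(data)
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("ply", "xyz", "las"))
  switch(format,
    ply = write_ply(data, path, binary = binary),
    xyz = write_xyz(data, path),
    las = write_las(data, path)
  )
  invisible(path)
}

#' Invert the vertical axis of a cloud
#'
#' Excavated root systems are scanned the way they grew: collar up, tips
#' down. Bottom-up modeling starts at the collar, so the cloud is flipped
#' with `z' = (z_min + z_max) - z`, which mirrors z inside its own range
#' (keeping coordinates positive) and leaves x and y untouched. Applying the
#' flip twice restores the input exactly.
#'
#' @param data a cloud tibble.
#' @return the inverted cloud.
#' @export
#' @examples
#' cloud <- tibble::tibble(x = 0, y = 0, z = c(0, 1, 2))
#' invert_axis(cloud)$z
invert_axis <- function(data) {
  data <- as_cloud(data)
  data$z <- (min(data$z) + max(data$z)) - data$z
  data
}

#' Crop a cloud to an axis-aligned box
#'
#' Keeps exactly the points inside the closed box `lo <= p <= hi`,
#' preserving point order.
#'
#' @param data a cloud tibble.
#' @param lo,hi numeric length-3 lower/upper box corners (m).
#' @return the cropped cloud.
#' @export
crop_box <- function(data, lo, hi) {
  data <- as_cloud(data)
  stopifnot(length(lo) == 3, length(hi) == 3)
  if (any(lo > hi)) abort("crop_box: `lo` must be <= `hi` componentwise.")
  keep <- data$x >= lo[1] & data$x <= hi[1] &
    data$y >= lo[2] & data$y <= hi[2] &
    data$z >= lo[3] & data$z <= hi[3]
  if (!any(keep)) {
    abort(paste0("crop_box: box retains 0 of ", nrow(data), " points."))
  }
  data[keep, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "xyz", "las")) return(ext)
  if (ext %in% c("txt", "pts", "asc")) return("xyz")
  abort(paste0("cannot guess point-cloud format from extension '.", ext,
               "'; pass `format` explicitly."))
}

# ---- PLY ----

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) {
    abort(paste0("not a PLY file (bad magic line): ", path))
  }
  fmt <- NULL
  elements <- list() # name -> list(count, props = tibble(name, type))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0) abort(paste0("truncated PLY header in ", path))
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]),
                              props = character(), types = character())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        elements[[cur]]$types <- c(elements[[cur]]$types, "list")
        elements[[cur]]$props <- c(elements[[cur]]$props, tok[5])
      } else {
        elements[[cur]]$types <- c(elements[[cur]]$types, tok[2])
        elements[[cur]]$props <- c(elements[[cur]]$props, tok[3])
      }
    } else if (tok[1] == "end_header") {
      break
    }
  }
  if (is.null(elements$vertex)) abort(paste0("PLY has no vertex element: ", path))
  if (names(elements)[1] != "vertex") {
    abort("PLY reader supports files whose first element is 'vertex'.")
  }
  el <- elements$vertex
  n <- el$count
  if (identical(fmt, "ascii")) {
    vals <- scan(con, what = numeric(), n = n * length(el$props), quiet = TRUE)
    if (length(vals) < n * length(el$props)) {
      abort(paste0("truncated PLY vertex data (expected ", n * length(el$props),
                   " values, got ", length(vals), ") in ", path))
    }
    m <- matrix(vals, ncol = length(el$props), byrow = TRUE)
  } else if (identical(fmt, "binary_little_endian")) {
    if (any(el$types == "list")) abort("list properties unsupported in vertex element")
    sizes <- ply_type_size[el$types]
    if (any(is.na(sizes))) abort("unknown PLY property type in vertex element")
    m <- matrix(NA_real_, nrow = n, ncol = length(el$props))
    raw <- readBin(con, "raw", n = n * sum(sizes))
    if (length(raw) < n * sum(sizes)) {
      abort(paste0("truncated PLY binary payload (", length(raw), " of ",
                   n * sum(sizes), " bytes) in ", path))
    }
    offs <- cumsum(c(0L, sizes))
    rec <- sum(sizes)
    for (j in seq_along(el$props)) {
      idx <- as.vector(outer(seq_len(sizes[j]) + offs[j], (seq_len(n) - 1L) * rec, `+`))
      bytes <- raw[idx]
      ty <- el$types[j]
      m[, j] <- switch(ty,
        float = , float32 = readBin(bytes, "numeric", n = n, size = 4, endian = "little"),
        double = , float64 = readBin(bytes, "numeric", n = n, size = 8, endian = "little"),
        char = , int8 = readBin(bytes, "integer", n = n, size = 1, signed = TRUE),
        uchar = , uint8 = readBin(bytes, "integer", n = n, size = 1, signed = FALSE),
        short = , int16 = readBin(bytes, "integer", n = n, size = 2, signed = TRUE, endian = "little"),
        ushort = , uint16 = readBin(bytes, "integer", n = n, size = 2, signed = FALSE, endian = "little"),
        int = , int32 = readBin(bytes, "integer", n = n, size = 4, endian = "little"),
        uint = , uint32 = readBin(bytes, "integer", n = n, size = 4, endian = "little"),
        abort(paste0("unsupported PLY type ", ty)))
    }
  } else {
    abort(paste0("unsupported PLY format '", fmt,
                 "' (ascii and binary_little_endian are supported)"))
  }
  colnames(m) <- el$props
  out <- as_tibble(as.data.frame(m))
  need <- c("x", "y", "z")
  if (!all(need %in% names(out))) abort("PLY vertex element lacks x/y/z properties")
  out[, c(need, setdiff(names(out), need))]
}

write_ply <- function(data, path, binary = FALSE) {
  n <- nrow(data)
  has_rgb <- all(c("red", "green", "blue") %in% names(data))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    paste("element vertex", n),
    "property float x", "property float y", "property float z",
    if (has_rgb) c("property uchar red", "property uchar green", "property uchar blue"),
    "end_header"
  )
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    xyz <- t(cloud_matrix(data))
    if (has_rgb) {
      rgb <- t(as.matrix(data[, c("red", "green", "blue")]))
      for (i in seq_len(n)) {
        writeBin(as.numeric(xyz[, i]), con, size = 4, endian = "little")
        writeBin(as.raw(rgb[, i]), con)
      }
    } else {
      writeBin(as.numeric(xyz), con, size = 4, endian = "little")
    }
  } else {
    cols <- c("x", "y", "z", if (has_rgb) c("red", "green", "blue"))
    lines <- do.call(paste, c(lapply(cols, function(cn) {
      v <- data[[cn]]
      if (cn %in% c("red", "green", "blue")) format(as.integer(v)) else sprintf("%.8g", v)
    })))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

# ---- XYZ ----

read_xyz <- function(path) {
  dat <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) abort(paste0("cannot parse XYZ file ", path, ": ",
                                     conditionMessage(e)))
  )
  if (ncol(dat) < 3) abort(paste0("XYZ file has fewer than 3 columns: ", path))
  names(dat)[1:3] <- c("x", "y", "z")
  if (ncol(dat) > 3) names(dat)[-(1:3)] <- paste0("v", seq(4, ncol(dat)))
  as_tibble(dat)
}

write_xyz <- function(data, path) {
  m <- cloud_matrix(data)
  writeLines(sprintf("%.8g %.8g %.8g", m[, 1], m[, 2], m[, 3]), path)
  invisible(path)
}

# ---- LAS 1.2, point format 0 ----

LAS_SCALE <- 1e-4 # 0.1 mm quantization

write_las <- function(data, path) {
  m <- cloud_matrix(data)
  n <- nrow(m)
  off <- floor(apply(m, 2, min))
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size, type = "integer") writeBin(x, con, size = size, endian = "little")
  writeChar("LASF", con, nchars = 4, eos = NULL)
  wb(0L, 2); wb(0L, 2)                       # source id, global encoding
  writeBin(raw(16), con)                     # GUID
  writeBin(as.raw(c(1L, 2L)), con)           # version 1.2
  writeChar(formatC("rootqsm", width = 32, flag = "-"), con, nchars = 32, eos = NULL)
  writeChar(formatC("rootqsm", width = 32, flag = "-"), con, nchars = 32, eos = NULL)
  wb(1L, 2); wb(2026L, 2)                    # day, year
  wb(227L, 2)                                # header size
  wb(227L, 4)                                # offset to point data
  wb(0L, 4)                                  # number of VLRs
  writeBin(as.raw(0L), con)                  # point data format 0
  wb(20L, 2)                                 # point record length
  wb(n, 4)                                   # number of points
  wb(rep(0L, 5), 4)                          # points by return
  writeBin(rep(LAS_SCALE, 3), con, size = 8, endian = "little")
  writeBin(as.numeric(off), con, size = 8, endian = "little")
  writeBin(as.numeric(c(max(m[, 1]), min(m[, 1]),
                        max(m[, 2]), min(m[, 2]),
                        max(m[, 3]), min(m[, 3]))), con, size = 8, endian = "little")
  q <- sweep(m, 2, off)
  q <- round(q / LAS_SCALE)
  if (any(abs(q) > 2^31 - 1)) abort("coordinates exceed LAS integer range at scale 0.0001")
  rec <- matrix(0L, nrow = 3, ncol = n)
  rec[] <- as.integer(t(q))
  tailbytes <- as.raw(rep(0L, 8))
  for (i in seq_len(n)) {
    writeBin(rec[, i], con, size = 4, endian = "little")
    writeBin(tailbytes, con)
  }
  invisible(path)
}

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) abort(paste0("not a LAS file: ", path))
  seek(con, 24)
  ver <- readBin(con, "integer", n = 2, size = 1, signed = FALSE)
  seek(con, 94)
  hdr_size <- readBin(con, "integer", n = 1, size = 2, signed = FALSE, endian = "little")
  offset <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  n_vlr <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  pdf <- readBin(con, "integer", n = 1, size = 1, signed = FALSE)
  reclen <- readBin(con, "integer", n = 1, size = 2, signed = FALSE, endian = "little")
  npts <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 131)
  scale <- readBin(con, "numeric", n = 3, size = 8, endian = "little")
  offs <- readBin(con, "numeric", n = 3, size = 8, endian = "little")
  if (pdf != 0) abort(paste0("unsupported LAS point data format ", pdf,
                             " (only format 0 is supported)"))
  seek(con, offset)
  raw <- readBin(con, "raw", n = npts * reclen)
  if (length(raw) < npts * reclen) {
    abort(paste0("truncated LAS payload (", length(raw), " of ",
                 npts * reclen, " bytes) in ", path))
  }
  pick <- function(field_off, width) {
    idx <- as.vector(outer(seq_len(width) + field_off,
                           (seq_len(npts) - 1L) * reclen, `+`))
    readBin(raw[idx], "integer", n = npts, size = width, endian = "little")
  }
  tibble(
    x = pick(0L, 4L) * scale[1] + offs[1],
    y = pick(4L, 4L) * scale[2] + offs[2],
    z = pick(8L, 4L) * scale[3] + offs[3]
  )
}
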