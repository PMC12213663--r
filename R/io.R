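#' Read an image file
#'
#' TIFF (fluorescence; 8/16-bit or float) and MRC modes 0/1/2 (EM images
#' and tomograms) are supported. For MRC the pixel size comes from the
#' header (`cella / mx`, Angstrom to nm) unless overridden; TIFF carries
#' no standard physical-size tag, so the pixel size is taken from the
#' sidecar JSON written by [write_image()] when present, else from
#' `pixel_size_nm`.
#'
#' @param path image path (`.tif`/`.tiff` or `.mrc`/`.rec`/`.st`).
#' @param pixel_size_nm override/fallback pixel size.
#' @param frame_id,channel metadata attached to the result.
#' @return An [image_plane()], or a [tomogram_stack()] for an MRC volume
#'   with more than one section.
#' @export
read_image <- function(path, pixel_size_nm = NULL, frame_id = "image",
                       channel = NA_character_) {
  if (!file.exists(path)) stop("read_image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tryCatch(tiff::readTIFF(path),
                   error = function(e) stop("read_image: cannot read '", path,
                                            "' as TIFF: ", conditionMessage(e)))
    if (length(dim(px)) == 3) px <- px[, , 1]
    ps <- pixel_size_nm
    side <- paste0(path, ".meta.json")
    if (file.exists(side)) {
      meta <- jsonlite::fromJSON(side)
      if (is.null(ps)) ps <- meta$pixel_size_nm
      if (!is.null(meta$value_scale)) px <- px * meta$value_scale
    }
    if (is.null(ps)) ps <- 1
    image_plane(px, ps, frame_id, channel)
  } else if (ext %in% c("mrc", "rec", "st", "map")) {
    read_mrc(path, pixel_size_nm = pixel_size_nm, frame_id = frame_id)
  } else stop("read_image: unsupported format '", ext, "' for ", path)
}

#' Write an image file
#'
#' TIFF output is 32-bit float with a JSON sidecar carrying the pixel
#' size; MRC output is mode 2 (float32) with the voxel size in the
#' header. Round-trips are lossless at float32 precision.
#'
#' @param obj an [image_plane()] or [tomogram_stack()].
#' @param path output path; the extension selects the format.
#' @export
write_image <- function(obj, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    stopifnot(inherits(obj, "image_plane"))
    m <- obj$pixels
    attributes(m) <- list(dim = dim(m))
    # libtiff float samples are only defined in [0, 1]: store scaled, record
    # the scale in the sidecar so reads restore physical values
    scale <- max(abs(m), 1)
    tiff::writeTIFF(m / scale, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(pixel_size_nm = obj$pixel_size_nm,
                              frame_id = obj$frame_id, channel = obj$channel,
                              value_scale = scale),
                         paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("mrc", "rec", "st", "map")) {
    write_mrc(obj, path)
  } else stop("write_image: unsupported format '", ext, "' for ", path)
  invisible(path)
}

# ---- minimal MRC-2014 reader/writer (modes 0, 1, 2) ------------------------

#' Read / write MRC files
#'
#' A minimal MRC-2014 implementation covering modes 0 (int8), 1 (int16)
#' and 2 (float32), little-endian, no extended header on write; an
#' extended header (`nsymbt`) is skipped on read. The voxel size is
#' `cella / mx` (Angstrom), reported in nm.
#'
#' @param path MRC file path.
#' @param pixel_size_nm override the header voxel size.
#' @param frame_id frame label for the result.
#' @export
read_mrc <- function(path, pixel_size_nm = NULL, frame_id = "tomogram") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_ints <- readBin(con, "integer", 10, size = 4, endian = "little")
  nx <- hdr_ints[1]; ny <- hdr_ints[2]; nz <- hdr_ints[3]; mode <- hdr_ints[4]
  mx <- hdr_ints[8]
  cella <- readBin(con, "double", 3, size = 4, endian = "little")
  if (!mode %in% c(0, 1, 2) || nx <= 0 || ny <= 0 || nz <= 0 || nx > 1e5 || ny > 1e5)
    stop("read_mrc: '", path, "' is not a supported MRC file (mode ", mode,
         ", dims ", nx, "x", ny, "x", nz, ")")
  seek(con, 23 * 4)
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- nx * ny * nz
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "double", n, size = 4, endian = "little"))
  if (length(data) < n) stop("read_mrc: '", path, "' truncated (corrupt header?)")
  ps <- pixel_size_nm
  if (is.null(ps)) ps <- if (mx > 0 && cella[1] > 0) cella[1] / mx / 10 else 1
  # file order: x fastest, then y, then z
  if (nz == 1) {
    image_plane(matrix(data, ny, nx, byrow = TRUE), ps, frame_id, channel = "EM")
  } else {
    vox <- aperm(array(data, dim = c(nx, ny, nz)), c(3, 2, 1))
    tomogram_stack(vox, ps, frame_id)
  }
}

#' @param obj an [image_plane()] or [tomogram_stack()].
#' @rdname read_mrc
#' @export
write_mrc <- function(obj, path) {
  if (inherits(obj, "image_plane")) {
    dims <- c(ncol(obj$pixels), nrow(obj$pixels), 1L)   # nx, ny, nz
    data <- as.numeric(t(obj$pixels))
    ps <- obj$pixel_size_nm
  } else if (inherits(obj, "tomogram_stack")) {
    d <- dim(obj$voxels)                                # z, y, x
    dims <- c(d[3], d[2], d[1])
    data <- as.numeric(aperm(obj$voxels, c(3, 2, 1)))
    ps <- obj$voxel_size_nm
  } else stop("write_mrc: need an image_plane or tomogram_stack")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(dims, 2L, 0L, 0L, 0L, dims)), con, size = 4,
           endian = "little")                            # n*, mode, nstart, m*
  writeBin(c(dims * ps * 10, 90, 90, 90), con, size = 4, endian = "little")
  writeBin(1:3, con, size = 4, endian = "little")        # mapc/mapr/maps
  writeBin(c(min(data), max(data), mean(data)), con, size = 4, endian = "little")
  writeBin(integer(2), con, size = 4, endian = "little") # ispg, nsymbt
  writeBin(raw(100), con)                                # extra
  writeBin(numeric(3), con, size = 4, endian = "little") # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)       # little-endian stamp
  writeBin(stats::sd(data), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")         # nlabl
  writeBin(raw(800), con)
  writeBin(data, con, size = 4, endian = "little")
  invisible(path)
}

#' Read / write fiducial point lists
#'
#' CSV with header `frame_id, x, y`; extra columns are preserved on read
#' and row order is stable.
#'
#' @param path CSV path.
#' @param pixel_size_nm pixel size attached to the returned [point_set()].
#' @export
read_points <- function(path, pixel_size_nm = NA_real_) {
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  if (anyDuplicated(header))
    stop("read_points: duplicated header column(s) in ", path, ": ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
  need <- c("frame_id", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("read_points: ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  for (cc in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad) > 0)
      stop(sprintf("read_points: non-numeric '%s' in %s at row %d ('%s')",
                   cc, path, bad[1], df[[cc]][bad[1]]))
    if (anyNA(v) && nrow(df) > 0)
      stop(sprintf("read_points: missing '%s' value in %s at row %d",
                   cc, path, which(is.na(v))[1]))
    df[[cc]] <- v
  }
  frame <- if (nrow(df) > 0) df$frame_id[1] else "empty"
  ps <- point_set(cbind(df$x, df$y), frame, pixel_size_nm)
  ps$extra <- df[, setdiff(names(df), c("x", "y")), drop = FALSE]
  ps
}

#' @param ps a [point_set()].
#' @rdname read_points
#' @export
write_points <- function(ps, path) {
  stopifnot(inherits(ps, "point_set"))
  df <- data.frame(frame_id = rep(ps$frame_id, nrow(ps$points)),
                   x = ps$points[, 1], y = ps$points[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
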