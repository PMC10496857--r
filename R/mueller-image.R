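#' Mueller-matrix image container
#'
#' An H x W grid of 4x4 real Mueller matrices plus acquisition
#' metadata. The pixel grid is stored as a numeric array of dimension
#' `c(H, W, 4, 4)`; element indexing follows the 1-based m11..m44
#' convention, so `pixels[i, j, r, c]` is element `m<r><c>` at pixel
#' `(i, j)`.
#'
#' @param pixels numeric array of dimension `c(H, W, 4, 4)`.
#' @param wavelength_nm measurement wavelength in nanometres
#'   (default 550, the green transmission band used for thin tissue
#'   sections).
#' @param pixel_size_um physical pixel pitch in micrometres.
#' @param provenance free-text description of where the image came from.
#' @return an object of class `mueller_image`.
#' @export
mueller_image <- function(pixels, wavelength_nm = 550, pixel_size_um = 1,
                          provenance = "") {
  if (!is.array(pixels) || length(dim(pixels)) != 4 ||
      !all(dim(pixels)[3:4] == c(4L, 4L)))
    stop("'pixels' must be an H x W x 4 x 4 array")
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1)
    stop("image must contain at least one pixel")
  if (!all(is.finite(pixels))) {
    bad <- which(apply(pixels, c(1, 2), function(m) any(!is.finite(m))),
                 arr.ind = TRUE)
    stop(sprintf("data error: non-finite Mueller elements at %d pixel(s), first at (%d, %d)",
                 nrow(bad), bad[1, 1], bad[1, 2]))
  }
  if (!is.numeric(wavelength_nm) || wavelength_nm <= 0)
    stop("'wavelength_nm' must be positive")
  structure(list(pixels = pixels,
                 wavelength_nm = wavelength_nm,
                 pixel_size_um = pixel_size_um,
                 provenance = provenance),
            class = "mueller_image")
}

#' @export
print.mueller_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<mueller_image> %d x %d pixels, %g nm, %g um/px\n",
              d[1], d[2], x$wavelength_nm, x$pixel_size_um))
  if (nzchar(x$provenance)) cat(" provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.mueller_image <- function(x) dim(x$pixels)[1:2]

.band_names <- as.vector(t(outer(1:4, 1:4, function(r, c)
  sprintf("m%d%d", r, c))))

#' Write a Mueller image to a 16-band float TIFF
#'
#' One float32 band per Mueller element in row-major order
#' m11, m12, ..., m44; wavelength, pixel size and provenance are stored
#' as JSON in the TIFF ImageDescription.
#'
#' @param img a [mueller_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mueller_image <- function(img, path) {
  stopifnot(inherits(img, "mueller_image"))
  bands <- lapply(seq_len(16), function(k) {
    r <- (k - 1) %/% 4 + 1; c <- (k - 1) %% 4 + 1
    img$pixels[, , r, c]
  })
  meta <- jsonlite::toJSON(list(wavelength_nm = img$wavelength_nm,
                                pixel_size_um = img$pixel_size_um,
                                provenance = img$provenance,
                                bands = .band_names),
                           auto_unbox = TRUE)
  write_float_tiff(bands, path, description = as.character(meta))
  invisible(path)
}

#' Read a Mueller image from a 16-band float TIFF
#'
#' Expects exactly 16 float32 bands in row-major element order
#' m11, m12, ..., m44. Metadata is read from the JSON ImageDescription;
#' files without metadata get the documented defaults (550 nm, 1 um
#' pixels) and a provenance note flagging the assumption.
#'
#' @param path input file path.
#' @param format container dialect; only `"tiff16"` is supported.
#' @return a [mueller_image()].
#' @export
read_mueller_image <- function(path, format = "tiff16") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tf <- read_float_tiff(path)
  if (length(tf$bands) != 16)
    stop(sprintf("format error: expected 16 bands (m11..m44), found %d",
                 length(tf$bands)))
  H <- nrow(tf$bands[[1]]); W <- ncol(tf$bands[[1]])
  px <- array(NA_real_, c(H, W, 4, 4))
  for (k in seq_len(16)) {
    r <- (k - 1) %/% 4 + 1; c <- (k - 1) %% 4 + 1
    px[, , r, c] <- tf$bands[[k]]
  }
  meta <- NULL
  if (!is.null(tf$description))
    meta <- tryCatch(jsonlite::fromJSON(tf$description),
                     error = function(e) NULL)
  if (is.null(meta)) {
    meta <- list(wavelength_nm = 550, pixel_size_um = 1,
                 provenance = sprintf("%s (no metadata; defaults assumed)",
                                      basename(path)))
  }
  mueller_image(px,
                wavelength_nm = meta$wavelength_nm,
                pixel_size_um = meta$pixel_size_um,
                provenance = if (is.null(meta$provenance)) "" else
                  meta$provenance)
}

#' Pixel validity mask
#'
#' Logical validity grid plus a per-pixel reason code for invalid or
#' flagged pixels: `"ok"`, `"non-physical"`, `"decomposition-failed"`,
#' `"below-noise-floor"`, `"no-tissue"`.
#'
#' @param valid logical H x W matrix.
#' @param reason character H x W matrix of reason codes (defaults to
#'   `"ok"` where valid).
#' @return an object of class `pixel_mask`.
#' @export
pixel_mask <- function(valid, reason = NULL) {
  stopifnot(is.matrix(valid), is.logical(valid))
  if (is.null(reason)) {
    reason <- matrix(ifelse(valid, "ok", "non-physical"),
                     nrow(valid), ncol(valid))
  }
  stopifnot(all(dim(reason) == dim(valid)))
  codes <- c("ok", "non-physical", "decomposition-failed",
             "below-noise-floor", "no-tissue")
  if (!all(reason %in% codes))
    stop("unknown mask reason code")
  structure(list(valid = valid, reason = reason), class = "pixel_mask")
}

#' Write derived property maps to disk
#'
#' Writes one float32 TIFF band per named map plus a trailing validity
#' band (1 valid / 0 invalid); invalid pixels are stored as NaN in every
#' property band. A CSV sidecar (same path with extension `.csv`) holds
#' one box-whisker summary row per map over the valid pixels.
#'
#' @param maps named list of numeric H x W matrices.
#' @param mask a [pixel_mask()] (or `NULL` for all-valid).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_maps <- function(maps, mask = NULL, path) {
  stopifnot(is.list(maps), length(maps) >= 1, !is.null(names(maps)))
  H <- nrow(maps[[1]]); W <- ncol(maps[[1]])
  for (m in maps)
    if (!is.matrix(m) || nrow(m) != H || ncol(m) != W)
      stop("all maps must share one shape")
  if (is.null(mask))
    mask <- pixel_mask(matrix(TRUE, H, W))
  if (!all(dim(mask$valid) == c(H, W)))
    stop("mask shape does not match the maps")
  bands <- lapply(maps, function(m) {
    m[!mask$valid] <- NaN
    m
  })
  bands$mask <- matrix(as.numeric(mask$valid), H, W)
  meta <- jsonlite::toJSON(list(bands = names(bands)), auto_unbox = TRUE)
  write_float_tiff(bands, path, description = as.character(meta))
  summaries <- do.call(rbind, lapply(names(maps), function(nm)
    boxwhisker_summary(maps[[nm]], mask, name = nm)))
  utils::write.csv(summaries, paste0(tools::file_path_sans_ext(path), ".csv"),
                   row.names = FALSE)
  invisible(path)
}
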