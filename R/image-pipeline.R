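#' Slit-fluorescence image container
#'
#' A 2-D grayscale frame (integer counts) plus the acquisition metadata the
#' pipeline needs: image-plane pixel pitch, viewing angle, soak time, the
#' slit column if known, and a label distinguishing control, soaked and
#' during-UVA frames.
#'
#' @param pixels Numeric matrix of counts, in `[0, 2^bit - 1]`.
#' @param pixel_pitch µm per pixel in the image plane (> 0).
#' @param view_angle Degrees between the camera axis and the surface normal.
#' @param soak_time Soak time in seconds.
#' @param slit_col Slit column in pixels, or `NA` if unknown.
#' @param label One of `"control"`, `"soaked"`, `"during_uva"`.
#' @return An object of class `slit_image`.
#' @export
slit_image <- function(pixels, pixel_pitch, view_angle = 45,
                       soak_time = NA_real_, slit_col = NA_integer_,
                       label = c("soaked", "control", "during_uva")) {
  label <- match.arg(label)
  stopifnot(is.matrix(pixels), pixel_pitch > 0)
  if (any(pixels < 0)) abort("Pixel counts must be nonnegative.")
  structure(list(
    pixels = pixels,
    meta = list(pixel_pitch = pixel_pitch, view_angle = view_angle,
                soak_time = soak_time, slit_col = slit_col, label = label)
  ), class = "slit_image")
}

#' @export
print.slit_image <- function(x, ...) {
  cat(sprintf("<slit_image> %d x %d px, %.3g um/px, %g deg, t = %g s [%s]\n",
              nrow(x$pixels), ncol(x$pixels), x$meta$pixel_pitch,
              x$meta$view_angle, x$meta$soak_time, x$meta$label))
  invisible(x)
}

#' Subtract the pre-riboflavin baseline frame
#'
#' Control images recorded before riboflavin instillation provide the
#' baseline (autofluorescence) intensities, which are subtracted per pixel
#' from the riboflavin frames. Differences are clipped at zero: negative
#' fluorescence is unphysical and the erf intensity model assumes
#' nonnegative values.
#'
#' @param image,control [slit_image()]s of identical shape and calibration.
#' @return A baseline-subtracted [slit_image()] retaining `image`'s
#'   metadata.
#' @export
subtract_baseline <- function(image, control) {
  stopifnot(inherits(image, "slit_image"), inherits(control, "slit_image"))
  if (!identical(dim(image$pixels), dim(control$pixels))) {
    abort("Image and control frames must have the same shape.",
          class = "ribodosim_shape_mismatch")
  }
  if (!isTRUE(all.equal(image$meta$pixel_pitch, control$meta$pixel_pitch)) ||
      !isTRUE(all.equal(image$meta$view_angle, control$meta$view_angle))) {
    abort("Image and control frames must share calibration metadata.",
          class = "ribodosim_shape_mismatch")
  }
  out <- image
  out$pixels <- pmax(image$pixels - control$pixels, 0)
  out
}

#' Detect the corneal leading edge
#'
#' Locates the fluorescent leading edge (the corneal surface) in each slit
#' column: scanning along the penetration direction (down the column), the
#' first row whose intensity exceeds `threshold_frac` times the column
#' maximum, refined to sub-pixel precision by linear interpolation of the
#' threshold crossing. A valid edge requires a sub-threshold pixel above the
#' crossing, so a uniform image raises a no-signal error.
#'
#' @param image A baseline-subtracted [slit_image()].
#' @param threshold_frac Fraction of the column maximum (default 0.5).
#' @param strip_width Number of columns around the slit to trace (default 1).
#' @return A `surface_trace` tibble with columns `col` and `row`
#'   (fractional), and an `apex` attribute `c(row, col)`.
#' @export
detect_surface <- function(image, threshold_frac = 0.5, strip_width = 1L) {
  stopifnot(inherits(image, "slit_image"))
  cols <- strip_cols(image, strip_width)
  px <- image$pixels
  rows <- vapply(cols, function(c) {
    col <- px[, c]
    m <- max(col)
    if (m <= 0) return(NA_real_)
    level <- threshold_frac * m
    above <- which(col > level)
    if (length(above) == 0L || above[1] == 1L) return(NA_real_) # no edge
    r <- above[1]
    # linear interpolation of the crossing between r-1 and r
    (r - 1) + (level - col[r - 1]) / (col[r] - col[r - 1])
  }, numeric(1))
  if (all(is.na(rows))) {
    abort("No fluorescent edge found in the slit region (no signal above threshold).",
          class = "ribodosim_no_signal")
  }
  out <- tibble(col = cols, row = rows)
  apex_i <- which.min(out$row)
  attr(out, "apex") <- c(row = out$row[apex_i], col = out$col[apex_i])
  class(out) <- c("surface_trace", class(out))
  out
}

# columns of the analysis strip centred on the slit; slit column from
# metadata, else the brightest column (ties broken toward the image centre)
strip_cols <- function(image, strip_width) {
  sc <- image$meta$slit_col
  if (is.na(sc)) {
    sums <- colSums(image$pixels)
    best <- which(sums == max(sums))
    sc <- best[which.min(abs(best - (ncol(image$pixels) + 1) / 2))]
  }
  first <- sc - (strip_width - 1L) %/% 2L
  cols <- first + seq_len(strip_width) - 1L
  if (any(cols < 1L) || any(cols > ncol(image$pixels))) {
    abort("Analysis strip extends outside the image.",
          class = "ribodosim_invalid_config")
  }
  as.integer(cols)
}

#' Extract the depth-intensity profile under the surface
#'
#' Averages intensity across `strip_width` columns centred on the slit and
#' samples it row by row from the detected surface inward. The depth axis is
#' the apparent image-plane distance (pixel index times pixel pitch), not
#' yet corrected for the oblique viewing angle; the first sample sits at
#' depth 0 on the surface row (the first whole row at or below the
#' fractional detected edge).
#'
#' @param image A baseline-subtracted [slit_image()].
#' @param surface A `surface_trace` from [detect_surface()].
#' @param strip_width Averaging width in columns (default 1).
#' @return A [concentration_profile()] with `kind = "intensity"` on the
#'   apparent-depth axis.
#' @export
extract_profile <- function(image, surface, strip_width = 1L) {
  stopifnot(inherits(image, "slit_image"), inherits(surface, "surface_trace"))
  cols <- strip_cols(image, strip_width)
  srow <- surface$row[match(cols, surface$col)]
  srow <- srow[!is.na(srow)]
  if (length(srow) == 0L) abort("Surface trace does not cover the strip.")
  r0 <- ceiling(min(srow) - 1e-6)
  rows <- seq.int(r0, nrow(image$pixels))
  vals <- rowMeans(image$pixels[rows, cols, drop = FALSE])
  concentration_profile((rows - r0) * image$meta$pixel_pitch, vals,
                        time_s = image$meta$soak_time, kind = "intensity")
}

#' Cosine correction of apparent depth
#'
#' The camera views the cornea at `view_angle` degrees to the surface
#' normal, so depth along an image column appears foreshortened by
#' `cos(view_angle)`. The correction divides the apparent depths by that
#' factor (true depth = apparent / cos(angle)) under the convention that the
#' pixel-pitch calibration is an image-plane measurement; intensities are
#' unchanged.
#'
#' @param profile A [concentration_profile()] on the apparent-depth axis.
#' @param view_angle Degrees, strictly between 0 (exclusive at 90) and 90;
#'   0 is accepted and is the identity.
#' @return The profile with `depth_um` rescaled to true corneal depth.
#' @export
cosine_correct <- function(profile, view_angle) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (!(view_angle >= 0 && view_angle < 90)) {
    abort("`view_angle` must lie in [0, 90) degrees.",
          class = "ribodosim_invalid_parameter")
  }
  concentration_profile(profile$depth_um / cospi(view_angle / 180),
                        profile$value,
                        time_s = profile_time(profile),
                        kind = profile_kind(profile))
}

#' Full image-to-profile pipeline
#'
#' Composes baseline subtraction, surface detection, strip extraction, the
#' cosine depth correction, and the semi-infinite fitting-window trim into
#' one call.
#'
#' @param image,control [slit_image()]s (riboflavin frame and pre-riboflavin
#'   control).
#' @param threshold_frac Surface-detection threshold (fraction of column
#'   max).
#' @param strip_width Averaging width in columns.
#' @param trim_frac Fitting-window cut as a fraction of the surface value;
#'   `NULL` to skip trimming.
#' @return A depth-corrected [concentration_profile()].
#' @export
image_to_profile <- function(image, control, threshold_frac = 0.5,
                             strip_width = 1L, trim_frac = 0.02) {
  sub <- subtract_baseline(image, control)
  surf <- detect_surface(sub, threshold_frac = threshold_frac,
                         strip_width = strip_width)
  prof <- extract_profile(sub, surf, strip_width = strip_width)
  prof <- cosine_correct(prof, image$meta$view_angle)
  if (!is.null(trim_frac)) prof <- trim_profile(prof, trim_frac) else prof
}

#' Read and write 8-bit grayscale image frames
#'
#' Frames are stored as 8-bit grayscale PNG or TIFF; a sidecar YAML next to
#' the image carries the acquisition metadata (pixel pitch, view angle,
#' soak time, slit column, label) so a round trip is lossless.
#'
#' @param image A [slit_image()].
#' @param path Image path ending in `.png` or `.tif`/`.tiff`.
#' @return `write_slit_image()` returns `path` invisibly;
#'   `read_slit_image()` returns a [slit_image()].
#' @export
write_slit_image <- function(image, path) {
  stopifnot(inherits(image, "slit_image"))
  arr <- image$pixels / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(arr, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  } else {
    abort("Unsupported image format; use .png or .tif/.tiff.")
  }
  yaml::write_yaml(image$meta, sidecar_path(path))
  invisible(path)
}

#' @rdname write_slit_image
#' @export
read_slit_image <- function(path) {
  arr <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    abort("Unsupported image format; use .png or .tif/.tiff.")
  }
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  meta_path <- sidecar_path(path)
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  slit_image(round(arr * 255),
             pixel_pitch = meta$pixel_pitch %||% 12.2,
             view_angle = meta$view_angle %||% 45,
             soak_time = meta$soak_time %||% NA_real_,
             slit_col = meta$slit_col %||% NA_integer_,
             label = meta$label %||% "soaked")
}

sidecar_path <- function(path) sub("\\.[A-Za-z]+$", ".yaml", path)
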