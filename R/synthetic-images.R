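#' Scene specification for the synthetic slit-image generator
#'
#' Describes the imaging geometry the renderer emulates: a cross-sectional
#' camera viewing the cornea at `view_angle` degrees to the surface normal
#' at the apex, a projected UVA slit one or a few pixels wide, a curved
#' (circular-arc) corneal leading edge, constant autofluorescence baseline,
#' and camera noise (Gaussian read noise, optional Poisson shot noise)
#' applied before 8-bit quantization.
#'
#' Defaults reflect the bench geometry the analysis assumes: 12.2 µm/px
#' image-plane calibration, 45° viewing angle, a one-pixel (~25 µm
#' footprint) slit, and a corneal radius of curvature of 8500 µm. The peak
#' fluorescence signal is kept near 80% of 8-bit saturation by choosing
#' boundary intensities around 190 counts.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param pixel_pitch Image-plane calibration, µm per pixel.
#' @param view_angle Camera angle to the corneal surface normal, degrees in
#'   (0, 90). Depth along a column appears foreshortened by `cos(view_angle)`.
#' @param corneal_radius Arc radius of the corneal leading edge, µm.
#' @param slit_col Column of the projected slit (pixels).
#' @param slit_width Slit width in pixels.
#' @param apex_row Row of the corneal apex at the slit column (pixels).
#' @param baseline_level Autofluorescence baseline, counts.
#' @param gain Counts per concentration unit (fluorescence is linear in
#'   concentration).
#' @param noise List with `gaussian_sd` (counts) and `poisson` (logical).
#' @param bit_depth Bits per pixel; fixes saturation at `2^bit_depth - 1`.
#' @param seed Integer seed; the renderer is a pure function of
#'   (spec, truth, t, seed).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(220, 64), pixel_pitch = 12.2,
                       view_angle = 45, corneal_radius = 8500,
                       slit_col = 32, slit_width = 1, apex_row = 20,
                       baseline_level = 10, gain = 1,
                       noise = list(gaussian_sd = 0, poisson = FALSE),
                       bit_depth = 8, seed = 1L) {
  if (!(pixel_pitch > 0)) {
    abort("`pixel_pitch` must be positive.", class = "ribodosim_invalid_config")
  }
  if (!(view_angle > 0 && view_angle < 90)) {
    abort("`view_angle` must lie strictly between 0 and 90 degrees.",
          class = "ribodosim_invalid_config")
  }
  if (slit_col < 1 || slit_col > image_shape[2]) {
    abort("`slit_col` must lie within the image.",
          class = "ribodosim_invalid_config")
  }
  if (slit_width < 1) {
    abort("`slit_width` must be at least 1 pixel.",
          class = "ribodosim_invalid_config")
  }
  structure(list(
    image_shape = as.integer(image_shape), pixel_pitch = pixel_pitch,
    view_angle = view_angle, corneal_radius = corneal_radius,
    slit_col = as.integer(slit_col), slit_width = as.integer(slit_width),
    apex_row = apex_row, baseline_level = baseline_level, gain = gain,
    noise = noise, bit_depth = as.integer(bit_depth), seed = as.integer(seed)
  ), class = "scene_spec")
}

# circular-arc surface row per column (fractional pixels); NA where the
# column lies outside the corneal arc
surface_rows <- function(spec) {
  cols <- seq_len(spec$image_shape[2])
  dx <- (cols - spec$slit_col) * spec$pixel_pitch
  sag <- ifelse(abs(dx) < spec$corneal_radius,
                spec$corneal_radius - sqrt(spec$corneal_radius^2 - dx^2),
                NA_real_)
  spec$apex_row + sag / spec$pixel_pitch
}

slit_columns <- function(spec) {
  first <- spec$slit_col - (spec$slit_width - 1L) %/% 2L
  cols <- first + seq_len(spec$slit_width) - 1L
  cols[cols >= 1L & cols <= spec$image_shape[2]]
}

#' Render one synthetic slit-fluorescence frame
#'
#' Produces the cross-sectional image the dosimetry camera would record at
#' soak time `t`: pixels in the slit strip, below the arc-shaped corneal
#' surface, carry `baseline + gain * C(depth)` where the apparent in-image
#' distance from the surface equals the true depth times `cos(view_angle)`
#' (the foreshortening the downstream cosine correction undoes). Noise is
#' added before quantization and the result is clipped to the bit depth.
#' `t = 0` yields the baseline-only control frame recorded before
#' riboflavin instillation.
#'
#' @param spec A [scene_spec()].
#' @param truth A [diffusion_params()] or [layered_params()] describing the
#'   true transport; its soak time field is ignored in favour of `t`.
#' @param t Soak time in seconds (`>= 0`); 0 renders the control frame.
#' @param seed Seed for the noise draw; defaults to `spec$seed`.
#' @return A [slit_image()].
#' @export
render_slit_image <- function(spec, truth, t, seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"), t >= 0)
  truth_at <- set_truth_time(truth, max(t, 1))   # placeholder time for t = 0
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  img <- matrix(spec$baseline_level, nrow = nr, ncol = nc)

  if (t > 0) {
    srow <- surface_rows(spec)
    cosf <- cospi(spec$view_angle / 180)
    for (c in slit_columns(spec)) {
      if (is.na(srow[c]) || srow[c] > nr) next
      rows <- seq.int(ceiling(srow[c] - 1e-6), nr)
      depth_true <- pmax(rows - srow[c], 0) * spec$pixel_pitch / cosf
      img[rows, c] <- spec$baseline_level +
        spec$gain * model_value(truth_at, depth_true)
    }
  }

  img <- withr::with_seed(seed, {
    out <- img
    if (isTRUE(spec$noise$poisson)) {
      out <- matrix(rpois(length(out), lambda = pmax(out, 0)),
                    nrow = nr, ncol = nc)
    }
    if ((spec$noise$gaussian_sd %||% 0) > 0) {
      out <- out + rnorm(length(out), sd = spec$noise$gaussian_sd)
    }
    out
  })

  sat <- 2^spec$bit_depth - 1
  img <- pmin(pmax(round(img), 0), sat)
  slit_image(img, pixel_pitch = spec$pixel_pitch, view_angle = spec$view_angle,
             soak_time = t, slit_col = spec$slit_col,
             label = if (t == 0) "control" else "soaked")
}

set_truth_time <- function(truth, t) {
  if (inherits(truth, "layered_params")) {
    layered_params(
      diffusion_params(truth$epi$D, t, truth$epi$C0),
      diffusion_params(truth$stroma$D, t, truth$stroma$C0),
      truth$boundary_depth
    )
  } else {
    diffusion_params(truth$D, t, truth$C0)
  }
}

#' Soak-series specification and renderer
#'
#' A soak series emulates the diffusion experiments: a control frame at
#' `t = 0` followed by one frame per soak time (the bench protocol imaged
#' every 3 minutes out to 21 minutes). Later frames show deeper riboflavin
#' penetration.
#'
#' @param scene A [scene_spec()].
#' @param truth A [diffusion_params()] or [layered_params()].
#' @param times Strictly increasing positive soak times in seconds; default
#'   3-minute steps from 180 s to 1260 s.
#' @return `soak_series_spec()` returns a spec object;
#'   `render_soak_series()` returns a list of [slit_image()] of length
#'   `length(times) + 1` whose first element is the control frame.
#' @export
soak_series_spec <- function(scene, truth, times = seq(180, 1260, by = 180)) {
  if (length(times) == 0L) abort("`times` must be nonempty.")
  if (any(times <= 0) || any(diff(times) <= 0)) {
    abort("`times` must be positive and strictly increasing.")
  }
  structure(list(scene = scene, truth = truth, times = as.numeric(times)),
            class = "soak_series_spec")
}

#' @rdname soak_series_spec
#' @param spec A `soak_series_spec`.
#' @export
render_soak_series <- function(spec) {
  stopifnot(inherits(spec, "soak_series_spec"))
  frames <- lapply(seq_along(spec$times), function(k) {
    render_slit_image(spec$scene, spec$truth, spec$times[k],
                      seed = spec$scene$seed + k)
  })
  c(list(render_slit_image(spec$scene, spec$truth, 0, seed = spec$scene$seed)),
    frames)
}

#' Render a riboflavin-consumption series (UVA photobleaching)
#'
#' Emulates the consumption experiment: a presoaked cornea is irradiated in
#' dose increments and imaged at each checkpoint while diffusion continues
#' between frames. Frame `k` scales the fluorescent concentration by
#' `exp(-bleach_rate_per_J * dose_k)` -- first-order photobleaching in
#' delivered dose, uniform over depth by default. A parallel control series
#' (zero bleach rate, same seeds) is produced, mirroring the unirradiated
#' control eyes.
#'
#' @param spec A [soak_series_spec()]; `spec$times` gives the elapsed time
#'   of each checkpoint relative to the first (aligned with `doses`, so
#'   `times[1]` corresponds to `doses[1] = 0`), and the truth's soak time
#'   field gives the presoak time at the first checkpoint.
#' @param bleach_rate_per_J Bleach rate per J/cm^2 (`>= 0`).
#' @param doses Nondecreasing cumulative doses in J/cm^2 starting at 0, one
#'   per checkpoint.
#' @return A list with elements `treated` and `control`, each a list of
#'   [slit_image()] (the control frame at `t = 0` is not included; the
#'   first checkpoint is the baseline-soaked, zero-dose frame).
#' @export
render_consumption_series <- function(spec, bleach_rate_per_J, doses) {
  stopifnot(inherits(spec, "soak_series_spec"))
  if (bleach_rate_per_J < 0) {
    abort("`bleach_rate_per_J` must be nonnegative.",
          class = "ribodosim_invalid_parameter")
  }
  if (length(doses) != length(spec$times)) {
    abort("`doses` must align with `spec$times` (one dose per checkpoint).")
  }
  if (doses[1] != 0 || any(diff(doses) < 0)) {
    abort("`doses` must be nondecreasing and start at 0.")
  }
  presoak <- if (inherits(spec$truth, "layered_params")) {
    spec$truth$epi$t
  } else {
    spec$truth$t
  }
  elapsed <- spec$times - spec$times[1]
  render_one <- function(rate) {
    lapply(seq_along(doses), function(k) {
      truth_k <- scale_truth(spec$truth, exp(-rate * doses[k]))
      img <- render_slit_image(spec$scene, truth_k, presoak + elapsed[k],
                               seed = spec$scene$seed + k)
      img$meta$label <- "during_uva"
      img
    })
  }
  list(treated = render_one(bleach_rate_per_J), control = render_one(0))
}

scale_truth <- function(truth, factor) {
  if (inherits(truth, "layered_params")) {
    layered_params(
      diffusion_params(truth$epi$D, truth$epi$t, truth$epi$C0 * factor),
      diffusion_params(truth$stroma$D, truth$stroma$t, truth$stroma$C0 * factor),
      truth$boundary_depth
    )
  } else {
    diffusion_params(truth$D, truth$t, truth$C0 * factor)
  }
}
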