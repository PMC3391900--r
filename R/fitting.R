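#' Fit the single-layer erf model to a depth-intensity profile
#'
#' Nonlinear least squares of `I(x) = I0 * (1 - erf(x / (2 sqrt(D t))))`
#' with the soak time `t` fixed at the recorded value (D and t are not
#' jointly identifiable from a single profile). Levenberg-Marquardt with a
#' positivity bound on `D`; starting values are deterministic: `I0` from the
#' surface sample and `D` from the half-intensity depth `x_half` via
#' `D_init = (x_half / (2 erfinv(0.5)))^2 / t`.
#'
#' Non-converged fits are returned with `converged = FALSE`, never silently
#' dropped.
#'
#' @param profile A depth-corrected [concentration_profile()] with at least
#'   5 samples and a known positive soak time (override with `t`).
#' @param t Soak time in seconds; defaults to the profile's `time_s`.
#' @return A `diffusion_fit` object; see [tidy.diffusion_fit()] and
#'   [glance.diffusion_fit()].
#' @examples
#' p <- erf_profile(diffusion_params(3.3e-7, 1080, 180), seq(0, 600, 17))
#' fit <- fit_single_layer(
#'   concentration_profile(p$depth_um, p$value, time_s = 1080)
#' )
#' glance(fit)
#' @export
fit_single_layer <- function(profile, t = profile_time(profile)) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (!is.finite(t) || t <= 0) {
    abort("Soak time `t` must be known and positive to fit.",
          class = "ribodosim_missing_time")
  }
  if (nrow(profile) < 5L) {
    abort("At least 5 profile samples are required.",
          class = "ribodosim_too_few_points")
  }
  if (sd(profile$value) == 0) {
    abort("Profile is flat; (I0, D) are not identifiable.",
          class = "ribodosim_not_identifiable")
  }

  x <- profile$depth_um
  y <- profile$value
  I0_init <- max(y[1], max(y) * 0.5, 1e-8)
  D_init <- init_D(x, y, I0_init, t)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ I0 * (1 - erf((x / UM_PER_CM) / (2 * sqrt(D * t)))),
      start = list(I0 = I0_init, D = D_init),
      lower = c(I0 = 0, D = 1e-14),
      data = list(x = x, y = y, t = t),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )

  if (inherits(fit, "error")) {
    return(new_diffusion_fit(I0_hat = NA_real_, D_hat = NA_real_,
                             D_se = NA_real_, residual_rms = NA_real_,
                             n_points = nrow(profile), converged = FALSE,
                             soak_time = t, message = conditionMessage(fit)))
  }

  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  conv <- isTRUE(fit$convInfo$isConv) && est[["D"]] > 1e-13
  new_diffusion_fit(
    I0_hat = est[["I0"]], D_hat = est[["D"]],
    D_se = unname(se[2]),
    residual_rms = sqrt(mean(stats::resid(fit)^2)),
    n_points = nrow(profile), converged = conv, soak_time = t,
    model = fit
  )
}

# deterministic D start from the half-intensity crossing depth
init_D <- function(x, y, I0, t) {
  half <- I0 / 2
  below <- which(y < half)
  x_half <- if (length(below) && below[1] > 1L) {
    i <- below[1]
    x[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
  } else {
    max(x) / 2
  }
  max(((x_half / UM_PER_CM) / (2 * erfinv(0.5)))^2 / t, 1e-12)
}

new_diffusion_fit <- function(I0_hat, D_hat, D_se, residual_rms, n_points,
                              converged, soak_time, model = NULL,
                              message = NULL) {
  structure(list(I0_hat = I0_hat, D_hat = D_hat, D_se = D_se,
                 residual_rms = residual_rms, n_points = n_points,
                 converged = converged, soak_time = soak_time,
                 model = model, message = message),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g +/- %.2g cm^2/s, I0 = %.4g, t = %g s, %s (n = %d, rms = %.3g)\n",
              x$D_hat, x$D_se, x$I0_hat, x$soak_time,
              if (x$converged) "converged" else "NOT converged",
              x$n_points, x$residual_rms))
  invisible(x)
}

#' Broom-style accessors for diffusion fits
#'
#' `tidy()` returns one row per parameter with estimates and standard
#' errors; `glance()` returns a one-row model summary.
#'
#' @param x A `diffusion_fit` or `layered_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.diffusion_fit <- function(x, ...) {
  se <- if (!is.null(x$model)) {
    tryCatch(sqrt(diag(vcov(x$model))), error = function(e) c(NA_real_, NA_real_))
  } else {
    c(NA_real_, x$D_se)
  }
  tibble(term = c("I0", "D"),
         estimate = c(x$I0_hat, x$D_hat),
         std.error = unname(se))
}

#' @rdname tidy.diffusion_fit
#' @exportS3Method generics::glance
glance.diffusion_fit <- function(x, ...) {
  tibble(I0_hat = x$I0_hat, D_hat = x$D_hat, D_se = x$D_se,
         residual_rms = x$residual_rms, n_points = x$n_points,
         converged = x$converged, soak_time = x$soak_time)
}

#' Plot a diffusion fit over its data
#'
#' @param object A `diffusion_fit` carrying its model.
#' @param profile The fitted [concentration_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.diffusion_fit <- function(object, profile, ...) {
  stopifnot(inherits(profile, "concentration_profile"))
  grid <- seq(min(profile$depth_um), max(profile$depth_um), length.out = 200)
  curve <- tibble(
    depth_um = grid,
    value = erf_value(grid, object$I0_hat, object$D_hat, object$soak_time)
  )
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$depth_um, y = .data$value)) +
    ggplot2::geom_point(colour = "steelblue", size = 0.9) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(x = "Depth (µm)", y = "Intensity (counts)",
                  subtitle = sprintf("D = %.3g cm²/s, t = %g s",
                                     object$D_hat, object$soak_time)) +
    ggplot2::theme_minimal()
}

#' Biphasic (epithelium/stroma) fit
#'
#' Fits the profile in two independent parts: the epithelial segment from
#' the surface to `boundary_depth` with depth origin 0, and the stromal
#' segment beyond the boundary with the depth origin reset to the top of
#' the stroma. Each segment gets its own boundary intensity and diffusion
#' coefficient; the two fits share only the soak time. The boundary depth
#' is a configuration input (default 75 µm epithelial thickness), not
#' estimated from data.
#'
#' @param profile A depth-corrected [concentration_profile()] spanning both
#'   sides of the boundary with at least 5 samples on each.
#' @param boundary_depth Epithelial thickness in µm (default 75).
#' @param t Soak time in seconds; defaults to the profile's `time_s`.
#' @return A `layered_fit` with elements `epi`, `stroma` (both
#'   `diffusion_fit`) and `boundary_depth`.
#' @export
fit_two_layer <- function(profile, boundary_depth = 75,
                          t = profile_time(profile)) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (boundary_depth <= 0) {
    abort("`boundary_depth` must be positive.",
          class = "ribodosim_invalid_parameter")
  }
  in_epi <- profile$depth_um <= boundary_depth
  if (sum(in_epi) < 5L) {
    abort(sprintf("Epithelial segment has %d samples; at least 5 required.",
                  sum(in_epi)), class = "ribodosim_segment_epi")
  }
  if (sum(!in_epi) < 5L) {
    abort(sprintf("Stromal segment has %d samples; at least 5 required.",
                  sum(!in_epi)), class = "ribodosim_segment_stroma")
  }
  epi_prof <- concentration_profile(profile$depth_um[in_epi],
                                    profile$value[in_epi],
                                    time_s = t, kind = profile_kind(profile))
  sd_depth <- profile$depth_um[!in_epi] - boundary_depth
  stroma_prof <- concentration_profile(sd_depth, profile$value[!in_epi],
                                       time_s = t, kind = profile_kind(profile))
  structure(list(epi = fit_single_layer(epi_prof, t = t),
                 stroma = fit_single_layer(stroma_prof, t = t),
                 boundary_depth = boundary_depth),
            class = "layered_fit")
}

#' @export
print.layered_fit <- function(x, ...) {
  cat(sprintf("<layered_fit> boundary at %g um\n", x$boundary_depth))
  cat("  epithelium: "); print(x$epi)
  cat("  stroma:     "); print(x$stroma)
  invisible(x)
}

#' @rdname tidy.diffusion_fit
#' @exportS3Method generics::tidy
tidy.layered_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$epi), layer = "epithelium", .before = 1),
    dplyr::mutate(tidy(x$stroma), layer = "stroma", .before = 1)
  )
}

#' @rdname tidy.diffusion_fit
#' @exportS3Method generics::glance
glance.layered_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$epi), layer = "epithelium", .before = 1),
    dplyr::mutate(glance(x$stroma), layer = "stroma", .before = 1)
  ) |>
    dplyr::mutate(boundary_depth_um = x$boundary_depth)
}

#' Aggregate diffusion coefficients across fits
#'
#' Unweighted mean and sample standard deviation of `D_hat` over the
#' converged fits whose soak times fall inside `time_window` (the bench
#' analysis averaged all images from 6 through 21 minutes across eyes).
#' Non-converged fits are excluded and counted.
#'
#' @param fits A list of `diffusion_fit` objects (or a `layered_fit`'s
#'   layer extracted by the caller).
#' @param time_window Length-2 numeric `c(min_s, max_s)`; fits with soak
#'   time inside the closed window are eligible. Default `c(360, 1260)`
#'   (6 to 21 minutes).
#' @return A one-row tibble: `D_mean`, `D_sd`, `n_fits`, `n_excluded`,
#'   `time_min_s`, `time_max_s`.
#' @export
aggregate_fits <- function(fits, time_window = c(360, 1260)) {
  stopifnot(is.list(fits), length(time_window) == 2L)
  if (inherits(fits, "diffusion_fit")) fits <- list(fits)
  g <- purrr::map_dfr(fits, glance)
  in_win <- g$soak_time >= time_window[1] & g$soak_time <= time_window[2]
  ok <- in_win & g$converged
  if (!any(ok)) {
    abort("No converged fits inside the time window.",
          class = "ribodosim_no_eligible_fits")
  }
  d <- g$D_hat[ok]
  tibble(D_mean = mean(d),
         D_sd = if (length(d) > 1L) sd(d) else 0,
         n_fits = length(d),
         n_excluded = sum(in_win & !g$converged),
         time_min_s = min(g$soak_time[ok]),
         time_max_s = max(g$soak_time[ok]))
}

#' Serialize fits to a flat CSV
#'
#' One row per fitted segment: `eye_id`, `soak_time_s`, `layer`, `I0`,
#' `D_cm2_s`, `D_se`, `rms`, `converged`.
#'
#' @param fits Named list of `diffusion_fit` / `layered_fit` objects; names
#'   are used as `eye_id`.
#' @param path Output CSV path, or `NULL` to just return the tibble.
#' @return The flat tibble, invisibly if written.
#' @export
fits_to_table <- function(fits, path = NULL) {
  rows <- purrr::imap_dfr(fits, function(f, id) {
    if (inherits(f, "layered_fit")) {
      g <- glance(f)
      tibble(eye_id = id, soak_time_s = g$soak_time, layer = g$layer,
             I0 = g$I0_hat, D_cm2_s = g$D_hat, D_se = g$D_se,
             rms = g$residual_rms, converged = g$converged)
    } else {
      g <- glance(f)
      tibble(eye_id = id, soak_time_s = g$soak_time, layer = "single",
             I0 = g$I0_hat, D_cm2_s = g$D_hat, D_se = g$D_se,
             rms = g$residual_rms, converged = g$converged)
    }
  })
  if (!is.null(path)) {
    utils::write.csv(rows, path, row.names = FALSE)
    return(invisible(rows))
  }
  rows
}
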