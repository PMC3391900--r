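#' Franz-cell cumulative-permeation series
#'
#' A Franz diffusion cell clamps an excised membrane (here a ~100 µm
#' corneal flap) between a riboflavin donor compartment and a saline
#' receiver; the cumulative amount `Q(t)` appearing in the receiver is
#' assayed over time. The container couples the measured series to the cell
#' geometry the flux analysis needs.
#'
#' @param time_s Increasing sampling times, seconds.
#' @param Q_ug Cumulative permeated amount, µg (nondecreasing within
#'   noise).
#' @param thickness_um Membrane thickness, µm (default 100).
#' @param area_cm2 Exposed membrane area, cm^2.
#' @param donor_conc Donor concentration, µg/mL (= µg/cm^3).
#' @param receiver_volume_mL Receiver volume, mL.
#' @param temperature_C Bath temperature, °C (default 37).
#' @return A tibble of class `franz_series` with the geometry in
#'   attributes.
#' @export
franz_series <- function(time_s, Q_ug, thickness_um = 100, area_cm2 = 1,
                         donor_conc = 1000, receiver_volume_mL = 5,
                         temperature_C = 37) {
  if (any(diff(time_s) <= 0)) abort("`time_s` must be strictly increasing.")
  if (length(time_s) != length(Q_ug)) abort("Lengths must match.")
  if (thickness_um <= 0 || area_cm2 <= 0 || donor_conc <= 0 ||
      receiver_volume_mL <= 0) {
    abort("Cell geometry must be positive.", class = "ribodosim_invalid_parameter")
  }
  out <- tibble(time_s = as.numeric(time_s), Q_ug = as.numeric(Q_ug))
  attr(out, "geometry") <- list(thickness_um = thickness_um,
                                area_cm2 = area_cm2, donor_conc = donor_conc,
                                receiver_volume_mL = receiver_volume_mL,
                                temperature_C = temperature_C)
  class(out) <- c("franz_series", class(out))
  out
}

franz_geometry <- function(series) attr(series, "geometry")

#' Specification and generator for synthetic Franz-cell series
#'
#' `render_franz_series()` evaluates the classical membrane-permeation
#' solution under sink conditions,
#' `Q(t) = A h C ( D t / h^2 - 1/6 - (2/pi^2) sum_n ((-1)^n / n^2)
#' exp(-D n^2 pi^2 t / h^2) )`,
#' which approaches the steady-state asymptote
#' `Q(t) -> A (D C / h) (t - h^2 / (6 D))` beyond the lag time
#' `h^2 / (6 D)`. Optional Gaussian noise on the cumulative amounts
#' emulates assay error. If every sampling time falls inside the lag
#' regime the returned series carries attribute `lag_only = TRUE`, with a
#' warning.
#'
#' @param D_true True membrane diffusivity, cm^2/s.
#' @param times Increasing sampling times, s; should extend past the lag
#'   time so a steady-state window exists.
#' @param thickness_um,area_cm2,donor_conc,receiver_volume_mL Cell
#'   geometry; see [franz_series()].
#' @param noise_sd Gaussian noise SD on `Q` (µg); 0 for noise-free.
#' @param seed Integer seed for the noise draw.
#' @return A [franz_series()].
#' @examples
#' s <- render_franz_series(3.8e-7, times = seq(0, 3600, by = 180))
#' @export
render_franz_series <- function(D_true, times = seq(0, 3600, by = 180),
                                thickness_um = 100, area_cm2 = 1,
                                donor_conc = 1000, receiver_volume_mL = 5,
                                noise_sd = 0, seed = 1L) {
  stopifnot(D_true > 0)
  h_cm <- thickness_um / UM_PER_CM
  tau <- D_true * times / h_cm^2
  n <- 1:60
  series_sum <- vapply(tau, function(tt) {
    sum(((-1)^n / n^2) * exp(-(n^2) * pi^2 * tt))
  }, numeric(1))
  Q <- area_cm2 * h_cm * donor_conc * (tau - 1/6 - (2 / pi^2) * series_sum)
  Q <- pmax(Q, 0)
  if (noise_sd > 0) {
    Q <- withr::with_seed(seed, pmax(Q + rnorm(length(Q), sd = noise_sd), 0))
    Q[times == 0] <- 0
  }
  out <- franz_series(times, Q, thickness_um = thickness_um,
                      area_cm2 = area_cm2, donor_conc = donor_conc,
                      receiver_volume_mL = receiver_volume_mL)
  lag <- h_cm^2 / (6 * D_true)
  if (all(times <= lag)) {
    warn("All sampling times fall inside the diffusion lag regime.")
    attr(out, "lag_only") <- TRUE
  }
  out
}

#' Steady-state flux from a permeation series
#'
#' Linear regression of `Q` on `t` over the late-time window (default the
#' last 50% of samples), normalised by the exposed area:
#' `J = slope / A` in µg cm^-2 s^-1. A rough diffusivity from the
#' full-series slope supplies a lag-time guard: the window must hold at
#' least 4 samples past `h^2 / (6 D_rough)`. A net-decreasing series is
#' rejected; a constant one legitimately yields zero flux.
#'
#' @param series A [franz_series()].
#' @param window Fraction of late samples to regress over (default 0.5).
#' @return A one-row tibble: `J_ug_cm2_s`, `J_se`, `window_n`,
#'   `window_start_s`.
#' @export
steady_state_flux <- function(series, window = 0.5) {
  stopifnot(inherits(series, "franz_series"))
  geo <- franz_geometry(series)
  n <- nrow(series)
  if (n < 4L) abort("Series too short.", class = "ribodosim_series_too_short")
  if (series$Q_ug[n] < series$Q_ug[1]) {
    abort("Cumulative amount decreases over the series.",
          class = "ribodosim_nonmonotone_series")
  }

  keep <- seq.int(n - ceiling(window * n) + 1L, n)
  # a flat series carries zero flux; skip the lag guard (no transport to lag)
  if (stats::var(series$Q_ug) == 0) {
    return(tibble(J_ug_cm2_s = 0, J_se = 0, window_n = length(keep),
                  window_start_s = series$time_s[keep[1]]))
  }
  # lag-time guard from a rough full-series diffusivity
  full_slope <- unname(coef(lm(Q_ug ~ time_s, data = series))[2])
  if (full_slope > 0) {
    D_rough <- full_slope / geo$area_cm2 * (geo$thickness_um / UM_PER_CM) /
      geo$donor_conc
    lag <- (geo$thickness_um / UM_PER_CM)^2 / (6 * D_rough)
    past <- keep[series$time_s[keep] > lag]
    if (length(past) < 4L) {
      abort("Fewer than 4 window samples lie past the diffusion lag time.",
            class = "ribodosim_window_in_lag")
    }
    keep <- past
  }

  fit <- lm(Q_ug ~ time_s, data = series[keep, ])
  slope <- unname(coef(fit)[2])
  # suppress the "essentially perfect fit" note noise-free series trigger
  se <- tryCatch(suppressWarnings(unname(sqrt(diag(vcov(fit)))[2])),
                 error = function(e) NA_real_)
  tibble(J_ug_cm2_s = slope / geo$area_cm2,
         J_se = se / geo$area_cm2,
         window_n = length(keep),
         window_start_s = series$time_s[keep[1]])
}

#' Membrane diffusivity via Fick's first law
#'
#' Under sink conditions the steady-state flux across a membrane of
#' thickness `h` with donor concentration `C` is `J = D C / h`, so
#' `D = J h / C` (with `h` converted µm to cm). The receiver concentration
#' is neglected in the driving gradient.
#'
#' @param J Steady-state flux, µg cm^-2 s^-1 (scalar or the tibble from
#'   [steady_state_flux()]).
#' @param thickness_um Membrane thickness, µm.
#' @param donor_conc Donor concentration, µg/mL.
#' @return Diffusivity in cm^2/s.
#' @examples
#' diffusivity_ficks_first(3.8e-5, thickness_um = 100, donor_conc = 1000)
#' @export
diffusivity_ficks_first <- function(J, thickness_um, donor_conc) {
  if (is.data.frame(J)) J <- J$J_ug_cm2_s
  if (donor_conc <= 0) {
    abort("`donor_conc` must be positive.", class = "ribodosim_invalid_parameter")
  }
  J * (thickness_um / UM_PER_CM) / donor_conc
}

#' End-to-end Franz-cell analysis
#'
#' Convenience wrapper: steady-state flux then Fick's-first-law
#' diffusivity, using the geometry carried by the series.
#'
#' @param series A [franz_series()].
#' @param window Late-sample fraction for the flux regression.
#' @return A one-row tibble with the flux columns plus `D_cm2_s`.
#' @export
analyze_franz <- function(series, window = 0.5) {
  geo <- franz_geometry(series)
  flux <- steady_state_flux(series, window = window)
  dplyr::mutate(flux, D_cm2_s = diffusivity_ficks_first(
    .data$J_ug_cm2_s, geo$thickness_um, geo$donor_conc))
}

#' Write / read Franz series as CSV plus YAML geometry
#'
#' The CSV holds `time_s, Q_ug`; the sidecar YAML holds the cell geometry.
#'
#' @param series A [franz_series()].
#' @param path CSV path; geometry goes to the `.yaml` sidecar.
#' @return `write_franz_csv()` returns `path` invisibly; `read_franz_csv()`
#'   returns a [franz_series()].
#' @export
write_franz_csv <- function(series, path) {
  stopifnot(inherits(series, "franz_series"))
  utils::write.csv(as.data.frame(series[c("time_s", "Q_ug")]), path,
                   row.names = FALSE)
  yaml::write_yaml(franz_geometry(series), sidecar_path(path))
  invisible(path)
}

#' @rdname write_franz_csv
#' @export
read_franz_csv <- function(path) {
  body <- utils::read.csv(path)
  geo <- yaml::read_yaml(sidecar_path(path))
  franz_series(body$time_s, body$Q_ug,
               thickness_um = geo$thickness_um, area_cm2 = geo$area_cm2,
               donor_conc = geo$donor_conc,
               receiver_volume_mL = geo$receiver_volume_mL,
               temperature_C = geo$temperature_C %||% 37)
}

#' Plot a Franz-cell permeation series with its steady-state fit
#'
#' @param object A [franz_series()].
#' @param window Late-sample fraction passed to [steady_state_flux()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.franz_series <- function(object, window = 0.5, ...) {
  flux <- tryCatch(steady_state_flux(object, window), error = function(e) NULL)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$Q_ug)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(x = "Time (s)", y = "Cumulative permeated amount (µg)") +
    ggplot2::theme_minimal()
  if (!is.null(flux)) {
    late <- object[object$time_s >= flux$window_start_s, ]
    fit <- lm(Q_ug ~ time_s, data = late)
    p <- p + ggplot2::geom_line(
      data = tibble(time_s = late$time_s,
                    Q_ug = stats::predict(fit)),
      colour = "firebrick"
    )
  }
  p
}
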