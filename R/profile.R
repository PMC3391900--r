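#' Depth-resolved concentration/intensity profiles
#'
#' A concentration profile is a tibble with columns `depth_um` (strictly
#' increasing, nonnegative) and `value` (finite), plus attributes `time_s`
#' (the soak time the profile was observed at) and `kind` (either
#' `"concentration"` or `"intensity"`). All model, pipeline and fitting
#' functions consume and produce this shape, so results chain with the pipe.
#'
#' @param depth_um Numeric vector of depths in micrometres, strictly
#'   increasing, all nonnegative.
#' @param value Numeric vector of the same length; concentration (arbitrary
#'   units) or fluorescence intensity (detector counts).
#' @param time_s Soak time in seconds the profile corresponds to.
#' @param kind `"concentration"` or `"intensity"`.
#' @return A tibble of class `concentration_profile`.
#' @examples
#' concentration_profile(c(0, 10, 20), c(5, 3, 1), time_s = 60)
#' @export
concentration_profile <- function(depth_um, value, time_s = NA_real_,
                                  kind = c("intensity", "concentration")) {
  kind <- match.arg(kind)
  depth_um <- as.numeric(depth_um)
  value <- as.numeric(value)
  if (length(depth_um) != length(value)) {
    abort("`depth_um` and `value` must have the same length.")
  }
  if (length(depth_um) && (any(depth_um < 0) || any(diff(depth_um) <= 0))) {
    abort("`depth_um` must be nonnegative and strictly increasing.")
  }
  if (any(!is.finite(value))) {
    abort("`value` must be finite.")
  }
  out <- tibble(depth_um = depth_um, value = value)
  attr(out, "time_s") <- as.numeric(time_s)
  attr(out, "kind") <- kind
  class(out) <- c("concentration_profile", class(out))
  out
}

#' @rdname concentration_profile
#' @param profile A `concentration_profile`.
#' @export
profile_time <- function(profile) attr(profile, "time_s")

#' @rdname concentration_profile
#' @export
profile_kind <- function(profile) attr(profile, "kind")

#' Restrict a profile to its semi-infinite fitting window
#'
#' Keeps samples from the surface down to the first depth at which the
#' intensity falls below `frac` of the surface value (default 2%). Fitting
#' only over this anterior window keeps the data inside the regime where
#' the semi-infinite erf solution applies and avoids the posterior corneal
#' boundary, which the model does not represent.
#'
#' @param profile A [concentration_profile()].
#' @param frac Fraction of the surface (first-sample) value below which
#'   samples are dropped. Default 0.02.
#' @return The trimmed `concentration_profile`.
#' @export
trim_profile <- function(profile, frac = 0.02) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (nrow(profile) == 0L) return(profile)
  cutoff <- frac * profile$value[1]
  below <- which(profile$value < cutoff)
  last <- if (length(below)) below[1] - 1L else nrow(profile)
  concentration_profile(profile$depth_um[seq_len(last)],
                        profile$value[seq_len(last)],
                        time_s = profile_time(profile),
                        kind = profile_kind(profile))
}

#' Write / read a profile as two-column CSV
#'
#' The CSV carries columns `depth_um` and `value`; header comment lines
#' (prefixed `#`) record the soak time and the kind so a round trip is
#' lossless.
#'
#' @param profile A [concentration_profile()].
#' @param path File path.
#' @return `write_profile_csv()` returns `path` invisibly;
#'   `read_profile_csv()` returns a `concentration_profile`.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "concentration_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# time_s: %.10g", profile_time(profile)),
    sprintf("# kind: %s", profile_kind(profile)),
    "depth_um,value"
  ), con)
  writeLines(sprintf("%.10g,%.10g", profile$depth_um, profile$value), con)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  time_s <- as.numeric(sub("^# time_s:\\s*", "", grep("time_s", meta, value = TRUE)[1]))
  kind <- sub("^# kind:\\s*", "", grep("kind", meta, value = TRUE)[1])
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  concentration_profile(body$depth_um, body$value, time_s = time_s,
                        kind = if (is.na(kind)) "intensity" else kind)
}

#' Plot a concentration profile
#'
#' @param object A [concentration_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.concentration_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_um, y = .data$value)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(
      x = "Depth (µm)",
      y = if (identical(profile_kind(object), "intensity")) {
        "Fluorescence intensity (counts)"
      } else {
        "Concentration (a.u.)"
      },
      subtitle = if (is.finite(profile_time(object))) {
        sprintf("soak time %g s", profile_time(object))
      } else NULL
    ) +
    ggplot2::theme_minimal()
}
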