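#' Diffusion model parameters
#'
#' Bundle of the three quantities the semi-infinite erf solution of Fick's
#' second law depends on: the diffusion coefficient `D`, the elapsed soak
#' time `t`, and the boundary value `C0` (a concentration in arbitrary
#' units, or a boundary fluorescence intensity in detector counts --
#' fluorescence is linear in concentration over the working range, so the
#' two are interchangeable up to a gain factor).
#'
#' @param D Diffusion coefficient in cm^2/s; must be positive. Stromal
#'   riboflavin diffusivities are of order 3e-7 cm^2/s, epithelial ones of
#'   order 5e-8 cm^2/s.
#' @param t Elapsed soak time in seconds; must be positive.
#' @param C0 Boundary concentration or boundary intensity; must be
#'   nonnegative.
#' @return An object of class `diffusion_params`.
#' @examples
#' diffusion_params(D = 3.3e-7, t = 18 * 60, C0 = 190)
#' @export
diffusion_params <- function(D, t, C0 = 1) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0) {
    abort("`D` must be a single positive number (cm^2/s).",
          class = "ribodosim_invalid_parameter")
  }
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0) {
    abort("`t` must be a single positive number (seconds).",
          class = "ribodosim_invalid_parameter")
  }
  if (!is.numeric(C0) || length(C0) != 1L || !is.finite(C0) || C0 < 0) {
    abort("`C0` must be a single nonnegative number.",
          class = "ribodosim_invalid_parameter")
  }
  structure(list(D = D, t = t, C0 = C0), class = "diffusion_params")
}

#' Two-layer (epithelium/stroma) model parameters
#'
#' The biphasic transport model treats the epithelium (0 to `boundary_depth`)
#' and the stroma (beyond `boundary_depth`) as independent semi-infinite
#' media, each with its own boundary value and diffusion coefficient. The
#' stromal segment's depth origin is reset at the layer boundary, so its
#' boundary value is the intensity at the top of the stroma. The two
#' segments share only the soak time; no flux-continuity constraint links
#' them.
#'
#' @param epi,stroma [diffusion_params()] for each layer. Both must carry
#'   the same soak time `t`.
#' @param boundary_depth Epithelial thickness in micrometres (> 0);
#'   default 75.
#' @return An object of class `layered_params`.
#' @examples
#' layered_params(
#'   epi    = diffusion_params(D = 4.7e-8, t = 1080, C0 = 190),
#'   stroma = diffusion_params(D = 4.6e-7, t = 1080, C0 = 90)
#' )
#' @export
layered_params <- function(epi, stroma, boundary_depth = 75) {
  stopifnot(inherits(epi, "diffusion_params"), inherits(stroma, "diffusion_params"))
  if (!is.numeric(boundary_depth) || length(boundary_depth) != 1L ||
      !is.finite(boundary_depth) || boundary_depth <= 0) {
    abort("`boundary_depth` must be a single positive number (micrometres).",
          class = "ribodosim_invalid_parameter")
  }
  if (!isTRUE(all.equal(epi$t, stroma$t))) {
    abort("Both layers must share the same soak time `t`.",
          class = "ribodosim_invalid_parameter")
  }
  structure(list(epi = epi, stroma = stroma, boundary_depth = boundary_depth),
            class = "layered_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf("<diffusion_params> D = %.4g cm^2/s, t = %g s, C0 = %g\n",
              x$D, x$t, x$C0))
  invisible(x)
}

#' @export
print.layered_params <- function(x, ...) {
  cat(sprintf("<layered_params> boundary at %g um\n", x$boundary_depth))
  cat(sprintf("  epithelium: D1 = %.4g cm^2/s, C1 = %g\n", x$epi$D, x$epi$C0))
  cat(sprintf("  stroma:     D2 = %.4g cm^2/s, C2 = %g\n", x$stroma$D, x$stroma$C0))
  invisible(x)
}
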