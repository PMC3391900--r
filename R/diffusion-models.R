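#' Semi-infinite erf concentration profile
#'
#' Evaluates the constant-boundary, semi-infinite solution of Fick's second
#' law, `C(x, t) = C0 * (1 - erf(x / (2 * sqrt(D * t))))`, at the requested
#' depths. Because fluorescence is linear in riboflavin concentration, the
#' same expression with `C0 -> I0` models a depth-intensity profile.
#'
#' Depths are given in micrometres while `D` is in cm^2/s; the micrometre to
#' centimetre conversion is applied internally.
#'
#' @param params A [diffusion_params()].
#' @param depths Numeric vector of nonnegative depths in micrometres.
#' @return A [concentration_profile()] evaluated at `depths`, nonincreasing
#'   in depth, with `value = C0` exactly at `x = 0`.
#' @examples
#' p <- diffusion_params(D = 3.3e-7, t = 1080, C0 = 100)
#' erf_profile(p, seq(0, 600, by = 25))
#' @export
erf_profile <- function(params, depths) {
  stopifnot(inherits(params, "diffusion_params"))
  if (any(depths < 0)) abort("`depths` must be nonnegative (micrometres).")
  concentration_profile(
    depths,
    erf_value(depths, params$C0, params$D, params$t),
    time_s = params$t,
    kind = "concentration"
  )
}

# scalar core shared by the renderer and the fitters
erf_value <- function(depth_um, C0, D, t) {
  x_cm <- depth_um / UM_PER_CM
  C0 * (1 - erf(x_cm / (2 * sqrt(D * t))))
}

#' Biphasic (epithelium/stroma) concentration profile
#'
#' Piecewise erf profile for a two-layer cornea: for depths up to
#' `boundary_depth` the epithelial parameters apply with depth origin at the
#' surface; beyond it the stromal parameters apply with the depth origin
#' reset to the top of the stroma. The two segments are independent -- no
#' continuity of value or flux is imposed, matching a two-part fit with
#' separate boundary intensities for each layer.
#'
#' @param params A [layered_params()].
#' @param depths Numeric vector of nonnegative depths in micrometres. If all
#'   depths lie within the epithelium only the epithelial segment is
#'   produced.
#' @return A [concentration_profile()].
#' @export
layered_profile <- function(params, depths) {
  stopifnot(inherits(params, "layered_params"))
  if (any(depths < 0)) abort("`depths` must be nonnegative (micrometres).")
  b <- params$boundary_depth
  value <- ifelse(
    depths <= b,
    erf_value(depths, params$epi$C0, params$epi$D, params$epi$t),
    erf_value(depths - b, params$stroma$C0, params$stroma$D, params$stroma$t)
  )
  concentration_profile(depths, value, time_s = params$epi$t,
                        kind = "concentration")
}

# evaluate either parameter object on a depth vector (renderer plumbing)
model_value <- function(truth, depths) {
  if (inherits(truth, "layered_params")) {
    layered_profile(truth, depths)$value
  } else {
    erf_profile(truth, depths)$value
  }
}

#' Finite-difference oracle for the 1-D diffusion equation
#'
#' Explicit (FTCS) solver for `dC/dt = d/dx (D(x) dC/dx)` on `[0, L]` with a
#' fixed boundary value at `x = 0`, zero initial condition, and a far
#' Dirichlet zero boundary placed deep enough that the domain behaves as
#' semi-infinite. Serves as the independent numerical check of the analytic
#' erf solution (uniform `D`) and of the layered model's qualitative
#' behaviour (piecewise `D`); it is never used for fitting.
#'
#' The scheme is flux-conservative with face diffusivities taken at cell
#' midpoints; the time step defaults to a Courant ratio
#' `r = D_max * dt / dx^2` of 0.25, half the explicit stability limit, and
#' the solver refuses to run if the requested `dt` violates
#' `dt <= dx^2 / (2 D_max)`, reporting the maximum stable step.
#'
#' @param D_of_x Either a single diffusivity (cm^2/s) or a function of depth
#'   (micrometres) returning the local diffusivity, e.g. piecewise constant
#'   for a layered cornea.
#' @param boundary_value Fixed concentration at `x = 0`.
#' @param t_end Integration time in seconds.
#' @param grid Depth step in micrometres.
#' @param dt Time step in seconds, or `NULL` to use the default Courant
#'   ratio.
#' @param domain_depth Domain depth in micrometres; defaults to
#'   `8e4 * sqrt(D_max * t_end)` so the far-boundary value stays below
#'   1e-6 of the boundary value.
#' @return A [concentration_profile()] on the grid at `t_end`.
#' @examples
#' num <- pde_oracle(3.3e-7, boundary_value = 1, t_end = 300, grid = 8)
#' @export
pde_oracle <- function(D_of_x, boundary_value, t_end, grid, dt = NULL,
                       domain_depth = NULL) {
  stopifnot(is.numeric(boundary_value), length(boundary_value) == 1L,
            t_end > 0, grid > 0)
  D_fun <- if (is.function(D_of_x)) D_of_x else function(x) rep(D_of_x, length(x))

  dx_cm <- grid / UM_PER_CM
  # probe for the maximum diffusivity to size the domain and check stability
  probe <- D_fun(seq(0, domain_depth %||% (grid * 4000), length.out = 2048))
  Dmax <- max(probe)
  if (!is.finite(Dmax) || Dmax <= 0) abort("`D_of_x` must be positive.")

  if (is.null(domain_depth)) {
    domain_depth <- 8 * sqrt(Dmax * t_end) * UM_PER_CM
  }
  n <- ceiling(domain_depth / grid)
  x <- seq(0, n) * grid                      # node depths, micrometres

  dt_max <- dx_cm^2 / (2 * Dmax)
  if (is.null(dt)) dt <- 0.5 * dt_max        # Courant ratio 0.25
  if (dt > dt_max * (1 + 1e-12)) {
    abort(sprintf(
      "Explicit scheme unstable: dt = %.4g s exceeds the maximum stable step %.4g s (dx^2 / (2 D_max)).",
      dt, dt_max), class = "ribodosim_unstable_scheme")
  }
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps

  D_face <- D_fun((x[-length(x)] + x[-1]) / 2)   # face diffusivities
  r_face <- D_face * dt / dx_cm^2

  C <- numeric(n + 1)
  C[1] <- boundary_value
  idx <- 2:n
  for (step in seq_len(nsteps)) {
    flux <- r_face * diff(C)                     # r_{i+1/2} * (C_{i+1} - C_i)
    C[idx] <- C[idx] + (flux[idx] - flux[idx - 1L])
    C[1] <- boundary_value
    C[n + 1] <- 0
  }
  if (abs(boundary_value) > 0 && abs(C[n]) > 1e-6 * abs(boundary_value)) {
    warn("Far boundary not effectively semi-infinite; increase `domain_depth`.")
  }
  concentration_profile(x, pmax(C, 0), time_s = t_end, kind = "concentration")
}
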