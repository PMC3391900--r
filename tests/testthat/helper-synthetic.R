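# shared study-condition fixtures: stromal/epithelial diffusivity magnitudes,
# 18-minute soak, 12.2 um/px at 45 degrees, peak signal near 80% of 8-bit range

D_STROMA <- 3.3e-7   # cm^2/s, riboflavin-dextran, de-epithelialized
D_EPI    <- 4.7e-8   # cm^2/s, epithelium
D_STROMA_BAK <- 4.6e-7  # cm^2/s, stroma under the transepithelial formulation
T_SOAK   <- 1080     # s (18 minutes)

single_truth <- function(C0 = 190, t = T_SOAK) diffusion_params(D_STROMA, t, C0)

layered_truth <- function(t = T_SOAK) {
  layered_params(diffusion_params(D_EPI, t, 190),
                 diffusion_params(D_STROMA_BAK, t, 90),
                 boundary_depth = 75)
}

quiet_scene <- function(...) scene_spec(noise = list(gaussian_sd = 0, poisson = FALSE), ...)

noisy_scene <- function(seed, sd = 2.55, ...) {
  # 1% of the 8-bit range
  scene_spec(noise = list(gaussian_sd = sd, poisson = FALSE), seed = seed, ...)
}

# render one soaked frame plus its control (independent noise draw, as two
# exposures have) and run the full pipeline
pipeline_profile <- function(scene, truth, t = T_SOAK, trim_frac = 0.02) {
  img <- render_slit_image(scene, truth, t)
  ctl <- render_slit_image(scene, truth, 0, seed = scene$seed + 9999L)
  image_to_profile(img, ctl, trim_frac = trim_frac)
}
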