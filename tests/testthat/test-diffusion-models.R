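test_that("erf profile honours its boundary and far-field limits", {
  p <- diffusion_params(D = 3.3e-7, t = 1080, C0 = 42)
  prof <- erf_profile(p, c(0, 50, 5000))
  expect_equal(prof$value[1], 42)                       # erf(0) = 0
  expect_lt(prof$value[3], 42 * 1e-10)                  # x >> 2 sqrt(Dt)
  expect_true(all(diff(prof$value) <= 0))               # nonincreasing
})

test_that("erf profile matches an independent erf evaluation at x = 2 sqrt(Dt)", {
  skip_if_not_installed("pracma")
  p <- diffusion_params(D = 2e-7, t = 900, C0 = 100)
  x_star <- 2 * sqrt(p$D * p$t) * 1e4                   # um
  got <- erf_profile(p, x_star)$value
  expect_equal(got, 100 * (1 - pracma::erf(1)), tolerance = 1e-12)
  # frozen from the independent oracle: 100 * (1 - erf(1))
  expect_equal(got, 15.7299207050285, tolerance = 1e-10)
})

test_that("invalid diffusion parameters are rejected", {
  expect_error(diffusion_params(D = -1e-7, t = 100), class = "ribodosim_invalid_parameter")
  expect_error(diffusion_params(D = 1e-7, t = 0), class = "ribodosim_invalid_parameter")
  expect_error(layered_params(diffusion_params(1e-7, 10), diffusion_params(1e-7, 10),
                              boundary_depth = 0),
               class = "ribodosim_invalid_parameter")
  expect_error(erf_profile(diffusion_params(1e-7, 10), c(-5, 0)))
})

test_that("erf profile is self-similar in x / sqrt(D t) and monotone in t", {
  depths <- seq(0, 800, by = 10)
  a <- erf_profile(diffusion_params(3.3e-7, 1080, 7), depths)
  b <- erf_profile(diffusion_params(3.3e-7 / 4, 4 * 1080, 7), depths)
  expect_identical(a$value, b$value)
  early <- erf_profile(diffusion_params(3.3e-7, 300, 7), depths)
  late <- erf_profile(diffusion_params(3.3e-7, 1200, 7), depths)
  expect_true(all(late$value >= early$value))
  expect_equal(early$value[1], 7)                       # boundary pinned at C0
})

test_that("layered profile composes two independent erf segments", {
  lp <- layered_params(diffusion_params(4.7e-8, 1080, 190),
                       diffusion_params(4.6e-7, 1080, 90), 75)
  depths <- seq(0, 700, by = 12)
  prof <- layered_profile(lp, depths)
  epi_ref <- erf_profile(lp$epi, depths[depths <= 75])
  stroma_ref <- erf_profile(lp$stroma, depths[depths > 75] - 75)
  expect_equal(prof$value[depths <= 75], epi_ref$value)
  expect_equal(prof$value[depths > 75], stroma_ref$value)
})

test_that("layered profile degenerates to single-medium within each segment", {
  same <- diffusion_params(2.5e-7, 600, 50)
  lp <- layered_params(same, same, 75)
  shallow <- seq(0, 70, by = 7)
  expect_equal(layered_profile(lp, shallow)$value,
               erf_profile(same, shallow)$value)
})

test_that("profiles serialize losslessly to CSV", {
  prof <- erf_profile(diffusion_params(3.3e-7, 1080, 99), seq(0, 400, by = 40))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  back <- read_profile_csv(path)
  expect_equal(back$depth_um, prof$depth_um)
  expect_equal(back$value, prof$value, tolerance = 1e-9)
  expect_equal(profile_time(back), 1080)
  expect_equal(profile_kind(back), "concentration")
})

test_that("PDE oracle agrees with the analytic solution for uniform D", {
  num <- pde_oracle(3.3e-7, boundary_value = 1, t_end = 1080, grid = 4)
  ana <- erf_profile(diffusion_params(3.3e-7, 1080, 1), num$depth_um)
  expect_lt(max(abs(num$value - ana$value)), 1e-3)
})

test_that("PDE oracle converges at second order in the grid spacing", {
  errs <- vapply(c(16, 8), function(g) {
    num <- pde_oracle(3.3e-7, 1, t_end = 600, grid = g)
    ana <- erf_profile(diffusion_params(3.3e-7, 600, 1), num$depth_um)
    max(abs(num$value - ana$value))
  }, numeric(1))
  order <- log2(errs[1] / errs[2])
  expect_gt(order, 1.7)
  expect_lt(order, 2.3)
})

test_that("PDE oracle refuses an unstable time step and names the limit", {
  dx_cm <- 4 / 1e4
  dt_max <- dx_cm^2 / (2 * 3.3e-7)
  expect_error(
    pde_oracle(3.3e-7, 1, t_end = 100, grid = 4, dt = 2 * dt_max),
    class = "ribodosim_unstable_scheme")
  err <- tryCatch(pde_oracle(3.3e-7, 1, t_end = 100, grid = 4, dt = 2 * dt_max),
                  error = identity)
  expect_match(conditionMessage(err), "maximum stable")
})

test_that("PDE oracle limits: short times and diffusion barriers", {
  near_zero <- pde_oracle(3.3e-7, 1, t_end = 1e-3, grid = 10, domain_depth = 400)
  expect_equal(near_zero$value[1], 1)
  # diffusion length sqrt(D t) ~ 0.2 um << 10 um grid: one explicit step
  # leaks at most the Courant ratio for that dt into the first interior node
  expect_lt(max(near_zero$value[-1]), 1e-3)
  expect_lt(max(near_zero$value[-(1:2)]), 1e-6)

  # epithelial barrier suppresses deep concentration vs. uniform fast medium
  barrier <- pde_oracle(function(x) ifelse(x < 75, 4.7e-8, 4.6e-7),
                        1, t_end = 600, grid = 5, domain_depth = 1500)
  uniform <- pde_oracle(4.6e-7, 1, t_end = 600, grid = 5, domain_depth = 1500)
  at <- which(barrier$depth_um == 200)
  expect_lt(barrier$value[at], uniform$value[at])
})
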