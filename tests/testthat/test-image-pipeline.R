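test_that("baseline subtraction is per-pixel, clipped at zero, shape-checked", {
  img <- render_slit_image(quiet_scene(), single_truth(), T_SOAK)
  expect_true(all(subtract_baseline(img, img)$pixels == 0))

  flat25 <- slit_image(matrix(25, 10, 8), pixel_pitch = 12.2)
  flat10 <- slit_image(matrix(10, 10, 8), pixel_pitch = 12.2)
  expect_true(all(subtract_baseline(flat25, flat10)$pixels == 15))
  expect_true(all(subtract_baseline(flat10, flat25)$pixels == 0))  # clipping
  sub <- subtract_baseline(img, render_slit_image(quiet_scene(), single_truth(), 0))
  expect_true(all(sub$pixels <= img$pixels))

  small <- slit_image(matrix(0, 5, 5), pixel_pitch = 12.2)
  expect_error(subtract_baseline(img, small), class = "ribodosim_shape_mismatch")
  other_pitch <- slit_image(matrix(10, 10, 8), pixel_pitch = 10)
  expect_error(subtract_baseline(flat25, other_pitch),
               class = "ribodosim_shape_mismatch")
})

test_that("surface detection finds the apex and rejects edgeless images", {
  sc <- quiet_scene()
  sub <- subtract_baseline(render_slit_image(sc, single_truth(), T_SOAK),
                           render_slit_image(sc, single_truth(), 0))
  surf <- detect_surface(sub)
  apex <- attr(surf, "apex")
  expect_lt(abs(apex["row"] - sc$apex_row), 1)          # within 1 px of truth

  errs <- vapply(1:20, function(s) {
    scn <- noisy_scene(seed = s)
    sb <- subtract_baseline(render_slit_image(scn, single_truth(), T_SOAK),
                            render_slit_image(scn, single_truth(), 0,
                                              seed = s + 9999L))
    abs(attr(detect_surface(sb), "apex")["row"] - scn$apex_row)
  }, numeric(1))
  expect_lt(median(errs), 2)                            # 1% noise: within 2 px

  uniform <- slit_image(matrix(50, 30, 9), pixel_pitch = 12.2, slit_col = 5)
  expect_error(detect_surface(uniform), class = "ribodosim_no_signal")
  dark <- slit_image(matrix(0, 30, 9), pixel_pitch = 12.2, slit_col = 5)
  expect_error(detect_surface(dark), class = "ribodosim_no_signal")
})

test_that("profile extraction starts at the surface and averages the strip", {
  sc <- quiet_scene()
  sub <- subtract_baseline(render_slit_image(sc, single_truth(), T_SOAK),
                           render_slit_image(sc, single_truth(), 0))
  surf <- detect_surface(sub)
  prof <- extract_profile(sub, surf, strip_width = 1L)
  expect_equal(prof$depth_um[1], 0)                     # origin at surface row
  r0 <- ceiling(min(surf$row) - 1e-6)
  expect_equal(prof$value, sub$pixels[r0:nrow(sub$pixels), sc$slit_col])

  expect_error(extract_profile(sub, surf, strip_width = 200L),
               class = "ribodosim_invalid_config")
})

test_that("strip averaging reduces white-noise variance about threefold", {
  # wide slit and a locally flat surface so the 3-column strip sees
  # i.i.d. noise on identical signal
  sds <- vapply(1:20, function(s) {
    scn <- noisy_scene(seed = s, sd = 3, slit_width = 5, corneal_radius = 1e9)
    sub <- subtract_baseline(render_slit_image(scn, single_truth(C0 = 120), T_SOAK),
                             render_slit_image(scn, single_truth(C0 = 120), 0,
                                               seed = s + 9999L))
    surf <- detect_surface(sub)
    ref <- erf_profile(single_truth(C0 = 120), seq(0, 300, by = 17.25))
    p1 <- extract_profile(sub, surf, strip_width = 1L)
    p3 <- extract_profile(sub, surf, strip_width = 3L)
    n <- length(ref$value)
    c(var(p1$value[1:n] - ref$value), var(p3$value[1:n] - ref$value))
  }, numeric(2))
  ratio <- mean(sds[1, ]) / mean(sds[2, ])
  expect_gt(ratio, 2)                                   # ~3x in expectation
  expect_lt(ratio, 4.5)
})

test_that("cosine correction rescales depth by 1/cos(angle) and inverts", {
  prof <- concentration_profile(seq(0, 9) * 12.2, 10:1, time_s = 60)
  corr <- cosine_correct(prof, 45)
  expect_equal(corr$depth_um[10], 9 * 12.2 / cos(pi / 4))
  # frozen by direct arithmetic: 10 px x 12.2 um / cos(45 deg) = 122 * sqrt(2)
  ten_px <- cosine_correct(concentration_profile(c(0, 10 * 12.2), c(1, 0)), 45)
  expect_equal(ten_px$depth_um[2], 172.534054609518, tolerance = 1e-10)

  expect_equal(cosine_correct(prof, 0)$depth_um, prof$depth_um)  # identity
  inv <- concentration_profile(corr$depth_um * cos(pi / 4), corr$value)
  expect_equal(inv$depth_um, prof$depth_um)              # invertible
  expect_true(all(diff(corr$depth_um) > diff(prof$depth_um)))  # spacing grows
  expect_error(cosine_correct(prof, 90), class = "ribodosim_invalid_parameter")
})

test_that("the composed pipeline reproduces the generating profile to 1 count", {
  sc <- quiet_scene()
  truth <- single_truth()
  prof <- pipeline_profile(sc, truth, trim_frac = NULL)
  ref <- erf_profile(truth, prof$depth_um)
  expect_lt(max(abs(prof$value - ref$value)), 1)

  lt <- layered_truth()
  lprof <- pipeline_profile(sc, lt, trim_frac = NULL)
  lref <- layered_profile(lt, lprof$depth_um)
  expect_lt(max(abs(lprof$value - lref$value)), 1)
})

test_that("trim keeps the profile inside the semi-infinite window", {
  prof <- erf_profile(single_truth(C0 = 100), seq(0, 2000, by = 20))
  trimmed <- trim_profile(concentration_profile(prof$depth_um, prof$value,
                                                time_s = T_SOAK), 0.02)
  expect_true(all(trimmed$value >= 0.02 * trimmed$value[1]))
  expect_lt(nrow(trimmed), nrow(prof))
})
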