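test_that("sigma_schedule is the geometric ladder over [r0/3, r1/3]", {
  s <- sigma_schedule(1.5, 15, 5)
  expect_equal(s$ratio, 10^(1 / 4))
  expect_equal(s$sigmas_mm, c(0.5, 0.8891397, 1.5811388, 2.8117066, 5.0),
               tolerance = 1e-6)
  expect_equal(s$sigmas_mm[1], 1.5 / 3, tolerance = 1e-9)
  expect_equal(s$sigmas_mm[5], 15 / 3, tolerance = 1e-9)
  expect_true(all(diff(s$sigmas_mm) > 0))
  expect_length(s$sigmas_mm, s$n_scales)
  expect_equal(sigma_schedule(3, 3, 1)$sigmas_mm, 1)        # degenerate range
  expect_equal(sigma_schedule(3, 9, 2)$sigmas_mm, c(1, 3))  # endpoints only
  expect_error(sigma_schedule(5, 3), "r0")
  expect_error(sigma_schedule(-1, 3), "positive")
  expect_error(sigma_schedule(1, 3, 1), "n_scales")
})

test_that("hessian eigenvalues at a dot center follow -1/sigma^2", {
  # hessian_field fuses smoothing at scale s with differentiation, so the
  # dot it measures has scale sigma_eff = sqrt(sigma_r^2 + s^2); choosing
  # amplitude (sigma_r^2 + s^2)/sigma_r^2 makes that effective dot have
  # unit amplitude, whose center eigenvalues are -1/sigma_eff^2
  for (sr in c(3, 5, 8)) {
    s <- 2
    amp <- (sr^2 + s^2) / sr^2
    img <- render_dot(c(48, 48), sr, amp, c(96, 96))
    hf <- hessian_field(img, s)
    expected <- -1 / (sr^2 + s^2)
    expect_equal(hf$lambda1[48, 48], expected, tolerance = 0.02)
    expect_equal(hf$lambda2[48, 48], expected, tolerance = 0.02)
  }
})

test_that("hessian eigenvalues on a line interior: lambda2 ~ 0", {
  img <- render_line(c(48, 16), c(48, 80), 3, 1, c(96, 96))
  hf <- hessian_field(img, 2)
  for (col in c(40, 48, 56)) {
    expect_lt(hf$lambda1[48, col], 0)
    expect_lt(abs(hf$lambda2[48, col]), 0.05 * abs(hf$lambda1[48, col]))
  }
})

test_that("hessian field invariants hold and match the eigen oracle", {
  set.seed(4)
  img <- image2d(matrix(runif(64 * 64, 0, 255), 64, 64))
  hf <- hessian_field(img, 2)
  expect_true(all(abs(hf$lambda1) >= abs(hf$lambda2) - 1e-12))
  expect_equal(hf$lambda1 + hf$lambda2, hf$fxx + hf$fyy, tolerance = 1e-6)
  # closed form (fxx+fyy)/2 +/- sqrt(((fxx-fyy)/2)^2 + fxy^2) against
  # base::eigen on sampled pixels
  idx <- cbind(sample(5:60, 25), sample(5:60, 25))
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    H <- matrix(c(hf$fxx[r, c], hf$fxy[r, c], hf$fxy[r, c], hf$fyy[r, c]), 2, 2)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    got <- sort(c(hf$lambda1[r, c], hf$lambda2[r, c]))
    expect_equal(got, sort(ev), tolerance = 1e-9)
  }
  cst <- hessian_field(matrix(5, 32, 32), 2)
  expect_lt(max(abs(cst$lambda1), abs(cst$lambda2)), 1e-12)
  expect_error(hessian_field(img, 0), "sigma")
})

test_that("dot_response implements the blobness measure", {
  expect_equal(dot_response(-3, -3), 3)       # ideal dot: w_d = |c|
  expect_equal(dot_response(-5, 0), 0)        # ideal line
  expect_equal(dot_response(-2, 1), 0)        # lambda2 > 0
  expect_equal(dot_response(2, 1), 0)         # bright-on-dark rejected
  m1 <- matrix(c(-4, -2, 3, 0), 2, 2)
  m2 <- matrix(c(-2, -1, 1, 0), 2, 2)
  w <- dot_response(m1, m2)
  expect_equal(w, matrix(c(1, 0.5, 0, 0), 2, 2))
  expect_true(all(dot_response(matrix(rnorm(100), 10),
                               matrix(rnorm(100), 10)) >= 0))
})

test_that("multiscale filter selects the dot's own scale and is monotone", {
  img <- render_dot(c(48, 48), 5, 255, c(96, 96), spacing_mm = 1)
  sched <- scale_schedule_from_sigmas(c(2, 3.5, 5, 7, 10))
  mf <- multiscale_dot_filter(img, sched)
  expect_equal(mf$scale_mm[48, 48], 5)  # argmax scale = planted sigma
  expect_true(all(mf$response >= 0))
  # single-scale schedule reduces to sigma^2-normalized dot_response
  one <- multiscale_dot_filter(img, scale_schedule_from_sigmas(3.5))
  hf <- hessian_field(img, 3.5)
  expect_equal(unclass(one$response), 3.5^2 * dot_response(hf$lambda1, hf$lambda2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # adding a scale never decreases the per-pixel max
  sub <- multiscale_dot_filter(img, scale_schedule_from_sigmas(c(2, 5)))
  sup <- multiscale_dot_filter(img, scale_schedule_from_sigmas(c(2, 5, 7)))
  expect_true(all(sup$response - sub$response >= -1e-12))
  expect_error(multiscale_dot_filter(img, scale_schedule_from_sigmas(numeric(0))),
               "positive")
})

test_that("response at a dot center is rotation robust", {
  els <- list(list(type = "dot", center = c(40, 58), sigma = 4, amplitude = 255),
              list(type = "line", p_start = c(70, 20), p_end = c(70, 90),
                   sigma = 2, amplitude = 255))
  img <- render_phantom(phantom_spec(c(112, 112), spacing_mm = 1, elements = els))
  rot <- image2d(rotate_bilinear(unclass(img), 45), 1)
  sched <- scale_schedule_from_sigmas(c(2, 3, 4, 6))
  r0 <- multiscale_dot_filter(img, sched)$response
  r1 <- multiscale_dot_filter(rot, sched)$response
  p <- round(rotate_point(c(40, 58), 45, c(112, 112)))
  expect_lt(abs(r1[p[1], p[2]] - r0[40, 58]) / r0[40, 58], 0.05)
})

test_that("extract_suspects labels, filters and localizes regions", {
  zero <- matrix(0, 32, 32)
  expect_equal(nrow(extract_suspects(zero)), 0)
  img <- render_dot(c(30, 30), 4, 255, c(96, 96), spacing_mm = 1)
  mf <- multiscale_dot_filter(img, scale_schedule_from_sigmas(c(3, 4, 6)))
  s1 <- extract_suspects(mf$response, mf$scale_mm)
  expect_equal(nrow(s1), 1)
  expect_lt(sqrt((s1$centroid_row - 30)^2 + (s1$centroid_col - 30)^2), 1)
  expect_equal(s1$best_scale_mm, 4)
  two <- image2d(unclass(render_dot(c(25, 25), 3, 255, c(96, 96))) +
                 unclass(render_dot(c(70, 70), 4, 255, c(96, 96))), 1)
  mf2 <- multiscale_dot_filter(two, scale_schedule_from_sigmas(c(3, 4)))
  expect_equal(nrow(extract_suspects(mf2$response)), 2)
  expect_error(extract_suspects(mf$response, rel_threshold = 1.2), "rel_threshold")
})
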