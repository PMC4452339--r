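test_that("N(p1) and T(p1) reproduce the worked neighborhood example", {
  nb <- c(0, 1, 0, 1, 1, 0, 1, 0)   # (p2..p9)
  expect_equal(neighbor_count(nb), 4L)
  expect_equal(transition_count(nb), 3L)
  expect_equal(neighbor_count(rep(0, 8)), 0L)
  expect_equal(neighbor_count(rep(1, 8)), 8L)
  expect_equal(transition_count(rep(0, 8)), 0L)
  expect_equal(transition_count(c(1, 0, 1, 0, 1, 0, 1, 0)), 4L)
})

test_that("N and T agree with exhaustive enumeration over all 256 neighborhoods", {
  for (code in 0:255) {
    nb <- as.integer(intToBits(code))[1:8]
    expect_identical(neighbor_count(nb), oracle_neighbor_count(nb))
    expect_identical(transition_count(nb), oracle_transition_count(nb))
  }
})

test_that("thin handles degenerate inputs and simple bars", {
  # isolated pixel: N(p1) = 0 violates condition (a)
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  expect_equal(sum(thin(m)), 1)
  expect_equal(sum(thin(matrix(0L, 8, 8))), 0)
  # filled 3 x 20 bar thins to a one-pixel path of about the bar's length
  bar <- matrix(0L, 11, 26)
  bar[5:7, 4:23] <- 1L
  sk <- thin(bar)
  pts <- skeleton_points(sk)
  expect_true(all(pts$n_neighbors[pts$pixels] <= 2))   # a simple path
  expect_equal(nrow(pts$endpoints), 2)
  # path length agrees with the scalar reference (ends erode by a pixel or
  # two) and stays close to the bar's length
  expect_identical(unclass(sk)[, ], oracle_thin(bar))
  expect_gte(sum(sk), 16); expect_lte(sum(sk), 22)
})

test_that("thin matches the scalar reference implementation of the rules", {
  for (seed in 1:6) {
    m <- make_blob_mask(seed, c(28L, 28L))
    expect_identical(unclass(thin(m))[, ], oracle_thin(m),
                     info = paste("seed", seed))
  }
})

test_that("thin is idempotent, subset-preserving and component-preserving", {
  for (seed in 1:100) {
    m <- make_blob_mask(seed)
    sk <- thin(m)
    expect_true(all(sk <= m), info = paste("seed", seed))       # no creation
    expect_identical(unclass(thin(sk))[, ], unclass(sk)[, ],
                     info = paste("seed", seed))                 # idempotent
    expect_equal(count_components(sk), count_components(m),
                 info = paste("seed", seed))
  }
})

test_that("prune_spurs removes burrs and protects long branches", {
  # straight path with a 3-px side spur (thinned first: prune_spurs
  # operates on one-pixel-wide skeletons)
  m <- matrix(0L, 15, 40)
  m[8, 3:38] <- 1L
  m[5:7, 20] <- 1L
  pr <- prune_spurs(thin(m), 3)
  expect_equal(sum(pr[5:7, 20]), 0)             # spur gone
  expect_gte(sum(pr[8, ]), 36 - 2 * 3)          # main retracts <= iterations
  # spur-free straight path with protected endpoints: length preserved
  p <- matrix(0L, 9, 40); p[5, 3:38] <- 1L
  kept <- prune_spurs(structure(p, class = c("skeleton", "matrix", "array")), 8)
  expect_equal(sum(kept), 36)
  # 0 iterations = identity; negative rejected
  expect_identical(unclass(prune_spurs(p, 0))[, ], p[, ])
  expect_error(prune_spurs(p, -1), "iterations")
})

test_that("fill_gaps reconnects severed crossings and respects limits", {
  v <- make_vessel_phantom("X")
  mask <- extract_soft_tissue(v$image)
  # carve out the crossing center as if a suspect had been removed there
  ctr <- round((dim(mask) + 1) / 2)
  rm <- matrix(0L, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if ((r - ctr[1])^2 + (c - ctr[2])^2 <= 64) rm[r, c] <- 1L
  }
  cut <- unclass(mask); cut[rm == 1L] <- 0L
  expect_gte(count_components(cut), 2)
  healed <- fill_gaps(binary_mask(cut), rm)
  expect_equal(count_components(healed), 1)
  # no removed regions: unchanged
  expect_identical(unclass(fill_gaps(mask, NULL))[, ], unclass(mask)[, ])
  # components farther apart than max_gap_px are not bridged
  far <- matrix(0L, 30, 80)
  far[15, 5:20] <- 1L; far[15, 60:75] <- 1L
  rmfar <- matrix(0L, 30, 80); rmfar[14:16, 38:42] <- 1L
  out <- fill_gaps(binary_mask(far), rmfar, max_gap_px = 5)
  expect_equal(count_components(out), 2)
})

test_that("fill_gaps never increases the component count", {
  for (seed in 1:10) {
    m <- make_blob_mask(seed, c(36L, 36L))
    set.seed(seed + 500)
    rm <- matrix(0L, 36, 36)
    r0 <- sample(5:25, 1); c0 <- sample(5:25, 1)
    rm[r0:(r0 + 6), c0:(c0 + 6)] <- 1L
    cut <- m; cut[rm == 1L] <- 0L
    before <- count_components(cut)
    expect_lte(count_components(fill_gaps(binary_mask(cut), rm)), before)
  }
})

test_that("fit_line_local recovers exact lines", {
  m <- matrix(0L, 20, 20)
  m[10, 3:17] <- 1L                      # horizontal: row y = 10
  f <- fit_line_local(m, c(10, 10), 15)
  expect_equal(f$alpha^2 + f$beta^2, 1, tolerance = 1e-9)
  expect_equal(f$slope, 0, tolerance = 1e-9)
  expect_equal(f$intercept, 10, tolerance = 1e-9)     # -gamma/beta
  d <- matrix(0L, 20, 20)
  for (i in 3:17) d[i, i] <- 1L                       # diagonal y = x
  fd <- fit_line_local(d, c(10, 10), 15)
  expect_equal(abs(fd$slope), 1, tolerance = 1e-6)
  two <- matrix(0L, 10, 10); two[2, 3] <- 1L; two[7, 8] <- 1L
  ft <- fit_line_local(two, c(5, 5), 15)
  expect_equal(abs(ft$alpha * 3 + ft$beta * 2 + ft$gamma), 0, tolerance = 1e-9)
  expect_equal(abs(ft$alpha * 8 + ft$beta * 7 + ft$gamma), 0, tolerance = 1e-9)
  expect_error(fit_line_local(matrix(0L, 5, 5), c(3, 3)), "fewer than 2")
})

test_that("fit_deviation measures replicate spread", {
  mk <- function(slope, intercept) {
    # build a line_fit with the requested slope/intercept
    n <- sqrt(1 + slope^2)
    structure(list(alpha = -slope / n, beta = 1 / n,
                   gamma = -intercept / n, slope = slope,
                   intercept = intercept, n_points = 10), class = "line_fit")
  }
  same <- list(mk(2, 5), mk(2, 5), mk(2, 5))
  expect_equal(unname(fit_deviation(same)), c(0, 0))
  mixed <- list(mk(1, 0), mk(1, 1), mk(1, 2))
  dv <- fit_deviation(mixed)
  expect_equal(unname(dv[1]), 0)
  expect_equal(unname(dv[2]), sqrt(2 / 3), tolerance = 1e-9)   # ~0.8165
  expect_equal(unname(fit_deviation(list(mk(0, 0), mk(0, 4)))[2]), 2)
  vert <- structure(list(alpha = 1, beta = 0, gamma = -3, slope = NA,
                         intercept = NA, n_points = 5), class = "line_fit")
  expect_error(fit_deviation(list(vert, vert)), "vertical")
  expect_error(fit_deviation(list(mk(1, 1))), ">= 2")
})
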