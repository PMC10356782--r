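test_that("dice and ncc agree with hand-evaluated formulas", {
  a <- matrix(FALSE, 5, 5); b <- matrix(FALSE, 5, 5)
  a[1, 1:4] <- TRUE               # |A| = 4
  b[1, 3:5] <- TRUE; b[2, 5] <- TRUE  # |B| = 4, overlap = 2
  expect_equal(dice(a, b), 2 * 2 / (4 + 4))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, matrix(c(rep(FALSE, 20), rep(TRUE, 5)), 5)), 0)
  expect_error(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "empty")

  x <- matrix(stats::rnorm(25), 5)
  expect_equal(ncc(x, x), 1)
  expect_equal(ncc(x, -x), -1)
  expect_equal(ncc(x, 3 * x + 7), 1)
  expect_error(ncc(x, matrix(1, 5, 5)), "constant")
  # masked NCC equals cor of the masked values
  m <- matrix(rep(c(TRUE, FALSE), length.out = 25), 5)
  y <- matrix(stats::rnorm(25), 5)
  expect_equal(ncc(x, y, m), stats::cor(x[m], y[m]))
})

test_that("self-registration yields the identity", {
  fx <- make_af_image(5)
  A <- block_matching_affine(fx$img, fx$img, mask = fx$mask)
  expect_lt(max(abs(A - cbind(diag(2), c(0, 0)))), 1e-3)
  bs <- bspline_deformable(fx$img, fx$img, mask = fx$mask)
  d <- mxif3d:::bspline_displacement_grid(bs$grid, dim(fx$img), 1)
  expect_lt(max(sqrt(d$dx^2 + d$dy^2)), 0.5)
})

test_that("block matching recovers known translations and rotations", {
  fx <- make_af_image(3)
  tt <- transform_pair(cbind(diag(2), c(12, -7)))
  mov <- apply_transform_image(fx$img, tt)
  A <- block_matching_affine(fx$img, mov, mask = fx$mask,
                             block_size_px = 48, search_radius_px = 20)
  # the estimate is the inverse warp: translation (-12, +7)
  expect_lt(max(abs(A[, 3] - c(-12, 7))), 0.5)

  th <- 5 * pi / 180
  ctr <- c(ncol(fx$img), nrow(fx$img)) / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  mov2 <- apply_transform_image(fx$img,
                                transform_pair(cbind(R, ctr - R %*% ctr)))
  A2 <- block_matching_affine(fx$img, mov2, mask = fx$mask,
                              block_size_px = 48, search_radius_px = 20)
  ang <- atan2(A2[2, 1], A2[1, 1]) * 180 / pi
  expect_lt(abs(ang - (-5)), 0.2)

  expect_error(block_matching_affine(matrix(0, 80, 80) + 0,
                                     matrix(1, 80, 80)),
               "insufficient texture")
})

test_that("deformable registration recovers a known smooth warp", {
  fx <- make_af_image(7)
  tr <- withr::with_seed(9, random_transform_pair(dim(fx$img),
                                                  max_rot_deg = 0,
                                                  max_trans_px = 0,
                                                  deform_max_px = 10))
  mov <- apply_transform_image(fx$img, tr)
  bs <- bspline_deformable(fx$img, mov, mask = fx$mask)
  expect_gte(bs$nmi_after, bs$nmi_before - 1e-9)   # NMI never decreases
  pts <- expand.grid(x_um = seq(35, ncol(fx$img) - 30, 10),
                     y_um = seq(35, nrow(fx$img) - 25, 10))
  pts <- tibble::as_tibble(pts)
  inv <- apply_transform_points(pts, tr, direction = "inverse")
  U <- mxif3d:::bspline_displacement_at(bs$grid, cbind(pts$x_um, pts$y_um))
  err <- sqrt((pts$x_um + U[, 1] - inv$x_um)^2 +
                (pts$y_um + U[, 2] - inv$y_um)^2)
  expect_lt(mean(err), 2)
  expect_error(bspline_deformable(fx$img, fx$img, grid_spacing_px = 2),
               ">= 4")
})

test_that("point transforms compose, invert and flag the trivial cases", {
  pts <- tibble::tibble(x_um = c(0, 10, 25.5), y_um = c(0, -4, 60))
  expect_equal(apply_transform_points(pts, identity_transform()), pts)
  tt <- transform_pair(cbind(diag(2), c(10, 0)))
  out <- apply_transform_points(pts, tt)
  expect_equal(out$x_um, pts$x_um + 10)
  expect_equal(out$y_um, pts$y_um)
  # random transform pairs: forward then inverse within 0.1 um
  for (seed in 1:5) {
    tr <- withr::with_seed(seed,
                           random_transform_pair(c(160, 192),
                                                 max_rot_deg = 3,
                                                 max_trans_px = 10,
                                                 deform_max_px = 10))
    p <- withr::with_seed(seed + 100, tibble::tibble(
      x_um = stats::runif(40, 20, 170), y_um = stats::runif(40, 20, 140)))
    fw <- apply_transform_points(p, tr)
    bk <- apply_transform_points(fw, tr, direction = "inverse")
    expect_lt(max(abs(bk$x_um - p$x_um), abs(bk$y_um - p$y_um)), 0.1)
  }
  expect_error(apply_transform_points(tibble::tibble(x_um = NA, y_um = 1),
                                      identity_transform()), "non-finite")
  expect_error(transform_pair(matrix(c(1, 1, 1, 1, 0, 0), 2)), "singular")
})

test_that("image resampling preserves labels under nearest interpolation", {
  lab <- matrix(sample(0:3, 48 * 56, replace = TRUE), 48)
  expect_identical(apply_transform_image(lab, identity_transform(),
                                         interpolation = "nearest"), lab)
  tt <- transform_pair(cbind(diag(2), c(-3, 2)))
  moved <- apply_transform_image(lab, tt, interpolation = "nearest")
  expect_true(all(moved %in% 0:3))
  expect_error(apply_transform_image(lab, tt, interpolation = "cubic"))
})

test_that("nmi behaves as a similarity measure", {
  x <- matrix(stats::rnorm(40 * 40), 40)
  expect_gt(nmi(x, x), nmi(x, matrix(stats::rnorm(1600), 40)))
  # invariant to monotone intensity scaling of one image
  expect_equal(nmi(x, x), nmi(x, 2 * x + 3), tolerance = 1e-9)
})

test_that("register_stack handles trivial and degenerate stacks", {
  fx <- make_af_image(13, shape = c(128, 144))
  base <- (fx$img - min(fx$img)) / diff(range(fx$img)) * 400 + 60
  base[!fx$mask] <- 60
  mk <- function(ri, pi) section(list(AF = base), 1, ri, pi)
  stack <- list(mk(0L, 0L), mk(1L, 1L), mk(2L, 2L))
  reg <- register_stack(stack)
  expect_equal(reg$qc$dsc, rep(1, 3))
  for (tr in reg$transforms) {
    expect_lt(max(abs(tr$affine - cbind(diag(2), c(0, 0)))), 1e-3)
  }
  single <- register_stack(list(mk(0L, 0L)))
  expect_equal(nrow(single$qc), 1L)
  expect_true(mxif3d:::is_identity_transform(single$transforms[[1]]))
})

test_that("3D refinement recovers identity and a known xz shear", {
  vol <- withr::with_seed(4, {
    base <- mxif3d:::gauss_blur(matrix(stats::rnorm(64 * 72), 64), 5)
    v <- array(0, c(64, 72, 14))
    for (k in 1:14) {
      v[, , k] <- base +
        0.35 * mxif3d:::gauss_blur(matrix(stats::rnorm(64 * 72), 64), 3)
    }
    v
  })
  sp <- c(2, 2, 5)
  r0 <- refine_to_reference_volume(vol, vol, sp, maxit = 250)
  expect_lt(max(abs(r0$affine[, 1:3] - diag(3))), 0.01)

  sh <- tan(5 * pi / 180)
  d <- dim(vol)
  grid <- expand.grid(r = 1:d[1], c = 1:d[2], s = 1:d[3])
  xu <- (grid$c - 1) * sp[1] + sh * ((grid$s - 1) * sp[3])
  mov <- array(mxif3d:::trilinear_sample(vol, xu / sp[1], grid$r - 1,
                                         grid$s - 1), d)
  r1 <- refine_to_reference_volume(vol, mov, sp, maxit = 800)
  # fixed-to-moving convention: the recovered shear is the inverse (-sh)
  expect_lt(abs(atan(r1$affine[1, 3]) - atan(-sh)) * 180 / pi, 0.5)
  expect_gt(r1$nmi_after, r1$nmi_before)
  expect_error(refine_to_reference_volume(array(0, c(4, 4, 2)),
                                          array(1, c(4, 4, 2)),
                                          c(1, 1, 5)), "empty")
})
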