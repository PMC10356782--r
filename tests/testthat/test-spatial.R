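test_that("nearest-structure distances honour the 3-4-5 fixture", {
  cells <- tibble::tibble(cell_id = 1L, x_um = 0, y_um = 0, z_um = 10,
                          retained_index = 2L)
  vox <- tibble::tibble(x_um = 3, y_um = 4, z_um = 10, retained_index = 2L)
  d3 <- nearest_structure_distance(cells, vox, "3D")
  d2 <- nearest_structure_distance(cells, vox, "2D")
  expect_equal(d3$distance_um, 5)
  expect_equal(d2$distance_um, 5)
})

test_that("3D can be much closer than same-section 2D", {
  cells <- tibble::tibble(cell_id = 1L, x_um = 0, y_um = 0, z_um = 0,
                          retained_index = 0L)
  vox <- tibble::tibble(
    x_um = c(80, 0), y_um = c(0, 0), z_um = c(0, 5),
    retained_index = c(0L, 1L))
  rec <- distance_records(cells, vox)
  expect_equal(rec$d2d_um, 80)
  expect_equal(rec$d3d_um, 5)
  expect_true(all(rec$d3d_um <= rec$d2d_um))
})

test_that("pruned search equals brute force on random configurations", {
  withr::with_seed(77, {
    cells <- tibble::tibble(cell_id = 1:500,
                            x_um = stats::runif(500, 0, 200),
                            y_um = stats::runif(500, 0, 150),
                            z_um = stats::runif(500, 0, 100),
                            retained_index = sample(0:9, 500, TRUE))
    vox <- tibble::tibble(x_um = stats::runif(2000, 0, 200),
                          y_um = stats::runif(2000, 0, 150),
                          retained_index = sample(0:9, 2000, TRUE))
    vox$z_um <- vox$retained_index * 10
  })
  got3 <- nearest_structure_distance(cells, vox, "3D")
  expect_equal(got3$distance_um, brute_nearest(cells, vox, "3D"))
  got2 <- nearest_structure_distance(cells, vox, "2D")
  expect_equal(got2$distance_um, brute_nearest(cells, vox, "2D"))
  # witness voxels actually achieve the reported distances
  expect_equal(sqrt((got3$nearest_x_um - cells$x_um)^2 +
                      (got3$nearest_y_um - cells$y_um)^2 +
                      (got3$nearest_z_um - cells$z_um)^2),
               got3$distance_um)
})

test_that("2D mode flags sections without structure", {
  cells <- tibble::tibble(cell_id = 1:2, x_um = 0, y_um = 0, z_um = c(0, 10),
                          retained_index = c(0L, 5L))
  vox <- tibble::tibble(x_um = 1, y_um = 0, z_um = 0, retained_index = 0L)
  d2 <- nearest_structure_distance(cells, vox, "2D")
  expect_false(d2$no_target_in_section[1])
  expect_true(d2$no_target_in_section[2])
  expect_true(is.na(d2$distance_um[2]))
  expect_error(nearest_structure_distance(cells, vox[0, ], "3D"), "empty")
})

test_that("distance ties resolve to the lexicographically smallest witness", {
  cells <- tibble::tibble(cell_id = 1L, x_um = 0, y_um = 0, z_um = 0,
                          retained_index = 0L)
  vox <- tibble::tibble(x_um = c(5, -5, 0, 0), y_um = c(0, 0, 5, -5),
                        z_um = 0, retained_index = 0L)
  d <- nearest_structure_distance(cells, vox, "3D")
  expect_equal(d$distance_um, 5)
  expect_equal(c(d$nearest_x_um, d$nearest_y_um), c(0, -5))  # smallest (y, x)
})

test_that("skin-surface distances use the nearest section's boundary", {
  surface <- tibble::tibble(retained_index = 0L,
                            x_um = seq(0, 100, by = 1), y_um = 0)
  sm <- tibble::tibble(retained_index = 0L, z_um = 0)
  cells <- tibble::tibble(cell_id = 1L, x_um = 50, y_um = 100, z_um = 2)
  d <- distance_to_skin_surface(cells, surface, sm)
  expect_equal(d$distance_um, 100)

  # sinusoidal boundary vs a dense-sampling oracle
  xs <- seq(0, 200, by = 0.25)
  sine <- tibble::tibble(retained_index = 0L, x_um = xs,
                         y_um = 30 + 8 * sin(2 * pi * xs / 120))
  cl <- tibble::tibble(cell_id = 1:5, x_um = c(20, 60, 100, 140, 180),
                       y_um = c(90, 70, 120, 60, 100), z_um = 0)
  got <- distance_to_skin_surface(cl, sine, sm)
  oracle <- vapply(seq_len(5), function(i) {
    min(sqrt((sine$x_um - cl$x_um[i])^2 + (sine$y_um - cl$y_um[i])^2))
  }, numeric(1))
  expect_equal(got$distance_um, oracle)
  expect_error(distance_to_skin_surface(cl, sine[0, ], sm), "no surface")
})

test_that("cluster density counts neighbours in 2D and 3D", {
  lone <- tibble::tibble(cell_id = 1L, x_um = 0, y_um = 0, z_um = 0,
                         retained_index = 0L)
  cd <- cluster_density(lone, lone)
  expect_equal(cd$count2d, c(0, 0))
  expect_equal(cd$count3d, c(0, 0))

  # 3 same-section neighbours at 10 um + 2 directly above at z = 5
  idx <- tibble::tibble(cell_id = 1L, x_um = 0, y_um = 0, z_um = 0,
                        retained_index = 0L)
  nb <- tibble::tibble(cell_id = 2:6,
                       x_um = c(10, -10, 0, 3, -3),
                       y_um = c(0, 0, 10, 0, 0),
                       z_um = c(0, 0, 0, 5, 5),
                       retained_index = c(0L, 0L, 0L, 1L, 1L))
  cd2 <- cluster_density(idx, dplyr::bind_rows(idx, nb), radius_um = 30)
  expect_equal(cd2$count2d, 3)
  expect_equal(cd2$count3d, 5)

  # brute-force agreement on 300 random cells
  all_cells <- withr::with_seed(15, tibble::tibble(
    cell_id = 1:300, x_um = stats::runif(300, 0, 120),
    y_um = stats::runif(300, 0, 120), z_um = sample(0:5, 300, TRUE) * 5,
    retained_index = NA_integer_))
  all_cells$retained_index <- as.integer(all_cells$z_um / 5)
  got <- cluster_density(all_cells[1:40, ], all_cells, radius_um = c(15, 30))
  for (r in c(15, 30)) {
    sub <- got[got$radius_um == r, ]
    for (i in 1:40) {
      dx <- all_cells$x_um - all_cells$x_um[i]
      dy <- all_cells$y_um - all_cells$y_um[i]
      dz <- all_cells$z_um - all_cells$z_um[i]
      same <- all_cells$cell_id != all_cells$cell_id[i]
      expect_equal(sub$count3d[i], sum(same & sqrt(dx^2 + dy^2 + dz^2) <= r))
      expect_equal(sub$count2d[i],
                   sum(same & dz == 0 & sqrt(dx^2 + dy^2) <= r))
    }
  }
  expect_true(all(got$count3d >= got$count2d))
})

test_that("KS statistic matches an exhaustive ECDF scan", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  disjoint <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(disjoint$statistic, 1)
  a <- c(0.3, 1.2, 2.2, 2.9); b <- c(0.5, 0.9, 3.1)
  got <- ks_two_sample(a, b)
  grid <- sort(unique(c(a, b)))
  oracle <- max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t),
                           numeric(1))))
  expect_equal(got$statistic, oracle)
  expect_error(ks_two_sample(numeric(0), 1), "n >= 1")
})

test_that("spearman_bh matches rank logic and the BH step-up by hand", {
  x <- c(1, 2, 3, 4, 5)
  cubic <- spearman_bh(tibble::tibble(hypothesis = "c", x = x, y = x^3))
  expect_equal(cubic$statistic, 1)
  rev <- spearman_bh(tibble::tibble(hypothesis = "r", x = x, y = -x^3))
  expect_equal(rev$statistic, -1)

  fam <- withr::with_seed(8, dplyr::bind_rows(lapply(1:5, function(h) {
    x <- stats::rnorm(10)
    tibble::tibble(hypothesis = paste0("h", h), x = x,
                   y = x * (h %% 2) + stats::rnorm(10))
  })))
  got <- spearman_bh(fam)
  # hand step-up: p_(i) * m / i, cumulative minimum from the largest
  p <- got$p_value
  m <- length(p)
  ord <- order(p)
  stepped <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  adj <- pmin(adj, 1)
  expect_equal(got$adjusted_p[ord], adj)
  expect_true(all(got$adjusted_p >= got$p_value))
  expect_error(spearman_bh(tibble::tibble(hypothesis = "s", x = 1:3,
                                          y = 1:3)), "n >= 4")
})

test_that("wilcoxon test is exact for small separated groups", {
  idn <- wilcoxon_two_group(c(1, 2, 3, 4), c(1, 2, 3, 4))
  # statistic at the null centre n1*n2/2 and p far from significance
  expect_equal(idn$statistic, 8)
  expect_gt(idn$p_value, 0.5)
  sep <- wilcoxon_two_group(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(sep$p_value, 2 / choose(8, 4))   # enumeration: 2/70
  expect_error(wilcoxon_two_group(numeric(0), 1), "n >= 1")
})
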