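mk_section <- function(ri, pi, shape = c(16L, 16L), mask = NULL) {
  af <- matrix(1, shape[1], shape[2])
  s <- section(list(AF = af), 1, ri, pi)
  s$af_mask <- mask %||% matrix(TRUE, shape[1], shape[2])
  s
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# one-footprint cell record helper: a square nucleus at (r0, c0)
mk_cell <- function(id, ri, r0, c0, size = 3L, shape = c(16L, 16L),
                    phenotype = "Thelper") {
  px <- as.vector(outer((r0:(r0 + size - 1L)),
                        (c0:(c0 + size - 1L)) - 1L,
                        function(r, c) r + c * shape[1]))
  tibble::tibble(nucleus_id = id, retained_index = ri,
                 phenotype = phenotype,
                 x_um = c0 + (size - 1) / 2 - 1, y_um = r0 + (size - 1) / 2 - 1,
                 area_px = size^2, pixels = list(px))
}

sec_map <- function(phys) {
  tibble::tibble(retained_index = seq_along(phys) - 1L,
                 physical_index = as.integer(phys),
                 z_um = as.integer(phys) * 5)
}

test_that("stacking places slabs at physical z with real gaps", {
  secs <- list(mk_section(0L, 0L), mk_section(1L, 1L), mk_section(2L, 3L))
  vol <- stack_sections(secs, "AF", 5)
  expect_equal(vol$z_um, c(0, 5, 15))
  expect_equal(dim(vol$voxels), c(16, 16, 3))

  one <- stack_sections(list(mk_section(0L, 4L)), "AF", 5)
  expect_equal(one$z_um, 20)

  cont <- stack_sections(lapply(0:23, function(i) mk_section(i, i)), "AF", 5)
  expect_equal(diff(range(cont$z_um)), 115)   # 23 x 5 um

  expect_error(stack_sections(list(mk_section(0L, 2L), mk_section(1L, 2L))),
               "duplicate")
})

test_that("tissue volume and density are exact arithmetic", {
  m <- matrix(FALSE, 10, 10); m[1:10, 1:10] <- FALSE
  secs <- list(mk_section(0L, 0L, c(10L, 10L), mask = m))
  empty <- compute_tissue_volume(stack_sections(secs, "af_mask", 5))
  expect_equal(empty$volume_um3, 0)

  m2 <- matrix(FALSE, 40, 25); m2[1:40, 1:25] <- TRUE
  secs2 <- list(mk_section(0L, 0L, c(40L, 25L), mask = m2))
  v <- compute_tissue_volume(stack_sections(secs2, "af_mask", 5))
  expect_equal(v$voxels, 1000)
  expect_equal(v$volume_um3, 5000)      # 1000 voxels at 1x1x5 um
  expect_equal(v$volume_cm3, 5e-9)

  expect_equal(density_per_cm3(100, 1e-5), 1e7)
  expect_equal(density_per_cm3(0, 1e-5), 0)
  expect_error(density_per_cm3(5, 0), "> 0")
})

test_that("fusion merges overlapping nuclei only across small z gaps", {
  # single nucleus -> single 3D cell
  one <- fuse_cells_3d(mk_cell(1L, 0L, 5L, 5L), sec_map(0), c(16L, 16L))
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_sections_spanned, 1L)

  # same footprint in adjacent sections -> one cell spanning 2
  two <- dplyr::bind_rows(mk_cell(1L, 0L, 5L, 5L), mk_cell(1L, 1L, 5L, 5L))
  fused <- fuse_cells_3d(two, sec_map(c(0, 1)), c(16L, 16L))
  expect_equal(nrow(fused), 1L)
  expect_equal(fused$n_sections_spanned, 2L)
  expect_equal(nrow(fused$members[[1]]), 2L)

  # gap of 15 um (> max_z_gap 5) -> never merged
  gap <- dplyr::bind_rows(mk_cell(1L, 0L, 5L, 5L), mk_cell(1L, 1L, 5L, 5L))
  fused_gap <- fuse_cells_3d(gap, sec_map(c(0, 3)), c(16L, 16L))
  expect_equal(nrow(fused_gap), 2L)

  # diagonal-contact footprints merge at 26- but not 6-connectivity
  diag2 <- dplyr::bind_rows(mk_cell(1L, 0L, 5L, 5L, size = 2L),
                            mk_cell(1L, 1L, 7L, 7L, size = 2L))
  expect_equal(nrow(fuse_cells_3d(diag2, sec_map(c(0, 1)), c(16L, 16L),
                                  connectivity = 26L)), 1L)
  expect_equal(nrow(fuse_cells_3d(diag2, sec_map(c(0, 1)), c(16L, 16L),
                                  connectivity = 6L)), 2L)

  # different phenotypes never merge
  mixed <- dplyr::bind_rows(mk_cell(1L, 0L, 5L, 5L, phenotype = "Thelper"),
                            mk_cell(1L, 1L, 5L, 5L, phenotype = "Treg"))
  expect_equal(nrow(fuse_cells_3d(mixed, sec_map(c(0, 1)), c(16L, 16L))), 2L)
})

test_that("fusion equals a brute-force union-find oracle on random stacks", {
  shape <- c(24L, 24L)
  for (seed in 1:6) {
    cells <- withr::with_seed(seed, {
      n_sec <- sample(2:5, 1)
      rows <- list()
      id <- 0L
      for (ri in seq_len(n_sec) - 1L) {
        taken <- integer(0)   # per-section instances must be disjoint
        for (j in seq_len(sample(3:6, 1))) {
          repeat {
            cand <- mk_cell(id + 1L, ri, sample(3:18, 1), sample(3:18, 1),
                            size = sample(2:4, 1), shape = shape)
            if (!length(intersect(cand$pixels[[1]], taken))) break
          }
          id <- id + 1L
          taken <- c(taken, cand$pixels[[1]])
          rows[[id]] <- cand
        }
      }
      dplyr::bind_rows(rows)
    })
    sm <- sec_map(seq_len(max(cells$retained_index) + 1L) - 1L)
    got <- fuse_cells_3d(cells, sm, shape)

    # oracle: pairwise voxel-overlap (26-connectivity = 3x3 dilation) and
    # an independent union-find
    n <- nrow(cells)
    parent <- uf_new(n)
    dilate_px <- function(px) {
      rc <- cbind((px - 1L) %% shape[1] + 1L, (px - 1L) %/% shape[1] + 1L)
      out <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- rc[, 1] + dr; c <- rc[, 2] + dc
        ok <- r >= 1 & r <= shape[1] & c >= 1 & c <= shape[2]
        out <- c(out, r[ok] + (c[ok] - 1L) * shape[1])
      }
      unique(out)
    }
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dz <- abs(cells$retained_index[i] - cells$retained_index[j])
        if (dz != 1L) next
        if (length(intersect(dilate_px(cells$pixels[[i]]),
                             cells$pixels[[j]])) > 0) {
          parent <- uf_union(parent, i, j)
        }
      }
    }
    comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
    expect_equal(nrow(got), length(unique(comp)), info = paste("seed", seed))
    # conservation: every nucleus in exactly one 3D cell
    members <- dplyr::bind_rows(got$members)
    expect_equal(nrow(members), n)
    expect_equal(nrow(dplyr::distinct(members)), n)
    # monotonicity
    expect_lte(nrow(got), n)
  }
})

test_that("phantom 3D cell count is recovered within 5%", {
  ph <- tiny_phantom()
  # paint truth footprints directly (isolates fusion from segmentation)
  shp <- ph$truth$config$image_shape
  fp <- dplyr::bind_rows(lapply(seq_len(nrow(ph$truth$cells)), function(i) {
    f <- ph$truth$cells$footprints[[i]]
    if (nrow(f) == 0) return(NULL)
    f$cell <- i
    f
  }))
  recs <- lapply(seq_len(nrow(fp)), function(j) {
    d <- mxif3d:::disc_pixels(fp$cx_px[j], fp$cy_px[j], fp$r_px[j], shp)
    tibble::tibble(nucleus_id = fp$cell[j],
                   retained_index = fp$retained_index[j],
                   phenotype = ph$truth$cells$phenotype[fp$cell[j]],
                   x_um = fp$cx_px[j], y_um = fp$cy_px[j],
                   area_px = nrow(d),
                   pixels = list(d$row + (d$col - 1L) * shp[1]))
  })
  cells2d <- dplyr::bind_rows(recs)
  fused <- fuse_cells_3d(cells2d, ph$truth$section_map, shp)
  n_true <- length(unique(fp$cell))   # cells visible in >= 1 section
  expect_lt(abs(nrow(fused) - n_true) / n_true, 0.05)
})
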