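test_that("same seed yields bit-identical phantoms", {
  cfg <- phantom_config(n_sections = 3, image_shape = c(96L, 112L),
                        seed = 7,
                        cell_density_per_type = c(Thelper = 10,
                                                  macrophage = 4),
                        include_damage_markers = FALSE)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(mxif3d:::object_hash(a$sections),
                   mxif3d:::object_hash(b$sections))
  expect_identical(mxif3d:::object_hash(a$truth$cells),
                   mxif3d:::object_hash(b$truth$cells))
  c3 <- generate_phantom(phantom_config(n_sections = 3,
                                        image_shape = c(96L, 112L),
                                        seed = 8,
                                        cell_density_per_type =
                                          c(Thelper = 10, macrophage = 4),
                                        include_damage_markers = FALSE))
  expect_false(identical(mxif3d:::object_hash(a$sections),
                         mxif3d:::object_hash(c3$sections)))
})

test_that("ground-truth cell counts match the configured densities", {
  ph <- tiny_phantom()
  want <- ph$truth$config$cell_density_per_type
  got <- table(ph$truth$cells$phenotype)
  for (ty in names(want)) {
    expect_equal(unname(got[[ty]]), unname(want[[ty]]), info = ty)
  }
  expect_equal(nrow(ph$truth$cells), sum(want))
})

test_that("zero cell densities give tissue-only sections with empty truth", {
  ph <- generate_phantom(phantom_config(
    n_sections = 2, image_shape = c(80L, 96L), seed = 3,
    cell_density_per_type = c(Thelper = 0), vessel_count = 2,
    include_damage_markers = FALSE))
  expect_equal(nrow(ph$truth$cells), 0L)
  expect_true(all(c("DAPI", "AF", "CD31") %in%
                    names(ph$sections[[1]]$channels)))
  expect_gt(nrow(ph$truth$vessels), 0)
  # DAPI carries no nuclei: only noise around zero
  expect_lt(stats::quantile(ph$sections[[1]]$channels$DAPI, 0.999),
            6 * ph$truth$config$noise_sigma)
})

test_that("retained-section schedule obeys the two-skipped-sections bound", {
  ph <- tiny_phantom()
  gaps <- diff(ph$truth$section_map$physical_index)
  expect_true(all(gaps >= 1 & gaps <= 3))
  expect_error(phantom_config(n_sections = 3,
                              skipped_pattern = c(0L, 4L, 5L)),
               "gaps exceed")
  expect_error(phantom_config(n_sections = 2,
                              skipped_pattern = c(3L, 1L)),
               "strictly increasing")
})

test_that("unpackable densities fail naming the offending type", {
  expect_error(
    phantom_config(image_shape = c(48L, 48L),
                   cell_density_per_type = c(Thelper = 5, epithelial = 5000)),
    "packable area at type 'epithelial'")
})

test_that("cell footprints lie inside tissue and span 1-3 sections", {
  ph <- tiny_phantom()
  fp <- dplyr::bind_rows(ph$truth$cells$footprints)
  spans <- vapply(ph$truth$cells$footprints, nrow, integer(1))
  expect_true(all(spans <= 3))
  surf <- ph$truth$skin_surface
  for (ri in unique(fp$retained_index)) {
    sub <- fp[fp$retained_index == ri, ]
    ssub <- surf[surf$retained_index == ri, ]
    sy <- ssub$y_um[match(round(sub$cx_px) * 1, ssub$x_um)]
    expect_true(all(sub$cy_px >= sy - 1), info = paste("section", ri))
  }
})

test_that("warp_section honors identity, translation and noise contracts", {
  img <- matrix(0, 48, 56)
  img[20, 30] <- 500
  expect_identical(warp_section(img, identity_transform(), 0), img)
  tt <- transform_pair(cbind(diag(2), c(-5, 0)))
  w <- warp_section(img, tt, 0)
  expect_equal(which(w == max(w)),
               which(matrix(seq_along(img), 48) == (35 - 1) * 48 + 20))
  # seeded noise is reproducible and leaves the global RNG untouched
  set.seed(99); before <- stats::runif(1)
  set.seed(99)
  n1 <- warp_section(img, identity_transform(), 10, seed = 4)
  expect_equal(stats::runif(1), before)
  n2 <- warp_section(img, identity_transform(), 10, seed = 4)
  expect_identical(n1, n2)
  expect_error(transform_pair(matrix(c(1, 0, 0, NA, 0, 0), 2)),
               "non-finite")
})

test_that("known warp followed by its inverse is a near-identity resampling", {
  fx <- make_af_image(11)
  tr <- withr::with_seed(5, random_transform_pair(dim(fx$img),
                                                  max_rot_deg = 2,
                                                  max_trans_px = 5,
                                                  deform_max_px = 8))
  w <- apply_transform_image(fx$img, tr, 1, "linear")
  back <- apply_transform_image(w, tr, 1, "linear", direction = "inverse")
  interior <- fx$mask
  interior[1:40, ] <- FALSE   # exclude regions warped from outside the frame
  expect_lt(mean(abs(back[interior] - fx$img[interior])), 0.05)
})

test_that("stored inverse transforms re-align warped sections to reference", {
  ph <- tiny_phantom()
  k <- ph$truth$reference_index + 1L       # list position of the reference
  ks <- if (k > 1L) 1L else 2L             # any warped section
  tr <- ph$truth$transforms[[ks]]
  realigned <- apply_transform_image(ph$sections[[ks]]$channels$AF, tr, 1,
                                     "linear", direction = "inverse")
  # the reference section shares the persistent AF component; correlation
  # after re-alignment must be far above the unaligned one
  m <- compute_af_mask(ph$sections[[k]]$channels$AF)
  m[1:25, ] <- FALSE
  r_aligned <- ncc(realigned, ph$sections[[k]]$channels$AF, m)
  r_raw <- ncc(ph$sections[[ks]]$channels$AF,
               ph$sections[[k]]$channels$AF, m)
  expect_gt(r_aligned, r_raw + 0.1)
  expect_gt(r_aligned, 0.4)
})

test_that("simulate_marker_section delivers the requested truth makeup", {
  sim <- simulate_marker_section(n_cells = 120, positive_fraction = 0.25,
                                 image_shape = c(192L, 224L), seed = 13)
  expect_equal(nrow(sim$truth), 120)
  expect_equal(sum(sim$truth$positive), 30)
  expect_setequal(names(sim$section$channels), c("DAPI", "AF", "CD68"))
  sim2 <- simulate_marker_section(n_cells = 120, positive_fraction = 0.25,
                                  image_shape = c(192L, 224L), seed = 13)
  expect_identical(mxif3d:::object_hash(sim), mxif3d:::object_hash(sim2))
})
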