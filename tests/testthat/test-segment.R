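make_blob <- function(shape, cx, cy, sigma, amp = 1) {
  r <- matrix(0, shape[1], shape[2])
  gy <- exp(-((seq_len(shape[1]) - 1 - cy)^2) / (2 * sigma^2))
  gx <- exp(-((seq_len(shape[2]) - 1 - cx)^2) / (2 * sigma^2))
  r + amp * outer(gy, gx)
}

test_that("multiscale LoG is zero on constants, linear, and scale-selective", {
  const <- matrix(3.7, 40, 48)
  resp <- multiscale_log(const, c(2, 4))
  expect_equal(max(abs(resp)), 0)

  blob <- make_blob(c(64, 64), 32, 32, 4)
  r <- multiscale_log(blob, c(2, 4, 8))
  centre <- abs(r[33, 33, ])
  expect_equal(unname(which.max(centre)), 2L)  # strongest response at sigma 4

  r1 <- multiscale_log(blob, c(3))
  r3 <- multiscale_log(3 * blob, c(3))
  expect_equal(r3, 3 * r1, tolerance = 1e-12)

  expect_error(multiscale_log(blob, numeric(0)), "empty scale")
  expect_error(multiscale_log(blob, c(4, 2)), "sorted")
})

test_that("nuclei detection finds isolated blobs with sub-pixel centroids", {
  expect_equal(nrow(segment_nuclei(matrix(0, 64, 64))), 0L)

  withr::with_seed(31, {
    shape <- c(256L, 288L)
    img <- matrix(0, shape[1], shape[2])
    n <- 40
    # jittered 5x8 grid: guaranteed well-separated blob centres
    grid <- expand.grid(gy = seq(30, 226, length.out = 5),
                        gx = seq(30, 258, length.out = 8))
    cx <- grid$gx + stats::runif(n, -6, 6)
    cy <- grid$gy + stats::runif(n, -6, 6)
    for (i in seq_len(n)) {
      img <- img + make_blob(shape, cx[i], cy[i], 3.5, amp = 600)
    }
    img <- img + matrix(stats::rnorm(prod(shape), 0, 40), shape[1])
    nuc <- segment_nuclei(normalize_zmuv(img))
    expect_equal(nrow(nuc), n)
    errs <- vapply(seq_len(n), function(i) {
      min(sqrt((nuc$x_um - cx[i])^2 + (nuc$y_um - cy[i])^2))
    }, numeric(1))
    expect_lt(max(errs), 1)
  })
})

test_that("watershed splitting separates touching blobs when requested", {
  shape <- c(64L, 96L)
  img <- make_blob(shape, 40, 32, 4, 600) + make_blob(shape, 49, 32, 4, 600)
  img <- img + matrix(stats::rnorm(prod(shape), 0, 5), shape[1])
  z <- normalize_zmuv(img)
  with_split <- segment_nuclei(z, split = TRUE)
  without <- segment_nuclei(z, split = FALSE)
  expect_equal(nrow(with_split), 2L)
  expect_equal(nrow(without), 1L)
})

test_that("two-class EM recovers a known mixture and its invariants", {
  x <- withr::with_seed(1, matrix(c(stats::rnorm(5000),
                                    stats::rnorm(5000, 6)), 100))
  fit <- fit_gmm_two_class(x, seed = 3)
  expect_lt(abs(fit$means[1] - 0), 0.2)
  expect_lt(abs(fit$means[2] - 6), 0.2)
  expect_equal(sum(fit$weights), 1)
  expect_gt(fit$means[2], fit$means[1])   # positive class = larger mean
  expect_true(all(fit$posterior[x > 4] > 0.9))
  # posterior is monotone in intensity (shared variance)
  expect_false(is.unsorted(fit$posterior[order(as.vector(x))]))
  # relabelling symmetry under negation
  fneg <- fit_gmm_two_class(-x, seed = 3)
  expect_equal(1 - fneg$posterior, fit$posterior, tolerance = 1e-8)
  # tidy/glance accessors
  td <- tidy(fit)
  expect_equal(td$class, c("background", "positive"))
  expect_true(glance(fit)$converged)
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  library(mclust)
  x <- withr::with_seed(2, matrix(c(stats::rnorm(3000, 0, 1),
                                    stats::rnorm(2000, 5, 1.3)), 50))
  fit <- fit_gmm_two_class(x, seed = 4, variance = "separate")
  ref <- mclust::Mclust(as.vector(x), G = 2, modelNames = "V",
                        verbose = FALSE)
  expect_equal(sort(fit$means), sort(unname(ref$parameters$mean)),
               tolerance = 0.02)
})

test_that("EM handles outliers and rejects degenerate input", {
  y <- withr::with_seed(5, matrix(stats::rnorm(2500), 50))
  y[10, 10] <- 10 * max(abs(y))
  fo <- fit_gmm_two_class(y, seed = 2)
  expect_gt(fo$posterior[10, 10], 0.5)
  expect_error(fit_gmm_two_class(matrix(1, 5, 5)), "degenerate|constant")
})

test_that("marker calls combine probability and overlap thresholds", {
  prob <- matrix(0.95, 32, 32)
  nuc <- tibble::tibble(nucleus_id = 1L, retained_index = 0L,
                        x_um = 10, y_um = 10, area_px = 20L,
                        pixels = list(101:120))
  call <- call_marker_on_nuclei(prob, nuc, "CD3")
  expect_true(call$positive)
  expect_equal(call$overlap_fraction, 1)
  expect_equal(call$p, 0.95)

  # 5% of pixels above threshold with overlap gate 0.1 -> negative even
  # though those pixels are very confident
  prob2 <- matrix(0.01, 32, 32)
  px <- 101:200
  prob2[px[1:5]] <- 1
  call2 <- call_marker_on_nuclei(prob2, tibble::tibble(
    nucleus_id = 1L, retained_index = 0L, x_um = 0, y_um = 0,
    area_px = 100L, pixels = list(px)), "CD3")
  expect_equal(call2$overlap_fraction, 0.05)
  expect_false(call2$positive)

  expect_error(call_marker_on_nuclei(prob, tibble::tibble(
    nucleus_id = 1L, retained_index = 0L, x_um = 0, y_um = 0,
    area_px = 2L, pixels = list(c(1L, 99999L))), "CD3"),
    "outside")
})

test_that("structure masks come from Otsu on probabilities", {
  p <- matrix(0.05, 40, 40)
  p[10:20, 10:30] <- 0.9
  m <- segment_structure_mask(p)
  expect_identical(unname(which(m)), unname(which(p == 0.9)))
  expect_warning(out <- segment_structure_mask(
    matrix(stats::runif(100, 0, 0.15), 10)), "below guard")
  expect_false(any(out))
})

test_that("phenotype precedence and ambiguity flags are honoured", {
  mk_calls <- function(id, pos, p = NULL) {
    markers <- c("CD3", "CD4", "CD8", "FOXP3", "CD68", "CD31")
    tibble::tibble(nucleus_id = id, marker = markers,
                   p = if (is.null(p)) ifelse(markers %in% pos, 0.9, 0.05)
                       else p,
                   overlap_fraction = 1,
                   positive = markers %in% pos)
  }
  nuc <- tibble::tibble(nucleus_id = 1:5, retained_index = 0L,
                        x_um = 1:5, y_um = 1:5, area_px = 30L,
                        pixels = replicate(5, 1:30, simplify = FALSE))
  calls <- dplyr::bind_rows(
    mk_calls(1L, c("CD3", "CD4", "FOXP3")),
    mk_calls(2L, character(0)),
    mk_calls(3L, c("CD3", "CD4", "CD8"),
             p = c(0.9, 0.6, 0.9, 0.05, 0.05, 0.05)),
    mk_calls(4L, c("CD31", "CD68")),
    mk_calls(5L, c("CD68")))
  out <- phenotype_cells(nuc, calls)
  expect_equal(out$phenotype, c("Treg", "other", "Tkiller", "endothelial",
                                "macrophage"))
  expect_equal(out$ambiguous, c(FALSE, FALSE, TRUE, FALSE, FALSE))

  expect_error(phenotype_cells(nuc, calls[calls$marker != "CD31", ]),
               "missing required marker")
})
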