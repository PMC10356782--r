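#' Phantom configuration
#'
#' Study conditions for the synthetic serial-section generator. Defaults
#' emulate the acquisition this package targets: a stack of 24 retained
#' sections cut at 5 µm with up to two skipped physical sections between
#' retained ones, nuclei as blobs spanning 1--3 adjacent sections, blood
#' vessels as tubular CD31+ structures, an epidermis band bounded by a
#' sinusoidal skin surface, marker intensities drawn from a two-component
#' (background vs positive) intensity model, and per-section affine jitter,
#' smooth B-spline deformation and Gaussian noise. Intensities are written
#' on the 16-bit unsigned scale of microscopy TIFFs.
#'
#' @param n_sections number of retained sections (>= 1).
#' @param section_thickness_um physical section thickness (default 5 µm).
#' @param skipped_pattern integer vector of retained *physical* indices
#'   (strictly increasing, gaps <= 3 i.e. at most two skipped sections);
#'   `NULL` draws a pattern from the seed.
#' @param image_shape `c(rows, cols)` in pixels.
#' @param pixel_size_um pixel size (default 1 µm).
#' @param cell_density_per_type named integer vector: cells to place per
#'   phenotype. Recognised names: `Thelper`, `Tkiller`, `Treg`,
#'   `macrophage`, `endothelial`, `epithelial`, `other`.
#' @param vessel_count number of vessel tubes.
#' @param marker_snr separation (in units of the noise SD) between the
#'   positive-marker plateau and background.
#' @param affine_jitter `c(max_rotation_deg, max_translation_px)` applied
#'   per section.
#' @param deform_max_px bound on the per-section smooth deformation.
#' @param noise_sigma additive Gaussian noise SD (16-bit intensity units).
#' @param seed integer; fully determines the phantom.
#' @param reference_index retained index left unwarped (identity transform,
#'   emulating the manually chosen reference section); default the middle.
#' @param damage_marker_fraction fraction of epithelial cells positive for
#'   each of p53/Ki67/DDB2 (independently).
#' @param background_level AF tissue intensity plateau.
#' @param af_z_corr_sections correlation length (in physical sections) of
#'   the autofluorescence texture along z; the default 3 (~15 µm at 5 µm
#'   sections) reflects the slowly varying dermal collagen structures that
#'   make adjacent real sections look alike.
#' @param include_damage_markers render p53/Ki67/DDB2 channels.
#' @param min_separation_px hard-core in-plane separation between nuclei.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_sections = 24L,
                           section_thickness_um = 5,
                           skipped_pattern = NULL,
                           image_shape = c(192L, 224L),
                           pixel_size_um = 1,
                           cell_density_per_type = c(Thelper = 60, Tkiller = 8,
                                                     Treg = 12, macrophage = 20,
                                                     endothelial = 20,
                                                     epithelial = 40,
                                                     other = 15),
                           vessel_count = 4L,
                           marker_snr = 6,
                           affine_jitter = c(3, 10),
                           deform_max_px = 10,
                           noise_sigma = 60,
                           seed = 1L,
                           reference_index = NULL,
                           damage_marker_fraction = 0.25,
                           background_level = 500,
                           af_z_corr_sections = 3,
                           include_damage_markers = TRUE,
                           min_separation_px = 9) {
  n_sections <- as.integer(n_sections)
  if (n_sections < 1L) stop("n_sections must be >= 1", call. = FALSE)
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 32L)) {
    stop("image_shape must be c(rows, cols) with both >= 32 px",
         call. = FALSE)
  }
  if (prod(image_shape) == 0) stop("zero image area", call. = FALSE)
  if (!is.null(skipped_pattern)) {
    skipped_pattern <- as.integer(skipped_pattern)
    if (length(skipped_pattern) != n_sections) {
      stop("skipped_pattern must list one physical index per retained section",
           call. = FALSE)
    }
    if (skipped_pattern[1] < 0L || any(diff(skipped_pattern) < 1L)) {
      stop("skipped_pattern must be non-negative and strictly increasing",
           call. = FALSE)
    }
    if (any(diff(skipped_pattern) > 3L)) {
      stop("skipped_pattern gaps exceed 2 skipped sections (diff > 3)",
           call. = FALSE)
    }
  }
  dens <- cell_density_per_type
  if (length(dens)) {
    known <- c("Thelper", "Tkiller", "Treg", "macrophage", "endothelial",
               "epithelial", "other")
    bad <- setdiff(names(dens), known)
    if (length(bad)) stop("unknown phenotype(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(dens < 0)) stop("cell densities must be >= 0", call. = FALSE)
    # packable-area guard: hard-core placement needs ~ pi/4 * sep^2 px per
    # cell within roughly 60% of the frame (tissue)
    capacity <- 0.6 * prod(image_shape) / (0.8 * min_separation_px^2)
    cum <- cumsum(dens)
    if (any(cum > capacity)) {
      off <- names(dens)[which(cum > capacity)[1]]
      stop(sprintf("cell density exceeds packable area at type '%s'", off),
           call. = FALSE)
    }
  }
  cfg <- list(n_sections = n_sections,
              section_thickness_um = section_thickness_um,
              skipped_pattern = skipped_pattern,
              image_shape = image_shape,
              pixel_size_um = pixel_size_um,
              cell_density_per_type = dens,
              vessel_count = as.integer(vessel_count),
              marker_snr = marker_snr,
              affine_jitter = affine_jitter,
              deform_max_px = deform_max_px,
              noise_sigma = noise_sigma,
              seed = as.integer(seed),
              reference_index = if (is.null(reference_index)) NULL
                                else as.integer(reference_index),
              damage_marker_fraction = damage_marker_fraction,
              background_level = background_level,
              af_z_corr_sections = af_z_corr_sections,
              include_damage_markers = include_damage_markers,
              min_separation_px = min_separation_px)
  class(cfg) <- "phantom_config"
  cfg
}

phenotype_marker_map <- function() {
  list(Thelper = c("CD3", "CD4"),
       Tkiller = c("CD3", "CD8"),
       Treg = c("CD3", "CD4", "FOXP3"),
       macrophage = "CD68",
       endothelial = "CD31",
       epithelial = "AE1",
       other = character(0))
}

#' Warp a section raster with a known transform
#'
#' Resamples `image` through `transform` (linear interpolation) and adds
#' Gaussian read-out noise. With an identity transform and zero noise the
#' input is returned bit-exactly.
#'
#' @param image numeric matrix.
#' @param transform a [transform_pair()].
#' @param noise_sigma additive Gaussian noise SD (0 = none).
#' @param seed optional seed for the noise draw (restores the global RNG).
#' @param pixel_size_um pixel size of `image`.
#' @return Numeric matrix.
#' @export
warp_section <- function(image, transform, noise_sigma = 0, seed = NULL,
                         pixel_size_um = 1) {
  assert_image(image)
  out <- apply_transform_image(image, transform, pixel_size_um,
                               interpolation = "linear")
  if (noise_sigma > 0) {
    noise_fun <- function() {
      matrix(stats::rnorm(length(out), 0, noise_sigma), nrow(out))
    }
    n <- if (is.null(seed)) noise_fun() else
      withr::with_seed(seed, noise_fun())
    out <- out + n
  }
  out
}

# draw n points with a hard-core minimum separation inside the candidate
# pixel set; returns 0-based px coordinates. Errors naming `type` when the
# density is not packable.
place_hardcore <- function(n, candidates_rc, min_sep_px, placed_xy, type) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  tries <- 0L
  max_tries <- 400L * n
  all_xy <- placed_xy
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf("cell density exceeds packable area at type '%s'", type),
           call. = FALSE)
    }
    i <- sample.int(nrow(candidates_rc), 1L)
    x <- candidates_rc[i, 2] - 1 + stats::runif(1, -0.4, 0.4)
    y <- candidates_rc[i, 1] - 1 + stats::runif(1, -0.4, 0.4)
    if (nrow(all_xy)) {
      d2 <- (all_xy[, 1] - x)^2 + (all_xy[, 2] - y)^2
      if (min(d2) < min_sep_px^2) next
    }
    got <- got + 1L
    out[got, ] <- c(x, y)
    all_xy <- rbind(all_xy, c(x, y))
  }
  out
}

# additive plateau disc (0-based px centre), lightly feathered at the rim
render_disc <- function(img, cx, cy, r_px, value) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, floor(cy - r_px) + 1L); r1 <- min(nr, ceiling(cy + r_px) + 1L)
  c0 <- max(1L, floor(cx - r_px) + 1L); c1 <- min(nc, ceiling(cx + r_px) + 1L)
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - 1 - cy; dx <- cols - 1 - cx
  d <- sqrt(outer(dy^2, dx^2, `+`))
  w <- pmin(1, pmax(0, r_px + 0.5 - d))   # 1 inside, linear rim falloff
  img[rows, cols] <- img[rows, cols] + value * w
  img
}

render_gaussian <- function(img, cx, cy, sigma_px, amplitude) {
  nr <- nrow(img); nc <- ncol(img)
  ext <- ceiling(3.2 * sigma_px)
  r0 <- max(1L, floor(cy - ext) + 1L); r1 <- min(nr, ceiling(cy + ext) + 1L)
  c0 <- max(1L, floor(cx - ext) + 1L); c1 <- min(nc, ceiling(cx + ext) + 1L)
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  gy <- exp(-((rows - 1 - cy)^2) / (2 * sigma_px^2))
  gx <- exp(-((cols - 1 - cx)^2) / (2 * sigma_px^2))
  img[rows, cols] <- img[rows, cols] + amplitude * outer(gy, gx)
  img
}

disc_pixels <- function(cx, cy, r_px, dim_px) {
  ext <- ceiling(r_px)
  rows <- max(1L, floor(cy - ext) + 1L):min(dim_px[1], ceiling(cy + ext) + 1L)
  cols <- max(1L, floor(cx - ext) + 1L):min(dim_px[2], ceiling(cx + ext) + 1L)
  grid <- expand.grid(row = rows, col = cols)
  d2 <- (grid$row - 1 - cy)^2 + (grid$col - 1 - cx)^2
  grid[d2 <= r_px^2, , drop = FALSE]
}

quantize16 <- function(img) {
  img[img < 0] <- 0
  img[img > 65535] <- 65535
  round(img)
}

#' Generate a synthetic serial-section stack with ground truth
#'
#' Builds reference-frame tissue (sinusoidal skin surface, epidermis band,
#' dermal vessel tubes, nuclei with phenotype-determined marker positivity),
#' slices it into retained sections, then perturbs every section except the
#' reference with a stored affine + B-spline warp and Gaussian noise. The
#' same seed yields bit-identical output.
#'
#' @param config a [phantom_config()].
#' @return A list with elements `sections` (list of [section()]) and
#'   `truth` (class `phantom_truth`: `cells`, `vessels`, `skin_surface`,
#'   `transforms`, `section_map`, `config`).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(cfg) {
  nr <- cfg$image_shape[1]; nc <- cfg$image_shape[2]
  px <- cfg$pixel_size_um
  th <- cfg$section_thickness_um
  n <- cfg$n_sections

  # retained physical indices
  phys <- cfg$skipped_pattern
  if (is.null(phys)) {
    gaps <- sample(c(1L, 1L, 2L, 3L), n - 1L, replace = TRUE)
    phys <- cumsum(c(0L, gaps))
  }
  ref_i <- cfg$reference_index %||% as.integer((n - 1L) %/% 2L)
  if (ref_i < 0L || ref_i >= n) stop("reference_index out of range",
                                     call. = FALSE)
  z_slab <- phys * th          # z position convention of the volume builder
  z_mid <- z_slab + th / 2

  # --- skin surface and tissue geometry (reference frame) -------------------
  xs_px <- 0:(nc - 1)
  y0 <- 0.18 * nr; amp <- 0.05 * nr
  lambda <- 0.95 * nc; phase <- stats::runif(1, 0, 2 * pi)
  surf_y <- function(zq) {   # px, per column; weak z dependence
    y0 + amp * sin(2 * pi * xs_px / lambda + phase + 0.0015 * zq)
  }
  band_px <- 35 / px          # epidermis thickness ~35 um
  row_idx <- matrix(0:(nr - 1), nr, nc)
  tissue_mask_at <- function(zq) {
    sy <- matrix(surf_y(zq), nr, nc, byrow = TRUE)
    row_idx >= sy & row_idx <= (nr - 4)
  }

  # --- AF: two-scale smooth 3D random field sliced per physical index -------
  # a coarse component persisting through the whole block (collagen bundles,
  # epidermis texture: the anchor that makes registration to one reference
  # possible) plus a fine component decorrelating over af_z_corr_sections
  n_phys <- max(phys) + 1L
  smooth_field <- function(sigma_xy, sigma_z) {
    if (!is.finite(sigma_z)) {          # fully persistent along z
      s2 <- gauss_blur(matrix(stats::rnorm(nr * nc), nr, nc), sigma_xy)
      a <- array(rep(s2, n_phys), c(nr, nc, n_phys))
      return(a / stats::sd(a))
    }
    a <- array(stats::rnorm(nr * nc * n_phys), c(nr, nc, n_phys))
    for (k in seq_len(n_phys)) a[, , k] <- gauss_blur(a[, , k], sigma_xy)
    if (n_phys > 1L && sigma_z > 0) {
      half <- as.integer(ceiling(3 * sigma_z))
      zk <- stats::dnorm(-half:half, sd = sigma_z); zk <- zk / sum(zk)
      sm <- array(0, dim(a))
      for (o in -half:half) {
        src <- pmin(pmax(seq_len(n_phys) + o, 1L), n_phys)
        sm <- sm + zk[o + half + 1L] * a[, , src, drop = FALSE]
      }
      a <- sm
    }
    a / stats::sd(a)
  }
  zc <- cfg$af_z_corr_sections %||% 3
  persistent <- sqrt(0.6) * smooth_field(11, Inf) +
    sqrt(0.4) * smooth_field(4, Inf)
  af_noise <- sqrt(0.55) * persistent + sqrt(0.45) * smooth_field(4, zc)
  af_noise <- af_noise / stats::sd(af_noise)

  # --- vessels: smooth tubes parameterised by physical z --------------------
  vessels <- list()
  dermis_top <- y0 + band_px + 10
  v_lo <- min(dermis_top + 5, nr - 30)
  v_hi <- max(v_lo + 2, nr - 25)
  for (v in seq_len(cfg$vessel_count)) {
    x0 <- stats::runif(1, 0.12 * nc, 0.88 * nc)
    yv0 <- stats::runif(1, v_lo, v_hi)
    drift <- apply(matrix(stats::rnorm(2 * n_phys, 0, 1.2), ncol = 2), 2,
                   cumsum)
    r_v <- stats::runif(1, 3.5, 5.5)
    vessels[[v]] <- list(x = x0 + drift[, 1], y = yv0 + drift[, 2], r = r_v)
  }

  # --- cell placement -------------------------------------------------------
  mid_mask <- tissue_mask_at(stats::median(z_mid))
  sy_mid <- surf_y(stats::median(z_mid))
  band_mask <- mid_mask &
    row_idx >= matrix(sy_mid + 4, nr, nc, byrow = TRUE) &
    row_idx < matrix(sy_mid + band_px - 2, nr, nc, byrow = TRUE)
  dermis_mask <- mid_mask &
    row_idx > matrix(sy_mid + band_px + 8, nr, nc, byrow = TRUE) &
    row_idx <= nr - 10
  types <- names(cfg$cell_density_per_type)
  placed_xy <- matrix(numeric(0), 0, 2)
  cells <- list()
  cid <- 0L
  z_lo <- min(z_mid) - th / 2; z_hi <- max(z_mid) + th / 2
  for (ty in types) {
    nty <- as.integer(cfg$cell_density_per_type[[ty]])
    if (nty == 0L) next
    if (ty == "endothelial") {
      pts <- matrix(NA_real_, nty, 2)
      zs <- numeric(nty)
      for (i in seq_len(nty)) {
        vv <- vessels[[sample.int(length(vessels), 1L)]]
        kz <- sample.int(n_phys, 1L)
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- vv$r + stats::runif(1, 1, 2.5)
        pts[i, ] <- c(vv$x[kz] + rad * cos(ang), vv$y[kz] + rad * sin(ang))
        zs[i] <- (kz - 1) * th + th / 2 + stats::runif(1, -1, 1)
      }
    } else {
      region <- if (ty == "epithelial") band_mask else dermis_mask
      cand <- which(region, arr.ind = TRUE)
      if (nrow(cand) == 0L) {
        stop(sprintf("cell density exceeds packable area at type '%s'", ty),
             call. = FALSE)
      }
      pts <- place_hardcore(nty, cand, cfg$min_separation_px, placed_xy, ty)
      zs <- if (n == 1L) rep(z_mid[1], nty) else
        stats::runif(nty, z_lo, z_hi)
    }
    placed_xy <- rbind(placed_xy, pts)
    for (i in seq_len(nty)) {
      cid <- cid + 1L
      cells[[cid]] <- list(cell_id = cid, phenotype = ty,
                           x_px = pts[i, 1], y_px = pts[i, 2], z_um = zs[i],
                           r_um = stats::runif(1, 3.6, 5.4))
    }
  }

  # marker truth per cell
  pm <- phenotype_marker_map()
  damage <- c("p53", "Ki67", "DDB2")
  for (i in seq_along(cells)) {
    mk <- pm[[cells[[i]]$phenotype]]
    if (cfg$include_damage_markers && cells[[i]]$phenotype == "epithelial") {
      mk <- c(mk, damage[stats::runif(3) < cfg$damage_marker_fraction])
    }
    cells[[i]]$markers <- mk
  }

  markers_all <- c("CD3", "CD4", "CD8", "FOXP3", "CD68", "CD31", "AE1")
  if (cfg$include_damage_markers) markers_all <- c(markers_all, damage)

  noise_ref <- if (cfg$noise_sigma > 0) cfg$noise_sigma else 1
  marker_amp <- cfg$marker_snr * noise_ref
  dapi_amp <- 10 * noise_ref

  # --- per-cell footprints --------------------------------------------------
  footprints <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    ce <- cells[[i]]
    dz <- abs(z_mid - ce$z_um)
    hit <- which(dz < ce$r_um)
    if (length(hit)) {
      r_s <- sqrt(ce$r_um^2 - dz[hit]^2) / px
      keep <- r_s >= 1.8
      hit <- hit[keep]; r_s <- r_s[keep]
    } else r_s <- numeric(0)
    footprints[[i]] <- tibble::tibble(
      retained_index = hit - 1L, physical_index = phys[hit],
      cx_px = ce$x_px, cy_px = ce$y_px, r_px = r_s)
  }

  # --- transforms -----------------------------------------------------------
  transforms <- vector("list", n)
  for (k in seq_len(n)) {
    transforms[[k]] <- if (k - 1L == ref_i) identity_transform() else
      random_transform_pair(cfg$image_shape, px,
                            max_rot_deg = cfg$affine_jitter[1],
                            max_trans_px = cfg$affine_jitter[2],
                            deform_max_px = cfg$deform_max_px)
  }

  # --- render + warp sections ----------------------------------------------
  sections <- vector("list", n)
  vessel_vox <- list()
  surface_rows <- list()
  for (k in seq_len(n)) {
    zq <- z_mid[k]
    tis <- tissue_mask_at(zq)
    af <- 60 + (cfg$background_level - 60) * tis +
      0.28 * cfg$background_level * af_noise[, , phys[k] + 1L] * tis
    chans <- list(AF = af)
    dapi <- matrix(0, nr, nc)
    marker_imgs <- stats::setNames(
      replicate(length(markers_all), matrix(0, nr, nc), simplify = FALSE),
      markers_all)
    # vessels into CD31
    kz <- phys[k] + 1L
    for (vv in vessels) {
      marker_imgs$CD31 <- render_disc(marker_imgs$CD31, vv$x[kz], vv$y[kz],
                                      vv$r, marker_amp)
      vox <- disc_pixels(vv$x[kz], vv$y[kz], vv$r, c(nr, nc))
      if (nrow(vox)) {
        vessel_vox[[length(vessel_vox) + 1L]] <- tibble::tibble(
          retained_index = k - 1L, physical_index = phys[k],
          row = vox$row, col = vox$col)
      }
    }
    # epidermis band into AE1 (contiguous epithelial structure)
    sy <- matrix(surf_y(zq), nr, nc, byrow = TRUE)
    band <- tis & row_idx < sy + band_px
    marker_imgs$AE1 <- marker_imgs$AE1 + marker_amp * band
    # nuclei
    for (i in seq_along(cells)) {
      fp <- footprints[[i]]
      j <- match(k - 1L, fp$retained_index)
      if (is.na(j)) next
      ce <- cells[[i]]
      dapi <- render_gaussian(dapi, ce$x_px, ce$y_px, 0.55 * fp$r_px[j],
                              dapi_amp)
      for (mk in ce$markers) {
        marker_imgs[[mk]] <- render_disc(marker_imgs[[mk]], ce$x_px,
                                         ce$y_px, 0.95 * fp$r_px[j],
                                         marker_amp)
      }
    }
    chans <- c(list(DAPI = dapi, AF = af), marker_imgs)
    warped <- lapply(chans, function(im) {
      quantize16(warp_section(im, transforms[[k]],
                              noise_sigma = cfg$noise_sigma,
                              pixel_size_um = px))
    })
    sections[[k]] <- section(warped, pixel_size_um = px,
                             retained_index = k - 1L,
                             physical_index = phys[k])
    surface_rows[[k]] <- tibble::tibble(
      retained_index = k - 1L, physical_index = phys[k],
      x_um = xs_px * px, y_um = surf_y(zq) * px, z_um = z_slab[k])
  }

  cells_tb <- if (length(cells)) {
    tibble::tibble(
      cell_id = vapply(cells, `[[`, integer(1), "cell_id"),
      phenotype = vapply(cells, `[[`, character(1), "phenotype"),
      x_um = vapply(cells, `[[`, numeric(1), "x_px") * px,
      y_um = vapply(cells, `[[`, numeric(1), "y_px") * px,
      z_um = vapply(cells, `[[`, numeric(1), "z_um"),
      radius_um = vapply(cells, `[[`, numeric(1), "r_um"),
      markers = lapply(cells, `[[`, "markers"),
      footprints = footprints)
  } else {
    tibble::tibble(cell_id = integer(0), phenotype = character(0),
                   x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                   radius_um = numeric(0), markers = list(),
                   footprints = list())
  }
  vessels_tb <- if (length(vessel_vox)) dplyr::bind_rows(vessel_vox) else
    tibble::tibble(retained_index = integer(0), physical_index = integer(0),
                   row = integer(0), col = integer(0))
  vessels_tb$x_um <- (vessels_tb$col - 1) * px
  vessels_tb$y_um <- (vessels_tb$row - 1) * px
  vessels_tb$z_um <- vessels_tb$physical_index * th

  truth <- structure(list(
    cells = cells_tb,
    vessels = vessels_tb,
    skin_surface = dplyr::bind_rows(surface_rows),
    transforms = transforms,
    section_map = tibble::tibble(retained_index = 0:(n - 1L),
                                 physical_index = phys,
                                 z_um = z_slab),
    reference_index = ref_i,
    config = cfg), class = "phantom_truth")
  list(sections = sections, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d sections, %d cells, %d vessel voxels\n",
              nrow(x$section_map), nrow(x$cells), nrow(x$vessels)))
  if (nrow(x$cells)) print(dplyr::count(x$cells, .data$phenotype))
  invisible(x)
}

#' Single-section marker phantom
#'
#' A lightweight phantom for benchmarking marker classification alone: one
#' section, `n_cells` nuclei on a plain tissue slab, a configurable fraction
#' truth-positive for one marker whose plateau sits `snr` noise-SDs above
#' background. No warping is applied.
#'
#' @param n_cells number of nuclei.
#' @param positive_fraction fraction of nuclei positive for the marker.
#' @param snr intensity separation in noise-SD units.
#' @param marker channel name to render (default `"CD68"`).
#' @param image_shape,pixel_size_um,noise_sigma,seed as in
#'   [phantom_config()].
#' @return list with `section` (a [section()] with DAPI, AF and the marker
#'   channel) and `truth` (tibble: `cell_id`, `x_um`, `y_um`, `radius_um`,
#'   `positive`).
#' @export
simulate_marker_section <- function(n_cells = 500L, positive_fraction = 0.4,
                                    snr = 6, marker = "CD68",
                                    image_shape = c(384L, 448L),
                                    pixel_size_um = 1, noise_sigma = 60,
                                    seed = 7L) {
  withr::with_seed(seed, {
    nr <- image_shape[1]; nc <- image_shape[2]
    margin <- 12L
    cand <- which(matrix(TRUE, nr - 2 * margin, nc - 2 * margin),
                  arr.ind = TRUE)
    cand <- cand + margin
    pts <- place_hardcore(n_cells, cand, 11, matrix(numeric(0), 0, 2),
                          "marker-phantom")
    r_um <- stats::runif(n_cells, 3.6, 5.2) * pixel_size_um
    positive <- seq_len(n_cells) %in%
      sample.int(n_cells, round(positive_fraction * n_cells))
    noise_ref <- if (noise_sigma > 0) noise_sigma else 1
    dapi <- matrix(0, nr, nc)
    mk <- matrix(0, nr, nc)
    af <- matrix(500, nr, nc)
    for (i in seq_len(n_cells)) {
      r_px <- r_um[i] / pixel_size_um
      dapi <- render_gaussian(dapi, pts[i, 1], pts[i, 2], 0.55 * r_px,
                              10 * noise_ref)
      if (positive[i]) {
        mk <- render_disc(mk, pts[i, 1], pts[i, 2], 0.95 * r_px,
                          snr * noise_ref)
      }
    }
    addn <- function(im) {
      if (noise_sigma > 0) {
        im <- im + matrix(stats::rnorm(length(im), 0, noise_sigma), nrow(im))
      }
      quantize16(im)
    }
    chans <- stats::setNames(list(addn(dapi), addn(af), addn(mk)),
                             c("DAPI", "AF", marker))
    list(section = section(chans, pixel_size_um, retained_index = 0L),
         truth = tibble::tibble(cell_id = seq_len(n_cells),
                                x_um = pts[, 1] * pixel_size_um,
                                y_um = pts[, 2] * pixel_size_um,
                                radius_um = r_um,
                                positive = positive))
  })
}
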