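#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two binary rasters or volumes;
#' the standard overlap QC for registered tissue masks.
#'
#' @param a,b logical (or 0/1 numeric) arrays of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) stop("both masks are empty", call. = FALSE)
  2 * sum(a & b) / (sa + sb)
}

#' Normalized cross correlation
#'
#' Pearson correlation of co-located intensities, optionally restricted to
#' a mask; the registration-quality metric used between adjacent
#' autofluorescence sections.
#'
#' @param a,b numeric arrays of the same shape.
#' @param mask optional logical array.
#' @return Scalar in `[-1, 1]`.
#' @export
ncc <- function(a, b, mask = NULL) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch", call. = FALSE)
  va <- if (is.null(mask)) as.vector(a) else a[mask]
  vb <- if (is.null(mask)) as.vector(b) else b[mask]
  if (length(va) < 2 || stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("constant image within mask: NCC undefined", call. = FALSE)
  }
  stats::cor(va, vb)
}

#' Normalized mutual information
#'
#' `(H(A) + H(B)) / H(A, B)` from a joint intensity histogram with linear
#' (soft) bin assignment; ranges from 1 (independent) to 2 (perfectly
#' predictable). Used as the similarity measure of the deformable and 3D
#' refinement registrations.
#'
#' @param a,b numeric arrays of the same shape.
#' @param mask optional logical array.
#' @param bins number of histogram bins per axis (default 32).
#' @return Scalar NMI.
#' @export
nmi <- function(a, b, mask = NULL, bins = 32L) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch", call. = FALSE)
  va <- if (is.null(mask)) as.vector(a) else a[mask]
  vb <- if (is.null(mask)) as.vector(b) else b[mask]
  soft_bin <- function(v) {
    rng <- range(v)
    u <- if (diff(rng) == 0) rep(0, length(v)) else
      (v - rng[1]) / diff(rng) * (bins - 1)
    i0 <- pmin(floor(u), bins - 2)
    list(i = i0 + 1L, w = u - i0)
  }
  ba <- soft_bin(va); bb <- soft_bin(vb)
  jt <- numeric(bins * bins)
  for (da in 0:1) {
    for (db in 0:1) {
      idx <- (ba$i + da) + (bb$i + db - 1L) * bins
      w <- (if (da == 0) 1 - ba$w else ba$w) *
           (if (db == 0) 1 - bb$w else bb$w)
      acc <- rowsum(w, idx)
      jt[as.integer(rownames(acc))] <- jt[as.integer(rownames(acc))] + acc
    }
  }
  p <- jt / sum(jt)
  pa <- rowSums(matrix(p, bins)); pb <- colSums(matrix(p, bins))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hab <- ent(p)
  if (hab == 0) return(2)
  (ent(pa) + ent(pb)) / hab
}

# ---- fast block NCC ---------------------------------------------------------

# Full NCC map of template `t` against image window `f` (valid placements),
# FFT cross-correlation + running-sum local statistics.
fast_ncc_map <- function(f, t) {
  B1 <- nrow(t); B2 <- ncol(t)
  H <- nrow(f); W <- ncol(f)
  if (H < B1 || W < B2) return(NULL)
  t0 <- t - mean(t)
  st <- sqrt(sum(t0^2))
  if (st < 1e-12) return(NULL)
  ph <- H + B1 - 1L; pw <- W + B2 - 1L
  fp <- matrix(0, ph, pw); fp[1:H, 1:W] <- f
  tp <- matrix(0, ph, pw); tp[1:B1, 1:B2] <- t0
  cc <- Re(stats::fft(stats::fft(fp) * Conj(stats::fft(tp)),
                      inverse = TRUE)) / (ph * pw)
  cc <- cc[1:(H - B1 + 1L), 1:(W - B2 + 1L), drop = FALSE]
  # windowed sums of f and f^2 via integral images
  ii <- function(x) {
    s <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed integral
    s <- t(s)
    s <- rbind(0, cbind(0, s))
    s[(B1 + 1):(H + 1), (B2 + 1):(W + 1), drop = FALSE] -
      s[1:(H - B1 + 1), (B2 + 1):(W + 1), drop = FALSE] -
      s[(B1 + 1):(H + 1), 1:(W - B2 + 1), drop = FALSE] +
      s[1:(H - B1 + 1), 1:(W - B2 + 1), drop = FALSE]
  }
  S1 <- ii(f); S2 <- ii(f * f)
  n <- B1 * B2
  denom <- st * sqrt(pmax(S2 - S1^2 / n, 0))
  out <- cc / denom
  out[denom < 1e-9] <- NA_real_
  out
}

# Whole-image translation estimate: one big NCC search of the central
# reference crop inside the moving image. Large support makes the estimate
# robust even when fine texture is only partially shared.
global_translation <- function(ref, mov, mask = NULL,
                               max_shift_px = 48L) {
  nr <- nrow(ref); nc <- ncol(ref)
  bb <- if (!is.null(mask) && any(mask)) {
    w <- which(mask, arr.ind = TRUE)
    c(min(w[, 1]), max(w[, 1]), min(w[, 2]), max(w[, 2]))
  } else c(1L, nr, 1L, nc)
  mr <- max(8L, (bb[2] - bb[1]) %/% 6L)
  mc <- max(8L, (bb[4] - bb[3]) %/% 6L)
  r0 <- bb[1] + mr; r1 <- bb[2] - mr
  c0 <- bb[3] + mc; c1 <- bb[4] - mc
  if (r1 - r0 < 16L || c1 - c0 < 16L) return(c(0, 0))
  tmpl <- ref[r0:r1, c0:c1]
  wr <- max(1L, r0 - max_shift_px):min(nr, r1 + max_shift_px)
  wc <- max(1L, c0 - max_shift_px):min(nc, c1 + max_shift_px)
  m <- fast_ncc_map(mov[wr, wc, drop = FALSE], tmpl)
  if (is.null(m) || all(is.na(m))) return(c(0, 0))
  k <- which.max(m)
  ur <- (k - 1L) %% nrow(m) + 1L
  uc <- (k - 1L) %/% nrow(m) + 1L
  c((wc[1] + uc - 1L) - c0, (wr[1] + ur - 1L) - r0)   # (dx, dy)
}

shift_image <- function(img, dx, dy) {
  out <- matrix(0, nrow(img), ncol(img))
  nr <- nrow(img); nc <- ncol(img)
  sr <- max(1L, 1L - dy):min(nr, nr - dy)
  sc <- max(1L, 1L - dx):min(nc, nc - dx)
  if (length(sr) == 0L || length(sc) == 0L) return(out)
  out[sr, sc] <- img[sr + dy, sc + dx]
  out
}

# Block-matching correspondences between ref and mov (same shape).
# Returns tibble: ref-block centre (px), displacement (px), peak NCC.
block_correspondences <- function(ref, mov, mask = NULL,
                                  block_size_px = 64L,
                                  search_radius_px = 32L,
                                  stride_px = NULL, min_coverage = 0.25) {
  B <- as.integer(block_size_px)
  R <- as.integer(search_radius_px)
  stride <- as.integer(stride_px %||% max(1L, B %/% 2L))
  nr <- nrow(ref); nc <- ncol(ref)
  if (nr < B || nc < B) return(NULL)
  rows0 <- unique(pmin(seq(1L, nr - B + 1L, by = stride), nr - B + 1L))
  cols0 <- unique(pmin(seq(1L, nc - B + 1L, by = stride), nc - B + 1L))
  out <- list()
  for (r0 in rows0) {
    for (c0 in cols0) {
      if (!is.null(mask)) {
        cov <- mean(mask[r0:(r0 + B - 1L), c0:(c0 + B - 1L)])
        if (cov < min_coverage) next
      }
      tblk <- ref[r0:(r0 + B - 1L), c0:(c0 + B - 1L)]
      wr <- max(1L, r0 - R):min(nr, r0 + B - 1L + R)
      wc <- max(1L, c0 - R):min(nc, c0 + B - 1L + R)
      m <- fast_ncc_map(mov[wr, wc, drop = FALSE], tblk)
      if (is.null(m) || all(is.na(m))) next
      k <- which.max(m)
      ur <- (k - 1L) %% nrow(m) + 1L
      uc <- (k - 1L) %/% nrow(m) + 1L
      # parabolic sub-pixel refinement of the peak, per axis
      subpx <- function(vm1, v0, vp1) {
        den <- vm1 - 2 * v0 + vp1
        if (!is.finite(den) || den >= 0) return(0)
        max(-0.5, min(0.5, 0.5 * (vm1 - vp1) / den))
      }
      fr <- if (ur > 1L && ur < nrow(m)) {
        subpx(m[ur - 1L, uc], m[ur, uc], m[ur + 1L, uc])
      } else 0
      fc <- if (uc > 1L && uc < ncol(m)) {
        subpx(m[ur, uc - 1L], m[ur, uc], m[ur, uc + 1L])
      } else 0
      out[[length(out) + 1L]] <- tibble::tibble(
        cx = c0 - 1 + (B - 1) / 2, cy = r0 - 1 + (B - 1) / 2,
        dx = (wc[1] + uc - 1L) - c0 + fc, dy = (wr[1] + ur - 1L) - r0 + fr,
        peak = m[k])
    }
  }
  if (length(out) == 0L) return(NULL)
  dplyr::bind_rows(out)
}

#' Block-matching affine registration
#'
#' Establishes sparse correspondences between a masked reference AF image
#' and a moving AF image by exhaustive normalized-cross-correlation search
#' of grid blocks within a search radius, then fits a full 6-parameter
#' affine by trimmed least squares (the worst 20% of residual
#' correspondences are dropped and the fit repeated). The returned 2x3
#' matrix maps reference-frame points (µm) into the moving frame.
#'
#' @param ref,mov numeric matrices (masked AF; same shape).
#' @param mask optional logical matrix (reference tissue mask) used to skip
#'   low-coverage blocks.
#' @param block_size_px,search_radius_px,stride_px block grid geometry
#'   (defaults 64, 32, block/2).
#' @param min_blocks minimum usable correspondences (default 6).
#' @param min_peak correspondences with NCC peak below this are discarded.
#' @param trim fraction of worst residuals dropped before the refit.
#' @param refine number of refinement passes: after the first fit the
#'   moving image is resampled and matched again with smaller blocks,
#'   which removes the rotation bias of translation-only block search.
#' @param pixel_size_um pixel size.
#' @return 2x3 affine matrix (µm frame).
#' @export
block_matching_affine <- function(ref, mov, mask = NULL,
                                  block_size_px = 64L, search_radius_px = 32L,
                                  stride_px = NULL, min_blocks = 6L,
                                  min_peak = 0.2, trim = 0.2, refine = 1L,
                                  pixel_size_um = 1) {
  assert_image(ref); assert_image(mov)
  assert_same_shape(ref, mov)
  if (identical(ref, mov)) return(diag_affine())
  # stage 0: global translation from one large central block, so the
  # per-block search can stay local (robust against repetitive texture)
  g <- global_translation(ref, mov, mask,
                          max_shift_px = as.integer(search_radius_px) + 16L)
  mov0 <- if (any(g != 0)) shift_image(mov, g[1], g[2]) else mov
  bc <- block_correspondences(ref, mov0, mask, block_size_px,
                              min(as.integer(search_radius_px), 12L),
                              stride_px)
  if (!is.null(bc)) bc <- bc[!is.na(bc$peak) & bc$peak >= min_peak, ]
  if (is.null(bc) || nrow(bc) < min_blocks) {
    stop("insufficient texture: fewer than min_blocks usable blocks",
         call. = FALSE)
  }
  fit_aff <- function(d) {
    X <- cbind(d$cx, d$cy, 1)
    cf <- qr.solve(X, cbind(d$cx + d$dx, d$cy + d$dy))
    t(cf)   # 2 x 3
  }
  A <- fit_aff(bc)
  # iterated trimming: outlier correspondences (mask-edge blocks, repeats)
  # are far off the consensus affine and are discarded over a few rounds
  kept <- bc
  for (round in 1:3) {
    if (nrow(kept) <= min_blocks) break
    pred <- cbind(kept$cx, kept$cy, 1) %*% t(A)
    res <- sqrt((pred[, 1] - (kept$cx + kept$dx))^2 +
                  (pred[, 2] - (kept$cy + kept$dy))^2)
    thr <- max(stats::quantile(res, 1 - trim), 3 * stats::median(res), 0.75)
    keep <- res <= thr
    if (all(keep) || sum(keep) < min_blocks) break
    kept <- kept[keep, ]
    A <- fit_aff(kept)
  }
  A[, 3] <- A[, 3] + g                 # undo the stage-0 shift
  # refinement passes against the A-resampled moving image with smaller
  # blocks: residual rotation/scale within a block is then negligible
  for (pass in seq_len(refine)) {
    t_cur <- transform_pair(A)
    mov_r <- apply_transform_image(mov, t_cur, 1, "linear")
    b2 <- max(16L, as.integer(block_size_px) %/% 2L)
    bc2 <- block_correspondences(ref, mov_r, mask, b2,
                                 search_radius_px = 6L,
                                 stride_px = max(8L, b2 %/% 2L))
    if (is.null(bc2)) break
    bc2 <- bc2[!is.na(bc2$peak) & bc2$peak >= min_peak, ]
    if (nrow(bc2) < min_blocks) break
    A2 <- fit_aff(bc2)
    kept <- bc2
    for (round in 1:3) {
      pred <- cbind(kept$cx, kept$cy, 1) %*% t(A2)
      res <- sqrt((pred[, 1] - (kept$cx + kept$dx))^2 +
                    (pred[, 2] - (kept$cy + kept$dy))^2)
      thr <- max(stats::quantile(res, 1 - trim), 3 * stats::median(res),
                 0.5)
      keep <- res <= thr
      if (all(keep) || sum(keep) < min_blocks) break
      kept <- kept[keep, ]
      A2 <- fit_aff(kept)
    }
    # compose: T(p) = A(A2(p))
    A <- cbind(A[, 1:2] %*% A2[, 1:2], A[, 1:2] %*% A2[, 3] + A[, 3])
  }
  # convert px-frame affine to µm frame (uniform pixel size: linear part
  # unchanged, translation scales)
  A[, 3] <- A[, 3] * pixel_size_um
  A
}

#' B-spline deformable registration
#'
#' Refines an affine pre-alignment with a cubic B-spline displacement
#' field. Control-point displacements are estimated multi-resolution
#' (default 64 then 32 px spacing): at each iteration local block matching
#' against the current warp proposes correspondences, the increment is
#' fitted to the control grid by weighted ridge least squares, and the step
#' is accepted at the largest scale that does not decrease the normalized
#' mutual information between the reference and the warped image. The
#' field is bounded by `max_disp_px`.
#'
#' @param ref numeric matrix (masked reference AF).
#' @param mov numeric matrix, already affine-aligned to `ref`.
#' @param mask optional logical matrix for block coverage.
#' @param grid_spacing_px control-point spacings, coarse to fine
#'   (default `c(64, 32)`; all >= 4).
#' @param max_disp_px bound on the displacement magnitude (default 30).
#' @param nmi_bins histogram bins for the NMI check.
#' @param max_iter iterations per resolution level (default 3).
#' @param pixel_size_um pixel size.
#' @return list: `grid` (B-spline control grid, µm), `nmi_before`,
#'   `nmi_after`, `converged`, `iterations`.
#' @export
bspline_deformable <- function(ref, mov, mask = NULL,
                               grid_spacing_px = c(64, 32),
                               max_disp_px = 30, nmi_bins = 32L,
                               max_iter = 3L, pixel_size_um = 1) {
  assert_image(ref); assert_image(mov)
  assert_same_shape(ref, mov)
  if (any(grid_spacing_px < 4)) stop("grid spacing must be >= 4 px",
                                     call. = FALSE)
  extent <- c(ncol(ref), nrow(ref)) * pixel_size_um
  nmi0 <- nmi(ref, mov, mask, nmi_bins)
  best_nmi <- nmi0
  cur <- NULL      # current control grid (µm)
  iterations <- 0L
  warp_with <- function(grid) {
    if (is.null(grid)) return(mov)
    t <- transform_pair(diag_affine(), grid)
    apply_transform_image(mov, t, pixel_size_um, "linear")
  }
  clamp_grid <- function(g) {
    dense <- bspline_displacement_grid(g, dim(ref), pixel_size_um)
    mx <- max(sqrt(dense$dx^2 + dense$dy^2))
    bound <- max_disp_px * pixel_size_um
    if (mx > bound) {
      g$dx <- g$dx * bound / mx
      g$dy <- g$dy * bound / mx
    }
    g
  }
  for (sp in grid_spacing_px) {
    # re-express the current field on this level's grid
    if (!is.null(cur) && cur$spacing_um != sp * pixel_size_um) {
      sub <- pmax(1L, as.integer(sp) %/% 4L)
      rr <- seq(1L, nrow(ref), by = sub); cc <- seq(1L, ncol(ref), by = sub)
      pts <- cbind(rep((cc - 1) * pixel_size_um, each = length(rr)),
                   rep((rr - 1) * pixel_size_um, times = length(cc)))
      d <- bspline_displacement_at(cur, pts)
      cur <- fit_bspline_grid(pts, d, extent, sp * pixel_size_um,
                              lambda = 1e-3)
    }
    for (it in seq_len(max_iter)) {
      iterations <- iterations + 1L
      warped <- warp_with(cur)
      b <- as.integer(min(max(16L, sp %/% 2L), min(dim(ref)) %/% 3L))
      bc <- block_correspondences(ref, warped, mask, block_size_px = b,
                                  search_radius_px = min(10L, max_disp_px),
                                  stride_px = max(4L, b %/% 2L))
      if (is.null(bc)) break
      bc <- bc[!is.na(bc$peak) & bc$peak > 0.1, ]
      if (nrow(bc) < 4L) break
      pts <- cbind(bc$cx, bc$cy) * pixel_size_um
      disp <- cbind(bc$dx, bc$dy) * pixel_size_um
      inc <- fit_bspline_grid(pts, disp, extent, sp * pixel_size_um,
                              w = pmax(bc$peak, 0), lambda = 5e-2)
      improved <- FALSE
      for (alpha in c(1, 0.5, 0.25)) {
        cand <- if (is.null(cur)) {
          g <- inc; g$dx <- alpha * g$dx; g$dy <- alpha * g$dy; g
        } else {
          g <- cur
          g$dx <- g$dx + alpha * inc$dx
          g$dy <- g$dy + alpha * inc$dy
          g
        }
        cand <- clamp_grid(cand)
        v <- nmi(ref, warp_with(cand), mask, nmi_bins)
        if (v > best_nmi + 1e-9) {
          cur <- cand
          best_nmi <- v
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
  }
  if (is.null(cur)) {
    cur <- bspline_grid_skeleton(extent,
                                 utils::tail(grid_spacing_px, 1) *
                                   pixel_size_um)
  }
  list(grid = cur, nmi_before = nmi0, nmi_after = best_nmi,
       converged = best_nmi >= nmi0 - 1e-9, iterations = iterations)
}

#' Register a serial-section stack to a reference section
#'
#' Every section's masked autofluorescence image is registered to the
#' chosen reference section: block-matching affine first, then B-spline
#' deformable refinement. The reference receives an identity transform.
#' QC reports the Dice coefficient of each registered tissue mask against
#' the reference mask and the NCC between adjacent registered AF images
#' (within the intersection of their masks).
#'
#' @param sections list of [section()] objects (AF channel required).
#' @param reference_index retained index of the reference section
#'   (default: middle of the stack).
#' @param closing_radius_px AF-mask closing radius for sections lacking a
#'   mask.
#' @param block_size_px,search_radius_px affine block-matching geometry.
#' @param grid_spacing_px deformable control spacings (coarse to fine).
#' @param max_disp_px deformable displacement bound.
#' @param deformable set `FALSE` for affine-only registration.
#' @return Object of class `mx_registration`: `transforms` (list of
#'   [transform_pair()]), `qc` (per-section tibble: `retained_index`,
#'   `dsc`, `nmi_before`, `nmi_after`, `converged`, `iterations`),
#'   `adjacent` (tibble: `index_a`, `index_b`, `ncc`), `reference_index`.
#' @export
register_stack <- function(sections, reference_index = NULL,
                           closing_radius_px = 5,
                           block_size_px = 64L, search_radius_px = 32L,
                           grid_spacing_px = c(64, 32), max_disp_px = 30,
                           deformable = TRUE) {
  stopifnot(length(sections) >= 1L)
  n <- length(sections)
  ridx <- vapply(sections, `[[`, integer(1), "retained_index")
  ord <- order(ridx)
  sections <- sections[ord]
  ridx <- ridx[ord]
  ref_i <- reference_index %||% ridx[(n + 1L) %/% 2L]
  kref <- match(ref_i, ridx)
  if (is.na(kref)) stop("reference_index not found in stack", call. = FALSE)
  px <- sections[[1]]$pixel_size_um

  masks <- lapply(sections, function(s) {
    s$af_mask %||% compute_af_mask(section_channel(s, "AF"),
                                   closing_radius_px)
  })
  afm <- lapply(seq_len(n), function(k) {
    af <- section_channel(sections[[k]], "AF")
    normalize_zmuv(af)[] * masks[[k]]
  })

  ref_img <- afm[[kref]]
  ref_mask <- masks[[kref]]
  transforms <- vector("list", n)
  qc_rows <- vector("list", n)
  reg_af <- vector("list", n)
  reg_mask <- vector("list", n)
  for (k in seq_len(n)) {
    if (k == kref) {
      transforms[[k]] <- identity_transform()
      reg_af[[k]] <- section_channel(sections[[k]], "AF")
      reg_mask[[k]] <- ref_mask
      qc_rows[[k]] <- tibble::tibble(retained_index = ridx[k], dsc = 1,
                                     nmi_before = NA_real_,
                                     nmi_after = NA_real_,
                                     converged = TRUE, iterations = 0L)
      next
    }
    A <- tryCatch(
      block_matching_affine(ref_img, afm[[k]], mask = ref_mask,
                            block_size_px = block_size_px,
                            search_radius_px = search_radius_px,
                            pixel_size_um = px),
      error = function(e) {
        stop(sprintf("affine registration failed for section %d: %s",
                     ridx[k], conditionMessage(e)), call. = FALSE)
      })
    t_aff <- transform_pair(A)
    mov_aligned <- apply_transform_image(afm[[k]], t_aff, px, "linear")
    if (deformable) {
      bs <- bspline_deformable(ref_img, mov_aligned, mask = ref_mask,
                               grid_spacing_px = grid_spacing_px,
                               max_disp_px = max_disp_px,
                               pixel_size_um = px)
      # compose: T(p) = A(p + U(p)) = A p + A_L U(p)
      g <- bs$grid
      AL <- A[, 1:2]
      dx2 <- AL[1, 1] * g$dx + AL[1, 2] * g$dy
      dy2 <- AL[2, 1] * g$dx + AL[2, 2] * g$dy
      g$dx <- dx2; g$dy <- dy2
      transforms[[k]] <- transform_pair(A, g)
      nmi_b <- bs$nmi_before; nmi_a <- bs$nmi_after
      conv <- bs$converged; iters <- bs$iterations
    } else {
      transforms[[k]] <- t_aff
      nmi_b <- NA_real_; nmi_a <- NA_real_; conv <- TRUE; iters <- 0L
    }
    reg_af[[k]] <- apply_transform_image(section_channel(sections[[k]], "AF"),
                                         transforms[[k]], px, "linear")
    reg_mask[[k]] <- apply_transform_image(
      matrix(as.numeric(masks[[k]]), nrow(ref_mask)), transforms[[k]], px,
      "nearest") > 0.5
    qc_rows[[k]] <- tibble::tibble(
      retained_index = ridx[k],
      dsc = dice(reg_mask[[k]], ref_mask),
      nmi_before = nmi_b, nmi_after = nmi_a,
      converged = conv, iterations = iters)
  }
  adjacent <- if (n > 1L) {
    purrr::map_dfr(seq_len(n - 1L), function(k) {
      m <- reg_mask[[k]] & reg_mask[[k + 1L]]
      tibble::tibble(index_a = ridx[k], index_b = ridx[k + 1L],
                     ncc = if (sum(m) > 2) ncc(reg_af[[k]],
                                               reg_af[[k + 1L]], m)
                           else NA_real_)
    })
  } else {
    tibble::tibble(index_a = integer(0), index_b = integer(0),
                   ncc = numeric(0))
  }
  structure(list(transforms = stats::setNames(transforms, ridx),
                 qc = dplyr::bind_rows(qc_rows),
                 adjacent = adjacent,
                 reference_index = ref_i),
            class = "mx_registration")
}

#' @export
print.mx_registration <- function(x, ...) {
  cat(sprintf("<mx_registration> %d sections, reference %d\n",
              nrow(x$qc), x$reference_index))
  cat(sprintf("  mean DSC %.3f; mean adjacent NCC %.3f\n",
              mean(x$qc$dsc), mean(x$adjacent$ncc, na.rm = TRUE)))
  invisible(x)
}

# trilinear sampling of a 3D array at fractional voxel coords (0-based)
trilinear_sample <- function(vol, x, y, z, fill = 0) {
  d <- dim(vol)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- rep(fill, length(x))
  inb <- x0 >= 0 & x0 <= d[2] - 1 & y0 >= 0 & y0 <= d[1] - 1 &
    z0 >= 0 & z0 <= d[3] - 1
  if (!any(inb)) return(out)
  gi <- function(r, c, s) vol[cbind(r, c, s)]
  r0 <- y0[inb] + 1L; c0 <- x0[inb] + 1L; s0 <- z0[inb] + 1L
  r1 <- pmin(r0 + 1L, d[1]); c1 <- pmin(c0 + 1L, d[2])
  s1 <- pmin(s0 + 1L, d[3])
  wx <- fx[inb]; wy <- fy[inb]; wz <- fz[inb]
  v <- (1 - wz) * ((1 - wy) * ((1 - wx) * gi(r0, c0, s0) +
                                 wx * gi(r0, c1, s0)) +
                     wy * ((1 - wx) * gi(r1, c0, s0) +
                             wx * gi(r1, c1, s0))) +
    wz * ((1 - wy) * ((1 - wx) * gi(r0, c0, s1) + wx * gi(r0, c1, s1)) +
            wy * ((1 - wx) * gi(r1, c0, s1) + wx * gi(r1, c1, s1)))
  out[inb] <- v
  out
}

#' Refine a reconstructed volume against a 3D reference
#'
#' Estimates the 3D affine that maximises normalized mutual information
#' between the reconstructed AF volume and an externally acquired reference
#' volume (e.g. a micro-CT scan of the block). Applying the result globally
#' to all cells and masks mitigates the cumulative drift of serial-section
#' registration, in which curved structures are incorrectly straightened.
#'
#' @param recon 3D numeric array (row, col, slab) — the reconstructed
#'   volume; treated as the fixed frame.
#' @param reference 3D numeric array — the reference volume (same voxel
#'   grid spacing).
#' @param spacing_um `c(dx, dy, dz)` voxel spacing in µm.
#' @param bins NMI histogram bins.
#' @param maxit optimiser iteration budget.
#' @param subsample use every k-th voxel in-plane for the metric
#'   (default 2).
#' @return list: `affine` (3x4 matrix, µm, fixed-to-moving), `nmi_before`,
#'   `nmi_after`.
#' @export
refine_to_reference_volume <- function(recon, reference, spacing_um,
                                       bins = 32L, maxit = 600L,
                                       subsample = 2L) {
  stopifnot(length(dim(recon)) == 3, length(dim(reference)) == 3,
            length(spacing_um) == 3)
  if (sum(recon != 0) == 0 || sum(reference != 0) == 0) {
    stop("empty volume", call. = FALSE)
  }
  d <- dim(recon)
  rr <- seq(1L, d[1], by = subsample)
  cc <- seq(1L, d[2], by = subsample)
  ss <- seq_len(d[3])
  grid <- expand.grid(y = rr - 1L, x = cc - 1L, z = ss - 1L)
  fixed_vals <- recon[cbind(grid$y + 1L, grid$x + 1L, grid$z + 1L)]
  pu <- cbind(grid$x * spacing_um[1], grid$y * spacing_um[2],
              grid$z * spacing_um[3])
  metric <- function(par) {
    M <- diag(3) + matrix(par[1:9], 3, 3)
    tr <- par[10:12]
    q <- pu %*% t(M)
    xs <- (q[, 1] + tr[1]) / spacing_um[1]
    ys <- (q[, 2] + tr[2]) / spacing_um[2]
    zs <- (q[, 3] + tr[3]) / spacing_um[3]
    inb <- xs >= 0 & xs <= dim(reference)[2] - 1 &
      ys >= 0 & ys <= dim(reference)[1] - 1 &
      zs >= 0 & zs <= dim(reference)[3] - 1
    if (mean(inb) < 0.05) return(1)    # near-total non-overlap
    mv <- trilinear_sample(reference, xs[inb], ys[inb], zs[inb])
    nmi_vec(fixed_vals[inb], mv, bins)
  }
  nmi_before <- metric(rep(0, 12))
  if (nmi_before == 1) {
    stop("volumes do not overlap at initialisation", call. = FALSE)
  }
  # Nelder-Mead with simplex restarts: restarting from the incumbent
  # rebuilds the simplex and reliably escapes premature collapse in 12-D
  par <- rep(0, 12)
  val <- -nmi_before
  for (run in 1:4) {
    opt <- stats::optim(par, function(p) -metric(p),
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10,
                                       parscale = c(rep(0.03, 9),
                                                    rep(2, 3))))
    improved <- opt$value < val - 1e-7
    par <- opt$par
    val <- opt$value
    if (!improved) break
  }
  M <- diag(3) + matrix(par[1:9], 3, 3)
  list(affine = cbind(M, par[10:12]),
       nmi_before = nmi_before, nmi_after = -val)
}

# NMI between two numeric vectors (soft binning), shared with nmi()
nmi_vec <- function(a, b, bins = 32L) {
  nmi(matrix(a, ncol = 1), matrix(b, ncol = 1), bins = bins)
}
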