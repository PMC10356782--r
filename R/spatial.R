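#' Distance from cells to the nearest structure voxel
#'
#' Euclidean distance (µm) from each cell centroid to the nearest
#' structure-positive voxel centre — the vasculature-based common
#' coordinate framework primitive. In `"2D"` mode candidates are restricted
#' to the cell's own section and the distance is in-plane; in `"3D"` mode
#' all structure voxels compete, so the 3D distance can never exceed the
#' same-section 2D distance. The search uses the axis-pruning filter:
#' candidates whose x, y or z axis offset already exceeds the current
#' minimum are skipped; the result is identical to exhaustive search, with
#' ties broken toward the lexicographically smallest `(z, y, x)` witness.
#'
#' @param cells tibble with `cell_id`, `x_um`, `y_um` and, for 3D/section
#'   lookup, `z_um` and/or `retained_index`; a `phenotype` column is
#'   carried through.
#' @param structure tibble of structure voxel centres: `x_um`, `y_um`,
#'   `z_um`, and `retained_index` (needed for 2D mode).
#' @param mode `"2D"` or `"3D"`.
#' @return Tibble: `cell_id`, `phenotype` (if present), `distance_um`,
#'   witness coordinates `nearest_x_um`, `nearest_y_um`, `nearest_z_um`,
#'   and `no_target_in_section` (2D mode flag; flagged records carry `NA`
#'   distance and are excluded from summaries).
#' @export
nearest_structure_distance <- function(cells, structure,
                                       mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  if (nrow(structure) == 0L) stop("structure voxel set is empty",
                                  call. = FALSE)
  n <- nrow(cells)
  out_d <- rep(NA_real_, n)
  wx <- rep(NA_real_, n); wy <- rep(NA_real_, n); wz <- rep(NA_real_, n)
  flag <- rep(FALSE, n)
  if (mode == "2D") {
    split_idx <- split(seq_len(nrow(structure)), structure$retained_index)
  }
  for (i in seq_len(n)) {
    if (mode == "2D") {
      key <- as.character(cells$retained_index[i])
      idx <- split_idx[[key]]
      if (is.null(idx)) {
        flag[i] <- TRUE
        next
      }
      sx <- structure$x_um[idx]; sy <- structure$y_um[idx]
      sz <- structure$z_um[idx]
      dx <- sx - cells$x_um[i]; dy <- sy - cells$y_um[i]
      dz <- rep(0, length(idx))
    } else {
      sx <- structure$x_um; sy <- structure$y_um; sz <- structure$z_um
      dx <- sx - cells$x_um[i]; dy <- sy - cells$y_um[i]
      dz <- sz - cells$z_um[i]
    }
    # axis-pruning filter: establish a current minimum from a coarse
    # subsample, discard every candidate whose per-axis offset exceeds it,
    # then finish exactly on the survivors
    probe <- seq(1L, length(dx), by = max(1L, length(dx) %/% 64L))
    dmin <- sqrt(min(dx[probe]^2 + dy[probe]^2 + dz[probe]^2))
    keep <- which(abs(dx) <= dmin & abs(dy) <= dmin & abs(dz) <= dmin)
    d2 <- dx[keep]^2 + dy[keep]^2 + dz[keep]^2
    # lexicographic (z, y, x) witness among ties
    ord <- order(d2, sz[keep], sy[keep], sx[keep])
    j <- keep[ord[1]]
    out_d[i] <- sqrt(d2[ord[1]])
    wx[i] <- sx[j]; wy[i] <- sy[j]; wz[i] <- sz[j]
  }
  res <- tibble::tibble(cell_id = cells$cell_id, distance_um = out_d,
                        nearest_x_um = wx, nearest_y_um = wy,
                        nearest_z_um = wz, no_target_in_section = flag)
  if ("phenotype" %in% names(cells)) {
    res <- tibble::add_column(res, phenotype = cells$phenotype,
                              .after = "cell_id")
  }
  res
}

#' Paired 2D/3D vessel distances
#'
#' Convenience wrapper computing, for each cell, the same-section in-plane
#' distance and the full-volume 3D distance to the structure; by
#' construction `d3d_um <= d2d_um` wherever both are defined.
#'
#' @inheritParams nearest_structure_distance
#' @return Tibble with `cell_id`, `phenotype` (if present), `d2d_um`,
#'   `d3d_um` and the 2D flag.
#' @export
distance_records <- function(cells, structure) {
  d2 <- nearest_structure_distance(cells, structure, mode = "2D")
  d3 <- nearest_structure_distance(cells, structure, mode = "3D")
  out <- tibble::tibble(cell_id = d2$cell_id,
                        d2d_um = d2$distance_um,
                        d3d_um = d3$distance_um,
                        no_target_in_section = d2$no_target_in_section)
  if ("phenotype" %in% names(d2)) {
    out <- tibble::add_column(out, phenotype = d2$phenotype,
                              .after = "cell_id")
  }
  out
}

#' Distance from marker-positive cells to the skin surface
#'
#' Each 3D cell centroid is projected to its nearest retained section and
#' the in-plane distance to that section's skin-surface boundary is
#' reported (the UV damage/repair and proliferation markers p53, DDB2 and
#' Ki67 are referenced to the surface this way). Ties between surface
#' points resolve to the lexicographically smallest `(y, x)` witness.
#'
#' @param cells tibble with `cell_id`, `x_um`, `y_um`, `z_um`.
#' @param surface tibble of per-section boundary points: `retained_index`,
#'   `x_um`, `y_um`.
#' @param section_map tibble with `retained_index` and `z_um`.
#' @return Tibble: `cell_id`, `retained_index` (section used),
#'   `distance_um`, `nearest_x_um`, `nearest_y_um`.
#' @export
distance_to_skin_surface <- function(cells, surface, section_map) {
  if (nrow(surface) == 0L) stop("no surface points in any section",
                                call. = FALSE)
  sm <- section_map[order(section_map$retained_index), ]
  surf_split <- split(seq_len(nrow(surface)), surface$retained_index)
  purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    zc <- cells$z_um[i]
    # nearest retained section (ties -> smaller z)
    k <- order(abs(sm$z_um + 0 - zc), sm$z_um)[1]
    ri <- sm$retained_index[k]
    idx <- surf_split[[as.character(ri)]]
    if (is.null(idx)) {
      stop(sprintf("no surface points in section %d", ri), call. = FALSE)
    }
    dx <- surface$x_um[idx] - cells$x_um[i]
    dy <- surface$y_um[idx] - cells$y_um[i]
    d2 <- dx^2 + dy^2
    ord <- order(d2, surface$y_um[idx], surface$x_um[idx])
    j <- idx[ord[1]]
    tibble::tibble(cell_id = cells$cell_id[i], retained_index = ri,
                   distance_um = sqrt(d2[ord[1]]),
                   nearest_x_um = surface$x_um[j],
                   nearest_y_um = surface$y_um[j])
  })
}

#' Immune-cell cluster density
#'
#' Counts, for each index cell (canonically T helper cells), the distinct
#' neighbour cells within a radius — in-plane within the same section
#' (2D) and through the full volume (3D). Both 15 and 30 µm radii are
#' evaluated by default; the index cell itself is never counted, and the
#' 3D count can never fall below the 2D count.
#'
#' @param index_cells tibble with `cell_id`, `x_um`, `y_um`, `z_um`,
#'   `retained_index`.
#' @param neighbor_cells tibble with the same columns (by default the
#'   T-cell set; pass all immune cells to reproduce the broader variant).
#' @param radius_um radii to evaluate (default `c(15, 30)`).
#' @return Tibble: `cell_id`, `radius_um`, `count2d`, `count3d`.
#' @export
cluster_density <- function(index_cells, neighbor_cells,
                            radius_um = c(15, 30)) {
  stopifnot(all(radius_um > 0))
  purrr::map_dfr(radius_um, function(r) {
    purrr::map_dfr(seq_len(nrow(index_cells)), function(i) {
      same <- !(neighbor_cells$cell_id == index_cells$cell_id[i])
      dx <- neighbor_cells$x_um - index_cells$x_um[i]
      dy <- neighbor_cells$y_um - index_cells$y_um[i]
      dz <- neighbor_cells$z_um - index_cells$z_um[i]
      d3 <- sqrt(dx^2 + dy^2 + dz^2)
      in2d <- same &
        neighbor_cells$retained_index == index_cells$retained_index[i] &
        sqrt(dx^2 + dy^2) <= r
      tibble::tibble(cell_id = index_cells$cell_id[i], radius_um = r,
                     count2d = sum(in2d),
                     count3d = sum(same & d3 <= r))
    })
  })
}

#' Two-sample Kolmogorov--Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic two-sided p value; used
#' to compare 2D against 3D distance distributions.
#'
#' @param a,b numeric samples (n >= 1 each).
#' @return One-row tibble: `test`, `statistic`, `p_value`, `adjusted_p`
#'   (`NA` outside a family), `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both samples need n >= 1",
                                           call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  tibble::tibble(test = "ks_two_sample",
                 statistic = unname(kt$statistic),
                 p_value = kt$p.value, adjusted_p = NA_real_,
                 n_a = length(a), n_b = length(b))
}

#' Spearman correlations with Benjamini-Hochberg correction
#'
#' Rank correlation (two-sided) for each hypothesis in a family, with BH
#' step-up adjustment applied within the family — the screen used for
#' cell-density versus age covariates.
#'
#' @param pairs tibble with columns `hypothesis`, `x`, `y`; each hypothesis
#'   needs n >= 4 complete pairs.
#' @return Tibble per hypothesis: `test`, `hypothesis`, `statistic` (rho),
#'   `p_value`, `adjusted_p`, `n`.
#' @export
spearman_bh <- function(pairs) {
  stopifnot(all(c("hypothesis", "x", "y") %in% names(pairs)))
  res <- pairs |>
    dplyr::group_by(.data$hypothesis) |>
    dplyr::group_map(function(g, key) {
      ok <- stats::complete.cases(g$x, g$y)
      if (sum(ok) < 4) stop("each hypothesis needs n >= 4", call. = FALSE)
      ct <- suppressWarnings(
        stats::cor.test(g$x[ok], g$y[ok], method = "spearman",
                        alternative = "two.sided"))
      tibble::tibble(test = "spearman", hypothesis = key$hypothesis,
                     statistic = unname(ct$estimate),
                     p_value = ct$p.value, n = sum(ok))
    }) |>
    dplyr::bind_rows()
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res[, c("test", "hypothesis", "statistic", "p_value", "adjusted_p", "n")]
}

#' Two-group Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon comparison (exact for small untied
#' samples, normal approximation otherwise); used for mild versus
#' moderate-marked UV exposure comparisons.
#'
#' @param a,b numeric samples (n >= 1 each).
#' @return One-row tibble in the [ks_two_sample()] layout.
#' @export
wilcoxon_two_group <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both groups need n >= 1",
                                           call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  tibble::tibble(test = "wilcoxon_two_group",
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value, adjusted_p = NA_real_,
                 n_a = length(a), n_b = length(b))
}
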