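#' Stack registered sections into a physical 3D volume
#'
#' Slabs are placed at `z = physical_index * thickness_um`, so skipped
#' physical sections leave real gaps on the z axis — no inter-section
#' interpolation is performed.
#'
#' @param sections list of registered [section()] objects (common frame and
#'   shape).
#' @param channel channel name to stack (or `"af_mask"` for the tissue
#'   mask).
#' @param thickness_um section thickness (default 5 µm).
#' @return Object of class `volume3d`: `voxels` (array row x col x slab),
#'   `spacing_um` `c(dx, dy, dz)`, `z_um` (slab z positions),
#'   `physical_index`, `retained_index`.
#' @export
stack_sections <- function(sections, channel = "AF", thickness_um = 5) {
  stopifnot(length(sections) >= 1L)
  ridx <- vapply(sections, `[[`, integer(1), "retained_index")
  sections <- sections[order(ridx)]
  phys <- vapply(sections, `[[`, integer(1), "physical_index")
  if (anyDuplicated(phys)) stop("duplicate physical indices", call. = FALSE)
  shp <- dim(sections[[1]])
  imgs <- lapply(sections, function(s) {
    if (channel == "af_mask") {
      if (is.null(s$af_mask)) stop("af_mask missing", call. = FALSE)
      m <- matrix(as.numeric(s$af_mask), shp[1], shp[2])
    } else {
      m <- section_channel(s, channel)
    }
    if (!identical(dim(m), shp)) stop("sections differ in shape",
                                      call. = FALSE)
    m
  })
  vox <- array(unlist(imgs), c(shp, length(imgs)))
  px <- sections[[1]]$pixel_size_um
  structure(list(voxels = vox,
                 spacing_um = c(px, px, thickness_um),
                 z_um = phys * thickness_um,
                 physical_index = phys,
                 retained_index = sort(ridx)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume3d> %dx%d px x %d slabs, spacing %.3g x %.3g x %.3g um, z %g..%g um\n",
              d[1], d[2], d[3], x$spacing_um[1], x$spacing_um[2],
              x$spacing_um[3], min(x$z_um), max(x$z_um)))
  invisible(x)
}

#' Fuse per-section 2D cells into 3D cells
#'
#' Nuclei whose painted one-slab-thick footprints overlap across adjacent
#' retained sections are merged into a single 3D cell (connected-component
#' fusion), preventing the overcounting that arises when one nucleus spans
#' several 5 µm sections. With 26-connectivity (default) footprints also
#' connect through diagonal pixel contact; `connectivity = 6` requires
#' direct overlap. Sections whose physical z gap exceeds `max_z_gap_um`
#' are never merged (a cell is not assumed to continue through unobserved
#' skipped sections).
#'
#' @param cells2d tibble of 2D cell records (from [phenotype_cells()] or
#'   equivalent) with columns `nucleus_id`, `retained_index`, `phenotype`,
#'   `x_um`, `y_um`, `area_px`, `pixels`.
#' @param section_map tibble mapping `retained_index` to `physical_index`
#'   (and optionally `z_um`).
#' @param image_shape `c(rows, cols)` of the common registered frame.
#' @param thickness_um section thickness (default 5).
#' @param max_z_gap_um largest physical z gap across which footprints may
#'   merge (default 5 = physically adjacent sections only).
#' @param connectivity 26 (default) or 6.
#' @param pixel_size_um pixel size.
#' @return Tibble of 3D cells: `cell3d_id`, `phenotype`, `x_um`, `y_um`,
#'   `z_um` (voxel-weighted centroid), `voxel_count`,
#'   `n_sections_spanned`, `members` (list of `retained_index` /
#'   `nucleus_id` tibbles).
#' @export
fuse_cells_3d <- function(cells2d, section_map, image_shape,
                          thickness_um = 5, max_z_gap_um = 5,
                          connectivity = 26L, pixel_size_um = 1) {
  stopifnot(connectivity %in% c(6L, 26L))
  if (nrow(cells2d) == 0L) {
    return(tibble::tibble(cell3d_id = integer(0), phenotype = character(0),
                          x_um = numeric(0), y_um = numeric(0),
                          z_um = numeric(0), voxel_count = integer(0),
                          n_sections_spanned = integer(0), members = list()))
  }
  df <- cells2d
  if (!"phenotype" %in% names(df)) df$phenotype <- "cell"
  df$.row <- seq_len(nrow(df))
  sm <- section_map[order(section_map$retained_index), ]
  if (!"z_um" %in% names(sm)) sm$z_um <- sm$physical_index * thickness_um
  npx <- prod(image_shape)

  edges <- list()
  for (ph in unique(df$phenotype)) {
    sub <- df[df$phenotype == ph, ]
    # label image per retained section: pixel -> global row id
    paint <- function(rows) {
      img <- integer(npx)
      for (i in rows) {
        img[df$pixels[[i]]] <- i
      }
      img
    }
    secs <- sort(unique(sub$retained_index))
    for (si in seq_along(secs)[-1]) {
      a_ri <- secs[si - 1L]; b_ri <- secs[si]
      za <- sm$z_um[match(a_ri, sm$retained_index)]
      zb <- sm$z_um[match(b_ri, sm$retained_index)]
      if ((zb - za) > max_z_gap_um + 1e-9) next
      ia <- paint(sub$.row[sub$retained_index == a_ri])
      ib <- paint(sub$.row[sub$retained_index == b_ri])
      ma <- matrix(ia, image_shape[1])
      mb <- matrix(ib, image_shape[1])
      shifts <- if (connectivity == 26L) {
        expand.grid(dr = -1:1, dc = -1:1)
      } else {
        data.frame(dr = 0L, dc = 0L)
      }
      for (s in seq_len(nrow(shifts))) {
        dr <- shifts$dr[s]; dc <- shifts$dc[s]
        ra <- max(1L, 1L + dr):min(image_shape[1], image_shape[1] + dr)
        ca <- max(1L, 1L + dc):min(image_shape[2], image_shape[2] + dc)
        rb <- ra - dr; cb <- ca - dc
        va <- ma[ra, ca]; vb <- mb[rb, cb]
        sel <- va > 0L & vb > 0L
        if (any(sel)) {
          edges[[length(edges) + 1L]] <- unique(cbind(va[sel], vb[sel]))
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = nrow(df), directed = FALSE)
  if (length(edges)) {
    em <- unique(do.call(rbind, edges))
    g <- igraph::add_edges(g, t(em))
  }
  comp <- igraph::components(g)$membership
  df$comp <- comp

  res <- df |>
    dplyr::group_by(.data$comp) |>
    dplyr::group_map(function(grp, key) {
      z <- sm$z_um[match(grp$retained_index, sm$retained_index)] +
        thickness_um / 2
      w <- grp$area_px
      tibble::tibble(
        phenotype = grp$phenotype[1],
        x_um = sum(grp$x_um * w) / sum(w),
        y_um = sum(grp$y_um * w) / sum(w),
        z_um = sum(z * w) / sum(w),
        voxel_count = sum(grp$area_px),
        n_sections_spanned = length(unique(grp$retained_index)),
        members = list(tibble::tibble(retained_index = grp$retained_index,
                                      nucleus_id = grp$nucleus_id)))
    }) |>
    dplyr::bind_rows()
  res <- res[order(res$z_um, res$y_um, res$x_um), ]
  res$cell3d_id <- seq_len(nrow(res))
  res[, c("cell3d_id", "phenotype", "x_um", "y_um", "z_um", "voxel_count",
          "n_sections_spanned", "members")]
}

#' Tissue volume from a mask volume
#'
#' Counts mask voxels and converts to physical volume; each slab is one
#' section thick.
#'
#' @param vol a [stack_sections()] result holding a binary mask.
#' @return Tibble with `voxels`, `volume_um3`, `volume_cm3`.
#' @export
compute_tissue_volume <- function(vol) {
  stopifnot(inherits(vol, "volume3d"))
  nvox <- sum(vol$voxels > 0)
  um3 <- nvox * prod(vol$spacing_um)
  tibble::tibble(voxels = nvox, volume_um3 = um3, volume_cm3 = um3 * 1e-12)
}

#' Cell density per cubic centimetre
#'
#' @param n_cells cell count.
#' @param volume_cm3 tissue volume in cm^3 (> 0).
#' @return Cells per cm^3.
#' @export
density_per_cm3 <- function(n_cells, volume_cm3) {
  if (volume_cm3 <= 0) stop("volume must be > 0", call. = FALSE)
  n_cells / volume_cm3
}
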