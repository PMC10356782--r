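#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow in one validated
#' object. All defaults match the module-level defaults; per-marker
#' probability/overlap thresholds can be overridden where a slide needs it
#' (in practice a small minority of slides).
#'
#' @param input_dir optional directory of a section stack written by
#'   [write_section_stack()]; when `NULL` the phantom generator supplies
#'   the input.
#' @param output_dir optional directory for result tables; `NULL` keeps
#'   results in memory only.
#' @param phantom a [phantom_config()] used when no `input_dir` is given.
#' @param channels named list: `dapi`, `af`, `markers` (character vector),
#'   `damage` (character vector, may be empty).
#' @param section_thickness_um,pixel_size_um stack geometry.
#' @param reference_index registration reference (default: middle section).
#' @param segment list of [segment_nuclei()] parameters.
#' @param register list of [register_stack()] parameters.
#' @param prob_threshold,overlap_threshold default marker-call thresholds.
#' @param threshold_overrides named list `marker -> c(prob, overlap)`.
#' @param cluster_radius_um cluster-density radii (default `c(15, 30)`).
#' @param neighbor_set `"tcells"` (default) or `"immune"` — the neighbour
#'   population counted around each T helper index cell.
#' @param seed integer master seed.
#' @return A validated `pipeline_config` object.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = NULL,
                            phantom = phantom_config(),
                            channels = list(
                              dapi = "DAPI", af = "AF",
                              markers = c("CD3", "CD4", "CD8", "FOXP3",
                                          "CD68", "CD31", "AE1"),
                              damage = c("p53", "Ki67", "DDB2")),
                            section_thickness_um = 5, pixel_size_um = 1,
                            reference_index = NULL,
                            segment = list(scales_um = c(2, 3, 4.5),
                                           response_threshold = 0.8,
                                           min_area_px = 20,
                                           max_area_px = 2000,
                                           split = TRUE),
                            register = list(block_size_px = 64L,
                                            search_radius_px = 32L,
                                            grid_spacing_px = c(64, 32),
                                            max_disp_px = 30,
                                            closing_radius_px = 5),
                            prob_threshold = 0.5, overlap_threshold = 0.1,
                            threshold_overrides = list(),
                            cluster_radius_um = c(15, 30),
                            neighbor_set = c("tcells", "immune"),
                            seed = 1L) {
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              phantom = phantom, channels = channels,
              section_thickness_um = section_thickness_um,
              pixel_size_um = pixel_size_um,
              reference_index = reference_index,
              segment = segment, register = register,
              prob_threshold = prob_threshold,
              overlap_threshold = overlap_threshold,
              threshold_overrides = threshold_overrides,
              cluster_radius_um = cluster_radius_um,
              neighbor_set = match.arg(neighbor_set),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Fail-fast validation: every condition that would make a later stage
#' abort is checked up front. Called automatically by [pipeline_config()]
#' and again (against the actual sections) by [run_pipeline()].
#'
#' @param config a `pipeline_config`.
#' @param sections optional section list to validate channel presence
#'   against.
#' @return `config`, invisibly; errors of class `mxif3d_validation_error`
#'   otherwise.
#' @export
validate_pipeline_config <- function(config, sections = NULL) {
  fail <- function(msg) {
    stop(structure(class = c("mxif3d_validation_error", "error",
                             "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  ch <- config$channels
  if (!all(c("dapi", "af", "markers") %in% names(ch))) {
    fail("channels must name dapi, af and markers")
  }
  required <- c("CD3", "CD4", "CD8", "FOXP3", "CD68", "CD31")
  miss <- setdiff(required, ch$markers)
  if (length(miss)) {
    fail(paste0("required phenotype marker channel(s) missing from config: ",
                paste(miss, collapse = ", ")))
  }
  thr <- c(config$prob_threshold, config$overlap_threshold,
           unlist(config$threshold_overrides))
  if (any(thr < 0 | thr > 1)) fail("thresholds must lie in [0, 1]")
  if (any(config$cluster_radius_um <= 0)) fail("cluster radii must be > 0")
  if (config$section_thickness_um <= 0) fail("section thickness must be > 0")
  if (is.null(config$input_dir) && is.null(config$phantom)) {
    fail("either input_dir or a phantom config is required")
  }
  if (!is.null(sections)) {
    need <- unique(c(ch$dapi, ch$af, ch$markers, ch$damage))
    for (s in sections) {
      miss <- setdiff(need, names(s$channels))
      if (length(miss)) {
        fail(sprintf("section %d is missing channel(s): %s",
                     s$retained_index, paste(miss, collapse = ", ")))
      }
    }
    phys <- vapply(sections, `[[`, integer(1), "physical_index")
    if (anyDuplicated(phys)) fail("duplicate physical indices in stack")
  }
  invisible(config)
}

marker_thresholds <- function(config, marker) {
  ov <- config$threshold_overrides[[marker]]
  if (is.null(ov)) c(config$prob_threshold, config$overlap_threshold)
  else c(ov[1], ov[2])
}

#' Run the full reconstruction + analysis pipeline
#'
#' Executes preprocess, register, segment, reconstruct and spatial
#' stages in order on a section stack (read from disk, passed in memory,
#' or generated as a phantom) and returns a run report holding every
#' result table. A rerun with the same configuration and seed reproduces
#' all tables exactly.
#'
#' @param config a [pipeline_config()].
#' @param sections optional list of [section()]s (overrides `input_dir`
#'   and the phantom).
#' @return Object of class `mx_run_report`; see [glance.mx_run_report()].
#' @export
run_pipeline <- function(config, sections = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  stages <- list()
  truth <- NULL
  warnings_log <- character(0)
  mark <- function(stage, status, t0) {
    stages[[stage]] <<- tibble::tibble(
      stage = stage, status = status,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      mark(stage, "failed", t0)
      stop(structure(class = c("mxif3d_stage_error", "error", "condition"),
                     list(message = sprintf("stage '%s' failed: %s", stage,
                                            conditionMessage(e)),
                          call = sys.call(-1), stage = stage,
                          partial = stages)))
    })
    mark(stage, "ok", t0)
    res
  }

  # ---- input ---------------------------------------------------------------
  sections <- run_stage("input", {
    if (!is.null(sections)) {
      sections
    } else if (!is.null(config$input_dir)) {
      read_section_stack(config$input_dir)
    } else {
      ph <- generate_phantom(config$phantom)
      truth <- ph$truth
      ph$sections
    }
  })
  validate_pipeline_config(config, sections)
  ch <- config$channels
  px <- config$pixel_size_um
  th <- config$section_thickness_um
  n <- length(sections)
  shp <- dim(sections[[1]])

  # ---- preprocess ----------------------------------------------------------
  sections <- run_stage("preprocess", {
    lapply(sections, function(s) {
      s$af_mask <- compute_af_mask(
        section_channel(s, ch$af),
        closing_radius_px = config$register$closing_radius_px %||% 5)
      s
    })
  })

  # ---- register ------------------------------------------------------------
  reg <- run_stage("register", {
    if (n > 1L) {
      do.call(register_stack,
              c(list(sections = sections,
                     reference_index = config$reference_index),
                config$register))
    } else {
      structure(list(transforms = stats::setNames(
                       list(identity_transform()),
                       sections[[1]]$retained_index),
                     qc = tibble::tibble(
                       retained_index = sections[[1]]$retained_index,
                       dsc = 1, nmi_before = NA_real_, nmi_after = NA_real_,
                       converged = TRUE, iterations = 0L),
                     adjacent = tibble::tibble(index_a = integer(0),
                                               index_b = integer(0),
                                               ncc = numeric(0)),
                     reference_index = sections[[1]]$retained_index),
                class = "mx_registration")
    }
  })
  registered <- run_stage("resample", {
    lapply(seq_len(n), function(k) {
      s <- sections[[k]]
      tr <- reg$transforms[[as.character(s$retained_index)]]
      s$channels <- lapply(s$channels, apply_transform_image,
                           transform = tr, pixel_size_um = px,
                           interpolation = "linear")
      s$af_mask <- apply_transform_image(
        matrix(as.numeric(s$af_mask), shp[1]), tr, px, "nearest") > 0.5
      s
    })
  })

  # ---- segment -------------------------------------------------------------
  seg <- run_stage("segment", {
    all_cells <- list()
    vessel_vox <- list()
    surface_pts <- list()
    damage_calls <- list()
    for (k in seq_len(n)) {
      s <- registered[[k]]
      ri <- s$retained_index
      dapi <- normalize_zmuv(section_channel(s, ch$dapi), s$af_mask)
      nuc <- do.call(segment_nuclei,
                     c(list(dapi = dapi, pixel_size_um = px,
                            retained_index = ri), config$segment))
      fits <- list()
      calls <- list()
      for (mk in c(ch$markers, ch$damage)) {
        img <- normalize_zmuv(section_channel(s, mk), s$af_mask)
        fits[[mk]] <- fit_gmm_two_class(img, mask = s$af_mask,
                                        seed = config$seed + ri)
        thr <- marker_thresholds(config, mk)
        calls[[mk]] <- call_marker_on_nuclei(fits[[mk]], nuc, marker = mk,
                                             prob_threshold = thr[1],
                                             overlap_threshold = thr[2])
      }
      cells2d <- phenotype_cells(nuc, dplyr::bind_rows(calls[ch$markers]))
      cells2d$physical_index <- s$physical_index
      if (length(ch$damage)) {
        dmg <- dplyr::bind_rows(calls[ch$damage])
        dmg$retained_index <- ri
        damage_calls[[k]] <- dmg
      }
      all_cells[[k]] <- cells2d
      # contiguous structures: vessels from CD31, surface from the tissue
      # mask's topmost row per column
      vmask <- segment_structure_mask(fits[["CD31"]]) & s$af_mask
      vi <- which(vmask)
      if (length(vi)) {
        vessel_vox[[k]] <- tibble::tibble(
          retained_index = ri, physical_index = s$physical_index,
          row = (vi - 1L) %% shp[1] + 1L, col = (vi - 1L) %/% shp[1] + 1L)
      }
      top <- apply(s$af_mask, 2, function(colv) {
        w <- which(colv)
        if (length(w)) w[1] else NA_integer_
      })
      ok <- !is.na(top)
      surface_pts[[k]] <- tibble::tibble(
        retained_index = ri,
        x_um = (which(ok) - 1) * px, y_um = (top[ok] - 1) * px)
    }
    list(cells2d = dplyr::bind_rows(all_cells),
         vessels = dplyr::bind_rows(vessel_vox),
         surface = dplyr::bind_rows(surface_pts),
         damage = dplyr::bind_rows(damage_calls))
  })

  # ---- reconstruct ---------------------------------------------------------
  recon <- run_stage("reconstruct", {
    section_map <- tibble::tibble(
      retained_index = vapply(registered, `[[`, integer(1),
                              "retained_index"),
      physical_index = vapply(registered, `[[`, integer(1),
                              "physical_index"))
    section_map$z_um <- section_map$physical_index * th
    mask_vol <- stack_sections(registered, "af_mask", th)
    tissue <- compute_tissue_volume(mask_vol)
    cells3d <- fuse_cells_3d(seg$cells2d, section_map, shp,
                             thickness_um = th, pixel_size_um = px)
    dens <- cells3d |>
      dplyr::count(.data$phenotype, name = "n_cells") |>
      dplyr::mutate(density_per_cm3 = density_per_cm3(
        .data$n_cells, tissue$volume_cm3[1]))
    list(section_map = section_map, tissue = tissue, cells3d = cells3d,
         densities = dens)
  })

  # ---- spatial -------------------------------------------------------------
  spa <- run_stage("spatial", {
    sm <- recon$section_map
    vox <- seg$vessels
    vox$x_um <- (vox$col - 1) * px
    vox$y_um <- (vox$row - 1) * px
    vox$z_um <- vox$physical_index * th
    cells3d <- recon$cells3d
    # a 3D cell's "own section" for 2D metrics: nearest retained slab
    cells3d$retained_index <- sm$retained_index[
      vapply(cells3d$z_um, function(z) which.min(abs(sm$z_um + th / 2 - z)),
             integer(1))]
    cells3d <- dplyr::rename(cells3d, cell_id = "cell3d_id")
    # distances are computed on the reconstructed voxel grid: each cell is
    # referenced at its section's slab z, so a same-section structure voxel
    # sits at z-offset 0 and d3d <= d2d holds exactly
    cells3d$z_um <- sm$z_um[match(cells3d$retained_index,
                                  sm$retained_index)]
    immune <- cells3d[cells3d$phenotype %in%
                        c("Thelper", "Tkiller", "Treg", "macrophage"), ]
    distances <- if (nrow(immune) && nrow(vox)) {
      distance_records(immune, vox)
    } else {
      tibble::tibble(cell_id = integer(0), phenotype = character(0),
                     d2d_um = numeric(0), d3d_um = numeric(0),
                     no_target_in_section = logical(0))
    }
    tcells <- cells3d[cells3d$phenotype %in%
                        c("Thelper", "Tkiller", "Treg"), ]
    neigh <- if (config$neighbor_set == "immune") immune else tcells
    clusters <- cluster_density(tcells[tcells$phenotype == "Thelper", ],
                                neigh, config$cluster_radius_um)
    ok <- !distances$no_target_in_section
    stats_tb <- if (sum(ok) >= 2) {
      ks_two_sample(distances$d2d_um[ok], distances$d3d_um[ok])
    } else {
      tibble::tibble(test = character(0), statistic = numeric(0),
                     p_value = numeric(0), adjusted_p = numeric(0),
                     n_a = integer(0), n_b = integer(0))
    }
    surface_d <- NULL
    if (nrow(seg$damage)) {
      pos <- seg$damage[seg$damage$positive, ]
      key <- dplyr::distinct(pos, .data$retained_index, .data$nucleus_id)
      dm_cells <- dplyr::inner_join(
        dplyr::select(seg$cells2d, "nucleus_id", "retained_index",
                      "x_um", "y_um"),
        key, by = c("nucleus_id", "retained_index"))
      if (nrow(dm_cells)) {
        dm_cells$z_um <- sm$z_um[match(dm_cells$retained_index,
                                       sm$retained_index)] + th / 2
        dm_cells$cell_id <- seq_len(nrow(dm_cells))
        surface_d <- distance_to_skin_surface(dm_cells, seg$surface, sm)
      }
    }
    list(distances = distances, clusters = clusters, stats = stats_tb,
         surface_distances = surface_d)
  })

  report <- structure(list(
    stages = dplyr::bind_rows(stages),
    qc = reg$qc, adjacent = reg$adjacent,
    reference_index = reg$reference_index,
    counts2d = dplyr::count(seg$cells2d, .data$phenotype, name = "n"),
    counts3d = dplyr::count(recon$cells3d, .data$phenotype, name = "n"),
    cells2d = seg$cells2d, cells3d = recon$cells3d,
    tissue = recon$tissue, densities = recon$densities,
    distances = spa$distances, clusters = spa$clusters,
    stats = spa$stats, surface_distances = spa$surface_distances,
    truth = truth, config = config,
    warnings = warnings_log,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "mx_run_report")
  if (!is.null(config$output_dir)) write_run_outputs(report)
  report
}

#' @export
print.mx_run_report <- function(x, ...) {
  cat("<mx_run_report>\n")
  print(x$stages)
  cat(sprintf("  2D cells %d, 3D cells %d; mean DSC %.3f; mean adj NCC %.3f\n",
              sum(x$counts2d$n), sum(x$counts3d$n), mean(x$qc$dsc),
              mean(x$adjacent$ncc, na.rm = TRUE)))
  invisible(x)
}

drop_or_flatten_lists <- function(df) {
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(v) {
        if (is.data.frame(v)) {
          paste(apply(v, 1, paste, collapse = ":"), collapse = ";")
        } else {
          paste(unlist(v), collapse = ";")
        }
      }, character(1))
    }
  }
  df
}

#' Write a result table as deterministic CSV
#'
#' Fixed column order (as given), floats rounded to 6 significant digits,
#' rows ordered by the first (id) column, list columns flattened to
#' `;`-separated strings. An empty table writes a header-only file.
#'
#' @param records data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tables <- function(records, path) {
  df <- tibble::as_tibble(records)
  df <- drop_or_flatten_lists(df)
  if (nrow(df) > 1) df <- df[order(df[[1]]), ]
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), signif6))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

write_run_outputs <- function(report) {
  dir.create(report$config$output_dir, recursive = TRUE,
             showWarnings = FALSE)
  out <- function(f) file.path(report$config$output_dir, f)
  cells2d <- report$cells2d
  cells2d$pixels <- NULL
  write_tables(cells2d, out("cells_2d.csv"))
  write_tables(report$cells3d, out("cells_3d.csv"))
  write_tables(report$distances, out("vessel_distances.csv"))
  write_tables(report$clusters, out("cluster_density.csv"))
  write_tables(report$qc, out("registration_qc.csv"))
  if (!is.null(report$surface_distances)) {
    write_tables(report$surface_distances, out("surface_distances.csv"))
  }
  jsonlite::write_json(list(stats = report$stats,
                            tissue = report$tissue,
                            densities = report$densities),
                       out("statistics.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(stages = report$stages,
                            reference_index = report$reference_index,
                            mean_dsc = mean(report$qc$dsc),
                            mean_adjacent_ncc =
                              mean(report$adjacent$ncc, na.rm = TRUE)),
                       out("run_report.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

# ---- stack I/O --------------------------------------------------------------

#' Write a section stack to disk
#'
#' One 16-bit TIFF per channel per section, named
#' `S{physical_index:03d}_{channel}.tif`, plus a `stack.json` sidecar with
#' the geometry and channel list.
#'
#' @param sections list of [section()]s.
#' @param dir output directory (created if needed).
#' @param thickness_um section thickness stored in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_section_stack <- function(sections, dir, thickness_um = 5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(pixel_size_um = sections[[1]]$pixel_size_um,
               section_thickness_um = thickness_um,
               channels = names(sections[[1]]$channels),
               sections = lapply(sections, function(s) {
                 list(retained_index = s$retained_index,
                      physical_index = s$physical_index)
               }))
  for (s in sections) {
    for (nm in names(s$channels)) {
      f <- file.path(dir, sprintf("S%03d_%s.tif", s$physical_index, nm))
      tiff::writeTIFF(pmin(pmax(s$channels[[nm]] / 65535, 0), 1), f,
                      bits.per.sample = 16L)
    }
  }
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a section stack written by [write_section_stack()]
#'
#' @param dir stack directory containing `stack.json`.
#' @return List of [section()]s sorted by physical index.
#' @export
read_section_stack <- function(dir) {
  sidecar <- file.path(dir, "stack.json")
  if (!file.exists(sidecar)) {
    stop(sprintf("missing sidecar: %s", sidecar), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (length(meta$sections) == 0) stop("empty stack", call. = FALSE)
  secs <- meta$sections
  if (anyDuplicated(secs$physical_index)) {
    stop("duplicate physical index in stack", call. = FALSE)
  }
  shp <- NULL
  out <- lapply(seq_len(nrow(secs)), function(i) {
    chans <- lapply(meta$channels, function(nm) {
      f <- file.path(dir, sprintf("S%03d_%s.tif", secs$physical_index[i],
                                  nm))
      if (!file.exists(f)) stop(sprintf("missing file: %s", f),
                                call. = FALSE)
      img <- tiff::readTIFF(f) * 65535
      if (is.null(shp)) shp <<- dim(img)
      if (!identical(dim(img), shp)) {
        stop("inconsistent image shapes in stack", call. = FALSE)
      }
      round(img)
    })
    names(chans) <- meta$channels
    section(chans, pixel_size_um = meta$pixel_size_um,
            retained_index = secs$retained_index[i],
            physical_index = secs$physical_index[i])
  })
  out[order(vapply(out, `[[`, integer(1), "physical_index"))]
}
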