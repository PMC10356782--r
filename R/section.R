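#' Serial-section container
#'
#' One physical tissue section: a named set of co-registered 2D channel
#' rasters (numeric matrices, rows = y, columns = x) plus its geometry. The
#' `retained_index` numbers the sections that were kept for analysis
#' (0-based, consecutive); the `physical_index` is the position in the
#' original cutting order, so skipped sections show up as gaps in physical
#' index and therefore as gaps on the z axis.
#'
#' @param channels named list of numeric matrices, all the same shape.
#'   Conventionally includes `DAPI` (nuclear stain) and `AF`
#'   (autofluorescence) plus biomarker channels.
#' @param pixel_size_um physical size of a pixel in µm.
#' @param retained_index integer >= 0.
#' @param physical_index integer >= `retained_index`.
#' @param af_mask optional logical matrix (tissue mask from the AF channel).
#' @return An object of class `mx_section`.
#' @export
section <- function(channels, pixel_size_um, retained_index,
                    physical_index = retained_index, af_mask = NULL) {
  stopifnot(is.list(channels), length(channels) > 0,
            !is.null(names(channels)), all(nzchar(names(channels))))
  shp <- dim(channels[[1]])
  for (nm in names(channels)) {
    assert_image(channels[[nm]], nm)
    if (!identical(dim(channels[[nm]]), shp)) {
      stop(sprintf("channel '%s' shape differs from '%s'",
                   nm, names(channels)[1]), call. = FALSE)
    }
  }
  retained_index <- as.integer(retained_index)
  physical_index <- as.integer(physical_index)
  if (retained_index < 0L) stop("retained_index must be >= 0", call. = FALSE)
  if (physical_index < retained_index) {
    stop("physical_index must be >= retained_index", call. = FALSE)
  }
  if (!is.null(af_mask)) {
    stopifnot(identical(dim(af_mask), shp))
    af_mask <- matrix(as.logical(af_mask), shp[1], shp[2])
  }
  structure(list(channels = channels,
                 pixel_size_um = as.numeric(pixel_size_um),
                 retained_index = retained_index,
                 physical_index = physical_index,
                 af_mask = af_mask),
            class = "mx_section")
}

#' @export
print.mx_section <- function(x, ...) {
  shp <- dim(x$channels[[1]])
  cat(sprintf("<mx_section> retained %d (physical %d), %dx%d px @ %.3g um/px\n",
              x$retained_index, x$physical_index, shp[1], shp[2],
              x$pixel_size_um))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  cat("  af_mask:", if (is.null(x$af_mask)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
dim.mx_section <- function(x) dim(x$channels[[1]])

section_channel <- function(s, name) {
  if (!name %in% names(s$channels)) {
    stop(sprintf("channel '%s' not present in section %d",
                 name, s$retained_index), call. = FALSE)
  }
  s$channels[[name]]
}
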