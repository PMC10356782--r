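#' Illumination model
#'
#' Flat-field model of the acquisition system: a background glass frame
#' (glints/reflections, acquired at a known exposure) and a smooth positive
#' non-uniformity field with unit mean describing the vignetting of each
#' objective/filter combination.
#'
#' @param background_frame numeric matrix, background glass image.
#' @param background_exposure exposure time of the background frame
#'   (arbitrary but consistent units, > 0).
#' @param nonuniformity_field numeric matrix, strictly positive, mean 1
#'   (within 1e-6); `NULL` means a unit field.
#' @return An object of class `illumination_model`.
#' @export
illumination_model <- function(background_frame, background_exposure = 1,
                               nonuniformity_field = NULL) {
  assert_image(background_frame)
  if (background_exposure <= 0) stop("background_exposure must be > 0",
                                     call. = FALSE)
  if (is.null(nonuniformity_field)) {
    nonuniformity_field <- matrix(1, nrow(background_frame),
                                  ncol(background_frame))
  }
  assert_image(nonuniformity_field)
  assert_same_shape(background_frame, nonuniformity_field)
  if (any(nonuniformity_field <= 0)) {
    stop("nonuniformity_field must be > 0 everywhere", call. = FALSE)
  }
  if (abs(mean(nonuniformity_field) - 1) > 1e-6) {
    stop("nonuniformity_field must have unit mean (within 1e-6)",
         call. = FALSE)
  }
  structure(list(background_frame = background_frame,
                 background_exposure = background_exposure,
                 nonuniformity_field = nonuniformity_field),
            class = "illumination_model")
}

#' Correct illumination of a raw frame
#'
#' Subtracts the exposure-scaled background glass image and divides out the
#' non-uniformity field; negative intensities are clipped at zero.
#'
#' @param image raw numeric matrix.
#' @param model an [illumination_model()].
#' @param exposure exposure time of `image` (> 0, same units as the model's
#'   background exposure).
#' @return Corrected numeric matrix.
#' @export
correct_illumination <- function(image, model, exposure = 1) {
  assert_image(image)
  stopifnot(inherits(model, "illumination_model"))
  if (exposure <= 0) stop("exposure must be > 0", call. = FALSE)
  assert_same_shape(image, model$background_frame)
  out <- (image - model$background_frame *
            (exposure / model$background_exposure)) /
    model$nonuniformity_field
  out[out < 0] <- 0
  out
}

#' Zero-mean unit-variance normalisation
#'
#' Whole-slide intensity normalisation applied before probabilistic marker
#' segmentation: the image is rescaled so that the intensities inside the
#' tissue mask (or the whole image when no mask is given) have mean 0 and
#' standard deviation 1. Pixels outside the mask are transformed with the
#' same affine map, so the normalisation is monotone everywhere.
#'
#' @param image numeric matrix.
#' @param mask optional logical matrix selecting the pixels that define the
#'   normalisation statistics.
#' @return Numeric matrix with attributes `zmuv_mean` and `zmuv_sd` (the
#'   affine map, so the normalisation can be inverted).
#' @export
normalize_zmuv <- function(image, mask = NULL) {
  assert_image(image)
  vals <- if (is.null(mask)) image else {
    assert_same_shape(image, mask)
    image[mask]
  }
  if (length(unique(as.vector(vals))) < 2) {
    stop("degenerate intensity distribution", call. = FALSE)
  }
  mu <- mean(vals)
  # population SD so that a balanced two-point input maps exactly to -1/+1
  sdv <- sqrt(mean((vals - mu)^2))
  out <- (image - mu) / sdv
  attr(out, "zmuv_mean") <- mu
  attr(out, "zmuv_sd") <- sdv
  out
}

#' Otsu threshold
#'
#' Classic histogram threshold maximising the between-class variance.
#' Intensities are binned into `n_bins` equal-width bins over the observed
#' min-max range; the returned threshold is the upper edge of the best
#' split bin, so `image > threshold` is the foreground.
#'
#' @param image numeric matrix (or vector) of intensities.
#' @param n_bins number of histogram bins (default 256).
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.vector(image)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) stop("constant image: Otsu threshold undefined",
                           call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)                       # class-0 probability at split k
  mu <- cumsum(p * seq_len(n_bins))        # first moment
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, Inf)
  sigma_b[denom <= 0] <- -Inf
  k <- which.max(sigma_b)                  # ties: lowest bin wins
  edges[k + 1L]
}

#' Tissue mask from the autofluorescence channel
#'
#' Otsu-thresholds the AF image, closes small holes with a disk structuring
#' element, and keeps the largest 8-connected foreground component. The AF
#' signal is intrinsic to tissue, so this mask separates tissue from glass
#' regardless of staining.
#'
#' @param af_image numeric matrix (autofluorescence channel).
#' @param closing_radius_px radius of the disk used for morphological
#'   closing (default 5).
#' @return Logical matrix (TRUE = tissue).
#' @export
compute_af_mask <- function(af_image, closing_radius_px = 5) {
  assert_image(af_image)
  thr <- otsu_threshold(af_image)          # errors on constant input
  fg <- af_image > thr
  if (!any(fg)) stop("no tissue found (empty Otsu foreground)",
                     call. = FALSE)
  if (closing_radius_px > 0) {
    size <- 2L * as.integer(closing_radius_px) + 1L
    brush <- EBImage::makeBrush(size, shape = "disc")
    fg <- EBImage::closing(matrix(as.numeric(fg), nrow(fg)), brush) > 0.5
  }
  lab <- label_components(fg, connectivity = 8L)
  if (max(lab) == 0L) stop("no tissue found (empty Otsu foreground)",
                           call. = FALSE)
  areas <- tabulate(lab[lab > 0L])
  best <- which(areas == max(areas))[1]    # anchor-order tie break
  lab == best
}

#' Preprocess a section in place
#'
#' Convenience wrapper running the standard order: optional illumination
#' correction, AF tissue-mask computation, then zero-mean unit-variance
#' normalisation of every non-AF channel inside the tissue mask.
#'
#' @param s an [section()].
#' @param illumination optional [illumination_model()] applied to every
#'   channel.
#' @param exposure exposure time of the raw frames.
#' @param closing_radius_px passed to [compute_af_mask()].
#' @param normalize logical; normalise the stain channels (default TRUE).
#' @return The section with `af_mask` set and channels preprocessed.
#' @export
preprocess_section <- function(s, illumination = NULL, exposure = 1,
                               closing_radius_px = 5, normalize = TRUE) {
  stopifnot(inherits(s, "mx_section"))
  if (!is.null(illumination)) {
    s$channels <- lapply(s$channels, correct_illumination,
                         model = illumination, exposure = exposure)
  }
  s$af_mask <- compute_af_mask(section_channel(s, "AF"),
                               closing_radius_px = closing_radius_px)
  if (normalize) {
    for (nm in setdiff(names(s$channels), "AF")) {
      s$channels[[nm]] <- normalize_zmuv(s$channels[[nm]], s$af_mask)
    }
  }
  s
}
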