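#' Multiscale Laplacian-of-Gaussian filtering
#'
#' Computes the scale-normalised LoG response (`sigma^2 * Laplacian(G_sigma * I)`)
#' at each requested scale. Blob-like structures (nuclei) appear as strong
#' local extrema, with the strongest response at the scale matching the
#' blob radius; bright blobs give negative extrema, so nuclei detection
#' thresholds the negated response.
#'
#' @param image 2D numeric matrix (ideally zero-mean unit-variance
#'   normalised).
#' @param scales_um blob scales (Gaussian sigmas) in µm, positive and
#'   sorted increasing.
#' @param pixel_size_um pixel size.
#' @return A 3D array `(rows, cols, scale)` with `dimnames` on the scale
#'   axis.
#' @export
multiscale_log <- function(image, scales_um, pixel_size_um = 1) {
  assert_image(image)
  if (length(scales_um) == 0) stop("empty scale list", call. = FALSE)
  if (any(scales_um <= 0) || is.unsorted(scales_um)) {
    stop("scales must be positive and sorted increasing", call. = FALSE)
  }
  out <- array(0, c(dim(image), length(scales_um)))
  for (i in seq_along(scales_um)) {
    s_px <- scales_um[i] / pixel_size_um
    out[, , i] <- log_filter(image, s_px) * s_px^2
  }
  dimnames(out) <- list(NULL, NULL, paste0("s", scales_um))
  out
}

# LoG via an explicit normalised kernel: (r^2 - 2 s^2)/s^4 * G_s, adjusted
# to zero sum so constants map exactly to zero.
log_filter <- function(image, sigma_px) {
  half <- max(2L, as.integer(ceiling(3.5 * sigma_px)))
  half <- min(half, (min(dim(image)) - 1L) %/% 2L)
  ax <- (-half):half
  g <- exp(-outer(ax^2, ax^2, `+`) / (2 * sigma_px^2))
  g <- g / sum(g)
  r2 <- outer(ax^2, ax^2, `+`)
  k <- (r2 - 2 * sigma_px^2) / sigma_px^4 * g
  k <- k - mean(k)
  as.matrix(EBImage::filter2(image, k, boundary = "replicate"))
}

#' Detect nuclei in a DAPI image
#'
#' Classical blob detector: the maximum over scales of the negated
#' scale-normalised LoG response is thresholded, 4-connected components are
#' extracted, components holding more than one interior response maximum are
#' optionally split by watershed, and components outside the area gate are
#' dropped. This is the default backend; a learned nuclei model can be
#' plugged in by supplying its foreground mask via `foreground`.
#'
#' @param dapi numeric matrix, zero-mean unit-variance normalised DAPI.
#' @param scales_um LoG scales (µm), default `c(2, 3, 4.5)`.
#' @param response_threshold threshold on the maximum negated LoG
#'   response, expressed in units of the image's robust noise SD
#'   (first-difference MAD estimate), so the cut adapts to the noise floor
#'   regardless of how much of the frame nuclei occupy (default 0.8).
#' @param min_area_px,max_area_px area gate (defaults 20 and 2000).
#' @param split split touching nuclei with watershed (default TRUE).
#' @param pixel_size_um pixel size.
#' @param retained_index section index recorded in the output.
#' @param foreground optional logical matrix overriding the LoG foreground
#'   (pluggable segmentation backend).
#' @return Tibble of nucleus instances: `nucleus_id`, `retained_index`,
#'   `x_um`, `y_um`, `area_px`, and `pixels` (list of 1-based matrix
#'   indices).
#' @export
segment_nuclei <- function(dapi, scales_um = c(2, 3, 4.5),
                           response_threshold = 0.8,
                           min_area_px = 20, max_area_px = 2000,
                           split = TRUE, pixel_size_um = 1,
                           retained_index = 0L, foreground = NULL) {
  assert_image(dapi)
  empty <- tibble::tibble(nucleus_id = integer(0),
                          retained_index = integer(0),
                          x_um = numeric(0), y_um = numeric(0),
                          area_px = integer(0), pixels = list())
  if (diff(range(dapi)) == 0) return(empty)
  resp <- -apply(multiscale_log(dapi, scales_um, pixel_size_um), c(1, 2),
                 max)
  resp <- pmax(resp, 0)
  # robust pixel-noise estimate (first-difference MAD), so the response
  # threshold is expressed in noise SDs and is insensitive to nucleus
  # density
  noise_sd <- stats::mad(diff(as.vector(dapi))) / sqrt(2)
  thr <- response_threshold * max(noise_sd, 1e-9)
  fg <- if (is.null(foreground)) resp > thr else foreground
  if (!any(fg)) return(empty)
  lab <- label_components(fg, connectivity = 4L)
  if (split) {
    ws <- EBImage::watershed(resp * fg, tolerance = thr, ext = 2)
    ws <- matrix(as.integer(ws), nrow(fg))
    # use the watershed labels only where they split a LoG component
    lab <- relabel_by_anchor(lab * (max(ws) + 1L) + ws * (lab > 0L))
  }
  n <- max(lab)
  if (n == 0L) return(empty)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  area <- tabulate(labs, nbins = n)
  keep <- which(area >= min_area_px & area <= max_area_px)
  if (length(keep) == 0L) return(empty)
  rr <- (idx - 1L) %% nrow(lab) + 1L
  cc <- (idx - 1L) %/% nrow(lab) + 1L
  sx <- rowsum(cc - 1, labs)[, 1]
  sy <- rowsum(rr - 1, labs)[, 1]
  pix_split <- split(idx, labs)
  tibble::tibble(
    nucleus_id = seq_along(keep),
    retained_index = as.integer(retained_index),
    x_um = (sx[keep] / area[keep]) * pixel_size_um,
    y_um = (sy[keep] / area[keep]) * pixel_size_um,
    area_px = as.integer(area[keep]),
    pixels = unname(pix_split[as.character(keep)]))
}

#' Two-component Gaussian mixture fit of a marker image
#'
#' Fits a two-class Gaussian mixture to the pixel intensities by
#' expectation-maximisation (k-means++ initialisation, shared variance by
#' default so the positive-class posterior is monotone in intensity) and
#' returns the posterior probability of the higher-mean ("positive")
#' component for every pixel.
#'
#' @param marker numeric matrix (zero-mean unit-variance normalised marker
#'   channel).
#' @param mask optional logical matrix restricting the pixels used to fit
#'   (the posterior raster always covers the full image).
#' @param seed seed for the k-means++ initialisation.
#' @param variance `"shared"` (default) or `"separate"` component
#'   variances.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return Object of class `gmm_fit`: component `means`, `sds`, `weights`
#'   (positive class last), `posterior` raster, `loglik` trace,
#'   `converged`, `n_iter`, `seed`.
#' @export
fit_gmm_two_class <- function(marker, mask = NULL, seed = 1L,
                              variance = c("shared", "separate"),
                              tol = 1e-6, max_iter = 300L) {
  variance <- match.arg(variance)
  assert_image(marker)
  x <- if (is.null(mask)) as.vector(marker) else {
    assert_same_shape(marker, mask)
    marker[mask]
  }
  if (length(unique(x)) < 2) {
    stop("degenerate intensity distribution (constant input)",
         call. = FALSE)
  }
  fit <- withr::with_seed(seed, em_two_gauss(x, variance, tol, max_iter))
  if (!fit$converged) {
    cond <- structure(class = c("mxif3d_em_error", "error", "condition"),
                      list(message = sprintf(
                        "EM did not converge after %d iterations", max_iter),
                        call = sys.call(), trace = fit$loglik))
    stop(cond)
  }
  post <- gmm_posterior_values(as.vector(marker), fit)
  structure(list(means = fit$means, sds = fit$sds, weights = fit$weights,
                 posterior = matrix(post, nrow(marker)),
                 loglik = fit$loglik, converged = fit$converged,
                 n_iter = fit$n_iter, variance = variance,
                 seed = seed), class = "gmm_fit")
}

# k-means++ seeding on 1D data
kpp_centers <- function(x, k = 2L) {
  n <- length(x)
  c1 <- x[sample.int(n, 1L)]
  d2 <- (x - c1)^2
  if (all(d2 == 0)) return(c(c1, c1 + 1e-8))
  c2 <- x[sample.int(n, 1L, prob = d2 / sum(d2))]
  c(c1, c2)
}

em_two_gauss <- function(x, variance, tol, max_iter) {
  n <- length(x)
  mu <- sort(kpp_centers(x))
  sd0 <- stats::sd(x)
  sds <- c(sd0, sd0) / 2
  w <- c(0.5, 0.5)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    la <- log(w[1]) + stats::dnorm(x, mu[1], sds[1], log = TRUE)
    lb <- log(w[2]) + stats::dnorm(x, mu[2], sds[2], log = TRUE)
    m <- pmax(la, lb)
    ll <- sum(m + log(exp(la - m) + exp(lb - m)))
    ll_trace <- c(ll_trace, ll)
    r2 <- 1 / (1 + exp(la - lb))              # responsibility of comp 2
    n2 <- sum(r2); n1 <- n - n2
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum((1 - r2) * x) / n1, sum(r2 * x) / n2)
    if (variance == "shared") {
      v <- (sum((1 - r2) * (x - mu[1])^2) + sum(r2 * (x - mu[2])^2)) / n
      sds <- sqrt(c(v, v))
    } else {
      sds <- sqrt(c(sum((1 - r2) * (x - mu[1])^2) / n1,
                    sum(r2 * (x - mu[2])^2) / n2))
    }
    sds <- pmax(sds, 1e-6 * max(sd0, 1e-12))
    w <- c(n1, n2) / n
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # positive class = larger mean, reported last
  ord <- order(mu)
  list(means = mu[ord], sds = sds[ord], weights = w[ord],
       loglik = ll_trace, converged = converged, n_iter = it)
}

gmm_posterior_values <- function(x, fit) {
  la <- log(fit$weights[1]) +
    stats::dnorm(x, fit$means[1], fit$sds[1], log = TRUE)
  lb <- log(fit$weights[2]) +
    stats::dnorm(x, fit$means[2], fit$sds[2], log = TRUE)
  1 / (1 + exp(la - lb))
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(
    "<gmm_fit> means %.3f / %.3f, sds %.3f / %.3f, weights %.2f / %.2f (%s variance)\n",
    x$means[1], x$means[2], x$sds[1], x$sds[2], x$weights[1], x$weights[2],
    x$variance))
  cat(sprintf("  %d EM iterations, logLik %.2f, converged: %s\n",
              x$n_iter, utils::tail(x$loglik, 1), x$converged))
  invisible(x)
}

#' Nucleus-level marker calls
#'
#' Fuses the pixel-level positive-class probabilities with the nuclei
#' segmentation: for each nucleus the mean positive probability over its
#' pixels and the fraction of its pixels at or above `prob_threshold` are
#' computed; a nucleus is called positive when both the mean probability
#' and the overlap fraction clear their thresholds. The overlap gate
#' removes imaging artifacts, debris and cells with background-level
#' marker intensity.
#'
#' @param fit a [fit_gmm_two_class()] result (or a probability matrix).
#' @param nuclei tibble from [segment_nuclei()].
#' @param marker marker name recorded in the output.
#' @param prob_threshold probability threshold (default 0.5).
#' @param overlap_threshold overlap-fraction threshold (default 0.1).
#' @return Tibble of marker calls: `nucleus_id`, `marker`, `p`,
#'   `overlap_fraction`, `positive`.
#' @export
call_marker_on_nuclei <- function(fit, nuclei, marker = "marker",
                                  prob_threshold = 0.5,
                                  overlap_threshold = 0.1) {
  prob <- if (inherits(fit, "gmm_fit")) fit$posterior else fit
  assert_image(prob)
  npix <- length(prob)
  res <- purrr::map2_dfr(nuclei$nucleus_id, nuclei$pixels, function(id, px) {
    if (any(px < 1L | px > npix)) {
      stop(sprintf("nucleus %d lies outside the probability raster", id),
           call. = FALSE)
    }
    pv <- prob[px]
    tibble::tibble(nucleus_id = id, p = mean(pv),
                   overlap_fraction = mean(pv >= prob_threshold))
  })
  if (nrow(res) == 0L) {
    return(tibble::tibble(nucleus_id = integer(0), marker = character(0),
                          p = numeric(0), overlap_fraction = numeric(0),
                          positive = logical(0)))
  }
  res$marker <- marker
  res$positive <- res$p >= prob_threshold &
    res$overlap_fraction >= overlap_threshold
  res[, c("nucleus_id", "marker", "p", "overlap_fraction", "positive")]
}

#' Contiguous-structure mask from a probability raster
#'
#' Otsu-thresholds the positive-class probabilities to segment structures
#' that are not nucleus-bound, such as blood vessels (CD31) and the
#' epithelial band (cytokeratin cocktails). No largest-component filter is
#' applied: vessels are legitimately multiple.
#'
#' @param fit a [fit_gmm_two_class()] result (or probability matrix).
#' @param min_prob guard: when no pixel reaches this probability the mask
#'   is empty and a warning is raised (default 0.2).
#' @return Logical matrix.
#' @export
segment_structure_mask <- function(fit, min_prob = 0.2) {
  prob <- if (inherits(fit, "gmm_fit")) fit$posterior else fit
  assert_image(prob)
  if (diff(range(prob)) == 0) stop("constant probabilities", call. = FALSE)
  if (max(prob) < min_prob) {
    warning("no structure found: all probabilities below guard",
            call. = FALSE)
    return(matrix(FALSE, nrow(prob), ncol(prob)))
  }
  prob > otsu_threshold(prob)
}

#' Assign phenotypes from marker calls
#'
#' Applies the phenotype precedence used throughout the package:
#' CD31+ cells are endothelial; then CD3+CD4+FOXP3+ are regulatory T cells,
#' CD3+CD4+ helper T cells, CD3+CD8+ killer T cells; CD68+ macrophages;
#' AE1/CK26+ epithelial; everything else `other`. CD4/CD8 double-positive
#' T cells are resolved toward the marker with the larger mean probability
#' and flagged ambiguous.
#'
#' @param nuclei tibble from [segment_nuclei()].
#' @param calls tibble of marker calls (rows from
#'   [call_marker_on_nuclei()], all markers stacked). Must cover CD3, CD4,
#'   CD8, FOXP3, CD68 and CD31 for every nucleus.
#' @return Tibble of 2D cell records: the nucleus columns plus `phenotype`
#'   and `ambiguous`.
#' @export
phenotype_cells <- function(nuclei, calls) {
  required <- c("CD3", "CD4", "CD8", "FOXP3", "CD68", "CD31")
  have <- unique(calls$marker)
  missing <- setdiff(required, have)
  if (length(missing)) {
    stop("missing required marker call(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pos <- tidyr::pivot_wider(calls, id_cols = "nucleus_id",
                            names_from = "marker",
                            values_from = c("positive", "p"))
  get <- function(nm, default) {
    if (nm %in% names(pos)) pos[[nm]] else rep(default, nrow(pos))
  }
  cd3 <- get("positive_CD3", FALSE); cd4 <- get("positive_CD4", FALSE)
  cd8 <- get("positive_CD8", FALSE); foxp3 <- get("positive_FOXP3", FALSE)
  cd68 <- get("positive_CD68", FALSE); cd31 <- get("positive_CD31", FALSE)
  epi <- get("positive_AE1", FALSE) | get("positive_CK26", FALSE)
  p4 <- get("p_CD4", 0); p8 <- get("p_CD8", 0)

  ambiguous <- cd3 & cd4 & cd8
  t4 <- cd4 & (!cd8 | p4 >= p8)      # double positives resolved by larger p
  t8 <- cd8 & (!cd4 | p8 > p4)
  phenotype <- dplyr::case_when(
    cd31 ~ "endothelial",
    cd3 & t4 & foxp3 ~ "Treg",
    cd3 & t4 ~ "Thelper",
    cd3 & t8 ~ "Tkiller",
    cd68 ~ "macrophage",
    epi ~ "epithelial",
    TRUE ~ "other")
  out <- dplyr::left_join(nuclei,
                          tibble::tibble(nucleus_id = pos$nucleus_id,
                                         phenotype = phenotype,
                                         ambiguous = ambiguous),
                          by = "nucleus_id")
  out$phenotype[is.na(out$phenotype)] <- "other"
  out$ambiguous[is.na(out$ambiguous)] <- FALSE
  out
}
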