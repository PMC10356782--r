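# Internal helpers shared across modules. Images are base-R numeric matrices
# with rows = y and columns = x; pixel (r, c) has its centre at
# x = (c - 1) * pixel_size_um, y = (r - 1) * pixel_size_um.

assert_image <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix (2D raster)", arg),
         call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite pixels", arg), call. = FALSE)
  }
  invisible(x)
}

assert_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("shape mismatch: %s are %s vs %s", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(NULL)
}

#' @noRd
pixel_centers_um <- function(dim_px, pixel_size_um) {
  list(x = (seq_len(dim_px[2]) - 1) * pixel_size_um,
       y = (seq_len(dim_px[1]) - 1) * pixel_size_um)
}

# Bilinear interpolation of `img` at fractional pixel coordinates
# (x_px, y_px), both 0-based (0 = centre of first column/row).
# Out-of-bounds samples return `fill`.
bilinear_sample <- function(img, x_px, y_px, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x_px); y0 <- floor(y_px)
  fx <- x_px - x0; fy <- y_px - y0
  c0 <- x0 + 1L; r0 <- y0 + 1L       # 1-based indices of top-left neighbour
  inb <- c0 >= 1L & c0 <= nc & r0 >= 1L & r0 <= nr
  # clamp the +1 neighbour to the border (replicate edge) for in-bound points
  c1 <- pmin(c0 + 1L, nc); r1 <- pmin(r0 + 1L, nr)
  out <- rep(fill, length(x_px))
  if (any(inb)) {
    ca <- c0[inb]; cb <- c1[inb]; ra <- r0[inb]; rb <- r1[inb]
    fxa <- fx[inb]; fya <- fy[inb]
    v00 <- img[cbind(ra, ca)]; v01 <- img[cbind(ra, cb)]
    v10 <- img[cbind(rb, ca)]; v11 <- img[cbind(rb, cb)]
    out[inb] <- (1 - fya) * ((1 - fxa) * v00 + fxa * v01) +
      fya * ((1 - fxa) * v10 + fxa * v11)
  }
  out
}

# Nearest-neighbour interpolation, same conventions as bilinear_sample().
nearest_sample <- function(img, x_px, y_px, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  cc <- as.integer(round(x_px)) + 1L
  rr <- as.integer(round(y_px)) + 1L
  inb <- cc >= 1L & cc <= nc & rr >= 1L & rr <= nr
  out <- rep(fill, length(x_px))
  if (any(inb)) out[inb] <- img[cbind(rr[inb], cc[inb])]
  out
}

# Gaussian smoothing with replicate boundary handling.
gauss_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  size <- 2L * as.integer(ceiling(3 * sigma_px)) + 1L
  size <- min(size, 2L * (min(dim(img)) %/% 2L) - 1L)
  if (size < 3L) return(img)
  k <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma_px)
  k <- k / sum(k)
  as.matrix(EBImage::filter2(img, k, boundary = "replicate"))
}

# 4- or 8-connected labelling of a logical mask; returns an integer matrix
# with 0 = background, components numbered in raster-scan order of their
# anchor (lowest row, then column).
label_components <- function(mask, connectivity = 4L) {
  stopifnot(connectivity %in% c(4L, 8L))
  if (connectivity == 4L) {
    lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
    lab <- matrix(as.integer(lab), nrow(mask))
  } else {
    lab <- label8(mask)
  }
  relabel_by_anchor(lab)
}

# 8-connected labelling via union of the 4-connected labels across
# diagonal-adjacent pairs.
label8 <- function(mask) {
  lab4 <- matrix(as.integer(EBImage::bwlabel(matrix(as.numeric(mask),
                                                    nrow(mask)))),
                 nrow(mask))
  n <- max(lab4)
  if (n <= 1L) return(lab4)
  nr <- nrow(lab4); nc <- ncol(lab4)
  ra <- seq_len(nr - 1L); ca <- seq_len(nc - 1L)
  pairs <- rbind(
    cbind(as.vector(lab4[ra, ca]),      as.vector(lab4[ra + 1L, ca + 1L])),
    cbind(as.vector(lab4[ra + 1L, ca]), as.vector(lab4[ra, ca + 1L])))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab4)
  map <- union_find(n, pairs)
  out <- lab4
  out[out > 0L] <- map[out[out > 0L]]
  out
}

# Simple union-find over 1..n given an edge matrix; returns the component id
# (root-canonical, renumbered 1..k) of each element.
union_find <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}

relabel_by_anchor <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(lab)
  idx <- which(lab > 0L)
  # raster-scan order: by row, then column (column-major index reordered)
  rr <- (idx - 1L) %% nrow(lab) + 1L
  cc <- (idx - 1L) %/% nrow(lab) + 1L
  ord <- order(rr, cc)
  first <- !duplicated(lab[idx][ord])
  map <- integer(n)
  map[lab[idx][ord][first]] <- seq_len(sum(first))
  out <- lab
  out[idx] <- map[lab[idx]]
  out
}

# Deterministic hash of an R object (used by determinism tests and reports).
object_hash <- function(x) rlang::hash(x)

signif6 <- function(x) signif(x, 6)
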