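# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# textured masked AF-like image pair for registration unit tests
make_af_image <- function(seed = 5, shape = c(160, 192)) {
  withr::with_seed(seed, {
    base <- mxif3d:::gauss_blur(matrix(stats::runif(prod(shape)), shape[1]),
                                4)
    mask <- matrix(FALSE, shape[1], shape[2])
    mask[25:(shape[1] - 15), 25:(shape[2] - 20)] <- TRUE
    img <- (base - mean(base)) / stats::sd(base) * mask
    list(img = img, mask = mask)
  })
}

# small phantom shared across phantom/reconstruct tests
tiny_phantom <- function() {
  cached("tiny_phantom", function() {
    generate_phantom(phantom_config(
      n_sections = 5, image_shape = c(128L, 160L), seed = 21,
      cell_density_per_type = c(Thelper = 25, Tkiller = 4, Treg = 5,
                                macrophage = 8, endothelial = 8,
                                epithelial = 15, other = 6),
      vessel_count = 3, include_damage_markers = FALSE))
  })
}

# independent union-find used by fusion oracles (kept separate from the
# package's igraph-based implementation)
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, a, b) {
  ra <- uf_find(parent, a); rb <- uf_find(parent, b)
  if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  parent
}

# brute-force nearest-structure search (all pairs), the oracle for the
# pruned implementation
brute_nearest <- function(cells, structure, mode = "3D") {
  sapply(seq_len(nrow(cells)), function(i) {
    if (mode == "2D") {
      idx <- which(structure$retained_index == cells$retained_index[i])
      if (length(idx) == 0) return(NA_real_)
      min(sqrt((structure$x_um[idx] - cells$x_um[i])^2 +
                 (structure$y_um[idx] - cells$y_um[i])^2))
    } else {
      min(sqrt((structure$x_um - cells$x_um[i])^2 +
                 (structure$y_um - cells$y_um[i])^2 +
                 (structure$z_um - cells$z_um[i])^2))
    }
  })
}
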