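#' Convert an RGB image to grayscale
#'
#' Collapses a 3-channel image to a single luminance channel using the
#' ITU-R BT.601 weights 0.299, 0.587, 0.114 (red, green, blue), the standard
#' convention for luma in image analysis. Output intensities are rounded to
#' the nearest integer so the result stays on the 0--255 grid.
#'
#' @param rgb a `height x width x 3` numeric array with channel values in
#'   \[0, 255\].
#' @return a numeric matrix (`height x width`) of intensities in \[0, 255\].
#' @examples
#' img <- array(0, c(2, 2, 3)); img[, , 1] <- 255 # pure red
#' to_grayscale(img)[1, 1] # 76
#' @export
to_grayscale <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("`rgb` must be a height x width x 3 array, got dimensions: ",
         paste(dim(rgb), collapse = " x "))
  if (min(rgb) < 0 || max(rgb) > 255)
    stop("channel values must lie in [0, 255]")
  g <- 0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
  round_half_up(matrix(g, dim(rgb)[1L], dim(rgb)[2L]), 0L)
}

#' Discretized Gaussian kernel
#'
#' @param size odd kernel side length (default 5).
#' @param sigma Gaussian standard deviation in pixels (default 1).
#' @return a `size x size` matrix normalized to sum to 1.
#' @export
gaussian_kernel <- function(size = 5L, sigma = 1) {
  if (size %% 2L != 1L || size < 1L) stop("`size` must be a positive odd integer")
  if (sigma <= 0) stop("`sigma` must be positive")
  d <- seq_len(size) - (size + 1L) / 2
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  k / sum(k)
}

#' Smooth a grayscale image with a 5x5 Gaussian filter
#'
#' Convolves the image with a normalized discretized Gaussian. Borders are
#' handled by mirror reflection (the edge row/column is included in the
#' reflection), which avoids the artificial darkening at the image edge that
#' zero padding would introduce and that would bias the Otsu threshold.
#'
#' @param gray a numeric matrix of intensities in \[0, 255\].
#' @param size odd kernel side length, default 5.
#' @param sigma Gaussian standard deviation, default 1 pixel.
#' @return a numeric matrix of the same dimensions (not re-rounded).
#' @export
gaussian_smooth <- function(gray, size = 5L, sigma = 1) {
  if (!is.matrix(gray)) stop("`gray` must be a matrix")
  k <- gaussian_kernel(size, sigma)
  h <- nrow(gray); w <- ncol(gray)
  if (h < size || w < size)
    stop("image (", h, " x ", w, ") is smaller than the ", size, " x ", size,
         " filter kernel")
  pad <- (size - 1L) %/% 2L
  ri <- c(pad:1, 1:h, h:(h - pad + 1L))
  ci <- c(pad:1, 1:w, w:(w - pad + 1L))
  p <- gray[ri, ci, drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(size))
    for (j in seq_len(size))
      out <- out + k[i, j] * p[i:(i + h - 1L), j:(j + w - 1L)]
  out
}

#' Otsu's optimal threshold
#'
#' Selects the intensity threshold maximizing the between-class variance of
#' the 256-bin histogram, i.e. the classical Otsu criterion
#' \eqn{\sigma_b^2(t) = \omega_0(t)\,\omega_1(t)\,(\mu_0(t) - \mu_1(t))^2}
#' for the split into pixels \eqn{\le t} (background) and \eqn{> t}
#' (foreground). Intensities are rounded to integers before binning. Ties are
#' broken toward the smallest threshold so the result is deterministic.
#'
#' @param gray a numeric matrix of intensities in \[0, 255\].
#' @return an integer threshold in 0..254; pass it to [binarize()].
#' @export
otsu_threshold <- function(gray) {
  v <- round_half_up(as.numeric(gray), 0L)
  if (min(v) < 0 || max(v) > 255) stop("intensities must lie in [0, 255]")
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    stop("cannot threshold a constant image (single intensity value)")
  n <- sum(counts)
  p <- counts / n
  lev <- 0:255
  w0 <- cumsum(p)[1:255]               # P(pixel <= t), t = 0..254
  mu0 <- cumsum(p * lev)[1:255]        # unnormalized class-0 mean
  mu_t <- sum(p * lev)
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 255)
  sigma_b[ok] <- (mu_t * w0[ok] - mu0[ok])^2 / (w0[ok] * w1[ok])
  as.integer(which.max(sigma_b) - 1L)  # which.max takes the first maximum
}

#' Binarize a grayscale image at a threshold
#'
#' Pixels strictly brighter than `t` become foreground (1). Seeds are imaged
#' as bright kernels on a near-black background, so the `> t` side is kept.
#'
#' @param gray a numeric matrix of intensities.
#' @param t threshold in \[0, 255\].
#' @return an integer 0/1 matrix of the same dimensions.
#' @export
binarize <- function(gray, t) {
  if (!is.matrix(gray)) stop("`gray` must be a matrix")
  if (length(t) != 1L || !is.finite(t) || t < 0 || t > 255)
    stop("`t` must be a single value in [0, 255]")
  m <- matrix(0L, nrow(gray), ncol(gray))
  m[gray > t] <- 1L
  m
}

#' Label connected seed regions in a binary mask
#'
#' Finds 8-connected components of the foreground and labels them 1..n in
#' raster-scan order of each component's first pixel (top row first, then
#' leftmost column), so labels are reproducible. Components smaller than
#' `min_area` pixels are treated as noise specks and discarded.
#'
#' 8-connectivity (two pixels are neighbours if they touch by edge *or*
#' corner) matches the 8-direction chain-code convention used for the
#' perimeter, so a region's boundary trace never leaves the region.
#'
#' @param mask an integer 0/1 matrix, e.g. from [binarize()].
#' @param min_area minimum component area in pixels (default 50).
#' @return an integer label matrix of the same dimensions; 0 is background
#'   and the attribute `n_regions` holds the number of retained regions.
#' @export
segment_seeds <- function(mask, min_area = 50L) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  if (!all(mask %in% c(0L, 1L))) stop("`mask` must contain only 0 and 1")
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  fg <- which(mask == 1L)              # column-major linear indices
  if (length(fg)) {
    id <- integer(h * w)               # linear index -> vertex id
    id[fg] <- seq_along(fg)
    r <- ((fg - 1L) %% h) + 1L
    co <- ((fg - 1L) %/% h) + 1L
    # half of the 8-neighbourhood (E, SE, S, SW); the rest follow by symmetry
    edges <- vector("list", 4L)
    off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
    for (i in seq_along(off)) {
      nr <- r + off[[i]][1L]; nc <- co + off[[i]][2L]
      keep <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      nb <- (nc[keep] - 1L) * h + nr[keep]
      has <- id[nb] > 0L
      edges[[i]] <- cbind(id[fg[keep]][has], id[nb][has])
    }
    el <- do.call(rbind, edges)
    g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
    if (nrow(el)) g <- igraph::add_edges(g, t(el))
    memb <- igraph::components(g)$membership
    # raster-scan key: row-major position of each pixel
    raster <- (r - 1L) * w + co
    first <- tapply(raster, memb, min)
    areas <- tabulate(memb)
    keep_comp <- which(areas >= min_area)
    keep_comp <- keep_comp[order(first[as.character(keep_comp)])]
    newlab <- integer(max(memb))
    newlab[keep_comp] <- seq_along(keep_comp)
    labels[fg] <- newlab[memb]
  }
  attr(labels, "n_regions") <- max(labels)
  labels
}

#' Number of labeled regions in a label map
#' @param labels an integer label matrix from [segment_seeds()].
#' @return the number of distinct positive labels.
#' @export
n_regions <- function(labels) {
  n <- attr(labels, "n_regions")
  if (is.null(n)) n <- max(0L, labels)
  as.integer(n)
}
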