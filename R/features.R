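#' Extract per-seed regions from a label map
#'
#' @param labels an integer label matrix from [segment_seeds()].
#' @return a list of `seed_region` objects, one per label, each a list with
#'   `label` and `pixels` (an `n x 2` matrix of (row, col) pixel coordinates
#'   in raster order).
#' @export
seed_regions <- function(labels) {
  n <- n_regions(labels)
  out <- vector("list", n)
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  for (i in seq_len(n)) {
    px <- idx[lab == i, , drop = FALSE]
    px <- px[order(px[, 1L], px[, 2L]), , drop = FALSE]
    colnames(px) <- c("row", "col")
    out[[i]] <- structure(list(label = i, pixels = px), class = "seed_region")
  }
  out
}

region_pixels <- function(region) {
  if (inherits(region, "seed_region")) region$pixels
  else if (is.matrix(region) && ncol(region) == 2L) region
  else stop("`region` must be a seed_region or an n x 2 (row, col) matrix")
}

# Freeman codes: 0 = E, then counter-clockwise (1 = NE, 2 = N, ..., 7 = SE).
# In matrix coordinates row grows downward, so N is row - 1.
.freeman <- matrix(c(0L, 1L,   -1L, 1L,  -1L, 0L,  -1L, -1L,
                     0L, -1L,   1L, -1L,  1L, 0L,   1L, 1L),
                   ncol = 2L, byrow = TRUE)

# neighbour offsets in visually clockwise order starting at W,
# used by the Moore trace
.moore_cw <- matrix(c(0L, -1L,  -1L, -1L,  -1L, 0L,  -1L, 1L,
                      0L, 1L,    1L, 1L,    1L, 0L,   1L, -1L),
                    ncol = 2L, byrow = TRUE)

#' Trace a region boundary as a Freeman chain code
#'
#' Moore-neighbour contour tracing over the 8-neighbourhood, visually
#' clockwise, starting from the topmost-then-leftmost pixel of the region.
#' The trace walks the outer boundary and returns to its start, so the chain
#' is closed; one-pixel-wide protrusions are traversed out and back. A
#' single-pixel region has, by convention, an empty chain.
#'
#' @param region a `seed_region` or an `n x 2` (row, col) pixel matrix.
#' @return a `chain_code` object: a list with `start` (the (row, col) start
#'   pixel) and `moves` (integer Freeman codes in 0..7; 0 = east,
#'   counter-clockwise).
#' @export
trace_boundary <- function(region) {
  px <- region_pixels(region)
  if (nrow(px) == 0L) stop("region has no pixels")
  rmin <- min(px[, 1L]); cmin <- min(px[, 2L])
  h <- max(px[, 1L]) - rmin + 1L; w <- max(px[, 2L]) - cmin + 1L
  # local mask with a 1-pixel background border so neighbour lookups
  # never leave bounds
  m <- matrix(FALSE, h + 2L, w + 2L)
  m[cbind(px[, 1L] - rmin + 2L, px[, 2L] - cmin + 2L)] <- TRUE
  ord <- order(px[, 1L], px[, 2L])
  start <- c(px[ord[1L], 1L] - rmin + 2L, px[ord[1L], 2L] - cmin + 2L)

  chain_out <- function(start_local, moves) {
    structure(list(start = c(start_local[1L] + rmin - 2L,
                             start_local[2L] + cmin - 2L),
                   moves = as.integer(moves)),
              class = "chain_code")
  }

  cur <- start
  bk <- start + c(0L, -1L)             # west neighbour is background
  seen <- new.env(hash = TRUE, parent = emptyenv())
  path <- matrix(0L, nrow = 8L * nrow(px) + 16L, ncol = 2L)
  np <- 0L
  cycle_from <- NA_integer_
  repeat {
    key <- paste(cur[1L], cur[2L], bk[1L], bk[2L])
    prev <- seen[[key]]
    if (!is.null(prev)) { cycle_from <- prev; break }
    np <- np + 1L
    seen[[key]] <- np
    path[np, ] <- cur
    # scan the 8 neighbours clockwise beginning at the backtrack pixel
    d <- bk - cur
    k0 <- which(.moore_cw[, 1L] == d[1L] & .moore_cw[, 2L] == d[2L])
    found <- FALSE
    for (j in 0:7) {
      k <- ((k0 - 1L + j) %% 8L) + 1L
      nb <- cur + .moore_cw[k, ]
      if (m[nb[1L], nb[2L]]) {
        kprev <- ((k0 - 1L + j - 1L) %% 8L) + 1L
        bk <- cur + .moore_cw[kprev, ]
        cur <- nb
        found <- TRUE
        break
      }
    }
    if (!found) return(chain_out(start, integer(0L)))  # isolated pixel
  }
  cyc <- path[cycle_from:np, , drop = FALSE]
  # rotate the cyclic boundary so the chain starts at the topmost-leftmost pixel
  i0 <- which(cyc[, 1L] == start[1L] & cyc[, 2L] == start[2L])[1L]
  if (i0 > 1L) cyc <- cyc[c(i0:nrow(cyc), 1:(i0 - 1L)), , drop = FALSE]
  nxt <- rbind(cyc[-1L, , drop = FALSE], cyc[1L, , drop = FALSE])
  dr <- nxt[, 1L] - cyc[, 1L]; dc <- nxt[, 2L] - cyc[, 2L]
  moves <- integer(nrow(cyc))
  for (i in seq_len(8L)) {
    moves[dr == .freeman[i, 1L] & dc == .freeman[i, 2L]] <- i - 1L
  }
  chain_out(cyc[1L, ], moves)
}

#' Chain-code perimeter
#'
#' Perimeter of a closed Freeman chain:
#' \deqn{P = \sqrt{2}\,N_d + N_x + N_y,}
#' where \eqn{N_d} is the number of diagonal (odd) codes and \eqn{N_x},
#' \eqn{N_y} the numbers of horizontal and vertical (even) codes. Each
#' axis-parallel step contributes a pixel side length of 1 and each diagonal
#' step \eqn{\sqrt 2}.
#'
#' @param chain a `chain_code` from [trace_boundary()].
#' @return the perimeter in pixel units (0 for an empty chain).
#' @export
chain_perimeter <- function(chain) {
  moves <- if (inherits(chain, "chain_code")) chain$moves else as.integer(chain)
  if (length(moves) && (min(moves) < 0L || max(moves) > 7L))
    stop("chain codes must lie in 0..7")
  n_d <- sum(moves %% 2L == 1L)
  n_x <- sum(moves %in% c(0L, 4L))
  n_y <- sum(moves %in% c(2L, 6L))
  sqrt(2) * n_d + n_x + n_y
}

#' Region area
#'
#' The area is the pixel count of the region; each pixel has unit side
#' length.
#'
#' @param region a `seed_region` or an `n x 2` pixel matrix.
#' @return the area in pixels.
#' @export
region_area <- function(region) {
  nrow(region_pixels(region))
}

#' Circularity
#'
#' \deqn{C = 4\pi A / P^2.} Equal to 1 for an ideal disk; smaller for shapes
#' deviating from a circle. For a plump, nearly cylindrical kernel projected
#' onto the image plane, circularity acts as a plumpness proxy. Note that on
#' the pixel grid small digital shapes can exceed 1 because the chain-code
#' perimeter underestimates the continuous boundary.
#'
#' @param A area in pixels.
#' @param P perimeter in pixel units; must be positive.
#' @return the dimensionless circularity.
#' @export
circularity <- function(A, P) {
  if (any(P <= 0)) stop("circularity is undefined for perimeter P = 0")
  4 * pi * A / P^2
}

#' Side lengths of the smallest enclosing rectangle
#'
#' Computes the major and minor side lengths (H, W) of the rectangle
#' enclosing the region. In `"rotated"` mode (default) this is the
#' minimum-area rectangle over the region's convex hull, found by rotating
#' calipers: the minimal rectangle has a side collinear with a hull edge, so
#' it suffices to test each edge direction. In `"aligned"` mode it is the
#' axis-aligned bounding box, which depends on the placement angle of the
#' seed. Side lengths are measured in pixels, counting each pixel as a unit
#' square (an `n`-pixel row has length `n`, not `n - 1`). Degenerate
#' (collinear) regions get minor side 1.
#'
#' @param region a `seed_region` or an `n x 2` pixel matrix.
#' @param mode `"rotated"` (minimum-area rectangle) or `"aligned"`
#'   (axis-aligned bounding box).
#' @return a named numeric vector `c(H = major, W = minor)` with `H >= W`.
#' @export
region_axes <- function(region, mode = c("rotated", "aligned")) {
  mode <- match.arg(mode)
  px <- region_pixels(region)
  if (nrow(px) == 0L) stop("region has no pixels")
  if (mode == "aligned") {
    sides <- c(max(px[, 1L]) - min(px[, 1L]) + 1,
               max(px[, 2L]) - min(px[, 2L]) + 1)
    return(c(H = max(sides), W = min(sides)))
  }
  pts <- unique(cbind(x = px[, 2L], y = px[, 1L]))
  if (nrow(pts) == 1L) return(c(H = 1, W = 1))
  hull <- pts[chull(pts), , drop = FALSE]
  if (nrow(hull) <= 2L || hull_area(hull) < 1e-9) {
    d <- max(dist(pts))
    return(c(H = d + 1, W = 1))
  }
  best <- c(Inf, 0, 0)
  nh <- nrow(hull)
  for (i in seq_len(nh)) {
    e <- hull[if (i == nh) 1L else i + 1L, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    u <- e / len; v <- c(-u[2L], u[1L])
    pu <- hull %*% u; pv <- hull %*% v
    s1 <- max(pu) - min(pu) + 1
    s2 <- max(pv) - min(pv) + 1
    if (s1 * s2 < best[1L]) best <- c(s1 * s2, s1, s2)
  }
  c(H = max(best[2:3]), W = min(best[2:3]))
}

hull_area <- function(hull) {
  x <- hull[, 1L]; y <- hull[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Elongation
#'
#' \deqn{E = H / W,} the ratio of the major to the minor side of the
#' enclosing rectangle, so \eqn{E \ge 1}: 1 for equiaxed shapes, large for
#' slender ones.
#'
#' @param H major side length; `W` minor side length (`W > 0`).
#' @param W minor side length.
#' @return the dimensionless elongation.
#' @export
elongation <- function(H, W) {
  if (any(W <= 0)) stop("elongation is undefined for W = 0")
  H / W
}

#' Rectangularity
#'
#' \deqn{R = A / (H \times W),} the fraction of the enclosing rectangle
#' filled by the region. 1 for a solid rectangle, about \eqn{\pi/4} for an
#' ellipse.
#'
#' @param A area in pixels.
#' @param H,W enclosing-rectangle side lengths (`H * W > 0`).
#' @return the dimensionless rectangularity.
#' @export
rectangularity <- function(A, H, W) {
  if (any(H * W <= 0)) stop("rectangularity is undefined for H * W = 0")
  A / (H * W)
}

#' Extract the five geometric descriptors of one seed region
#'
#' Assembles area, chain-code perimeter, circularity, elongation and
#' rectangularity for a region.
#'
#' @param region a `seed_region` or an `n x 2` pixel matrix.
#' @param axis_mode passed to [region_axes()].
#' @return a named numeric vector `c(A, P, C, E, R)`.
#' @export
extract_features <- function(region, axis_mode = c("rotated", "aligned")) {
  axis_mode <- match.arg(axis_mode)
  px <- region_pixels(region)
  if (nrow(px) == 0L) stop("region has no pixels")
  A <- region_area(px)
  P <- chain_perimeter(trace_boundary(px))
  C <- circularity(A, P)               # errors for single-pixel regions
  hw <- region_axes(px, axis_mode)
  c(A = A, P = P, C = C,
    E = elongation(hw[["H"]], hw[["W"]]),
    R = rectangularity(A, hw[["H"]], hw[["W"]]))
}

#' Feature table for all regions of a label map
#'
#' Applies [extract_features()] to every labeled region. Single-pixel
#' regions, whose perimeter is zero and whose circularity is therefore
#' undefined, are dropped with a warning.
#'
#' @param labels an integer label matrix from [segment_seeds()], or a list of
#'   `seed_region`s.
#' @param axis_mode passed to [region_axes()].
#' @return a data frame with columns `Num, A, P, C, E, R`, one row per
#'   retained region.
#' @export
feature_table <- function(labels, axis_mode = c("rotated", "aligned")) {
  axis_mode <- match.arg(axis_mode)
  regions <- if (is.list(labels)) labels else seed_regions(labels)
  rows <- lapply(regions, function(rg) {
    if (nrow(region_pixels(rg)) < 2L) {
      warning("dropping single-pixel region ", rg$label,
              " (perimeter 0, circularity undefined)")
      return(NULL)
    }
    fv <- extract_features(rg, axis_mode)
    data.frame(Num = rg$label, A = fv[["A"]], P = fv[["P"]], C = fv[["C"]],
               E = fv[["E"]], R = fv[["R"]])
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(data.frame(Num = integer(0L), A = numeric(0L), P = numeric(0L),
                      C = numeric(0L), E = numeric(0L), R = numeric(0L)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
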