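# Independent oracles and small shape builders used across the test files.

# exhaustive between-class-variance maximizer (Otsu oracle)
brute_otsu <- function(gray) {
  v <- as.integer(round(as.numeric(gray)))
  best_t <- -1L
  best <- -Inf
  for (t in 0:254) {
    g0 <- v[v <= t]
    g1 <- v[v > t]
    if (!length(g0) || !length(g1)) next
    w0 <- length(g0) / length(v)
    s <- w0 * (1 - w0) * (mean(g0) - mean(g1))^2
    if (s > best + 1e-12) {
      best <- s
      best_t <- t
    }
  }
  best_t
}

between_class_variance <- function(gray, t) {
  v <- as.integer(round(as.numeric(gray)))
  g0 <- v[v <= t]; g1 <- v[v > t]
  if (!length(g0) || !length(g1)) return(-Inf)
  w0 <- length(g0) / length(v)
  w0 * (1 - w0) * (mean(g0) - mean(g1))^2
}

# dominant eigenvalue by power iteration (consistency oracle)
power_eigen <- function(M, iters = 1000L) {
  M <- unclass(M)
  v <- rep(1, nrow(M))
  for (i in seq_len(iters)) {
    v <- as.vector(M %*% v)
    v <- v / sum(v)
  }
  mean(as.vector(M %*% v) / v)
}

# per-move Euclidean step lengths of a chain (perimeter oracle)
chain_step_length <- function(chain) {
  moves <- chain$moves
  sum(ifelse(moves %% 2L == 1L, sqrt(2), 1))
}

# replay a chain from its start pixel; returns the visited pixel path
replay_chain <- function(chain) {
  steps <- matrix(c(0L, 1L, -1L, 1L, -1L, 0L, -1L, -1L,
                    0L, -1L, 1L, -1L, 1L, 0L, 1L, 1L),
                  ncol = 2L, byrow = TRUE)
  pos <- matrix(0L, length(chain$moves) + 1L, 2L)
  pos[1L, ] <- chain$start
  for (i in seq_along(chain$moves))
    pos[i + 1L, ] <- pos[i, ] + steps[chain$moves[i] + 1L, ]
  pos
}

# pixel matrix of a solid axis-aligned rectangle
rect_pixels <- function(r0, c0, h, w) {
  as.matrix(expand.grid(row = r0:(r0 + h - 1L), col = c0:(c0 + w - 1L)))
}

# mask with given foreground pixel matrix
pixels_to_mask <- function(px, dim) {
  m <- matrix(0L, dim[1L], dim[2L])
  m[px] <- 1L
  m
}

# rasterized ellipse pixel set (package-internal rasterizer)
ellipse_pixels <- function(center, a, b, angle = 0, dim = c(200L, 200L)) {
  wheatgrade:::rasterize_blob(blob_spec(center, a, b, angle), dim)
}

# printed reference values of the worked example, used by several files
ref_weights <- c(A = 0.2824, P = 0.2616, C = 0.1144, E = 0.1889, R = 0.1525)
ref_scores <- data.frame(
  Num = 1:14,
  S = c(0.6907, 0.7072, 0.7753, 0.817, 0.6646, 0.7167, 0.52,
        0.8497, 0.8084, 0.7679, 0.7869, 0.888, 0.8416, 0.8059))
ref_order <- c(12, 8, 13, 4, 9, 14, 11, 3, 10, 6, 2, 1, 5, 7)
ref_normalized <- matrix(c(
  0.7425, 0.6517, 1,      0.4328, 0.7499,
  0.6379, 0.7978, 0.5733, 0.6659, 0.8328,
  0.6108, 0.7528, 0.6164, 1,      0.9604,
  0.9073, 0.8539, 0.7116, 0.6399, 0.8861,
  0.659,  0.7416, 0.6853, 0.477,  0.7609,
  0.7378, 0.7528, 0.7446, 0.5526, 0.7993,
  0.3585, 0.7528, 0.3619, 0.4962, 0.5684,
  0.8707, 0.8427, 0.7012, 0.7973, 1,
  1,      0.8764, 0.7446, 0.4769, 0.7966,
  0.9009, 0.7528, 0.9092, 0.4637, 0.8192,
  0.7043, 0.8202, 0.5988, 0.8402, 0.9589,
  0.8583, 1,      0.4909, 0.9399, 0.9858,
  0.8663, 0.9326, 0.5697, 0.8116, 0.8822,
  0.8794, 0.7753, 0.8368, 0.606,  0.9477),
  ncol = 5L, byrow = TRUE, dimnames = list(NULL, c("A", "P", "C", "E", "R")))
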