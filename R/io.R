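#' Read a seed photograph (PNG or BMP)
#'
#' Reads an image file into a `height x width x 3` array with channel values
#' in \[0, 255\]. PNG files are read with the \pkg{png} package (an alpha
#' channel, if present, is dropped; grayscale PNGs are replicated across the
#' three channels). BMP files are parsed directly: uncompressed 8-bit
#' (palette), 24-bit and 32-bit Windows bitmaps are supported.
#'
#' @param path path to a `.png` or `.bmp` file.
#' @return a numeric `h x w x 3` array in \[0, 255\].
#' @export
read_seed_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    if (dim(a)[3L] >= 4L) a <- a[, , 1:3, drop = FALSE]
    if (dim(a)[3L] == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
    if (dim(a)[3L] == 2L) a <- array(rep(a[, , 1L], 3L), c(dim(a)[1:2], 3L))
    return(a * 255)
  }
  if (ext == "bmp") return(read_bmp(path))
  stop("unsupported image format '.", ext, "' (expected PNG or BMP)")
}

# minimal reader for uncompressed Windows BMP (8/24/32 bits per pixel)
read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file: ", path)
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * c(1, 256))
  u32 <- function(i) sum(as.integer(raw[i + 0:3]) * 256^(0:3))
  data_off <- u32(11L)
  hdr_size <- u32(15L)
  width <- u32(19L)
  height_raw <- u32(23L)
  top_down <- height_raw > 2^31 - 1
  height <- if (top_down) 2^32 - height_raw else height_raw
  bpp <- u16(29L)
  compression <- u32(31L)
  if (compression != 0) stop("compressed BMP files are not supported")
  if (!bpp %in% c(8L, 24L, 32L))
    stop("unsupported BMP bit depth: ", bpp)
  palette <- NULL
  if (bpp == 8L) {
    n_colors <- u32(47L)
    if (n_colors == 0) n_colors <- 256L
    pal_off <- 14L + hdr_size
    idx <- pal_off + 4L * (seq_len(n_colors) - 1L)
    palette <- cbind(r = as.integer(raw[idx + 3L]),   # stored BGRA
                     g = as.integer(raw[idx + 2L]),
                     b = as.integer(raw[idx + 1L]))
  }
  bytes_pp <- bpp %/% 8L
  row_bytes <- ((width * bytes_pp + 3L) %/% 4L) * 4L
  out <- array(0, c(height, width, 3L))
  for (i in seq_len(height)) {
    # rows are stored bottom-up unless the height field was negative
    r_img <- if (top_down) i else height - i + 1L
    start <- data_off + (i - 1L) * row_bytes
    row <- as.integer(raw[start + seq_len(width * bytes_pp)])
    if (bpp == 8L) {
      out[r_img, , ] <- palette[row + 1L, , drop = FALSE]
    } else {
      m <- matrix(row, ncol = bytes_pp, byrow = TRUE)   # B, G, R(, A)
      out[r_img, , 1L] <- m[, 3L]
      out[r_img, , 2L] <- m[, 2L]
      out[r_img, , 3L] <- m[, 1L]
    }
  }
  out
}

#' Write a binary mask or label map as a PNG image
#'
#' A 0/1 mask is written black/white; a label map is written with one gray
#' level per label (background black).
#'
#' @param x an integer matrix (mask or label map).
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(x, path) {
  mx <- max(x, 1L)
  png::writePNG(x / mx, path)
  invisible(path)
}

#' Write a label map as a CSV of (row, col, label) triples
#'
#' Only foreground pixels are written.
#'
#' @param labels an integer label matrix from [segment_seeds()].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  fg <- which(labels > 0L, arr.ind = TRUE)
  df <- data.frame(row = fg[, 1L], col = fg[, 2L],
                   label = labels[fg])
  df <- df[order(df$label, df$row, df$col), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write a seed feature table
#'
#' The on-disk dialect is a CSV with header `Num,A,P,C,E,R`: seed number,
#' area (pixels), perimeter, circularity, elongation, rectangularity.
#'
#' @param path a `.csv` path.
#' @return `read_feature_table()` returns a data frame with columns
#'   `Num, A, P, C, E, R`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  need <- c("Num", "A", "P", "C", "E", "R")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("feature table is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  if (anyNA(df) || !all(vapply(df, is.numeric, logical(1L))))
    stop("feature table contains missing or non-numeric values")
  df
}

#' @rdname read_feature_table
#' @param features a feature data frame (`Num,A,P,C,E,R`).
#' @export
write_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pairwise comparison matrix from CSV or JSON
#'
#' CSV: an `n x n` table whose header row gives the criterion names; cells
#' may be decimals or fractions written as `a/b` (e.g. `1/3`), the usual way
#' reciprocal judgments are recorded. JSON: an object with fields
#' `criteria` (array of names) and `matrix` (array of rows).
#'
#' @param path a `.csv` or `.json` file.
#' @return a validated [comparison_matrix()].
#' @export
read_comparison_matrix <- function(path) {
  if (!file.exists(path)) stop("comparison matrix file not found: ", path)
  if (tolower(tools::file_ext(path)) == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    m <- as.matrix(obj$matrix)
    return(comparison_matrix(m, criteria = obj$criteria))
  }
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  m <- apply(as.matrix(df), c(1L, 2L), parse_fraction)
  comparison_matrix(m, criteria = names(df))
}

parse_fraction <- function(s) {
  s <- trimws(s)
  if (grepl("^[0-9.]+\\s*/\\s*[0-9.]+$", s)) {
    parts <- as.numeric(strsplit(s, "/")[[1L]])
    return(parts[1L] / parts[2L])
  }
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("cannot parse matrix entry: '", s, "'")
  v
}
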