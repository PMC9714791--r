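## Shared raster utilities: separable Gaussian filtering, connected
## components (via the pixel-adjacency graph), hole filling, Otsu
## threshold, and plain-text PGM image I/O.

## 1-D Gaussian kernel, truncated at 3.5 sigma, normalised to sum 1.
.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

## Convolve along matrix columns (i.e. across the row index) with
## replicate padding, by accumulating shifted copies.
.conv_dim1 <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k)) {
    idx <- pmin(pmax(seq_len(n) + (i - 1L - r), 1L), n)
    out <- out + k[i] * m[idx, , drop = FALSE]
  }
  out
}

#' Separable Gaussian blur
#'
#' @param image numeric matrix.
#' @param sigma Gaussian SD in pixels.
#' @return blurred matrix of the same shape (replicate-padded edges).
#' @export
gaussian_blur <- function(image, sigma) {
  stopifnot(is.matrix(image), sigma > 0)
  k <- .gauss_kernel(sigma)
  t(.conv_dim1(t(.conv_dim1(image, k)), k))
}

#' Label connected components of a binary mask
#'
#' 4- or 8-connectivity; labelling is performed on the pixel-adjacency
#' graph via [igraph::components()].
#'
#' @param mask logical matrix.
#' @param connectivity 4 (default) or 8.
#' @return integer matrix of labels (0 = background), with attribute
#'   `"n"` giving the component count.
#' @export
label_components <- function(mask, connectivity = 4) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, nr, nc)
  if (length(idx) == 0L) { attr(out, "n") <- 0L; return(out) }
  id <- match(seq_len(nr * nc), idx)    # pixel -> vertex id (NA if bg)
  edge_pairs <- function(shift_valid, offset) {
    from <- idx[shift_valid(idx)]
    to <- from + offset
    keep <- !is.na(id[to])
    cbind(id[from[keep]], id[to[keep]])
  }
  row_of <- function(i) ((i - 1L) %% nr) + 1L
  col_of <- function(i) ((i - 1L) %/% nr) + 1L
  edges <- rbind(
    edge_pairs(function(i) row_of(i) < nr, 1L),        # down
    edge_pairs(function(i) col_of(i) < nc, nr)         # right
  )
  if (connectivity == 8) {
    edges <- rbind(edges,
      edge_pairs(function(i) row_of(i) < nr & col_of(i) < nc, nr + 1L),
      edge_pairs(function(i) row_of(i) > 1L & col_of(i) < nc, nr - 1L))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  lab <- igraph::components(g)$membership
  out[idx] <- lab
  attr(out, "n") <- max(lab)
  out
}

#' Fill holes in a binary mask
#'
#' A hole is a background component (4-connectivity) that does not touch
#' the image border.
#'
#' @param mask logical matrix.
#' @return logical matrix with holes set to `TRUE`.
#' @export
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 4)
  border <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  border <- setdiff(border, 0L)
  mask | (bg != 0L & !(bg %in% border))
}

#' Otsu threshold
#'
#' @param image numeric matrix.
#' @param n_bins histogram resolution (default 256).
#' @return scalar threshold maximising between-class variance.
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1L])
  br <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Read and write plain-text PGM (P2) images
#'
#' Portable graymap in its ASCII (`P2`) form: a self-describing,
#' text-only raster format readable without any imaging library.  Used in
#' place of 16-bit TIFF, which has no reader in the offline R stack;
#' intensities are stored as integers up to `maxval` and mapped to
#' `[0, 1]` on read.
#'
#' @param path file path.
#' @param image numeric matrix in `[0, 1]` (values clipped).
#' @param maxval integer full scale on disk (default 65535, 16-bit).
#' @return `read_pgm` returns a numeric matrix in `[0, 1]`.
#' @export
write_pgm <- function(image, path, maxval = 65535L) {
  stopifnot(is.matrix(image))
  q <- round(pmin(pmax(image, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), as.character(maxval)), con)
  ## one image row per line
  writeLines(apply(q, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1L] != "P2") stop("only plain (P2) PGM is supported")
  nc <- as.integer(toks[2L]); nr <- as.integer(toks[3L])
  maxval <- as.numeric(toks[4L])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != nr * nc) stop("corrupt PGM payload")
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE) / maxval
}
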