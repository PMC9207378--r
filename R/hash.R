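# Block partition used by the 8x8 average hash: boundaries at
# floor(i * n / 8) so every pixel belongs to exactly one block and the same
# partition applies to a template and to equally-sized sliding windows.
.hashGrid <- function(n, grid = 8L) floor(seq(0L, n, length.out = grid + 1L))

#' 64-bit average hash of a glyph raster
#'
#' Downsamples a grayscale raster onto an 8 x 8 grid of block means and
#' thresholds each block at the mean of the 64 block means. The tie rule is
#' fixed: a block whose mean is greater than or equal to the threshold maps
#' to bit 1, so a constant raster hashes to all ones. Identical rasters
#' always yield identical hashes.
#'
#' @param pixels numeric intensity matrix (any size >= 8 in each dimension
#'   works; smaller rasters are rejected).
#' @return integer vector of 64 bits (row-major over the 8 x 8 grid).
#' @examples
#' h <- hashGlyph(textGlyph("2"))
#' sum(h)
#' @seealso [hammingDistance()], [locatePanel()]
#' @export
hashGlyph <- function(pixels) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    .fvlStop("fvlInvalidInput", "glyph raster must be a non-empty matrix")
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    .fvlStop("fvlInvalidInput", "glyph raster must be at least 8 x 8")
  rb <- .hashGrid(nrow(pixels))
  cb <- .hashGrid(ncol(pixels))
  means <- matrix(0, 8L, 8L)
  for (i in 1:8) for (j in 1:8) {
    means[i, j] <- mean(pixels[(rb[i] + 1L):rb[i + 1L],
                               (cb[j] + 1L):cb[j + 1L]])
  }
  as.integer(t(means) >= mean(means))  # row-major bit order
}

#' Hamming distance between two 64-bit hashes
#'
#' @param a,b integer bit vectors of equal length.
#' @return number of differing bits.
#' @examples
#' hammingDistance(hashGlyph(textGlyph("2")), hashGlyph(textGlyph("4")))
#' @export
hammingDistance <- function(a, b) {
  if (length(a) != length(b))
    .fvlStop("fvlInvalidInput", "hashes must have equal length")
  sum(a != b)
}

# Hamming distance of the template hash against every sliding window of the
# page (or a sub-rectangle of it), vectorized with an integral image: each
# of the 64 hash blocks is a box sum, so all window positions are evaluated
# with 64 x 4 submatrix reads instead of an explicit per-window loop.
# Returns list(dist = matrix [window top rows x left cols], rows, cols).
.hashSearch <- function(pixels, template, rows = NULL, cols = NULL) {
  tpx <- template@pixels
  h <- nrow(tpx); w <- ncol(tpx)
  if (is.null(rows)) rows <- c(1L, nrow(pixels))
  if (is.null(cols)) cols <- c(1L, ncol(pixels))
  sub <- pixels[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  H <- nrow(sub); W <- ncol(sub)
  if (H < h || W < w)
    .fvlStop("fvlInvalidInput", "search region smaller than the template")
  nY <- H - h + 1L; nX <- W - w + 1L
  P <- matrix(0, H + 1L, W + 1L)
  P[-1L, -1L] <- t(apply(apply(sub, 2L, cumsum), 1L, cumsum))
  rb <- .hashGrid(h); cb <- .hashGrid(w)
  yi <- seq_len(nY); xi <- seq_len(nX)
  blockMeans <- vector("list", 64L)
  k <- 0L
  for (i in 1:8) for (j in 1:8) {
    a <- rb[i] + 1L; b <- rb[i + 1L]
    cc <- cb[j] + 1L; d <- cb[j + 1L]
    s <- P[yi + b, xi + d, drop = FALSE] -
         P[yi + a - 1L, xi + d, drop = FALSE] -
         P[yi + b, xi + cc - 1L, drop = FALSE] +
         P[yi + a - 1L, xi + cc - 1L, drop = FALSE]
    k <- k + 1L
    blockMeans[[k]] <- s / ((b - a + 1L) * (d - cc + 1L))
  }
  wmean <- Reduce(`+`, blockMeans) / 64
  tb <- template@hashBits
  # hashGlyph emits bits row-major (t(means)); blockMeans is filled in the
  # same (i inner over j? no: i outer, j inner) order, matching t(means).
  D <- matrix(0L, nY, nX)
  for (k in 1:64) {
    bit <- blockMeans[[k]] >= wmean
    D <- D + (bit != tb[k])
  }
  list(dist = D, rowOffset = rows[1] - 1L, colOffset = cols[1] - 1L,
       h = h, w = w)
}

# All acceptable matches (distance <= threshold) with greedy non-maximum
# suppression at the template's footprint; ordered by distance then scan
# order (leftmost column, then topmost row). Returns data.frame(row, col,
# dist) in absolute page coordinates of the window top-left.
.hashMatches <- function(search, threshold) {
  D <- search$dist
  idx <- which(D <= threshold)
  if (length(idx) == 0L)
    return(data.frame(row = integer(), col = integer(), dist = integer()))
  rr <- ((idx - 1L) %% nrow(D)) + 1L
  cc <- ((idx - 1L) %/% nrow(D)) + 1L
  ord <- order(D[idx], idx)  # ties resolved in column-major scan order
  rr <- rr[ord]; cc <- cc[ord]; dd <- D[idx][ord]
  keep <- logical(0)
  kr <- integer(0); kc <- integer(0); kd <- integer(0)
  for (m in seq_along(rr)) {
    if (length(kr) == 0L ||
        all(abs(kr - rr[m]) >= search$h | abs(kc - cc[m]) >= search$w)) {
      kr <- c(kr, rr[m]); kc <- c(kc, cc[m]); kd <- c(kd, dd[m])
    }
  }
  data.frame(row = kr + search$rowOffset, col = kc + search$colOffset,
             dist = kd)
}
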