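#' Image utilities
#'
#' Images throughout the package are numeric matrices with intensities in
#' `[0, 1]`, row = image row (top to bottom), column = image column. These
#' helpers provide bilinear resizing, small affine warps (used by the
#' synthetic pose model), and a plain-text raster format for on-disk
#' fixtures.
#'
#' @name image-utils
NULL

#' Resize an image with bilinear interpolation
#'
#' Resamples a grayscale image matrix to a square target side using
#' center-aligned bilinear interpolation. This is the resizing step applied
#' after any region-of-interest crop and before the classifier input layer;
#' pixel values are interpolated, never padded.
#'
#' @param img Numeric matrix (H x W), intensities in `[0, 1]`.
#' @param side Target side in pixels (output is `side` x `side`).
#' @return A `side` x `side` numeric matrix.
#' @export
resize_bilinear <- function(img, side) {
  stopifnot(is.matrix(img), is.numeric(img), side >= 1)
  h <- nrow(img)
  w <- ncol(img)
  if (h == side && w == side) return(img)
  # center-aligned mapping: target pixel centers land on source coordinates
  src_r <- (seq_len(side) - 0.5) * h / side - 0.5
  src_c <- (seq_len(side) - 0.5) * w / side - 0.5
  src_r <- pmin(pmax(src_r, 0), h - 1)
  src_c <- pmin(pmax(src_c, 0), w - 1)
  r0 <- floor(src_r); c0 <- floor(src_c)
  r1 <- pmin(r0 + 1, h - 1); c1 <- pmin(c0 + 1, w - 1)
  fr <- src_r - r0; fc <- src_c - c0
  # gather the four neighbours for the full grid in one shot
  i00 <- img[cbind(rep(r0 + 1, times = side), rep(c0 + 1, each = side))]
  i10 <- img[cbind(rep(r1 + 1, times = side), rep(c0 + 1, each = side))]
  i01 <- img[cbind(rep(r0 + 1, times = side), rep(c1 + 1, each = side))]
  i11 <- img[cbind(rep(r1 + 1, times = side), rep(c1 + 1, each = side))]
  wr <- rep(fr, times = side)
  wc <- rep(fc, each = side)
  out <- (1 - wr) * (1 - wc) * i00 + wr * (1 - wc) * i10 +
    (1 - wr) * wc * i01 + wr * wc * i11
  matrix(out, nrow = side, ncol = side)
}

#' Apply an affine warp about the image center
#'
#' Warps a grayscale image by a 2x2 linear map applied about the image
#' center, sampling with bilinear interpolation and filling out-of-frame
#' samples with a constant. Used by the synthetic generator to realise
#' in-plane rotation and mild tilt foreshortening.
#'
#' @param img Numeric matrix.
#' @param mat 2x2 forward linear map (row, col) applied about the center.
#' @param fill Fill value for samples outside the source frame.
#' @return Warped matrix of the same size.
#' @export
warp_affine <- function(img, mat, fill = 0) {
  stopifnot(is.matrix(img), is.matrix(mat), all(dim(mat) == c(2, 2)))
  h <- nrow(img)
  w <- ncol(img)
  inv <- solve(mat)
  cy <- (h - 1) / 2
  cx <- (w - 1) / 2
  ty <- rep(seq_len(h) - 1 - cy, times = w)
  tx <- rep(seq_len(w) - 1 - cx, each = h)
  sy <- inv[1, 1] * ty + inv[1, 2] * tx + cy
  sx <- inv[2, 1] * ty + inv[2, 2] * tx + cx
  inside <- sy >= 0 & sy <= h - 1 & sx >= 0 & sx <= w - 1
  out <- rep(fill, h * w)
  if (any(inside)) {
    sy_i <- sy[inside]; sx_i <- sx[inside]
    r0 <- floor(sy_i); c0 <- floor(sx_i)
    r1 <- pmin(r0 + 1, h - 1); c1 <- pmin(c0 + 1, w - 1)
    fr <- sy_i - r0; fc <- sx_i - c0
    v <- (1 - fr) * (1 - fc) * img[cbind(r0 + 1, c0 + 1)] +
      fr * (1 - fc) * img[cbind(r1 + 1, c0 + 1)] +
      (1 - fr) * fc * img[cbind(r0 + 1, c1 + 1)] +
      fr * fc * img[cbind(r1 + 1, c1 + 1)]
    out[inside] <- v
  }
  matrix(out, nrow = h, ncol = w)
}

#' Rotation/tilt pose matrix
#'
#' Composes an in-plane rotation with tilt/pitch foreshortening (cosine
#' scaling along each axis), the affine proxy for a camera looking at the
#' subject from an off-axis direction.
#'
#' @param angle_deg In-plane rotation in degrees.
#' @param tilt_deg,pitch_deg Off-axis angles in degrees; each shrinks one
#'   axis by its cosine.
#' @return A 2x2 matrix for [warp_affine()].
#' @export
pose_matrix <- function(angle_deg, tilt_deg = 0, pitch_deg = 0) {
  th <- angle_deg * pi / 180
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  sc <- diag(c(cos(tilt_deg * pi / 180), cos(pitch_deg * pi / 180)))
  rot %*% sc
}

#' Read and write plain-text PGM rasters
#'
#' ASCII (P2) portable graymap input/output. Intensities are quantised to
#' `maxval` levels on write and rescaled to `[0, 1]` on read; a write/read
#' round trip is exact up to that quantisation.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path File path.
#' @param maxval Maximum gray level (default 255).
#' @return `read_pgm` returns a numeric matrix in `[0, 1]`;
#'   `write_pgm` returns `path` invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  stopifnot(is.matrix(img))
  q <- round(pmin(pmax(img, 0), 1) * maxval)
  header <- c("P2", paste(ncol(img), nrow(img)), as.character(maxval))
  body <- apply(q, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  w <- as.integer(toks[2])
  h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM payload in ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}
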