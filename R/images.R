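# Image arrays are numeric H x W x 3 arrays with intensities in [0, 255].
# Grayscale images are H x W matrices on the same scale.

#' Convert an RGB image array to grayscale
#'
#' @param img H x W x 3 numeric array in \[0, 255\].
#' @param weights optional length-3 channel weights (e.g. luma
#'   `c(0.299, 0.587, 0.114)`). The default is the unweighted channel mean,
#'   the reading used by the brightness filter.
#' @return H x W numeric matrix in \[0, 255\].
#' @export
img_gray <- function(img, weights = NULL) {
  if (length(dim(img)) == 2L) return(img)
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  if (is.null(weights)) weights <- rep(1 / 3, 3)
  stopifnot(length(weights) == 3L)
  weights <- weights / sum(weights)
  img[, , 1] * weights[1] + img[, , 2] * weights[2] + img[, , 3] * weights[3]
}

lanczos_kernel <- function(x, a) {
  out <- numeric(length(x))
  ax <- abs(x)
  nz <- ax > 1e-12 & ax < a
  out[ax <= 1e-12] <- 1
  xs <- x[nz]
  out[nz] <- a * sin(pi * xs) * sin(pi * xs / a) / (pi^2 * xs^2)
  out
}

# Row-resampling matrix (n_out x n_in) for Lanczos-a interpolation along one
# axis; rows sum to 1, so constant signals are preserved exactly. When
# n_in == n_out the matrix is the identity (sinc vanishes at integers).
lanczos_matrix <- function(n_in, n_out, a = 3) {
  scale <- n_in / n_out
  fscale <- max(1, scale)
  support <- a * fscale
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    center <- (i - 0.5) * scale - 0.5
    lo <- max(0L, as.integer(floor(center - support)))
    hi <- min(n_in - 1L, as.integer(ceiling(center + support)))
    idx <- lo:hi
    w <- lanczos_kernel((idx - center) / fscale, a)
    s <- sum(w)
    if (s == 0) {
      w[which.min(abs(idx - center))] <- 1
      s <- 1
    }
    W[i, idx + 1L] <- w / s
  }
  W
}

#' Resize an image with Lanczos resampling
#'
#' Separable Lanczos-a interpolation (default a = 3, the filter commonly
#' called "Lanczos" by imaging libraries). For downscaling, the kernel is
#' stretched by the scale factor so it acts as a proper anti-aliasing
#' filter. Constant images are preserved exactly; resizing to the input
#' size is the identity.
#'
#' @param img H x W x 3 array or H x W matrix in \[0, 255\].
#' @param out_h,out_w output dimensions in pixels.
#' @param a kernel support parameter.
#' @param clip clamp the result to \[0, 255\] (Lanczos can overshoot).
#' @return resized image of the same kind as the input.
#' @export
resize_lanczos <- function(img, out_h, out_w, a = 3, clip = TRUE) {
  stopifnot_scalar_number(out_h, "out_h", positive = TRUE)
  stopifnot_scalar_number(out_w, "out_w", positive = TRUE)
  gray <- length(dim(img)) == 2L
  d <- dim(img)
  Wy <- lanczos_matrix(d[1], out_h, a)
  Wx <- lanczos_matrix(d[2], out_w, a)
  if (gray) {
    out <- Wy %*% img %*% t(Wx)
  } else {
    out <- array(0, c(out_h, out_w, d[3]))
    for (ch in seq_len(d[3])) out[, , ch] <- Wy %*% img[, , ch] %*% t(Wx)
  }
  if (clip) out <- pmin(pmax(out, 0), 255)
  out
}

#' Gaussian blur
#'
#' Separable Gaussian convolution with edge replication.
#'
#' @param img image array or matrix in \[0, 255\].
#' @param sigma standard deviation in pixels; `sigma <= 0` returns the
#'   input unchanged.
#' @return blurred image.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_mat <- function(m) {
    h <- nrow(m); w <- ncol(m)
    # replicate-pad then convolve each axis by shifted accumulation
    pad <- m[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
    out <- matrix(0, h, w)
    for (j in seq_along(k)) out <- out + k[j] * pad[(j - 1L) + seq_len(h), , drop = FALSE]
    pad <- out[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
    out2 <- matrix(0, h, w)
    for (j in seq_along(k)) out2 <- out2 + k[j] * pad[, (j - 1L) + seq_len(w), drop = FALSE]
    out2
  }
  if (length(dim(img)) == 2L) return(blur_mat(img))
  out <- img
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- blur_mat(img[, , ch])
  out
}

#' Rotate an image about its center
#'
#' Bilinear interpolation; source coordinates outside the image are clamped
#' to the nearest edge pixel, so the output has no fill-value border.
#'
#' @param img H x W x 3 array or H x W matrix.
#' @param angle_deg rotation angle in degrees (counter-clockwise).
#' @return rotated image, same dimensions.
#' @export
rotate_bilinear <- function(img, angle_deg) {
  if (abs(angle_deg) < 1e-12) return(img)
  gray <- length(dim(img)) == 2L
  d <- dim(img)
  h <- d[1]; w <- d[2]
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse mapping: output pixel -> source location
  sy <- cos(th) * yy - sin(th) * xx + cy
  sx <- sin(th) * yy + cos(th) * xx + cx
  sy <- pmin(pmax(sy, 1), h)
  sx <- pmin(pmax(sx, 1), w)
  y0 <- pmin(floor(sy), h - 1); x0 <- pmin(floor(sx), w - 1)
  fy <- sy - y0; fx <- sx - x0
  sample_mat <- function(m) {
    i00 <- cbind(as.vector(y0), as.vector(x0))
    i10 <- cbind(as.vector(y0 + 1), as.vector(x0))
    i01 <- cbind(as.vector(y0), as.vector(x0 + 1))
    i11 <- cbind(as.vector(y0 + 1), as.vector(x0 + 1))
    v <- (1 - as.vector(fy)) * (1 - as.vector(fx)) * m[i00] +
      as.vector(fy) * (1 - as.vector(fx)) * m[i10] +
      (1 - as.vector(fy)) * as.vector(fx) * m[i01] +
      as.vector(fy) * as.vector(fx) * m[i11]
    matrix(v, h, w)
  }
  if (gray) return(sample_mat(img))
  out <- img
  for (ch in seq_len(d[3])) out[, , ch] <- sample_mat(img[, , ch])
  out
}

# Vectorized HSV -> RGB on [0,1] vectors (h in [0,1] as grDevices::rgb2hsv
# returns it); inverse of rgb2hsv up to floating point.
hsv_to_rgb_num <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
    ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
    ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
    ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

# Apply a stain perturbation (hue rotation in degrees + saturation scaling)
# to selected pixels of an RGB image in [0,255].
shift_stain <- function(img, mask, hue_delta, sat_scale) {
  if (!any(mask)) return(img)
  idx <- which(mask)
  rgb <- rbind(img[, , 1][idx], img[, , 2][idx], img[, , 3][idx])
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  h <- (hsv[1, ] + hue_delta / 360) %% 1
  s <- pmin(pmax(hsv[2, ] * sat_scale, 0), 1)
  out <- hsv_to_rgb_num(h, s, hsv[3, ]) * 255
  img[, , 1][idx] <- out[, 1]
  img[, , 2][idx] <- out[, 2]
  img[, , 3][idx] <- out[, 3]
  img
}

#' Read / write an RGB image as PNG
#'
#' Thin wrappers around the \pkg{png} package converting between files and
#' the package's H x W x 3 \[0, 255\] array convention.
#'
#' @param path file path.
#' @return `read_image()` returns an H x W x 3 array in \[0, 255\].
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  a * 255
}

#' @rdname read_image
#' @param img H x W x 3 array in \[0, 255\].
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), target = path)
  invisible(path)
}
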