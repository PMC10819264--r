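# ---- small internal image utilities ----

# integer block index of each row/col for a given block size
block_index <- function(n, block_size) ((seq_len(n) - 1L) %/% block_size) + 1L

# per-block aggregate of a pixel matrix; FUN applied to the pixels of each block
block_apply <- function(m, block_size, FUN) {
  ri <- block_index(nrow(m), block_size)
  ci <- block_index(ncol(m), block_size)
  nb_r <- max(ri); nb_c <- max(ci)
  out <- matrix(NA_real_, nb_r, nb_c)
  for (i in seq_len(nb_r)) {
    rows <- which(ri == i)
    for (j in seq_len(nb_c)) {
      out[i, j] <- FUN(m[rows, ci == j])
    }
  }
  out
}

# expand a block-grid matrix back to pixel resolution
block_expand <- function(bm, block_size, nr, nc) {
  bm[cbind(rep(block_index(nr, block_size), times = nc),
           rep(block_index(nc, block_size), each = nr))] |>
    matrix(nr, nc)
}

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 2-D linear convolution via FFT, returning the central (same-size) part
conv2_same <- function(img, kern) {
  nr <- nrow(img) + nrow(kern) - 1L
  nc <- ncol(img) + ncol(kern) - 1L
  pi_ <- matrix(0, nr, nc); pk <- matrix(0, nr, nc)
  pi_[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  pk[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kern
  full <- Re(fft(fft(pi_) * fft(pk), inverse = TRUE)) / (nr * nc)
  r0 <- (nrow(kern) - 1L) %/% 2L
  c0 <- (ncol(kern) - 1L) %/% 2L
  full[r0 + seq_len(nrow(img)), c0 + seq_len(ncol(img))]
}

# normalized Gaussian smoothing of a matrix, ignoring NA, with border
# renormalization (weights of out-of-range/NA cells redistributed)
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  k <- outer(g, g)
  ok <- !is.na(m)
  m0 <- ifelse(ok, m, 0)
  num <- conv2_same(m0, k)
  den <- conv2_same(matrix(as.numeric(ok), nrow(m), ncol(m)), k)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# bilinear interpolation at 0-based (x, y); NA outside the image
bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  r <- y0 + 1L; cc <- x0 + 1L
  ok <- r >= 1L & cc >= 1L & r + 1L <= nr & cc + 1L <= nc
  out <- rep(NA_real_, length(x))
  if (any(ok)) {
    ro <- r[ok]; co <- cc[ok]; fxo <- fx[ok]; fyo <- fy[ok]
    v00 <- img[cbind(ro, co)];     v01 <- img[cbind(ro, co + 1L)]
    v10 <- img[cbind(ro + 1L, co)]; v11 <- img[cbind(ro + 1L, co + 1L)]
    out[ok] <- v00 * (1 - fxo) * (1 - fyo) + v01 * fxo * (1 - fyo) +
      v10 * (1 - fxo) * fyo + v11 * fxo * fyo
  }
  out
}

# ---- segmentation ----

#' Segment the fingerprint foreground
#'
#' Splits the image into `block_size` x `block_size` blocks and marks as
#' foreground the blocks whose gray-level variance (computed on the globally
#' standardized image) reaches `variance_threshold`. Ridge-bearing regions
#' have high local variance; smooth background does not.
#'
#' @param img a [gray_image()].
#' @param block_size block side in pixels (>= 4). Default 16, the standard
#'   choice at 500 dpi.
#' @param variance_threshold minimum standardized per-block variance for a
#'   block to count as foreground.
#' @return logical pixel matrix, `TRUE` on foreground.
#' @export
segment <- function(img, block_size = 16L, variance_threshold = 0.1) {
  stopifnot(block_size >= 4)
  assert_image_size(img)
  v <- stats::var(as.vector(img))
  z <- if (v > 0) (img - mean(img)) / sqrt(v) else img * 0
  bv <- block_apply(z, block_size, function(px) mean((px - mean(px))^2))
  fg <- bv >= variance_threshold
  if (!any(fg)) stop("no fingerprint region found")
  block_expand(fg, block_size, nrow(img), ncol(img))
}

# ---- normalization ----

#' Normalize image mean and variance
#'
#' Applies the affine-on-deviation rule
#' `out = target_mean + (in - mean(in)) * sqrt(target_var / var(in))`,
#' so the output has exactly the requested global mean and variance.
#'
#' @param img a [gray_image()].
#' @param target_mean,target_var requested global moments; `target_var > 0`.
#' @return a normalized [gray_image()].
#' @export
normalize_image <- function(img, target_mean = 0, target_var = 1) {
  stopifnot(target_var > 0)
  mu <- mean(img)
  v <- mean((img - mu)^2)
  if (v == 0) stop("cannot normalize a constant (zero-variance) image")
  gray_image(target_mean + (unclass(img) - mu) * sqrt(target_var / v))
}

# ---- orientation ----

#' Estimate the ridge orientation field
#'
#' Least-mean-square gradient method: per-block sums of the doubled-angle
#' gradient tensor give the dominant gradient direction; the ridge
#' orientation is its perpendicular. The field is then smoothed in the
#' doubled-angle domain (`cos 2theta`, `sin 2theta`) with a Gaussian of
#' `smooth_sigma` blocks, which handles flat blocks and angle wrap-around.
#'
#' @param img a normalized [gray_image()].
#' @param block_size block side in pixels.
#' @param smooth_sigma Gaussian sigma in blocks for orientation smoothing.
#' @return an object of class `orientation_field`: list with `theta`
#'   (block-grid matrix of angles in `[0, pi)`, measured counter-clockwise
#'   from the positive x axis) and `block_size`.
#' @export
estimate_orientation <- function(img, block_size = 16L, smooth_sigma = 1) {
  assert_image_size(img)
  m <- unclass(img)
  # central-difference gradients; replicate borders
  gx <- (shift_mat(m, 0, -1, NA) - shift_mat(m, 0, 1, NA)) / 2
  gy <- (shift_mat(m, -1, 0, NA) - shift_mat(m, 1, 0, NA)) / 2
  gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
  sxx <- block_apply(gx^2 - gy^2, block_size, sum)
  sxy <- block_apply(2 * gx * gy, block_size, sum)
  c2 <- gauss_smooth(sxx, smooth_sigma)
  s2 <- gauss_smooth(sxy, smooth_sigma)
  # gradient angle + pi/2 = ridge angle, folded into [0, pi)
  theta <- (0.5 * atan2(s2, c2) + pi / 2) %% pi
  structure(list(theta = theta, block_size = as.integer(block_size)),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %d x %d blocks (block_size %d)\n",
              nrow(x$theta), ncol(x$theta), x$block_size))
  invisible(x)
}

# ---- frequency ----

# fill NA blocks from the mean of valid 8-neighbours, iteratively
fill_from_neighbors <- function(fm) {
  while (any(is.na(fm))) {
    ok <- !is.na(fm)
    v0 <- ifelse(ok, fm, 0)
    num <- matrix(0, nrow(fm), ncol(fm)); den <- num
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      num <- num + shift_mat(v0, dr, dc, 0)
      den <- den + shift_mat(matrix(as.numeric(ok), nrow(fm), ncol(fm)), dr, dc, 0)
    }
    cand <- is.na(fm) & den > 0
    if (!any(cand)) break   # isolated island; cannot propagate further
    fm[cand] <- num[cand] / den[cand]
  }
  fm
}

#' Estimate the ridge frequency field
#'
#' For each block, the image is sampled along the line through the block
#' centre perpendicular to the local ridge orientation (the x-signature) and
#' the ridge wavelength is the mean spacing between successive peaks of that
#' profile. Blocks whose wavelength falls outside the plausible 3-25 px
#' range (or with fewer than two peaks) are flagged invalid and interpolated
#' from valid neighbouring blocks.
#'
#' @param img a normalized [gray_image()].
#' @param orient an `orientation_field` from [estimate_orientation()].
#' @param window profile length in pixels.
#' @return object of class `frequency_field`: list with `freq` (cycles/pixel
#'   per block, interpolated where invalid), `valid` (logical matrix of
#'   directly-estimated blocks) and `block_size`.
#' @export
estimate_frequency <- function(img, orient, window = 32L) {
  bs <- orient$block_size
  th <- orient$theta
  nbr <- nrow(th); nbc <- ncol(th)
  freq <- matrix(NA_real_, nbr, nbc)
  s <- seq(-window / 2, window / 2, by = 1)
  for (i in seq_len(nbr)) for (j in seq_len(nbc)) {
    cx <- (j - 0.5) * bs - 0.5   # block centre, 0-based x
    cy <- (i - 0.5) * bs - 0.5
    ux <- -sin(th[i, j]); uy <- cos(th[i, j])   # perpendicular to ridges
    prof <- bilinear(unclass(img), cx + s * ux, cy + s * uy)
    prof <- prof[!is.na(prof)]
    if (length(prof) < 6) next
    prof <- prof - mean(prof)
    n <- length(prof)
    pk <- which(prof[2:(n - 1)] > prof[1:(n - 2)] &
                prof[2:(n - 1)] >= prof[3:n]) + 1L
    if (length(pk) < 2) next
    wl <- mean(diff(pk))
    if (wl >= 3 && wl <= 25) freq[i, j] <- 1 / wl
  }
  valid <- !is.na(freq)
  if (!any(valid)) stop("ridge frequency could not be estimated in any block")
  freq <- fill_from_neighbors(freq)
  structure(list(freq = freq, valid = valid, block_size = bs),
            class = "frequency_field")
}

#' @export
print.frequency_field <- function(x, ...) {
  cat(sprintf("<frequency_field> %d x %d blocks, %d/%d valid, median wavelength %.1f px\n",
              nrow(x$freq), ncol(x$freq), sum(x$valid), length(x$valid),
              1 / stats::median(x$freq, na.rm = TRUE)))
  invisible(x)
}

# ---- Gabor enhancement ----

gabor_kernel <- function(theta, freq) {
  sigma <- 0.5 / freq          # sigma_x = sigma_y, truncated at 3 sigma
  rad <- ceiling(3 * sigma)
  xs <- -rad:rad
  X <- matrix(rep(xs, each = length(xs)), length(xs))   # x = column offset
  Y <- matrix(rep(xs, times = length(xs)), length(xs))  # y = row offset
  # wave varies along the direction perpendicular to the ridges
  xt <- -X * sin(theta) + Y * cos(theta)
  yt <- X * cos(theta) + Y * sin(theta)
  k <- exp(-(xt^2 + yt^2) / (2 * sigma^2)) * cos(2 * pi * freq * xt)
  k - mean(k)                  # zero-mean so response threshold 0 is neutral
}

#' Contextual Gabor filtering and binarization
#'
#' Filters every foreground pixel with an even-symmetric Gabor kernel tuned
#' to the local block orientation and frequency, then binarizes the response
#' at zero (the kernels are zero-mean). Orientation is quantized to 16
#' levels and wavelength to whole pixels so blocks sharing a configuration
#' reuse one FFT convolution.
#'
#' @param img a normalized [gray_image()].
#' @param orient an `orientation_field`.
#' @param freq a `frequency_field`.
#' @param mask optional logical foreground mask; background pixels forced 0.
#' @return binary (0/1) [gray_image()] of enhanced ridges.
#' @export
gabor_enhance <- function(img, orient, freq, mask = NULL) {
  bs <- orient$block_size
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  th_px <- block_expand(orient$theta, bs, nr, nc)
  wl_px <- block_expand(round(1 / freq$freq), bs, nr, nc)
  qth <- round(th_px / (pi / 16)) %% 16L        # 16 orientation bins
  out <- matrix(0, nr, nc)
  m <- unclass(img)
  for (key in unique(paste(qth[mask], wl_px[mask]))) {
    parts <- as.numeric(strsplit(key, " ")[[1]])
    sel <- mask & qth == parts[1] & wl_px == parts[2]
    k <- gabor_kernel(parts[1] * pi / 16, 1 / parts[2])
    resp <- conv2_same(m, k)
    out[sel] <- as.numeric(resp[sel] > 0)
  }
  gray_image(out)
}

# ---- skeletonization ----

#' Thin a binary ridge image to a unit-width skeleton
#'
#' Zhang-Suen iterative thinning: alternating sub-iterations delete boundary
#' pixels whose neighbourhood satisfies the connectivity-preserving
#' conditions, until no pixel changes. The result has no 2x2 all-ridge
#' block and keeps each ridge connected.
#'
#' @param binary a binary [gray_image()] (nonzero = ridge).
#' @param mask optional logical foreground mask stored with the skeleton.
#' @return a [skeleton_image()].
#' @export
skeletonize <- function(binary, mask = NULL) {
  P <- matrix(as.numeric(unclass(binary) != 0), nrow(binary), ncol(binary))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW),
      # rows increase downward so "north" is row - 1
      p2 <- shift_mat(P, 1, 0);  p3 <- shift_mat(P, 1, -1)
      p4 <- shift_mat(P, 0, -1); p5 <- shift_mat(P, -1, -1)
      p6 <- shift_mat(P, -1, 0); p7 <- shift_mat(P, -1, 1)
      p8 <- shift_mat(P, 0, 1);  p9 <- shift_mat(P, 1, 1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- P == 1 & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) { P[del] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  skeleton_image(P, mask)
}

# ---- pipeline ----

#' Full enhancement pipeline: raw image to ridge skeleton
#'
#' Runs segmentation, normalization (to mean 0 / variance 1), orientation
#' and frequency estimation, oriented Gabor filtering and Zhang-Suen
#' thinning, and returns the skeleton together with the intermediate fields.
#'
#' @param img a raw [gray_image()].
#' @param config parameter list; see [default_config()]. Only the
#'   preprocessing entries (`block_size`, `smooth_sigma`,
#'   `variance_threshold`) are used.
#' @return list with `skeleton` ([skeleton_image()]), `mask`, `orientation`,
#'   `frequency`, and the binarized `enhanced` image.
#' @export
enhance_fingerprint <- function(img, config = default_config()) {
  mask <- segment(img, config$block_size, config$variance_threshold)
  norm <- normalize_image(img, 0, 1)
  orient <- estimate_orientation(norm, config$block_size, config$smooth_sigma)
  freq <- estimate_frequency(norm, orient)
  enh <- gabor_enhance(norm, orient, freq, mask)
  skel <- skeletonize(enh, mask)
  list(skeleton = skel, mask = mask, orientation = orient,
       frequency = freq, enhanced = enh)
}
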