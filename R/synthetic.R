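# ---- synthetic minutia patterns, ridge images, and benchmarks ----

#' Synthetic generation parameters
#'
#' The generator emulates the variation between impressions of one finger:
#' a rigid transform (rotation about the image centre plus translation),
#' per-point Gaussian placement jitter, random minutia drop-out (missed
#' extractions) and spurious insertions (noise minutiae).
#'
#' @param k minutiae per print (default 30, comparable to the ~23-35
#'   registered minutiae seen on 500 dpi captures).
#' @param extent image side in pixels (default 300, optical FVC-style).
#' @param termination_fraction fraction of terminations among generated
#'   minutiae (default 0.6).
#' @param jitter_sigma per-coordinate Gaussian jitter in pixels.
#' @param drop_rate,spurious_rate probability of dropping each minutia /
#'   spurious count as a fraction of `k`.
#' @param rotation rotation in degrees about the extent centre.
#' @param translation numeric `c(dx, dy)` in pixels.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return named list of class `synthetic_params`.
#' @export
synthetic_params <- function(k = 30L, extent = 300, termination_fraction = 0.6,
                             jitter_sigma = 0, drop_rate = 0,
                             spurious_rate = 0, rotation = 0,
                             translation = c(0, 0), seed = NULL) {
  stopifnot(k >= 1, extent > 0,
            termination_fraction >= 0, termination_fraction <= 1,
            jitter_sigma >= 0, drop_rate >= 0, drop_rate <= 1,
            spurious_rate >= 0, length(translation) == 2)
  structure(list(k = as.integer(k), extent = extent,
                 termination_fraction = termination_fraction,
                 jitter_sigma = jitter_sigma, drop_rate = drop_rate,
                 spurious_rate = spurious_rate, rotation = rotation,
                 translation = translation, seed = seed),
            class = "synthetic_params")
}

# minimum pairwise spacing: twice the default validation delta, so that
# validation is a no-op on unperturbed sets
min_spacing <- function() 2 * validation_params()$delta

# sequential rejection sampling of points with minimum spacing
sample_spaced <- function(k, extent, existing = NULL, max_tries = 300L) {
  pts <- if (is.null(existing)) matrix(numeric(0), 0, 2) else existing
  added <- 0L
  tries <- 0L
  out <- matrix(NA_real_, k, 2)
  while (added < k) {
    if (tries > max_tries * k) {
      stop("could not place minutiae with the required minimum spacing")
    }
    p <- stats::runif(2, 0, extent)
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_spacing()) {
      added <- added + 1L
      out[added, ] <- p
      pts <- rbind(pts, p)
    }
    tries <- tries + 1L
  }
  out
}

#' Generate a synthetic minutia point pattern
#'
#' Scatters `k` labeled minutiae uniformly over the extent with a minimum
#' pairwise spacing of twice the default validation distance, so the
#' validation stage leaves an unperturbed set untouched.
#'
#' @param p a [synthetic_params()].
#' @return a [minutia_set()] (provenance `"raw"`).
#' @export
generate_minutia_set <- function(p = synthetic_params()) {
  if (!is.null(p$seed)) set.seed(p$seed)
  pts <- sample_spaced(p$k, p$extent)
  nt <- round(p$k * p$termination_fraction)
  type <- c(rep("T", nt), rep("B", p$k - nt))
  minutia_set(pts[, 1], pts[, 2], type,
              width = p$extent, height = p$extent)
}

#' Apply a rigid transform to raw coordinates
#'
#' Rotation (degrees, counter-clockwise in the x right / y down frame)
#' about `c(cx, cy)` followed by translation.
#'
#' @param xy two-column matrix.
#' @param rotation degrees.
#' @param translation `c(dx, dy)`.
#' @param center `c(cx, cy)` rotation centre.
#' @return transformed two-column matrix.
#' @export
rigid_transform <- function(xy, rotation = 0, translation = c(0, 0),
                            center = c(0, 0)) {
  th <- rotation * pi / 180
  dx <- xy[, 1] - center[1]; dy <- xy[, 2] - center[2]
  cbind(center[1] + dx * cos(th) - dy * sin(th) + translation[1],
        center[2] + dx * sin(th) + dy * cos(th) + translation[2])
}

#' Perturb a minutia set into a new impression
#'
#' Applies, in order: rotation about the extent centre, translation,
#' per-point Gaussian jitter of `jitter_sigma`, drop-out at `drop_rate`,
#' and insertion of `round(spurious_rate * k)` spurious minutiae placed
#' with the same minimum-spacing rule. Coordinates may leave the original
#' extent (as they do when a finger shifts on a sensor); bounds metadata is
#' cleared accordingly.
#'
#' @param s a [minutia_set()].
#' @param p a [synthetic_params()].
#' @return the perturbed [minutia_set()].
#' @export
perturb_minutia_set <- function(s, p) {
  if (!is.null(p$seed)) set.seed(p$seed)
  ctr <- c(p$extent / 2, p$extent / 2)
  xy <- rigid_transform(as.matrix(s[, c("x", "y")]), p$rotation,
                        p$translation, ctr)
  type <- s$type
  if (p$jitter_sigma > 0) {
    xy <- xy + matrix(stats::rnorm(length(xy), 0, p$jitter_sigma), ncol = 2)
  }
  if (p$drop_rate > 0) {
    keep <- stats::runif(nrow(xy)) >= p$drop_rate
    xy <- xy[keep, , drop = FALSE]
    type <- type[keep]
  }
  n_spur <- round(p$spurious_rate * p$k)
  if (n_spur > 0) {
    spur <- sample_spaced(n_spur, p$extent, existing = xy)
    xy <- rbind(xy, spur)
    type <- c(type, sample(c("T", "B"), n_spur, replace = TRUE))
  }
  minutia_set(xy[, 1], xy[, 2], type, width = NA_integer_,
              height = NA_integer_)
}

#' Generate an oriented sinusoidal ridge image
#'
#' A plane wave whose stripes run along `orientation` (degrees from the
#' x axis) with the given wavelength, intensity range roughly 0-255, plus
#' optional Gaussian noise. Ground truth is attached as attributes
#' `orientation` and `wavelength` for testing the enhancement estimators.
#'
#' @param orientation ridge direction in degrees.
#' @param wavelength ridge period in pixels (3-25).
#' @param extent image side in pixels.
#' @param noise_sigma Gaussian noise standard deviation (intensity units).
#' @param seed optional integer seed.
#' @return a [gray_image()] with ground-truth attributes.
#' @export
generate_ridge_image <- function(orientation = 30, wavelength = 8,
                                 extent = 128, noise_sigma = 0, seed = NULL) {
  stopifnot(wavelength >= 3, wavelength <= 25)
  if (!is.null(seed)) set.seed(seed)
  th <- orientation * pi / 180
  x <- matrix(rep(0:(extent - 1), each = extent), extent)   # column index
  y <- matrix(rep(0:(extent - 1), times = extent), extent)  # row index
  phase <- 2 * pi / wavelength * (-x * sin(th) + y * cos(th))
  img <- 127.5 + 100 * cos(phase)
  if (noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sigma), extent)
  }
  out <- gray_image(img)
  attr(out, "orientation") <- orientation
  attr(out, "wavelength") <- wavelength
  out
}

# ---- benchmark runner ----

#' Benchmark specification
#'
#' Mirrors the structure of the fingerprint-verification-competition
#' databases at desk scale: `num_fingers` fingers with
#' `impressions_per_finger` impressions each. Genuine comparisons pair
#' impressions of the same finger; impostor comparisons pair the first
#' impressions of different fingers. Each impression beyond the first gets
#' a random rigid transform (rotation uniform in +/-30 degrees,
#' translation uniform in +/-5% of the extent per axis) plus the stated
#' jitter/drop-out/spurious perturbation.
#'
#' @param num_fingers number of distinct fingers.
#' @param impressions_per_finger impressions per finger (>= 2 for genuine
#'   pairs to exist).
#' @param gen a [synthetic_params()] for the base pattern of each finger;
#'   its `jitter_sigma`, `drop_rate` and `spurious_rate` are applied to
#'   the non-first impressions.
#' @param seed integer master seed for the whole benchmark.
#' @return named list of class `benchmark_spec`.
#' @export
benchmark_spec <- function(num_fingers = 20L, impressions_per_finger = 2L,
                           gen = synthetic_params(), seed = 1L) {
  stopifnot(num_fingers >= 2, impressions_per_finger >= 2)
  structure(list(num_fingers = as.integer(num_fingers),
                 impressions_per_finger = as.integer(impressions_per_finger),
                 gen = gen, seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Run a synthetic verification benchmark end to end
#'
#' Builds every impression, validates its minutiae, fits a polygon model,
#' scores all genuine and impostor comparisons, and reports confusion
#' metrics at the configured `tmc` plus the full FMR/FNMR threshold sweep.
#' Everything is driven by the single master seed, so reports are
#' reproducible run to run.
#'
#' @param spec a [benchmark_spec()].
#' @param vparams a [validation_params()].
#' @param mparams a [model_params()].
#' @param params a [match_params()].
#' @return list with `confusion`, `metrics`, `sweep`, `genuine_counts`,
#'   `impostor_counts`, `labels` and `counts`.
#' @export
run_benchmark <- function(spec = benchmark_spec(),
                          vparams = validation_params(),
                          mparams = model_params(),
                          params = match_params()) {
  set.seed(spec$seed)
  g <- spec$gen
  models <- vector("list", spec$num_fingers)
  for (f in seq_len(spec$num_fingers)) {
    base <- generate_minutia_set(synthetic_params(
      k = g$k, extent = g$extent,
      termination_fraction = g$termination_fraction))
    impressions <- vector("list", spec$impressions_per_finger)
    impressions[[1]] <- base
    for (j in 2:spec$impressions_per_finger) {
      pp <- synthetic_params(
        k = g$k, extent = g$extent,
        termination_fraction = g$termination_fraction,
        jitter_sigma = g$jitter_sigma, drop_rate = g$drop_rate,
        spurious_rate = g$spurious_rate,
        rotation = stats::runif(1, -30, 30),
        translation = stats::runif(2, -0.05, 0.05) * g$extent)
      impressions[[j]] <- perturb_minutia_set(base, pp)
    }
    models[[f]] <- lapply(impressions, function(s) {
      build_model(validate_minutiae(s, vparams), mparams)
    })
  }
  genuine_counts <- integer(0)
  for (f in seq_len(spec$num_fingers)) {
    prs <- utils::combn(spec$impressions_per_finger, 2)
    for (cix in seq_len(ncol(prs))) {
      r <- match_fingerprints(models[[f]][[prs[1, cix]]],
                              models[[f]][[prs[2, cix]]], params)
      genuine_counts <- c(genuine_counts, r$matched_count)
    }
  }
  impostor_counts <- integer(0)
  for (f1 in seq_len(spec$num_fingers - 1)) {
    for (f2 in (f1 + 1):spec$num_fingers) {
      r <- match_fingerprints(models[[f1]][[1]], models[[f2]][[1]], params)
      impostor_counts <- c(impostor_counts, r$matched_count)
    }
  }
  counts <- c(genuine_counts, impostor_counts)
  labels <- c(rep("genuine", length(genuine_counts)),
              rep("impostor", length(impostor_counts)))
  conf <- confusion(counts >= params$tmc, labels)
  list(confusion = conf, metrics = metrics(conf),
       sweep = sweep_tmc(genuine_counts, impostor_counts),
       genuine_counts = genuine_counts, impostor_counts = impostor_counts,
       labels = labels, counts = counts)
}
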