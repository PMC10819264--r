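# ---- image I/O (PGM) ----

#' Read a grayscale image
#'
#' Supports portable graymap files (PGM, both ASCII `P2` and binary `P5`,
#' 8-bit) and plain CSV matrices. PGM is the only image container this
#' package reads natively; convert other formats externally (e.g.
#' `convert in.png out.pgm`).
#'
#' @param path file path (`.pgm` or `.csv`).
#' @return a [gray_image()].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    return(gray_image(as.matrix(utils::read.csv(path, header = FALSE))))
  }
  if (ext != "pgm") {
    stop("unsupported image format '", ext, "' (supported: pgm, csv): ", path)
  }
  read_pgm(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header tokens: magic, width, height, maxval (comments start with #)
  tokens <- character(0)
  buf <- ""
  while (length(tokens) < 4) {
    ch <- rawToChar(readBin(con, "raw", 1))
    if (!length(ch) || ch == "") stop("truncated PGM header: ", path)
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1))
        if (ch %in% c("\n", "")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(buf)) { tokens <- c(tokens, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (magic ", magic, "): ", path)
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", w * h))
  } else {
    rest <- rawToChar(readBin(con, "raw", file.info(path)$size))
    as.integer(strsplit(trimws(rest), "[[:space:]]+")[[1]])
  }
  if (length(vals) != w * h) stop("truncated PGM pixel data: ", path)
  gray_image(matrix(vals, nrow = h, ncol = w, byrow = TRUE) * (255 / maxval))
}

#' Write a grayscale or binary image as ASCII PGM
#'
#' @param img a [gray_image()] or [skeleton_image()]; binary images are
#'   written with values 0/255.
#' @param path output path.
#' @export
write_pgm <- function(img, path) {
  m <- if (inherits(img, "skeleton_image")) img$pixels * 255L
       else round(pmin(pmax(unclass(img), 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- minutiae template I/O ----

#' Write a minutia set as a plain-text template
#'
#' One minutia per line, `x y type` with type in T/B/A and coordinates at
#' six decimals; a header comment carries the image dimensions.
#'
#' @param s a [minutia_set()].
#' @param path output path.
#' @export
write_template <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s %s", attr(s, "width"), attr(s, "height")), con)
  if (nrow(s)) {
    writeLines(sprintf("%.6f %.6f %s", s$x, s$y, s$type), con)
  }
  invisible(path)
}

#' Read a minutiae template file
#'
#' @param path template path written by [write_template()].
#' @return a [minutia_set()].
#' @export
read_template <- function(path) {
  if (!file.exists(path)) stop("template file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#", lines[1])) {
    stop("template missing '# width height' header: ", path)
  }
  hdr <- strsplit(trimws(sub("^#", "", lines[1])), "[[:space:]]+")[[1]]
  dims <- suppressWarnings(as.integer(hdr))
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  x <- y <- numeric(length(body)); type <- character(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(trimws(body[i]), "[[:space:]]+")[[1]]
    if (length(f) != 3 || !f[3] %in% c("T", "B", "A") ||
        is.na(suppressWarnings(as.numeric(f[1]))) ||
        is.na(suppressWarnings(as.numeric(f[2])))) {
      stop("malformed template line ", i + 1, " in ", path, ": '", body[i], "'")
    }
    x[i] <- as.numeric(f[1]); y[i] <- as.numeric(f[2]); type[i] <- f[3]
  }
  minutia_set(x, y, type, width = dims[1], height = dims[2])
}

# ---- model I/O (JSON) ----

#' Write a fingerprint model as JSON
#'
#' @param model a `fingerprint_model` from [build_model()].
#' @param path output path.
#' @export
write_model <- function(model, path) {
  s <- model$minutiae
  minutiae <- lapply(seq_len(nrow(s)), function(i) {
    d <- model$descriptors[[i]]
    list(x = s$x[i], y = s$y[i], type = s$type[i],
         descriptors = if (is.null(d)) list() else apply(d, 1, identity,
                                                         simplify = FALSE))
  })
  obj <- list(format = "polyfinger-model", version = 1L,
              params = unclass(model$params),
              width = attr(s, "width"), height = attr(s, "height"),
              minutiae = minutiae)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fingerprint model from JSON
#'
#' @param path path written by [write_model()].
#' @return a `fingerprint_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "polyfinger-model")) {
    stop("not a polyfinger model file: ", path)
  }
  p <- model_params(obj$params$n, obj$params$r_step, obj$params$r_max)
  xs <- vapply(obj$minutiae, function(m) m$x, numeric(1))
  ys <- vapply(obj$minutiae, function(m) m$y, numeric(1))
  tys <- vapply(obj$minutiae, function(m) m$type, character(1))
  w <- if (is.null(obj$width)) NA_integer_ else obj$width
  h <- if (is.null(obj$height)) NA_integer_ else obj$height
  s <- minutia_set(xs, ys, tys, width = w, height = h,
                   provenance = "validated")
  descriptors <- lapply(obj$minutiae, function(m) {
    if (!length(m$descriptors)) return(NULL)
    do.call(rbind, lapply(m$descriptors, function(v) as.numeric(unlist(v))))
  })
  structure(list(minutiae = s, descriptors = descriptors,
                 registered = which(!vapply(descriptors, is.null, logical(1))),
                 params = p),
            class = "fingerprint_model")
}

# ---- configuration ----

#' Default pipeline configuration
#'
#' All tunable parameters with their defaults: preprocessing block size 16
#' px and orientation smoothing sigma 1 block; segmentation variance
#' threshold 0.1; validation delta = gamma = cloud_radius = 10 px; polygon
#' model n = 5 vertices, radius step 5 px up to 120 px; matching
#' thresholds th_rel 11%, th_l 5 px, th_a 10 degrees, tmc 12.
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(block_size = 16L, smooth_sigma = 1, variance_threshold = 0.1,
       delta = 10, gamma = 10, cloud_radius = 10,
       n = 5L, r_step = 5, r_max = 120,
       th_rel = 11, th_l = 5, th_a = 10, tmc = 12,
       seed = 1L)
}

#' Load a configuration file
#'
#' Reads a JSON object of parameter overrides, fills unset keys from
#' [default_config()], warns on unknown keys and validates every value
#' against its module's preconditions, naming the offending key.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      warning("unknown config keys ignored: ", paste(unknown, collapse = ", "))
    }
    for (k in intersect(names(user), names(cfg))) cfg[[k]] <- user[[k]]
  }
  check <- function(ok, key, why) {
    if (!ok) stop("invalid config value for '", key, "': ", why)
  }
  check(cfg$block_size >= 4, "block_size", "must be >= 4")
  check(cfg$variance_threshold >= 0, "variance_threshold", "must be >= 0")
  check(cfg$smooth_sigma >= 0, "smooth_sigma", "must be >= 0")
  check(cfg$delta >= 0, "delta", "must be >= 0")
  check(cfg$gamma >= 0, "gamma", "must be >= 0")
  check(cfg$cloud_radius >= 0, "cloud_radius", "must be >= 0")
  check(cfg$n >= 3, "n", "polygons need at least 3 vertices")
  check(cfg$r_step > 0 && cfg$r_step <= cfg$r_max, "r_step",
        "must satisfy 0 < r_step <= r_max")
  check(cfg$th_rel >= 0, "th_rel", "must be >= 0")
  check(cfg$th_l >= 0, "th_l", "must be >= 0")
  check(cfg$th_a >= 0, "th_a", "must be >= 0")
  check(cfg$tmc >= 0, "tmc", "must be >= 0")
  cfg$block_size <- as.integer(cfg$block_size)
  cfg$n <- as.integer(cfg$n)
  cfg
}

config_vparams <- function(cfg) {
  validation_params(cfg$delta, cfg$gamma, cfg$cloud_radius)
}
config_mparams <- function(cfg) model_params(cfg$n, cfg$r_step, cfg$r_max)
config_matchparams <- function(cfg) {
  match_params(cfg$th_rel, cfg$th_l, cfg$th_a, cfg$tmc)
}
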