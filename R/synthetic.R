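#' Synthetic benchmarks and marbled-slice generator
#'
#' Two families of test material are generated fully in code:
#'
#' * *benchmark fractals* with analytic Renyi dimensions (Sierpinski carpet,
#'   filled square, horizontal line), used as oracles for the sandbox
#'   estimator;
#' * *synthetic slice images*: a dark-red lean matrix with white/yellow fat
#'   streaks and clusters of controllable area fraction, shaded by a smooth
#'   multiplicative illumination field — the heterogeneity the high-pass
#'   path is designed to remove — plus per-pixel sensor noise.
#'
#' All randomness flows through one seed; identical parameters and seed give
#' bit-identical rasters.
#'
#' @name synthetic
NULL

benchmark_fractal <- function(mask, d0, d1, d2, name) {
  structure(list(mask = mask, analytic_D0 = d0, analytic_D1 = d1,
                 analytic_D2 = d2, name = name),
            class = "benchmark_fractal")
}

#' @export
print.benchmark_fractal <- function(x, ...) {
  cat("benchmark fractal:", x$name, "\n",
      " mask:", nrow(x$mask), "x", ncol(x$mask),
      "(", sum(x$mask), "set pixels )\n",
      " analytic D0/D1/D2:", format(c(x$analytic_D0, x$analytic_D1,
                                      x$analytic_D2), digits = 5), "\n")
  invisible(x)
}

#' Sierpinski carpet benchmark
#'
#' The standard carpet at a given subdivision level: a \code{3^level x
#' 3^level} binary mask with \code{8^level} set pixels. The uniform measure
#' on a self-similar set is monofractal, so all generalized dimensions equal
#' \code{log(8) / log(3)} (about 1.8928).
#'
#' @param level Subdivision level, 1 to 6.
#' @return A \code{benchmark_fractal}: mask plus analytic D0/D1/D2.
#' @export
make_sierpinski_carpet <- function(level) {
  level <- as.integer(level)
  if (length(level) != 1L || is.na(level) || level < 1L || level > 6L)
    stop("level must be an integer in 1..6")
  m <- matrix(TRUE, 1, 1)
  for (k in seq_len(level)) {
    n <- nrow(m)
    big <- matrix(FALSE, 3L * n, 3L * n)
    for (i in 0:2) for (j in 0:2) {
      if (i == 1 && j == 1) next
      big[i * n + seq_len(n), j * n + seq_len(n)] <- m
    }
    m <- big
  }
  d <- log(8) / log(3)
  benchmark_fractal(m, d, d, d, sprintf("sierpinski_carpet_level%d", level))
}

#' Filled-square benchmark (plane-filling control)
#'
#' @param side_px Side in pixels (>= 8).
#' @return A \code{benchmark_fractal} with all pixels set and analytic
#'   dimensions exactly 2.
#' @export
make_filled_square <- function(side_px) {
  side_px <- as.integer(side_px)
  if (side_px < 8L) stop("side_px must be >= 8")
  benchmark_fractal(matrix(TRUE, side_px, side_px), 2, 2, 2,
                    sprintf("filled_square_%d", side_px))
}

#' Horizontal-line benchmark
#'
#' A single row of set pixels through the image center; analytic dimensions
#' all 1.
#'
#' @param side_px Side in pixels (>= 8).
#' @return A \code{benchmark_fractal}.
#' @export
make_line <- function(side_px) {
  side_px <- as.integer(side_px)
  if (side_px < 8L) stop("side_px must be >= 8")
  m <- matrix(FALSE, side_px, side_px)
  m[side_px %/% 2L, ] <- TRUE
  benchmark_fractal(m, 1, 1, 1, sprintf("line_%d", side_px))
}

#' Parameters of a synthetic marbled slice
#'
#' @param side_px Image side in pixels (default 512).
#' @param fat_fraction_target Target fat area fraction, in (0, 1).
#' @param n_clusters Number of accumulated fat clusters (ellipses).
#' @param streak_density Marbling streaks per pixel squared; sets the size
#'   of the streak pool from which the generator draws (default 4e-4, about
#'   100 streaks on a 512 px slice).
#' @param illumination_amplitude Peak relative deviation of the smooth
#'   multiplicative shading field from 1 (0 = flat illumination).
#' @param illumination_scale_px Correlation length of the shading field in
#'   pixels; keep it above the high-pass radius so the filter can remove it
#'   (default 128).
#' @param lean_rgb,fat_rgb 8-bit base colors of the lean matrix and the fat
#'   phase. Defaults are a dark red (120, 30, 30) and an off-white
#'   (250, 245, 230), whose lumas sit on opposite sides of the 175
#'   unfiltered threshold.
#' @param noise_sd Standard deviation of per-pixel additive Gaussian sensor
#'   noise, in gray levels (default 3).
#' @param seed Integer seed; same seed and parameters give bit-identical
#'   output.
#' @return An object of class \code{"slice_params"}.
#' @export
slice_params <- function(side_px = 512L, fat_fraction_target = 0.2,
                         n_clusters = 3L, streak_density = 4e-4,
                         illumination_amplitude = 0,
                         illumination_scale_px = 128,
                         lean_rgb = c(120L, 30L, 30L),
                         fat_rgb = c(250L, 245L, 230L),
                         noise_sd = 3, seed = 1L) {
  p <- list(side_px = as.integer(side_px),
            fat_fraction_target = fat_fraction_target,
            n_clusters = as.integer(n_clusters),
            streak_density = streak_density,
            illumination_amplitude = illumination_amplitude,
            illumination_scale_px = illumination_scale_px,
            lean_rgb = as.integer(lean_rgb), fat_rgb = as.integer(fat_rgb),
            noise_sd = noise_sd, seed = as.integer(seed))
  if (p$side_px < 32L) stop("side_px must be >= 32")
  if (!(p$fat_fraction_target > 0 && p$fat_fraction_target < 1))
    stop("fat_fraction_target must lie in (0, 1)")
  if (p$n_clusters < 0L) stop("n_clusters must be non-negative")
  if (p$streak_density < 0) stop("streak_density must be >= 0")
  if (p$illumination_amplitude < 0) stop("illumination_amplitude must be >= 0")
  if (p$illumination_scale_px <= 0) stop("illumination_scale_px must be > 0")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(p$lean_rgb) != 3L || length(p$fat_rgb) != 3L ||
      any(c(p$lean_rgb, p$fat_rgb) < 0L) || any(c(p$lean_rgb, p$fat_rgb) > 255L))
    stop("lean_rgb and fat_rgb must be 8-bit color triples")
  structure(p, class = "slice_params")
}

# Rasterize one marbling streak: a random-walk polyline dilated to width
# w in 1..4 px.  Returns linear pixel indices into a side x side matrix.
draw_streak <- function(side) {
  len <- stats::runif(1, 0.04 * side, 0.16 * side)
  width <- sample(1:4, 1L)
  n_steps <- ceiling(len)
  start <- stats::runif(2, 1, side)
  ang <- stats::runif(1, 0, 2 * pi) + cumsum(stats::rnorm(n_steps, 0, 0.15))
  r <- pmin(pmax(start[1] + c(0, cumsum(cos(ang))), 1), side)
  c <- pmin(pmax(start[2] + c(0, cumsum(sin(ang))), 1), side)
  rad <- width / 2
  h <- ceiling(rad)
  off <- expand.grid(dr = -h:h, dc = -h:h)
  off <- off[off$dr^2 + off$dc^2 <= rad^2 + 0.25, , drop = FALSE]
  pr <- pmin(pmax(round(rep(r, each = nrow(off))) + off$dr, 1), side)
  pc <- pmin(pmax(round(rep(c, each = nrow(off))) + off$dc, 1), side)
  unique((pc - 1) * side + pr)
}

# Rasterize one accumulated-fat cluster as a rotated ellipse; returns
# linear pixel indices.
draw_cluster <- function(side) {
  ctr <- stats::runif(2, 0.1 * side, 0.9 * side)
  ax <- stats::runif(2, side / 64, 3 * side / 64)
  th <- stats::runif(1, 0, pi)
  h <- ceiling(max(ax))
  rr <- pmax(1, floor(ctr[1] - h)):pmin(side, ceiling(ctr[1] + h))
  cc <- pmax(1, floor(ctr[2] - h)):pmin(side, ceiling(ctr[2] + h))
  g <- expand.grid(r = rr, c = cc)
  x <- g$r - ctr[1]; y <- g$c - ctr[2]
  u <- cos(th) * x + sin(th) * y
  v <- -sin(th) * x + cos(th) * y
  g <- g[(u / ax[1])^2 + (v / ax[2])^2 <= 1, , drop = FALSE]
  (g$c - 1) * side + g$r
}

# Smooth multiplicative shading field: a sum of a few low-frequency
# harmonics with random orientations and phases, centered so its mean is
# exactly 1 and scaled so its peak deviation equals `amplitude`.
shading_field <- function(side, amplitude, scale_px, n_harmonics = 4L) {
  if (amplitude == 0) return(matrix(1, side, side))
  rc <- seq_len(side)
  S <- matrix(0, side, side)
  for (k in seq_len(n_harmonics)) {
    wavelength <- stats::runif(1, 2 * scale_px, 4 * scale_px)
    th <- stats::runif(1, 0, 2 * pi)
    phase <- stats::runif(1, 0, 2 * pi)
    kx <- 2 * pi * cos(th) / wavelength
    ky <- 2 * pi * sin(th) / wavelength
    S <- S + outer(rc, rc, function(r, c) cos(kx * r + ky * c + phase))
  }
  S <- S - mean(S)
  1 + amplitude * S / max(abs(S))
}

#' Generate a synthetic marbled slice with its ground-truth mask
#'
#' Builds the fat mask from \code{n_clusters} elliptical clusters plus
#' marbling streaks drawn from a seeded pool, adding streaks until the
#' realized fat fraction reaches the target (the pool is extended up to 20
#' times before the target is declared unattainable). The RGB image is then
#' \code{shading_field * base_color + noise}, rounded and clipped to 8 bits.
#' The realized fat fraction is guaranteed within 0.05 of the target.
#'
#' @param params A [slice_params()] object.
#' @return A list with elements \code{image} (\code{side x side x 3} array,
#'   0-255), \code{mask} (logical ground-truth fat mask), \code{params},
#'   and \code{realized_fat_fraction}.
#' @export
make_slice <- function(params) {
  stopifnot(inherits(params, "slice_params"))
  withr::with_seed(params$seed, make_slice_impl(params))
}

make_slice_impl <- function(params) {
  side <- params$side_px
  npx <- side^2
  target <- params$fat_fraction_target
  mask <- matrix(FALSE, side, side)
  for (i in seq_len(params$n_clusters)) mask[draw_cluster(side)] <- TRUE
  if (mean(mask) > target + 0.05)
    stop("fat_fraction_target ", target, " unattainable: ", params$n_clusters,
         " clusters alone cover ", round(mean(mask), 3), " of the image")
  pool_n <- max(32L, ceiling(params$streak_density * npx))
  extensions <- 0L
  while (mean(mask) < target && extensions <= 20L) {
    for (s in seq_len(pool_n)) {
      mask[draw_streak(side)] <- TRUE
      if (mean(mask) >= target) break
    }
    extensions <- extensions + 1L
  }
  realized <- mean(mask)
  if (abs(realized - target) > 0.05)
    stop("could not reach fat_fraction_target ", target,
         " after bounded retries (realized ", round(realized, 3), ")")
  field <- shading_field(side, params$illumination_amplitude,
                         params$illumination_scale_px)
  img <- array(0, c(side, side, 3L))
  for (ch in 1:3) {
    base <- ifelse(mask, params$fat_rgb[ch], params$lean_rgb[ch])
    plane <- field * base
    if (params$noise_sd > 0)
      plane <- plane + stats::rnorm(npx, 0, params$noise_sd)
    img[, , ch] <- pmin(pmax(round_half_up(plane), 0), 255)
  }
  list(image = img, mask = mask, params = params,
       realized_fat_fraction = realized)
}

#' Generate a labeled multi-class fixture of synthetic slices
#'
#' Emulates a sample design with several quality classes: for each class
#' specification, \code{n_per_class} slices are drawn with small
#' multiplicative jitter (plus or minus 10 percent) on the fat-fraction
#' target so within-class dispersion exists. Per-image seeds derive
#' deterministically from \code{seed}.
#'
#' @param class_specs Named list of [slice_params()] objects, one per class;
#'   names are the class labels.
#' @param n_per_class Slices per class (>= 2).
#' @param seed Integer seed for the whole fixture.
#' @return A list of records, each with \code{image}, \code{mask},
#'   \code{class_label}, \code{image_id}, \code{params},
#'   \code{realized_fat_fraction}.
#' @export
make_class_fixture <- function(class_specs, n_per_class, seed = 1L) {
  if (length(class_specs) == 0L) stop("class_specs must name at least one class")
  if (n_per_class < 2L) stop("n_per_class must be >= 2")
  labels <- names(class_specs)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("class_specs must be a named list (names are class labels)")
  n_total <- length(class_specs) * n_per_class
  draws <- withr::with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n_total),
    jitter = stats::runif(n_total, 0.9, 1.1)))
  out <- vector("list", n_total)
  i <- 0L
  for (lab in labels) {
    spec <- class_specs[[lab]]
    stopifnot(inherits(spec, "slice_params"))
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      p <- unclass(spec)
      p$fat_fraction_target <- min(0.95, max(0.02,
        spec$fat_fraction_target * draws$jitter[i]))
      p$seed <- draws$seeds[i]
      sl <- make_slice(do.call(slice_params, p))
      sl$class_label <- lab
      sl$image_id <- sprintf("%s_%02d", lab, j)
      out[[i]] <- sl
    }
  }
  out
}
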