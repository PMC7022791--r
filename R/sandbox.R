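#' Sandbox estimation of generalized (Renyi) dimensions
#'
#' The sandbox method estimates the generalized dimensions D_q of a binary
#' set by centering discs ("sandboxes") of growing radius r on randomly
#' chosen set pixels, counting the set mass M(r) inside each disc, and
#' reading the dimension off the slope of a log-log regression:
#'
#' for q != 1, the moment form
#'   y(r) = (1 / (q - 1)) * log( < (M(r) / M0)^(q - 1) > )
#' and for q = 1 the entropy (L'Hopital limit) form
#'   y(r) = < log(M(r) / M0) >,
#' each regressed on x(r) = log(r / side) by ordinary least squares; the
#' slope is the dimension estimate, and its OLS standard error and R^2 are
#' reported as fit diagnostics. M0 is the total set mass and < . > the
#' arithmetic mean over centers (taken before the logarithm for q != 1,
#' after for q = 1). The conventional trio is q = 0 (capacity/box-counting
#' dimension D0), q = 1 (information dimension D1) and q = 2 (correlation
#' dimension D2); D_q is non-increasing in q.
#'
#' @name sandbox
NULL

#' Sandbox estimator configuration
#'
#' @param n_centers Number of disc centers drawn (with replacement) from the
#'   set, default 1000.
#' @param r_min_px,r_max_px Smallest and largest disc radius in pixels;
#'   \code{r_max_px = NULL} means side/4, chosen at analysis time. Radii are
#'   geometrically spaced.
#' @param n_radii Number of radii (default 12, >= 3).
#' @param q_values Moment orders; default \code{c(0, 1, 2)} for D0/D1/D2.
#' @param seed Integer seed for center sampling.
#' @param min_support_px Minimum number of set pixels required (default 100).
#' @return An object of class \code{"sandbox_config"}.
#' @export
sandbox_config <- function(n_centers = 1000L, r_min_px = 5, r_max_px = NULL,
                           n_radii = 12L, q_values = c(0, 1, 2), seed = 1L,
                           min_support_px = 100L) {
  cfg <- list(n_centers = as.integer(n_centers), r_min_px = r_min_px,
              r_max_px = r_max_px, n_radii = as.integer(n_radii),
              q_values = as.numeric(q_values), seed = as.integer(seed),
              min_support_px = as.integer(min_support_px))
  if (cfg$n_centers < 10L) stop("n_centers must be >= 10")
  if (cfg$n_radii < 3L) stop("n_radii must be >= 3")
  if (cfg$r_min_px <= 0) stop("r_min_px must be > 0")
  if (!is.null(cfg$r_max_px) && cfg$r_max_px <= cfg$r_min_px)
    stop("r_max_px must exceed r_min_px")
  structure(cfg, class = "sandbox_config")
}

resolve_radii <- function(cfg, side) {
  r_max <- if (is.null(cfg$r_max_px)) side / 4 else cfg$r_max_px
  if (r_max > side / 2) stop("r_max_px must not exceed side/2")
  if (cfg$r_min_px >= r_max) stop("r_min_px must be below r_max_px")
  exp(seq(log(cfg$r_min_px), log(r_max), length.out = cfg$n_radii))
}

#' Sample sandbox centers on the set
#'
#' Draws \code{n_centers} positions uniformly with replacement from the fat
#' pixels lying at least \code{r_max} from every image border, so that every
#' disc fits inside the image (no edge-truncation bias).
#'
#' @param mask Logical fat mask.
#' @param cfg A [sandbox_config()].
#' @return Integer matrix with columns \code{row}, \code{col}.
#' @export
sample_centers <- function(mask, cfg = sandbox_config()) {
  assert_mask(mask)
  if (sum(mask) < cfg$min_support_px)
    stop("insufficient support: ", sum(mask), " set pixels, need >= ",
         cfg$min_support_px)
  side <- nrow(mask)
  radii <- resolve_radii(cfg, side)
  r_max <- max(radii)
  idx <- which(mask, arr.ind = TRUE)
  eligible <- idx[idx[, 1] - 1 >= r_max & nrow(mask) - idx[, 1] >= r_max &
                  idx[, 2] - 1 >= r_max & ncol(mask) - idx[, 2] >= r_max, ,
                  drop = FALSE]
  if (nrow(eligible) == 0L)
    stop("no set pixels at distance >= r_max (", round(r_max, 1),
         " px) from the borders; use a smaller r_max_px")
  picks <- withr::with_seed(cfg$seed,
    sample.int(nrow(eligible), cfg$n_centers, replace = TRUE))
  centers <- eligible[picks, , drop = FALSE]
  colnames(centers) <- c("row", "col")
  centers
}

#' Count sandbox masses
#'
#' For every center and radius, counts the fat pixels whose Euclidean
#' center-to-center distance from the center is at most the radius. Discs
#' are nested, so masses are non-decreasing along the radius axis, and every
#' mass is at least 1 because centers lie on the set.
#'
#' @param mask Logical fat mask.
#' @param centers Integer matrix of (row, col) positions on the set.
#' @param radii Ascending vector of disc radii in pixels.
#' @return An object of class \code{"mass_matrix"}: list with
#'   \code{masses} (n_centers x n_radii integer matrix), \code{centers},
#'   \code{radii}, \code{total_mass} and \code{side}.
#' @export
count_masses <- function(mask, centers, radii) {
  assert_mask(mask)
  if (is.unsorted(radii, strictly = TRUE)) stop("radii must be strictly ascending")
  centers <- as.matrix(centers)
  if (!all(mask[centers])) stop("all centers must lie on the set")
  idx <- which(mask, arr.ind = TRUE)
  fr <- idx[, 1]; fc <- idx[, 2]
  r2 <- radii^2
  n_r <- length(radii)
  masses <- matrix(0L, nrow(centers), n_r)
  for (i in seq_len(nrow(centers))) {
    d2 <- (fr - centers[i, 1])^2 + (fc - centers[i, 2])^2
    # k = number of radii strictly below each pixel's distance; pixel i is
    # inside disc j iff k <= j - 1, so masses are cumulative bin counts
    k <- findInterval(d2, r2, left.open = TRUE)
    masses[i, ] <- cumsum(tabulate(k + 1L, nbins = n_r + 1L))[seq_len(n_r)]
  }
  structure(list(masses = masses, centers = centers, radii = radii,
                 total_mass = length(fr), side = nrow(mask)),
            class = "mass_matrix")
}

#' Estimate one generalized dimension from sandbox masses
#'
#' Ordinary least squares of the order-q sandbox statistic on
#' \code{log(r / side)} over all configured radii; no automatic
#' scaling-range selection is performed, and the reported \code{r_squared}
#' lets the caller judge (and re-fit on a sub-range if desired).
#'
#' @param mm A \code{mass_matrix} from [count_masses()].
#' @param q Moment order (real; q = 1 uses the entropy limit form).
#' @param side Linear size of the image in pixels; defaults to the size
#'   recorded in \code{mm}.
#' @return An object of class \code{"dimension_estimate"}: list with
#'   \code{q}, \code{value} (slope), \code{std_error} (OLS slope SE),
#'   \code{r_squared}, \code{n_points}.
#' @export
estimate_dimension <- function(mm, q, side = mm$side) {
  stopifnot(inherits(mm, "mass_matrix"), length(q) == 1L, is.finite(q))
  if (length(mm$radii) < 3L) stop("need at least 3 radii")
  rel <- mm$masses / mm$total_mass
  y <- if (q == 1) {
    colMeans(log(rel))
  } else {
    log(colMeans(rel^(q - 1))) / (q - 1)
  }
  x <- log(mm$radii / side)
  if (stats::var(x) == 0) stop("zero variance in log-radii")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(q = q, value = unname(stats::coef(fit)[2]),
                 std_error = s$coefficients[2, 2],
                 r_squared = s$r.squared,
                 n_points = length(x)),
            class = "dimension_estimate")
}

#' @export
print.dimension_estimate <- function(x, ...) {
  cat(sprintf("D_%g = %.4f (se %.4f, R^2 %.4f, %d radii)\n",
              x$q, x$value, x$std_error, x$r_squared, x$n_points))
  invisible(x)
}

#' Full sandbox analysis of a mask
#'
#' Samples centers once and counts masses once, then estimates every
#' requested D_q from the shared mass matrix so the dimensions are directly
#' comparable; also reports the fat fraction of the mask.
#'
#' @param mask Logical fat mask.
#' @param cfg A [sandbox_config()].
#' @return An object of class \code{"mfa_result"}: list with
#'   \code{estimates} (data.frame with columns q, value, std_error,
#'   r_squared, n_points), \code{fat_fraction}, \code{config} and
#'   \code{mass_matrix}.
#' @export
analyze_mask <- function(mask, cfg = sandbox_config()) {
  centers <- sample_centers(mask, cfg)
  radii <- resolve_radii(cfg, nrow(mask))
  mm <- count_masses(mask, centers, radii)
  est <- lapply(cfg$q_values, function(q) estimate_dimension(mm, q))
  structure(list(
    estimates = data.frame(
      q = vapply(est, `[[`, numeric(1), "q"),
      value = vapply(est, `[[`, numeric(1), "value"),
      std_error = vapply(est, `[[`, numeric(1), "std_error"),
      r_squared = vapply(est, `[[`, numeric(1), "r_squared"),
      n_points = vapply(est, `[[`, integer(1), "n_points")),
    fat_fraction = fat_fraction(mask),
    config = cfg,
    mass_matrix = mm), class = "mfa_result")
}

#' @export
print.mfa_result <- function(x, ...) {
  cat("sandbox multifractal analysis\n")
  cat(sprintf("  fat fraction: %.4f\n", x$fat_fraction))
  for (i in seq_len(nrow(x$estimates)))
    cat(sprintf("  D_%g = %.4f (se %.4f, R^2 %.4f)\n",
                x$estimates$q[i], x$estimates$value[i],
                x$estimates$std_error[i], x$estimates$r_squared[i]))
  invisible(x)
}
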