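#' Per-class, per-method reporting of dimension estimates
#'
#' Aggregation mirrors the usual reporting surfaces of marbling studies:
#' per-class/per-method means with across-sample standard errors, scatter
#' data of dimension versus fat fraction, five-number box-plot summaries,
#' and a dispersion (IQR) comparison across segmentation methods.
#'
#' A results table has one row per (image, method) with columns
#' \code{image_id}, \code{class_label}, \code{method} (one of
#' \code{"unfiltered"}, \code{"hp25"}, \code{"hp50"}), \code{fat_fraction},
#' \code{D0}, \code{D1}, \code{D2} (and optionally their regression
#' standard errors \code{D0_se} etc., which are kept separate from the
#' across-sample standard errors computed here and never mixed with them).
#'
#' @name summarize
NULL

METHODS <- c("unfiltered", "hp25", "hp50")
DIMS <- c("D0", "D1", "D2")

assert_results <- function(results) {
  need <- c("image_id", "class_label", "method", "fat_fraction", DIMS)
  missing <- setdiff(need, names(results))
  if (length(missing))
    stop("results table lacks columns: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(results$method), METHODS)
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(METHODS, collapse = "/"), ")")
  invisible(results)
}

#' Per-class, per-method means and standard errors
#'
#' The standard error is the across-sample \code{sd / sqrt(n)} of the n
#' per-image dimension estimates in the group (not the regression standard
#' error of any single estimate).
#'
#' @param results Results table (see \link{summarize}).
#' @return Long data.frame with columns \code{class_label}, \code{method},
#'   \code{dimension}, \code{mean}, \code{se}, \code{n}; one row per group
#'   per dimension. Output order is independent of input row order.
#' @export
summarize_results <- function(results) {
  assert_results(results)
  groups <- unique(results[, c("class_label", "method")])
  groups <- groups[order(groups$class_label, match(groups$method, METHODS)), ,
                   drop = FALSE]
  out <- list()
  for (g in seq_len(nrow(groups))) {
    sel <- results$class_label == groups$class_label[g] &
      results$method == groups$method[g]
    n <- sum(sel)
    if (n < 2L)
      stop("group (", groups$class_label[g], ", ", groups$method[g],
           ") has only ", n, " result; need >= 2 for a standard error")
    for (d in DIMS) {
      v <- results[[d]][sel]
      out[[length(out) + 1L]] <- data.frame(
        class_label = groups$class_label[g], method = groups$method[g],
        dimension = d, mean = mean(v), se = stats::sd(v) / sqrt(n), n = n)
    }
  }
  do.call(rbind, out)
}

#' Five-number summary (box-and-whisker statistics)
#'
#' Minimum, first quartile, median, third quartile and maximum, with
#' quartiles by inclusive linear interpolation (\code{quantile} type 7, the
#' convention of mainstream statistics GUIs).
#'
#' @param values Numeric vector with at least 5 values.
#' @return Named numeric vector \code{minimum, q1, median, q3, maximum}.
#' @export
five_number <- function(values) {
  if (length(values) < 5L) stop("need at least 5 values")
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  c(minimum = q[1], q1 = q[2], median = q[3], q3 = q[4], maximum = q[5])
}

#' Box-plot statistics per class, method and dimension
#'
#' @param results Results table (see \link{summarize}).
#' @return Data.frame with one row per (class, method, dimension) carrying
#'   the five-number summary.
#' @export
box_stats <- function(results) {
  assert_results(results)
  groups <- unique(results[, c("class_label", "method")])
  groups <- groups[order(groups$class_label, match(groups$method, METHODS)), ,
                   drop = FALSE]
  out <- list()
  for (g in seq_len(nrow(groups))) {
    sel <- results$class_label == groups$class_label[g] &
      results$method == groups$method[g]
    for (d in DIMS) {
      fn <- five_number(results[[d]][sel])
      out[[length(out) + 1L]] <- data.frame(
        class_label = groups$class_label[g], method = groups$method[g],
        dimension = d, t(fn))
    }
  }
  do.call(rbind, out)
}

#' Dispersion comparison across segmentation methods
#'
#' Pools all classes and computes, per method and dimension, the
#' interquartile range of the estimates; flags whether the 25 px high-pass
#' method is at most as dispersed as the unfiltered method. A tighter
#' spread under filtering indicates that illumination heterogeneity, not
#' tissue structure, drove the unfiltered scatter.
#'
#' @param results Results table containing all three methods.
#' @return Data.frame with columns \code{method}, \code{dimension},
#'   \code{iqr}, and logical \code{hp25_le_unfiltered} (same value repeated
#'   within each dimension).
#' @export
dispersion_comparison <- function(results) {
  assert_results(results)
  present <- unique(results$method)
  missing <- setdiff(METHODS, present)
  if (length(missing))
    stop("dispersion comparison needs all three methods; missing: ",
         paste(missing, collapse = ", "))
  out <- expand.grid(method = METHODS, dimension = DIMS,
                     stringsAsFactors = FALSE)
  out$iqr <- mapply(function(m, d)
    stats::IQR(results[[d]][results$method == m], type = 7),
    out$method, out$dimension)
  flag <- vapply(DIMS, function(d)
    out$iqr[out$method == "hp25" & out$dimension == d] <=
      out$iqr[out$method == "unfiltered" & out$dimension == d],
    logical(1))
  out$hp25_le_unfiltered <- flag[out$dimension]
  rownames(out) <- NULL
  out
}

#' Tidy scatter export: dimension versus fat fraction
#'
#' @param results Results table.
#' @return Data.frame with columns \code{class_label}, \code{method},
#'   \code{fat_fraction}, \code{D0}, \code{D1}, \code{D2}; one row per
#'   input row.
#' @export
scatter_table <- function(results) {
  assert_results(results)
  res <- results[, c("class_label", "method", "fat_fraction", DIMS)]
  rownames(res) <- NULL
  res
}
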