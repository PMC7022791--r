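#' Batch orchestration
#'
#' [validate_config()] turns a raw configuration (a named list, or a JSON or
#' YAML file) into a fully defaulted, validated run configuration;
#' [run_batch()] executes it: for every image and every requested
#' segmentation method it writes the fat mask (PNG), the pixel table
#' (headerless CSV) and the sandbox analysis (JSON), then the per-class
#' summary tables, and finally a manifest that records the provenance of
#' every output. One seed in the configuration determines all randomness;
#' repeated runs are byte-identical.
#'
#' @name batch
NULL

config_defaults <- function() {
  list(
    seed = 1L,
    methods = c("unfiltered", "hp25", "hp50"),
    filter = list(radius_hp25 = 25, radius_hp50 = 50,
                  threshold_filtered = 150L, threshold_unfiltered = 175L,
                  crop_side = 512L),
    sandbox = list(n_centers = 1000L, r_min_px = 5, r_max_px = NULL,
                   n_radii = 12L, q_values = c(0, 1, 2),
                   min_support_px = 100L),
    synthetic = NULL,
    images = NULL,
    out_dir = "hamfrac_out")
}

merge_config <- function(defaults, raw, path = character()) {
  for (key in names(raw)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(raw[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], raw[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- raw[[key]]
    }
  }
  defaults
}

#' Validate and default a run configuration
#'
#' Accepts a named list or a path to a JSON/YAML file. Recognized keys:
#' \describe{
#'   \item{seed}{integer, master seed for the whole run (default 1).}
#'   \item{methods}{subset of \code{unfiltered}, \code{hp25}, \code{hp50};
#'     default all three.}
#'   \item{filter}{\code{radius_hp25} (25), \code{radius_hp50} (50),
#'     \code{threshold_filtered} (150), \code{threshold_unfiltered} (175),
#'     \code{crop_side} (512).}
#'   \item{sandbox}{fields of [sandbox_config()] except the seed, which is
#'     derived from the master seed.}
#'   \item{synthetic}{\code{classes}: named list, each entry a list of
#'     [slice_params()] fields; \code{n_per_class}.}
#'   \item{images}{list of records \code{path}, \code{class_label},
#'     \code{crop} = (row, col) of the crop window, optional
#'     \code{image_id}; alternative to \code{synthetic}.}
#'   \item{out_dir}{output directory.}
#' }
#' Violations are reported with their field path.
#'
#' @param raw Named list, or path to a JSON or YAML configuration file.
#' @return An object of class \code{"run_config"}.
#' @export
validate_config <- function(raw) {
  if (is.character(raw) && length(raw) == 1L) {
    ext <- tolower(tools::file_ext(raw))
    raw <- switch(ext,
      json = jsonlite::read_json(raw, simplifyVector = TRUE),
      yaml = , yml = {
        if (!requireNamespace("yaml", quietly = TRUE))
          stop("YAML configuration requires the 'yaml' package")
        yaml::read_yaml(raw)
      },
      stop("unsupported configuration format: ", ext))
  }
  if (!is.list(raw)) stop("configuration must be a named list or a file path")
  unknown <- setdiff(names(raw), names(config_defaults()))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- merge_config(config_defaults(), raw)
  cfg$seed <- as.integer(cfg$seed)
  cfg$methods <- as.character(cfg$methods)
  if (length(cfg$methods) == 0L)
    stop("methods: at least one of unfiltered/hp25/hp50 is required")
  bad <- setdiff(cfg$methods, METHODS)
  if (length(bad)) stop("methods: unknown method(s) ", paste(bad, collapse = ", "))
  f <- cfg$filter
  for (nm in c("threshold_filtered", "threshold_unfiltered"))
    if (f[[nm]] < 0 || f[[nm]] > 255)
      stop("filter.", nm, ": must lie in [0, 255], got ", f[[nm]])
  for (nm in c("radius_hp25", "radius_hp50"))
    if (f[[nm]] <= 0 || f[[nm]] >= f$crop_side / 2)
      stop("filter.", nm, ": must lie in (0, crop_side/2), got ", f[[nm]])
  if (is.null(cfg$synthetic) && is.null(cfg$images))
    stop("configuration needs either 'synthetic' or 'images'")
  if (!is.null(cfg$synthetic)) {
    if (is.null(cfg$synthetic$classes) || length(cfg$synthetic$classes) == 0L)
      stop("synthetic.classes: at least one named class is required")
    if (is.null(cfg$synthetic$n_per_class) || cfg$synthetic$n_per_class < 2)
      stop("synthetic.n_per_class: must be >= 2")
  }
  if (!all(c(0, 1, 2) %in% cfg$sandbox$q_values))
    stop("sandbox.q_values: batch reporting requires q = 0, 1 and 2")
  # instantiating the sandbox config validates its ranges
  do.call(sandbox_config, c(cfg$sandbox, list(seed = cfg$seed)))
  structure(cfg, class = "run_config")
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical (name-sorted, unboxed) JSON serialization, so the
#' hash is invariant under field reordering.
#'
#' @param cfg A list (typically a \code{run_config}).
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x) && !is.null(names(x))) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canon(unclass(cfg)), tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

method_filter_config <- function(cfg, method) {
  f <- cfg$filter
  radius <- switch(method, hp25 = f$radius_hp25, hp50 = f$radius_hp50, 25)
  filter_config(radius_px = radius,
                threshold_filtered = f$threshold_filtered,
                threshold_unfiltered = f$threshold_unfiltered,
                crop_side = f$crop_side)
}

segment_image <- function(image, method, cfg) {
  fc <- method_filter_config(cfg, method)
  if (method == "unfiltered") run_unfiltered(image, fc) else run_highpass(image, fc)
}

load_batch_inputs <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    specs <- lapply(cfg$synthetic$classes, function(cl)
      do.call(slice_params, c(cl, list(side_px = cfg$filter$crop_side))))
    fixture <- make_class_fixture(specs, cfg$synthetic$n_per_class,
                                  seed = cfg$seed)
    lapply(fixture, function(sl)
      list(image = sl$image, image_id = sl$image_id,
           class_label = sl$class_label,
           provenance = list(generator = "make_slice",
                             params = unclass(sl$params))))
  } else {
    lapply(seq_along(cfg$images), function(i) {
      rec <- cfg$images[[i]]
      img <- read_image(rec$path)
      crop <- if (is.null(rec$crop)) c(1L, 1L) else as.integer(rec$crop)
      img <- crop_square(img, crop, cfg$filter$crop_side)
      list(image = img,
           image_id = if (is.null(rec$image_id))
             sprintf("img_%03d", i) else rec$image_id,
           class_label = rec$class_label,
           provenance = list(source = rec$path, crop = crop))
    })
  }
}

#' Run the full batch pipeline
#'
#' For each input image and each requested method, segments the image,
#' writes the mask (\code{masks/}), the pixel table (\code{tables/}) and
#' the sandbox analysis (\code{mfa/}); then writes \code{summary.csv},
#' \code{boxstats.csv}, \code{scatter.csv} and \code{dispersion.csv} (the
#' latter only when all three methods ran), and \code{manifest.json} last.
#' A failure on one image is recorded in the manifest and the batch
#' continues.
#'
#' @param cfg A \code{run_config} from [validate_config()] (or a raw list /
#'   file path, which is validated first).
#' @return The manifest, invisibly (a list; also written as JSON).
#' @export
run_batch <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  out_dir <- cfg$out_dir
  for (d in file.path(out_dir, c("masks", "tables", "mfa")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  inputs <- load_batch_inputs(cfg)
  # one sandbox seed per (image, method), all derived from the master seed
  n_jobs <- length(inputs) * length(cfg$methods)
  job_seeds <- withr::with_seed(cfg$seed,
    sample.int(.Machine$integer.max - 1L, n_jobs))
  records <- list(); rows <- list(); errors <- list()
  job <- 0L
  for (inp in inputs) {
    for (method in cfg$methods) {
      job <- job + 1L
      stem <- paste0(inp$image_id, "_", method)
      res <- tryCatch({
        mask <- segment_image(inp$image, method, cfg)
        scfg <- do.call(sandbox_config,
                        c(cfg$sandbox, list(seed = job_seeds[job])))
        mfa <- analyze_mask(mask, scfg)
        paths <- list(mask = file.path(out_dir, "masks", paste0(stem, ".png")),
                      table = file.path(out_dir, "tables", paste0(stem, ".csv")),
                      mfa = file.path(out_dir, "mfa", paste0(stem, ".json")))
        write_mask_png(mask, paths$mask)
        write_pixel_table(mask_to_table(mask), paths$table)
        write_mfa_json(mfa, paths$mfa)
        est <- mfa$estimates
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = inp$image_id, class_label = inp$class_label,
          method = method, fat_fraction = mfa$fat_fraction,
          D0 = est$value[est$q == 0], D1 = est$value[est$q == 1],
          D2 = est$value[est$q == 2],
          D0_se = est$std_error[est$q == 0],
          D1_se = est$std_error[est$q == 1],
          D2_se = est$std_error[est$q == 2])
        list(image_id = inp$image_id, class_label = inp$class_label,
             method = method, status = "ok", outputs = paths,
             sandbox_seed = job_seeds[job], provenance = inp$provenance)
      }, error = function(e) {
        errors[[length(errors) + 1L]] <<- conditionMessage(e)
        list(image_id = inp$image_id, class_label = inp$class_label,
             method = method, status = "error",
             message = conditionMessage(e), provenance = inp$provenance)
      })
      records[[length(records) + 1L]] <- res
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  summary_files <- character()
  if (!is.null(results) && nrow(results) >= 2L) {
    wr <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(df, p, row.names = FALSE, eol = "\n")
      p
    }
    summary_files <- c(summary_files, wr(results, "results.csv"))
    ok_groups <- all(table(results$class_label, results$method) != 1L)
    if (ok_groups)
      summary_files <- c(summary_files,
                         wr(summarize_results(results), "summary.csv"))
    if (all(table(results$class_label, results$method) >= 5L))
      summary_files <- c(summary_files, wr(box_stats(results), "boxstats.csv"))
    summary_files <- c(summary_files, wr(scatter_table(results), "scatter.csv"))
    if (all(METHODS %in% results$method))
      summary_files <- c(summary_files,
                         wr(dispersion_comparison(results), "dispersion.csv"))
  }
  manifest <- list(config = unclass(cfg),
                   config_hash = config_hash(cfg),
                   n_images = length(inputs),
                   n_jobs = n_jobs,
                   n_failed = length(errors),
                   summary_files = as.list(summary_files),
                   records = records)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
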