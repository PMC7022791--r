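# Compact batch configuration used throughout: two classes, two slices
# each, 128 px crops and a light sandbox, so a full run stays fast.
small_config <- function(out_dir, seed = 5L) {
  list(
    seed = seed,
    filter = list(crop_side = 128L),
    sandbox = list(n_centers = 150L, r_min_px = 4, r_max_px = 32,
                   min_support_px = 50L),
    synthetic = list(
      classes = list(
        lean = list(fat_fraction_target = 0.15, n_clusters = 1L,
                    illumination_amplitude = 0.2),
        marbled = list(fat_fraction_target = 0.3, n_clusters = 1L,
                       illumination_amplitude = 0.2)),
      n_per_class = 2L),
    out_dir = out_dir)
}

test_that("validate_config fills defaults and reports violations by field path", {
  cfg <- validate_config(small_config(withr::local_tempdir()))
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$methods, c("unfiltered", "hp25", "hp50"))
  expect_equal(cfg$filter$radius_hp25, 25)
  expect_equal(cfg$filter$radius_hp50, 50)
  expect_equal(cfg$filter$threshold_filtered, 150L)
  expect_equal(cfg$filter$threshold_unfiltered, 175L)
  expect_equal(cfg$sandbox$n_radii, 12L)

  bad <- small_config(tempdir())
  bad$filter$radius_hp25 <- 300
  expect_error(validate_config(bad), "filter.radius_hp25")
  bad2 <- small_config(tempdir())
  bad2$filter$threshold_filtered <- 300L
  expect_error(validate_config(bad2), "filter.threshold_filtered")
  bad3 <- small_config(tempdir())
  bad3$methods <- character()
  expect_error(validate_config(bad3), "at least one")
  bad4 <- small_config(tempdir())
  bad4$nonsense <- 1
  expect_error(validate_config(bad4), "unknown configuration key")
  bad5 <- small_config(tempdir())
  bad5$sandbox$wrong <- 1
  expect_error(validate_config(bad5), "sandbox.wrong")
  expect_error(validate_config(list(seed = 1)), "synthetic.*images|images.*synthetic")
})

test_that("configs load from JSON and hash stably under field reordering", {
  raw <- small_config("out")
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, tmp, auto_unbox = TRUE, digits = NA)
  cfg_file <- validate_config(tmp)
  cfg_list <- validate_config(raw)
  expect_equal(config_hash(cfg_file), config_hash(cfg_list))

  reordered <- raw[rev(seq_along(raw))]
  reordered$filter <- raw$filter[rev(seq_along(raw$filter))]
  expect_equal(config_hash(validate_config(reordered)), config_hash(cfg_list))

  different <- raw
  different$seed <- 99L
  expect_false(config_hash(validate_config(different)) ==
               config_hash(cfg_list))
})

test_that("run_batch writes every artifact and an accurate manifest", {
  out <- withr::local_tempdir()
  man <- run_batch(small_config(out))
  expect_equal(man$n_images, 4L)
  expect_equal(man$n_jobs, 12L)  # 4 images x 3 methods
  expect_equal(man$n_failed, 0L)
  expect_length(man$records, 12L)
  ok <- vapply(man$records, function(r) r$status == "ok", logical(1))
  expect_true(all(ok))
  for (r in man$records)
    for (p in unlist(r$outputs)) expect_true(file.exists(p))
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(file.exists(file.path(out, "summary.csv")))
  expect_true(file.exists(file.path(out, "scatter.csv")))
  expect_true(file.exists(file.path(out, "dispersion.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))

  results <- utils::read.csv(file.path(out, "results.csv"))
  expect_equal(nrow(results), 12L)
  expect_true(all(c("D0", "D1", "D2", "fat_fraction") %in% names(results)))
  # classes ordered by design: marbled slices carry more fat for each method
  for (m in unique(results$method)) {
    sel <- results$method == m
    expect_gt(mean(results$fat_fraction[sel & results$class_label == "marbled"]),
              mean(results$fat_fraction[sel & results$class_label == "lean"]))
  }

  # a mask written to disk reloads into the same table that was exported
  rec <- man$records[[1]]
  mask <- read_mask_png(rec$outputs$mask)
  expect_identical(mask_to_table(mask), read_pixel_table(rec$outputs$table))
})

test_that("run_batch is byte-identical when repeated with the same seed", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  cfg1 <- small_config(out1); cfg2 <- small_config(out2)
  run_batch(cfg1); run_batch(cfg2)
  files1 <- sort(list.files(out1, recursive = TRUE))
  files2 <- sort(list.files(out2, recursive = TRUE))
  expect_equal(files1, files2)
  # the manifest embeds the (differing) out_dir; all other outputs must match
  comparable <- setdiff(files1, "manifest.json")
  for (f in comparable) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     label = paste("md5 of", f))
  }
  # manifests agree after removing the output-path fields
  m1 <- jsonlite::read_json(file.path(out1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(out2, "manifest.json"))
  strip <- function(m) {
    # out_dir differs between the runs, so so does the hash of the config
    m$config$out_dir <- NULL; m$config_hash <- NULL; m$summary_files <- NULL
    m$records <- lapply(m$records, function(r) { r$outputs <- NULL; r })
    m
  }
  expect_equal(strip(m1), strip(m2))
})

test_that("a failing image is recorded and the batch continues", {
  out <- withr::local_tempdir()
  raw <- small_config(out)
  # an all-but-empty fat phase starves the sandbox of support
  raw$synthetic$classes$lean$fat_fraction_target <- 0.001
  raw$synthetic$classes$lean$n_clusters <- 0L
  raw$sandbox$min_support_px <- 5000L
  man <- run_batch(raw)
  expect_gt(man$n_failed, 0L)
  failed <- Filter(function(r) r$status == "error", man$records)
  expect_true(all(grepl("insufficient support",
                        vapply(failed, `[[`, character(1), "message"))))
  expect_true(file.exists(file.path(out, "manifest.json")))
})
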