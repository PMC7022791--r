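# Shared illumination-robustness fixture: 20 slices at fat fraction 0.2
# under multiplicative shading (amplitude 0.3, correlation length 128 px),
# segmented by all three methods and analyzed with the default sandbox
# configuration. Built once per test run and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

shading_fixture <- function() {
  if (!is.null(.fixture_cache$fx)) return(.fixture_cache$fx)
  n <- 20L
  methods <- c("unfiltered", "hp25", "hp50")
  cfgs <- list(unfiltered = filter_config(25),
               hp25 = filter_config(25), hp50 = filter_config(50))
  acc <- matrix(NA_real_, n, 3, dimnames = list(NULL, methods))
  est <- list()
  for (i in seq_len(n)) {
    sl <- make_slice(slice_params(fat_fraction_target = 0.2,
                                  illumination_amplitude = 0.3,
                                  illumination_scale_px = 128, seed = i))
    scfg <- sandbox_config(seed = 1000L + i)
    for (m in methods) {
      mask <- if (m == "unfiltered") run_unfiltered(sl$image, cfgs[[m]])
              else run_highpass(sl$image, cfgs[[m]])
      acc[i, m] <- mean(mask == sl$mask)
      res <- analyze_mask(mask, scfg)
      e <- res$estimates
      e$slice <- i; e$method <- m; e$fat_fraction <- res$fat_fraction
      est[[length(est) + 1L]] <- e
    }
  }
  fx <- list(accuracy = acc, estimates = do.call(rbind, est))
  .fixture_cache$fx <- fx
  fx
}
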