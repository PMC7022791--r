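test_that("sample_centers honors the border margin, seed and support checks", {
  sq <- make_filled_square(512)$mask
  cfg <- sandbox_config(n_centers = 200L, r_max_px = 128, seed = 3L)
  ctr <- sample_centers(sq, cfg)
  expect_equal(nrow(ctr), 200L)
  expect_true(all(ctr >= 129L & ctr <= 384L))
  expect_identical(sample_centers(sq, cfg), ctr)
  expect_false(identical(sample_centers(sq, sandbox_config(n_centers = 200L,
    r_max_px = 128, seed = 4L)), ctr))

  expect_error(sample_centers(matrix(FALSE, 64, 64), sandbox_config()),
               "insufficient support")
  # support present but none far enough from the border
  edge <- matrix(FALSE, 64, 64); edge[1:2, ] <- TRUE
  expect_error(sample_centers(edge, sandbox_config(r_max_px = 30,
    min_support_px = 10L)), "smaller r_max")
})

test_that("count_masses counts discrete discs correctly", {
  sq <- make_filled_square(64)$mask
  mm <- count_masses(sq, cbind(row = 32L, col = 32L), c(1, 5, 10))
  expect_equal(mm$masses[1, ], c(5L, 81L, 317L))  # discrete discs |d| <= r
  expect_equal(mm$total_mass, 4096L)

  # isolated pixel is its own sandbox: mass 1 at every radius
  lone <- matrix(FALSE, 32, 32); lone[16, 16] <- TRUE
  mm1 <- count_masses(lone, cbind(16L, 16L), c(2, 4, 8))
  expect_true(all(mm1$masses == 1L))

  expect_error(count_masses(sq, cbind(32L, 32L), c(5, 5, 10)), "ascending")
  expect_error(count_masses(lone, cbind(1L, 1L), c(2, 4)), "on the set")
})

test_that("count_masses equals naive per-pixel enumeration on random masks", {
  radii <- c(1.5, 3, 5.5, 8, 12)
  for (rep in 1:12) {
    mask <- withr::with_seed(100 + rep, {
      m <- matrix(stats::runif(64 * 64) < stats::runif(1, 0.05, 0.5), 64, 64)
      m
    })
    if (sum(mask) < 3) next
    on <- which(mask, arr.ind = TRUE)
    centers <- on[withr::with_seed(rep, sample.int(nrow(on), 3L)), ,
                  drop = FALSE]
    mm <- count_masses(mask, centers, radii)
    expect_identical(mm$masses, naive_masses(mask, centers, radii))
    # nested discs: non-decreasing along the radius axis
    expect_true(all(apply(mm$masses, 1, function(v) !is.unsorted(v))))
    expect_true(all(mm$masses >= 1L))
  }
})

test_that("estimate_dimension implements the moment and entropy forms", {
  carp <- make_sierpinski_carpet(4)$mask
  cfg <- sandbox_config(n_centers = 400L, r_min_px = 3, seed = 5L)
  ctr <- sample_centers(carp, cfg)
  mm <- count_masses(carp, ctr, hamfrac:::resolve_radii(cfg, nrow(carp)))

  d0 <- estimate_dimension(mm, 0)
  expect_s3_class(d0, "dimension_estimate")
  expect_equal(d0$n_points, 12L)
  expect_gt(d0$r_squared, 0.99)
  expect_equal(d0$value, log(8) / log(3), tolerance = 0.1)

  # q = 1 entropy form is the limit of the moment form
  d1 <- estimate_dimension(mm, 1)
  d1eps <- estimate_dimension(mm, 1 + 1e-6)
  expect_equal(d1$value, d1eps$value, tolerance = 1e-4)

  # the OLS slope and its standard error agree with a hand-rolled fit
  rel <- mm$masses / mm$total_mass
  y <- colMeans(log(rel)); x <- log(mm$radii / nrow(carp))
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  resid <- y - mean(y) - beta * (x - mean(x))
  se <- sqrt(sum(resid^2) / (length(x) - 2) / sum((x - mean(x))^2))
  expect_equal(d1$value, beta, tolerance = 1e-12)
  expect_equal(d1$std_error, se, tolerance = 1e-12)

  expect_error(estimate_dimension(structure(list(masses = mm$masses[, 1:3],
    radii = c(5, 5, 5), total_mass = mm$total_mass, side = mm$side),
    class = "mass_matrix"), 0), "zero variance")
})

test_that("analyze_mask shares centers across q and reports fat fraction", {
  carp <- make_sierpinski_carpet(4)$mask
  res <- analyze_mask(carp, sandbox_config(n_centers = 400L, r_min_px = 3,
                                           seed = 2L))
  expect_equal(res$estimates$q, c(0, 1, 2))
  expect_equal(res$fat_fraction, 8^4 / 9^4)
  # shared mass matrix implies the Renyi ordering holds tightly here
  v <- res$estimates$value
  expect_true(all(diff(v) <= 1e-9 + 2 * sqrt(res$estimates$std_error[-3]^2 +
                                             res$estimates$std_error[-1]^2)))
})

test_that("dimension estimates are stable under pixel-replication upsampling", {
  carp <- make_sierpinski_carpet(4)$mask
  up <- carp[rep(seq_len(nrow(carp)), each = 2), rep(seq_len(ncol(carp)), each = 2)]
  cfg <- sandbox_config(n_centers = 600L, r_min_px = 4, r_max_px = 20, seed = 9L)
  cfg_up <- sandbox_config(n_centers = 600L, r_min_px = 8, r_max_px = 40, seed = 9L)
  for (q in c(0, 1, 2)) {
    d <- estimate_dimension(count_masses(carp, sample_centers(carp, cfg),
      hamfrac:::resolve_radii(cfg, nrow(carp))), q)
    du <- estimate_dimension(count_masses(up, sample_centers(up, cfg_up),
      hamfrac:::resolve_radii(cfg_up, nrow(up))), q)
    expect_lt(abs(d$value - du$value), 0.05)
  }
})

test_that("two independent center seeds agree on the level-5 carpet", {
  carp <- make_sierpinski_carpet(5)$mask
  r1 <- analyze_mask(carp, sandbox_config(seed = 21L))
  r2 <- analyze_mask(carp, sandbox_config(seed = 22L))
  expect_true(all(abs(r1$estimates$value - r2$estimates$value) < 0.03))
})
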