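test_that("histogram counts are conserved and degenerate volumes flagged", {
  cf <- cube_fixture(10, 10, intensity = 1000, background = 0)
  h <- intensity_histogram(cf$volume, 2)
  expect_equal(sum(h$counts), length(cf$volume$intensities))
  expect_equal(sort(h$counts), sort(c(1000L,
                                      length(cf$volume$intensities) - 1000L)))
  flat <- ct_volume(array(5, c(4, 4, 4)), spacing = 1)
  hf <- intensity_histogram(flat, 64)
  expect_true(hf$degenerate)
  expect_error(ki_threshold(hf), class = "femurfe_threshold_error")
})

test_that("KI threshold matches the exhaustive criterion-scan oracle", {
  # two well-separated Gaussian modes
  withr::with_seed(42, {
    x <- c(rnorm(20000, 300, 50), rnorm(20000, 1100, 50))
  })
  vol <- ct_volume(array(x, c(40, 40, 25)), spacing = 1)
  h <- intensity_histogram(vol, 256)
  thr <- ki_threshold(h)
  oracle <- ki_threshold_bruteforce(h$bin_edges, h$counts)
  bw <- diff(h$bin_edges)[1]
  expect_lt(abs(thr - oracle), bw + 1e-12)
  expect_gt(thr, 300); expect_lt(thr, 1100)

  # random histograms of several resolutions, unequal weights
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n_bins <- sample(c(64, 128, 256, 512), 1)
      w <- runif(1, 0.1, 0.9)
      x <- c(rnorm(round(2e4 * w), 200, 60), rnorm(round(2e4 * (1 - w)), 900, 120))
    })
    vol <- ct_volume(array(x, c(length(x), 1, 1)), spacing = 1)
    h <- intensity_histogram(vol, n_bins)
    expect_equal(ki_threshold(h),
                 ki_threshold_bruteforce(h$bin_edges, h$counts))
  }
})

test_that("two delta spikes give a threshold strictly between them", {
  x <- c(rep(100, 500), rep(800, 300))
  vol <- ct_volume(array(x, c(800, 1, 1)), spacing = 1)
  thr <- ki_threshold(intensity_histogram(vol, 256))
  expect_gt(thr, 100)
  expect_lt(thr, 800)
})

test_that("narrowed_range trims symmetrically with exact width ratio", {
  r <- narrowed_range(c(100, 300), 0.95)
  expect_equal(r$low, 105)
  expect_equal(r$high, 295)
  full <- list(low = 137.2, high = 991.4)
  for (p in c(1, 0.99, 0.975, 0.95)) {
    nr <- narrowed_range(full, p)
    expect_equal((nr$high - nr$low) / (full$high - full$low), p)
  }
  expect_equal(narrowed_range(c(5, 5), 0.95), list(low = 5, high = 5))
  expect_identical(narrowed_range(full, 1), full)
})

test_that("method descriptors map names to retained fractions", {
  ms <- seg_methods_all()
  expect_equal(vapply(ms, `[[`, 0, "p"),
               c("KI" = 1, "KI-99.0" = 0.99, "KI-97.5" = 0.975,
                 "KI-95.0" = 0.95))
})

test_that("noiseless phantom segments exactly to the ground truth", {
  ph <- generate_phantom(toy_params(noise_sd = 0))
  m <- segment_volume(ph$volume, "KI")
  expect_identical(m$values, ph$truth$bone_mask)
})

test_that("masks are nested KI >= KI-99.0 >= KI-97.5 >= KI-95.0", {
  for (seed in c(2L, 12L)) {
    ph <- generate_phantom(toy_params(seed = seed, artifact_count = 1L))
    masks <- lapply(names(seg_methods_all()), function(mn) {
      segment_volume(ph$volume, mn, largest_component = FALSE)$values
    })
    counts <- vapply(masks, sum, 0L)
    for (k in 1:3) {
      expect_true(all(masks[[k]] | !masks[[k + 1]]))  # superset relation
    }
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("narrowing excludes artifact voxels at least as well as full KI", {
  p <- toy_params(seed = 8L, artifact_count = 3L)
  ph <- generate_phantom(p)
  artifact <- ph$volume$intensities > p$bone_intensity * 1.15 &
    !ph$truth$bone_mask
  skip_if(sum(artifact) == 0)  # speck placement can fail on tiny grids
  kept <- vapply(c("KI", "KI-95.0"), function(mn) {
    sum(segment_volume(ph$volume, mn, largest_component = FALSE)$values &
          artifact)
  }, 0L)
  expect_lte(kept[["KI-95.0"]], kept[["KI"]])
})

test_that("largest-component cleanup removes bright specks from the mask", {
  p <- toy_params(seed = 8L, artifact_count = 3L)
  ph <- generate_phantom(p)
  m <- segment_volume(ph$volume, "KI")
  lab <- label_components3d(m$values, 26L)
  expect_equal(max(lab), 1L)
})

test_that("segmenting pure background raises a segmentation error", {
  vol <- ct_volume(array(c(rep(0, 500), rep(1000, 12)), c(8, 8, 8)),
                   spacing = 1)
  # all mass effectively one mode either errors on thresholding or empties
  expect_error(
    segment_volume(ct_volume(array(50, c(8, 8, 8)) +
                               array(runif(512), c(8, 8, 8)) * 0,
                             spacing = 1), "KI"),
    class = "femurfe_threshold_error")
})

test_that("percentile mode narrows by distribution mass instead of range", {
  ph <- generate_phantom(toy_params(seed = 4L))
  m_range <- segment_volume(ph$volume, "KI-95.0", mode = "range")
  m_pct <- segment_volume(ph$volume, "KI-95.0", mode = "percentile")
  expect_false(identical(m_range$values, m_pct$values))
  # percentile mode drops about 5% of above-threshold voxels
  m_full <- segment_volume(ph$volume, "KI", largest_component = FALSE)
  m_pct_raw <- segment_volume(ph$volume, "KI-95.0", mode = "percentile",
                              largest_component = FALSE)
  frac <- sum(m_pct_raw$values) / sum(m_full$values)
  expect_gt(frac, 0.9); expect_lt(frac, 0.99)
})
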