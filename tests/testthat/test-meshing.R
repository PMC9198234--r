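test_that("a single voxel yields a closed surface with Euler characteristic 2", {
  arr <- array(FALSE, c(5, 5, 5)); arr[3, 3, 3] <- TRUE
  s <- extract_surface(binary_mask(arr, c(1, 1, 1)))
  expect_equal(euler_characteristic(s), 2)
  expect_true(is_watertight(s))
})

test_that("sphere surface area is reproduced within 5%", {
  n <- 40; h <- 0.5; r <- 8
  co <- (seq_len(n) - 1) * h; ctr <- mean(co)
  arr <- array(FALSE, c(n, n, n))
  for (k in seq_len(n)) {
    arr[, , k] <- outer(co, co, function(x, y) (x - ctr)^2 + (y - ctr)^2) +
      (co[k] - ctr)^2 <= r^2
  }
  s <- extract_surface(binary_mask(arr, rep(h, 3)))
  expect_lt(abs(surface_area(s) / (4 * pi * r^2) - 1), 0.05)
  expect_true(is_watertight(s))
})

test_that("empty masks are rejected", {
  arr <- array(FALSE, c(4, 4, 4))
  expect_error(extract_surface(binary_mask(arr, c(1, 1, 1))),
               class = "femurfe_empty_mask")
  expect_error(tetrahedralize(binary_mask(arr, c(1, 1, 1))),
               class = "femurfe_empty_mask")
})

test_that("standardization removes duplicates and keeps the largest piece", {
  arr <- array(FALSE, c(16, 8, 8))
  arr[2:7, 2:7, 2:7] <- TRUE     # big component
  arr[12:13, 3:4, 3:4] <- TRUE   # small far-away component
  s <- extract_surface(binary_mask(arr, c(1, 1, 1)), smooth_sigma = 0)
  # inject duplicate faces
  k <- 5L
  dup <- surface_mesh(s$vertices, rbind(s$faces, s$faces[seq_len(k), ]))
  clean <- standardize_surface(dup, taubin_iter = 0L)
  # duplicates gone and only the big component left
  comps_area <- surface_area(clean)
  expect_lt(comps_area, surface_area(s))  # small piece dropped
  expect_true(is_watertight(clean))
  # idempotence of topology
  again <- standardize_surface(clean, taubin_iter = 0L)
  expect_equal(nrow(again$vertices), nrow(clean$vertices))
  expect_equal(nrow(again$faces), nrow(clean$faces))
})

test_that("hole closure restores watertightness", {
  arr <- array(FALSE, c(8, 8, 8)); arr[3:6, 3:6, 3:6] <- TRUE
  s <- extract_surface(binary_mask(arr, c(1, 1, 1)), smooth_sigma = 0)
  holed <- surface_mesh(s$vertices, s$faces[-1, , drop = FALSE])
  expect_false(is_watertight(holed))
  fixed <- standardize_surface(holed, taubin_iter = 0L)
  expect_true(is_watertight(fixed))
})

test_that("cropping keeps only voxels on the head side of the junction", {
  ph <- generate_phantom(toy_params(seed = 6L))
  m <- segment_volume(ph$volume, "KI")
  cm <- crop_and_orient(m, ph$truth$junction_point, ph$truth$junction_normal)
  idx <- which(cm$values, arr.ind = TRUE)
  z <- cm$origin[3] + (idx[, 3] - 1) * cm$spacing[3]
  expect_true(all(z >= -1e-9))
  # junction plane sits at z = 0 in the output frame
  expect_equal(cm$origin[3], 0)
})

test_that("axis-aligned cropping is identity up to translation", {
  ph <- generate_phantom(toy_params(noise_sd = 0))
  m <- segment_volume(ph$volume, "KI")
  cm <- crop_and_orient(m, ph$truth$junction_point, ph$truth$junction_normal)
  # direct voxel count above the plane in the source frame
  idx <- which(m$values, arr.ind = TRUE)
  z <- m$origin[3] + (idx[, 3] - 1) * m$spacing[3]
  n_above <- sum(z >= ph$truth$junction_point[3] - 1e-9)
  expect_equal(sum(cm$values), n_above)
})

test_that("rotated phantoms crop to nearly the same head voxel count", {
  p0 <- toy_params(noise_sd = 0)
  ph0 <- generate_phantom(p0)
  m0 <- segment_volume(ph0$volume, "KI")
  c0 <- crop_and_orient(m0, ph0$truth$junction_point, ph0$truth$junction_normal)
  axis <- c(1, 1, 2) / sqrt(6)
  p1 <- phantom_params(head_radius = 6.5, neck_radius = 3.2, neck_length = 5,
                       cortical_thickness = 1.5, grid_shape = 26L,
                       noise_sd = 0, neck_axis = axis)
  ph1 <- generate_phantom(p1)
  m1 <- segment_volume(ph1$volume, "KI")
  c1 <- crop_and_orient(m1, ph1$truth$junction_point, ph1$truth$junction_normal)
  expect_lt(abs(sum(c1$values) / sum(c0$values) - 1), 0.05)
})

test_that("tetrahedralization conserves volume exactly", {
  arr <- array(FALSE, c(6, 6, 6)); arr[3, 3, 3] <- TRUE
  tm1 <- tetrahedralize(binary_mask(arr, c(1, 1, 1)))
  expect_equal(nrow(tm1$elements), 6L)
  expect_lt(abs(sum(tet_volumes(tm1)) - 1), 1e-12)
  withr::with_seed(21, {
    arr2 <- array(runif(14 * 12 * 10) < 0.4, c(14, 12, 10))
  })
  arr2 <- largest_component3d(arr2, 6L)
  h <- 0.7
  tm2 <- tetrahedralize(binary_mask(arr2, rep(h, 3)))
  expect_lt(abs(sum(tet_volumes(tm2)) - sum(arr2) * h^3) /
              (sum(arr2) * h^3), 1e-9)
  expect_true(all(tet_volumes(tm2) > 0))
})

test_that("nested masks share nodes on common voxels", {
  arr_small <- array(FALSE, c(8, 8, 8)); arr_small[3:5, 3:5, 3:5] <- TRUE
  arr_big <- arr_small; arr_big[3:6, 3:6, 3:6] <- TRUE
  tm_s <- tetrahedralize(binary_mask(arr_small, c(1, 1, 1)))
  tm_b <- tetrahedralize(binary_mask(arr_big, c(1, 1, 1)))
  key <- function(nd) paste(round(nd[, 1], 9), round(nd[, 2], 9),
                            round(nd[, 3], 9))
  expect_true(all(key(tm_s$nodes) %in% key(tm_b$nodes)))
})

test_that("node sets select the inferior layer and proximal cap", {
  cf <- cube_fixture(10, 5)
  tm <- tetrahedralize(binary_mask(cf$truth$bone_mask, cf$volume$spacing))
  nd <- tm$nodes
  expect_equal(sort(tm$node_sets$inferior_fixed),
               which(abs(nd[, 3] - min(nd[, 3])) < 1e-9))
  lf <- tm$node_sets$proximal_load
  expect_gt(nrow(lf), 0)
  zc <- (nd[lf[, 1], 3] + nd[lf[, 2], 3] + nd[lf[, 3], 3]) / 3
  expect_true(all(abs(zc - max(nd[, 3])) < 1e-9))
})

test_that("stl round trip preserves geometry", {
  arr <- array(FALSE, c(6, 6, 6)); arr[3:4, 3:4, 3:4] <- TRUE
  s <- extract_surface(binary_mask(arr, c(1, 1, 1)), smooth_sigma = 0)
  path <- tempfile(fileext = ".stl")
  write_stl(s, path)
  back <- read_stl(path)
  expect_equal(nrow(back$faces), nrow(s$faces))
  expect_equal(surface_area(back), surface_area(s), tolerance = 1e-5)
  unlink(path)
})
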