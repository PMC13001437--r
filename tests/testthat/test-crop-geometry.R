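test_that("midline of a flat slab is its mid-row with zero tangent", {
  m <- rect_mask(300, 600, 100:200, 1:600)
  ax <- tissue_midline(m)
  expect_true(all(abs(ax$y - 150) <= 1.5))
  expect_true(all(abs(ax$tangent) <= 1))
})

test_that("midline tangent tracks a tilted slab away from the edges", {
  m <- tilted_band(400, 600, 10, y_top = 80, h = 100)
  ax <- tissue_midline(m)
  mid <- ax$x > 100 & ax$x < 500
  expect_true(all(abs(ax$tangent[mid] - 10) <= 2))
  # axis tracks the analytic per-column centroid line
  cent <- 80 + tan(10 * pi / 180) * (ax$x - 1) + 100 / 2
  expect_true(all(abs(ax$y[mid] - cent[mid]) <= 2))
})

test_that("midline of a sinusoidal phantom tracks the analytic mid-curve", {
  cfg <- phantom_config()
  b <- generate_bscan(cfg, seed = 2)
  ax <- tissue_midline(b$labels != 0)
  total <- sum(cfg$base_thickness)
  y_true <- cfg$top_margin +
    cfg$curvature_amplitude * sin(2 * pi * (ax$x - 1) /
                                  cfg$curvature_period) + total / 2
  mid <- ax$x > 50 & ax$x < cfg$width - 50
  expect_true(all(abs(ax$y[mid] - y_true[mid]) <= 2))
})

test_that("degenerate tissue masks are rejected", {
  expect_error(tissue_midline(matrix(0L, 50, 50)), "empty")
  two <- rect_mask(100, 200, 10:40, 1:200)
  two[60:90, ] <- 1L
  expect_error(tissue_midline(two), "multiple large components")
  narrow <- rect_mask(100, 200, 40:60, 1:60)
  expect_error(tissue_midline(narrow), "width")
})

test_that("crop planning follows positions and local tangents", {
  flat <- tissue_midline(rect_mask(300, 1024, 100:200, 1:1024))
  plans <- plan_crops(flat)
  expect_length(plans, 3L)
  expect_equal(vapply(plans, function(p) p$center[["x"]], 0),
               c(256, 512, 768))
  expect_true(all(abs(vapply(plans, `[[`, 0, "rotation")) <= 1))

  tilt <- tissue_midline(tilted_band(400, 1024, 10, y_top = 60, h = 100))
  p2 <- plan_crops(tilt, positions = 512)
  expect_true(abs(p2[[1]]$rotation - 10) <= 2)

  expect_warning(p3 <- plan_crops(flat, positions = 5000), "outside")
  expect_length(p3, 0L)
})

test_that("rotation-0 extraction equals direct slicing", {
  cfg <- flat_crop_config(width = 600, height = 340)
  b <- generate_bscan(cfg, seed = 3)
  plan <- structure(list(center = c(x = 300, y = 150), rotation = 0,
                         width = 200L, height = 280L, position = 300),
                    class = "crop_plan")
  cr <- extract_crop(b$image, b$labels, plan)
  direct <- b$labels[(150 - 139):(150 + 140), (300 - 99):(300 + 100)]
  expect_identical(cr$labels, matrix(direct, nrow = 280L))
  expect_equal(cr$image, matrix(b$image[(150 - 139):(150 + 140),
                                        (300 - 99):(300 + 100)],
                                nrow = 280L))
  expect_true(all(unique(as.vector(cr$labels)) %in% unique(as.vector(b$labels))))
})

test_that("rotated extraction re-levels a tilted slab", {
  m <- tilted_band(400, 1024, 10, y_top = 60, h = 120)
  ax <- tissue_midline(m)
  plan <- plan_crops(ax, positions = 512, width = 256, height = 300)[[1]]
  cr <- extract_crop(NULL, m, plan)
  tops <- apply(cr$labels, 2, function(col) which(col != 0)[1])
  inner <- 20:236
  expect_lt(max(tops[inner]) - min(tops[inner]), 4)  # horizontal within 2 px
})

test_that("ONH offsets follow the registration arithmetic and equivariance", {
  reg <- onh_registration(c(512, 512), scanline_y = 612, x_scale = 1)
  expect_equal(onh_offsets(reg, 412), c(onh_dx = -100, onh_dy = 100))
  expect_equal(onh_offsets(onh_registration(c(300, 400), 400), 300),
               c(onh_dx = 0, onh_dy = 0))

  # translation equivariance via segment_onh on a shifted mask
  f <- matrix(0L, 200, 200)
  f[80:120, 90:130] <- 1L
  c1 <- segment_onh(f)
  shift <- matrix(0L, 200, 200)
  shift[(80:120) + 15, (90:130) + 7] <- 1L
  c2 <- segment_onh(shift)
  r1 <- onh_offsets(onh_registration(c1, scanline_y = 50), 60)
  r2 <- onh_offsets(onh_registration(c2, scanline_y = 50), 60)
  expect_equal(r2 - r1, c(onh_dx = -7, onh_dy = -15))
})

test_that("segment_onh finds centroids of disks, largest blobs, pixels", {
  f <- matrix(0L, 600, 600)
  gx <- matrix(seq_len(600), 600, 600, byrow = TRUE)
  gy <- matrix(seq_len(600), 600, 600)
  f[(gx - 300)^2 + (gy - 400)^2 <= 50^2] <- 1L
  expect_equal(segment_onh(f), c(x = 300, y = 400))

  # two disjoint blobs: centroid of the largest (areas by flood-fill oracle)
  f2 <- matrix(0L, 100, 100)
  f2[10:40, 10:40] <- 1L
  f2[70:80, 70:80] <- 1L
  expect_equal(max(flood_fill_label(f2)), 2L)
  expect_equal(segment_onh(f2), c(x = 25, y = 25))

  f3 <- matrix(0L, 10, 10); f3[7, 3] <- 1L
  expect_equal(segment_onh(f3), c(x = 3, y = 7))
  expect_error(segment_onh(matrix(0L, 5, 5)), "empty")
})
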