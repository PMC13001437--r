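test_that("flat phantom stacks layers at exactly the configured thickness", {
  cfg <- flat_crop_config()
  b <- generate_bscan(cfg, seed = 1)
  sc <- layer_scheme()
  for (ly in sc$layers) {
    counts <- colSums(b$labels == sc$label_values[[ly]])
    expect_true(all(counts == cfg$base_thickness[[ly]]),
                info = paste("layer", ly))
  }
  # truth table equals per-column mask row-counts exactly
  for (ly in c(sc$layers, "RD")) {
    tr <- b$truth$thickness
    expect_equal(tr$thickness[tr$layer == ly],
                 unname(colSums(b$labels == sc$label_values[[ly]])))
  }
})

test_that("injected lesions are recoverable from the emitted mask", {
  cfg <- flat_crop_config()
  # domain break: INL splits into 2 components (flood-fill oracle)
  b <- generate_bscan(cfg, lesion_spec("domain_break", "INL",
                                       center_x = 128, extent = 20,
                                       magnitude = 1), seed = 2)
  expect_equal(max(flood_fill_label(b$labels == 2L)), 2L)
  # detachment: RD class sits between ISOS and RPE at center_x
  b2 <- generate_bscan(cfg, lesion_spec("detachment", center_x = 128,
                                        extent = 60, magnitude = 15),
                       seed = 2)
  col <- b2$labels[, 128]
  rd_rows <- which(col == 9L)
  expect_equal(length(rd_rows), 15L)
  expect_equal(col[min(rd_rows) - 1L], 6L)   # ISOS above
  expect_equal(col[max(rd_rows) + 1L], 7L)   # RPE below
  # truth round-trips for the lesioned masks too
  tr <- b2$truth$thickness
  expect_equal(tr$thickness[tr$layer == "RD"],
               unname(colSums(b2$labels == 9L)))
  # focal thinning reduces the target layer at the center only
  b3 <- generate_bscan(cfg, lesion_spec("focal_thinning", "ONL",
                                        center_x = 128, extent = 80,
                                        magnitude = 0.5), seed = 2)
  onl <- colSums(b3$labels == 4L)
  expect_equal(onl[128], 30)
  expect_equal(onl[1], 60)
})

test_that("invalid lesions and overflowing stacks are rejected", {
  cfg <- flat_crop_config()
  expect_error(generate_bscan(cfg, lesion_spec("focal_thinning", "ONL",
                                               center_x = 5000, extent = 10,
                                               magnitude = 0.5)),
               "outside image width")
  expect_error(generate_bscan(cfg, lesion_spec("focal_thinning", "XXX",
                                               center_x = 10, extent = 10,
                                               magnitude = 0.5)),
               "not in layer_order")
  big <- phantom_config(width = 64, height = 280, top_margin = 20,
                        curvature_amplitude = 0)
  expect_error(generate_bscan(big, lesion_spec("detachment", center_x = 32,
                                               extent = 30, magnitude = 60)),
               "overflows")
  expect_error(lesion_spec("detachment", center_x = 10, extent = -1,
                           magnitude = 5), "extent")
  expect_error(phantom_config(layer_order = c("IPL", "INL")), "exactly 8")
})

test_that("identical (config, lesions, seed) reproduce bit-identical output", {
  cfg <- flat_crop_config()
  les <- list(lesion_spec("detachment", center_x = 100, extent = 40,
                          magnitude = 10))
  a <- generate_bscan(cfg, les, seed = 9)
  b <- generate_bscan(cfg, les, seed = 9)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  c <- generate_bscan(cfg, les, seed = 10)
  expect_false(identical(a$image, c$image))
})

test_that("cohort plan has one record per design cell and honors effects", {
  spec <- cohort_spec(groups = list(list(name = "g", n_mice = 1)),
                      timepoints = 6, eyes_per_mouse = 2,
                      replicates_per_scanline = 2, seed = 1)
  plan <- plan_cohort(spec)
  expect_equal(nrow(plan), 1 * 2 * 3 * 2)      # eyes x scanlines x reps

  # null case: equal groups differ by less than 2 sampling SEs
  spec0 <- cohort_spec(groups = list(list(name = "a", n_mice = 8),
                                     list(name = "b", n_mice = 8)),
                       eyes_per_mouse = 1, replicates_per_scanline = 1,
                       seed = 4)
  p0 <- plan_cohort(spec0)
  ma <- tapply(p0$thick_ONL, p0$group, mean)
  se <- sqrt(sum(tapply(p0$thick_ONL, p0$group, var) /
                 tapply(p0$thick_ONL, p0$group, length)))
  expect_lt(abs(ma[["a"]] - ma[["b"]]), 2 * se)

  # 0.67x ONL effect realized within 5% at n = 8 mice
  spec1 <- cohort_spec(groups = list(list(name = "ctrl", n_mice = 8),
                                     list(name = "mut", n_mice = 8,
                                          effect = c(ONL = 0.67))),
                       eyes_per_mouse = 1, replicates_per_scanline = 1,
                       seed = 5)
  p1 <- plan_cohort(spec1)
  ratio <- mean(p1$thick_ONL[p1$group == "mut"]) /
    mean(p1$thick_ONL[p1$group == "ctrl"])
  expect_lt(abs(ratio - 0.67) / 0.67, 0.05)

  expect_error(cohort_spec(groups = list()), "at least one group")
  expect_error(cohort_spec(groups = list(list(name = "g", n_mice = 2,
                                              effect = c(ONL = 3)))),
               "effect fractions")
})

test_that("generate_cohort writes a readable, deterministic cohort tree", {
  td <- withr::local_tempdir()
  spec <- cohort_spec(groups = list(list(name = "g", n_mice = 1,
                                         lesion_rate = 1)),
                      timepoints = 6, eyes_per_mouse = 1,
                      scanlines = c("superior", "midline"),
                      replicates_per_scanline = 1,
                      base_config = flat_crop_config(), seed = 3)
  meta <- generate_cohort(spec, td)
  expect_equal(nrow(meta), 2L)
  expect_true(file.exists(file.path(td, "metadata.csv")))
  m <- read_metadata(file.path(td, "metadata.csv"))
  lab <- read_labelmap(file.path(td, m$mask_path[1]))
  expect_true(9L %in% lab)                      # lesion_rate 1 -> RD present
  truth <- read.csv(file.path(td, "ground_truth.csv"))
  expect_true(all(truth$lesion))
  # same spec + seed reproduces byte-identical masks
  td2 <- withr::local_tempdir()
  generate_cohort(spec, td2)
  expect_identical(readBin(file.path(td, m$mask_path[1]), "raw", 1e6),
                   readBin(file.path(td2, m$mask_path[1]), "raw", 1e6))
})
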