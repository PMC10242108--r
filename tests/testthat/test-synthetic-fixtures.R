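test_that("scene specs enforce their invariants", {
  expect_error(scene_spec(zone_layout = data.frame(
    zone = "white", red_intensity = 255, area_fraction = 0.9)), "sum to 1")
  expect_error(scene_spec(radius_range = c(1, 5)), ">= 2")
  expect_error(scene_spec(n_nuclei = -1), ">= 0")
  # layout must respect the threshold intervals it exercises
  expect_error(scene_spec(zone_layout = data.frame(
    zone = "dark_red", red_intensity = 120, area_fraction = 1)),
    "threshold intervals")
  expect_error(scene_spec(zone_layout = data.frame(
    zone = "white", red_intensity = 150, area_fraction = 1)),
    "threshold intervals")
})

test_that("an empty all-white scene renders uniformly blank", {
  sp <- scene_spec(width_px = 32, height_px = 24, n_nuclei = 0,
                   noise_sd = 0, illumination_gradient = 0,
                   zone_layout = data.frame(zone = "white",
                                            red_intensity = 255,
                                            area_fraction = 1), seed = 1)
  sc <- render_scene(sp)
  expect_true(all(sc$field$pixels == 255))
  expect_equal(unname(sc$truth$pixel_fraction_truth["white"]), 1)
})

test_that("a single DAB-positive nucleus darkens the DAB channel locally", {
  sp <- scene_spec(width_px = 48, height_px = 48, n_nuclei = 1,
                   noise_sd = 0, illumination_gradient = 0,
                   dab_positive_fraction = 1,
                   zone_layout = data.frame(zone = "white",
                                            red_intensity = 255,
                                            area_fraction = 1), seed = 5)
  sc <- render_scene(sp)
  expect_equal(sc$truth$n_placed, 1)
  ch <- deconvolve(sc$field)
  nt <- sc$truth$nucleus_table
  inside <- ch$dab[nt$row, nt$col]
  outside <- ch$dab[1, 1]
  expect_lt(inside, outside - 50)
})

test_that("rendering is bit-identical for the same seed", {
  sp <- scene_spec(width_px = 96, height_px = 96, n_nuclei = 15,
                   noise_sd = 4, illumination_gradient = 15, seed = 77)
  a <- render_scene(sp)
  b <- render_scene(sp)
  expect_identical(a$field$pixels, b$field$pixels)
  expect_identical(a$truth$nucleus_table, b$truth$nucleus_table)
  # and RNG state outside is untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(render_scene(sp)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("ground-truth fractions equal fractions measured on the mask", {
  sp <- scene_spec(width_px = 100, height_px = 50, n_nuclei = 5,
                   noise_sd = 2, seed = 8)
  sc <- render_scene(sp)
  zt <- sc$truth$zone_mask_truth
  measured <- c(dark_red = mean(zt == 2L), light_pink = mean(zt == 1L),
                white = mean(zt == 0L))
  expect_equal(sc$truth$pixel_fraction_truth, measured)
  expect_equal(sum(sc$truth$pixel_fraction_truth), 1)
  # every nucleus centre lies inside the image
  nt <- sc$truth$nucleus_table
  expect_true(all(nt$row >= 1 & nt$row <= 50))
  expect_true(all(nt$col >= 1 & nt$col <= 100))
})

test_that("noiseless rendering round-trips concentrations through unmixing", {
  sp <- scene_spec(width_px = 96, height_px = 96, n_nuclei = 10,
                   noise_sd = 0, illumination_gradient = 0, seed = 14)
  sc <- render_scene(sp)
  ch <- deconvolve(sc$field)
  img2 <- compose_rgb(attr(ch, "concentrations"))
  expect_lte(max(abs(img2 - sc$field$pixels)), 1)
  # transmitted-intensity error below one quantisation step
  expect_lt(max(abs(10^-attr(ch, "concentrations")[[1]] -
                    10^-(-log10(pmax(sc$field$pixels[, , 1], 1) / 255)))),
            1)
})

test_that("overlap requests produce touching nuclei", {
  sp <- scene_spec(width_px = 160, height_px = 160, n_nuclei = 30,
                   overlap_fraction = 0.3, noise_sd = 0, seed = 6)
  sc <- render_scene(sp)
  nt <- sc$truth$nucleus_table
  dmat <- as.matrix(dist(nt[, c("row", "col")]))
  rsum <- outer(nt$radius, nt$radius, "+")
  diag(dmat) <- Inf
  touching <- rowSums(dmat < rsum) > 0
  expect_gte(sum(touching), 2 * round(0.3 * 30) * 0.8)
})

test_that("scene files are written in plain formats", {
  sp <- scene_spec(width_px = 32, height_px = 32, n_nuclei = 3, seed = 2)
  sc <- render_scene(sp)
  d <- file.path(tempdir(), "scene_out")
  paths <- write_scene(sc, sp, d)
  expect_true(all(file.exists(paths)))
  back <- read_rgb_field(paths[["image"]])
  expect_equal(back$pixels, sc$field$pixels, ignore_attr = TRUE)
  truth <- read.csv(paths[["nuclei"]])
  expect_equal(nrow(truth), sc$truth$n_placed)
})

test_that("ct simulation matches its construction exactly at zero noise", {
  ct <- simulate_ct_table(3, effect_log2 = 0, noise_sd = 0, seed = 1)
  f <- fold_enrichment(ct$ct_target, ct$ct_reference)
  expect_equal(unique(f), 2^-5)
  ct1 <- simulate_ct_table(3, effect_log2 = 1, noise_sd = 0, seed = 1)
  f1 <- fold_enrichment(ct1$ct_target, ct1$ct_reference)
  expect_equal(mean(f1[ct1$group == "FDG_pos"]) /
               mean(f1[ct1$group == "FDG_neg"]), 2)
  expect_error(simulate_ct_table(0), ">= 1")
  expect_error(simulate_ct_table(3, noise_sd = -1), ">= 0")
})
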