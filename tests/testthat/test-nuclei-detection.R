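test_that("three separated intensity clusters are recovered exactly", {
  ch <- matrix(rep(c(0, 128, 255), each = 100), 10, 30)
  cl <- classify_intensities(ch)
  expect_equal(unname(cl$centers), c(255, 128, 0))
  expect_equal(names(cl$centers),
               c("background", "weak_cytoplasmic", "nuclear"))
  expect_identical(cl$nuclear, ch == 0)
})

test_that("degenerate channels degrade gracefully", {
  const <- matrix(255, 4, 4)
  cl <- classify_intensities(const)
  expect_false(any(cl$nuclear))
  expect_length(cl$centers, 1)
  two <- matrix(c(40, 40, 200, 200), 2, 2)
  cl2 <- classify_intensities(two)
  expect_identical(cl2$nuclear, two == 40)
  expect_error(classify_intensities(matrix(1, 2, 2), k = 1), ">= 2")
})

test_that("classification attains the exhaustive 1-D k-means optimum", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(10:60, 1)
    x <- sample(0:255, n, replace = TRUE)
    ch <- matrix(x, 1)
    cl <- classify_intensities(ch)
    if (length(unique(x)) < 3) next
    expect_equal(intensity_class_sse(ch, cl), oracle_kmeans3_sse(x),
                 tolerance = 1e-9)
  }
})

test_that("light clusters are never called nuclear", {
  ch <- matrix(c(rep(230, 50), rep(244, 30), rep(255, 120)), 10, 20)
  cl <- classify_intensities(ch)
  expect_false(any(cl$nuclear))
})

test_that("watershed splits discs and labels are contiguous", {
  mask <- matrix(FALSE, 40, 40)
  xy <- expand.grid(r = 1:40, c = 1:40)
  mask[(xy$r - 20)^2 + (xy$c - 20)^2 <= 64] <- TRUE
  lab <- segment_nuclei(mask)
  expect_equal(max(lab), 1L)                      # one disc -> one label
  expect_identical(lab > 0L, mask)

  # two discs overlapping by ~30% of the radius -> two labels near truth
  mask2 <- matrix(FALSE, 50, 60)
  g <- expand.grid(r = 1:50, c = 1:60)
  mask2[(g$r - 25)^2 + (g$c - 22)^2 <= 81] <- TRUE
  mask2[(g$r - 25)^2 + (g$c - 36)^2 <= 81] <- TRUE
  lab2 <- segment_nuclei(mask2)
  expect_equal(max(lab2), 2L)
  cents <- nucleus_features(lab2, list(fastred = mask2 * 0,
                                       fastblue = mask2 * 0,
                                       dab = mask2 * 0))
  expect_true(any(abs(cents$col - 22) < 2) && any(abs(cents$col - 36) < 2))
  expect_true(all(abs(cents$row - 25) < 2))

  empty <- segment_nuclei(matrix(FALSE, 10, 10))
  expect_equal(max(empty), 0L)
})

test_that("size filtering keeps only nucleus-sized objects", {
  lab <- matrix(0L, 30, 120)
  lab[1:5, 1] <- 1L                 # area 5
  lab[1:10, 11:20] <- 2L            # area 100
  lab[1:30, 31:120] <- 3L           # area 2700
  out <- filter_by_size(lab, 20, 2000)
  expect_equal(max(out), 1L)
  expect_equal(sum(out == 1L), 100)
  expect_error(filter_by_size(lab, 100, 50), "min_area < max_area")
  # all-compliant map is identity up to renumbering
  out2 <- filter_by_size(lab, 1, 1e6)
  expect_equal(max(out2), 3L)
  expect_equal(filter_by_size(matrix(0L, 4, 4), 10, 100),
               matrix(0L, 4, 4))
})

test_that("marker classes are disjoint, exhaustive and follow the DAB rule", {
  lab <- matrix(0L, 10, 10)
  lab[2:4, 2:4] <- 1L
  lab[7:9, 7:9] <- 2L
  dabnuc <- matrix(FALSE, 10, 10)
  dabnuc[2:4, 2:4] <- TRUE          # nucleus 1 fully DAB
  mk <- classify_marker(lab, dabnuc)
  expect_equal(mk, c("DAB_pos", "FB_only"))
  expect_true(all(mk %in% c("DAB_pos", "FB_only")))
  # threshold behaviour at exactly half the pixels
  dab2 <- matrix(FALSE, 10, 10)
  dab2[2:4, 2] <- TRUE              # 3 of 9 pixels
  expect_equal(classify_marker(lab, dab2)[1], "FB_only")
  expect_equal(classify_marker(lab, dab2,
                               dab_fraction_threshold = 1 / 3)[1], "DAB_pos")
  expect_error(classify_marker(lab, matrix(FALSE, 5, 5)), "shapes")
})

test_that("nucleus zone assignment uses plurality with declared tie-break", {
  lab <- matrix(0L, 10, 10)
  lab[1:2, 1:5] <- 1L               # 10 px
  masks <- assign_zones(matrix(255, 10, 10))  # all white
  expect_equal(assign_nucleus_zone(lab, masks), "white")
  # 60/40 split -> plurality
  fr <- matrix(255, 10, 10); fr[1:2, 1:3] <- 150
  expect_equal(assign_nucleus_zone(lab, assign_zones(fr)), "light_pink")
  # exact 50/50 dark_red vs white -> dark_red by tie-break
  fr2 <- matrix(255, 10, 10); fr2[1, 1:5] <- 50
  expect_equal(assign_nucleus_zone(lab, assign_zones(fr2)), "dark_red")
})

test_that("counts are invariant under label permutation", {
  sp <- scene_spec(width_px = 96, height_px = 96, n_nuclei = 12,
                   noise_sd = 0, illumination_gradient = 0, seed = 9)
  sc <- render_scene(sp)
  ch <- deconvolve(sc$field)
  det <- detect_nuclei(ch, assign_zones(ch$fastred))
  lab <- det$labels
  # permute the label ids
  perm <- sample(max(lab))
  lab2 <- lab
  lab2[lab > 0] <- perm[lab[lab > 0]]
  dab <- classify_intensities(ch$dab)
  expect_equal(sort(table(classify_marker(lab, dab))),
               sort(table(classify_marker(lab2, dab))))
  f1 <- nucleus_features(lab, ch)
  f2 <- nucleus_features(lab2, ch)
  expect_equal(sort(f1$area), sort(f2$area))
})

test_that("end-to-end nucleus recovery matches generator ground truth", {
  sp <- scene_spec(width_px = 192, height_px = 192, n_nuclei = 40,
                   noise_sd = 0, illumination_gradient = 0,
                   overlap_fraction = 0, dab_positive_fraction = 0.25,
                   seed = 21)
  sc <- render_scene(sp)
  ch <- deconvolve(sc$field)
  det <- detect_nuclei(ch, assign_zones(ch$fastred))
  expect_equal(nrow(det$nuclei), sc$truth$n_placed)
  expect_equal(mean(det$nuclei$marker_class == "DAB_pos"),
               mean(sc$truth$nucleus_table$marker_class == "DAB_pos"))
  # detection is deterministic
  det2 <- detect_nuclei(ch, assign_zones(ch$fastred))
  expect_identical(det$labels, det2$labels)
})
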