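test_that("detect_roi brackets a bright disk and matches the scan oracle", {
  fr <- disk_frame(center = c(100, 100), radius = 20, level = 200)
  roi <- detect_roi(fr, tau0 = 0.5)
  bb <- bf_bright_bbox(fr$pixels, 0.5 * 200)
  expect_equal(c(roi$row0, roi$col0, roi$row1, roi$col1),
               c(bb[1], bb[2], bb[3], bb[4]))
  expect_equal(roi$form_value, 1)
  expect_equal(roi$threshold_used, 0.5)
  # symmetry point of the ROI lands on the true center within a pixel
  sp <- symmetry_point(roi)
  expect_lt(max(abs(sp$rc - c(100, 100))), 1)
})

test_that("detect_roi lowers the threshold until the form test passes", {
  # bright plus-shape: at high threshold only a 4x40 bar passes (form
  # far from 1); a dimmer square becomes visible at lower threshold
  px <- matrix(0, 120, 120)
  px[59:62, 41:80] <- 250
  px[41:80, 41:80] <- pmax(px[41:80, 41:80], 100)
  fr <- photometric_frame(px, thickness_mm = 1, power_mW = 1)
  roi <- detect_roi(fr, tau0 = 0.9, tau_step = 0.1, tau_min = 0.05)
  expect_lt(roi$threshold_used, 0.9)
  expect_equal(roi$form_value, 1)
  expect_equal(c(roi$row0, roi$row1), c(40, 80))
})

test_that("detect_roi reports failures honestly", {
  blank <- photometric_frame(matrix(0, 50, 50), thickness_mm = 1,
                             power_mW = 1)
  expect_error(detect_roi(blank), "no bright area")
  # a 10x40 bar can never satisfy the square form test
  px <- matrix(0, 100, 100)
  px[46:55, 31:70] <- 200
  bar <- photometric_frame(px, thickness_mm = 1, power_mW = 1)
  expect_error(detect_roi(bar, form_limits = c(0.8, 1.25)),
               "form_value = 0.25")
})

test_that("symmetry point follows the odd/even central-pixel rule", {
  mk_roi <- function(r0, c0, r1, c1)
    structure(list(row0 = r0, col0 = c0, row1 = r1, col1 = c1,
                   threshold_used = 0.5, form_value = 1),
              class = "region_of_interest")
  odd <- symmetry_point(mk_roi(0L, 0L, 5L, 5L))   # side 5
  expect_equal(odd$rc, c(2.5, 2.5))
  expect_equal(odd$parity, "odd")
  even <- symmetry_point(mk_roi(0L, 0L, 4L, 4L))  # side 4
  expect_equal(even$rc, c(2.0, 2.0))
  expect_equal(even$parity, "even")
  big <- symmetry_point(mk_roi(80L, 80L, 122L, 122L))  # side 42
  expect_equal(big$rc, c(101.0, 101.0))
  expect_equal(big$parity, "even")
})

test_that("zone masks equal the per-pixel distance oracle and partition the disk", {
  set.seed(101)
  shape <- c(90L, 110L)
  for (i in 1:12) {
    R1 <- runif(1, 2, 8); R2 <- R1 + runif(1, 3, 10)
    R3 <- R2 + runif(1, 3, 10)
    ctr <- c(runif(1, R3 + 1, shape[1] - R3 - 1),
             runif(1, R3 + 1, shape[2] - R3 - 1))
    geom <- zone_geometry(ctr, R1, R2, R3)
    masks <- zone_masks(geom, shape)
    cls <- bf_classify_pixels(ctr, R1, R2, R3, shape)
    expect_identical(masks$A1, cls == "A1")
    expect_identical(masks$A2, cls == "A2")
    expect_identical(masks$A3, cls == "A3")
    # partition: pairwise disjoint, union = R3 disk
    expect_false(any(masks$A1 & masks$A2))
    expect_false(any(masks$A1 & masks$A3))
    expect_false(any(masks$A2 & masks$A3))
    expect_identical(masks$A1 | masks$A2 | masks$A3, cls != "bg")
  }
  # R1 = 1 centered on a pixel center captures exactly that pixel
  g1 <- zone_geometry(c(10.5, 10.5), 1, 3, 5)
  m1 <- zone_masks(g1, c(21L, 21L))
  expect_equal(sum(m1$A1), 1L)
  expect_true(m1$A1[11, 11])
  expect_error(zone_masks(zone_geometry(c(5, 5), 1, 3, 6), c(21L, 21L)),
               "exceeds")
})

test_that("zone illuminance is summed DN over included pixel area", {
  geom <- zone_geometry(c(30, 30), 5, 12, 20)
  u <- photometric_frame(matrix(77, 60, 60), thickness_mm = 1, power_mW = 1)
  zi <- zone_illuminance(u, geom)
  expect_equal(c(zi$E_A1, zi$E_A2, zi$E_A3), c(77, 77, 77))
  # partition property on the areas
  d2 <- zone_geometry(c(30, 30), 12, 20, 25)
  zi2 <- zone_illuminance(u, d2)
  expect_equal(zi$area_A1 + zi$area_A2, zi2$area_A1)

  # a single hot pixel in A2 contributes k / |A2|
  px <- matrix(0, 60, 60)
  px[30, 40] <- 200   # distance 9.5-ish from center -> inside A2
  one <- photometric_frame(px, thickness_mm = 1, power_mW = 1)
  zo <- zone_illuminance(one, geom)
  expect_equal(zo$E_A2, 200 / zo$area_A2)
  expect_equal(zo$E_A1, 0)
})

test_that("zone sums over the partition equal the brute-force disk sum", {
  set.seed(5)
  px <- matrix(sample(0:255, 80 * 80, replace = TRUE), 80, 80)
  fr <- photometric_frame(px, thickness_mm = 1, power_mW = 1)
  geom <- zone_geometry(c(40.2, 39.7), 6, 15, 24)
  zi <- zone_illuminance(fr, geom)
  total <- zi$E_A1 * zi$area_A1 + zi$E_A2 * zi$area_A2 +
    zi$E_A3 * zi$area_A3
  cls <- bf_classify_pixels(c(40.2, 39.7), 6, 15, 24, c(80, 80))
  expect_equal(total, sum(px[cls != "bg"]))
})

test_that("excluding occluded pixels removes their influence entirely", {
  sm <- spot_model(c(60, 60), 10, 25, 40, 200, 120, 60, background = 0)
  clean <- render_frame(sm, NULL, shape = c(120L, 120L), bit_depth = 8L)
  box <- c(55, 55, 70, 70)   # straddles A1/A2
  occ <- occlusion_spec(list(box), attenuation = 0)
  dark <- render_frame(sm, occ, shape = c(120L, 120L), bit_depth = 8L)
  geom <- zone_geometry(c(60, 60), 10, 25, 40)
  zi_clean_excl <- zone_illuminance(clean, geom, exclude = occ)
  zi_dark_excl <- zone_illuminance(dark, geom, exclude = occ)
  # any pixel value inside the excluded box is irrelevant
  expect_equal(zi_dark_excl[c("E_A1", "E_A2", "E_A3")],
               zi_clean_excl[c("E_A1", "E_A2", "E_A3")])
  # without exclusion the darkened frame reads lower in A1
  expect_lt(zone_illuminance(dark, geom)$E_A1, 200)
  expect_error(zone_illuminance(clean, geom,
                                exclude = occlusion_spec(list(c(0, 0, 120,
                                                                120)),
                                                         attenuation = 0)),
               "zero included")
})

test_that("replicate averaging is the arithmetic mean per condition", {
  base <- data.frame(thickness_mm = 2, power_mW = 4.2, mode = "transmitted",
                     E_A1 = 9, E_A2 = c(1, 2, 3), E_A3 = c(4, 5, 9))
  avg <- average_replicates(base)
  expect_equal(nrow(avg), 1L)
  expect_equal(avg$E_A2, 2)
  expect_equal(avg$E_A3, 6)
  expect_equal(avg$n_frames, 3L)
  expect_error(average_replicates(base[0, ]), "empty")

  # 3 sites x 3 captures of seeded noisy frames: mean equals sum/9
  fm <- table1_model()
  st <- generate_study(fm, thickness_grid = 2, power_grid = 4.2,
                       modes = "transmitted", sites = 3L, captures = 3L,
                       noise_sd = 2, seed = 3L, shape = c(96L, 96L),
                       geometry = list(center_rc = c(48, 48), R1_px = 8,
                                       R2_px = 20, R3_px = 32))
  il <- analyze_frameset(st$frameset,
                         geometry = zone_geometry(c(48, 48), 8, 20, 32))
  expect_equal(nrow(il), 9L)
  avg2 <- average_replicates(il)
  expect_equal(avg2$E_A2, sum(il$E_A2) / 9)
})
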