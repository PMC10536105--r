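test_that("model_illuminance evaluates the published polynomials", {
  fm <- table1_model()
  # hand-computed quadratic: m(4.2) = 757.62 + 1799.9*4.2 - 32.413*4.2^2
  m42 <- 757.62 + 1799.9 * 4.2 - 32.413 * 4.2^2
  expect_equal(model_illuminance(fm, "A2", "transmitted", d = 1e-12, P = 4.2),
               m42 * exp(0), tolerance = 1e-10)
  # degenerate coefficient tables isolate each term
  flat <- data.frame(name = c("m", "n", "a", "b"), ring = "A2",
                     mode = c("transmitted", "transmitted", "reflected",
                              "reflected"),
                     c0 = c(100, 0, 0, 5), c1 = 0, c2 = 0, c3 = NA, c4 = NA,
                     c5 = NA, c6 = NA)
  fm0 <- forward_model(flat)
  expect_equal(model_illuminance(fm0, "A2", "transmitted", d = c(1, 5, 9),
                                 P = 7), rep(100, 3))       # n == 0
  expect_equal(model_illuminance(fm0, "A2", "reflected", d = 1, P = 3), 5)
  expect_error(model_illuminance(fm, "A2", "reflected", d = 0, P = 1), "d")
})

test_that("transmitted illuminance decays in thickness, reflected grows", {
  fm <- table1_model()
  d <- seq(0.8, 10, by = 0.1)
  for (P in reference_power_grid()) {
    for (ring in c("A2", "A3")) {
      et <- model_illuminance(fm, ring, "transmitted", d, P)
      expect_true(all(diff(et) < 0),
                  label = sprintf("ET decreasing, ring %s, P=%g", ring, P))
      er <- model_illuminance(fm, ring, "reflected", d, P)
      expect_true(all(diff(er) > 0),
                  label = sprintf("ER increasing, ring %s, P=%g", ring, P))
    }
  }
})

test_that("render_frame paints exact zone levels without noise", {
  sm <- spot_model(c(60, 60), 10, 25, 40, level_A1 = 200, level_A2 = 120,
                   level_A3 = 60, background = 0, noise_sd = 0)
  fr <- render_frame(sm, shape = c(120L, 120L), bit_depth = 8L)
  cls <- bf_classify_pixels(c(60, 60), 10, 25, 40, c(120, 120))
  expect_true(all(fr$pixels[cls == "A1"] == 200))
  expect_true(all(fr$pixels[cls == "A2"] == 120))
  expect_true(all(fr$pixels[cls == "A3"] == 60))
  expect_true(all(fr$pixels[cls == "bg"] == 0))

  # degenerate: all levels equal the background -> uniform frame
  smu <- spot_model(c(60, 60), 10, 25, 40, 50, 50, 50, background = 50)
  expect_true(all(render_frame(smu, shape = c(120L, 120L),
                               bit_depth = 8L)$pixels == 50))
  # zones must fit inside the frame
  expect_error(render_frame(sm, shape = c(70L, 70L)), "exceeds")
})

test_that("zone means converge to requested levels as noise shrinks", {
  geom <- zone_geometry(c(60, 60), 10, 25, 40)
  for (sd in c(4, 1)) {
    sm <- spot_model(c(60, 60), 10, 25, 40, level_A1 = 2000,
                     level_A2 = 1200, level_A3 = 600, background = 0,
                     noise_sd = sd, seed = 7L)
    fr <- render_frame(sm, shape = c(120L, 120L), bit_depth = 16L)
    zi <- zone_illuminance(fr, geom)
    # mean of |A3| iid draws: tolerance ~4 sd / sqrt(n) plus quantization
    n3 <- zi$area_A3
    expect_lt(abs(zi$E_A3 - 600), 4 * sd / sqrt(n3) + 0.5)
    expect_lt(abs(zi$E_A2 - 1200), 4 * sd / sqrt(zi$area_A2) + 0.5)
  }
})

test_that("occlusion rectangles attenuate only their pixels", {
  sm <- spot_model(c(60, 60), 10, 25, 40, 200, 120, 60, background = 0)
  occ <- occlusion_spec(list(c(55, 40, 65, 80)), attenuation = 0.2)
  fr <- render_frame(sm, occ, shape = c(120L, 120L), bit_depth = 8L)
  fr0 <- render_frame(sm, NULL, shape = c(120L, 120L), bit_depth = 8L)
  inbox <- matrix(FALSE, 120, 120)
  inbox[56:65, 41:80] <- TRUE
  expect_identical(fr$pixels[!inbox], fr0$pixels[!inbox])
  expect_equal(fr$pixels[inbox], round(fr0$pixels[inbox] * 0.2))
})

test_that("generate_study enumerates conditions and is seed-deterministic", {
  fm <- table1_model()
  st <- generate_study(fm, thickness_grid = 2, power_grid = 4.2,
                       sites = 3L, captures = 3L, noise_sd = 1,
                       seed = 11L, shape = c(96L, 96L),
                       geometry = list(center_rc = c(48, 48), R1_px = 8,
                                       R2_px = 20, R3_px = 32))
  expect_length(st$frameset, 18L)  # 1 d x 1 P x 2 modes x 3 x 3
  expect_equal(nrow(st$manifest), 18L)
  st2 <- generate_study(fm, thickness_grid = 2, power_grid = 4.2,
                        sites = 3L, captures = 3L, noise_sd = 1,
                        seed = 11L, shape = c(96L, 96L),
                        geometry = list(center_rc = c(48, 48), R1_px = 8,
                                        R2_px = 20, R3_px = 32))
  for (i in seq_len(18))
    expect_identical(st$frameset$frames[[i]]$pixels,
                     st2$frameset$frames[[i]]$pixels)
  expect_error(generate_study(fm, thickness_grid = numeric(0)), "non-empty")
  expect_error(generate_study(fm, thickness_grid = c(-1, 2)), "positive")
})

test_that("noiseless rendered study reproduces gain-scaled model levels", {
  fm <- table1_model(gain = 4)   # headroom: 16-bit ceiling is 65535
  geom_cfg <- list(center_rc = c(80, 80), R1_px = 10, R2_px = 30, R3_px = 50)
  st <- generate_study(fm, thickness_grid = c(2, 5, 8), power_grid = 4.2,
                       modes = "transmitted", sites = 1L, captures = 1L,
                       noise_sd = 0, shape = c(160L, 160L),
                       geometry = geom_cfg, background = 0)
  geom <- zone_geometry(geom_cfg$center_rc, 10, 30, 50)
  for (fr in st$frameset$frames) {
    zi <- zone_illuminance(fr, geom)
    for (ring in c("A2", "A3")) {
      want <- 4 * model_illuminance(fm, ring, "transmitted",
                                    fr$thickness_mm, fr$power_mW) / 4
      got <- zi[[paste0("E_", ring)]] / 4
      expect_lt(abs(got - want), 0.5 / 4)  # quantization bound on DN
    }
  }
})
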