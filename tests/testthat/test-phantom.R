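# phantom module: geometry, physiology, forward model, calibration vials

test_that("label volume matches a brute-force voxel-center oracle", {
  # independent oracle: enumerate all voxel centers of a 32^3 grid and
  # count those inside the sphere
  g <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
  expected <- sum((g$x - 16)^2 + (g$y - 16)^2 + (g$z - 16)^2 <= 4^2)
  spec <- phantom_spec(c(32, 32, 32), 0.088,
                       list(organ("s", c(16, 16, 16), c(4, 4, 4), c(50, 50),
                                  organ_physiology(0.1))),
                       noise_sd = 0)
  lab <- build_label_volume(spec)
  expect_identical(sum(lab == 1L), expected)
  expect_identical(sum(lab == 1L), 257L)  # frozen from the oracle

  # oracle agreement voxel-by-voxel, not just in count
  inside <- array((g$x - 16)^2 + (g$y - 16)^2 + (g$z - 16)^2 <= 16,
                  c(32, 32, 32))
  expect_identical(unname(lab == 1L), inside)
})

test_that("no organs gives all background; overlap resolved by priority", {
  spec <- phantom_spec(c(8, 8, 8), 0.1, list(), noise_sd = 0)
  expect_true(all(build_label_volume(spec) == 0L))

  two <- phantom_spec(c(16, 16, 16), 0.1,
                      list(organ("a", c(7, 8, 8), c(4, 4, 4), c(0, 0),
                                 organ_physiology(0.1)),
                           organ("b", c(10, 8, 8), c(4, 4, 4), c(0, 0),
                                 organ_physiology(0.2))),
                      noise_sd = 0)
  lab <- build_label_volume(two)
  # voxel (8,8,8) is inside both ellipsoids; 'b' is listed later, so wins
  expect_identical(lab[8, 8, 8], 2L)
  # reversing priorities flips the overlap
  two$organs[[1]]$priority <- 5
  lab2 <- build_label_volume(two)
  expect_identical(lab2[8, 8, 8], 1L)
})

test_that("an organ escaping the grid raises an error naming it", {
  spec <- phantom_spec(c(16, 16, 16), 0.1,
                       list(organ("runaway", c(2, 8, 8), c(4, 4, 4),
                                  c(0, 0), organ_physiology(0.1))),
                       noise_sd = 0)
  expect_error(build_label_volume(spec), "runaway")
})

test_that("physiology maps to concentrations per timepoint", {
  spec <- mouse_phantom_spec(n = 32, noise_sd = 0)
  lab <- build_label_volume(spec)
  tumor <- label_mask(lab, "tumor")
  blood <- label_mask(lab, "blood")
  expect_gt(sum(tumor), 0)

  d3 <- physiology_to_concentrations(lab, spec, "day3_pre")
  # tumor day3 gold: FBV_day3 * 5.3 + 0.7 = 0.13 * 5.3 + 0.7
  expect_equal(unique(d3$gold[tumor]), 0.13 * 5.3 + 0.7)
  expect_equal(unique(d3$gold[tumor]), 1.389)
  expect_true(all(d3$iodine == 0))          # iodine not injected yet

  post <- physiology_to_concentrations(lab, spec, "day3_post")
  expect_equal(unique(post$iodine[blood]), 16.6)   # FBV = 1 in blood
  expect_equal(unique(post$gold[tumor]), 1.389)    # gold unchanged by iodine

  d1 <- physiology_to_concentrations(lab, spec, "day1")
  expect_true(all(d1$iodine == 0))
  expect_equal(unique(d1$gold[tumor]), 0.14 * 9.1)
  expect_true(all(d1$gold >= 0) && all(post$iodine >= 0))
})

test_that("missing physiology for a present label errors", {
  spec <- phantom_spec(c(16, 16, 16), 0.1,
                       list(organ("bare", c(8, 8, 8), c(3, 3, 3), c(0, 0))),
                       noise_sd = 0)
  lab <- build_label_volume(spec)
  expect_error(physiology_to_concentrations(lab, spec, "day1"), "bare")
})

test_that("forward model reproduces the linear attenuation combination", {
  spec <- sphere_spec(n = 16, r = 5, baseline = c(50, 50), noise_sd = 0)
  lab <- build_label_volume(spec)
  inside <- lab == 1L

  zero <- array(0, dim(lab))
  v <- forward_model(zero, zero, lab, spec, ref_m, "day1")
  expect_equal(unique(v$v40[inside]), 50)   # baseline only
  expect_equal(unique(v$v80[inside]), 50)
  expect_equal(unique(v$v40[!inside]), -1000)

  # blood-level gold on zero baseline: 88.5 * 9.1 = 805.35 HU at 40 kVp
  spec0 <- sphere_spec(n = 16, r = 5, baseline = c(0, 0), noise_sd = 0)
  au <- zero; au[inside] <- 9.1
  v <- forward_model(zero, au, lab, spec0, ref_m, "day1")
  expect_equal(unique(v$v40[inside]), 805.35)

  # mixed agents on 50 HU baseline
  io <- zero; io[inside] <- 16.6
  au[inside] <- 5.3
  v <- forward_model(io, au, lab, spec, ref_m, "day3_post")
  expect_equal(unique(v$v40[inside]), 995.47)
  expect_equal(unique(v$v80[inside]), 1068.80)
})

test_that("noiseless HU is strictly monotone in each concentration", {
  spec <- sphere_spec(n = 12, r = 3, noise_sd = 0)
  lab <- build_label_volume(spec)
  zero <- array(0, dim(lab))
  base <- forward_model(zero, zero, lab, spec, ref_m, "day1")
  for (dc in c(0.1, 1, 5)) {
    io <- zero; io[lab == 1L] <- dc
    v <- forward_model(io, zero, lab, spec, ref_m, "day1")
    expect_true(all(v$v40[lab == 1L] > base$v40[lab == 1L]))
    expect_true(all(v$v80[lab == 1L] > base$v80[lab == 1L]))
    v <- forward_model(zero, io, lab, spec, ref_m, "day1")
    expect_true(all(v$v40[lab == 1L] > base$v40[lab == 1L]))
    expect_true(all(v$v80[lab == 1L] > base$v80[lab == 1L]))
  }
})

test_that("volumes are deterministic given spec + seed, and scans differ", {
  spec <- sphere_spec(n = 16, noise_sd = 20, seed = 42)
  lab <- build_label_volume(spec)
  conc <- physiology_to_concentrations(lab, spec, "day1")
  a <- forward_model(conc$iodine, conc$gold, lab, spec, ref_m, "day1")
  b <- forward_model(conc$iodine, conc$gold, lab, spec, ref_m, "day1")
  expect_identical(a, b)                       # bit-identical
  c2 <- forward_model(conc$iodine, conc$gold, lab, spec, ref_m, "day3_pre")
  expect_false(identical(a$v40, c2$v40))       # independent noise per scan
})

test_that("noise sd inside a flat region is calibrated", {
  spec <- sphere_spec(n = 48, r = 20, noise_sd = 20, seed = 7)
  lab <- build_label_volume(spec)
  zero <- array(0, dim(lab))
  v <- forward_model(zero, zero, lab, spec, ref_m, "day1")
  flat <- lab == 1L
  expect_gt(sum(flat), 1e4)
  expect_lt(abs(sd(v$v40[flat]) - 20) / 20, 0.05)
  expect_lt(abs(sd(v$v80[flat]) - 20) / 20, 0.05)
})

test_that("per-voxel conservation holds at every timepoint", {
  spec <- mouse_phantom_spec(n = 32, noise_sd = 0)
  lab <- build_label_volume(spec)
  blood <- spec$blood
  for (tp in c("day1", "day3_pre", "day3_post")) {
    conc <- physiology_to_concentrations(lab, spec, tp)
    for (l in spec$labels) {
      p <- spec$physiology[[l]]
      mask <- label_mask(lab, l)
      expected <- if (tp == "day1") p$fbv_day1 * blood$c_au_day1
                  else p$fbv_day3 * blood$c_au_day3 + p$c_au_accum_day3
      expect_equal(unique(conc$gold[mask]), expected,
                   info = paste(tp, l))
    }
  }
})

test_that("misregistration and bias field perturb only what they should", {
  spec <- sphere_spec(n = 16, r = 5, noise_sd = 0)
  lab <- build_label_volume(spec)
  conc <- physiology_to_concentrations(lab, spec, "day1")
  clean <- forward_model(conc$iodine, conc$gold, lab, spec, ref_m, "day1")

  spec$misregistration <- c(0.4, 0, 0)
  mis <- forward_model(conc$iodine, conc$gold, lab, spec, ref_m, "day1")
  expect_identical(as.vector(mis$v40), as.vector(clean$v40))
  expect_false(identical(as.vector(mis$v80), as.vector(clean$v80)))

  spec$misregistration <- NULL
  spec$bias_amplitude <- 0.1
  bia <- forward_model(conc$iodine, conc$gold, lab, spec, ref_m, "day1")
  # background has zero contrast: bias must not touch it
  expect_equal(bia$v40[lab == 0L], clean$v40[lab == 0L])
  expect_false(isTRUE(all.equal(bia$v40[lab == 1L], clean$v40[lab == 1L])))
})

test_that("calibration vials follow the linear model and the seed contract", {
  v <- make_calibration_phantom(list(c(0, 0), c(1, 0), c(0, 1), c(2, 3)),
                                ref_m, noise_sd = 0)
  expect_equal(v$hu40, c(0, 28.7, 88.5, 322.9))
  expect_equal(v$hu80, c(0, 42.6, 58.8, 261.6))

  expect_identical(nrow(make_calibration_phantom(list())), 0L)

  a <- make_calibration_phantom(list(c(1, 1)), ref_m, noise_sd = 5, seed = 3)
  b <- make_calibration_phantom(list(c(1, 1)), ref_m, noise_sd = 5, seed = 3)
  expect_identical(a, b)
})

test_that("spec validation rejects malformed phantoms", {
  expect_error(phantom_spec(c(4, 8, 8), 0.1, list()), "at least 8")
  expect_error(phantom_spec(c(8, 8, 8), 0, list()), "voxel")
  expect_error(phantom_spec(c(8, 8, 8), 0.1, list(), noise_sd = -1), ">= 0")
  expect_error(
    phantom_spec(c(16, 16, 16), 0.1,
                 list(organ("x", c(8, 8, 8), c(2, 2, 2), c(0, 0),
                            organ_physiology(0.1)),
                      organ("x", c(8, 8, 8), c(2, 2, 2), c(0, 0),
                            organ_physiology(0.9)))),
    "different physiology")
  expect_error(organ_physiology(1.2), "fbv")
})
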