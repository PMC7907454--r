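test_that("technological yield follows the cooking-loss formula", {
  expect_equal(technological_yield(600, 500, 20), 20.0)
  expect_equal(technological_yield(500, 500, 0), 0.0)
  expect_equal(technological_yield(600, 580, 580), 100.0)
  expect_error(technological_yield(0, 0, 0), "positive")
  expect_error(technological_yield(600, 10, 20), "melted")
  expect_error(technological_yield(500, 700, 20), "cooked")
})

test_that("simulated cohorts respect the configured design", {
  cc <- cohort_config(seed = 7)
  cohort <- simulate_cohort(cc)
  phen <- cohort$phenotypes
  expect_equal(nrow(phen), 65)
  expect_equal(as.vector(table(phen$day)), c(16, 16, 16, 17))
  expect_true(all(phen$lw >= 302.3 & phen$lw <= 914.9))
  expect_true(all(phen$ty >= 54.8 & phen$ty <= 99.5))
  # liver weight grows along the overfeeding period in expectation
  day_means <- tapply(phen$lw, phen$day, mean)
  expect_true(all(diff(day_means) > 0))
  # square config from the worked example: 4 x 16 animals
  cc64 <- cohort_config(n_per_timepoint = 16, seed = 7)
  expect_equal(nrow(simulate_cohort(cc64)$phenotypes), 64)
})

test_that("cohort generation is bit-reproducible given the seed", {
  a <- simulate_cohort(cohort_config(seed = 42))
  b <- simulate_cohort(cohort_config(seed = 42))
  expect_identical(a, b)
  c <- simulate_cohort(cohort_config(seed = 43))
  expect_false(identical(a$phenotypes$lw, c$phenotypes$lw))
})

test_that("LW-TY correlation is planted at the target level", {
  for (target in c(-0.82, -0.6)) {
    cors <- vapply(1:60, function(s) {
      phen <- simulate_cohort(
        cohort_config(target_lw_ty_correlation = target,
                      seed = s))$phenotypes
      cor(phen$lw, phen$ty)
    }, numeric(1))
    expect_lt(abs(mean(cors) - target), 0.05)
  }
})

test_that("null configuration produces no concentration-trait correlation", {
  eff <- default_effect_table()
  eff$effect <- 0; eff$sign <- 0; eff$baseline <- 10
  cors <- vapply(1:100, function(s) {
    cohort <- simulate_cohort(
      cohort_config(effect_table = eff, target_lw_ty_correlation = 0,
                    seed = s))
    cor(cohort$ground_truth$concentrations[, "lactate"],
        cohort$phenotypes$lw)
  }, numeric(1))
  # mean correlation within 3 Monte-Carlo SE of zero
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(length(cors)))
})

test_that("planted signs are recovered across seeded replicates", {
  hits <- vapply(1:60, function(s) {
    cohort <- simulate_cohort(cohort_config(seed = s))
    conc <- cohort$ground_truth$concentrations
    lw <- cohort$phenotypes$lw
    cor(conc[, "lactate"], lw) > 0 && cor(conc[, "alanine"], lw) < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("implausible effect sizes are rejected", {
  eff <- default_effect_table()
  eff$baseline <- 0.01    # almost everything truncates at zero
  expect_error(simulate_cohort(cohort_config(effect_table = eff, seed = 1)),
               "truncated")
})

test_that("synthetic spectra weight multiplet areas by proton counts", {
  lib <- lactate_library()
  sp <- synthesize_spectrum(c(lactate = 1), lib, seed = 1,
                            ppm = test_grid())
  ratio <- integrate_window(sp, 1.26, 1.37) /
    integrate_window(sp, 4.03, 4.17)
  expect_equal(ratio, 3, tolerance = 0.005)   # 3H doublet vs 1H quartet
})

test_that("zero concentrations leave only the instrumental artifacts", {
  lib <- tiny_library()
  sp <- synthesize_spectrum(c(metA = 0, metB = 0), lib, seed = 1,
                            ppm = test_grid())
  # TSP, water hump and methanol are present...
  expect_gt(integrate_window(sp, -0.05, 0.05), 0)
  expect_gt(integrate_window(sp, 4.5, 5.1), 0)
  expect_gt(integrate_window(sp, 3.33, 3.38), 0)
  # ...but the metabolite regions are empty
  expect_equal(integrate_window(sp, 0.9, 1.1), 0, tolerance = 1e-8)
  expect_equal(integrate_window(sp, 1.9, 2.1), 0, tolerance = 1e-8)
})

test_that("spectra are linear and monotone in concentration", {
  lib <- tiny_library()
  grid <- test_grid()
  base <- synthesize_spectrum(c(metA = 0, metB = 0), lib, seed = 1,
                              ppm = grid)
  s1 <- synthesize_spectrum(c(metA = 1, metB = 0.5), lib, seed = 1,
                            ppm = grid)
  s2 <- synthesize_spectrum(c(metA = 2, metB = 1), lib, seed = 1,
                            ppm = grid)
  contrib1 <- s1$intensity - base$intensity
  contrib2 <- s2$intensity - base$intensity
  expect_equal(contrib2, 2 * contrib1, tolerance = 1e-12)
  # apex intensity strictly increasing in concentration
  apex <- which.min(abs(grid - 1.0))
  heights <- vapply(c(0.5, 1, 2, 4), function(cc) {
    synthesize_spectrum(c(metA = cc, metB = 0), lib, seed = 1,
                        ppm = grid)$intensity[apex]
  }, numeric(1))
  expect_true(all(diff(heights) > 0))
})

test_that("noiseless spectrum integrals conserve proton mass", {
  lib <- tiny_library()
  conc <- c(metA = 2, metB = 3)
  sp <- synthesize_spectrum(conc, lib, seed = 1, ppm = test_grid())
  artifacts <- synthesize_spectrum(c(metA = 0, metB = 0), lib, seed = 1,
                                   ppm = test_grid())
  expected <- 2 * 2 + 3 * 4   # conc_j x total protons of j
  got <- gavageNMR:::spectrum_integral(sp) -
    gavageNMR:::spectrum_integral(artifacts)
  expect_equal(got, expected, tolerance = 1e-3)  # < 0.1 % quadrature error
})

test_that("spectrum synthesis is deterministic and validates inputs", {
  lib <- tiny_library()
  a <- synthesize_spectrum(c(1, 1), lib, noise_sd = 5,
                           shift_jitter_sd = 0.003, seed = 9,
                           ppm = test_grid())
  b <- synthesize_spectrum(c(1, 1), lib, noise_sd = 5,
                           shift_jitter_sd = 0.003, seed = 9,
                           ppm = test_grid())
  expect_identical(a$intensity, b$intensity)
  expect_error(
    synthesize_spectrum(c(1, 1), lib, ppm = default_ppm_grid(span = c(2.5, 10.5))),
    "cover")
  expect_error(fingerprint_library(list()), "length")
})

test_that("spectrum files round-trip through the TSV dialect", {
  lib <- tiny_library()
  sp <- synthesize_spectrum(c(1, 2), lib, noise_sd = 1, seed = 3,
                            ppm = default_ppm_grid(n = 2048),
                            sample_id = "S007")
  path <- tempfile(fileext = ".tsv")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_equal(back$sample_id, "S007")
  expect_equal(back$ppm, sp$ppm)
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-12)
})
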