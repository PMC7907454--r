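test_that("deconvolution recovers single metabolites and mixture ratios", {
  lib <- tiny_library()
  grid <- test_grid()
  # pure single metabolite: exactly one nonzero coefficient
  spA <- synthesize_spectrum(c(metA = 1.5, metB = 0), lib, seed = 1,
                             ppm = grid, artifacts = FALSE)
  qA <- quantify_by_fingerprint(spA, lib)
  expect_gt(qA["metA"], 0)
  expect_equal(unname(qA["metB"]), 0, tolerance = 1e-10)
  # disjoint-peak mixture at 2:1 recovers the ratio
  sp <- synthesize_spectrum(c(metA = 2, metB = 1), lib, seed = 1,
                            ppm = grid, artifacts = FALSE)
  q <- quantify_by_fingerprint(sp, lib)
  expect_equal(unname(q["metA"] / q["metB"]), 2, tolerance = 1e-6)
  # with instrumental artifacts present the crosstalk stays tiny
  spArt <- synthesize_spectrum(c(metA = 1.5, metB = 0), lib, seed = 1,
                               ppm = grid)
  qArt <- quantify_by_fingerprint(spArt, lib)
  expect_lt(qArt["metB"] / qArt["metA"], 1e-3)
})

test_that("cohort deconvolution tracks ground-truth concentrations", {
  lib <- tiny_library()
  grid <- test_grid()
  set.seed(31)
  conc <- matrix(runif(2 * 20, 0.5, 3), 20, 2,
                 dimnames = list(sprintf("S%02d", 1:20), c("metA", "metB")))
  sps <- synthesize_cohort_spectra(conc, lib, noise_sd = 2,
                                   shift_jitter_sd = 0, seed = 17,
                                   ppm = grid)
  est <- quantify_cohort(sps, lib)
  expect_true(all(est >= 0))
  for (m in colnames(conc))
    expect_gt(cor(est[, m], conc[, m]), 0.9)
})

test_that("presence filter applies the within-day 50% rule", {
  phen <- data.frame(animal_id = sprintf("S%02d", 1:32),
                     day = rep(c(6, 8), each = 16))
  tab <- matrix(0, 32, 3,
                dimnames = list(phen$animal_id, c("kept", "dropped", "all")))
  tab[1:9, "kept"] <- 1          # 9/16 at day 6 -> kept
  tab[c(1:7, 17:23), "dropped"] <- 1   # 7/16 at both days -> dropped
  tab[, "all"] <- 1
  out <- presence_filter(tab, phen)
  expect_equal(colnames(out), c("kept", "all"))
  # all-positive table passes unchanged
  expect_equal(presence_filter(tab[, "all", drop = FALSE], phen),
               tab[, "all", drop = FALSE])
  bad <- tab; rownames(bad)[1] <- "unknown"
  expect_error(presence_filter(bad, phen), "unknown sample")
})

test_that("bucket mapping uses interval overlap and grows with tolerance", {
  g <- bucket_grid()
  labels <- g$center[g$retained]
  lib <- default_fingerprint_library()
  mapping <- map_buckets_to_metabolites(labels, lib)
  lact <- mapping[["lactate"]]
  expect_equal(sort(labels[lact$peak_buckets[[1]]]),
               c(1.305, 1.315, 1.325))
  # a peak inside the water exclusion maps to nothing and is flagged
  wet <- fingerprint_library(list(
    list(name = "wet", peaks = list(list(low = 4.7, high = 4.8,
                                         multiplicity = "singlet",
                                         protons = 1)))))
  wm <- map_buckets_to_metabolites(labels, wet)
  expect_true(wm[["wet"]]$unmapped[1])
  # widening the tolerance never shrinks a mapping
  wider <- map_buckets_to_metabolites(labels, lib, tolerance = 0.01)
  for (m in names(mapping))
    for (i in seq_along(mapping[[m]]$peak_buckets))
      expect_true(all(mapping[[m]]$peak_buckets[[i]] %in%
                        wider[[m]]$peak_buckets[[i]]))
})

test_that("relative concentration follows the per-proton mean formula", {
  lib2 <- fingerprint_library(list(
    list(name = "two", peaks = list(
      list(low = 1.0, high = 1.01, multiplicity = "doublet", protons = 3),
      list(low = 2.0, high = 2.01, multiplicity = "quartet", protons = 1)))))
  labels <- c(2.005, 1.005)
  mapping <- map_buckets_to_metabolites(labels, lib2)
  m <- mapping[["two"]]
  # doublet buckets sum 0.006 over 3H, quartet sums 0.002 over 1H
  row <- c(0.002, 0.006)
  names(row) <- sprintf("%.3f", labels)
  rc <- relative_concentration(row, lib2$metabolites[["two"]], m)
  expect_equal(rc, mean(c(0.006 / 3, 0.002 / 1)))
  # one-peak metabolite: peak sum / proton count
  one <- fingerprint_library(list(
    list(name = "one", peaks = list(
      list(low = 1.0, high = 1.01, multiplicity = "singlet",
           protons = 2)))))
  mo <- map_buckets_to_metabolites(labels, one)
  expect_equal(relative_concentration(row, one$metabolites[["one"]],
                                      mo[["one"]]),
               0.006 / 2)
  # unmapped peaks are skipped; fully unmapped is an error
  skip_lib <- fingerprint_library(list(
    list(name = "skip", peaks = list(
      list(low = 1.0, high = 1.01, multiplicity = "singlet", protons = 2),
      list(low = 8.0, high = 8.01, multiplicity = "singlet",
           protons = 1)))))
  ms <- map_buckets_to_metabolites(labels, skip_lib)
  expect_true(ms[["skip"]]$unmapped[2])
  expect_equal(relative_concentration(row, skip_lib$metabolites[["skip"]],
                                      ms[["skip"]]), 0.006 / 2)
  far <- fingerprint_library(list(
    list(name = "far", peaks = list(
      list(low = 9.0, high = 9.01, multiplicity = "singlet",
           protons = 1)))))
  mf <- map_buckets_to_metabolites(labels, far)
  expect_error(relative_concentration(row, far$metabolites[["far"]],
                                      mf[["far"]]), "unmapped")
})

test_that("RC is invariant to the spectrum's overall scale", {
  lib <- tiny_library()
  grid <- test_grid()
  g <- bucket_grid()
  sp <- synthesize_spectrum(c(1, 2), lib, seed = 2, ppm = grid)
  sp10 <- nmr_spectrum(grid, sp$intensity * 10)
  bt <- normalize_buckets(rbind(S1 = bucketize(sp, g),
                                S2 = bucketize(sp10, g)))
  rc <- rc_table(bt, lib)
  expect_equal(rc["S1", ], rc["S2", ], tolerance = 1e-10)
})

test_that("bucket-RC and deconvolution rank noiseless samples identically", {
  lib <- tiny_library()
  grid <- test_grid()
  g <- bucket_grid()
  concs <- c(0.5, 1, 2, 3.5, 5)
  sps <- lapply(seq_along(concs), function(i) {
    synthesize_spectrum(c(metA = concs[i], metB = 0), lib, seed = 1,
                        ppm = grid, sample_id = paste0("S", i))
  })
  bt <- normalize_buckets(bucketize_spectra(sps, g))
  rc <- rc_table(bt, lib, metabolites = "metA")
  q <- quantify_cohort(sps, lib)[, "metA"]
  expect_equal(cor(rc[, "metA"], q, method = "spearman"), 1)
})
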