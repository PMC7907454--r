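# Shared fixtures and independent oracles for the test suite.

# A tiny fingerprint library with well-separated peaks; fast to render.
tiny_library <- function() {
  fingerprint_library(list(
    list(name = "metA", hmdb_id = "HMDB_TEST_A",
         peaks = list(list(low = 1.00, high = 1.00,
                           multiplicity = "singlet", protons = 2))),
    list(name = "metB", hmdb_id = "HMDB_TEST_B",
         peaks = list(list(low = 2.00, high = 2.01,
                           multiplicity = "doublet", protons = 3),
                      list(low = 3.00, high = 3.04,
                           multiplicity = "quartet", protons = 1)))
  ))
}

# Lactate-only library matching the shipped doublet/quartet definition.
lactate_library <- function() {
  fingerprint_library(list(
    list(name = "lactate", hmdb_id = "HMDB0000190",
         peaks = list(list(low = 1.31, high = 1.32,
                           multiplicity = "doublet", protons = 3),
                      list(low = 4.08, high = 4.12,
                           multiplicity = "quartet", protons = 1)))
  ))
}

# Medium-resolution grid for tests that do not need the full 2^15 points.
test_grid <- function() default_ppm_grid(n = 2^14)

# Integrate a spectrum over a ppm window (ascending internally).
integrate_window <- function(spectrum, low, high) {
  pa <- rev(spectrum$ppm); ia <- rev(spectrum$intensity)
  sel <- pa >= low & pa <= high
  pracma::trapz(pa[sel], ia[sel])
}

# Brute-force Benjamini-Hochberg step-up: adj_(i) over the sorted p-values
# is min_{j >= i} p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    cand <- sorted[i:m] * m / (i:m)
    adj[ord[i]] <- min(1, min(cand))
  }
  adj
}

# Independent single-component PLS oracle: covariance weights computed by
# explicit loops, scores by explicit sums, prediction via lm().
pls1_oracle <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  yc <- y - mean(y)
  w <- numeric(p)
  for (j in seq_len(p)) w[j] <- sum(X[, j] * yc)
  w <- w / sqrt(sum(w^2))
  t <- numeric(n)
  for (i in seq_len(n)) t[i] <- sum(X[i, ] * w)
  fit <- stats::lm(y ~ t)
  pl <- numeric(p)
  for (j in seq_len(p)) pl[j] <- sum(X[, j] * t) / sum(t^2)
  list(w = w, t = t, p = pl,
       q = unname(coef(fit)[2]),
       r2y = summary(fit)$r.squared)
}

# Cohort config with a sparse planted set used by parameter-recovery tests:
# six biomarkers at a uniform |effect| (lactate trait-positive, five amino
# acids trait-negative), every other library metabolite null.
recovery_cohort_config <- function(seed, effect = 1.0) {
  eff <- default_effect_table()
  planted <- c(lactate = 1, alanine = -1, glutamine = -1, glycine = -1,
               proline = -1, serine = -1)
  eff$effect <- 0
  eff$sign <- 0
  idx <- match(names(planted), eff$metabolite)
  eff$effect[idx] <- effect
  eff$sign[idx] <- unname(planted)
  eff$baseline <- 10 + 4 * eff$effect
  cohort_config(effect_table = eff, seed = seed)
}

# Run the metabolite (deconvolution) selection route on one synthetic
# cohort and return the selection table plus ground truth.
run_metabolite_selection <- function(seed, effect = 1.0) {
  cc <- recovery_cohort_config(seed, effect)
  cohort <- simulate_cohort(cc)
  lib <- default_fingerprint_library()
  conc <- cohort$ground_truth$concentrations
  spectra <- synthesize_cohort_spectra(conc[, names(lib$metabolites)], lib,
                                       noise_sd = 10,
                                       shift_jitter_sd = 0.003,
                                       seed = seed * 1000)
  spectra <- lapply(spectra, calibrate_to_tsp)
  conc_hat <- quantify_cohort(spectra, lib)
  conc_hat <- presence_filter(conc_hat, cohort$phenotypes)
  Xs <- suppressWarnings(pareto_scale(conc_hat))
  model <- fit_pls(Xs, cohort$phenotypes$lw)
  uni <- univariate_bh(conc_hat, cohort$phenotypes$lw)
  evidence <- data.frame(metabolite = model$variable_names,
                         vip = unname(model$vip),
                         stringsAsFactors = FALSE)
  evidence$p_bh <- uni$p_bh[match(evidence$metabolite, uni$variable)]
  sel <- select_biomarkers(evidence, "metabolite")
  list(selection = sel,
       planted = cohort$ground_truth$planted_biomarkers$lw$metabolite,
       all = names(lib$metabolites))
}
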