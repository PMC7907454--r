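#' Pipeline run configuration
#'
#' Bundles every stage parameter. The defaults reproduce the analysis
#' settings this pipeline mirrors: 0.01 ppm buckets over 0.5--10 ppm with
#' water (4.5--5.1) and methanol (3.33--3.38) exclusions, 50% within-day
#' presence filtering, Pareto scaling, single-component PLS, 7-fold
#' cross-validation, 500 permutations, VIP > 1 importance, BH significance
#' at 0.05 with a tendency band to 0.10.
#'
#' @param cohort a [cohort_config()] for the synthetic cohort stage.
#' @param spectrum_noise_sd,shift_jitter_sd spectrum forging parameters.
#' @param grid a [bucket_grid()].
#' @param folds,permutations,vip_threshold,significant,tendency,
#'   network_threshold,presence_min_fraction analysis constants.
#' @param seed master integer seed; stage seeds are derived from it.
#' @param outdir optional output directory; when set, stage outputs and
#'   `report.json` are written there.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       spectrum_noise_sd = 10,
                       shift_jitter_sd = 0.003,
                       grid = bucket_grid(),
                       folds = 7,
                       permutations = 500,
                       vip_threshold = 1.0,
                       significant = 0.05,
                       tendency = 0.10,
                       network_threshold = 0.3,
                       presence_min_fraction = 0.5,
                       seed = 1L,
                       outdir = NULL) {
  stopifnot(folds >= 2, permutations >= 0, vip_threshold > 0,
            significant < tendency)
  structure(list(cohort = cohort, spectrum_noise_sd = spectrum_noise_sd,
                 shift_jitter_sd = shift_jitter_sd, grid = grid,
                 folds = folds, permutations = permutations,
                 vip_threshold = vip_threshold, significant = significant,
                 tendency = tendency,
                 network_threshold = network_threshold,
                 presence_min_fraction = presence_min_fraction,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

# Evidence + selection for one trait with the metabolite (deconvolution)
# method: PLS on the quantified concentration table, VIP > threshold
# candidacy, univariate BH over the whole table.
select_metabolite_method <- function(conc, trait, config, cv_seed) {
  Xs <- suppressWarnings(pareto_scale(conc))
  model <- fit_pls(Xs, trait)
  cv <- q2_cross_validate(Xs, trait, k = config$folds, seed = cv_seed)
  model$q2 <- cv$q2
  uni <- univariate_bh(conc, trait)
  evidence <- data.frame(metabolite = model$variable_names,
                         vip = unname(model$vip),
                         stringsAsFactors = FALSE)
  evidence$p_bh <- uni$p_bh[match(evidence$metabolite, uni$variable)]
  sel <- select_biomarkers(evidence, "metabolite", config$vip_threshold,
                           config$significant, config$tendency)
  list(model = model, cv = cv, univariate = uni, selection = sel)
}

# Evidence + selection for one trait with the bucket method: PLS on the
# normalized bucket table, a metabolite is a candidate when >= 1 of its
# mapped buckets has VIP > threshold, then its RC regression decides.
select_bucket_method <- function(bucket_tab, library, trait, config,
                                 cv_seed) {
  Xs <- suppressWarnings(pareto_scale(bucket_tab$normalized))
  model <- fit_pls(Xs, trait)
  cv <- q2_cross_validate(Xs, trait, k = config$folds, seed = cv_seed)
  model$q2 <- cv$q2
  mapping <- map_buckets_to_metabolites(bucket_tab$bucket_labels, library,
                                        interval = config$grid$interval)
  important <- model$vip > config$vip_threshold
  vip_idx <- match(model$variable_names,
                   sprintf("%.3f", bucket_tab$bucket_labels))
  n_imp <- vapply(mapping, function(m) {
    sum(vapply(m$peak_buckets, function(idx) {
      sum(important[match(idx, vip_idx)], na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  evidence <- data.frame(metabolite = names(mapping),
                         n_important_buckets = as.integer(n_imp),
                         stringsAsFactors = FALSE)
  candidates <- evidence$metabolite[evidence$n_important_buckets >= 1]
  if (length(candidates) == 0) {
    evidence$p_bh <- NA_real_
    sel <- evidence
    sel$method <- "bucket"; sel$candidate <- FALSE
    sel$class <- "rejected"; sel$selected <- FALSE
    return(list(model = model, cv = cv, rc = NULL, univariate = NULL,
                selection = sel))
  }
  rc <- suppressWarnings(rc_table(bucket_tab, library,
                                  metabolites = candidates))
  uni <- univariate_bh(rc, trait)
  evidence$p_bh <- uni$p_bh[match(evidence$metabolite, uni$variable)]
  evidence$p_bh[is.na(evidence$p_bh) &
                  evidence$n_important_buckets >= 1] <- 1
  evidence$p_bh[is.na(evidence$p_bh)] <- 1
  sel <- select_biomarkers(evidence, "bucket", config$vip_threshold,
                           config$significant, config$tendency)
  list(model = model, cv = cv, rc = rc, univariate = uni, selection = sel)
}

model_stats <- function(res, config, perm) {
  list(r2x = res$model$r2x, r2y = res$model$r2y, q2 = res$cv$q2,
       rmsee = rmsee(res$model), rmsecv = res$cv$rmsecv,
       n_vip_gt_1 = sum(res$model$vip > config$vip_threshold),
       validation = if (is.null(perm)) "unvalidated"
                    else if (perm$valid) "valid" else "not valid",
       q2_intercept = if (is.null(perm)) NULL else perm$q2_intercept)
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes simulate -> forge spectra -> calibrate/align -> bucket ->
#' quantify -> PLS (+ permutation validation) -> select -> Venn -> network
#' for both traits (LW, TY) and both methods (bucket, metabolite) on a
#' synthetic cohort, and assembles a run report. With `permutations = 0`
#' the models are marked `"unvalidated"`. Every random draw derives from
#' the seeds in the configuration, so a rerun reproduces the report
#' exactly.
#'
#' @param config a [run_config()].
#' @param library a [fingerprint_library()]; the shipped default by
#'   default.
#' @return an object of class `run_report` (also written to
#'   `config$outdir/report.json` when an output directory is configured).
#' @export
run_pipeline <- function(config = run_config(),
                         library = default_fingerprint_library()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  cohort <- simulate_cohort(config$cohort)
  phen <- cohort$phenotypes
  conc_true <- cohort$ground_truth$concentrations
  lib_order <- names(library$metabolites)
  if (!all(colnames(conc_true) %in% lib_order))
    stop("cohort effect table contains metabolites missing from library")
  conc_in <- matrix(0, nrow(conc_true), length(lib_order),
                    dimnames = list(rownames(conc_true), lib_order))
  conc_in[, colnames(conc_true)] <- conc_true

  spectra <- synthesize_cohort_spectra(conc_in, library,
                                       noise_sd = config$spectrum_noise_sd,
                                       shift_jitter_sd =
                                         config$shift_jitter_sd,
                                       seed = seed * 1000L)
  spectra <- lapply(spectra, calibrate_to_tsp)
  spectra <- align_spectra(spectra)

  raw <- bucketize_spectra(spectra, config$grid)
  bucket_tab <- normalize_buckets(raw)

  conc_hat <- quantify_cohort(spectra, library,
                              span = config$grid$span,
                              exclusions = config$grid$exclusions)
  conc_hat <- presence_filter(conc_hat, phen,
                              min_fraction = config$presence_min_fraction)

  traits <- list(lw = phen$lw, ty = phen$ty)
  models <- list(); selections <- list(); perms <- list()
  i <- 0
  for (trait_name in names(traits)) {
    y <- traits[[trait_name]]
    for (method in c("bucket", "metabolite")) {
      i <- i + 1
      res <- if (method == "bucket")
        select_bucket_method(bucket_tab, library, y, config,
                             cv_seed = seed + 10L * i)
      else
        select_metabolite_method(conc_hat, y, config,
                                 cv_seed = seed + 10L * i)
      key <- paste(trait_name, method, sep = "_")
      perm <- NULL
      if (config$permutations > 0) {
        Xp <- if (method == "bucket") bucket_tab$normalized else conc_hat
        perm <- permutation_validate(suppressWarnings(pareto_scale(Xp)), y,
                                     n_permutations = config$permutations,
                                     seed = seed + 100L * i,
                                     k = config$folds)
      }
      models[[key]] <- model_stats(res, config, perm)
      selections[[key]] <- res$selection
      perms[[key]] <- perm
      if (method == "bucket") attr(selections[[key]], "rc") <- res$rc
    }
  }

  venns <- list(); networks <- list(); biomarkers <- list()
  for (trait_name in names(traits)) {
    bsel <- selections[[paste0(trait_name, "_bucket")]]
    msel <- selections[[paste0(trait_name, "_metabolite")]]
    v <- venn_compare(bsel$metabolite[bsel$selected],
                      msel$metabolite[msel$selected])
    venns[[trait_name]] <- v
    union_sel <- union(bsel$metabolite[bsel$selected],
                       msel$metabolite[msel$selected])
    biomarkers[[trait_name]] <- union_sel
    if (length(union_sel) >= 1) {
      rc_all <- suppressWarnings(rc_table(bucket_tab, library,
                                          metabolites = union_sel))
      keep <- apply(rc_all, 2, stats::sd) > 0
      if (any(keep))
        networks[[trait_name]] <- correlation_network(
          rc_all[, keep, drop = FALSE], traits[[trait_name]],
          threshold = config$network_threshold,
          trait_name = toupper(trait_name))
    }
  }

  report <- structure(list(
    schema_version = "1.0",
    seed = seed,
    n_samples = nrow(phen),
    lw_ty_correlation = stats::cor(phen$lw, phen$ty),
    n_buckets = ncol(bucket_tab$raw),
    n_quantified = ncol(conc_hat),
    models = models,
    biomarkers = biomarkers,
    venn = lapply(venns, function(v) as.list(v$counts)),
    phenotypes = phen,
    bucket_table = bucket_tab,
    concentrations = conc_hat,
    selections = selections,
    networks = networks,
    ground_truth = cohort$ground_truth),
    class = "run_report")

  if (!is.null(config$outdir)) write_run_outputs(report, config)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "Pipeline run (seed %d): %d samples, %d buckets, %d quantified metabolites\n",
    x$seed, x$n_samples, x$n_buckets, x$n_quantified))
  cat(sprintf("  corr(LW, TY) = %.3f\n", x$lw_ty_correlation))
  for (key in names(x$models)) {
    m <- x$models[[key]]
    cat(sprintf("  %-14s R2X %.3f R2Y %.3f Q2 %6.3f  %s\n", key,
                m$r2x, m$r2y, m$q2, m$validation))
  }
  for (tn in names(x$biomarkers))
    cat(sprintf("  %s biomarkers: %s\n", toupper(tn),
                paste(x$biomarkers[[tn]], collapse = ", ")))
  invisible(x)
}

write_run_outputs <- function(report, config) {
  dir <- config$outdir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  write_bucket_table(report$bucket_table, dir)
  utils::write.csv(data.frame(sample_id = rownames(report$concentrations),
                              report$concentrations, check.names = FALSE),
                   file.path(dir, "metabolite_concentrations.csv"),
                   row.names = FALSE)
  for (key in names(report$selections))
    utils::write.csv(report$selections[[key]],
                     file.path(dir, sprintf("biomarkers_%s.csv", key)),
                     row.names = FALSE)
  for (tn in names(report$networks))
    utils::write.csv(report$networks[[tn]]$edges,
                     file.path(dir, sprintf("network_%s.csv", tn)),
                     row.names = FALSE)
  # PCA score export (outlier screening is visual; no automatic exclusion)
  pc <- stats::prcomp(report$bucket_table$normalized, rank. = 2)
  utils::write.csv(data.frame(sample_id = report$bucket_table$sample_ids,
                              pc$x),
                   file.path(dir, "pca_scores.csv"), row.names = FALSE)
  slim <- report[c("schema_version", "seed", "n_samples",
                   "lw_ty_correlation", "n_buckets", "n_quantified",
                   "models", "biomarkers", "venn")]
  jsonlite::write_json(slim, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
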