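#' Cooking technological yield
#'
#' TY is the percentage of crude liver mass retained through cooking once the
#' visibly melted lipids are credited back:
#' `TY (%) = (crude - (cooked - melted)) * 100 / crude`.
#'
#' @param crude_g crude (raw) liver weight, g. Must be positive.
#' @param cooked_g cooked liver weight, g.
#' @param melted_g visible melted lipids, g.
#' @return technological yield in percent; in `[0, 100]` whenever
#'   `0 <= melted_g <= cooked_g <= crude_g + melted_g`.
#' @examples
#' technological_yield(600, 500, 20) # 20
#' @export
technological_yield <- function(crude_g, cooked_g, melted_g) {
  if (any(crude_g <= 0)) stop("crude weight must be positive")
  if (any(melted_g < 0) || any(melted_g > cooked_g))
    stop("melted lipids must satisfy 0 <= melted_g <= cooked_g")
  if (any(cooked_g > crude_g + melted_g))
    stop("cooked weight cannot exceed crude weight plus melted lipids")
  (crude_g - (cooked_g - melted_g)) * 100 / crude_g
}

#' Default planted-effect table
#'
#' One row per library metabolite with the sign and size of its planted
#' linear dependence on standardized liver weight. Signs and magnitudes
#' emulate the reported duck-plasma correlation structure: lactate rises
#' with liver weight while the amino acids (and most other biomarkers)
#' fall; valine is modelled trait-positive for LW (it tracks technological
#' yield negatively) and glucose, xylitol and ethanolamine are nulls. Effect
#' sizes are expressed in concentration-noise SD units and derived from the
#' target correlations as `|r| / sqrt(1 - r^2)`.
#'
#' @param correlations optional named numeric vector of target
#'   concentration-LW correlations overriding the defaults.
#' @return data frame with columns `metabolite`, `sign`, `effect`,
#'   `baseline`.
#' @export
default_effect_table <- function(correlations = NULL) {
  r <- c(
    "lactate"            =  0.62,
    "alanine"            = -0.97,
    "arginine"           = -0.92,
    "glutamine"          = -0.93,
    "glycine"            = -0.87,
    "isoleucine"         = -0.29,
    "leucine"            = -0.65,
    "lysine"             = -0.84,
    "proline"            = -0.64,
    "pyroglutamic acid"  = -0.32,
    "serine"             = -0.82,
    "glycerol"           = -0.96,
    "methylmalonic acid" = -0.29,
    "glucuronic acid"    = -0.63,
    "mannose"            = -0.78,
    "sorbitol"           = -0.76,
    "glutamic acid"      = -0.96,
    "methionine"         = -0.79,
    "valine"             =  0.58,
    "isovaleric acid"    = -0.62,
    "glucose"            =  0.00,
    "xylitol"            =  0.00,
    "ethanolamine"       =  0.00
  )
  if (!is.null(correlations)) r[names(correlations)] <- correlations
  effect <- abs(r) / sqrt(1 - r^2)
  data.frame(metabolite = names(r),
             sign = sign(r),
             effect = unname(effect),
             baseline = 10 + 4 * unname(effect),
             stringsAsFactors = FALSE)
}

#' Cohort simulation configuration
#'
#' Bundles every parameter of the synthetic duck cohort. Defaults reproduce
#' the study design being emulated: 65 animals sampled at overfeeding days
#' 6/8/10/12 (16, 16, 16 and 17 birds), liver weights spanning
#' 302.3--914.9 g, technological yields spanning 54.8--99.5 % and an LW-TY
#' correlation of -0.82.
#'
#' @param n_per_timepoint animals per sampling day; a scalar or one count per
#'   element of `timepoints`.
#' @param timepoints overfeeding days at slaughter.
#' @param lw_range `(min, max)` liver weight bounds, g.
#' @param ty_range `(min, max)` technological yield bounds, %.
#' @param target_lw_ty_correlation target LW-TY sample correlation, in
#'   `[-1, 0]`.
#' @param effect_table planted metabolite effects, see
#'   [default_effect_table()].
#' @param noise_sd concentration noise SD (arbitrary units).
#' @param lw_sd within-day liver-weight SD, g (an assumption of the
#'   generator, not a reported value).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_timepoint = c(16, 16, 16, 17),
                          timepoints = c(6, 8, 10, 12),
                          lw_range = c(302.3, 914.9),
                          ty_range = c(54.8, 99.5),
                          target_lw_ty_correlation = -0.82,
                          effect_table = default_effect_table(),
                          noise_sd = 1,
                          lw_sd = 80,
                          seed = 1L) {
  if (length(n_per_timepoint) == 1)
    n_per_timepoint <- rep(n_per_timepoint, length(timepoints))
  stopifnot(length(n_per_timepoint) == length(timepoints),
            all(n_per_timepoint >= 2),
            lw_range[1] < lw_range[2],
            ty_range[1] < ty_range[2],
            abs(target_lw_ty_correlation) <= 1,
            target_lw_ty_correlation <= 0,
            all(effect_table$baseline > 0),
            noise_sd >= 0)
  structure(list(n_per_timepoint = n_per_timepoint,
                 timepoints = timepoints,
                 lw_range = lw_range, ty_range = ty_range,
                 target_lw_ty_correlation = target_lw_ty_correlation,
                 effect_table = effect_table,
                 noise_sd = noise_sd, lw_sd = lw_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0
  while (length(bad) > 0 && tries < 1000) {
    x[bad] <- stats::rnorm(length(bad), mean[pmin(length(mean), bad)], sd)
    bad <- which(x < lower | x > upper)
    tries <- tries + 1
  }
  pmin(pmax(x, lower), upper)
}

#' Simulate a duck overfeeding cohort
#'
#' Draws phenotypes and plasma metabolite concentrations with the study's
#' statistical structure. Liver weight follows day-specific Gaussians whose
#' means interpolate `lw_range` across the overfeeding days (truncated to the
#' range); technological yield is generated jointly with LW so the sample
#' correlation approaches `target_lw_ty_correlation`. Concentrations are
#' `baseline + sign * effect * noise_sd * z(LW) + N(0, noise_sd)`, truncated
#' at zero, where `z(LW)` is the standardized liver weight.
#'
#' @param config a [cohort_config()].
#' @return a list with `phenotypes` (data frame: `animal_id`, `day`, `lw`,
#'   `ty`) and `ground_truth` (list: `concentrations` samples x metabolites
#'   matrix, `planted_biomarkers` per-trait data frames of non-null
#'   metabolites and their expected correlation signs).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    days <- rep(config$timepoints, config$n_per_timepoint)
    n <- length(days)
    lw_lo <- config$lw_range[1]; lw_hi <- config$lw_range[2]
    width <- lw_hi - lw_lo
    # day means interpolate the range, keeping ~1 SD of headroom at the ends
    frac <- (days - min(config$timepoints)) /
      diff(range(config$timepoints))
    mu <- lw_lo + width * (0.15 + 0.70 * frac)
    lw <- rnorm_trunc(n, mu, config$lw_sd, lw_lo, lw_hi)
    z <- as.numeric(scale(lw))

    rho <- config$target_lw_ty_correlation
    ty_mid <- mean(config$ty_range)
    ty_sd <- diff(config$ty_range) / 6
    ty_star <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
    ty <- ty_mid + ty_sd * ty_star
    ty <- pmin(pmax(ty, max(0, config$ty_range[1])),
               min(100, config$ty_range[2]))

    eff <- config$effect_table
    m <- nrow(eff)
    conc <- matrix(stats::rnorm(n * m, sd = config$noise_sd), n, m)
    conc <- sweep(conc, 2, eff$baseline, `+`) +
      outer(z, eff$sign * eff$effect * config$noise_sd)
    truncated <- colMeans(conc < 0)
    if (any(truncated > 0.5))
      stop("implausible configuration: >50% zero-truncated concentrations ",
           "for ", paste(eff$metabolite[truncated > 0.5], collapse = ", "))
    conc[conc < 0] <- 0
    colnames(conc) <- eff$metabolite
    rownames(conc) <- sprintf("S%03d", seq_len(n))

    planted_lw <- eff[eff$effect > 0, c("metabolite", "sign")]
    planted_ty <- planted_lw
    if (rho < 0) planted_ty$sign <- -planted_ty$sign
    rownames(planted_lw) <- rownames(planted_ty) <- NULL

    list(
      phenotypes = data.frame(animal_id = rownames(conc),
                              day = days, lw = lw, ty = ty,
                              stringsAsFactors = FALSE),
      ground_truth = list(
        concentrations = conc,
        planted_biomarkers = list(lw = planted_lw, ty = planted_ty))
    )
  })
}
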