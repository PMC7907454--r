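#' One-by-one regressions with Benjamini-Hochberg correction
#'
#' Regresses each variable on the trait (simple ordinary least squares; the
#' two-sided slope t-test p-value is direction-invariant for simple
#' regression) and adjusts the p-values by the Benjamini-Hochberg step-up
#' procedure across the variable family of this run. Zero-variance
#' variables get slope 0 and p = 1 and are flagged.
#'
#' @param X samples x variables matrix.
#' @param y trait vector (LW or TY).
#' @return data frame with `variable`, `slope`, `r2`, `p_raw`, `p_bh`,
#'   `degenerate`.
#' @export
univariate_bh <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3, length(y) == n)
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  yc <- y - mean(y)
  syy <- sum(yc^2)
  if (syy == 0) stop("trait vector is constant")
  xc <- sweep(X, 2, colMeans(X))
  sxy <- crossprod(xc, yc)[, 1]
  sxx <- colSums(xc^2)
  degenerate <- sxx == 0
  slope <- ifelse(degenerate, 0, sxy / syy)          # variable ~ trait
  r2 <- ifelse(degenerate | syy == 0, 0, sxy^2 / (sxx * syy))
  r2 <- pmin(r2, 1)
  tstat <- sqrt(pmax(n - 2, 1)) * sqrt(r2) / sqrt(pmax(1 - r2, 1e-300))
  p_raw <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tstat), df = n - 2))
  data.frame(variable = colnames(X), slope = slope, r2 = r2,
             p_raw = p_raw,
             p_bh = stats::p.adjust(p_raw, method = "BH"),
             degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the biomarker selection rule
#'
#' A metabolite is a *candidate* when the multivariate importance criterion
#' holds — metabolite method: its VIP exceeds `vip_threshold`; bucket
#' method: at least one of its mapped buckets has VIP above the threshold.
#' Candidates are then classed on the BH-adjusted p-value of the
#' metabolite's own univariate regression: `significant` below
#' `significant`, `tendency` in `[significant, tendency)`, otherwise
#' `rejected`. Selected biomarkers are the significant and tendency
#' candidates.
#'
#' @param evidence data frame with columns `metabolite`, `p_bh` and either
#'   `vip` (metabolite method) or `n_important_buckets` (bucket method).
#' @param method `"metabolite"` or `"bucket"`.
#' @param vip_threshold VIP importance cutoff.
#' @param significant,tendency BH p-value class boundaries.
#' @return data frame of biomarker records: the evidence columns plus
#'   `candidate`, `class` and `selected`.
#' @export
select_biomarkers <- function(evidence, method = c("metabolite", "bucket"),
                              vip_threshold = 1.0, significant = 0.05,
                              tendency = 0.10) {
  method <- match.arg(method)
  stopifnot(is.data.frame(evidence), "metabolite" %in% names(evidence),
            "p_bh" %in% names(evidence))
  if (anyDuplicated(evidence$metabolite))
    stop("duplicate metabolite names in evidence")
  candidate <- if (method == "metabolite") {
    if (!"vip" %in% names(evidence)) stop("metabolite method needs 'vip'")
    evidence$vip > vip_threshold
  } else {
    if (!"n_important_buckets" %in% names(evidence))
      stop("bucket method needs 'n_important_buckets'")
    evidence$n_important_buckets >= 1
  }
  cls <- ifelse(evidence$p_bh < significant, "significant",
                ifelse(evidence$p_bh < tendency, "tendency", "rejected"))
  cls[!candidate] <- "rejected"
  out <- evidence
  out$method <- method
  out$candidate <- candidate
  out$class <- cls
  out$selected <- candidate & cls %in% c("significant", "tendency")
  out
}

#' Compare two biomarker lists (Venn partition)
#'
#' @param list_a,list_b character vectors of metabolite names (no
#'   duplicates).
#' @return an object of class `venn_result` with `only_a`, `only_b`,
#'   `both` and their counts.
#' @export
venn_compare <- function(list_a, list_b) {
  if (anyDuplicated(list_a) || anyDuplicated(list_b))
    stop("duplicate names within a biomarker list")
  both <- intersect(list_a, list_b)
  res <- list(only_a = setdiff(list_a, both),
              only_b = setdiff(list_b, both),
              both = both)
  res$counts <- c(only_a = length(res$only_a), only_b = length(res$only_b),
                  both = length(res$both),
                  union = length(union(list_a, list_b)))
  structure(res, class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("Venn: %d only in A, %d only in B, %d shared (union %d)\n",
              x$counts["only_a"], x$counts["only_b"], x$counts["both"],
              x$counts["union"]))
  invisible(x)
}

#' Biomarker-trait correlation network
#'
#' Pearson correlations for every biomarker-trait and biomarker-biomarker
#' pair; edges whose |r| reaches `threshold` are kept. The trait node is
#' always part of the network even when no edge survives.
#'
#' @param rc samples x biomarkers matrix (relative concentrations).
#' @param trait trait vector aligned to the rows of `rc`.
#' @param threshold minimum |r| for an edge.
#' @param trait_name label for the trait node.
#' @return an object of class `correlation_network` with `nodes` and an
#'   edge data frame (`node_a`, `node_b`, `r`).
#' @export
correlation_network <- function(rc, trait, threshold = 0.3,
                                trait_name = "trait") {
  rc <- as.matrix(rc)
  stopifnot(nrow(rc) == length(trait))
  if (any(apply(rc, 2, stats::sd) == 0) || stats::sd(trait) == 0)
    stop("constant column in network input")
  dat <- cbind(rc, trait)
  colnames(dat)[ncol(dat)] <- trait_name
  cm <- stats::cor(dat)
  nodes <- colnames(dat)
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  edges <- data.frame(node_a = nodes[pairs[, 1]],
                      node_b = nodes[pairs[, 2]],
                      r = cm[pairs], stringsAsFactors = FALSE)
  edges <- edges[abs(edges$r) >= threshold, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 trait_name = trait_name),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("Correlation network: %d nodes, %d edges (|r| >= %.2f)\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Load a shipped reported-evidence table
#'
#' The package ships four small evidence tables summarising the published
#' duck-plasma biomarker screens (per trait and per method): per-metabolite
#' BH-adjusted p-values plus, for the metabolite method, VIP scores and,
#' for the bucket method, counts of important peaks/buckets. They serve as
#' worked-example fixtures for the selection and Venn operations.
#'
#' @param trait `"lw"` or `"ty"`.
#' @param method `"bucket"` or `"metabolite"`.
#' @return data frame.
#' @export
reported_evidence <- function(trait = c("lw", "ty"),
                              method = c("bucket", "metabolite")) {
  trait <- match.arg(trait); method <- match.arg(method)
  path <- system.file("extdata", "evidence",
                      sprintf("evidence_%s_%s.csv", trait, method),
                      package = "gavageNMR")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
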