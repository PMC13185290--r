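# feature identity within an oriented table: snp and/or feature columns
ai_feature_key <- function(oriented) {
  cols <- intersect(c("snp", "feature"), names(oriented))
  if (length(cols) == 0L) stop("no feature identifier column found")
  do.call(paste, c(oriented[, cols, drop = FALSE], list(sep = "|")))
}

#' Permutation p-value for allelic imbalance
#'
#' Builds a null distribution by randomly permuting the reference and
#' alternative allele within each individual: every permutation
#' independently swaps `k_i <-> n_i - k_i` per sample with probability 1/2,
#' then refits the intercept-only beta-binomial regression. The statistic is
#' the intercept Wald z, and the p-value uses the add-one estimator
#' `p = (1 + #{|z_perm| >= |z_obs|}) / (1 + n_used)`, so the smallest
#' achievable value is `1 / (n_perm + 1)`. Non-convergent permutation fits
#' are redrawn up to a retry cap and then skipped (the count is recorded in
#' the `n_skipped` attribute).
#'
#' @param ref,alt Per-sample reference and alternative UMI counts
#'   (pseudobulk: one entry per sample).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param retry_cap Redraw attempts per non-convergent permutation.
#' @return The permutation p-value, with attributes `z_obs` and `n_skipped`.
#' @export
permutation_pvalue <- function(ref, alt, n_perm = 1000L, seed = 1L,
                               retry_cap = 3L) {
  n <- ref + alt
  keep <- n > 0
  k <- ref[keep]; n <- n[keep]
  if (length(k) < 2L) stop("insufficient data: need at least 2 observations")
  X <- matrix(1, length(k), 1L)
  obs <- bb_ml_core(k, n, X)
  if (!obs$converged || is.na(obs$se[1L]) || obs$se[1L] == 0)
    return(structure(NA_real_, z_obs = NA_real_, n_skipped = n_perm))
  z_obs <- obs$beta[1L] / obs$se[1L]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_hit <- 0L; n_used <- 0L; n_skipped <- 0L
  for (b in seq_len(n_perm)) {
    z_perm <- NA_real_
    for (try in seq_len(retry_cap)) {
      swap <- stats::runif(length(k)) < 0.5
      kp <- ifelse(swap, n - k, k)
      perm <- bb_ml_core(kp, n, X)
      if (perm$converged && perm$se[1L] > 0) {
        z_perm <- perm$beta[1L] / perm$se[1L]
        break
      }
    }
    if (is.na(z_perm)) {
      n_skipped <- n_skipped + 1L
    } else {
      n_used <- n_used + 1L
      if (abs(z_perm) >= abs(z_obs)) n_hit <- n_hit + 1L
    }
  }
  structure((1 + n_hit) / (1 + n_used), z_obs = z_obs,
            n_skipped = n_skipped)
}

ai_result_row <- function(feature, snp, stratum, method, fit_coef, n_samples,
                          total_umis) {
  data.frame(feature = feature, snp = snp, stratum = stratum,
             method = method, effect = fit_coef$effect, se = fit_coef$se,
             p_value = fit_coef$p, adjusted_p = NA_real_,
             n_samples = n_samples, total_umis = total_umis,
             converged = fit_coef$converged, stringsAsFactors = FALSE)
}

# run one feature's test; rows already restricted to one feature + stratum
ai_test_one <- function(d, method, seed, n_perm) {
  k <- d$ref_umis; n <- d$ref_umis + d$alt_umis
  keep <- n > 0
  d <- d[keep, , drop = FALSE]; k <- k[keep]; n <- n[keep]
  na_res <- list(effect = NA_real_, se = NA_real_, p = NA_real_,
                 converged = FALSE)
  if (nrow(d) < 2L) return(na_res)
  if (method == "pseudobulk_bb") {
    if (all(k == 0) || all(k == n)) return(na_res)
    f <- bb_ml_core(k, n, matrix(1, length(k), 1L))
    z <- f$beta[1L] / f$se[1L]
    list(effect = f$beta[1L], se = f$se[1L],
         p = if (f$converged) 2 * stats::pnorm(-abs(z)) else NA_real_,
         converged = f$converged)
  } else if (method == "quasibinom") {
    fit <- fit_quasibinom(cbind(ref_umis, alt_umis) ~ 1, d)
    list(effect = fit$coefficients[1L], se = fit$se[1L],
         p = fit$p.values[1L], converged = fit$converged)
  } else if (method == "permutation") {
    p <- permutation_pvalue(d$ref_umis, d$alt_umis, n_perm = n_perm,
                            seed = seed)
    f <- bb_ml_core(k, n, matrix(1, length(k), 1L))
    list(effect = f$beta[1L], se = f$se[1L], p = as.numeric(p),
         converged = f$converged)
  } else if (method == "mixed_bb") {
    fit <- fit_betabinom_mixed(cbind(ref_umis, alt_umis) ~ 1, d)
    list(effect = fit$coefficients[1L], se = fit$se[1L],
         p = fit$p.values[1L], converged = fit$converged)
  } else stop("unknown method: ", method)
}

#' Test features for allelic imbalance across individuals
#'
#' For every feature (SNP/gene pair) and stratum, tests the null of balanced
#' allelic expression (`logit(ref fraction) = 0`) on oriented counts.
#' Methods: `pseudobulk_bb` (beta-binomial regression on per-sample
#' pseudobulk rows), `quasibinom` (quasi-binomial alternative),
#' `permutation` (per-sample allele-swap null distribution), `mixed_bb`
#' (beta-binomial mixed model on cell-level rows with a per-sample random
#' intercept). P-values are Benjamini-Hochberg adjusted within each stratum.
#'
#' @param oriented Oriented counts (long format) with columns `sample`,
#'   `ref_umis`, `alt_umis` and feature identifier column(s) (`snp`,
#'   `feature`). For `mixed_bb`, rows are cell-level and `sample` is the
#'   individual.
#' @param method One of `"pseudobulk_bb"`, `"quasibinom"`, `"permutation"`,
#'   `"mixed_bb"`.
#' @param stratify_by Optional grouping column (e.g. cell type); tests and
#'   BH adjustment run within each stratum.
#' @param n_perm Permutations for `method = "permutation"`.
#' @param seed Seed for the permutation method.
#' @return A data.frame with one row per (feature, stratum): `feature`,
#'   `snp`, `stratum`, `method`, `effect` (logit scale), `se`, `p_value`,
#'   `adjusted_p`, `n_samples`, `total_umis`, `converged`.
#' @export
test_allelic_imbalance <- function(oriented,
                                   method = c("pseudobulk_bb", "quasibinom",
                                              "permutation", "mixed_bb"),
                                   stratify_by = NULL, n_perm = 1000L,
                                   seed = 1L) {
  method <- match.arg(method)
  stopifnot(all(c("sample", "ref_umis", "alt_umis") %in% names(oriented)))
  strata <- if (is.null(stratify_by)) rep("all", nrow(oriented)) else
    as.character(oriented[[stratify_by]])
  fkey <- ai_feature_key(oriented)
  out <- list()
  for (st in unique(strata)) {
    si <- strata == st
    if (!any(si)) next
    for (fk in unique(fkey[si])) {
      d <- oriented[si & fkey == fk, , drop = FALSE]
      res <- ai_test_one(d, method, seed = seed + sum(utf8ToInt(fk)) %% 10000L,
                         n_perm = n_perm)
      out[[length(out) + 1L]] <- ai_result_row(
        feature = if ("feature" %in% names(d)) d$feature[1L] else fk,
        snp = if ("snp" %in% names(d)) d$snp[1L] else NA_character_,
        stratum = st, method = method, fit_coef = res,
        n_samples = length(unique(d$sample)),
        total_umis = sum(d$ref_umis + d$alt_umis))
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  for (st in unique(res$stratum)) {
    i <- res$stratum == st
    res$adjusted_p[i] <- adjust_pvalues(res$p_value[i], "BH")
  }
  rownames(res) <- NULL
  res
}

#' Within-sample allelic imbalance test
#'
#' Intercept-only beta-binomial regression across the cells of a single
#' sample for one feature — the single-sample, cell-level test. Requires at
#' least `min_cells` cells with at least one phased UMI; otherwise the
#' result is `NA`.
#'
#' @param cell_counts Cell-level counts for one sample and one feature, with
#'   columns `ref_umis` and `alt_umis` (one row per cell).
#' @param min_cells Minimum informative cells, default 5.
#' @return A one-row result data.frame (see [test_allelic_imbalance()]).
#' @export
test_within_sample <- function(cell_counts, min_cells = 5L) {
  stopifnot(all(c("ref_umis", "alt_umis") %in% names(cell_counts)))
  n <- cell_counts$ref_umis + cell_counts$alt_umis
  d <- cell_counts[n > 0, , drop = FALSE]
  na_res <- list(effect = NA_real_, se = NA_real_, p = NA_real_,
                 converged = FALSE)
  res <- if (nrow(d) < min_cells) na_res else {
    k <- d$ref_umis; nn <- d$ref_umis + d$alt_umis
    if (all(k == 0) || all(k == nn)) na_res else {
      f <- bb_ml_core(k, nn, matrix(1, length(k), 1L))
      z <- f$beta[1L] / f$se[1L]
      list(effect = f$beta[1L], se = f$se[1L],
           p = if (f$converged) 2 * stats::pnorm(-abs(z)) else NA_real_,
           converged = f$converged)
    }
  }
  ai_result_row(feature = if ("feature" %in% names(cell_counts) &&
                              nrow(cell_counts))
                  cell_counts$feature[1L] else NA_character_,
                snp = NA_character_, stratum = "within_sample",
                method = "within_sample_bb", fit_coef = res,
                n_samples = 1L, total_umis = sum(n))
}

#' Test for differential allelic imbalance between conditions
#'
#' Adds a condition indicator to the design (`~ Condition`) and reports the
#' condition coefficient: a nonzero value means the allelic ratio differs
#' between conditions (e.g. case vs control). Available for the pseudobulk
#' beta-binomial, quasi-binomial and mixed-model methods.
#'
#' @param oriented Oriented counts with a condition column.
#' @param method `"pseudobulk_bb"`, `"quasibinom"` or `"mixed_bb"`.
#' @param condition_col Name of the condition column (2+ levels required).
#' @return A data.frame as in [test_allelic_imbalance()], where `effect` is
#'   the condition coefficient on the logit scale.
#' @export
test_differential_imbalance <- function(oriented,
                                        method = c("pseudobulk_bb",
                                                   "quasibinom", "mixed_bb"),
                                        condition_col = "condition") {
  method <- match.arg(method)
  if (!condition_col %in% names(oriented))
    stop(sprintf("column '%s' not found", condition_col))
  if (length(unique(oriented[[condition_col]])) < 2L)
    stop("need at least 2 condition levels with data")
  fkey <- ai_feature_key(oriented)
  fml <- stats::as.formula(paste("cbind(ref_umis, alt_umis) ~",
                                 condition_col))
  out <- list()
  for (fk in unique(fkey)) {
    d <- oriented[fkey == fk, , drop = FALSE]
    n <- d$ref_umis + d$alt_umis
    d <- d[n > 0, , drop = FALSE]
    na_res <- list(effect = NA_real_, se = NA_real_, p = NA_real_,
                   converged = FALSE)
    res <- if (nrow(d) < 3L || length(unique(d[[condition_col]])) < 2L)
      na_res
    else {
      fit <- tryCatch(switch(method,
        pseudobulk_bb = fit_betabinom(fml, d),
        quasibinom = fit_quasibinom(fml, d),
        mixed_bb = fit_betabinom_mixed(fml, d)),
        error = function(e) NULL)
      if (is.null(fit) || length(fit$coefficients) < 2L) na_res else
        list(effect = fit$coefficients[2L], se = fit$se[2L],
             p = fit$p.values[2L], converged = fit$converged)
    }
    out[[length(out) + 1L]] <- ai_result_row(
      feature = if ("feature" %in% names(d) && nrow(d)) d$feature[1L] else fk,
      snp = if ("snp" %in% names(d) && nrow(d)) d$snp[1L] else NA_character_,
      stratum = "all", method = paste0("differential_", method),
      fit_coef = res, n_samples = length(unique(d$sample)),
      total_umis = sum(d$ref_umis + d$alt_umis))
  }
  res <- do.call(rbind, out)
  res$adjusted_p <- adjust_pvalues(res$p_value, "BH")
  rownames(res) <- NULL
  res
}

#' Test whether a peak's allelic ratio differs from the rest of its gene
#'
#' Compares the allelic ratio inside a peak with the ratio of the rest of
#' the gene (gene counts minus peak counts, per sample) by fitting a
#' beta-binomial regression on two rows per sample with a peak-indicator
#' covariate; the reported p-value is for the indicator. This contrast is a
#' construction of this package (the comparison itself is standard, the
#' statistic is not prescribed); the method label marks it accordingly.
#'
#' @param peak_counts,gene_counts Per-sample counts with columns `sample`,
#'   `ref_umis`, `alt_umis`; `gene_counts` are whole-gene counts and must
#'   dominate `peak_counts` elementwise.
#' @return A one-row result data.frame; `NA` when the peak is the whole gene
#'   (rest-of-gene counts all zero).
#' @export
test_peak_vs_gene <- function(peak_counts, gene_counts) {
  stopifnot(all(c("sample", "ref_umis", "alt_umis") %in% names(peak_counts)),
            all(c("sample", "ref_umis", "alt_umis") %in% names(gene_counts)))
  m <- match(peak_counts$sample, gene_counts$sample)
  if (anyNA(m)) stop("every peak sample needs whole-gene counts")
  rest_ref <- gene_counts$ref_umis[m] - peak_counts$ref_umis
  rest_alt <- gene_counts$alt_umis[m] - peak_counts$alt_umis
  if (any(rest_ref < 0) || any(rest_alt < 0))
    stop("gene counts must dominate peak counts elementwise")
  na_res <- list(effect = NA_real_, se = NA_real_, p = NA_real_,
                 converged = FALSE)
  total_umis <- sum(peak_counts$ref_umis + peak_counts$alt_umis +
                      rest_ref + rest_alt)
  feature <- if ("feature" %in% names(peak_counts))
    peak_counts$feature[1L] else NA_character_
  if (all(rest_ref + rest_alt == 0)) {
    res <- na_res  # the peak is the gene: no contrast exists
  } else {
    d <- data.frame(
      sample = c(peak_counts$sample, peak_counts$sample),
      ref_umis = c(peak_counts$ref_umis, rest_ref),
      alt_umis = c(peak_counts$alt_umis, rest_alt),
      is_peak = rep(c(1L, 0L), each = nrow(peak_counts)))
    d <- d[d$ref_umis + d$alt_umis > 0, , drop = FALSE]
    fit <- tryCatch(fit_betabinom(cbind(ref_umis, alt_umis) ~ is_peak, d),
                    error = function(e) NULL)
    res <- if (is.null(fit) || length(fit$coefficients) < 2L) na_res else
      list(effect = fit$coefficients[2L], se = fit$se[2L],
           p = fit$p.values[2L], converged = fit$converged)
  }
  ai_result_row(feature = feature, snp = NA_character_, stratum = "all",
                method = "peak_vs_gene_bb", fit_coef = res,
                n_samples = length(unique(peak_counts$sample)),
                total_umis = total_umis)
}

#' Multiple-testing correction
#'
#' Benjamini-Hochberg step-up or Bonferroni adjustment via
#' [stats::p.adjust()]. `NA` p-values are propagated and excluded from the
#' number of tests.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
adjust_pvalues <- function(pvals, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = method)
  out
}

#' False-positive-rate calibration under per-sample allele permutation
#'
#' The calibration harness: each replicate independently swaps the reference
#' and alternative allele per (sample, feature) with probability 1/2 —
#' constructing a dataset with no true allelic imbalance — runs the chosen
#' test over all features, and records the fraction of features with
#' p-value below `alpha`. A well-calibrated test yields a median fraction
#' near `alpha` (5% by default).
#'
#' @param oriented Oriented counts as for [test_allelic_imbalance()].
#' @param method Test method (default `"pseudobulk_bb"`).
#' @param n_reps Number of permutation replicates (default 100).
#' @param seed Integer seed; replicate r uses stream `seed + r`.
#' @param alpha Significance threshold (default 0.05).
#' @return A list of class `fpr_calibration`: `fractions` (per replicate),
#'   `median`, `alpha`, `method`.
#' @export
fpr_calibration <- function(oriented, method = "pseudobulk_bb",
                            n_reps = 100L, seed = 1L, alpha = 0.05) {
  stopifnot(all(c("sample", "ref_umis", "alt_umis") %in% names(oriented)))
  fractions <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed + r)
    swap <- stats::runif(nrow(oriented)) < 0.5
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    perm <- oriented
    perm$ref_umis <- ifelse(swap, oriented$alt_umis, oriented$ref_umis)
    perm$alt_umis <- ifelse(swap, oriented$ref_umis, oriented$alt_umis)
    res <- test_allelic_imbalance(perm, method = method, seed = seed + r)
    p <- res$p_value[!is.na(res$p_value)]
    fractions[r] <- if (length(p)) mean(p < alpha) else NA_real_
  }
  structure(list(fractions = fractions,
                 median = stats::median(fractions, na.rm = TRUE),
                 alpha = alpha, method = method),
            class = "fpr_calibration")
}

#' @export
print.fpr_calibration <- function(x, ...) {
  cat(sprintf(
    "FPR calibration (%s): median fraction p < %.2f over %d replicates = %.3f\n",
    x$method, x$alpha, length(x$fractions), x$median))
  invisible(x)
}
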