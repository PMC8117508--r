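#' Filter a count matrix by counts-per-million
#'
#' Retains miRNAs with `CPM >= cpm_min` (inclusive) in at least
#' `min_samples` samples, where `CPM = 1e6 * count / library size`.
#'
#' @param counts Nonnegative integer matrix, miRNAs x samples.
#' @param cpm_min CPM threshold.
#' @param min_samples Minimum number of samples meeting the threshold.
#' @return The filtered count matrix.
#' @export
cpm_filter <- function(counts, cpm_min = 1, min_samples = 6L) {
  counts <- as.matrix(counts)
  if (min_samples > ncol(counts)) {
    stop("min_samples exceeds the number of samples", call. = FALSE)
  }
  lib <- colSums(counts)
  stopifnot(all(lib > 0))
  cpm <- t(t(counts) / lib) * 1e6
  counts[rowSums(cpm >= cpm_min) >= min_samples, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Weighted trimmed mean of M-values: the reference library is the one
#' whose upper-quartile (of count/library-size) is closest to the mean
#' upper quartile; for every other library the gene-wise log2 ratios
#' (M) against the reference are trimmed by `trim_m` from each tail and
#' the average log intensities (A) by `trim_a` from each tail, and the
#' remaining M values are averaged with inverse approximate-variance
#' (delta-method binomial) weights. Factors are rescaled so their
#' log-mean is zero (product one).
#'
#' @param counts Nonnegative matrix, genes x samples (>= 2 samples).
#' @param trim_m Trim fraction on M values (per tail).
#' @param trim_a Trim fraction on A values (per tail).
#' @return Named numeric vector of normalization factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2L)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("a library has zero total count", call. = FALSE)

  f75 <- apply(counts, 2L, function(y) quantile(y / sum(y), 0.75,
                                                names = FALSE))
  ref <- which.min(abs(f75 - mean(f75)))
  yR <- counts[, ref]
  nR <- lib[ref]

  one_factor <- function(yO, nO) {
    keep0 <- yO > 0 & yR > 0
    if (!any(keep0)) return(1)
    o <- yO[keep0] / nO
    r <- yR[keep0] / nR
    M <- log2(o / r)
    A <- (log2(o) + log2(r)) / 2
    w <- (nO - yO[keep0]) / (nO * yO[keep0]) +
      (nR - yR[keep0]) / (nR * yR[keep0])
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (!length(M) || max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_m) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1
    hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    f <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
    if (!is.finite(f)) 1 else f
  }

  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) 1 else one_factor(counts[, j], lib[j])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

# NB density generalized to non-integer x via gamma functions, so that
# quantile-scaled pseudo-counts can be evaluated directly.
#' @noRd
dnb_cont <- function(x, size, mu) {
  if (mu <= 0) return(as.numeric(x == 0))
  exp(lgamma(x + size) - lgamma(size) - lgamma(x + 1) +
        size * log(size / (size + mu)) + x * log(mu / (size + mu)))
}

# Conditional two-sided exact p for one gene: group sums s1 (control)
# and s2, n1/n2 samples, dispersion phi. Conditions on the total and
# sums the probabilities of all splits as or less probable than the
# observed one; the NB probability parameter cancels in the
# normalization, so the conditional law does not depend on mu.
#' @noRd
exact_nb_p <- function(s1, s2, n1, n2, phi) {
  t_real <- s1 + s2
  if (t_real <= 0) return(1)
  t_int <- round(t_real)
  mu_hat <- t_real / (n1 + n2)
  size1 <- if (phi > 0) n1 / phi else 1e8
  size2 <- if (phi > 0) n2 / phi else 1e8
  grid <- 0:t_int
  probs <- dnb_cont(grid, size1, n1 * mu_hat) *
    dnb_cont(t_int - grid, size2, n2 * mu_hat)
  tot <- sum(probs)
  if (tot <= 0) return(1)
  p_obs <- dnb_cont(s1, size1, n1 * mu_hat) *
    dnb_cont(t_real - s1, size2, n2 * mu_hat)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]) / tot)
}

#' Negative-binomial conditional exact test at fixed dispersion
#'
#' Two-group exact test for count data with a common, fixed dispersion
#' `phi = bcv^2` (no dispersion estimation). Effective library sizes
#' (library size times TMM factor) are equalized by scaling each
#' sample's counts to the geometric-mean effective size; the test then
#' conditions on the per-miRNA total and sums the conditional tail
#' probabilities of all splits as or more extreme (as or less probable)
#' than the observed one. log2 fold changes (B+ over B-) use the
#' normalized group means with a prior count of 0.125.
#'
#' @param counts Matrix, miRNAs x samples.
#' @param design Data frame with `sample_id`, `tissue`, `sex`,
#'   `b_status` (one row per counts column); may be `NULL` when `group`
#'   is given.
#' @param contrast Length-2 character vector `c(tissue, sex)` selecting
#'   the samples to compare; ignored when `group` is given.
#' @param bcv Biological coefficient of variation (dispersion is
#'   `bcv^2`).
#' @param group Optional explicit `"Bminus"`/`"Bplus"` label per counts
#'   column, bypassing `design`/`contrast`.
#' @param norm_factors Optional per-sample normalization factors for
#'   the selected columns (defaults to [tmm_factors()] of the selected
#'   submatrix).
#' @param lib_sizes Optional per-sample library sizes (defaults to
#'   column sums); useful for testing single genes against a known
#'   sequencing depth.
#' @param prior_count Prior added to normalized group means for the
#'   log2 fold change.
#' @return Data frame with `mirna_id`, `log2fc`, `p_value`.
#' @export
exact_test <- function(counts, design = NULL, contrast = NULL, bcv = 0.4,
                       group = NULL, norm_factors = NULL,
                       lib_sizes = NULL, prior_count = 0.125) {
  counts <- as.matrix(counts)
  if (is.null(group)) {
    stopifnot(!is.null(design), !is.null(contrast))
    design <- design[match(colnames(counts), design$sample_id), ,
                     drop = FALSE]
    sel <- design$tissue == contrast[[1]] & design$sex == contrast[[2]]
    if (!any(sel)) stop("contrast selects no samples", call. = FALSE)
    counts <- counts[, sel, drop = FALSE]
    group <- design$b_status[sel]
  }
  if (!all(c("Bminus", "Bplus") %in% group)) {
    stop("both groups (Bminus, Bplus) must be present", call. = FALSE)
  }
  lib <- if (is.null(lib_sizes)) colSums(counts) else lib_sizes
  if (is.null(norm_factors)) {
    norm_factors <- tmm_factors(counts)
  }
  eff <- lib * norm_factors
  if (any(!is.finite(eff)) || any(eff <= 0)) {
    stop("effective library sizes must be positive", call. = FALSE)
  }
  target <- exp(mean(log(eff)))
  pseudo <- t(t(counts) * (target / eff))

  i1 <- group == "Bminus"
  i2 <- group == "Bplus"
  n1 <- sum(i1); n2 <- sum(i2)
  s1 <- rowSums(pseudo[, i1, drop = FALSE])
  s2 <- rowSums(pseudo[, i2, drop = FALSE])
  phi <- bcv^2
  p <- vapply(seq_len(nrow(counts)), function(g) {
    exact_nb_p(s1[g], s2[g], n1, n2, phi)
  }, numeric(1))
  log2fc <- log2((s2 / n2 + prior_count) / (s1 / n1 + prior_count))
  data.frame(mirna_id = rownames(counts), log2fc = log2fc,
             p_value = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially expressed miRNAs
#'
#' A miRNA is DE when `p < alpha` and its linear fold change exceeds
#' `fc_min` strictly in either direction. The signed linear fold-change
#' convention reports `+2^|log2fc|` for upregulation in B+ and
#' `-2^|log2fc|` for downregulation (magnitude always >= 1).
#'
#' @param results Data frame from [exact_test()].
#' @param alpha Raw p-value threshold (no multiple-testing correction
#'   by default, matching the screening character of the analysis).
#' @param fc_min Linear fold-change threshold (strict).
#' @param adjust Apply Benjamini-Hochberg adjustment before
#'   thresholding.
#' @return `results` with `fold_change`, `is_de` and `direction` added.
#' @export
call_de <- function(results, alpha = 0.05, fc_min = 1.5, adjust = FALSE) {
  p <- if (adjust) p.adjust(results$p_value, "BH") else results$p_value
  lin <- 2^abs(results$log2fc)
  results$fold_change <- ifelse(results$log2fc >= 0, lin, -lin)
  results$is_de <- p < alpha & lin > fc_min
  results$direction <- ifelse(results$log2fc >= 0, "up", "down")
  results
}

#' Nonredundant union of DE miRNAs across contrasts
#'
#' Aggregates per-contrast DE calls into the nonredundant DE set, a
#' contrast membership matrix, and (when contrasts are named
#' `tissue_sex`) per-tissue Venn region counts for three tissues.
#'
#' @param results_list Named list of [call_de()] outputs; names like
#'   `"gonad_F"` identify the contrast.
#' @return List with `union` (miRNA ids DE in any contrast),
#'   `membership` (logical matrix miRNA x contrast) and `venn` (named
#'   counts of the 7 regions for exactly 3 tissues, else `NULL`).
#' @export
nonredundant_de <- function(results_list) {
  stopifnot(length(results_list) >= 1L, !is.null(names(results_list)))
  de_sets <- lapply(results_list, function(r) r$mirna_id[r$is_de])
  ids <- sort(unique(unlist(de_sets)))
  membership <- vapply(de_sets, function(s) ids %in% s,
                       logical(length(ids)))
  if (length(ids) == 0L) {
    membership <- matrix(FALSE, 0L, length(de_sets),
                         dimnames = list(NULL, names(results_list)))
  } else {
    membership <- matrix(membership, nrow = length(ids),
                         dimnames = list(ids, names(results_list)))
  }
  tissues <- vapply(strsplit(names(results_list), "_"), `[[`, "", 1L)
  venn <- NULL
  if (length(unique(tissues)) == 3L) {
    per_tissue <- lapply(unique(tissues), function(ti) {
      unique(unlist(de_sets[tissues == ti]))
    })
    names(per_tissue) <- unique(tissues)
    tn <- names(per_tissue)
    in_t <- vapply(per_tissue, function(s) ids %in% s,
                   logical(length(ids)))
    if (length(ids)) {
      key <- apply(in_t, 1L, function(z) paste(tn[z], collapse = "&"))
      venn <- table(key)
      venn <- setNames(as.integer(venn), names(venn))
    } else {
      venn <- integer(0)
    }
  }
  list(union = ids, membership = membership, venn = venn)
}
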