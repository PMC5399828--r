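#' Construct the design for a two-group comparison
#'
#' @param sample_ids Character vector of sample ids.
#' @param condition Factor-like vector (two levels) aligned with
#'   `sample_ids`; the first level is the reference group.
#' @param offset Optional per-sample normalization offset on the natural
#'   log scale; by default the log of each sample's total count over the
#'   tested features is used at fit time.
#' @return A design tibble with columns `sample_id`, `condition` (factor)
#'   and optionally `offset`.
#' @export
make_design <- function(sample_ids, condition, offset = NULL) {
  cond <- as.factor(condition)
  if (nlevels(cond) != 2) abort("`condition` must have exactly two levels")
  out <- tibble(sample_id = sample_ids, condition = cond)
  if (!is.null(offset)) {
    if (any(!is.finite(offset))) abort("offsets must be finite")
    out$offset <- offset
  }
  out
}

#' Fit an overdispersed Poisson GLM to one feature
#'
#' Model: `log E[y_j] = b0 + b1 x_j + offset_j`, with `x_j` the group
#' indicator. The mean parameters are fit by iteratively reweighted least
#' squares (relative deviance change below `1e-8`, at most 50 iterations);
#' the dispersion is the per-feature Pearson chi-square divided by `n - 2`,
#' floored at 1 so underdispersion is never rewarded; the standard error of
#' `b1` is the Poisson standard error inflated by the square root of the
#' dispersion; the p-value is from a two-sided t test with `n - 2` degrees
#' of freedom on `b1 / se`.
#'
#' When one group has all-zero counts the maximum-likelihood fold change is
#' infinite; the estimate is then computed from group totals with a 0.5
#' continuity correction (in that case only) and flagged in the `separated`
#' column rather than reported as infinite.
#'
#' @param y Non-negative integer counts, one per sample; an all-zero
#'   feature is an error (pre-filter with
#'   [representativeness_filter()]).
#' @param design Design tibble (see [make_design()]); rows aligned with
#'   `y`. A missing `offset` column means zero offsets.
#' @return A one-row tibble: `logFC` (natural log; group 2 vs group 1),
#'   `log2FC`, `se`, `t`, `df`, `p`, `dispersion`, `separated`.
#' @export
fit_odp_glm <- function(y, design) {
  n <- length(y)
  if (n != nrow(design)) abort("`y` and `design` lengths differ")
  grp <- as.integer(design$condition == levels(design$condition)[2])
  if (min(table(design$condition)) < 2) {
    abort("each group needs at least 2 samples")
  }
  if (all(y == 0)) abort("all-zero feature: filter before fitting")
  off <- if ("offset" %in% names(design)) design$offset else rep(0, n)
  df_resid <- n - 2
  t1 <- sum(y[grp == 1])
  t0 <- sum(y[grp == 0])
  o1 <- sum(exp(off[grp == 1]))
  o0 <- sum(exp(off[grp == 0]))
  separated <- (t1 == 0) || (t0 == 0)
  if (separated) {
    # continuity-corrected closed form (group totals are sufficient)
    b1 <- log((t1 + 0.5) / o1) - log((t0 + 0.5) / o0)
    mu <- exp(ifelse(grp == 1, log((t1 + 0.5) / o1), log((t0 + 0.5) / o0)) + off)
    se_pois <- sqrt(1 / (t1 + 0.5) + 1 / (t0 + 0.5))
  } else {
    fit <- stats::glm(y ~ grp + offset(off), family = stats::poisson(),
                      control = stats::glm.control(epsilon = 1e-8, maxit = 50))
    b1 <- unname(stats::coef(fit)["grp"])
    mu <- fit$fitted.values
    se_pois <- unname(sqrt(diag(stats::vcov(fit))["grp"]))
  }
  phi <- max(1, sum((y - mu)^2 / mu) / df_resid)
  se <- sqrt(phi) * se_pois
  tstat <- b1 / se
  p <- 2 * stats::pt(-abs(tstat), df = df_resid)
  tibble(logFC = b1, log2FC = b1 / log(2), se = se, t = tstat,
         df = df_resid, p = p, dispersion = phi, separated = separated)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Standard step-up FDR adjustment with monotonicity enforcement,
#' order-preserving with respect to the input indexing.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return FDR-adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Test every feature of an abundance matrix for differential abundance
#'
#' Per-feature overdispersed Poisson GLM ([fit_odp_glm()]) followed by
#' Benjamini-Hochberg correction across all tested features of the level.
#' When the design has no `offset` column, the offset of a sample is the
#' natural log of its total count over the supplied matrix (pass offsets
#' computed on the unfiltered matrix to normalize by the full annotated
#' library size).
#'
#' @param m Abundance tibble, normally representativeness-filtered.
#' @param design Design tibble (see [make_design()]); must cover the
#'   matrix's samples.
#' @param alpha FDR significance threshold (default 0.05).
#' @return An object of class `finebin_da`: a tibble with columns
#'   `feature_id`, `logFC`, `log2FC`, `se`, `t`, `df`, `p`, `fdr`,
#'   `dispersion`, `separated`, `significant`, sorted by `fdr` then
#'   `feature_id`. Attributes carry `alpha` and the level tag.
#' @export
run_differential_abundance <- function(m, design, alpha = 0.05) {
  samples <- abundance_samples(m)
  if (!all(samples %in% design$sample_id)) {
    abort("design does not cover all samples of the matrix")
  }
  design <- design[match(samples, design$sample_id), , drop = FALSE]
  cm <- abundance_counts(m)
  if (!"offset" %in% names(design)) {
    tot <- colSums(cm)
    if (any(tot == 0)) abort("a sample has zero total count; supply offsets")
    design$offset <- log(tot)
  }
  res <- purrr::map_dfr(seq_len(nrow(cm)), function(i) fit_odp_glm(cm[i, ], design))
  res <- res %>%
    mutate(feature_id = m$feature_id, .before = 1) %>%
    mutate(fdr = bh_fdr(.data$p), significant = .data$fdr < alpha) %>%
    arrange(.data$fdr, .data$feature_id)
  structure(res, class = c("finebin_da", class(res)),
            alpha = alpha, level = attr(m, "level"),
            groups = levels(design$condition))
}

#' @export
tidy.finebin_da <- function(x, ...) {
  as_tibble(unclass(x)[setdiff(names(x), character(0))])
}

#' @export
glance.finebin_da <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    level = as.character(attr(x, "level") %||% NA_character_),
    median_dispersion = stats::median(x$dispersion)
  )
}

#' @export
print.finebin_da <- function(x, ...) {
  cat(sprintf("Differential abundance: %d features, %d significant (FDR < %g)\n",
              nrow(x), sum(x$significant), attr(x, "alpha")))
  print(tidy(x), ...)
  invisible(x)
}

#' Volcano plot of a differential-abundance result
#'
#' @param object A `finebin_da` object.
#' @param ... Unused.
#' @return A ggplot object: log fold change against -log10 p, colored by
#'   FDR significance.
#' @export
autoplot.finebin_da <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$logFC, y = -log10(.data$p),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                                 name = sprintf("FDR < %g", attr(object, "alpha"))) +
    ggplot2::labs(x = "log fold change (natural log)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Write a differential-abundance result as TSV
#'
#' @param x `finebin_da` object (or plain results tibble).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_da_results <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
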