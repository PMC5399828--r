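#' Binomially downsample the counts of affected regions
#'
#' Each affected region's count `Y` is replaced by a `Binomial(Y, p)` draw
#' (so the expected between-group fold change of a feature downsampled in
#' one group is `1/p`); all other counts are untouched. With `p = 1` the
#' counts are returned unchanged. Draws come from the current RNG stream,
#' so results are reproducible under `set.seed()`.
#'
#' @param y Named non-negative integer vector of region counts for one
#'   sample (names are region ids).
#' @param affected_regions Character vector of region ids to thin.
#' @param p Retention probability in `(0, 1]`.
#' @return The downsampled named count vector.
#' @export
downsample_counts <- function(y, affected_regions, p) {
  check_fraction(p, "p", lower_open = TRUE)
  if (p == 1) return(y)
  unknown <- setdiff(affected_regions, names(y))
  if (length(unknown) > 0) {
    abort(paste0("unknown region in affected set: '", unknown[1], "'"))
  }
  idx <- names(y) %in% affected_regions
  y[idx] <- stats::rbinom(sum(idx), size = y[idx], prob = p)
  y
}

#' Features containing at least one affected region
#'
#' A bin or sub-bin at any clustering level is considered affected when at
#' least one of its member regions carries the planted effect.
#'
#' @param affected_regions Character vector of affected region ids.
#' @param structure Cluster-structure tibble at the evaluated level.
#' @return Character vector of affected feature ids (sorted).
#' @export
mark_affected <- function(affected_regions, structure) {
  unknown <- setdiff(affected_regions, structure$region_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown region in affected set: '", unknown[1], "'"))
  }
  sort(unique(structure$subbin_id[structure$region_id %in% affected_regions]))
}

#' Configuration of a downsampling power experiment
#'
#' @param effect_level Name of the clustering level (in `structures`) where
#'   effects are planted.
#' @param eval_levels Names of the levels at which detection is evaluated.
#' @param n_samples_per_group Samples per group drawn each iteration
#'   (default 15).
#' @param effect_fraction Fraction of the effect level's sub-bins given an
#'   effect (default 0.10).
#' @param downsample_p Binomial retention probability (default `1/7`, an
#'   expected 7-fold change).
#' @param n_iterations Number of resampling iterations (default 100).
#' @param alpha FDR threshold for calling a detection (default 0.05).
#' @param min_presence Representativeness filter fraction (default 0.75).
#' @param seed Integer seed making the experiment reproducible.
#' @return A `finebin_power_config` list.
#' @export
power_config <- function(effect_level, eval_levels,
                         n_samples_per_group = 15, effect_fraction = 0.10,
                         downsample_p = 1 / 7, n_iterations = 100,
                         alpha = 0.05, min_presence = 0.75, seed = 1) {
  check_fraction(downsample_p, "downsample_p", lower_open = TRUE)
  check_fraction(effect_fraction, "effect_fraction", lower_open = TRUE)
  structure(list(
    effect_level = effect_level, eval_levels = eval_levels,
    n_samples_per_group = as.integer(n_samples_per_group),
    effect_fraction = effect_fraction, downsample_p = downsample_p,
    n_iterations = as.integer(n_iterations), alpha = alpha,
    min_presence = min_presence, seed = as.integer(seed)
  ), class = "finebin_power_config")
}

#' Run the binomial-downsampling power experiment
#'
#' Per iteration: draw `2 * n_samples_per_group` samples without
#' replacement and split them into two groups; select `effect_fraction` of
#' the sub-bins at the effect level and thin all counts of their member
#' regions in group 2 with `Binomial(Y, downsample_p)`; rebuild the
#' abundance matrix at every evaluated level (library-size offsets
#' recomputed after downsampling, on the unfiltered matrix), apply the
#' representativeness filter and the differential-abundance test; record
#' per level the fraction of affected, tested features detected at
#' `FDR < alpha` (power) and the mean `|logFC|` of affected, tested
#' features (signal dilution). Affected features that the
#' representativeness filter removes are excluded from the power
#' denominator (they are undetectable by construction).
#'
#' @param region_counts Long count tibble (`sample_id`, `region_id`,
#'   `count`) for all available samples.
#' @param structures Named list of cluster-structure tibbles, one per
#'   level (e.g. `list("0.8" = ..., bin = ...)`).
#' @param config A [power_config()].
#' @return A `finebin_power` object: list with `summary` (tibble: `level`,
#'   `power`, `power_se`, `mean_abs_logfc`, `logfc_se`, `n_iterations`),
#'   `iterations` (per-iteration tibble) and `config`.
#' @export
run_power_experiment <- function(region_counts, structures, config) {
  if (!config$effect_level %in% names(structures)) {
    abort("`effect_level` not found in `structures`")
  }
  if (!all(config$eval_levels %in% names(structures))) {
    abort("all `eval_levels` must be present in `structures`")
  }
  samples <- sort(unique(region_counts$sample_id))
  need <- 2L * config$n_samples_per_group
  if (length(samples) < need) abort("not enough samples for the requested split")
  eff_struct <- structures[[config$effect_level]]
  eff_subbins <- sort(unique(eff_struct$subbin_id))
  n_eff <- max(1L, round(config$effect_fraction * length(eff_subbins)))
  counts_wide <- tidyr::pivot_wider(region_counts, id_cols = "region_id",
                                    names_from = "sample_id",
                                    values_from = "count", values_fill = 0L)

  iter_rows <- with_seed(config$seed, purrr::map(seq_len(config$n_iterations), function(it) {
    chosen <- sample(samples, need)
    g1 <- chosen[seq_len(config$n_samples_per_group)]
    g2 <- chosen[config$n_samples_per_group + seq_len(config$n_samples_per_group)]
    affected_sb <- sort(sample(eff_subbins, n_eff))
    affected_regions <- sort(unique(
      eff_struct$region_id[eff_struct$subbin_id %in% affected_sb]))
    cw <- counts_wide[, c("region_id", g1, g2)]
    for (s in g2) {
      v <- stats::setNames(cw[[s]], cw$region_id)
      cw[[s]] <- unname(downsample_counts(v, affected_regions,
                                          config$downsample_p))
    }
    long <- tidyr::pivot_longer(cw, -"region_id", names_to = "sample_id",
                                values_to = "count")
    design <- make_design(c(g1, g2),
                          factor(rep(c("group1", "group2"), each = length(g1)),
                                 levels = c("group1", "group2")))
    purrr::map_dfr(config$eval_levels, function(lev) {
      m <- build_matrix(long, structures[[lev]])
      tot <- colSums(abundance_counts(m))
      des <- design
      des$offset <- log(pmax(tot[des$sample_id], 1))
      mf <- representativeness_filter(m, config$min_presence)
      affected_feats <- mark_affected(affected_regions, structures[[lev]])
      tested_affected <- intersect(affected_feats, mf$feature_id)
      if (nrow(mf) == 0 || length(tested_affected) == 0) {
        return(tibble(iteration = it, level = lev, power = NA_real_,
                      mean_abs_logfc = NA_real_, n_affected_tested = 0L))
      }
      da <- run_differential_abundance(mf, des, alpha = config$alpha)
      detected <- da$feature_id[da$significant]
      aff_rows <- da[da$feature_id %in% tested_affected, ]
      tibble(
        iteration = it, level = lev,
        power = length(intersect(detected, tested_affected)) /
          length(tested_affected),
        mean_abs_logfc = mean(abs(aff_rows$logFC)),
        n_affected_tested = length(tested_affected)
      )
    })
  }))
  iterations <- bind_rows(iter_rows)
  summ <- iterations %>%
    group_by(.data$level) %>%
    summarise(
      power_se = stats::sd(.data$power, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$power))),
      logfc_se = stats::sd(.data$mean_abs_logfc, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$mean_abs_logfc))),
      power = mean(.data$power, na.rm = TRUE),
      mean_abs_logfc = mean(.data$mean_abs_logfc, na.rm = TRUE),
      n_iterations = dplyr::n(), .groups = "drop"
    ) %>%
    select("level", "power", "power_se", "mean_abs_logfc", "logfc_se",
           "n_iterations") %>%
    arrange(match(.data$level, config$eval_levels))
  structure(list(summary = summ, iterations = iterations, config = config),
            class = "finebin_power")
}

#' @export
tidy.finebin_power <- function(x, ...) x$summary

#' @export
glance.finebin_power <- function(x, ...) {
  tibble(n_levels = nrow(x$summary), n_iterations = x$config$n_iterations,
         effect_level = x$config$effect_level,
         downsample_p = x$config$downsample_p, alpha = x$config$alpha)
}

#' @export
print.finebin_power <- function(x, ...) {
  cat(sprintf(
    "Downsampling power experiment: effect at level '%s', p = %.4g, %d iterations\n",
    x$config$effect_level, x$config$downsample_p, x$config$n_iterations))
  print(x$summary, ...)
  invisible(x)
}

#' Plot power and fold-change dilution across clustering levels
#'
#' @param object A `finebin_power` object.
#' @param ... Unused.
#' @return A ggplot object with one panel for detection power and one for
#'   the mean absolute log fold change of affected features, by level.
#' @export
autoplot.finebin_power <- function(object, ...) {
  d <- object$summary %>%
    mutate(level = factor(.data$level, levels = object$config$eval_levels)) %>%
    tidyr::pivot_longer(c("power", "mean_abs_logfc"),
                        names_to = "metric", values_to = "value") %>%
    mutate(se = ifelse(.data$metric == "power", .data$power_se, .data$logfc_se),
           metric = dplyr::recode(.data$metric, power = "Power (FDR < alpha)",
                                  mean_abs_logfc = "Mean |logFC| of affected"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$se,
                                        ymax = .data$value + .data$se),
                           width = 0.2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "clustering level", y = NULL) +
    ggplot2::theme_minimal()
}
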