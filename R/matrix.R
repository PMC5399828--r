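#' Roll region counts up into a bin or sub-bin abundance matrix
#'
#' A sub-bin's count in a sample is the sum of the counts of its member
#' regions; at the bin level (structure from [bin_structure()]) it is the
#' sum over all the domain's regions. Every feature of the structure
#' appears in the matrix (zero-filled where unobserved), so bin counts
#' equal the sum of their sub-bin counts at any cutoff.
#'
#' @param counts Long count tibble with columns `sample_id`, `region_id`,
#'   `count` covering all samples (see [count_overlaps()]).
#' @param structure A single-level cluster-structure tibble
#'   ([cluster_domains()] or [bin_structure()]).
#' @return A wide abundance tibble: column `feature_id` then one integer
#'   column per sample (sorted sample ids); attribute `level` is the
#'   clustering cutoff or `"bin"`.
#' @export
build_matrix <- function(counts, structure) {
  unknown <- setdiff(unique(counts$region_id), structure$region_id)
  if (length(unknown) > 0) {
    abort(paste0("counts contain region '", unknown[1],
                 "' absent from the cluster structure"))
  }
  lev <- unique(structure$cutoff)
  if (length(lev) != 1) abort("`structure` must contain a single level")
  samples <- sort(unique(counts$sample_id))
  joined <- counts %>%
    left_join(structure %>% select("subbin_id", "region_id"),
              by = "region_id", relationship = "many-to-many") %>%
    group_by(.data$subbin_id, .data$sample_id) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  features <- sort(unique(structure$subbin_id))
  wide <- tidyr::pivot_wider(joined, id_cols = "subbin_id",
                             names_from = "sample_id",
                             values_from = "count", values_fill = 0L)
  wide <- wide[match(features, wide$subbin_id), , drop = FALSE]
  missing_feat <- is.na(wide$subbin_id)
  wide$subbin_id[missing_feat] <- features[missing_feat]
  wide[is.na(wide)] <- 0L
  out <- tibble(feature_id = wide$subbin_id)
  for (s in samples) {
    out[[s]] <- if (s %in% names(wide)) as.integer(wide[[s]]) else 0L
  }
  attr(out, "level") <- if (is.na(lev)) "bin" else lev
  out
}

abundance_samples <- function(m) setdiff(names(m), "feature_id")

abundance_counts <- function(m) {
  as.matrix(m[, abundance_samples(m), drop = FALSE])
}

#' Keep features represented in a minimum fraction of samples
#'
#' A feature is "represented" in a sample when its count is positive; it
#' is kept when it is represented in at least `min_frac` of all samples
#' (inclusive: 6 of 8 samples passes at 0.75). The sample set is
#' unchanged.
#'
#' @param m Abundance tibble (see [build_matrix()]).
#' @param min_frac Required presence fraction in `(0, 1]` (default 0.75).
#' @return The filtered abundance tibble (attributes preserved).
#' @export
representativeness_filter <- function(m, min_frac = 0.75) {
  check_fraction(min_frac, "min_frac", lower_open = TRUE)
  cm <- abundance_counts(m)
  keep <- rowMeans(cm > 0) >= min_frac
  out <- m[keep, , drop = FALSE]
  attr(out, "level") <- attr(m, "level")
  out
}

#' Read / write an abundance matrix as TSV
#'
#' Features in rows (`feature_id` column), samples in columns with a
#' header row of sample ids.
#'
#' @param m Abundance tibble.
#' @param path File path.
#' @param level Level tag to attach on read (`"bin"` or a cutoff).
#' @return `write_abundance_matrix()` returns `path` invisibly;
#'   `read_abundance_matrix()` returns the abundance tibble.
#' @export
write_abundance_matrix <- function(m, path) {
  readr::write_tsv(m, path)
  invisible(path)
}

#' @rdname write_abundance_matrix
#' @export
read_abundance_matrix <- function(path, level = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(), .default = readr::col_integer()))
  out <- as_tibble(df)
  attr(out, "level") <- level
  out
}
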