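#' Global pairwise amino-acid identity
#'
#' Fraction of identical aligned residue pairs over the total number of
#' alignment columns (internal and terminal gap columns included) under a
#' global alignment with fixed scoring: match `+1`, mismatch `-1`, gap of
#' length L costs `5 + L`. Among co-optimal alignments the one with the
#' most identical pairs (then the fewest columns) defines the identity, so
#' the value is a deterministic function of the sequence pair.
#'
#' @param a,b Non-empty amino-acid strings.
#' @return A single number in `[0, 1]`; symmetric in its arguments.
#' @examples
#' pairwise_identity("MKV", "MKV") # 1
#' pairwise_identity("AAAA", "CCCC") # 0
#' @export
pairwise_identity <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 || length(b) != 1 ||
      is.na(a) || is.na(b) || nchar(a) == 0 || nchar(b) == 0) {
    abort("`a` and `b` must be single non-empty strings")
  }
  unname(.gotoh_identity_cpp(a, b)[["identity"]])
}

# Identity of one query against many subjects (C++ kernel, no per-call
# validation).
identity_many <- function(query, subjects) {
  vapply(subjects, function(s) .gotoh_identity_cpp(query, s)[["identity"]],
         numeric(1), USE.NAMES = FALSE)
}

order_by_length <- function(sequences) {
  ids <- names(sequences)
  ids[order(-nchar(sequences), ids)]
}

#' Greedy centroid clustering of domain sequences
#'
#' Centroid-based clustering in the style of UCLUST: sequences are
#' processed in decreasing length order (ties by id) and each sequence
#' joins the first existing centroid with identity at or above `cutoff`
#' (`assign = "best"` joins the best-matching qualifying centroid instead);
#' otherwise it founds a new cluster with itself as centroid.
#'
#' @param sequences Named character vector (or `AAStringSet`) of amino-acid
#'   sequences of one domain, named by region id.
#' @param cutoff Identity cutoff in `(0, 1]`.
#' @param assign `"first"` (default, UCLUST semantics) or `"best"`.
#' @return A tibble with columns `cluster` (integer, founding order),
#'   `centroid_region_id`, `region_id`, `identity` (to the centroid), in
#'   processing order. Empty input yields an empty tibble.
#' @export
greedy_centroid_cluster <- function(sequences, cutoff, assign = c("first", "best")) {
  assign <- match.arg(assign)
  sequences <- as_aa_vector(sequences)
  check_fraction(cutoff, "cutoff", lower_open = TRUE)
  if (length(sequences) == 0) {
    return(tibble(cluster = integer(), centroid_region_id = character(),
                  region_id = character(), identity = double()))
  }
  ord <- order_by_length(sequences)
  centroid_ids <- character(0)
  rows <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    id <- ord[i]
    hit <- NA_integer_
    ident <- 1
    if (length(centroid_ids) > 0) {
      if (assign == "first") {
        for (ci in seq_along(centroid_ids)) {
          v <- .gotoh_identity_cpp(sequences[[id]],
                                   sequences[[centroid_ids[ci]]])[["identity"]]
          if (v >= cutoff) {
            hit <- ci
            ident <- v
            break
          }
        }
      } else {
        v <- identity_many(sequences[[id]], sequences[centroid_ids])
        if (any(v >= cutoff)) {
          hit <- which.max(v)
          ident <- v[hit]
        }
      }
    }
    if (is.na(hit)) {
      centroid_ids <- c(centroid_ids, id)
      hit <- length(centroid_ids)
      ident <- 1
    }
    rows[[i]] <- tibble(cluster = hit, centroid_region_id = centroid_ids[hit],
                        region_id = id, identity = ident)
  }
  bind_rows(rows)
}

#' Complete-linkage hierarchical clustering of domain sequences
#'
#' Agglomerative clustering on distance `1 - identity` with complete
#' linkage, cut at distance `1 - cutoff`, so every returned cluster has
#' maximum within-cluster distance at most `1 - cutoff`. Agglomeration
#' merges the pair of clusters at minimum complete-linkage distance; exact
#' ties are broken by the smallest pair of cluster indices (clusters
#' indexed by their smallest member in id-sorted order). Intended for small
#' bins: the full quadratic distance matrix is computed.
#'
#' @inheritParams greedy_centroid_cluster
#' @return A tibble as in [greedy_centroid_cluster()]; the centroid of a
#'   cluster is its longest member (ties by id). The `identity` column is
#'   the identity of each member to that centroid.
#' @export
hierarchical_cluster <- function(sequences, cutoff) {
  sequences <- as_aa_vector(sequences)
  check_fraction(cutoff, "cutoff", lower_open = TRUE)
  if (length(sequences) == 0) {
    return(tibble(cluster = integer(), centroid_region_id = character(),
                  region_id = character(), identity = double()))
  }
  ids <- sort(names(sequences))
  n <- length(ids)
  d <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      v <- identity_many(sequences[[ids[i]]], sequences[ids[(i + 1):n]])
      d[i, (i + 1):n] <- 1 - v
      d[(i + 1):n, i] <- 1 - v
    }
  }
  members <- as.list(seq_len(n))
  h <- 1 - cutoff + 1e-12 # tolerate representation error at the cut
  repeat {
    k <- length(members)
    if (k == 1) break
    best <- NULL
    best_d <- Inf
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        dd <- max(d[members[[i]], members[[j]]])
        if (dd < best_d - 1e-15) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    if (best_d > h) break
    members[[best[1]]] <- sort(c(members[[best[1]]], members[[best[2]]]))
    members[best[2]] <- NULL
  }
  # stable cluster numbering: by smallest member index
  members <- members[order(vapply(members, min, integer(1)))]
  bind_rows(purrr::imap(members, function(ix, ci) {
    mem <- ids[ix]
    cen <- mem[order(-nchar(sequences[mem]), mem)][1]
    tibble(cluster = as.integer(ci), centroid_region_id = cen,
           region_id = mem,
           identity = identity_many(sequences[[cen]], sequences[mem]))
  }))
}

as_aa_vector <- function(sequences) {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) == 0) return(character(0))
  if (is.null(names(sequences)) || any(names(sequences) == "") ||
      anyDuplicated(names(sequences))) {
    abort("sequences must be uniquely named by region id")
  }
  if (any(nchar(sequences) == 0)) abort("empty sequence")
  sequences
}

#' Cluster every functional bin into sub-bins
#'
#' Applies [greedy_centroid_cluster()] (or [hierarchical_cluster()]) to the
#' amino-acid sequences of each domain at one identity cutoff, producing
#' the cluster structure used to roll region counts up into sub-bins.
#' Sub-bin ids are `<domain_id>_<cutoff>_<cluster index>`.
#'
#' @param regions Annotated-region tibble (needs `region_id`, `domain_id`,
#'   `aa_sequence`).
#' @param cutoff Identity cutoff in `(0, 1]`.
#' @param method `"greedy"` or `"hierarchical"`.
#' @return A cluster-structure tibble with columns `domain_id`, `cutoff`,
#'   `subbin_id`, `centroid` (logical), `region_id`, ordered by domain then
#'   cluster index; one row per region.
#' @export
cluster_domains <- function(regions, cutoff, method = c("greedy", "hierarchical")) {
  method <- match.arg(method)
  fun <- if (method == "greedy") greedy_centroid_cluster else hierarchical_cluster
  doms <- sort(unique(regions$domain_id))
  bind_rows(purrr::map(doms, function(d) {
    sub <- regions[regions$domain_id == d, ]
    seqs <- stats::setNames(sub$aa_sequence, sub$region_id)
    cl <- fun(seqs, cutoff)
    cl %>%
      arrange(.data$cluster, .data$region_id) %>%
      mutate(
        domain_id = d, cutoff = cutoff,
        subbin_id = paste0(d, "_", format_cutoff(cutoff), "_", .data$cluster),
        centroid = .data$region_id == .data$centroid_region_id
      ) %>%
      select("domain_id", "cutoff", "subbin_id", "centroid", "region_id")
  }))
}

#' Bin-level structure of an annotation
#'
#' The degenerate one-cluster-per-domain structure, letting the bin level
#' be treated uniformly with sub-bin levels in roll-up and power analyses.
#'
#' @param regions Annotated-region tibble (or a cluster structure, whose
#'   `domain_id`/`region_id` pairs are reused).
#' @return A cluster-structure tibble with `subbin_id = domain_id` and
#'   `cutoff = NA`.
#' @export
bin_structure <- function(regions) {
  distinct(tibble(
    domain_id = regions$domain_id,
    cutoff = NA_real_,
    subbin_id = regions$domain_id,
    centroid = FALSE,
    region_id = regions$region_id
  ))
}

#' Fraction of fine sub-bins nested within a single coarse sub-bin
#'
#' For two cluster structures over the same region universe, the fraction
#' of sub-bins of the finer (higher-cutoff) structure whose member set is
#' wholly contained in one sub-bin of the coarser structure ("perfect
#' subsets"). Centroid clustering is not hierarchical, so this need not be
#' 1.
#'
#' @param fine,coarse Cluster-structure tibbles; `fine` must have the
#'   higher cutoff.
#' @return A fraction in `[0, 1]`.
#' @export
subset_consistency <- function(fine, coarse) {
  fc <- unique(fine$cutoff)
  cc <- unique(coarse$cutoff)
  if (length(fc) == 1 && length(cc) == 1 && !anyNA(c(fc, cc)) && fc < cc) {
    abort("`fine` must not have a lower cutoff than `coarse`")
  }
  if (!setequal(fine$region_id, coarse$region_id)) {
    abort("cluster structures cover different region universes")
  }
  coarse_of <- stats::setNames(coarse$subbin_id, coarse$region_id)
  per_fine <- split(coarse_of[fine$region_id], fine$subbin_id)
  mean(vapply(per_fine, function(v) length(unique(v)) == 1L, logical(1)))
}

#' Read / write the cluster-structure file
#'
#' Tab-separated, one row per member region: `domain_id`, `cutoff`,
#' `subbin_id`, `centroid_flag` (0/1), `region_id`. The writer is
#' deterministic (fixed row order) so identical structures produce
#' byte-identical files.
#'
#' @param structure Cluster-structure tibble.
#' @param path File path.
#' @return `write_cluster_structure()` returns `path` invisibly;
#'   `read_cluster_structure()` returns the structure tibble.
#' @export
write_cluster_structure <- function(structure, path) {
  df <- structure %>%
    arrange(.data$domain_id, .data$subbin_id, .data$region_id) %>%
    mutate(centroid_flag = as.integer(.data$centroid),
           cutoff = ifelse(is.na(.data$cutoff), "bin",
                           vapply(.data$cutoff, format_cutoff, character(1)))) %>%
    select("domain_id", "cutoff", "subbin_id", "centroid_flag", "region_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_cluster_structure
#' @export
read_cluster_structure <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    domain_id = readr::col_character(), cutoff = readr::col_character(),
    subbin_id = readr::col_character(), centroid_flag = readr::col_integer(),
    region_id = readr::col_character()))
  tibble(
    domain_id = df$domain_id,
    cutoff = suppressWarnings(as.numeric(ifelse(df$cutoff == "bin", NA, df$cutoff))),
    subbin_id = df$subbin_id,
    centroid = df$centroid_flag == 1L,
    region_id = df$region_id
  )
}
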