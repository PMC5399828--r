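test_that("greedy clustering handles degenerate inputs", {
  five <- setNames(rep("MKVLLDTT", 5), paste0("s", 1:5))
  cl <- greedy_centroid_cluster(five, 0.75)
  expect_equal(length(unique(cl$cluster)), 1)
  expect_equal(nrow(cl), 5)
  three <- c(a = "AAAAAAAA", b = "CCCCCCCC", c = "DDDDDDDD")
  cl3 <- greedy_centroid_cluster(three, 0.5)
  expect_equal(length(unique(cl3$cluster)), 3)
  expect_equal(nrow(greedy_centroid_cluster(character(0), 0.5)), 0)
})

test_that("planted families are recovered at an intermediate cutoff", {
  fam <- make_domain_families(n_domains = 1, families_per_domain = 3,
                              members_per_family = 10, within_id = 0.9,
                              between_id = 0.4, seed = 31)
  seqs <- setNames(fam$sequences$aa_sequence, fam$sequences$region_id)
  cl <- greedy_centroid_cluster(seqs, 0.75)
  got <- partition_of(cl)
  want <- lapply(split(fam$sequences$region_id, fam$sequences$family), sort)
  names(want) <- NULL
  want <- want[order(vapply(want, `[[`, character(1), 1))]
  expect_equal(got, want)
})

test_that("greedy clustering matches an independent oracle on random inputs", {
  set.seed(32)
  for (rep in 1:25) {
    n <- sample(5:9, 1)
    seqs <- setNames(vapply(seq_len(n), function(i)
      random_aa_str(sample(8:20, 1)), character(1)), paste0("s", 1:n))
    # mix in near-duplicates so non-trivial clusters form
    seqs[n] <- paste0(substr(seqs[[1]], 1, nchar(seqs[[1]]) - 1), "A")
    cutoff <- runif(1, 0.3, 0.9)
    cl <- greedy_centroid_cluster(seqs, cutoff)
    expect_equal(partition_of(cl), oracle_greedy(seqs, cutoff))
  }
})

test_that("all greedy members reach the cutoff against their centroid", {
  fam <- make_domain_families(n_domains = 1, families_per_domain = 2,
                              members_per_family = 8, within_id = 0.85,
                              seed = 33)
  seqs <- setNames(fam$sequences$aa_sequence, fam$sequences$region_id)
  cl <- greedy_centroid_cluster(seqs, 0.6)
  expect_true(all(cl$identity >= 0.6))
  for (i in seq_len(nrow(cl))) {
    expect_gte(pairwise_identity(seqs[[cl$region_id[i]]],
                                 seqs[[cl$centroid_region_id[i]]]), 0.6)
  }
})

test_that("cutoff 1 on distinct sequences yields singletons", {
  set.seed(34)
  seqs <- setNames(vapply(1:6, function(i) random_aa_str(15), character(1)),
                   paste0("s", 1:6))
  stopifnot(!anyDuplicated(seqs))
  cl <- greedy_centroid_cluster(seqs, 1)
  expect_equal(length(unique(cl$cluster)), 6)
})

test_that("hierarchical clusters respect the complete-linkage guarantee", {
  set.seed(35)
  seqs <- setNames(vapply(1:12, function(i) random_aa_str(sample(10:18, 1)),
                          character(1)), sprintf("s%02d", 1:12))
  seqs[7] <- seqs[1]
  cutoff <- 0.4
  cl <- hierarchical_cluster(seqs, cutoff)
  for (cid in unique(cl$cluster)) {
    mem <- cl$region_id[cl$cluster == cid]
    if (length(mem) > 1) {
      pairs <- utils::combn(mem, 2)
      dmax <- max(vapply(seq_len(ncol(pairs)), function(j)
        1 - pairwise_identity(seqs[[pairs[1, j]]], seqs[[pairs[2, j]]]),
        numeric(1)))
      expect_lte(dmax, 1 - cutoff + 1e-9)
    }
  }
  ident <- setNames(rep("MMMM", 4), paste0("s", 1:4))
  expect_equal(length(unique(hierarchical_cluster(ident, 0.9)$cluster)), 1)
})

test_that("hierarchical clustering matches a Lance-Williams oracle", {
  set.seed(36)
  for (rep in 1:20) {
    n <- sample(6:9, 1)
    seqs <- setNames(vapply(seq_len(n), function(i)
      random_aa_str(sample(8:16, 1)), character(1)), paste0("s", 1:n))
    seqs[n] <- paste0(substr(seqs[[2]], 1, nchar(seqs[[2]]) - 2), "AC")
    cutoff <- runif(1, 0.3, 0.8)
    cl <- hierarchical_cluster(seqs, cutoff)
    expect_equal(partition_of(cl), oracle_complete_linkage(seqs, cutoff),
                 info = paste("rep", rep))
  }
})

test_that("hierarchical agreement with hclust on unique-distance fixtures", {
  fam <- make_domain_families(n_domains = 1, families_per_domain = 3,
                              members_per_family = 5, within_id = 0.9,
                              seed = 37)
  seqs <- setNames(fam$sequences$aa_sequence, fam$sequences$region_id)
  ids <- sort(names(seqs))
  d <- matrix(0, length(ids), length(ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j) {
        d[i, j] <- d[j, i] <- 1 - pairwise_identity(seqs[[ids[i]]], seqs[[ids[j]]])
      }
    }
  }
  ct <- stats::cutree(stats::hclust(stats::as.dist(d), method = "complete"),
                      h = 1 - 0.75)
  cl <- hierarchical_cluster(seqs, 0.75)
  got <- partition_of(cl)
  want <- lapply(split(ids, ct), sort)
  names(want) <- NULL
  want <- want[order(vapply(want, `[[`, character(1), 1))]
  expect_equal(got, want)
})

test_that("every region lands in exactly one sub-bin per cutoff", {
  fam <- make_domain_families(n_domains = 2, families_per_domain = 2,
                              members_per_family = 4, within_id = 0.9, seed = 38)
  regions <- tibble::tibble(
    region_id = fam$sequences$region_id,
    domain_id = fam$sequences$domain_id,
    aa_sequence = fam$sequences$aa_sequence)
  for (cutoff in c(0.5, 0.75)) {
    st <- cluster_domains(regions, cutoff)
    expect_setequal(st$region_id, regions$region_id)
    expect_equal(anyDuplicated(st$region_id), 0)
    expect_true(all(startsWith(
      st$subbin_id, paste0(st$domain_id, "_", sprintf("%g", cutoff)))))
    # one centroid per sub-bin, and the centroid is a member
    per <- split(st$centroid, st$subbin_id)
    expect_true(all(vapply(per, sum, integer(1)) == 1L))
  }
})

test_that("cluster structures round-trip through the TSV file byte-identically", {
  fam <- make_domain_families(n_domains = 1, families_per_domain = 2,
                              members_per_family = 4, within_id = 0.9, seed = 39)
  regions <- tibble::tibble(
    region_id = fam$sequences$region_id,
    domain_id = fam$sequences$domain_id,
    aa_sequence = fam$sequences$aa_sequence)
  st <- cluster_domains(regions, 0.75)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_structure(st, f1)
  write_cluster_structure(cluster_domains(regions, 0.75), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_cluster_structure(f1)
  expect_equal(as.data.frame(back[order(back$region_id), ]),
               as.data.frame(st[order(st$region_id), ]),
               ignore_attr = TRUE)
})

test_that("subset consistency is 1 for nested and 0 for split structures", {
  mk <- function(cutoff, assign) {
    tibble::tibble(domain_id = "D", cutoff = cutoff,
                   subbin_id = paste0("D_", cutoff, "_", assign),
                   centroid = FALSE, region_id = names(assign))
  }
  fine <- mk(0.9, c(a = 1, b = 2))
  coarse <- mk(0.5, c(a = 1, b = 1))
  expect_equal(subset_consistency(fine, coarse), 1)
  expect_equal(subset_consistency(mk(0.9, c(a = 1, b = 1)),
                                  mk(0.5, c(a = 1, b = 2))), 0)
  expect_equal(subset_consistency(fine, fine), 1)
  expect_error(subset_consistency(fine, mk(0.5, c(a = 1, z = 1))), "universe")
})

test_that("planted families are nested across cutoffs by construction", {
  fam <- make_domain_families(n_domains = 2, families_per_domain = 3,
                              members_per_family = 5, within_id = 0.9, seed = 40)
  regions <- tibble::tibble(
    region_id = fam$sequences$region_id,
    domain_id = fam$sequences$domain_id,
    aa_sequence = fam$sequences$aa_sequence)
  fine <- cluster_domains(regions, 0.9 * 0.95) # just under the within-id target
  coarse <- cluster_domains(regions, 0.5)
  expect_equal(subset_consistency(fine, coarse), 1)
})
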