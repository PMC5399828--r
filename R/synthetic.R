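# Synthetic-data generator: fully specified toy metagenomes with truth
# manifests, so every pipeline stage is testable without external data.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

random_nt <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                                 collapse = "")

# Substitute a fraction `d` of positions (distinct, random) with a
# different residue drawn from `alphabet`.
mutate_string <- function(s, d, alphabet) {
  chars <- strsplit(s, "")[[1]]
  n_mut <- round(d * length(chars))
  if (n_mut == 0) return(s)
  pos <- sample(length(chars), n_mut)
  for (i in pos) {
    chars[i] <- sample(setdiff(alphabet, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate planted domain families of amino-acid sequences
#'
#' For every domain, `families_per_domain` independent random ancestor
#' sequences (length drawn from `len_range`) are each expanded into
#' `members_per_family` members by substituting a fraction
#' `(1 - within_id) / 2` of positions per member, so that the expected
#' pairwise identity within a family is close to `within_id` while
#' between-family identity stays near the random-sequence background.
#' Realized within-family identities are recorded in the manifest.
#'
#' @param n_domains,families_per_domain,members_per_family Counts.
#' @param within_id Target within-family pairwise identity (in
#'   `(0.5, 1]`; substitution-only mutation cannot reliably reach lower
#'   targets).
#' @param between_id Expected ceiling on between-family identity; must be
#'   below `within_id` (used only for feasibility checking).
#' @param len_range Ancestor length range (default 120-300 residues).
#' @param seed Optional integer seed (local RNG stream).
#' @return A list with `sequences` (tibble: `domain_id`, `family`,
#'   `region_id`, `aa_sequence`) and `manifest` (parameters plus a
#'   `families` tibble with realized mean within-family identity).
#' @export
make_domain_families <- function(n_domains = 2, families_per_domain = 3,
                                 members_per_family = 5, within_id = 0.9,
                                 between_id = 0.4, len_range = c(120, 300),
                                 seed = NULL) {
  if (between_id >= within_id) {
    abort("infeasible identity targets: `between_id` must be below `within_id`")
  }
  if (within_id <= 0.5 || within_id > 1) {
    abort("infeasible identity target: `within_id` must lie in (0.5, 1]")
  }
  with_seed(seed, {
    d <- (1 - within_id) / 2
    rows <- list()
    fam_rows <- list()
    for (dm in seq_len(n_domains)) {
      domain_id <- sprintf("DOM%04d", dm)
      for (f in seq_len(families_per_domain)) {
        len <- sample(seq(len_range[1], len_range[2]), 1)
        anc <- random_aa(len)
        members <- vapply(seq_len(members_per_family),
                          function(i) mutate_string(anc, d, AA20), character(1))
        ids <- sprintf("%s_fam%d_m%d", domain_id, f, seq_len(members_per_family))
        rows[[length(rows) + 1]] <- tibble(
          domain_id = domain_id, family = f, region_id = ids,
          aa_sequence = members)
        realized <- if (members_per_family > 1) {
          pairs <- utils::combn(members_per_family, 2)
          mean(vapply(seq_len(ncol(pairs)), function(j) {
            pairwise_identity(members[pairs[1, j]], members[pairs[2, j]])
          }, numeric(1)))
        } else 1
        fam_rows[[length(fam_rows) + 1]] <- tibble(
          domain_id = domain_id, family = f, ancestor_length = len,
          n_members = members_per_family, realized_within_identity = realized)
      }
    }
    list(
      sequences = bind_rows(rows),
      manifest = list(
        within_id = within_id, between_id = between_id,
        n_domains = n_domains, families_per_domain = families_per_domain,
        members_per_family = members_per_family,
        families = bind_rows(fam_rows)
      )
    )
  })
}

reverse_translate <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  vapply(strsplit(aa, ""), function(chars) {
    paste(vapply(chars, function(a) sample(by_aa[[a]], 1), character(1)),
          collapse = "")
  }, character(1))
}

#' Embed planted families in contigs and simulate per-sample reads
#'
#' Each family member is reverse-translated (uniform codon choice, so the
#' translation round-trips exactly) and embedded in its own contig between
#' random background flanks, on a random strand and frame. Reads of length
#' `read_length` are drawn per sample: a Poisson number per annotated
#' region (uniform start within the region, either read strand) plus a
#' Poisson number of background reads per contig drawn from the flanks, so
#' at `error_rate = 0` region counts from true placements equal the
#' Poisson draws exactly. A fraction `lowq_read_fraction` of reads is
#' given 60% of bases at Q2 (the rest Q35), so the default quality filter
#' removes exactly those reads; all other bases are Q35.
#'
#' @param families Output of [make_domain_families()].
#' @param n_samples Number of samples to simulate.
#' @param reads_per_region_mean Poisson mean of reads per region and
#'   sample (default 20).
#' @param background_reads_mean Poisson mean of background reads per
#'   contig and sample (default 5).
#' @param error_rate Per-base substitution probability in reads.
#' @param lowq_read_fraction Fraction of reads planted as low quality.
#' @param read_length Read length (default 100).
#' @param flank_length Background flank on each side of the embedded
#'   domain (default 150; must be at least `read_length`).
#' @param seed Optional integer seed (local RNG stream).
#' @return A list: `refs` (reference tibble), `regions` (annotated-region
#'   tibble), `hits` (equivalent domain-hit tibble, e.g. for
#'   [write_domtblout()]), `reads` (named list of per-sample read
#'   tibbles) and `manifest` (list with `provenance`, `region_counts` and
#'   `lowq_reads`).
#' @export
make_reference_and_reads <- function(families, n_samples = 2,
                                     reads_per_region_mean = 20,
                                     background_reads_mean = 5,
                                     error_rate = 0, lowq_read_fraction = 0,
                                     read_length = 100, flank_length = 150,
                                     seed = NULL) {
  check_fraction(error_rate, "error_rate")
  check_fraction(lowq_read_fraction, "lowq_read_fraction")
  if (flank_length < read_length) {
    abort("`flank_length` must be at least `read_length`")
  }
  seqs <- families$sequences
  with_seed(seed, {
    nt <- reverse_translate(seqs$aa_sequence)
    n <- nrow(seqs)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    # shift start by 0-2 bases to exercise all reading frames
    shift <- sample(0:2, n, replace = TRUE)
    contig_id <- sprintf("contig%04d", seq_len(n))
    contigs <- character(n)
    nt_start <- integer(n)
    for (i in seq_len(n)) {
      emb <- if (strand[i] == "+") nt[i] else reverse_complement_chr(nt[i])
      contigs[i] <- paste0(random_nt(flank_length + shift[i]), emb,
                           random_nt(flank_length))
      nt_start[i] <- flank_length + shift[i]
    }
    nt_end <- nt_start + nchar(nt)
    refs <- tibble(id = contig_id, sequence = contigs)
    regions <- tibble(
      region_id = paste0(contig_id, ":", seqs$domain_id, ":", nt_start + 1L,
                         "-", nt_end, ":", strand),
      reference_id = contig_id, domain_id = seqs$domain_id,
      nt_start = as.integer(nt_start), nt_end = as.integer(nt_end),
      strand = strand, aa_sequence = seqs$aa_sequence
    )
    # equivalent hit coordinates on the translated frames
    L <- nchar(contigs)
    a0 <- ifelse(strand == "+", nt_start, L - nt_end) # start on read frame strand
    frame_k <- (a0 %% 3L) + 1L
    aa_start <- (a0 - (frame_k - 1L)) %/% 3L + 1L
    aa_len <- nchar(seqs$aa_sequence)
    hits <- tibble(
      reference_id = contig_id, domain_id = seqs$domain_id,
      frame = as.integer(ifelse(strand == "+", frame_k, -frame_k)),
      aa_start = as.integer(aa_start),
      aa_end = as.integer(aa_start + aa_len - 1L),
      evalue = 1e-20, bitscore = 100
    )

    sample_ids <- sprintf("S%02d", seq_len(n_samples))
    prov_rows <- list()
    count_rows <- list()
    reads <- list()
    for (sm in sample_ids) {
      rows <- list()
      for (i in seq_len(n)) {
        n_reads <- stats::rpois(1, reads_per_region_mean)
        count_rows[[length(count_rows) + 1]] <- tibble(
          sample_id = sm, region_id = regions$region_id[i],
          count = as.integer(n_reads))
        if (n_reads > 0) {
          starts <- sample(seq(nt_start[i], nt_end[i] - read_length), n_reads,
                           replace = TRUE)
          rows[[length(rows) + 1]] <- tibble(
            origin = regions$region_id[i], reference_id = contig_id[i],
            start = as.integer(starts))
        }
        n_bg <- stats::rpois(1, background_reads_mean)
        if (n_bg > 0) {
          left <- stats::runif(n_bg) < 0.5
          starts <- ifelse(left,
                           sample.int(flank_length - read_length + 1L, n_bg,
                                      replace = TRUE) - 1L,
                           nt_end[i] + sample.int(flank_length - read_length + 1L,
                                                  n_bg, replace = TRUE) - 1L)
          rows[[length(rows) + 1]] <- tibble(
            origin = "background", reference_id = contig_id[i],
            start = as.integer(starts))
        }
      }
      placed <- bind_rows(rows)
      n_tot <- nrow(placed)
      read_id <- sprintf("%s_r%05d", sm, seq_len(n_tot))
      seq_fwd <- substr(contigs[match(placed$reference_id, contig_id)] %>%
                          unname(), placed$start + 1L, placed$start + read_length)
      rc <- stats::runif(n_tot) < 0.5
      read_seq <- ifelse(rc, reverse_complement_chr(seq_fwd), seq_fwd)
      if (error_rate > 0) {
        read_seq <- vapply(read_seq, function(s) {
          mutate_string(s, error_rate, c("A", "C", "G", "T"))
        }, character(1), USE.NAMES = FALSE)
      }
      lowq <- stats::runif(n_tot) < lowq_read_fraction
      qual <- vapply(lowq, function(is_low) {
        q <- rep(35L, read_length)
        if (is_low) q[sample(read_length, ceiling(0.6 * read_length))] <- 2L
        intToUtf8(q + 33L)
      }, character(1))
      reads[[sm]] <- tibble(read_id = read_id, sequence = read_seq,
                            quality = qual)
      prov_rows[[length(prov_rows) + 1]] <- tibble(
        sample_id = sm, read_id = read_id, origin = placed$origin,
        reference_id = placed$reference_id, start = placed$start,
        end = placed$start + read_length,
        strand = ifelse(rc, "-", "+"), low_quality = lowq)
    }
    provenance <- bind_rows(prov_rows)
    list(
      refs = refs, regions = regions, hits = hits, reads = reads,
      manifest = list(
        provenance = provenance,
        region_counts = bind_rows(count_rows),
        lowq_reads = provenance[provenance$low_quality,
                                c("sample_id", "read_id")],
        read_length = read_length, error_rate = error_rate,
        lowq_read_fraction = lowq_read_fraction
      )
    )
  })
}

#' Simulate a bin/sub-bin count matrix with overdispersed noise
#'
#' Counts are negative binomial with the given mean and dispersion
#' (`dispersion = 0` gives Poisson) around per-sample size factors
#' (log-normal, sd `size_factor_sd`); a random `effect_fraction` of
#' features has its group-2 mean divided by `fold`. The returned truth
#' table and design (with log size-factor offsets) make the generator an
#' oracle for the statistical module.
#'
#' @param n_features Number of features.
#' @param n_samples_per_group Samples per group (default 15).
#' @param mean Baseline mean count (default 100).
#' @param dispersion Negative-binomial dispersion; variance is
#'   `mu + dispersion * mu^2` (default 0.1).
#' @param effect_fraction Fraction of features with a planted effect.
#' @param fold Planted fold change (group 2 mean divided by `fold`).
#' @param size_factor_sd Log-normal sd of per-sample size factors.
#' @param seed Optional integer seed (local RNG stream).
#' @return A list: `matrix` (abundance tibble), `truth` (tibble:
#'   `feature_id`, `affected`, `true_logfc`) and `design` (tibble with
#'   `offset = log(size factor)`).
#' @export
make_count_matrix <- function(n_features = 500, n_samples_per_group = 15,
                              mean = 100, dispersion = 0.1,
                              effect_fraction = 0, fold = 1,
                              size_factor_sd = 0.2, seed = NULL) {
  check_fraction(effect_fraction, "effect_fraction")
  if (fold <= 0) abort("`fold` must be positive")
  with_seed(seed, {
    n_s <- 2L * n_samples_per_group
    sample_id <- sprintf("%s_%02d", rep(c("g1", "g2"), each = n_samples_per_group),
                         rep(seq_len(n_samples_per_group), 2))
    group2 <- rep(c(FALSE, TRUE), each = n_samples_per_group)
    sf <- exp(stats::rnorm(n_s, 0, size_factor_sd))
    feature_id <- sprintf("f%05d", seq_len(n_features))
    n_aff <- round(effect_fraction * n_features)
    affected <- seq_len(n_features) %in% sample(n_features, n_aff)
    mu <- outer(rep(mean, n_features), sf)
    mu[affected, group2] <- mu[affected, group2] / fold
    counts <- if (dispersion <= 0) {
      matrix(stats::rpois(length(mu), mu), nrow = n_features)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             nrow = n_features)
    }
    m <- tibble(feature_id = feature_id)
    for (j in seq_len(n_s)) m[[sample_id[j]]] <- as.integer(counts[, j])
    attr(m, "level") <- "simulated"
    list(
      matrix = m,
      truth = tibble(feature_id = feature_id, affected = affected,
                     true_logfc = ifelse(affected, -log(fold), 0)),
      design = make_design(sample_id,
                           factor(ifelse(group2, "group2", "group1"),
                                  levels = c("group1", "group2")),
                           offset = log(sf))
    )
  })
}

#' Nested cluster structures for dilution experiments
#'
#' Builds a region universe partitioned into sub-bins at a fine and a
#' coarse cutoff plus the bin level, nested by construction (every fine
#' sub-bin is a perfect subset of a coarse sub-bin, every coarse sub-bin of
#' its bin). Used to study how an effect planted at the fine level dilutes
#' toward the bin level.
#'
#' @param n_domains Number of domains (bins).
#' @param fine_per_domain Fine sub-bins per domain.
#' @param regions_per_subbin Regions per fine sub-bin.
#' @param coarse_group Number of fine sub-bins merged into one coarse
#'   sub-bin.
#' @param fine_cutoff,coarse_cutoff Cutoff labels for the two levels.
#' @return A named list of cluster-structure tibbles:
#'   `as.character(fine_cutoff)`, `as.character(coarse_cutoff)`, `"bin"`.
#' @export
make_nested_structures <- function(n_domains = 10, fine_per_domain = 4,
                                   regions_per_subbin = 3, coarse_group = 2,
                                   fine_cutoff = 0.8, coarse_cutoff = 0.5) {
  rows <- list()
  for (dm in seq_len(n_domains)) {
    domain_id <- sprintf("DOM%04d", dm)
    for (fb in seq_len(fine_per_domain)) {
      cb <- (fb - 1) %/% coarse_group + 1
      for (r in seq_len(regions_per_subbin)) {
        rows[[length(rows) + 1]] <- tibble(
          domain_id = domain_id,
          region_id = sprintf("%s_f%02d_r%02d", domain_id, fb, r),
          fine = fb, coarse = cb)
      }
    }
  }
  all <- bind_rows(rows)
  mk <- function(cutoff, idx) {
    tibble(domain_id = all$domain_id, cutoff = cutoff,
           subbin_id = paste0(all$domain_id, "_", format_cutoff(cutoff), "_", idx),
           centroid = FALSE, region_id = all$region_id)
  }
  out <- list(mk(fine_cutoff, all$fine), mk(coarse_cutoff, all$coarse),
              bin_structure(all))
  names(out) <- c(format_cutoff(fine_cutoff), format_cutoff(coarse_cutoff), "bin")
  out
}

#' Simulate region-level counts for a region universe
#'
#' Negative-binomial counts per region and sample (`dispersion = 0` gives
#' Poisson), the raw material for [run_power_experiment()].
#'
#' @param region_ids Character vector of region ids.
#' @param n_samples Number of samples.
#' @param mean Mean count per region (default 200).
#' @param dispersion Negative-binomial dispersion (default 0.05).
#' @param seed Optional integer seed (local RNG stream).
#' @return A long count tibble (`sample_id`, `region_id`, `count`).
#' @export
make_region_counts <- function(region_ids, n_samples = 30, mean = 200,
                               dispersion = 0.05, seed = NULL) {
  with_seed(seed, {
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    n <- length(region_ids)
    bind_rows(purrr::map(sample_ids, function(sm) {
      y <- if (dispersion <= 0) stats::rpois(n, mean)
      else stats::rnbinom(n, mu = mean, size = 1 / dispersion)
      tibble(sample_id = sm, region_id = region_ids, count = as.integer(y))
    }))
  })
}
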