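phred_string <- function(q) intToUtf8(q + 33L)

test_that("quality filter applies the low-quality-fraction rule inclusively", {
  reads <- tibble::tibble(
    read_id = c("half_low", "under_half"),
    sequence = strrep("A", 10),
    quality = c(phred_string(c(rep(9L, 5), rep(30L, 5))),
                phred_string(c(rep(9L, 4), rep(30L, 6)))))
  kept <- quality_filter(reads)
  expect_equal(kept$read_id, "under_half") # 5/10 >= 0.5 removed, 4/10 kept
  expect_equal(quality_filter(kept), kept) # idempotent
})

test_that("quality filter removes exactly the generator's planted reads", {
  fam <- make_domain_families(n_domains = 1, families_per_domain = 2,
                              members_per_family = 3, within_id = 0.9, seed = 51)
  sim <- make_reference_and_reads(fam, n_samples = 2, reads_per_region_mean = 12,
                                  lowq_read_fraction = 0.2, seed = 52)
  for (sm in names(sim$reads)) {
    kept <- quality_filter(sim$reads[[sm]])
    planted <- sim$manifest$lowq_reads$read_id[
      sim$manifest$lowq_reads$sample_id == sm]
    expect_setequal(setdiff(sim$reads[[sm]]$read_id, kept$read_id), planted)
  }
})

test_that("malformed FASTQ records are reported with the record id", {
  reads <- tibble::tibble(read_id = "bad", sequence = "ACGT", quality = "III")
  expect_error(quality_filter(reads), "bad")
})

test_that("interval overlap counting uses coverageBed semantics", {
  regions <- tibble::tibble(
    region_id = c("rA", "rB"), reference_id = "c1",
    domain_id = "D", nt_start = c(100L, 50L), nt_end = c(200L, 150L),
    strand = "+", aa_sequence = "M")
  one <- tibble::tibble(read_id = "x", reference_id = "c1",
                        start = 10L, end = 110L)
  got <- count_overlaps(one, regions[1, ], "s")
  expect_equal(got$count, 1L) # 10-base overlap
  adj <- tibble::tibble(read_id = "x", reference_id = "c1",
                        start = 0L, end = 50L)
  expect_equal(count_overlaps(adj, regions[2, ], "s")$count, 0L) # half-open
  # one read overlapping two regions increments both
  both <- tibble::tibble(read_id = "x", reference_id = "c1",
                         start = 120L, end = 160L)
  expect_equal(count_overlaps(both, regions, "s")$count, c(1L, 1L))
})

test_that("counting is invariant to alignment order and validates references", {
  set.seed(53)
  regions <- tibble::tibble(
    region_id = sprintf("r%d", 1:5), reference_id = "c1", domain_id = "D",
    nt_start = seq(0L, 800L, by = 200L),
    nt_end = seq(150L, 950L, by = 200L), strand = "+", aa_sequence = "M")
  aln <- tibble::tibble(
    read_id = sprintf("x%d", 1:100), reference_id = "c1",
    start = sample(0:900, 100, TRUE))
  aln$end <- aln$start + 100L
  a <- count_overlaps(aln, regions, "s")
  b <- count_overlaps(aln[sample(100), ], regions, "s")
  expect_equal(a, b)
  bad <- tibble::tibble(read_id = "x", reference_id = "nope",
                        start = 0L, end = 10L)
  expect_error(count_overlaps(bad, regions, "s", known_references = "c1"),
               "unknown reference")
})

test_that("provenance placements reproduce the generator's count manifest", {
  fam <- make_domain_families(n_domains = 2, families_per_domain = 2,
                              members_per_family = 3, within_id = 0.9, seed = 54)
  sim <- make_reference_and_reads(fam, n_samples = 2, reads_per_region_mean = 25,
                                  seed = 55)
  for (sm in names(sim$reads)) {
    prov <- sim$manifest$provenance[sim$manifest$provenance$sample_id == sm, ]
    got <- count_overlaps(prov[, c("read_id", "reference_id", "start", "end")],
                          sim$regions, sm)
    want <- sim$manifest$region_counts[
      sim$manifest$region_counts$sample_id == sm, ]
    merged <- merge(got, want, by = "region_id")
    expect_equal(merged$count.x, merged$count.y)
  }
})

test_that("the naive mapper recovers exact and lightly mutated reads", {
  set.seed(56)
  refs <- c(c1 = random_nt_str(600), c2 = random_nt_str(500))
  sub <- substr(refs[["c1"]], 101, 200)
  reads <- tibble::tibble(
    read_id = c("exact", "absent"),
    sequence = c(sub, random_nt_str(100)),
    quality = strrep("I", 100))
  aln <- naive_map(reads, refs)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$read_id, "exact")
  expect_equal(aln$reference_id, "c1")
  expect_equal(aln$start, 100L)
  expect_equal(aln$identity, 1)
})

test_that("lightly mutated reads map back to their origin", {
  # 2 substitutions per 100-base read: a clean 31-mer seed always exists,
  # so near-total recovery is attainable; at higher error rates exact
  # seeding is geometrically impossible for a growing fraction of reads
  fam <- make_domain_families(n_domains = 2, families_per_domain = 2,
                              members_per_family = 3, within_id = 0.9, seed = 57)
  sim <- make_reference_and_reads(fam, n_samples = 1, reads_per_region_mean = 20,
                                  error_rate = 0.02, seed = 58)
  reads <- sim$reads[[1]]
  aln <- naive_map(reads, sim$refs)
  prov <- sim$manifest$provenance
  m <- merge(aln, prov, by = "read_id", suffixes = c("", ".true"))
  correct <- m$reference_id == m$reference_id.true & m$start == m$start.true
  expect_gte(sum(correct) / nrow(reads), 0.99)
})

test_that("SAM alignments and alignment tibbles give identical counts", {
  fam <- make_domain_families(n_domains = 1, families_per_domain = 2,
                              members_per_family = 2, within_id = 0.95, seed = 59)
  sim <- make_reference_and_reads(fam, n_samples = 1, reads_per_region_mean = 10,
                                  seed = 60)
  aln <- naive_map(sim$reads[[1]], sim$refs)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", sim$refs$id, nchar(sim$refs$sequence)),
    sprintf("%s\t%d\t%s\t%d\t60\t100M\t*\t0\t0\t*\t*",
            aln$read_id, ifelse(aln$strand == "+", 0L, 16L),
            aln$reference_id, aln$start + 1L)), sam)
  c_sam <- count_overlaps(sam, sim$regions, "S01")
  c_tbl <- count_overlaps(aln, sim$regions, "S01")
  expect_equal(c_sam, c_tbl)
})

test_that("blast8 input keeps the best hit per read", {
  b8 <- withr::local_tempfile(fileext = ".blast8")
  writeLines(c(
    "r1\tc1\t98.0\t100\t2\t0\t1\t100\t151\t250\t1e-40\t180",
    "r1\tc2\t90.0\t100\t10\t0\t1\t100\t11\t110\t1e-20\t120",
    "r2\tc2\t95.0\t100\t5\t0\t1\t100\t310\t211\t1e-30\t150"), b8)
  aln <- read_blast8(b8)
  expect_equal(nrow(aln), 2)
  expect_equal(aln$reference_id[aln$read_id == "r1"], "c1")
  r2 <- aln[aln$read_id == "r2", ]
  expect_equal(r2$strand, "-")
  expect_equal(r2$start, 210L) # 0-based of min(sstart, send)
  expect_equal(r2$end, 310L)
})
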