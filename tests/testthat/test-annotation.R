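make_hits <- function(...) {
  tibble::tibble(...)
}

test_that("domtblout parsing applies the per-domain e-value cutoff", {
  hits <- make_hits(
    reference_id = "c1", domain_id = c("TIGR00001", "TIGR00002", "TIGR00003"),
    frame = c(1L, 2L, -1L), aa_start = c(1L, 5L, 2L), aa_end = c(40L, 60L, 33L),
    evalue = c(1e-20, 1e-9, 1e-12), bitscore = c(80, 30, 55))
  path <- withr::local_tempfile(fileext = ".tbl")
  write_domtblout(hits, path)
  got <- parse_domtblout(path, evalue_cutoff = 1e-10)
  expect_equal(nrow(got), 2)
  expect_setequal(got$domain_id, c("TIGR00001", "TIGR00003"))
})

test_that("comment-only domtblout files parse to an empty hit table", {
  path <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c("# header", "#"), path)
  got <- parse_domtblout(path)
  expect_equal(nrow(got), 0)
  expect_named(got, c("reference_id", "domain_id", "frame", "aa_start",
                      "aa_end", "evalue", "bitscore"))
})

test_that("hits survive a write/parse round trip unchanged", {
  set.seed(11)
  hits <- make_hits(
    reference_id = sprintf("c%d", sample(1:5, 20, TRUE)),
    domain_id = sprintf("TIGR%05d", sample(1:8, 20, TRUE)),
    frame = sample(c(-3:-1, 1:3), 20, TRUE),
    aa_start = sample(1:50, 20, TRUE))
  hits$aa_end <- hits$aa_start + sample(10:60, 20, TRUE)
  hits$evalue <- 10^-sample(11:40, 20, TRUE)
  hits$bitscore <- round(runif(20, 20, 300), 1)
  path <- withr::local_tempfile(fileext = ".tbl")
  write_domtblout(hits, path)
  got <- parse_domtblout(path, evalue_cutoff = 1e-10)
  expect_equal(as.data.frame(got), as.data.frame(hits), tolerance = 1e-6)
})

test_that("malformed rows and unknown frame suffixes are reported by line", {
  path <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c("# c", "too few fields"), path)
  expect_error(parse_domtblout(path), "line 2")
  writeLines(c("# c", paste(c("c1_nosuffix", rep("x", 21)), collapse = " ")), path)
  expect_error(parse_domtblout(path), "_frame")
})

test_that("fully overlapping hits keep only the better score unless p = 1", {
  two <- make_hits(
    reference_id = "c1", domain_id = c("A", "B"), frame = 1L,
    aa_start = 1L, aa_end = 50L, evalue = c(1e-30, 1e-20),
    bitscore = c(50, 40))
  kept <- resolve_overlaps(two, max_acceptable_overlap = 0.5)
  expect_equal(kept$domain_id, "A")
  expect_equal(resolve_overlaps(two, max_acceptable_overlap = 1), two)
  expect_error(resolve_overlaps(two, 1.2), "max_acceptable_overlap")
})

test_that("overlap resolution matches the brute-force greedy oracle", {
  set.seed(12)
  lens <- c(c1 = 3000L)
  for (rep in 1:10) {
    n <- 50
    hits <- make_hits(
      reference_id = "c1",
      domain_id = sprintf("D%02d", sample(1:10, n, TRUE)),
      frame = sample(c(-3:-1, 1:3), n, TRUE),
      aa_start = sample(1:200, n, TRUE))
    hits$aa_end <- pmin(hits$aa_start + sample(20:150, n, TRUE), 900L)
    hits$evalue <- 10^-runif(n, 11, 40)
    hits$bitscore <- runif(n, 20, 300)
    kept <- resolve_overlaps(hits, 0.3, ref_lengths = lens)
    expect_equal(kept, hits[oracle_resolve(hits, 0.3, lens), ])
  }
})

test_that("overlap resolution is idempotent and never grows the hit set", {
  set.seed(13)
  lens <- c(c1 = 2000L)
  hits <- make_hits(
    reference_id = "c1", domain_id = sprintf("D%d", 1:30),
    frame = sample(1:3, 30, TRUE), aa_start = sample(1:150, 30, TRUE))
  hits$aa_end <- hits$aa_start + sample(20:100, 30, TRUE)
  hits$evalue <- 10^-runif(30, 11, 30)
  hits$bitscore <- runif(30, 20, 200)
  once <- resolve_overlaps(hits, 0.25, ref_lengths = lens)
  expect_lte(nrow(once), nrow(hits))
  expect_equal(resolve_overlaps(once, 0.25, ref_lengths = lens), once)
})

test_that("plus-frame projections follow the stated arithmetic", {
  ref <- c(r1 = paste(rep("ACGTGA", 10), collapse = "")) # 60 nt
  h1 <- make_hits(reference_id = "r1", domain_id = "D", frame = 1L,
                  aa_start = 1L, aa_end = 10L, evalue = 1e-20, bitscore = 10)
  r1 <- project_to_nucleotides(h1, ref)
  expect_equal(c(r1$nt_start, r1$nt_end, r1$strand), c("0", "30", "+"),
               ignore_attr = TRUE)
  h2 <- make_hits(reference_id = "r1", domain_id = "D", frame = 2L,
                  aa_start = 1L, aa_end = 5L, evalue = 1e-20, bitscore = 10)
  r2 <- project_to_nucleotides(h2, ref)
  expect_equal(r2$nt_start, 1L)
  expect_equal(r2$nt_end, 16L)
  h3 <- make_hits(reference_id = "r1", domain_id = "D", frame = 1L,
                  aa_start = 1L, aa_end = 30L, evalue = 1e-20, bitscore = 10)
  expect_error(project_to_nucleotides(h3, ref), "bounds")
})

test_that("projected slices re-translate to the hit's amino-acid sequence", {
  set.seed(14)
  for (rep in 1:300) {
    reflen <- 3 * sample(30:80, 1)
    ref <- c(r1 = random_nt_str(reflen))
    frame <- sample(c(-3:-1, 1:3), 1)
    k <- abs(frame)
    max_aa <- (reflen - (k - 1)) %/% 3
    s <- sample(seq_len(max_aa - 1), 1)
    e <- sample(s:max_aa, 1)
    hit <- make_hits(reference_id = "r1", domain_id = "D", frame = frame,
                     aa_start = s, aa_end = e, evalue = 1e-20, bitscore = 1)
    reg <- project_to_nucleotides(hit, ref)
    expect_equal(reg$aa_sequence,
                 substr(oracle_translate(ref[[1]], frame), s, e))
    expect_equal((reg$nt_end - reg$nt_start) %% 3, 0)
    expect_equal(nchar(reg$aa_sequence), (reg$nt_end - reg$nt_start) / 3)
  }
})

test_that("domain sequence extraction yields one record per region", {
  regions <- tibble::tibble(
    region_id = c("r1", "r2", "r3"), reference_id = "c1",
    domain_id = c("D1", "D1", "D2"), nt_start = 0L, nt_end = 9L,
    strand = "+", aa_sequence = c("MAK", "MAR", "WWW"))
  aa <- extract_domain_sequences(regions)
  expect_equal(length(aa), 3)
  expect_equal(names(aa), regions$region_id)
  expect_equal(unname(table(regions$domain_id)[c("D1", "D2")]),
               c(2L, 1L), ignore_attr = TRUE)
  expect_equal(length(extract_domain_sequences(regions[0, ])), 0)
  expect_error(extract_domain_sequences(regions[c(1, 1), ]), "duplicate")
})

test_that("TSV and GFF3 annotation encodings produce identical regions", {
  set.seed(15)
  ref <- c(c1 = random_nt_str(120), c2 = random_nt_str(90))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\tTIGR00001\t1\t30\t+",
               "c1\tTIGR00002\t31\t90\t-",
               "c2\tTIGR00001\t4\t63\t+"), tsv)
  r_tsv <- read_user_annotation(tsv, ref)
  expect_equal(r_tsv$nt_start[1], 0L)
  expect_equal(r_tsv$nt_end[1], 30L)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_regions_gff(r_tsv, gff)
  r_gff <- read_user_annotation(gff, ref)
  expect_equal(as.data.frame(r_gff), as.data.frame(r_tsv))
  # re-emitting the parsed GFF reproduces the file byte for byte
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  write_regions_gff(r_gff, gff2)
  expect_identical(readLines(gff2), readLines(gff))
})

test_that("annotation errors carry the offending line number", {
  ref <- c(c1 = paste(rep("ACG", 40), collapse = ""))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\tD1\t1\t30\t+", "c1\tD1\t30\t10\t+"), tsv)
  expect_error(read_user_annotation(tsv, ref), "line 2.*end < start")
  writeLines(c("c1\tD1\t1\t30\t?"), tsv)
  expect_error(read_user_annotation(tsv, ref), "line 1.*strand")
  writeLines(c("c1\tD1\t100\t201\t+"), tsv)
  expect_error(read_user_annotation(tsv, ref), "line 1.*bounds")
})
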