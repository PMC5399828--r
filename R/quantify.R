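#' Read and write FASTQ as a tidy read table
#'
#' Reads are represented as a tibble with columns `read_id`, `sequence` and
#' `quality` (Phred+33 ASCII string of the same length).
#'
#' @param path FASTQ path.
#' @param reads Read tibble.
#' @return `read_fastq()` returns the read tibble; `write_fastq()` returns
#'   `path` invisibly.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  out <- tibble(
    read_id = names(x),
    sequence = as.character(x),
    quality = as.character(S4Vectors::mcols(x)$qualities)
  )
  bad <- nchar(out$quality) != nchar(out$sequence)
  if (any(bad)) {
    abort(paste0("malformed FASTQ record '", out$read_id[bad][1],
                 "': quality and sequence lengths differ"))
  }
  out
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

phred_scores <- function(quality) {
  lapply(quality, function(s) utf8ToInt(s) - 33L)
}

#' Quality-filter sequence reads
#'
#' Removes a read when at least `min_frac` of its bases have a Phred
#' quality below `qmin` (defaults: at least 50% of bases below Q10). The
#' order of surviving reads is preserved, so the filter is idempotent.
#'
#' @param reads Read tibble (see [read_fastq()]).
#' @param min_frac Removal threshold on the fraction of low-quality bases,
#'   compared inclusively (`>=`).
#' @param qmin Phred score below which a base counts as low quality.
#' @return The surviving subset of `reads`.
#' @export
quality_filter <- function(reads, min_frac = 0.5, qmin = 10) {
  check_fraction(min_frac, "min_frac", lower_open = TRUE)
  bad <- nchar(reads$quality) != nchar(reads$sequence)
  if (any(bad)) {
    abort(paste0("malformed FASTQ record '", reads$read_id[bad][1],
                 "': quality and sequence lengths differ"))
  }
  frac_low <- vapply(phred_scores(reads$quality),
                     function(q) mean(q < qmin), numeric(1))
  reads[frac_low < min_frac, , drop = FALSE]
}

#' Naive exact-seed read mapper for desk-scale data
#'
#' A deliberately simple substitute for a production mapper, used on toy
#' and simulated data: exact 31-mer seeding against an index of the
#' references, ungapped extension over the full read on either strand, and
#' the single best placement per read reported when its identity over the
#' read is at least `min_identity`. Ties are broken deterministically
#' (higher identity, then lexicographically lowest reference id, then
#' lowest coordinate, then forward strand). Production workflows should
#' supply external SAM/BAM alignments instead.
#'
#' Because seeding is exact, a read can only be placed when it contains at
#' least one error-free `k`-mer; with the default `k = 31` that caps the
#' tolerable substitution rate at roughly 2-3 errors per 100-base read, and
#' the mapped fraction degrades quickly beyond that even though
#' `min_identity` would still accept the placement.
#'
#' @param reads Read tibble (ideally already quality-filtered).
#' @param refs Reference sequences.
#' @param min_identity Minimum identity over the read (default 0.9).
#' @param k Seed length (default 31).
#' @return An alignment tibble with columns `read_id`, `reference_id`,
#'   `start`, `end` (0-based half-open on the forward strand), `strand`,
#'   `identity`; unmapped reads are omitted.
#' @export
naive_map <- function(reads, refs, min_identity = 0.9, k = 31L) {
  x <- ref_as_character(refs)
  check_fraction(min_identity, "min_identity", lower_open = TRUE)
  index <- new.env(parent = emptyenv(), hash = TRUE)
  for (rid in names(x)) {
    s <- x[[rid]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    for (i in seq_along(kmers)) {
      km <- kmers[i]
      index[[km]] <- c(index[[km]], list(c(rid, starts[i])))
    }
  }
  ref_split <- lapply(x, function(s) strsplit(s, "")[[1]])
  out <- vector("list", nrow(reads))
  for (r in seq_len(nrow(reads))) {
    seqs <- c(reads$sequence[r], reverse_complement_chr(reads$sequence[r]))
    len <- nchar(seqs[1])
    best <- NULL
    for (si in 1:2) {
      s <- seqs[si]
      strand <- c("+", "-")[si]
      if (len < k) next
      # non-overlapping seeds first; fall back to every offset so that any
      # read containing one clean k-mer can still be placed
      sparse <- unique(c(seq(1L, len - k + 1L, by = k), len - k + 1L))
      collect <- function(offsets) {
        cand <- list()
        for (off in offsets) {
          hits <- index[[substr(s, off, off + k - 1L)]]
          for (h in hits) {
            start0 <- as.integer(h[2]) - 1L - (off - 1L) # 0-based read start
            cand[[length(cand) + 1L]] <- c(h[1], start0)
          }
        }
        cand
      }
      cand <- collect(sparse)
      if (length(cand) == 0) cand <- collect(setdiff(seq_len(len - k + 1L), sparse))
      if (length(cand) == 0) next
      cand <- unique(cand)
      rs <- strsplit(s, "")[[1]]
      for (cn in cand) {
        rid <- cn[1]
        start0 <- as.integer(cn[2])
        if (start0 < 0 || start0 + len > nchar(x[[rid]])) next
        ident <- mean(rs == ref_split[[rid]][(start0 + 1L):(start0 + len)])
        key <- list(identity = ident, reference_id = rid, start = start0,
                    strand = strand)
        if (is.null(best) || better_placement(key, best)) best <- key
      }
    }
    if (!is.null(best) && best$identity >= min_identity) {
      out[[r]] <- tibble(read_id = reads$read_id[r],
                         reference_id = best$reference_id,
                         start = best$start, end = best$start + len,
                         strand = best$strand, identity = best$identity)
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(read_id = character(), reference_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  identity = double())
  }
  res
}

better_placement <- function(a, b) {
  if (a$identity != b$identity) return(a$identity > b$identity)
  if (a$reference_id != b$reference_id) return(a$reference_id < b$reference_id)
  if (a$start != b$start) return(a$start < b$start)
  a$strand == "+" && b$strand == "-"
}

#' Read blast8 tabular alignments as best-hit placements
#'
#' Parses 12-column blast8/BLAST-tabular output (query, subject, identity,
#' length, mismatches, gap opens, qstart, qend, sstart, send, evalue,
#' bitscore), keeps the best hit per read by bitscore (ties by subject id
#' then coordinate) and returns reference-coordinate intervals; `sstart >
#' send` encodes a minus-strand placement.
#'
#' @param path blast8 file path.
#' @return An alignment tibble as in [naive_map()] (without `identity`
#'   rescaling; the blast8 percent identity is carried over as a fraction).
#' @export
read_blast8 <- function(path) {
  df <- readr::read_tsv(path, col_names = c(
    "query", "subject", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore"),
    col_types = "ccdiiiiiiidd", comment = "#")
  if (nrow(df) == 0) {
    return(tibble(read_id = character(), reference_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  identity = double()))
  }
  df %>%
    mutate(strand = ifelse(.data$sstart <= .data$send, "+", "-"),
           lo = pmin(.data$sstart, .data$send),
           hi = pmax(.data$sstart, .data$send)) %>%
    arrange(.data$query, dplyr::desc(.data$bitscore), .data$subject, .data$lo) %>%
    group_by(.data$query) %>%
    slice(1) %>%
    ungroup() %>%
    mutate(read_id = .data$query, reference_id = .data$subject,
           start = .data$lo - 1L, end = .data$hi,
           identity = .data$pident / 100) %>%
    select("read_id", "reference_id", "start", "end", "strand", "identity")
}

# Normalize alignment input (tibble from naive_map/read_blast8, or a
# SAM/BAM path) to a tibble of reference intervals.
alignments_as_tibble <- function(alignments) {
  if (is.data.frame(alignments)) {
    req <- c("read_id", "reference_id", "start", "end")
    if (!all(req %in% names(alignments))) {
      abort("alignment tibble needs columns read_id, reference_id, start, end")
    }
    return(alignments)
  }
  if (is.character(alignments) && length(alignments) == 1) {
    path <- alignments
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      dest <- tempfile(fileext = "")
      path <- suppressMessages(Rsamtools::asBam(path, dest,
                                                overwrite = TRUE,
                                                indexDestination = FALSE))
    }
    flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE)
    ga <- GenomicAlignments::readGAlignments(
      path, param = Rsamtools::ScanBamParam(flag = flags, what = "qname"))
    return(tibble(
      read_id = S4Vectors::mcols(ga)$qname,
      reference_id = as.character(GenomicAlignments::seqnames(ga)),
      start = GenomicAlignments::start(ga) - 1L,
      end = GenomicAlignments::end(ga),
      strand = as.character(GenomicAlignments::strand(ga)),
      identity = NA_real_
    ))
  }
  abort("`alignments` must be an alignment tibble or a SAM/BAM path")
}

#' Count reads overlapping each annotated region
#'
#' coverageBed-style counting: a read increments a region's count when its
#' aligned reference interval overlaps the region's nucleotide interval by
#' at least one base, regardless of strand; a read overlapping several
#' regions increments each of them, and each (read, region) pair counts at
#' most once. Unmapped, secondary and supplementary SAM/BAM records are
#' ignored.
#'
#' @param alignments An alignment tibble ([naive_map()], [read_blast8()])
#'   or a SAM/BAM file path.
#' @param regions Annotated-region tibble.
#' @param sample_id Sample label attached to the counts.
#' @param known_references Optional character vector of valid reference
#'   ids; an alignment referencing any other id raises an error.
#' @return A tibble with columns `sample_id`, `region_id`, `count`, one
#'   row per region (zero counts included), in `regions` order.
#' @export
count_overlaps <- function(alignments, regions, sample_id = "sample",
                           known_references = NULL) {
  aln <- alignments_as_tibble(alignments)
  universe <- unique(c(regions$reference_id, known_references))
  if (!is.null(known_references)) {
    bad <- !aln$reference_id %in% universe
    if (any(bad)) {
      abort(paste0("alignment references unknown reference id '",
                   aln$reference_id[bad][1], "'"))
    }
  }
  reg_gr <- GenomicRanges::GRanges(
    seqnames = regions$reference_id,
    ranges = IRanges::IRanges(start = regions$nt_start + 1L,
                              end = regions$nt_end))
  if (nrow(aln) == 0) {
    return(tibble(sample_id = sample_id, region_id = regions$region_id,
                  count = 0L))
  }
  aln_gr <- GenomicRanges::GRanges(
    seqnames = aln$reference_id,
    ranges = IRanges::IRanges(start = aln$start + 1L, end = aln$end))
  n <- suppressWarnings(GenomicRanges::countOverlaps(
    reg_gr, aln_gr, minoverlap = 1L, ignore.strand = TRUE))
  tibble(sample_id = sample_id, region_id = regions$region_id,
         count = as.integer(n))
}
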