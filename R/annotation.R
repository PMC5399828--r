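#' Parse a per-domain profile-HMM hit table (domtblout dialect)
#'
#' Reads the whitespace-separated per-domain tabular output of an
#' `hmmsearch --domtblout` run of a domain-model library against six-frame
#' translated reference sequences (see [write_translated_fasta()] for the
#' `_frame<+k|-k>` query naming convention the parser relies on). Hits whose
#' independent (per-domain) e-value exceeds `evalue_cutoff` are dropped.
#'
#' Columns used: target name (1; translated reference, frame-suffixed),
#' query name (4; domain model accession), i-Evalue (13), domain bit score
#' (14) and the alignment coordinates on the translated sequence (18, 19;
#' 1-based inclusive amino-acid positions).
#'
#' @param path Path to the domtblout file. Lines starting with `#` are
#'   ignored.
#' @param evalue_cutoff Keep hits with independent e-value `<=` this value
#'   (default `1e-10`).
#' @return A domain-hit tibble with columns `reference_id`, `domain_id`,
#'   `frame`, `aa_start`, `aa_end`, `evalue`, `bitscore`.
#' @export
parse_domtblout <- function(path, evalue_cutoff = 1e-10) {
  if (!is.numeric(evalue_cutoff) || evalue_cutoff <= 0) {
    abort("`evalue_cutoff` must be a positive number")
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) return(empty_hits())
  rows <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(rows)
  if (any(nf < 22)) {
    bad <- idx[which(nf < 22)[1]]
    abort(sprintf("malformed domtblout row at line %d: expected >= 22 fields, got %d",
                  bad, nf[which(nf < 22)[1]]))
  }
  field <- function(i) vapply(rows, `[[`, character(1), i)
  target <- field(1)
  m <- regmatches(target, regexec("^(.*)_frame([+-][123])$", target))
  bad_frame <- vapply(m, length, integer(1)) != 3
  if (any(bad_frame)) {
    abort(sprintf(
      "line %d: target id '%s' lacks the '_frame<+k|-k>' suffix",
      idx[which(bad_frame)[1]], target[which(bad_frame)[1]]))
  }
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(field(i)))
    if (anyNA(v)) {
      abort(sprintf("line %d: non-numeric %s field", idx[which(is.na(v))[1]], what))
    }
    v
  }
  hits <- tibble(
    reference_id = vapply(m, `[[`, character(1), 2),
    domain_id = field(4),
    frame = as.integer(vapply(m, `[[`, character(1), 3)),
    aa_start = as.integer(num(18, "ali-from")),
    aa_end = as.integer(num(19, "ali-to")),
    evalue = num(13, "i-Evalue"),
    bitscore = num(14, "bit score")
  )
  if (any(hits$aa_start > hits$aa_end)) {
    abort(sprintf("line %d: ali-from exceeds ali-to",
                  idx[which(hits$aa_start > hits$aa_end)[1]]))
  }
  if (any(hits$evalue < 0)) abort("negative e-value in domtblout")
  hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
}

empty_hits <- function() {
  tibble(reference_id = character(), domain_id = character(),
         frame = integer(), aa_start = integer(), aa_end = integer(),
         evalue = double(), bitscore = double())
}

#' Serialize domain hits in the domtblout dialect
#'
#' Writes the minimal per-domain tabular file [parse_domtblout()] reads;
#' used by the synthetic-data generator so parsing can be exercised without
#' an external HMM search.
#'
#' @param hits Domain-hit tibble (see [parse_domtblout()]).
#' @param path Output path.
#' @param qlen Optional named vector of translated-query lengths; defaults
#'   to `aa_end`.
#' @return Invisibly, `path`.
#' @export
write_domtblout <- function(hits, path, qlen = NULL) {
  target <- paste0(hits$reference_id, "_frame", sprintf("%+d", hits$frame))
  tlen <- if (is.null(qlen)) hits$aa_end else unname(qlen[target])
  lines <- sprintf(
    "%s - %d %s - %d %.2g %.1f 0.0 1 1 %.2g %.2g %.1f 0.0 1 %d %d %d %d %d 0.90 -",
    target, tlen, hits$domain_id, hits$aa_end - hits$aa_start + 1L,
    hits$evalue, hits$bitscore, hits$evalue, hits$evalue, hits$bitscore,
    hits$aa_end - hits$aa_start + 1L, hits$aa_start, hits$aa_end,
    hits$aa_start, hits$aa_end)
  writeLines(c(
    "# target name accession tlen query name accession qlen E-value score bias # of c-Evalue i-Evalue score bias from to from to from to acc description",
    "#", lines), path)
  invisible(path)
}

# Nucleotide projection of hit coordinates, 0-based half-open on the
# forward strand. Needs reference lengths for minus-frame hits.
hit_nt_intervals <- function(hits, ref_lengths) {
  k <- abs(hits$frame)
  a <- (k - 1L) + 3L * (hits$aa_start - 1L)
  b <- (k - 1L) + 3L * hits$aa_end
  minus <- hits$frame < 0
  if (any(minus)) {
    if (is.null(ref_lengths)) {
      abort("reference lengths are required to project minus-frame hits")
    }
    L <- unname(ref_lengths[hits$reference_id[minus]])
    if (anyNA(L)) abort("hit references a reference id with unknown length")
    tmp_a <- L - b[minus]
    b[minus] <- L - a[minus]
    a[minus] <- tmp_a
  }
  tibble(nt_start = a, nt_end = b,
         strand = ifelse(hits$frame > 0, "+", "-"))
}

#' Resolve overlapping domain hits, keeping the best-scoring one
#'
#' When two hits on the same reference overlap (in projected nucleotide
#' coordinates, either strand) by more than `max_acceptable_overlap` times
#' the length of the shorter annotation, only the better-scoring hit is
#' kept. Resolution is greedy in decreasing bitscore order, ties broken by
#' lower e-value, then by reference id and projected coordinates for
#' determinism. With `max_acceptable_overlap = 1` the input is returned
#' unchanged (all hits reported). The rule is applied to all hit pairs,
#' including multiple hits of the same domain.
#'
#' @param hits Domain-hit tibble (see [parse_domtblout()]).
#' @param max_acceptable_overlap Fraction `p` in `[0, 1]`; pairs overlapping
#'   more than `p` of the shorter annotation conflict.
#' @param refs Reference sequences (or a named vector of lengths via
#'   `ref_lengths`); required when minus-frame hits are present.
#' @param ref_lengths Optional named integer vector of reference lengths.
#' @return The retained subset of `hits`, in input order.
#' @export
resolve_overlaps <- function(hits, max_acceptable_overlap, refs = NULL,
                             ref_lengths = NULL) {
  check_fraction(max_acceptable_overlap, "max_acceptable_overlap")
  if (nrow(hits) == 0 || max_acceptable_overlap == 1) return(hits)
  if (is.null(ref_lengths) && !is.null(refs)) {
    x <- ref_as_character(refs)
    ref_lengths <- stats::setNames(nchar(x), names(x))
  }
  iv <- hit_nt_intervals(hits, ref_lengths)
  ord <- order(-hits$bitscore, hits$evalue, hits$reference_id,
               iv$nt_start, iv$nt_end, hits$domain_id)
  keep <- logical(nrow(hits))
  for (i in ord) {
    acc <- which(keep & hits$reference_id == hits$reference_id[i])
    ok <- TRUE
    for (j in acc) {
      ov <- min(iv$nt_end[i], iv$nt_end[j]) - max(iv$nt_start[i], iv$nt_start[j])
      min_len <- min(iv$nt_end[i] - iv$nt_start[i], iv$nt_end[j] - iv$nt_start[j])
      if (ov > max_acceptable_overlap * min_len) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  hits[keep, , drop = FALSE]
}

#' Project domain hits from translated-frame to reference coordinates
#'
#' Converts amino-acid hit coordinates on a reading frame into 0-based
#' half-open nucleotide intervals on the forward strand of the reference,
#' and extracts the translated amino-acid sequence of each region. For
#' frame `+k` and 1-based amino-acid positions `s..e` the interval is
#' `[(k-1) + 3(s-1), (k-1) + 3e)`; for `-k` the analogous interval on the
#' reverse complement is mapped back to forward coordinates with strand
#' `-`.
#'
#' @inheritParams resolve_overlaps
#' @param refs Reference sequences (tibble, named character vector or
#'   `DNAStringSet`).
#' @return An annotated-region tibble with columns `region_id`,
#'   `reference_id`, `domain_id`, `nt_start`, `nt_end`, `strand`,
#'   `aa_sequence`.
#' @export
project_to_nucleotides <- function(hits, refs) {
  x <- ref_as_character(refs)
  if (!all(hits$reference_id %in% names(x))) {
    abort("hit references an unknown reference id")
  }
  L <- stats::setNames(nchar(x), names(x))
  iv <- hit_nt_intervals(hits, L)
  if (any(iv$nt_start < 0) || any(iv$nt_end > L[hits$reference_id])) {
    abort("projected interval exceeds reference bounds")
  }
  slice_nt <- substr(x[hits$reference_id], iv$nt_start + 1L, iv$nt_end)
  minus <- iv$strand == "-"
  if (any(minus)) slice_nt[minus] <- reverse_complement_chr(slice_nt[minus])
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(unname(slice_nt)), if.fuzzy.codon = "X",
    no.init.codon = TRUE))
  tibble(
    region_id = paste0(hits$reference_id, ":", hits$domain_id, ":",
                       iv$nt_start + 1L, "-", iv$nt_end, ":", iv$strand),
    reference_id = hits$reference_id,
    domain_id = hits$domain_id,
    nt_start = as.integer(iv$nt_start),
    nt_end = as.integer(iv$nt_end),
    strand = iv$strand,
    aa_sequence = aa
  )
}

#' Extract amino-acid sequences of annotated regions
#'
#' One FASTA record per region, named by `region_id`; the grouping key for
#' the downstream sub-binning step is `domain_id` (encoded in the region
#' table, not the FASTA header).
#'
#' @param regions Annotated-region tibble (see [project_to_nucleotides()]).
#' @param path Optional FASTA output path.
#' @return An `AAStringSet` named by region id (invisibly when `path` is
#'   given).
#' @export
extract_domain_sequences <- function(regions, path = NULL) {
  if (anyDuplicated(regions$region_id)) {
    abort(paste0("duplicate region_id: ",
                 regions$region_id[anyDuplicated(regions$region_id)]))
  }
  aa <- Biostrings::AAStringSet(
    stats::setNames(regions$aa_sequence, regions$region_id))
  if (!is.null(path)) {
    Biostrings::writeXStringSet(aa, path)
    return(invisible(aa))
  }
  aa
}

#' Read user-supplied annotation of reference coordinates
#'
#' Accepts either a 5-column tab-separated file (`reference_id`,
#' `domain_id`, `start`, `end`, `strand`; 1-based inclusive coordinates, as
#' in GFF) or a GFF3 file (domain id taken from the `domain_id`, `Name` or
#' `ID` attribute, in that order). Coordinates are converted to the internal
#' 0-based half-open convention and the amino-acid sequence of each region
#' is derived by translating the (strand-aware) slice.
#'
#' @param path Annotation file path.
#' @param refs Reference sequences.
#' @param format `"auto"` (by extension), `"tsv"` or `"gff3"`.
#' @return An annotated-region tibble (see [project_to_nucleotides()]).
#' @export
read_user_annotation <- function(path, refs, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  x <- ref_as_character(refs)
  L <- stats::setNames(nchar(x), names(x))
  if (format == "tsv") {
    lines <- readLines(path)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    idx <- which(keep)
    if (length(idx) == 0) return(regions_from_coords(character(0), character(0),
                                                     integer(0), integer(0),
                                                     character(0), x))
    rows <- strsplit(lines[idx], "\t")
    nf <- lengths(rows)
    if (any(nf < 5)) {
      abort(sprintf("line %d: expected 5 tab-separated columns, got %d",
                    idx[which(nf < 5)[1]], nf[which(nf < 5)[1]]))
    }
    ref_id <- vapply(rows, `[[`, character(1), 1)
    dom <- vapply(rows, `[[`, character(1), 2)
    start1 <- suppressWarnings(as.integer(vapply(rows, `[[`, character(1), 3)))
    end1 <- suppressWarnings(as.integer(vapply(rows, `[[`, character(1), 4)))
    strand <- vapply(rows, `[[`, character(1), 5)
    check_annotation_rows(ref_id, start1, end1, strand, L, idx)
    regions_from_coords(ref_id, dom, start1 - 1L, end1, strand, x)
  } else {
    g <- rtracklayer::import(path, format = "gff3")
    mc <- S4Vectors::mcols(g)
    dom <- if ("domain_id" %in% names(mc)) mc$domain_id
      else if ("Name" %in% names(mc)) mc$Name
      else if ("ID" %in% names(mc)) mc$ID
      else abort("GFF3 records lack a domain_id/Name/ID attribute")
    ref_id <- as.character(GenomicRanges::seqnames(g))
    start1 <- GenomicRanges::start(g)
    end1 <- GenomicRanges::end(g)
    strand <- as.character(GenomicRanges::strand(g))
    check_annotation_rows(ref_id, start1, end1, strand, L, seq_along(g))
    regions_from_coords(ref_id, as.character(dom), start1 - 1L, end1, strand, x)
  }
}

check_annotation_rows <- function(ref_id, start1, end1, strand, L, lineno) {
  fail <- function(i, msg) abort(sprintf("line %d: %s", lineno[i], msg))
  if (anyNA(start1) || anyNA(end1)) {
    fail(which(is.na(start1) | is.na(end1))[1], "non-integer coordinate")
  }
  bad <- !ref_id %in% names(L)
  if (any(bad)) fail(which(bad)[1], paste0("unknown reference id '",
                                           ref_id[bad][1], "'"))
  if (any(end1 < start1)) fail(which(end1 < start1)[1], "end < start")
  if (any(start1 < 1) || any(end1 > L[ref_id])) {
    fail(which(start1 < 1 | end1 > L[ref_id])[1], "coordinates out of bounds")
  }
  if (any(!strand %in% c("+", "-"))) {
    fail(which(!strand %in% c("+", "-"))[1],
         paste0("unknown strand symbol '", strand[!strand %in% c("+", "-")][1], "'"))
  }
  len <- end1 - start1 + 1L
  if (any(len %% 3L != 0L)) {
    fail(which(len %% 3L != 0L)[1], "region length not divisible by 3")
  }
  invisible(TRUE)
}

regions_from_coords <- function(ref_id, dom, nt_start, nt_end, strand, x) {
  if (length(ref_id) == 0) {
    return(tibble(region_id = character(), reference_id = character(),
                  domain_id = character(), nt_start = integer(),
                  nt_end = integer(), strand = character(),
                  aa_sequence = character()))
  }
  slice_nt <- substr(x[ref_id], nt_start + 1L, nt_end)
  minus <- strand == "-"
  if (any(minus)) slice_nt[minus] <- reverse_complement_chr(slice_nt[minus])
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(unname(slice_nt)), if.fuzzy.codon = "X",
    no.init.codon = TRUE))
  tibble(
    region_id = paste0(ref_id, ":", dom, ":", nt_start + 1L, "-", nt_end,
                       ":", strand),
    reference_id = ref_id, domain_id = dom,
    nt_start = as.integer(nt_start), nt_end = as.integer(nt_end),
    strand = strand, aa_sequence = aa
  )
}

#' Write annotated regions as GFF3
#'
#' Deterministic writer (fixed column set and attribute order) so that the
#' same region set always produces byte-identical output.
#'
#' @param regions Annotated-region tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_regions_gff <- function(regions, path) {
  body <- sprintf("%s\tfinebin\tprotein_domain\t%d\t%d\t.\t%s\t.\tID=%s;domain_id=%s",
                  regions$reference_id, regions$nt_start + 1L, regions$nt_end,
                  regions$strand, regions$region_id, regions$domain_id)
  writeLines(c("##gff-version 3", body), path)
  invisible(path)
}

#' Annotate a reference set from profile-HMM hits or user coordinates
#'
#' Convenience wrapper for the supervised binning step: parse hit evidence,
#' drop hits above the e-value cutoff, resolve overlapping hits, and project
#' the survivors onto nucleotide reference coordinates.
#'
#' @param refs Reference sequences.
#' @param domtblout Path to a per-domain profile-HMM hit table (see
#'   [parse_domtblout()]); mutually exclusive with `annotation`.
#' @param annotation Path to a user annotation file (see
#'   [read_user_annotation()]).
#' @param evalue_cutoff Independent e-value cutoff for HMM hits.
#' @param max_acceptable_overlap Overlap-resolution fraction `p`
#'   (see [resolve_overlaps()]); `1` reports all hits.
#' @return An annotated-region tibble.
#' @export
annotate_reference <- function(refs, domtblout = NULL, annotation = NULL,
                               evalue_cutoff = 1e-10,
                               max_acceptable_overlap = 1) {
  if (is.null(domtblout) == is.null(annotation)) {
    abort("supply exactly one of `domtblout` or `annotation`")
  }
  if (!is.null(annotation)) {
    return(read_user_annotation(annotation, refs))
  }
  hits <- parse_domtblout(domtblout, evalue_cutoff)
  hits <- resolve_overlaps(hits, max_acceptable_overlap, refs = refs)
  project_to_nucleotides(hits, refs)
}
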