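#' Translate reference sequences in all six reading frames
#'
#' Frames `+1,+2,+3` translate the forward strand starting at offsets 0, 1
#' and 2; frames `-1,-2,-3` translate the reverse complement at the same
#' offsets. A trailing partial codon is dropped, codons containing `N`
#' translate to `X`, and stop codons translate to `*` (a domain hit spanning
#' a stop is kept as-is downstream). The `query_id` column carries the
#' `<reference_id>_frame<+k|-k>` naming convention used when writing
#' translated sequences for a profile-HMM search; [parse_domtblout()] relies
#' on this suffix to recover the frame.
#'
#' @param refs Reference sequences: a tibble with columns `id` and
#'   `sequence`, a named character vector, or a `DNAStringSet`.
#' @return A tibble with columns `reference_id`, `frame` (integer in
#'   `{-3,...,-1,+1,...,+3}`), `query_id` and `aa_sequence`, six rows per
#'   reference.
#' @examples
#' translate_six_frames(c(c1 = "ATGGCC"))
#' @export
translate_six_frames <- function(refs) {
  x <- ref_as_character(refs)
  dna <- Biostrings::DNAStringSet(x)
  fwd_frames <- purrr::map(1:3, function(k) frame_translate(dna, k))
  rc <- Biostrings::reverseComplement(dna)
  rev_frames <- purrr::map(1:3, function(k) frame_translate(rc, k))
  purrr::map_dfr(c(1, 2, 3, -1, -2, -3), function(f) {
    aa <- if (f > 0) fwd_frames[[f]] else rev_frames[[-f]]
    tibble(
      reference_id = names(x),
      frame = as.integer(f),
      query_id = paste0(names(x), "_frame", sprintf("%+d", f)),
      aa_sequence = unname(aa)
    )
  }) %>%
    arrange(match(.data$reference_id, names(x)), match(
      .data$frame, c(1, 2, 3, -1, -2, -3)
    ))
}

# Translate each sequence of `dna` starting at 1-based offset k, dropping
# the trailing partial codon. Returns a character vector.
frame_translate <- function(dna, k) {
  len <- Biostrings::width(dna)
  w <- pmax(0L, (len - k + 1L) %/% 3L) * 3L
  sub <- Biostrings::subseq(dna, start = pmin(k, len + 1L), width = w)
  as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

#' Write six-frame translations as an amino-acid FASTA
#'
#' Produces the query FASTA a profile-HMM search (e.g. `hmmsearch` against a
#' domain model library) runs on. Record ids follow the
#' `<reference_id>_frame<+k|-k>` convention that [parse_domtblout()] expects.
#'
#' @inheritParams translate_six_frames
#' @param path Output FASTA path.
#' @return Invisibly, the translation tibble (see [translate_six_frames()]).
#' @export
write_translated_fasta <- function(refs, path) {
  tr <- translate_six_frames(refs)
  aa <- Biostrings::AAStringSet(stats::setNames(tr$aa_sequence, tr$query_id))
  Biostrings::writeXStringSet(aa, path)
  invisible(tr)
}

reverse_complement_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
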