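# Internal helpers shared across modules.

# Coerce a reference set (tibble with id/sequence, named character vector, or
# DNAStringSet) to a named character vector of upper-case nucleotide strings.
ref_as_character <- function(refs) {
  if (methods::is(refs, "DNAStringSet")) {
    out <- stats::setNames(as.character(refs), names(refs))
  } else if (is.data.frame(refs)) {
    if (!all(c("id", "sequence") %in% names(refs))) {
      abort("reference tibble must have columns 'id' and 'sequence'")
    }
    out <- stats::setNames(toupper(refs$sequence), refs$id)
  } else if (is.character(refs)) {
    if (is.null(names(refs)) || any(names(refs) == "")) {
      abort("reference character vector must be named by sequence id")
    }
    out <- toupper(refs)
  } else {
    abort("unsupported reference representation")
  }
  if (anyDuplicated(names(out))) abort("reference ids must be unique")
  if (any(nchar(out) < 1)) abort("reference sequences must be non-empty")
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    abort(paste0("reference sequence '", names(out)[bad][1],
                 "' contains characters outside {A,C,G,T,N}"))
  }
  out
}

ref_as_tibble <- function(refs) {
  x <- ref_as_character(refs)
  tibble(id = names(x), sequence = unname(x))
}

# Deterministic text rendering of a clustering cutoff for use in ids and
# file columns ("0.75", "0.5", "bin").
format_cutoff <- function(cutoff) {
  if (identical(cutoff, "bin")) return("bin")
  sprintf("%g", cutoff)
}

check_fraction <- function(x, name, lower = 0, upper = 1,
                           lower_open = FALSE, upper_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (lower_open) x > lower else x >= lower) &&
    (if (upper_open) x < upper else x <= upper)
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s%g, %g%s", name,
                  if (lower_open) "(" else "[", lower, upper,
                  if (upper_open) ")" else "]"))
  }
  invisible(x)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is restored afterwards.  With seed = NULL the global stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
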