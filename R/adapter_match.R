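#' Describe an adapter and its matching dialect
#'
#' An `adapter_spec` bundles the adapter sequence with the matching
#' semantics used throughout the package: the mode (`"back"` for a 3'
#' adapter, `"front"` for a 5' adapter/primer, `"anywhere"` for adapters
#' that may appear on either side, mirroring the `-a`/`-g`/`-b` trimming
#' idioms), the per-aligned-base error rate and the minimum overlap.
#'
#' @param sequence uppercase DNA string, length >= 8.
#' @param mode one of `"back"`, `"front"`, `"anywhere"`.
#' @param error_rate allowed errors per aligned adapter base, in `[0, 0.5)`;
#'   a candidate alignment with `aligned` adapter bases is admissible when
#'   `errors <= floor(error_rate * aligned)`.
#' @param min_overlap minimum number of adapter bases that must be aligned
#'   (default 3).
#' @param name label used in reports.
#' @return An object of class `adapter_spec`.
#' @export
adapter_spec <- function(sequence, mode = c("back", "front", "anywhere"),
                         error_rate = 0.1, min_overlap = 3L,
                         name = "adapter") {
  mode <- match.arg(mode)
  sequence <- toupper(sequence)
  stopifnot(nchar(sequence) >= 8L, !grepl("[^ACGTN]", sequence),
            error_rate >= 0, error_rate < 0.5, min_overlap >= 1L)
  structure(list(name = name, sequence = sequence, mode = mode,
                 error_rate = error_rate,
                 min_overlap = as.integer(min_overlap)),
            class = "adapter_spec")
}

#' @export
print.adapter_spec <- function(x, ...) {
  cat(sprintf("adapter_spec '%s': %s (%s, error_rate %.2f, min_overlap %d)\n",
              x$name, x$sequence, x$mode, x$error_rate, x$min_overlap))
  invisible(x)
}

mode_code <- function(mode) {
  c(back = 1L, front = 2L, anywhere = 3L)[[mode]]
}

#' Built-in platform adapter presets
#'
#' `"illumina-truseq-smallrna"`: TruSeq small RNA 3' adapter
#' `TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC` (back mode, error rate 0.1) plus the
#' 5' primer `CGACAGGTTCAGAGTTCTACAGTCCGACGATC` (front mode, error rate
#' 0.1; full-length evidence required, see the methods vignette).
#' `"iontorrent-smallrna"`: `ATCACCGACTGCCCATAGAGAGGAAAGCGG` in anywhere
#' mode with error rate 0.2.
#'
#' @param name preset name.
#' @return A list with elements `adapter3` and (Illumina only) `adapter5`.
#' @export
adapter_presets <- function(name = c("illumina-truseq-smallrna",
                                     "iontorrent-smallrna")) {
  name <- match.arg(name)
  if (name == "illumina-truseq-smallrna") {
    primer <- "CGACAGGTTCAGAGTTCTACAGTCCGACGATC"
    list(adapter3 = adapter_spec("TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC",
                                 "back", 0.1, 3L, "truseq-smallrna-3p"),
         adapter5 = adapter_spec(primer, "front", 0.1,
                                 min_overlap = nchar(primer),
                                 name = "truseq-smallrna-5p-primer"))
  } else {
    list(adapter3 = adapter_spec("ATCACCGACTGCCCATAGAGAGGAAAGCGG",
                                 "anywhere", 0.2, 3L, "iontorrent-smallrna"))
  }
}

match_matrix_to_df <- function(m) {
  data.frame(read_start = unname(m[, "start"]),
             read_end = unname(m[, "end"]),
             adapter_bases_aligned = unname(m[, "aligned"]),
             errors = unname(m[, "errors"]),
             matched = unname(m[, "matched"]) == 1L,
             row.names = NULL)
}

# Vectorised matcher over a character vector of base strings.
match_adapter_vec <- function(bases, spec) {
  m <- cpp_match_adapter(bases, spec$sequence, mode_code(spec$mode),
                         spec$error_rate, spec$min_overlap)
  match_matrix_to_df(m)
}

#' Locate an adapter inside a read
#'
#' Finds the best error-tolerant semi-global alignment of the adapter in
#' the read under unit-cost edit distance.  In back mode the candidate set
#' is the full adapter at any position plus adapter prefixes reaching the
#' read's 3' end; front mode instead admits adapter suffixes anchored at
#' the read's 5' start; anywhere mode admits both.  A candidate is
#' admissible iff `errors <= floor(error_rate * adapter_bases_aligned)` and
#' at least `min_overlap` adapter bases are aligned.  The best candidate
#' has the fewest errors, then the most adapter bases aligned, then the
#' smallest `read_start` (then the smallest `read_end`, for bit-stable
#' reports).  Coordinates are 0-based, half-open.
#'
#' @param read an [srna_reads()] object (all reads are matched) or a single
#'   base string.
#' @param spec an [adapter_spec()].
#' @return A data frame with one row per read: `read_start`, `read_end`,
#'   `adapter_bases_aligned`, `errors`, `matched`.  Unmatched reads carry
#'   `NA` coordinates and `matched = FALSE`.
#' @examples
#' ad <- adapter_presets("illumina-truseq-smallrna")$adapter3
#' find_adapter(ad$sequence, ad)   # a pure dimer read: match at position 0
#' @export
find_adapter <- function(read, spec) {
  bases <- if (inherits(read, "srna_reads")) read$bases else as.character(read)
  if (!length(bases) || any(!nzchar(bases))) stop("reads must be non-empty")
  match_adapter_vec(bases, spec)
}

# Brute-force reference matcher (exhaustive enumeration of all candidate
# alignments); exported for verification, not for production use.
#' @rdname find_adapter
#' @export
find_adapter_oracle <- function(read, spec) {
  bases <- if (inherits(read, "srna_reads")) read$bases else as.character(read)
  m <- cpp_match_adapter_oracle(bases, spec$sequence, mode_code(spec$mode),
                                spec$error_rate, spec$min_overlap)
  match_matrix_to_df(m)
}

#' Insert length implied by an adapter match
#'
#' The biological insert is the read content on the near side of the
#' adapter: bases preceding a 3'-portion hit (`read_start`), bases
#' following a 5'-portion hit (`read_length - read_end`).  A hit is in the
#' 5' portion when `read_start < read_length - read_end`; back mode always
#' reads the preceding side and front mode the following side.  An insert
#' of 0 is the adapter-dimer geometry.
#'
#' @param match data frame from [find_adapter()].
#' @param read_length integer vector of read lengths (recycled).
#' @param mode matching mode of the adapter used.
#' @return Integer vector of insert lengths; `NA` where unmatched.
#' @export
insert_length <- function(match, read_length,
                          mode = c("back", "front", "anywhere")) {
  mode <- match.arg(mode)
  if (any(!match$matched))
    stop("insert_length is only defined for matched reads")
  n <- as.integer(read_length)
  switch(mode,
         back = match$read_start,
         front = n - match$read_end,
         anywhere = {
           five_prime <- match$read_start < (n - match$read_end)
           ifelse(five_prime, n - match$read_end, match$read_start)
         })
}
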