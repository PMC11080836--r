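# Shared test fixtures: random sequence builders and a tiny pure-R
# alignment oracle used to cross-validate the compiled brute-force
# reference on small inputs.

rand_dna <- function(n, with_n = FALSE) {
  alph <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  prob <- if (with_n) c(rep(0.24, 4), 0.04) else NULL
  paste(sample(alph, n, replace = TRUE, prob = prob), collapse = "")
}

const_qual_reads <- function(bases, q = 40L) {
  srna_reads(sprintf("r%03d", seq_along(bases)), bases,
             vapply(nchar(bases),
                    function(L) paste(rep(intToUtf8(q + 33L), L),
                                      collapse = ""), character(1)))
}

# Pure-R exhaustive matcher over all (start, end, adapter span)
# candidates.  Edit distances come from utils::adist; 'N matches nothing'
# is enforced by mapping read and adapter Ns onto distinct sentinels.
r_oracle_match <- function(read, spec) {
  read <- chartr("N", "#", read)
  ad <- chartr("N", "%", spec$sequence)
  n <- nchar(read); m <- nchar(ad)
  edist <- function(a, b) as.integer(utils::adist(a, b))
  cands <- list()
  push <- function(errors, aligned, start, end) {
    if (aligned < spec$min_overlap) return()
    if (errors > floor(spec$error_rate * aligned + 1e-9)) return()
    cands[[length(cands) + 1L]] <<- c(errors, aligned, start, end)
  }
  for (s in 0:n) for (e in s:n)       # full adapter, free both ends
    push(edist(ad, substr(read, s + 1L, e)), m, s, e)
  if (spec$mode != "front")            # adapter prefix at read 3' end
    for (i in 1:(m - 1L)) for (s in 0:n)
      push(edist(substr(ad, 1L, i), substr(read, s + 1L, n)), i, s, n)
  if (spec$mode != "back")             # adapter suffix at read 5' start
    for (i in 1:(m - 1L)) for (e in 0:n)
      push(edist(substr(ad, m - i + 1L, m), substr(read, 1L, e)), i, 0L, e)
  if (!length(cands))
    return(data.frame(read_start = NA_integer_, read_end = NA_integer_,
                      adapter_bases_aligned = NA_integer_,
                      errors = NA_integer_, matched = FALSE))
  cm <- do.call(rbind, cands)
  ord <- order(cm[, 1], -cm[, 2], cm[, 3], cm[, 4])
  b <- cm[ord[1], ]
  data.frame(read_start = b[3], read_end = b[4],
             adapter_bases_aligned = b[2], errors = b[1], matched = TRUE)
}

expect_match_equal <- function(a, b) {
  expect_equal(a$matched, b$matched)
  expect_equal(a$read_start, b$read_start)
  expect_equal(a$read_end, b$read_end)
  expect_equal(a$adapter_bases_aligned, b$adapter_bases_aligned)
  expect_equal(a$errors, b$errors)
}

ion_profile <- function() platform_preset("iontorrent-smallrna")
ill_profile <- function() platform_preset("illumina-truseq-smallrna")
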