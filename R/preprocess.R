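#' Platform profile: one pre-processing dialect
#'
#' A platform profile fixes everything the read classifier needs: the 3'
#' adapter (and optional 5' primer) with their matching dialects, the
#' quality-trimming threshold, the minimum informative insert length, the
#' maximum insert length still called an adapter dimer, and (Illumina) the
#' fixed instrument read length.
#'
#' @param name profile label.
#' @param adapter3 an [adapter_spec()] for the 3' adapter.
#' @param adapter5 optional [adapter_spec()] for a 5' primer/adapter pass.
#' @param quality_threshold Phred threshold for 3' quality trimming
#'   (default 20, i.e. bases with q < 20 are trim candidates).
#' @param min_length minimum insert length kept after trimming (nt).
#' @param dimer_max_insert largest insert still classified as an adapter
#'   dimer; the default 2 tolerates a couple of junk bases at the ligation
#'   junction, and 0 recovers the strict adapter-at-position-0 definition.
#' @param fixed_read_length instrument read length for fixed-length
#'   platforms, or `NA` for variable-length reads.
#' @return An object of class `platform_profile`.
#' @export
platform_profile <- function(name, adapter3, adapter5 = NULL,
                             quality_threshold = 20L, min_length = 15L,
                             dimer_max_insert = 2L,
                             fixed_read_length = NA_integer_) {
  stopifnot(inherits(adapter3, "adapter_spec"),
            is.null(adapter5) || inherits(adapter5, "adapter_spec"),
            min_length > dimer_max_insert, dimer_max_insert >= 0,
            quality_threshold >= 0, quality_threshold <= 41)
  structure(list(name = name, adapter3 = adapter3, adapter5 = adapter5,
                 quality_threshold = as.integer(quality_threshold),
                 min_length = as.integer(min_length),
                 dimer_max_insert = as.integer(dimer_max_insert),
                 fixed_read_length = as.integer(fixed_read_length)),
            class = "platform_profile")
}

#' @rdname platform_profile
#' @param preset preset name, see [adapter_presets()].
#' @export
platform_preset <- function(preset = c("illumina-truseq-smallrna",
                                       "iontorrent-smallrna")) {
  preset <- match.arg(preset)
  ad <- adapter_presets(preset)
  if (preset == "illumina-truseq-smallrna") {
    platform_profile(preset, ad$adapter3, ad$adapter5,
                     fixed_read_length = 75L)
  } else {
    platform_profile(preset, ad$adapter3)
  }
}

#' @export
print.platform_profile <- function(x, ...) {
  cat(sprintf(paste0("platform_profile '%s': q>=%d, min_length %d, ",
                     "dimer_max_insert %d\n"),
              x$name, x$quality_threshold, x$min_length, x$dimer_max_insert))
  print(x$adapter3)
  if (!is.null(x$adapter5)) print(x$adapter5)
  invisible(x)
}

# internal unvalidated constructor: trimmed reads may be empty
new_reads <- function(read_id, bases, quals) {
  structure(list(read_id = read_id, bases = bases, quals = quals),
            class = "srna_reads")
}

#' Trim low-quality 3' ends
#'
#' Removes the 3' suffix chosen by the partial-sum rule (the standard
#' BWA-style `-q` algorithm): cut at the position minimising the running
#' sum of `qual - threshold` accumulated from the 3' end; ties keep the
#' longest read.  Reads may come back empty.
#'
#' @param reads an [srna_reads()] object.
#' @param threshold Phred threshold.
#' @return The trimmed reads (class `srna_reads`; possibly empty strings).
#' @export
quality_trim_end <- function(reads, threshold) {
  stopifnot(threshold >= 0)
  keep <- cpp_trim_lengths(reads$quals, as.integer(threshold))
  new_reads(reads$read_id, substr(reads$bases, 1L, keep),
            substr(reads$quals, 1L, keep))
}

# Keep interval [s, e) (0-based) implied by an adapter match, per mode.
trim_interval <- function(match, read_len, mode) {
  s <- integer(length(read_len)); e <- read_len
  hit <- match$matched
  if (mode == "back") {
    e[hit] <- match$read_start[hit]
  } else if (mode == "front") {
    s[hit] <- match$read_end[hit]
  } else {
    five <- hit & (match$read_start < read_len - match$read_end)
    s[five] <- match$read_end[five]
    three <- hit & !five
    e[three] <- match$read_start[three]
  }
  list(s = s, e = e)
}

# Full classification pipeline; returns per-read detail for aggregation.
classify_core <- function(reads, profile) {
  n <- length(reads)
  read_len <- nchar(reads$bases)
  m3 <- match_adapter_vec(reads$bases, profile$adapter3)
  ins <- rep(NA_integer_, n)
  if (any(m3$matched))
    ins[m3$matched] <- insert_length(m3[m3$matched, , drop = FALSE],
                                     read_len[m3$matched],
                                     profile$adapter3$mode)
  is_dimer <- m3$matched & !is.na(ins) & ins <= profile$dimer_max_insert

  iv <- trim_interval(m3, read_len, profile$adapter3$mode)
  bases <- substr(reads$bases, iv$s + 1L, iv$e)
  quals <- substr(reads$quals, iv$s + 1L, iv$e)

  if (!is.null(profile$adapter5)) {
    todo <- which(!is_dimer & nzchar(bases))
    if (length(todo)) {
      m5 <- match_adapter_vec(bases[todo], profile$adapter5)
      iv5 <- trim_interval(m5, nchar(bases[todo]), profile$adapter5$mode)
      bases[todo] <- substr(bases[todo], iv5$s + 1L, iv5$e)
      quals[todo] <- substr(quals[todo], iv5$s + 1L, iv5$e)
    }
  }

  pre_q_len <- nchar(bases)
  keep <- cpp_trim_lengths(quals, profile$quality_threshold)
  bases <- substr(bases, 1L, keep)
  quals <- substr(quals, 1L, keep)
  final_len <- nchar(bases)

  cls <- rep("CLEAN", n)
  too_short <- final_len < profile$min_length
  cls[too_short & (m3$matched | pre_q_len < profile$min_length)] <- "SHORT"
  cls[too_short & !(m3$matched | pre_q_len < profile$min_length)] <-
    "LOW_QUALITY"
  cls[is_dimer] <- "DIMER"
  cls <- factor(cls, levels = c("DIMER", "SHORT", "LOW_QUALITY", "CLEAN"))

  list(class = cls, match3 = m3, insert = ins,
       trimmed = new_reads(reads$read_id, bases, quals),
       read_len = read_len)
}

#' Classify reads into dimer / short / low-quality / clean
#'
#' Per-read pipeline: (1) locate the 3' adapter; a match with insert
#' length at most `dimer_max_insert` is an adapter `DIMER`.  (2) Trim the
#' adapter (and the 5' primer, if the profile configures one).  (3)
#' Quality-trim the 3' end.  (4) Reads ending below `min_length` are
#' `SHORT` when an adapter was found or the read was already short before
#' quality trimming, otherwise `LOW_QUALITY`.  (5) Everything else is
#' `CLEAN`.
#'
#' @param reads an [srna_reads()] object.
#' @param profile a [platform_profile()].
#' @return A list: `class` (factor, one level per read), `trimmed`
#'   (`srna_reads` of post-trimming reads, possibly empty strings) and
#'   `insert` (insert length where the 3' adapter matched, else `NA`).
#' @export
classify_reads <- function(reads, profile) {
  res <- classify_core(reads, profile)
  list(class = res$class, trimmed = res$trimmed, insert = res$insert)
}

#' Per-sample QC aggregation
#'
#' Streams `classify_reads` over a sample and aggregates: raw/class
#' counts (which partition the raw count exactly), read-loss percentages,
#' the cumulative 3'-adapter content curve over read positions, exact
#' overrepresented-sequence counts and mean quality per position.
#'
#' @param reads an [srna_reads()] object, or a FASTQ path which is
#'   streamed chunk-wise under bounded memory.
#' @param profile a [platform_profile()].
#' @param sample_id sample label.
#' @param overrep_threshold_pct report sequences above this percentage of
#'   all reads (strictly greater; default 0.1).
#' @param clean_out optional FASTQ path receiving the trimmed CLEAN reads.
#' @param chunk_size records per streamed chunk when `reads` is a path.
#' @return An object of class `sample_qc`.
#' @export
process_sample <- function(reads, profile, sample_id,
                           overrep_threshold_pct = 0.1, clean_out = NULL,
                           chunk_size = 100000L) {
  state <- new.env(parent = emptyenv())
  state$n <- 0L
  state$class_counts <- c(DIMER = 0L, SHORT = 0L, LOW_QUALITY = 0L,
                          CLEAN = 0L)
  state$start_tab <- integer(0)     # adapter match starts (0-based), tab
  state$qual_sum <- numeric(0)      # per-position quality sums
  state$qual_n <- integer(0)
  state$seq_counts <- integer(0)    # named: exact sequence counts
  state$wrote_clean <- FALSE

  grow <- function(x, len, fill = 0) {
    if (length(x) < len) x <- c(x, rep(fill, len - length(x)))
    x
  }
  eat <- function(chunk) {
    res <- classify_core(chunk, profile)
    state$n <- state$n + length(chunk)
    tc <- table(res$class)
    state$class_counts <- state$class_counts + as.integer(tc[names(
      state$class_counts)])
    maxlen <- max(res$read_len, 0L)
    hit <- res$match3$matched
    if (any(hit)) {
      tab <- tabulate(res$match3$read_start[hit] + 1L, nbins = maxlen)
      state$start_tab <- grow(state$start_tab, maxlen, 0L)
      state$start_tab[seq_len(maxlen)] <-
        state$start_tab[seq_len(maxlen)] + tab
    } else {
      state$start_tab <- grow(state$start_tab, maxlen, 0L)
    }
    qs <- qual_position_sums(chunk$quals)
    state$qual_sum <- grow(state$qual_sum, length(qs$sum))
    state$qual_n <- grow(state$qual_n, length(qs$n), 0L)
    idx <- seq_along(qs$sum)
    state$qual_sum[idx] <- state$qual_sum[idx] + qs$sum
    state$qual_n[idx] <- state$qual_n[idx] + qs$n
    tt <- table(chunk$bases)
    all_names <- union(names(state$seq_counts), names(tt))
    merged <- integer(length(all_names)); names(merged) <- all_names
    merged[names(state$seq_counts)] <- state$seq_counts
    merged[names(tt)] <- merged[names(tt)] + as.integer(tt)
    state$seq_counts <- merged
    if (!is.null(clean_out)) {
      cl <- which(res$class == "CLEAN")
      write_fastq(subset_reads(res$trimmed, cl), clean_out,
                  append = state$wrote_clean)
      state$wrote_clean <- TRUE
    }
    NULL
  }

  if (is.character(reads)) {
    fastq_chunk_apply(reads, eat, chunk_size = chunk_size)
  } else {
    if (length(reads)) eat(reads)
    else if (!is.null(clean_out)) write_fastq(reads, clean_out)
  }

  n_raw <- state$n
  cc <- state$class_counts
  flags <- character(0)
  if (n_raw == 0L) flags <- "empty_sample"
  pct <- function(k) if (n_raw > 0L) 100 * k / n_raw else NA_real_
  curve <- if (n_raw > 0L) 100 * cumsum(state$start_tab) / n_raw
           else numeric(0)
  over <- overrepresented_from_counts(state$seq_counts, n_raw,
                                      overrep_threshold_pct)
  meanq <- ifelse(state$qual_n > 0L, state$qual_sum / state$qual_n,
                  NA_real_)
  qc <- structure(list(
    sample_id = sample_id,
    n_raw = n_raw,
    n_dimer = unname(cc["DIMER"]), n_short = unname(cc["SHORT"]),
    n_lowq = unname(cc["LOW_QUALITY"]), n_clean = unname(cc["CLEAN"]),
    pct_dimer = pct(cc[["DIMER"]]), pct_short = pct(cc[["SHORT"]]),
    pct_lowq = pct(cc[["LOW_QUALITY"]]), pct_clean = pct(cc[["CLEAN"]]),
    pct_read_loss = if (n_raw > 0L) 100 * (n_raw - cc[["CLEAN"]]) / n_raw
                    else NA_real_,
    adapter_content_curve = curve,
    overrepresented = over,
    mean_quality_per_position = as.numeric(meanq),
    parameters = profile_parameters(profile),
    flags = flags), class = "sample_qc")
  qc
}

profile_parameters <- function(profile) {
  list(profile = profile$name,
       adapter3 = profile$adapter3$sequence,
       adapter3_mode = profile$adapter3$mode,
       adapter3_error_rate = profile$adapter3$error_rate,
       adapter5 = if (is.null(profile$adapter5)) NULL
                  else profile$adapter5$sequence,
       quality_threshold = profile$quality_threshold,
       min_length = profile$min_length,
       dimer_max_insert = profile$dimer_max_insert)
}

#' @export
print.sample_qc <- function(x, ...) {
  cat(sprintf("sample_qc '%s': %d raw reads\n", x$sample_id, x$n_raw))
  if (x$n_raw > 0L)
    cat(sprintf(
      "  dimer %.1f%%  short %.1f%%  low-quality %.1f%%  clean %.1f%%  (read loss %.1f%%)\n",
      x$pct_dimer, x$pct_short, x$pct_lowq, x$pct_clean, x$pct_read_loss))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

qual_position_sums <- function(quals) {
  if (!length(quals)) return(list(sum = numeric(0), n = integer(0)))
  maxlen <- max(nchar(quals))
  s <- numeric(maxlen); cnt <- integer(maxlen)
  for (q in quals) {
    v <- utf8ToInt(q) - 33L
    idx <- seq_along(v)
    s[idx] <- s[idx] + v
    cnt[idx] <- cnt[idx] + 1L
  }
  list(sum = s, n = cnt)
}

#' Cumulative 3'-adapter content per read position
#'
#' `curve[p]` is the percentage of reads whose 3'-adapter match starts at
#' 0-based position `p - 1` or earlier; the curve is non-decreasing and
#' bounded by 100.  A high value at the first positions is the
#' adapter-dimer signature: the first sequenced base is already adapter.
#'
#' @param reads an [srna_reads()] object.
#' @param adapter3 an [adapter_spec()].
#' @return Numeric vector over read positions (1-based indexing of the
#'   vector corresponds to 0-based read positions).
#' @export
adapter_content_curve <- function(reads, adapter3) {
  if (!length(reads)) stop("reads must be non-empty")
  m <- match_adapter_vec(reads$bases, adapter3)
  maxlen <- max(nchar(reads$bases))
  tab <- tabulate(m$read_start[m$matched] + 1L, nbins = maxlen)
  100 * cumsum(tab) / length(reads)
}

overrepresented_from_counts <- function(counts, n_raw, threshold_pct) {
  if (!length(counts) || n_raw == 0L)
    return(data.frame(sequence = character(0), count = integer(0),
                      percentage = numeric(0)))
  pct <- 100 * counts / n_raw
  keep <- pct > threshold_pct
  counts <- counts[keep]; pct <- pct[keep]
  ord <- order(-counts, names(counts), method = "radix")
  data.frame(sequence = names(counts)[ord],
             count = unname(counts[ord]),
             percentage = unname(pct[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exact overrepresented-sequence counts
#'
#' Counts identical full read sequences and reports those present at a
#' percentage strictly greater than `threshold_pct` of all reads, sorted
#' by count (descending) then sequence.  In a diverse library no sequence
#' should pass; full 3' adapter sequences passing are the post-sequencing
#' dimer fingerprint.
#'
#' @param reads an [srna_reads()] object.
#' @param threshold_pct reporting threshold (percent, default 0.1).
#' @return Data frame with columns `sequence`, `count`, `percentage`.
#' @export
overrepresented_sequences <- function(reads, threshold_pct = 0.1) {
  if (!length(reads)) stop("reads must be non-empty")
  tt <- table(reads$bases)
  overrepresented_from_counts(
    structure(as.integer(tt), names = names(tt)), length(reads),
    threshold_pct)
}
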