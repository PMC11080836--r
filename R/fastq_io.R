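#' Construct a set of sequencing reads
#'
#' `srna_reads` is the package's read container: parallel vectors of read
#' ids, base strings over \{A,C,G,T,N\} and Phred quality strings
#' (offset-33 encoded, one character per base).  All per-read operations in
#' the package are vectorised over this container.
#'
#' @param read_id character vector of read identifiers.
#' @param bases character vector of base strings.
#' @param quals character vector of Phred+33 quality strings, same lengths
#'   as `bases`; alternatively a list of integer Phred scores.
#' @return An object of class `srna_reads`.
#' @export
srna_reads <- function(read_id, bases, quals) {
  if (is.list(quals)) quals <- vapply(quals, phred_encode, character(1))
  stopifnot(length(read_id) == length(bases),
            length(bases) == length(quals))
  x <- list(read_id = as.character(read_id), bases = toupper(bases),
            quals = as.character(quals))
  class(x) <- "srna_reads"
  validate_srna_reads(x)
  x
}

validate_srna_reads <- function(x) {
  nb <- nchar(x$bases); nq <- nchar(x$quals)
  bad <- which(nb != nq)
  if (length(bad))
    stop("quality length differs from sequence length for record(s) ",
         paste(head(bad, 5L), collapse = ", "))
  if (any(nb == 0L) && length(nb))
    stop("empty sequence in record(s) ",
         paste(head(which(nb == 0L), 5L), collapse = ", "))
  if (length(x$bases) && grepl("[^ACGTN]", paste(x$bases, collapse = "")))
    stop("bases outside {A,C,G,T,N}")
  qr <- range_phred(x$quals)
  if (length(x$quals) && (qr[1] < 0L || qr[2] > 60L))
    stop("Phred scores outside [0, 60]; offset-64 encoded input is ",
         "rejected, not guessed")
  invisible(x)
}

range_phred <- function(quals) {
  if (!length(quals)) return(c(0L, 0L))
  codes <- utf8ToInt(paste(quals, collapse = ""))
  if (!length(codes)) return(c(0L, 0L))
  range(codes) - 33L
}

#' @export
length.srna_reads <- function(x) length(x$read_id)

#' @export
print.srna_reads <- function(x, ...) {
  cat("srna_reads with", length(x), "read(s)\n")
  n <- min(3L, length(x))
  for (i in seq_len(n))
    cat(sprintf("  %s  %s\n", x$read_id[i], x$bases[i]))
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

subset_reads <- function(x, i) {
  out <- list(read_id = x$read_id[i], bases = x$bases[i], quals = x$quals[i])
  class(out) <- "srna_reads"
  out
}

concat_reads <- function(a, b) {
  out <- list(read_id = c(a$read_id, b$read_id),
              bases = c(a$bases, b$bases), quals = c(a$quals, b$quals))
  class(out) <- "srna_reads"
  out
}

phred_encode <- function(q) intToUtf8(as.integer(q) + 33L)
phred_decode <- function(s) utf8ToInt(s) - 33L

#' Read a FASTQ file
#'
#' Parses 4-line FASTQ records with Phred+33 qualities.  gzip-compressed
#' input is decompressed transparently (detected from the file's magic
#' bytes by the connection layer, not from its extension).  Malformed
#' records - a quality string whose length differs from the sequence, a
#' truncated trailing record, a missing `@`/`+` marker - raise an error
#' naming the 1-based record index.
#'
#' @param path path to a FASTQ or FASTQ.gz file.
#' @return An [srna_reads()] object with the records in file order.
#' @seealso [fastq_chunk_apply()] for bounded-memory streaming.
#' @export
read_fastq <- function(path) {
  acc <- NULL
  fastq_chunk_apply(path, function(chunk) {
    acc <<- if (is.null(acc)) chunk else concat_reads(acc, chunk)
    NULL
  })
  if (is.null(acc)) acc <- srna_reads(character(0), character(0),
                                      character(0))
  acc
}

#' Stream a FASTQ file in fixed-size chunks
#'
#' Applies `fun` to successive [srna_reads()] chunks of at most
#' `chunk_size` records, so memory use is bounded by the chunk size rather
#' than the file size.
#'
#' @param path FASTQ path (plain or gzip).
#' @param fun function taking one `srna_reads` chunk.
#' @param chunk_size records per chunk.
#' @return Invisibly, the number of records processed.
#' @export
fastq_chunk_apply <- function(path, fun, chunk_size = 100000L) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- gzfile(path, open = "rt")   # gzfile sniffs magic bytes; plain ok
  on.exit(close(con))
  done <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_size)
    if (!length(lines)) break
    if (length(lines) %% 4L != 0L)
      stop("truncated FASTQ record at record ",
           done + length(lines) %/% 4L + 1L, " in ", path)
    idx <- seq(1L, length(lines), by = 4L)
    hdr <- lines[idx]; seqs <- lines[idx + 1L]
    plus <- lines[idx + 2L]; quals <- lines[idx + 3L]
    bad <- which(substr(hdr, 1L, 1L) != "@" | substr(plus, 1L, 1L) != "+")
    if (length(bad))
      stop("malformed FASTQ record at record ", done + bad[1L], " in ", path)
    bad <- which(nchar(seqs) != nchar(quals))
    if (length(bad))
      stop("sequence/quality length mismatch at record ", done + bad[1L],
           " in ", path)
    ids <- sub("^@", "", hdr)
    ids <- sub("[ \t].*$", "", ids)
    chunk <- srna_reads(ids, seqs, quals)
    fun(chunk)
    done <- done + length(chunk)
    if (length(lines) < 4L * chunk_size) break
  }
  invisible(done)
}

#' Write reads to a FASTQ file
#'
#' Writes 4-line Phred+33 records; paths ending in `.gz` are
#' gzip-compressed.  Round-trips through [read_fastq()] reproduce the
#' input exactly.
#'
#' @param reads an [srna_reads()] object.
#' @param path output path.
#' @param append append to an existing file (used by streaming writers).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, append = FALSE) {
  con <- if (grepl("\\.gz$", path)) {
    gzfile(path, open = if (append) "ab" else "wb")
  } else {
    file(path, open = if (append) "ab" else "wb")
  }
  on.exit(close(con))
  if (length(reads)) {
    out <- rbind(paste0("@", reads$read_id), reads$bases, "+", reads$quals)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}

#' Write / read a QC report as JSON
#'
#' The report schema is stable and versioned: `schema_version`,
#' `tool_version`, the resolved platform parameters, per-class counts and
#' percentages, and the diagnostic curves.
#'
#' @param qc a `sample_qc` object from [process_sample()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(qc, path) {
  stopifnot(inherits(qc, "sample_qc"))
  payload <- unclass(qc)
  payload$schema_version <- 1L
  payload$tool_version <- dimerqc_version()
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_qc_json
#' @export
read_qc_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$schema_version <- NULL; x$tool_version <- NULL
  class(x) <- "sample_qc"
  x
}

#' Write / read a TSV table with a header row
#'
#' @param x a data frame.
#' @param path file path.
#' @return `path` (write) or a data frame (read).
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, comment.char = "#")
}
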