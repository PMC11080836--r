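# brute-force reference for the 3' partial-sum quality trimmer: try all
# cut positions, minimise the sum of (q - t) over the removed suffix,
# keep the longest read among ties.
brute_trim_keep <- function(q, t) {
  f <- vapply(0:length(q), function(k)
    sum(q[seq_len(length(q) - k) + k] - t), numeric(1))
  # f[k+1] = sum over removed suffix when keeping k bases
  max(which(f == min(f))) - 1L
}

test_that("quality trimming follows the partial-sum rule", {
  mk <- function(q) srna_reads("r", strrep("A", length(q)), list(q))
  expect_equal(nchar(quality_trim_end(mk(rep(40, 10)), 20)$bases), 10L)
  expect_equal(nchar(quality_trim_end(mk(rep(2, 10)), 20)$bases), 0L)
  q <- c(40, 40, 10, 40, 5, 5)
  expect_equal(nchar(quality_trim_end(mk(q), 20)$bases),
               brute_trim_keep(q, 20))
  set.seed(12)
  for (i in 1:200) {
    q <- sample(0:41, sample(1:30, 1), replace = TRUE)
    t <- sample(0:30, 1)
    expect_equal(nchar(quality_trim_end(mk(q), t)$bases),
                 brute_trim_keep(q, t))
  }
})

test_that("single reads classify by the dimer/short/clean geometry", {
  prof <- ill_profile()
  ad <- prof$adapter3$sequence
  dimer <- const_qual_reads(paste0(ad, substr(strrep("ATCTCGTATGCCG", 10),
                                              1, 75 - nchar(ad))))
  expect_equal(as.character(classify_reads(dimer, prof)$class), "DIMER")
  set.seed(8)
  clean <- const_qual_reads(substr(paste0(rand_dna(22), ad, rand_dna(40)),
                                   1, 75))
  res <- classify_reads(clean, prof)
  expect_equal(as.character(res$class), "CLEAN")
  expect_equal(nchar(res$trimmed$bases), 22L)
  short <- const_qual_reads(substr(paste0(rand_dna(10), ad, rand_dna(40)),
                                   1, 75))
  expect_equal(as.character(classify_reads(short, prof)$class), "SHORT")
})

test_that("adapterless reads collapsing under quality trimming are LOW_QUALITY", {
  prof <- ill_profile()
  bases <- strrep("A", 75)   # provably adapter-free
  lowq <- srna_reads("r", bases, list(c(rep(35, 10), rep(2, 65))))
  expect_equal(as.character(classify_reads(lowq, prof)$class),
               "LOW_QUALITY")
  # same read with good quality is CLEAN (no adapter found, full length)
  good <- const_qual_reads(bases)
  expect_equal(as.character(classify_reads(good, prof)$class), "CLEAN")
})

test_that("process_sample reproduces an exactly constructed composition", {
  prof <- ill_profile()
  ad <- prof$adapter3$sequence
  set.seed(33)
  mk75 <- function(core) substr(paste0(core, rand_dna(80)), 1, 75)
  bases <- c(replicate(40, mk75(ad)),                       # dimers
             replicate(10, mk75(paste0(rand_dna(8), ad))),  # short inserts
             replicate(50, mk75(paste0(rand_dna(22), ad)))) # clean
  qc <- process_sample(const_qual_reads(bases), prof, "constructed")
  expect_equal(qc$n_raw, 100L)
  expect_equal(qc$pct_dimer, 40)
  expect_equal(qc$pct_short, 10)
  expect_equal(qc$pct_clean, 50)
  expect_equal(qc$pct_read_loss, 50)
  expect_equal(qc$pct_read_loss, 100 * (qc$n_raw - qc$n_clean) / qc$n_raw)
})

test_that("class counts partition the raw count on simulated samples", {
  for (s in 1:4) {
    cfg <- sim_config(n_reads = 800L, dimer_fraction = runif(1, 0, 0.6),
                      short_fraction = runif(1, 0, 0.3),
                      platform = sample(c("illumina", "iontorrent"), 1),
                      substitution_rate = 0.01, seed = 100L + s)
    lib <- simulate_library(cfg)
    prof <- if (cfg$platform == "illumina") ill_profile() else ion_profile()
    qc <- process_sample(lib$reads, prof, paste0("s", s))
    expect_identical(qc$n_raw,
                     qc$n_dimer + qc$n_short + qc$n_lowq + qc$n_clean)
    expect_equal(qc$pct_dimer + qc$pct_short + qc$pct_lowq,
                 qc$pct_read_loss, tolerance = 1e-12)
  }
})

test_that("noisy simulated fractions are recovered within 3 binomial SE", {
  cfg <- sim_config(n_reads = 10000L, dimer_fraction = 0.4,
                    short_fraction = 0.1, platform = "iontorrent",
                    substitution_rate = 0.01, indel_rate = 0.01, seed = 7L)
  lib <- simulate_library(cfg)
  qc <- process_sample(lib$reads, ion_profile(), "noisy")
  for (cls in c("dimer", "short", "clean")) {
    p <- lib$fractions[[cls]]
    se <- sqrt(p * (1 - p) / cfg$n_reads) * 100
    expect_lt(abs(qc[[paste0("pct_", cls)]] - 100 * p), 3 * se)
  }
})

test_that("the adapter content curve is the cumulative dimer fingerprint", {
  prof <- ill_profile()
  ad <- prof$adapter3$sequence
  set.seed(44)
  mk75 <- function(core) substr(paste0(core, rand_dna(80)), 1, 75)
  dimers <- const_qual_reads(replicate(10, mk75(ad)))
  curve <- adapter_content_curve(dimers, prof$adapter3)
  expect_equal(curve[1], 100)
  noad <- const_qual_reads(replicate(10, paste(rep("A", 75), collapse = "")))
  expect_true(all(adapter_content_curve(noad, prof$adapter3) == 0))
  mix <- const_qual_reads(c(replicate(30, mk75(ad)),
                            replicate(70, mk75(paste0(rand_dna(22), ad)))))
  curve <- adapter_content_curve(mix, prof$adapter3)
  expect_equal(curve[1], 30)          # position 0
  expect_equal(curve[23], 100)        # position 22
  expect_true(all(diff(curve) >= 0))
  expect_true(all(curve <= 100))
})

test_that("overrepresented sequences use a strict threshold and stable order", {
  reads <- const_qual_reads(rep(strrep("ACGT", 5), 1000))
  ov <- overrepresented_sequences(reads)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$percentage, 100)
  set.seed(6)
  distinct <- const_qual_reads(replicate(1000, rand_dna(20)))
  expect_equal(nrow(overrepresented_sequences(distinct)), 0L)
  # one sequence at exactly the threshold percentage is excluded
  one <- const_qual_reads(c(rep(strrep("A", 20), 2),
                            replicate(1998, rand_dna(21))))
  expect_equal(nrow(overrepresented_sequences(one, threshold_pct = 0.1)),
               0L)
  ov <- overrepresented_sequences(one, threshold_pct = 0.09)
  expect_equal(ov$sequence, strrep("A", 20))
  expect_equal(ov$count, 2L)
})

test_that("an empty sample is flagged with undefined percentages", {
  empty <- srna_reads(character(0), character(0), character(0))
  qc <- process_sample(empty, ill_profile(), "void")
  expect_equal(qc$n_raw, 0L)
  expect_true("empty_sample" %in% qc$flags)
  expect_true(is.na(qc$pct_read_loss))
})

test_that("cleaned-FASTQ output contains exactly the trimmed clean reads", {
  cfg <- sim_config(n_reads = 300L, dimer_fraction = 0.4,
                    short_fraction = 0.2, seed = 15L)
  lib <- simulate_library(cfg)
  out <- withr::local_tempfile(fileext = ".fastq.gz")
  qc <- process_sample(lib$reads, ill_profile(), "s", clean_out = out)
  cleaned <- read_fastq(out)
  expect_length(cleaned, qc$n_clean)
  expect_true(all(nchar(cleaned$bases) >= ill_profile()$min_length))
  keep <- lib$truth$true_class == "CLEAN"
  expect_equal(cleaned$read_id, lib$reads$read_id[keep])
  expect_equal(nchar(cleaned$bases), lib$truth$true_insert_length[keep])
})
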