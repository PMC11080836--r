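test_that("identical config and seed give bit-identical libraries", {
  cfg <- sim_config(n_reads = 300L, dimer_fraction = 0.3,
                    substitution_rate = 0.01, seed = 5L)
  a <- simulate_library(cfg); b <- simulate_library(cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  cfg2 <- cfg; cfg2$seed <- 6L
  expect_false(identical(simulate_library(cfg2)$reads$bases,
                         a$reads$bases))
})

test_that("pure dimer libraries classify as all DIMER on both platforms", {
  for (plat in c("illumina", "iontorrent")) {
    cfg <- sim_config(n_reads = 300L, dimer_fraction = 1,
                      short_fraction = 0, platform = plat, q_sd = 0,
                      seed = 2L)
    lib <- simulate_library(cfg)
    prof <- if (plat == "illumina") ill_profile() else ion_profile()
    cl <- classify_reads(lib$reads, prof)
    expect_true(all(cl$class == "DIMER"))
    expect_true(all(lib$truth$true_insert_length == 0L))
  }
})

test_that("noise-free clean libraries round-trip read-for-read", {
  for (plat in c("illumina", "iontorrent")) {
    cfg <- sim_config(n_reads = 400L, dimer_fraction = 0,
                      short_fraction = 0, platform = plat, q_sd = 0,
                      seed = 3L)
    lib <- simulate_library(cfg)
    prof <- if (plat == "illumina") ill_profile() else ion_profile()
    cl <- classify_reads(lib$reads, prof)
    expect_true(all(cl$class == "CLEAN"))
    expect_equal(nchar(cl$trimmed$bases), lib$truth$true_insert_length)
  }
})

test_that("construct geometry matches the platform", {
  ill <- simulate_library(sim_config(n_reads = 200L, dimer_fraction = 0.3,
                                     short_fraction = 0.3, seed = 8L))
  expect_true(all(nchar(ill$reads$bases) == 75L))
  ion <- simulate_library(sim_config(n_reads = 200L, dimer_fraction = 0.3,
                                     short_fraction = 0.3,
                                     platform = "iontorrent", seed = 8L))
  expect_gt(length(unique(nchar(ion$reads$bases))), 3L)
  # dimer reads start with the full 3' adapter
  ad <- ion_profile()$adapter3$sequence
  dimers <- ion$reads$bases[ion$truth$true_class == "DIMER"]
  expect_true(all(substr(dimers, 1, nchar(ad)) == ad))
})

test_that("truth bookkeeping is internally consistent", {
  cfg <- sim_config(n_reads = 500L, dimer_fraction = 0.25,
                    short_fraction = 0.15, seed = 12L)
  lib <- simulate_library(cfg)
  expect_equal(sum(lib$feature_counts),
               sum(lib$truth$true_class == "CLEAN"))
  expect_equal(unname(lib$fractions["dimer"]),
               mean(lib$truth$true_class == "DIMER"))
  expect_true(all(lib$truth$true_insert_length[
    lib$truth$true_class == "SHORT"] < cfg$min_length))
  expect_true(all(lib$truth$true_insert_length[
    lib$truth$true_class == "SHORT"] > cfg$dimer_max_insert))
})

test_that("recovery error against the configured rate shrinks with library size", {
  err_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- sim_config(n_reads = n, dimer_fraction = 0.4,
                        short_fraction = 0.1, platform = "iontorrent",
                        substitution_rate = 0.01, seed = s)
      lib <- simulate_library(cfg)
      qc <- process_sample(lib$reads, ion_profile(), "s")
      abs(qc$pct_dimer / 100 - cfg$dimer_fraction)
    }, numeric(1)))
  }
  e500 <- err_at(500L, 51:58)
  e8000 <- err_at(8000L, 51:58)
  expect_lt(e8000, e500)
  # roughly the 1/sqrt(n) regime: a 16x larger library should cut the
  # mean error well beyond half
  expect_lt(e8000, e500 / 1.5)
})

test_that("raising the dimer fraction raises classified read loss", {
  losses <- vapply(c(0.1, 0.5, 0.9), function(df) {
    cfg <- sim_config(n_reads = 600L, dimer_fraction = df,
                      short_fraction = 0.05, seed = 14L)
    lib <- simulate_library(cfg)
    process_sample(lib$reads, ill_profile(), "s")$pct_read_loss
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("cohorts are reproducible and their counts sum to clean reads", {
  cfg <- sim_config(n_reads = 400L, n_features = 50L, seed = 9L)
  a <- simulate_cohort(4, c(0.1, 0.2, 0.4, 0.7), cfg)
  b <- simulate_cohort(4, c(0.1, 0.2, 0.4, 0.7), cfg)
  expect_identical(a$counts, b$counts)
  for (s in 1:4)
    expect_equal(sum(a$counts[, s]),
                 sum(a$libraries[[s]]$truth$true_class == "CLEAN"))
  # count-only mode agrees in expectation and is deterministic
  c1 <- simulate_cohort(4, c(0.1, 0.2, 0.4, 0.7), cfg, emit_reads = FALSE)
  c2 <- simulate_cohort(4, c(0.1, 0.2, 0.4, 0.7), cfg, emit_reads = FALSE)
  expect_identical(c1$counts, c2$counts)
  expect_equal(unname(colSums(c1$counts)) / cfg$n_reads,
               1 - c(0.1, 0.2, 0.4, 0.7) - cfg$short_fraction,
               tolerance = 0.1)
})

test_that("dimer-coupled composition bias tilts abundances along one direction", {
  cfg0 <- sim_config(n_reads = 5000L, n_features = 40L, seed = 22L,
                     dimer_bias_coupling = 0)
  cfg1 <- sim_config(n_reads = 5000L, n_features = 40L, seed = 22L,
                     dimer_bias_coupling = 2)
  fr <- c(0.05, 0.05, 0.8, 0.8)
  co0 <- simulate_cohort(4, fr, cfg0, emit_reads = FALSE)
  co1 <- simulate_cohort(4, fr, cfg1, emit_reads = FALSE)
  # without coupling, low- and high-dimer samples share composition
  p0 <- prop.table(co0$counts, 2)
  expect_lt(max(abs(rowMeans(p0[, 1:2]) - rowMeans(p0[, 3:4]))), 0.05)
  # with coupling, the shift follows the bias direction's sign
  p1 <- prop.table(co1$counts, 2)
  shift <- rowMeans(p1[, 3:4]) - rowMeans(p1[, 1:2])
  expect_gt(cor(shift, co1$bias_direction), 0.5)
})

test_that("cohort export writes loadable FASTQ, truth and counts files", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_reads = 100L, n_features = 20L, seed = 33L)
  co <- simulate_cohort(2, c(0.2, 0.6), cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "sample_01.fastq.gz")))
  reads <- read_fastq(file.path(dir, "sample_01.fastq.gz"))
  expect_length(reads, 100L)
  counts <- read_count_matrix(file.path(dir, "counts.tsv"))
  expect_equal(unname(counts), unname(co$counts))
  truth <- read_tsv(file.path(dir, "truth.tsv"))
  expect_equal(truth$sample_id, c("sample_01", "sample_02"))
})
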