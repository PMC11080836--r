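test_that("the TruSeq 3' adapter matches itself exactly at position 0", {
  ad <- adapter_presets("illumina-truseq-smallrna")$adapter3
  m <- find_adapter(ad$sequence, ad)
  expect_true(m$matched)
  expect_equal(m$read_start, 0L)
  expect_equal(m$errors, 0L)
  expect_equal(m$adapter_bases_aligned, nchar(ad$sequence))
})

test_that("a homopolymer read cannot host any admissible alignment at zero error budget", {
  read <- strrep("A", 40)
  for (mode in c("back", "front", "anywhere")) {
    m <- find_adapter(read, adapter_spec("TGGAATTCTCGG", mode,
                                         error_rate = 0))
    expect_false(m$matched)
  }
})

test_that("an embedded adapter with a substitution and a deletion is found as the DP optimum", {
  ad <- adapter_presets("iontorrent-smallrna")$adapter3
  adbases <- strsplit(ad$sequence, "")[[1]]
  adbases[7] <- setdiff(c("A", "C", "G", "T"), adbases[7])[1]  # substitution
  mutated <- paste(adbases[-17], collapse = "")                # + deletion
  # poly-A flanks share no 3-mer with the adapter ends, so the damaged
  # embedded copy is the unique minimum-error candidate
  read <- paste0(strrep("A", 21), mutated, strrep("A", 10))
  got <- find_adapter(read, ad)
  ref <- find_adapter_oracle(read, ad)
  expect_match_equal(got, ref)
  expect_true(got$matched)
  expect_equal(got$errors, 2L)
  expect_lte(abs(got$read_start - 21L), 1L)
})

test_that("the compiled brute-force reference agrees with a pure-R enumeration on small inputs", {
  set.seed(77)
  for (i in 1:40) {
    read <- rand_dna(sample(8:16, 1), with_n = TRUE)
    spec <- adapter_spec(rand_dna(sample(8:10, 1)),
                         sample(c("back", "front", "anywhere"), 1),
                         sample(c(0, 0.1, 0.2, 0.25), 1),
                         min_overlap = sample(2:4, 1))
    expect_match_equal(find_adapter_oracle(read, spec),
                       r_oracle_match(read, spec))
  }
})

test_that("matcher equals the exhaustive DP oracle on randomized triples", {
  set.seed(2024)
  specs <- list(adapter_presets("illumina-truseq-smallrna")$adapter3,
                adapter_presets("illumina-truseq-smallrna")$adapter5,
                adapter_presets("iontorrent-smallrna")$adapter3)
  for (spec in specs) {
    for (er in c(0, 0.1, 0.2)) {
      s <- spec; s$error_rate <- er
      reads <- vapply(sample(20:100, 120, replace = TRUE),
                      rand_dna, character(1), with_n = TRUE)
      half <- sample(length(reads), 60)   # embed noisy adapter copies
      reads[half] <- vapply(reads[half], function(r) {
        pos <- sample(0:(nchar(r) - 10), 1)
        frag <- substr(s$sequence, 1, min(nchar(s$sequence),
                                          nchar(r) - pos))
        paste0(substr(r, 1, pos), frag,
               substr(r, pos + nchar(frag) + 1, nchar(r)))
      }, character(1))
      expect_match_equal(find_adapter(reads, s),
                         find_adapter_oracle(reads, s))
    }
  }
})

test_that("raising the error rate never unmatches a read, and matching is deterministic", {
  set.seed(5)
  ad <- adapter_presets("iontorrent-smallrna")$adapter3
  reads <- vapply(rep(60, 200), rand_dna, character(1))
  rates <- c(0, 0.05, 0.1, 0.2, 0.3)
  prev <- rep(FALSE, length(reads))
  for (er in rates) {
    s <- ad; s$error_rate <- er
    m <- find_adapter(reads, s)
    expect_true(all(m$matched[prev]))      # monotone in error budget
    prev <- m$matched
    expect_identical(m, find_adapter(reads, s))  # determinism
  }
})

test_that("min_overlap suppresses matches shorter than the required evidence", {
  ad <- adapter_spec("TGGAATTCTCGG", "back", error_rate = 0,
                     min_overlap = 6L)
  # read ends with only a 4-base adapter prefix: below min_overlap
  m <- find_adapter(paste0(strrep("C", 30), "TGGA"), ad)
  expect_false(m$matched)
  ad$min_overlap <- 3L
  m <- find_adapter(paste0(strrep("C", 30), "TGGA"), ad)
  expect_true(m$matched)
  expect_equal(m$adapter_bases_aligned, 4L)
})

test_that("insert lengths follow the match geometry", {
  ad <- adapter_presets("illumina-truseq-smallrna")$adapter3
  dimer <- paste0(ad$sequence, rand_dna(20))
  m <- find_adapter(dimer, ad)
  expect_equal(insert_length(m, nchar(dimer), "back"), 0L)
  insert22 <- paste0(rand_dna(22), ad$sequence)
  m <- find_adapter(insert22, ad)
  expect_equal(insert_length(m, nchar(insert22), "back"), 22L)
  expect_error(insert_length(find_adapter(strrep("A", 30), ad), 30, "back"),
               "matched")
})

test_that("measured insert lengths equal simulated truth in error-free libraries", {
  for (plat in c("illumina", "iontorrent")) {
    cfg <- sim_config(n_reads = 400L, dimer_fraction = 0.3,
                      short_fraction = 0.2, platform = plat, q_sd = 0,
                      seed = 31L)
    lib <- simulate_library(cfg)
    prof <- if (plat == "illumina") ill_profile() else ion_profile()
    m <- find_adapter(lib$reads, prof$adapter3)
    expect_true(all(m$matched))
    ins <- insert_length(m, nchar(lib$reads$bases), prof$adapter3$mode)
    expect_equal(ins, lib$truth$true_insert_length)
  }
})
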