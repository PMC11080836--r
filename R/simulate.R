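#' Configuration for a simulated small RNA library
#'
#' The generator implements the library-construct geometry of small RNA
#' sequencing: a biological insert flanked by adapters.  Three construct
#' classes are drawn per read: `DIMER` (zero-length insert, the read
#' starts with the full 3' adapter), `SHORT` (an insert below the minimum
#' informative length) and `CLEAN` (an insert drawn from a feature pool
#' with Dirichlet abundances).  Illumina reads are built as insert + 3'
#' adapter + downstream construct filler, truncated/padded to the fixed
#' instrument read length (adapter read-through); Ion Torrent reads are
#' insert + adapter at their natural, variable length.  Substitution and
#' (Ion-style) indel noise and a linear quality-decay model with Gaussian
#' jitter are applied on top.
#'
#' Defaults reflect a TruSeq-style small RNA experiment: miRNA-sized
#' inserts (mean 22 nt, sd 2, truncated to 16-30 nt, matching a 22-30 nt
#' size selection), 75 nt fixed Illumina reads, a 300-feature pool with
#' symmetric Dirichlet(1) abundances, and noise off unless requested.
#'
#' @param n_reads reads per library.
#' @param dimer_fraction,short_fraction expected fractions of dimer and
#'   short constructs (`dimer_fraction + short_fraction <= 1`).
#' @param insert_mean,insert_sd,insert_min,insert_max truncated-normal
#'   insert length distribution (nt) for clean constructs.
#' @param n_features size of the feature pool.
#' @param dirichlet_alpha symmetric Dirichlet concentration for feature
#'   abundances; ignored when `feature_probs` is given.
#' @param feature_probs optional explicit abundance simplex.
#' @param platform `"illumina"` (fixed-length, back-mode adapter) or
#'   `"iontorrent"` (variable length, anywhere-mode adapter).
#' @param fixed_read_length instrument read length (Illumina).
#' @param substitution_rate,indel_rate per-base error rates in `[0, 0.2]`;
#'   indels are an Ion Torrent characteristic and default to 0.
#' @param q_start,q_slope,q_sd linear quality model: Phred at position p
#'   is `q_start + q_slope * p` plus `N(0, q_sd)` jitter, clipped to
#'   `[2, 40]`.  `NULL` picks platform defaults (Illumina 36/-0.05/2;
#'   Ion 30/-0.08/3).
#' @param dimer_bias_coupling strength of the dimer-correlated
#'   composition bias used by [simulate_cohort()] for batch-effect power
#'   studies (multiplicative logit tilt per unit dimer fraction; 0 = no
#'   bias).
#' @param min_length,dimer_max_insert classification geometry mirrored by
#'   the generator: short inserts are drawn uniformly from
#'   `dimer_max_insert + 1` to `min_length - 1` so the three construct
#'   classes are geometrically disjoint.
#' @param seed RNG seed; identical config and seed give bit-identical
#'   output.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_reads = 10000L, dimer_fraction = 0.1,
                       short_fraction = 0.1, insert_mean = 22,
                       insert_sd = 2, insert_min = 16L, insert_max = 30L,
                       n_features = 300L, dirichlet_alpha = 1,
                       feature_probs = NULL,
                       platform = c("illumina", "iontorrent"),
                       fixed_read_length = 75L, substitution_rate = 0,
                       indel_rate = 0, q_start = NULL, q_slope = NULL,
                       q_sd = NULL, dimer_bias_coupling = 0,
                       min_length = 15L, dimer_max_insert = 2L,
                       seed = 1L) {
  platform <- match.arg(platform)
  if (dimer_fraction + short_fraction > 1 + 1e-12)
    stop("dimer_fraction + short_fraction must not exceed 1")
  stopifnot(dimer_fraction >= 0, short_fraction >= 0,
            substitution_rate >= 0, substitution_rate <= 0.2,
            indel_rate >= 0, indel_rate <= 0.2,
            insert_min >= 1, insert_max >= insert_min,
            min_length > dimer_max_insert)
  qdef <- if (platform == "illumina") c(36, -0.05, 2) else c(30, -0.08, 3)
  structure(list(
    n_reads = as.integer(n_reads), dimer_fraction = dimer_fraction,
    short_fraction = short_fraction, insert_mean = insert_mean,
    insert_sd = insert_sd, insert_min = as.integer(insert_min),
    insert_max = as.integer(insert_max),
    n_features = as.integer(n_features),
    dirichlet_alpha = dirichlet_alpha, feature_probs = feature_probs,
    platform = platform, fixed_read_length = as.integer(fixed_read_length),
    substitution_rate = substitution_rate, indel_rate = indel_rate,
    q_start = if (is.null(q_start)) qdef[1] else q_start,
    q_slope = if (is.null(q_slope)) qdef[2] else q_slope,
    q_sd = if (is.null(q_sd)) qdef[3] else q_sd,
    dimer_bias_coupling = dimer_bias_coupling,
    min_length = as.integer(min_length),
    dimer_max_insert = as.integer(dimer_max_insert),
    seed = as.integer(seed)), class = "sim_config")
}

sim_platform_profile <- function(config) {
  platform_preset(if (config$platform == "illumina")
    "illumina-truseq-smallrna" else "iontorrent-smallrna")
}

# TruSeq-style post-adapter construct context (index primer read-through)
# so Illumina dimer reads show the full adapter at position 0 followed by
# deterministic construct sequence, as on a real instrument.
POST_ADAPTER_FILLER <- "ATCTCGTATGCCGTCTTCTGCTTGAAAAAAAAAA"

#' Generate a shared feature pool
#'
#' Feature sequences are random DNA with truncated-normal lengths;
#' abundances are a Dirichlet draw (or the explicit simplex from the
#' config).
#'
#' @param config a [sim_config()].
#' @return List: `sequence`, `length`, `probs`.
#' @export
simulate_features <- function(config) {
  with_seed(config$seed + 7919L, {
    lo <- max(config$insert_min, config$min_length)
    hi <- config$insert_max
    lens <- integer(config$n_features)
    for (i in seq_len(config$n_features)) {
      repeat {
        l <- round(rnorm(1, config$insert_mean, config$insert_sd))
        if (l >= lo && l <= hi) { lens[i] <- l; break }
      }
    }
    seqs <- vapply(lens, random_dna, character(1))
    probs <- if (!is.null(config$feature_probs)) {
      stopifnot(length(config$feature_probs) == config$n_features)
      config$feature_probs / sum(config$feature_probs)
    } else {
      g <- rgamma(config$n_features, shape = config$dirichlet_alpha)
      g / sum(g)
    }
    list(sequence = seqs, length = lens, probs = probs,
         id = sprintf("feat_%04d", seq_len(config$n_features)))
  })
}

apply_substitutions <- function(bases, rate) {
  if (rate <= 0) return(bases)
  L <- nchar(bases)
  k <- rbinom(length(bases), L, rate)
  for (r in which(k > 0L)) {
    ch <- strsplit(bases[r], "", fixed = TRUE)[[1]]
    pos <- sample.int(L[r], k[r])
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
    bases[r] <- paste(ch, collapse = "")
  }
  bases
}

apply_indels <- function(bases, rate) {
  if (rate <= 0) return(bases)
  L <- nchar(bases)
  k <- rbinom(length(bases), L, rate)
  for (r in which(k > 0L)) {
    ch <- strsplit(bases[r], "", fixed = TRUE)[[1]]
    pos <- sort(sample.int(L[r], k[r]), decreasing = TRUE)
    for (p in pos) {
      if (runif(1) < 0.5 && length(ch) > 1L) {
        ch <- ch[-p]                                   # deletion
      } else {
        ch <- append(ch, sample(c("A", "C", "G", "T"), 1L), after = p - 1L)
      }
    }
    bases[r] <- paste(ch, collapse = "")
  }
  bases
}

sim_qualities <- function(lens, q_start, q_slope, q_sd) {
  vapply(lens, function(L) {
    q <- q_start + q_slope * (seq_len(L) - 1L)
    if (q_sd > 0) q <- q + rnorm(L, 0, q_sd)
    phred_encode(pmin(pmax(round(q), 2L), 40L))
  }, character(1))
}

#' Simulate one small RNA library with ground truth
#'
#' @param config a [sim_config()].
#' @param features optional shared feature pool from
#'   [simulate_features()] (a cohort passes one pool to all samples).
#' @param sample_id prefix for read ids.
#' @return List: `reads` (an [srna_reads()]), `truth` (data frame
#'   `read_id`, `true_class`, `true_feature`, `true_insert_length`),
#'   `fractions` (named true class fractions), `feature_counts` (clean
#'   reads per feature, summing to the number of clean reads) and
#'   `features`.
#' @export
simulate_library <- function(config, features = NULL, sample_id = "sim") {
  profile <- sim_platform_profile(config)
  ad3 <- profile$adapter3$sequence
  if (is.null(features)) features <- simulate_features(config)
  with_seed(config$seed, {
    n <- config$n_reads
    cls <- sample(c("DIMER", "SHORT", "CLEAN"), n, replace = TRUE,
                  prob = c(config$dimer_fraction, config$short_fraction,
                           1 - config$dimer_fraction -
                             config$short_fraction))
    feat <- rep(NA_integer_, n)
    insert <- character(n)
    is_clean <- cls == "CLEAN"
    if (any(is_clean)) {
      feat[is_clean] <- sample.int(config$n_features, sum(is_clean),
                                   replace = TRUE, prob = features$probs)
      insert[is_clean] <- features$sequence[feat[is_clean]]
    }
    is_short <- cls == "SHORT"
    if (any(is_short)) {
      slen <- sample(seq(config$dimer_max_insert + 1L,
                         config$min_length - 1L), sum(is_short),
                     replace = TRUE)
      insert[is_short] <- vapply(slen, random_dna, character(1))
    }
    core <- paste0(insert, ad3)
    if (config$platform == "illumina") {
      L <- config$fixed_read_length
      core <- paste0(core, POST_ADAPTER_FILLER)
      pad <- pmax(L - nchar(core), 0L)
      if (any(pad > 0L)) {
        idx <- which(pad > 0L)
        core[idx] <- paste0(core[idx],
                            vapply(pad[idx], random_dna, character(1)))
      }
      bases <- substr(core, 1L, L)
    } else {
      bases <- core
    }
    bases <- apply_substitutions(bases, config$substitution_rate)
    bases <- apply_indels(bases, config$indel_rate)
    quals <- sim_qualities(nchar(bases), config$q_start, config$q_slope,
                           config$q_sd)
    ids <- sprintf("%s_%06d", sample_id, seq_len(n))
    reads <- srna_reads(ids, bases, quals)
    truth <- data.frame(
      read_id = ids, true_class = cls,
      true_feature = ifelse(is.na(feat), NA_character_,
                            features$id[feat]),
      true_insert_length = nchar(insert), stringsAsFactors = FALSE)
    fc <- tabulate(feat[is_clean], nbins = config$n_features)
    names(fc) <- features$id
    fractions <- c(dimer = mean(cls == "DIMER"),
                   short = mean(cls == "SHORT"),
                   clean = mean(is_clean))
    list(reads = reads, truth = truth, fractions = fractions,
         feature_counts = fc, features = features)
  })
}

tilt_probs <- function(probs, direction, amount) {
  p <- probs * exp(amount * direction)
  p / sum(p)
}

#' Simulate a cohort of libraries and its count matrix
#'
#' One library per sample over a shared feature pool.  With
#' `dimer_bias_coupling > 0` each sample's feature abundances are tilted
#' along a fixed random direction proportionally to its dimer fraction
#' (multiplicative logit tilt), which couples expression composition to
#' the technical contamination level - the mechanism behind
#' dimer-driven batch effects.  The count matrix holds the true
#' clean-read feature counts.
#'
#' @param n_samples number of samples.
#' @param dimer_fractions per-sample dimer fractions (recycled).
#' @param config base [sim_config()]; per-sample seeds are derived from
#'   `config$seed`.
#' @param short_fractions optional per-sample short fractions.
#' @param emit_reads build actual reads (`TRUE`) or only class/feature
#'   counts (`FALSE`, statistically identical and much faster - used for
#'   calibration studies that never touch the reads).
#' @param out_dir optional directory receiving one FASTQ.gz per sample
#'   plus `truth.tsv` and `counts.tsv`.
#' @return List: `sample_id`, `counts` (features x samples),
#'   `dimer_fractions`, `truth_fractions` (per-sample true class
#'   fractions), `libraries` (per-sample [simulate_library()] results
#'   when `emit_reads`), `features`, `bias_direction`.
#' @export
simulate_cohort <- function(n_samples, dimer_fractions, config,
                            short_fractions = NULL, emit_reads = TRUE,
                            out_dir = NULL) {
  dimer_fractions <- rep_len(dimer_fractions, n_samples)
  if (is.null(short_fractions))
    short_fractions <- rep_len(config$short_fraction, n_samples)
  features <- simulate_features(config)
  bias <- with_seed(config$seed + 104729L,
                    sample(c(-1, 1), config$n_features, replace = TRUE))
  ids <- sprintf("sample_%02d", seq_len(n_samples))
  counts <- matrix(0L, config$n_features, n_samples,
                   dimnames = list(features$id, ids))
  truth_fractions <- matrix(NA_real_, n_samples, 3,
                            dimnames = list(ids,
                                            c("dimer", "short", "clean")))
  libraries <- if (emit_reads) vector("list", n_samples) else NULL
  for (s in seq_len(n_samples)) {
    cfg <- config
    cfg$dimer_fraction <- dimer_fractions[s]
    cfg$short_fraction <- short_fractions[s]
    cfg$seed <- config$seed + s
    probs_s <- tilt_probs(features$probs, bias,
                          config$dimer_bias_coupling * dimer_fractions[s])
    feats_s <- features; feats_s$probs <- probs_s
    if (emit_reads) {
      lib <- simulate_library(cfg, feats_s, sample_id = ids[s])
      counts[, s] <- lib$feature_counts
      truth_fractions[s, ] <- lib$fractions[c("dimer", "short", "clean")]
      libraries[[s]] <- lib
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        write_fastq(lib$reads, file.path(out_dir,
                                         paste0(ids[s], ".fastq.gz")))
      }
    } else {
      cc <- with_seed(cfg$seed, {
        ncls <- as.integer(rmultinom(1, cfg$n_reads,
                                     c(cfg$dimer_fraction,
                                       cfg$short_fraction,
                                       1 - cfg$dimer_fraction -
                                         cfg$short_fraction)))
        list(ncls = ncls,
             fc = as.integer(rmultinom(1, ncls[3], probs_s)))
      })
      counts[, s] <- cc$fc
      truth_fractions[s, ] <- cc$ncls / cfg$n_reads
    }
  }
  out <- list(sample_id = ids, counts = counts,
              dimer_fractions = dimer_fractions,
              truth_fractions = truth_fractions, libraries = libraries,
              features = features, bias_direction = bias)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ct <- data.frame(feature = rownames(counts), counts,
                     check.names = FALSE)
    write_tsv(ct, file.path(out_dir, "counts.tsv"))
    tf <- data.frame(sample_id = ids, dimer_fraction = dimer_fractions,
                     truth_fractions, check.names = FALSE)
    write_tsv(tf, file.path(out_dir, "truth.tsv"))
  }
  out
}
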