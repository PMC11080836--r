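#' Assemble a cohort table from per-sample QC
#'
#' @param qc_list list of `sample_qc` objects, or a data frame already
#'   holding the columns `sample_id`, `pct_read_loss`, `pct_dimer`,
#'   `pct_short`, `pct_lowq` (and optionally `rna_input_ng`).
#' @param rna_input optional named numeric vector of RNA input (ng) per
#'   sample id.
#' @return A data frame of class `cohort_table`.
#' @export
cohort_table <- function(qc_list, rna_input = NULL) {
  if (is.data.frame(qc_list)) {
    tab <- qc_list
  } else {
    tab <- do.call(rbind, lapply(qc_list, function(q)
      data.frame(sample_id = q$sample_id, pct_read_loss = q$pct_read_loss,
                 pct_dimer = q$pct_dimer, pct_short = q$pct_short,
                 pct_lowq = q$pct_lowq, stringsAsFactors = FALSE)))
  }
  need <- c("sample_id", "pct_read_loss", "pct_dimer", "pct_short",
            "pct_lowq")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("cohort table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(rna_input))
    tab$rna_input_ng <- unname(rna_input[tab$sample_id])
  pc <- unlist(tab[c("pct_read_loss", "pct_dimer", "pct_short", "pct_lowq")])
  if (any(pc < -1e-9 | pc > 100 + 1e-9, na.rm = TRUE))
    stop("percentages must lie in [0, 100]")
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

# Residual sum of squares, slope, intercept of y ~ x on index range [i, j],
# all in O(1) from cumulative sums.
seg_stats <- function(cs, i, j) {
  n <- j - i + 1
  sx <- cs$x[j + 1] - cs$x[i]; sy <- cs$y[j + 1] - cs$y[i]
  sxx <- cs$xx[j + 1] - cs$xx[i]; syy <- cs$yy[j + 1] - cs$yy[i]
  sxy <- cs$xy[j + 1] - cs$xy[i]
  vx <- sxx - sx * sx / n
  cxy <- sxy - sx * sy / n
  tss <- syy - sy * sy / n
  slope <- if (vx > 0) cxy / vx else 0
  rss <- max(tss - slope * cxy, 0)
  list(slope = slope, intercept = (sy - slope * sx) / n,
       rss = rss, tss = tss,
       r_squared = if (tss > 1e-12) max(0, 1 - rss / tss) else 1)
}

#' Stratify samples by piecewise linear regression on ordered read loss
#'
#' Samples are ordered by ascending read-loss percentage and read loss is
#' regressed on rank (1..n) piecewise: every placement of up to
#' `max_segments - 1` breakpoints with at least `min_segment` samples per
#' segment is fitted by ordinary least squares, and the segmentation
#' minimising BIC (computed from the total residual sum of squares, with
#' two parameters per segment plus one per breakpoint) is returned.  A
#' steep, well-fitting terminal segment is the signature of a
#' high-contamination sample group.
#'
#' @param table a [cohort_table()].
#' @param max_segments maximum number of segments tried (default 3).
#' @param min_segment minimum samples per segment (default 3).
#' @return An object of class `segmentation`: `order` (sample ids sorted by
#'   loss), `breakpoints` (0-based indices into the order where each
#'   later segment starts), and a `segments` data frame with per-segment
#'   `start`, `end` (0-based, inclusive), `slope` (% per rank),
#'   `intercept` and `r_squared`.
#' @export
segment_by_read_loss <- function(table, max_segments = 3L,
                                 min_segment = 3L) {
  loss <- table$pct_read_loss
  n <- length(loss)
  if (n < 2L) stop("segmentation needs at least 2 samples")
  ord <- order(loss)
  y <- loss[ord]
  x <- seq_len(n)
  cs <- list(x = c(0, cumsum(x)), y = c(0, cumsum(y)),
             xx = c(0, cumsum(x * x)), yy = c(0, cumsum(y * y)),
             xy = c(0, cumsum(x * y)))

  best <- NULL
  consider <- function(bounds) {
    k <- nrow(bounds)
    st <- lapply(seq_len(k), function(s) seg_stats(cs, bounds[s, 1],
                                                   bounds[s, 2]))
    rss <- sum(vapply(st, `[[`, numeric(1), "rss"))
    p <- 2 * k + (k - 1)
    bic <- n * log(max(rss, 1e-12) / n) + p * log(n)
    if (is.null(best) || bic < best$bic - 1e-9)
      best <<- list(bic = bic, bounds = bounds, stats = st)
  }

  consider(cbind(1, n))
  if (n >= 6L && max_segments >= 2L) {
    for (b1 in seq(min_segment, n - min_segment)) {
      consider(rbind(c(1, b1), c(b1 + 1, n)))
      if (max_segments >= 3L && n >= 3L * min_segment &&
          b1 <= n - 2L * min_segment) {
        for (b2 in seq(b1 + min_segment, n - min_segment))
          consider(rbind(c(1, b1), c(b1 + 1, b2), c(b2 + 1, n)))
      }
    }
  }

  segs <- data.frame(
    start = best$bounds[, 1] - 1L, end = best$bounds[, 2] - 1L,
    n = best$bounds[, 2] - best$bounds[, 1] + 1L,
    slope = vapply(best$stats, `[[`, numeric(1), "slope"),
    intercept = vapply(best$stats, `[[`, numeric(1), "intercept"),
    r_squared = vapply(best$stats, `[[`, numeric(1), "r_squared"))
  structure(list(order = table$sample_id[ord],
                 loss_sorted = y,
                 breakpoints = if (nrow(segs) > 1L) segs$start[-1L]
                               else integer(0),
                 segments = segs, bic = best$bic),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d segment(s), BIC %.2f\n",
              nrow(x$segments), x$bic))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Decompose per-sample read loss into its causes
#'
#' Expresses each sample's dimer/short/low-quality percentages as
#' fractions of its total read loss and labels the dominant cause.
#' Samples whose components do not reconstruct the total loss within
#' `tolerance` raise an error naming them; zero-loss samples are labelled
#' `NONE` with undefined fractions.
#'
#' @param table a [cohort_table()].
#' @param tolerance reconstruction tolerance in percentage points.
#' @return Data frame: `sample_id`, `frac_dimer`, `frac_short`,
#'   `frac_lowq`, `dominant` (factor `DIMER`/`SHORT`/`LOW_QUALITY`/`NONE`).
#' @export
decompose_loss <- function(table, tolerance = 0.1) {
  gap <- abs(table$pct_dimer + table$pct_short + table$pct_lowq -
             table$pct_read_loss)
  bad <- which(gap > tolerance)
  if (length(bad))
    stop("loss components do not sum to total read loss for sample(s): ",
         paste(table$sample_id[bad], collapse = ", "))
  loss <- table$pct_read_loss
  comp <- cbind(DIMER = table$pct_dimer, SHORT = table$pct_short,
                LOW_QUALITY = table$pct_lowq)
  frac <- comp / ifelse(loss > 0, loss, NA_real_)
  dominant <- ifelse(loss > 0,
                     colnames(comp)[max.col(comp, ties.method = "first")],
                     "NONE")
  data.frame(sample_id = table$sample_id,
             frac_dimer = unname(frac[, "DIMER"]),
             frac_short = unname(frac[, "SHORT"]),
             frac_lowq = unname(frac[, "LOW_QUALITY"]),
             dominant = factor(dominant,
                               levels = c("DIMER", "SHORT", "LOW_QUALITY",
                                          "NONE")),
             stringsAsFactors = FALSE)
}

#' Correlation between RNA input and read loss
#'
#' Spearman rank correlation between the RNA quantity used for library
#' preparation and the read-loss percentage.  The p-value uses the exact
#' null distribution of the rank statistic for n <= 9 (no ties), and the
#' large-sample approximation otherwise.
#'
#' @param table a [cohort_table()] with an `rna_input_ng` column.
#' @return List: `spearman_rho`, `p`, `n`, `flag` (`"constant_input"` and
#'   `NA` statistics when the input does not vary).
#' @export
loss_vs_input_correlation <- function(table) {
  if (is.null(table$rna_input_ng))
    stop("cohort table has no rna_input_ng column")
  ok <- !is.na(table$rna_input_ng) & !is.na(table$pct_read_loss)
  x <- table$rna_input_ng[ok]; y <- table$pct_read_loss[ok]
  n <- length(x)
  if (n < 5L) stop("need at least 5 samples with RNA input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(spearman_rho = NA_real_, p = NA_real_, n = n,
                flag = "constant_input"))
  }
  exact <- n <= 9L && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  list(spearman_rho = unname(ct$estimate), p = ct$p.value, n = n,
       flag = character(0))
}
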