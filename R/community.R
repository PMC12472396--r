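#' Relative taxon abundances with pseudocounting
#'
#' Zero cells are replaced by a single pseudocount before computing
#' percentages, preventing division by zero in downstream fold-change
#' ratios; column totals are taken after pseudocounting.
#'
#' @param counts Non-negative integer matrix (genera x samples).
#' @return Matrix of percentages; each column sums to 100.
#' @export
relative_abundance <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  counts[counts == 0] <- 1
  totals <- colSums(counts)
  if (any(totals == 0)) stop("sample with zero total reads")
  sweep(counts, 2, totals, "/") * 100
}

#' Inclusion filter for a genus
#'
#' For taxa showing increased abundance the treated sample must reach
#' `min_pct` representation; for suppressed taxa the control sample must.
#' The genus is retained when the direction-relevant sample meets the
#' threshold in at least `min_pairs` of the subject pairs.
#'
#' @param pcts_treated,pcts_control Per-subject percentage vectors (one
#'   entry per paired sample).
#' @param direction `"increased"` or `"suppressed"`.
#' @param min_pct Representation threshold in percent (default 0.01).
#' @param min_pairs Minimum number of qualifying pairs (default 4).
#' @return Logical scalar.
#' @export
include_genus <- function(pcts_treated, pcts_control,
                          direction = c("increased", "suppressed"),
                          min_pct = 0.01, min_pairs = 4L) {
  direction <- match.arg(direction)
  stopifnot(length(pcts_treated) == length(pcts_control))
  relevant <- if (direction == "increased") pcts_treated else pcts_control
  sum(relevant >= min_pct) >= min_pairs
}

#' Z-statistic of fold-change ratios against a null of 1
#'
#' Spreadsheet-style recomputation: the per-subject fold-change ratios
#' (treated percentage / control percentage) are averaged, the sample
#' standard deviation (n - 1 denominator) is taken, and
#' `z = (mean - 1) / (sd / sqrt(n))` is tested one-sided against the
#' standard normal upper tail of `|z|` (`p = 1 - Phi(|z|)`), with the
#' direction carried separately. The tail is evaluated directly in the
#' upper tail (not as `1 - Phi`), so it stays accurate for large `|z|`;
#' `log_p` additionally reports the log tail, which never underflows even
#' for z-scores far beyond 8.
#'
#' @param fcrs Numeric vector of per-subject fold-change ratios (n >= 4).
#' @return A list: `n`, `mean_fcr`, `sd`, `z`, `p`, `log_p`, `direction`
#'   (`"increased"` when the mean exceeds 1, else `"suppressed"`) and
#'   `degenerate` (`TRUE`, with `z` and `p` set `NA`, when the ratios have
#'   zero spread).
#' @export
response_stat <- function(fcrs) {
  n <- length(fcrs)
  if (n < 4L) stop("at least 4 replicate fold-change ratios are required")
  m <- mean(fcrs)
  s <- stats::sd(fcrs)
  direction <- if (m > 1) "increased" else "suppressed"
  if (s == 0) {
    return(list(n = n, mean_fcr = m, sd = s, z = NA_real_, p = NA_real_,
                log_p = NA_real_, direction = direction, degenerate = TRUE))
  }
  z <- (m - 1) / (s / sqrt(n))
  p <- stats::pnorm(abs(z), lower.tail = FALSE)
  log_p <- stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
  list(n = n, mean_fcr = m, sd = s, z = z, p = p, log_p = log_p,
       direction = direction, degenerate = FALSE)
}

#' Mean absolute deviation
#'
#' Mean of absolute deviations from the mean, the variability metric used
#' for pooled fold-change ratios (distinct from the median-based
#' [stats::mad()]).
#'
#' @param values Non-empty numeric vector.
#' @return Mean absolute deviation.
#' @export
mean_abs_dev <- function(values) {
  if (length(values) == 0L) stop("empty input")
  mean(abs(values - mean(values)))
}

#' Per-genus response statistics for a treated community
#'
#' Full workflow over a genus x sample count table: pseudocounted relative
#' abundances, per-subject fold-change ratios (treated / control, on
#' percentages), the direction-dependent inclusion filter, and the
#' z-statistic against a null ratio of 1 - the data behind a volcano plot.
#'
#' @param counts Genus x sample count matrix with column names matching
#'   `samples$sample`.
#' @param samples Data frame describing the columns: `sample`, `subject`,
#'   `treatment` (`"control"` or `"treated"`); each subject must carry one
#'   control and one treated sample.
#' @param min_pct,min_pairs Inclusion thresholds (see [include_genus()]).
#' @return Data frame with one row per genus: `genus`, `included`,
#'   `direction`, `n`, `mean_fcr`, `log2_fcr`, `sd`, `z`, `p`, `mad`.
#' @export
community_response <- function(counts, samples, min_pct = 0.01,
                               min_pairs = 4L) {
  counts <- as.matrix(counts)
  stopifnot(all(samples$sample %in% colnames(counts)),
            all(samples$treatment %in% c("control", "treated")))
  pct <- relative_abundance(counts)
  subjects <- unique(samples$subject)
  col_of <- function(subj, trt) {
    s <- samples$sample[samples$subject == subj & samples$treatment == trt]
    if (length(s) != 1L) stop("subject ", subj, " lacks a unique ", trt, " sample")
    s
  }
  treated_cols <- vapply(subjects, col_of, "", trt = "treated")
  control_cols <- vapply(subjects, col_of, "", trt = "control")
  rows <- lapply(rownames(counts), function(g) {
    pt <- pct[g, treated_cols]
    pc <- pct[g, control_cols]
    fcrs <- pt / pc
    st <- response_stat(fcrs)
    inc <- include_genus(pt, pc, direction = st$direction,
                         min_pct = min_pct, min_pairs = min_pairs)
    data.frame(genus = g, included = inc, direction = st$direction,
               n = st$n, mean_fcr = st$mean_fcr,
               log2_fcr = log2(st$mean_fcr), sd = st$sd, z = st$z,
               p = st$p, mad = mean_abs_dev(fcrs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
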