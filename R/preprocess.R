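#' Quality-control parameters for raw small-RNA reads
#'
#' Defaults mirror the pipeline's pre-processing stage: a read is kept when
#' at least 90% of its bases reach Phred Q20, 3' adapter remnants starting
#' with `ATCACCGACTGCCCA` are removed, and only 16-50 nt inserts enter the
#' analysis.
#'
#' @param q_threshold Phred score a base must reach (default 20).
#' @param min_fraction Minimum fraction of bases at or above `q_threshold`
#'   (default 0.90).
#' @param adapter_prefix 5'-terminal sequence of the 3' adapter used to spot
#'   remnants (default `"ATCACCGACTGCCCA"`).
#' @param len_min,len_max Inclusive insert-length band in nt (defaults 16
#'   and 50).
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(q_threshold = 20L, min_fraction = 0.90,
                      adapter_prefix = "ATCACCGACTGCCCA",
                      len_min = 16L, len_max = 50L) {
  stopifnot(min_fraction > 0, min_fraction <= 1,
            len_min <= len_max, nzchar(adapter_prefix))
  structure(list(q_threshold = as.integer(q_threshold),
                 min_fraction = min_fraction,
                 adapter_prefix = normalize_nt(adapter_prefix),
                 len_min = as.integer(len_min),
                 len_max = as.integer(len_max)),
            class = "qc_params")
}

#' Filter reads on per-base quality
#'
#' A read is retained iff the fraction of bases with Phred score at or
#' above `p$q_threshold` is at least `p$min_fraction`. Reads without
#' quality strings pass unchanged, with a warning.
#'
#' @param reads Read data frame (`id`, `seq`, `qual`).
#' @param p A [qc_params()] object.
#' @return The retained subset of `reads`.
#' @export
quality_filter <- function(reads, p = qc_params()) {
  if (nrow(reads) == 0L) return(reads)
  has_qual <- !is.na(reads$qual)
  if (any(!has_qual)) {
    warning(sum(!has_qual), " read(s) lack quality strings and pass unfiltered")
  }
  keep <- rep(TRUE, nrow(reads))
  if (any(has_qual)) {
    frac <- vapply(reads$qual[has_qual], function(q) {
      phred <- utf8ToInt(q) - 33L
      mean(phred >= p$q_threshold)
    }, numeric(1), USE.NAMES = FALSE)
    keep[has_qual] <- frac >= p$min_fraction
  }
  reads[keep, , drop = FALSE]
}

#' Trim 3'-adapter remnants
#'
#' Each read is truncated immediately before the first occurrence of the
#' adapter prefix; everything 3' of that point (the remnant and any tail)
#' is removed, with quality strings truncated in step. Reads whose
#' truncated insert is empty are discarded; reads without the motif are
#' unchanged. The operation is idempotent.
#'
#' @param reads Read data frame.
#' @param p A [qc_params()] object.
#' @return The trimmed read set (possibly fewer rows).
#' @export
trim_adapter <- function(reads, p = qc_params()) {
  if (nrow(reads) == 0L) return(reads)
  pos <- stringi::stri_locate_first_fixed(reads$seq, p$adapter_prefix)[, "start"]
  hit <- !is.na(pos)
  if (any(hit)) {
    newlen <- pos[hit] - 1L
    reads$seq[hit] <- substr(reads$seq[hit], 1L, newlen)
    q <- reads$qual[hit]
    reads$qual[hit] <- ifelse(is.na(q), q, substr(q, 1L, newlen))
  }
  reads[nchar(reads$seq) > 0L, , drop = FALSE]
}

#' Select reads by insert length
#'
#' Retains reads with `len_min <= length <= len_max`. The number of reads
#' surviving this final stage is the library's QC-read count (`n_qc`) used
#' to normalize 5'-end profiles per million quality-controlled reads.
#'
#' @param reads Read data frame.
#' @param p A [qc_params()] object.
#' @return The retained subset of `reads`.
#' @export
length_select <- function(reads, p = qc_params()) {
  n <- nchar(reads$seq)
  reads[n >= p$len_min & n <= p$len_max, , drop = FALSE]
}

#' Full pre-processing pipeline
#'
#' Applies, in fixed order, [quality_filter()], [trim_adapter()] and
#' [length_select()], and reports the read counts surviving each stage.
#'
#' @param reads Read data frame.
#' @param p A [qc_params()] object.
#' @return A list with `reads` (the surviving set), `n_qc` (count after
#'   length selection) and `counts` (named vector: input, after_quality,
#'   after_trim, after_length).
#' @export
preprocess <- function(reads, p = qc_params()) {
  n0 <- nrow(reads)
  reads <- quality_filter(reads, p)
  n1 <- nrow(reads)
  reads <- trim_adapter(reads, p)
  n2 <- nrow(reads)
  reads <- length_select(reads, p)
  n3 <- nrow(reads)
  list(reads = reads,
       n_qc = n3,
       counts = c(input = n0, after_quality = n1,
                  after_trim = n2, after_length = n3))
}
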