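#' Shannon diversity index of a copy-number distribution
#'
#' `H = -sum(p_i * ln(p_i))` in nats, where `p_i` is the frequency of each
#' unique sequence among all copies. `H = 0` when a single unique sequence
#' is present; `H = ln(n)` for `n` unique sequences in equal copy number.
#'
#' @param counts Numeric vector of copy numbers (>= 1), one per unique
#'   sequence; names optional.
#' @return Shannon index in nats.
#' @export
shannon_index <- function(counts) {
  if (length(counts) == 0L) stop("empty copy-number mapping")
  if (any(counts < 1)) stop("copy numbers must be >= 1")
  p <- counts / sum(counts)
  -sum(p * log(p)) + 0   # "+ 0" normalizes IEEE negative zero
}

# Number of positionally matching characters between equal-length strings.
hamming_matches <- function(a, b) {
  n <- length(a)
  out <- integer(n)
  for (L in unique(nchar(a))) {
    idx <- which(nchar(a) == L)
    if (L == 0L) next
    ma <- matrix(unlist(strsplit(a[idx], "", fixed = TRUE)),
                 ncol = L, byrow = TRUE)
    mb <- matrix(unlist(strsplit(b[idx], "", fixed = TRUE)),
                 ncol = L, byrow = TRUE)
    out[idx] <- as.integer(rowSums(ma == mb))
  }
  out
}

#' Does a 3' flank diverge from the genomic continuation?
#'
#' For flank length `L = 4` complete divergence from the genome is
#' required; for longer flanks up to `L - 4` positional matches are
#' permitted (equivalently, at least 4 mismatches). A continuation
#' truncated at a genome end counts every missing base as a mismatch.
#'
#' @param ext Character vector of flank sequences (length `L` each).
#' @param cont Genomic continuation(s) of the same length (recycled when a
#'   single string is given).
#' @return Logical vector.
#' @export
flank_diverges <- function(ext, cont) {
  if (length(cont) == 1L && length(ext) > 1L) cont <- rep(cont, length(ext))
  if (length(ext) != length(cont) || any(nchar(ext) != nchar(cont))) {
    stop("flank and continuation lengths differ")
  }
  if (any(nchar(ext) < 4L)) stop("divergence rule is defined for L >= 4")
  hamming_matches(ext, cont) <= nchar(ext) - 4L
}

# 5'-end positions of every exact occurrence of a sequence on both strands.
kmer_occurrences <- function(seq, genome) {
  fwd <- locate_all(genome$seq, seq)
  rev <- locate_all(genome$seq, revcomp(seq))
  data.frame(pos = as.integer(c(fwd[, "start"], rev[, "end"])),
             strand = c(rep("+", nrow(fwd)), rep("-", nrow(rev))))
}

#' Attribute a candidate read to genomic anchor occurrences
#'
#' The read's 5' k-mer is located at every genomic occurrence (both
#' strands); the read is attributed, at full weight, to every occurrence
#' whose downstream continuation the read's L-flank diverges from (see
#' [flank_diverges()]).
#'
#' @param read_seq A single read sequence of length `k + L`.
#' @param genome A [genome()] object.
#' @param k Anchor k-mer length.
#' @param L Flank length (>= 4).
#' @return Data frame of attributed occurrences (`pos`, `strand`); zero
#'   rows when no occurrence passes.
#' @export
attribute_read <- function(read_seq, genome, k, L) {
  genome <- as_genome(genome)
  stopifnot(nchar(read_seq) == k + L)
  occ <- kmer_occurrences(substr(read_seq, 1L, k), genome)
  if (nrow(occ) == 0L) return(occ)
  flank <- substring(read_seq, k + 1L)
  cont <- vapply(seq_len(nrow(occ)), function(i) {
    genomic_continuation(genome, occ$pos[i], occ$strand[i], skip = k, len = L)
  }, character(1))
  occ[flank_diverges(rep(flank, nrow(occ)), cont), , drop = FALSE]
}

#' One run of the random-extension scan at fixed (k, L)
#'
#' Processes reads of exactly `k + L` nt (after defensive re-trimming of
#' 3'-adapter remnants). Reads that perfectly match the genome anywhere on
#' either strand are filtered out; the remainder qualify when their 5'
#' k-mer occurs in the genome and their L-flank passes the divergence rule
#' at one or more occurrences. Qualifying reads are attributed to every
#' passing occurrence at full weight, grouped per (position, strand), and
#' each group's 3'-end diversity is scored with the Shannon index over
#' unique read sequences. Groups sharing at least half of their read
#' copies with another group are annotated as potentially
#' cross-contributed.
#'
#' @param reads Read data frame (or character vector of sequences).
#' @param genome A [genome()] object.
#' @param k Anchor k-mer length.
#' @param L Flank length (4-10 in the default grid).
#' @param adapter_prefix 3'-adapter remnant prefix removed defensively.
#' @return Data frame with one row per (position, strand) group: `pos`,
#'   `strand`, `k`, `L`, `n_reads`, `n_unique`, `H`, `cross_contributed`.
#' @export
randext_run <- function(reads, genome, k, L,
                        adapter_prefix = "ATCACCGACTGCCCA") {
  genome <- as_genome(genome)
  stopifnot(k >= 1L, L >= 4L)
  if (is.character(reads)) {
    reads <- data.frame(id = as.character(seq_along(reads)), seq = reads,
                        qual = rep_len(NA_character_, length(reads)))
  }
  reads <- trim_adapter(reads, qc_params(adapter_prefix = adapter_prefix))
  seqs <- reads$seq[nchar(reads$seq) == k + L]
  empty <- data.frame(pos = integer(), strand = character(),
                      k = integer(), L = integer(), n_reads = numeric(),
                      n_unique = integer(), H = numeric(),
                      cross_contributed = logical())
  if (!length(seqs)) return(empty)
  counts <- table(seqs)
  uniq <- names(counts)
  # drop full-length perfect genome matches (either strand)
  full <- stringi::stri_detect_fixed(genome$seq, uniq) |
    stringi::stri_detect_fixed(genome$seq, revcomp(uniq))
  uniq <- uniq[!full]
  if (!length(uniq)) return(empty)
  assign <- list()
  for (s in uniq) {
    att <- attribute_read(s, genome, k, L)
    if (nrow(att) == 0L) next
    assign[[length(assign) + 1L]] <- data.frame(
      seq = s, count = as.numeric(counts[[s]]),
      pos = att$pos, strand = att$strand, n_sites = nrow(att))
  }
  if (!length(assign)) return(empty)
  assign <- do.call(rbind, assign)
  key <- paste(assign$pos, assign$strand)
  groups <- lapply(split(assign, key), function(gr) {
    data.frame(pos = gr$pos[1], strand = gr$strand[1],
               k = as.integer(k), L = as.integer(L),
               n_reads = sum(gr$count), n_unique = nrow(gr),
               H = shannon_index(gr$count),
               cross_contributed = sum(gr$count[gr$n_sites > 1L]) >=
                 0.5 * sum(gr$count))
  })
  out <- do.call(rbind, c(groups, list(make.row.names = FALSE)))
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "assignments") <- assign
  out
}

#' Grid scan for loci emitting randomly extended fragments
#'
#' Runs [randext_run()] for every (k, L) combination and aggregates, per
#' genomic position and strand, the maximum Shannon index over all runs
#' (H values from different runs are never averaged, only maximized; the
#' lexicographically smallest (k, L) wins ties). Positions whose maximal H
#' exceeds `h_threshold` are flagged as variable loci.
#'
#' @param reads Read data frame (or character vector of sequences).
#' @param genome A [genome()] object.
#' @param k_range Anchor k-mer lengths to scan (default 13:22).
#' @param L_range Flank lengths to scan (default 4:10).
#' @param h_threshold Diversity floor for flagging (default 2.0).
#' @param adapter_prefix 3'-adapter remnant prefix.
#' @return Data frame with one row per (position, strand): `pos`, `strand`,
#'   `max_H`, `best_k`, `best_L`, `n_reads`, `n_unique`, `flagged`,
#'   `cross_contributed`. Zero rows when no read qualifies anywhere.
#' @export
grid_scan <- function(reads, genome, k_range = 13:22, L_range = 4:10,
                      h_threshold = 2.0,
                      adapter_prefix = "ATCACCGACTGCCCA") {
  if (!length(k_range) || !length(L_range)) stop("empty parameter grid")
  runs <- list()
  for (k in sort(k_range)) {
    for (L in sort(L_range)) {
      r <- randext_run(reads, genome, k, L, adapter_prefix = adapter_prefix)
      if (nrow(r)) runs[[length(runs) + 1L]] <- r
    }
  }
  if (!length(runs)) {
    return(data.frame(pos = integer(), strand = character(),
                      max_H = numeric(), best_k = integer(),
                      best_L = integer(), n_reads = numeric(),
                      n_unique = integer(), flagged = logical(),
                      cross_contributed = logical()))
  }
  all <- do.call(rbind, runs)
  key <- paste(all$pos, all$strand)
  agg <- lapply(split(all, key), function(gr) {
    best <- gr[order(-gr$H, gr$k, gr$L), ][1, ]
    data.frame(pos = best$pos, strand = best$strand, max_H = best$H,
               best_k = best$k, best_L = best$L, n_reads = best$n_reads,
               n_unique = best$n_unique, flagged = best$H > h_threshold,
               cross_contributed = best$cross_contributed)
  })
  out <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
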