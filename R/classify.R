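DEVIATION_CATEGORIES <- c("correct", "nontemplate_addition", "chimera",
                          "indel", "mismatch")

#' Define an anchor at a genomic position
#'
#' An anchor is the exact genomic sequence starting at a peak 5'-end
#' position, long enough (12-14 nt by default) to assign reads to the locus
#' by prefix identity regardless of downstream deviations.
#'
#' @param genome A [genome()] object.
#' @param pos 1-based genomic position of the anchor's 5' end.
#' @param strand `"+"` or `"-"`.
#' @param len Anchor length in nt.
#' @param len_range Permitted length bounds (default `c(12, 14)`).
#' @return An object of class `anchor` with fields `seq`, `genome_pos`,
#'   `strand`, `len`.
#' @export
anchor <- function(genome, pos, strand = c("+", "-"), len = 12L,
                   len_range = c(12L, 14L)) {
  genome <- as_genome(genome)
  strand <- match.arg(strand)
  len <- as.integer(len)
  if (len < len_range[1] || len > len_range[2]) {
    stop("anchor length ", len, " outside configured bounds [",
         len_range[1], ", ", len_range[2], "]")
  }
  seq <- genomic_sequence(genome, pos, strand, len)
  if (is.na(seq)) stop("anchor extends beyond the genome")
  structure(list(seq = seq, genome_pos = as.integer(pos), strand = strand,
                 len = len), class = "anchor")
}

# Genomic sequence of length `len` whose 5' end sits at `pos` on `strand`;
# NA when it would run off the genome.
genomic_sequence <- function(genome, pos, strand, len) {
  if (strand == "+") {
    if (pos < 1L || pos + len - 1L > genome$length) return(NA_character_)
    substr(genome$seq, pos, pos + len - 1L)
  } else {
    if (pos > genome$length || pos - len + 1L < 1L) return(NA_character_)
    revcomp(substr(genome$seq, pos - len + 1L, pos))
  }
}

# Genomic continuation 3'-ward of a feature whose 5' end is at `pos` and
# which spans `skip` bases; missing bases past the genome end are padded
# with "-" (which never matches a nucleotide).
genomic_continuation <- function(genome, pos, strand, skip, len) {
  if (strand == "+") {
    from <- pos + skip
    to <- min(pos + skip + len - 1L, genome$length)
    s <- if (from > genome$length) "" else substr(genome$seq, from, to)
  } else {
    to <- pos - skip
    from <- max(pos - skip - len + 1L, 1L)
    s <- if (to < 1L) "" else revcomp(substr(genome$seq, from, to))
  }
  paste0(s, strrep("-", len - nchar(s)))
}

#' Collect reads whose 5' end matches an anchor
#'
#' Returns the reads whose 5'-terminal `anchor$len` bases equal the anchor
#' sequence exactly, including reads that do not map to the genome in full
#' (the very reads the deviation classifier is after).
#'
#' @param reads Read data frame.
#' @param anchor An [anchor()] object.
#' @return The collected subset of `reads`.
#' @export
collect_by_anchor <- function(reads, anchor) {
  reads[startsWith(reads$seq, anchor$seq), , drop = FALSE]
}

#' Classify a 3'-terminal extension
#'
#' Extensions of 1-3 nt of any sequence, and longer extensions containing
#' only 1-2 distinct nucleotides, are non-template additions; extensions of
#' at least 4 nt containing at least 3 distinct nucleotides are chimeras
#' (interpreted as illegitimately ligated foreign oligonucleotides).
#'
#' @param ext Character vector of non-empty extension strings.
#' @return Character vector: `"nontemplate_addition"` or `"chimera"`.
#' @export
classify_extension <- function(ext) {
  if (any(!nzchar(ext))) stop("empty extension; correct reads are not classified here")
  n <- nchar(ext)
  distinct <- vapply(stringi::stri_split_boundaries(ext, type = "character"),
                     function(ch) length(unique(ch)), integer(1))
  ifelse(n <= 3L | distinct <= 2L, "nontemplate_addition", "chimera")
}

# Banded global alignment of read tail `r` against genomic continuation `g`
# (unit costs, band `band`); the genome suffix is free. Returns per-read-base
# operations ("M" match, "X" substitution, "I" insertion) plus deletion
# boundaries, with gaps pushed rightmost among cost-ties.
banded_align <- function(r, g, band = 3L) {
  m <- nchar(r)
  ng <- nchar(g)
  if (m == 0L) return(list(ops = character(0), deletions = integer(0)))
  rc <- strsplit(r, "", fixed = TRUE)[[1]]
  gc <- strsplit(g, "", fixed = TRUE)[[1]]
  INF <- .Machine$integer.max %/% 2L
  D <- matrix(INF, nrow = m + 1L, ncol = ng + 1L)
  for (j in 0:min(band, ng)) D[1L, j + 1L] <- j
  for (i in 0:min(band, m)) D[i + 1L, 1L] <- i
  for (i in 1:m) {
    jlo <- max(1L, i - band)
    jhi <- min(ng, i + band)
    if (jlo > jhi) next
    for (j in jlo:jhi) {
      sub <- D[i, j] + (rc[i] != gc[j])
      ins <- D[i, j + 1L] + 1L
      del <- D[i + 1L, j] + 1L
      D[i + 1L, j + 1L] <- min(sub, ins, del)
    }
  }
  jcand <- max(0L, m - band):min(ng, m + band)
  best <- min(D[m + 1L, jcand + 1L])
  # endpoint: minimal cost, then closest to the diagonal, then smaller j
  jopt <- jcand[D[m + 1L, jcand + 1L] == best]
  jend <- jopt[order(abs(jopt - m), jopt)][1]
  ops <- character(m)
  deletions <- integer(0)
  i <- m; j <- jend
  while (i > 0L || j > 0L) {
    here <- D[i + 1L, j + 1L]
    if (i > 0L && D[i, j + 1L] != INF && D[i, j + 1L] + 1L == here) {
      ops[i] <- "I"; i <- i - 1L
    } else if (j > 0L && D[i + 1L, j] != INF && D[i + 1L, j] + 1L == here) {
      deletions <- c(deletions, i); j <- j - 1L
    } else {
      ops[i] <- if (rc[i] == gc[j]) "M" else "X"
      i <- i - 1L; j <- j - 1L
    }
  }
  list(ops = ops, deletions = deletions)
}

#' Classify one anchored read against the genome
#'
#' The read's post-anchor portion is aligned to the genomic continuation by
#' banded edit distance (band 3, unit costs). The maximal trailing run of
#' read bases not aligned as matches is the 3' extension; aligned
#' substitutions outside the read's terminal triplets are mismatches;
#' aligned gaps are indels. For the single-count tally the category is
#' taken from the extension when one is present (via
#' [classify_extension()]), otherwise `indel`, then `mismatch`, then
#' `correct`; all individual deviations are recorded regardless.
#'
#' @param read_seq A single read sequence beginning with the anchor.
#' @param anchor An [anchor()] object.
#' @param genome A [genome()] object.
#' @param band Alignment band width (default 3).
#' @return A one-row data frame: `category`, `extension`, `n_mismatch`,
#'   `n_indel`, `n_deviation_types`.
#' @export
classify_read <- function(read_seq, anchor, genome, band = 3L) {
  genome <- as_genome(genome)
  if (!startsWith(read_seq, anchor$seq)) {
    stop("read does not begin with the anchor sequence")
  }
  len_full <- nchar(read_seq)
  tail_seq <- substring(read_seq, anchor$len + 1L)
  m <- nchar(tail_seq)
  cont <- genomic_continuation(genome, anchor$genome_pos, anchor$strand,
                               skip = anchor$len, len = m + band)
  al <- banded_align(tail_seq, cont, band = band)
  ops <- al$ops
  # trailing run of read bases not aligned as matches
  ext_len <- 0L
  while (ext_len < m && ops[m - ext_len] != "M") ext_len <- ext_len + 1L
  extension <- if (ext_len > 0L) substring(tail_seq, m - ext_len + 1L) else ""
  core <- if (m - ext_len >= 1L) seq_len(m - ext_len) else integer(0)
  offsets <- anchor$len + core
  n_mismatch <- sum(ops[core] == "X" & offsets > 3L & offsets <= len_full - 3L)
  n_indel <- sum(ops[core] == "I") + sum(al$deletions < m - ext_len)
  category <- if (ext_len > 0L) {
    classify_extension(extension)
  } else if (n_indel > 0L) {
    "indel"
  } else if (n_mismatch > 0L) {
    "mismatch"
  } else {
    "correct"
  }
  n_types <- (ext_len > 0L) + (n_indel > 0L) + (n_mismatch > 0L)
  data.frame(category = category, extension = extension,
             n_mismatch = n_mismatch, n_indel = n_indel,
             n_deviation_types = n_types)
}

#' Collect and classify all reads at a locus
#'
#' @param reads Read data frame.
#' @param anchor An [anchor()] object.
#' @param genome A [genome()] object.
#' @param band Alignment band width (default 3).
#' @return A data frame of deviation records, one row per collected read:
#'   `read_id`, `category`, `extension`, `n_mismatch`, `n_indel`,
#'   `n_deviation_types`.
#' @export
classify_locus <- function(reads, anchor, genome, band = 3L) {
  collected <- collect_by_anchor(reads, anchor)
  if (nrow(collected) == 0L) {
    return(data.frame(read_id = character(), category = character(),
                      extension = character(), n_mismatch = integer(),
                      n_indel = integer(), n_deviation_types = integer()))
  }
  recs <- lapply(collected$seq, classify_read, anchor = anchor,
                 genome = genome, band = band)
  cbind(read_id = collected$id, do.call(rbind, recs))
}

#' Summarize deviation frequencies across two replicates
#'
#' When each replicate holds at least `min_each` reads, per-category
#' percentages are computed per replicate and averaged
#' (`policy = "mean_of_two"`). Otherwise, when the pooled count reaches
#' `min_total`, percentages are computed on the pool (`policy = "pooled"`);
#' below that the sample is ignored and no percentages are reported.
#'
#' @param rep1,rep2 Deviation-record data frames from [classify_locus()].
#' @param min_each Per-replicate read floor for averaging (default 100).
#' @param min_total Pooled-read floor (default 80).
#' @return A list with `policy` (`"mean_of_two"`, `"pooled"` or
#'   `"ignored"`), `n` (per-replicate counts) and `percentages` (named
#'   vector over the five categories, `NULL` when ignored).
#' @export
summarize_frequencies <- function(rep1, rep2, min_each = 100L, min_total = 80L) {
  pct <- function(records) {
    tab <- table(factor(records$category, levels = DEVIATION_CATEGORIES))
    100 * as.vector(tab) / nrow(records)
  }
  n1 <- nrow(rep1); n2 <- nrow(rep2)
  if (n1 >= min_each && n2 >= min_each) {
    p <- (pct(rep1) + pct(rep2)) / 2
    policy <- "mean_of_two"
  } else if (n1 + n2 >= min_total) {
    p <- pct(rbind(rep1, rep2))
    policy <- "pooled"
  } else {
    return(list(policy = "ignored", n = c(n1, n2), percentages = NULL))
  }
  list(policy = policy, n = c(n1, n2),
       percentages = stats::setNames(p, DEVIATION_CATEGORIES))
}
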