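new_profile <- function(genome_id, plus, minus, n_qc, normalized) {
  structure(list(genome_id = genome_id, plus = plus, minus = minus,
                 n_qc = n_qc, normalized = normalized),
            class = "five_prime_profile")
}

#' @export
print.five_prime_profile <- function(x, ...) {
  cat("<five_prime_profile>", x$genome_id, "-", length(x$plus), "bp;",
      sum(x$plus != 0) + sum(x$minus != 0), "nonzero positions;",
      if (x$normalized) "normalized" else "raw", "\n")
  invisible(x)
}

# All exact occurrences of `pattern` in `subject`, overlapping included.
# Returns a matrix with columns start, end (0 rows when absent).
locate_all <- function(subject, pattern) {
  m <- stringi::stri_locate_all_fixed(subject, pattern, overlap = TRUE)[[1]]
  if (anyNA(m[, 1])) m <- m[0, , drop = FALSE]
  m
}

#' Map a read's 5' end to a genome by exact matching
#'
#' Finds every exact occurrence of the read on both genome strands. A
#' plus-strand occurrence reports the 1-based position of the leftmost
#' genomic base of the match; a minus-strand occurrence (read equal to the
#' reverse complement of a genomic interval) reports the rightmost genomic
#' base, i.e. the biological 5' end. Reads matching several loci are
#' attributed to all of them in equal proportions; overlapping
#' self-occurrences count as distinct loci. Reads containing `N` are
#' unmapped by definition.
#'
#' @param read_seq A single read sequence (character).
#' @param genome A [genome()] object (or nucleotide string).
#' @return `NULL` when unmapped, otherwise a list with `positions` (data
#'   frame of `pos`, `strand`) and `weight_each` (`1 / nrow(positions)`).
#' @export
map_read <- function(read_seq, genome) {
  genome <- as_genome(genome)
  read_seq <- normalize_nt(read_seq)
  if (!nzchar(read_seq) || grepl("N", read_seq, fixed = TRUE)) return(NULL)
  fwd <- locate_all(genome$seq, read_seq)
  rev <- locate_all(genome$seq, revcomp(read_seq))
  pos <- c(fwd[, "start"], rev[, "end"])
  strand <- c(rep("+", nrow(fwd)), rep("-", nrow(rev)))
  if (length(pos) == 0L) return(NULL)
  list(positions = data.frame(pos = as.integer(pos), strand = strand),
       weight_each = 1 / length(pos))
}

#' Build a genome-wide profile of read 5'-ends
#'
#' Each mapped read contributes a total weight of 1, split equally across
#' all of its exact genomic occurrences; per-position tallies sum these
#' fractional weights over reads of all lengths. With `normalize = TRUE`
#' the tallies are scaled per one million quality-controlled reads
#' (multiplied by `1e6 / n_qc`).
#'
#' @param reads Read data frame (`seq` column used).
#' @param genome A [genome()] object.
#' @param n_qc QC-read count of the source library (must be > 0).
#' @param normalize Scale per million QC reads (default `TRUE`).
#' @return A `five_prime_profile` with per-strand numeric vectors of length
#'   `genome$length`, plus `n_qc`, `normalized` and the number of mapped
#'   reads in attribute `"n_mapped"`.
#' @export
build_profile <- function(reads, genome, n_qc, normalize = TRUE) {
  genome <- as_genome(genome)
  if (missing(n_qc) || length(n_qc) != 1L || is.na(n_qc) || n_qc <= 0) {
    stop("n_qc must be a positive count")
  }
  plus <- numeric(genome$length)
  minus <- numeric(genome$length)
  n_mapped <- 0
  if (nrow(reads) > 0L) {
    counts <- table(normalize_nt(reads$seq))
    for (s in names(counts)) {
      hit <- map_read(s, genome)
      if (is.null(hit)) next
      cnt <- as.numeric(counts[[s]])
      n_mapped <- n_mapped + cnt
      w <- cnt * hit$weight_each
      for (i in seq_len(nrow(hit$positions))) {
        p <- hit$positions$pos[i]
        if (hit$positions$strand[i] == "+") plus[p] <- plus[p] + w
        else minus[p] <- minus[p] + w
      }
    }
  }
  if (normalize) {
    plus <- plus * 1e6 / n_qc
    minus <- minus * 1e6 / n_qc
  }
  prof <- new_profile(genome$id, plus, minus, n_qc = n_qc,
                      normalized = normalize)
  attr(prof, "n_mapped") <- n_mapped
  prof
}

#' Pearson correlation between two 5'-end profiles
#'
#' Standard product-moment correlation over the concatenated per-position
#' values of both strands, used to assess consistency between replicate
#' libraries.
#'
#' @param a,b Two `five_prime_profile` objects over the same genome and in
#'   the same normalization state.
#' @return Correlation coefficient in `[-1, 1]`, or `NA` (with a warning)
#'   when either profile has zero variance.
#' @export
pearson_r <- function(a, b) {
  stopifnot(inherits(a, "five_prime_profile"), inherits(b, "five_prime_profile"))
  if (length(a$plus) != length(b$plus)) {
    stop("profiles have different genome lengths (",
         length(a$plus), " vs ", length(b$plus), ")")
  }
  if (a$normalized != b$normalized) {
    stop("profiles differ in normalization state")
  }
  va <- c(a$plus, a$minus)
  vb <- c(b$plus, b$minus)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("profile with zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(va, vb)
}
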