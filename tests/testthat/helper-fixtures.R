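# Shared fixtures and independent oracles used across the test files.

random_genome <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome("toy", paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
}

read_df <- function(seqs, qual = NA_character_) {
  data.frame(id = sprintf("r%03d", seq_along(seqs)), seq = seqs,
             qual = rep_len(qual, length(seqs)))
}

# quality string with `n_good` bases at q30 and the rest at q10
qual_mix <- function(len, n_good) {
  paste0(strrep("?", n_good), strrep("+", len - n_good))
}

# Naive O(n*m) sliding-window oracle for exact occurrences: 5'-end positions
# on both strands, by direct substring comparison.
naive_occurrences <- function(read, g) {
  gl <- nchar(g$seq)
  w <- nchar(read)
  if (w > gl) return(data.frame(pos = integer(), strand = character()))
  starts <- seq_len(gl - w + 1L)
  subs <- substring(g$seq, starts, starts + w - 1L)
  plus <- starts[subs == read]
  minus <- starts[subs == revcomp(read)] + w - 1L
  data.frame(pos = c(plus, minus),
             strand = c(rep("+", length(plus)), rep("-", length(minus))))
}

# Brute-force Shannon index from an expanded multiset of labels.
shannon_oracle <- function(counts) {
  labels <- rep(seq_along(counts), counts)
  tab <- table(labels)
  p <- as.numeric(tab) / length(labels)
  -sum(p * log(p))
}

# Distinct-letter oracle for extension classification.
classify_oracle <- function(ext) {
  n <- nchar(ext)
  d <- length(unique(strsplit(ext, "", fixed = TRUE)[[1]]))
  if (n <= 3 || d <= 2) "nontemplate_addition" else "chimera"
}

# All strings of length n over ACGT.
all_kmers <- function(n) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), n),
                              stringsAsFactors = FALSE))
}

# Positional mismatch-counting oracle for the flank divergence rule.
diverges_oracle <- function(ext, cont) {
  a <- strsplit(ext, "", fixed = TRUE)[[1]]
  b <- strsplit(cont, "", fixed = TRUE)[[1]]
  sum(a != b) >= 4
}

# Window map built directly from per-window values (single-window genome
# abstractions for rule tests).
manual_window_map <- function(starts, plus, minus = rep(0, length(plus)),
                              window = 5L) {
  structure(list(starts = as.integer(starts), plus = plus, minus = minus,
                 window = as.integer(window)), class = "window_map")
}

# A genome in which every planted locus is followed by a poly-T run, so
# that A/C/G tails can never coincide with the genomic continuation and
# planted categories are unambiguous.
t_continuation_genome <- function(n_loci = 4L, frag_len = 19L, gap = 60L,
                                  seed = 42L) {
  set.seed(seed)
  pieces <- character(0)
  positions <- integer(0)
  at <- 1L
  for (i in seq_len(n_loci)) {
    frag <- paste(sample(c("A", "C", "G"), frag_len, TRUE), collapse = "")
    pieces <- c(pieces, frag, strrep("T", gap))
    positions <- c(positions, at)
    at <- at + frag_len + gap
  }
  list(genome = genome("tcont", paste(pieces, collapse = "")),
       positions = positions, frag_len = frag_len)
}
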