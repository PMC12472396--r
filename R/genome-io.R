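#' @importFrom stats cor pnorm sd setNames
#' @importFrom utils read.delim write.table head
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a genome object
#'
#' A genome is an identified uppercase nucleotide sequence with 1-based
#' inclusive coordinates. Both strands are addressable; minus-strand
#' features are reported by the genomic coordinate of their biological
#' 5' end (the rightmost genomic base of the feature).
#'
#' @param id Text label for the sequence.
#' @param seq Nucleotide string. Lowercase is uppercased and RNA `U` is
#'   transliterated to `T`; `N` is permitted.
#' @return An object of class `genome` with fields `id`, `seq`, `length`.
#' @export
genome <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- normalize_nt(seq)
  bad <- stringi::stri_count_charclass(seq, "[^ACGTN]")
  if (bad > 0L) {
    stop("genome '", id, "' contains ", bad,
         " characters outside the {A,C,G,T,N} alphabet")
  }
  structure(list(id = id, seq = seq, length = nchar(seq)), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome>", x$id, "-", x$length, "bp\n")
  invisible(x)
}

# Uppercase and transliterate RNA to the internal DNA alphabet.
normalize_nt <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (`A`,`C`,`G`,`T`,`N`).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

as_genome <- function(x) {
  if (inherits(x, "genome")) return(x)
  if (is.character(x) && length(x) == 1L) return(genome("genome", x))
  stop("expected a genome object or a single nucleotide string")
}

#' Read genomes from a FASTA file
#'
#' Sequences are uppercased and RNA `U` residues are transliterated to `T`,
#' so the same reader accepts both DNA references and RNA oligonucleotide
#' listings.
#'
#' @param path Path to a FASTA file.
#' @return A list of [genome()] objects in file order.
#' @export
read_fasta <- function(path) {
  validate_fasta(path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  lapply(seq_along(set), function(i) {
    genome(names(set)[i], as.character(set[[i]]))
  })
}

# Light structural validation so format errors can name the offending line.
validate_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("FASTA file is empty: ", path)
  if (!startsWith(lines[nonempty[1]], ">")) {
    stop("malformed FASTA: line ", nonempty[1], " is not a header in ", path)
  }
  headers <- which(startsWith(lines, ">"))
  for (i in seq_along(headers)) {
    h <- headers[i]
    if (!nzchar(trimws(substring(lines[h], 2)))) {
      stop("malformed FASTA: empty header at line ", h, " in ", path)
    }
    upto <- if (i < length(headers)) headers[i + 1] - 1L else length(lines)
    body <- lines[setdiff(seq(h, upto), h)]
    if (sum(nchar(trimws(body))) == 0L) {
      stop("malformed FASTA: empty record at line ", h, " in ", path)
    }
  }
  invisible(TRUE)
}

#' Read a small-RNA read set from FASTQ or FASTA
#'
#' @param path Path to the read file.
#' @param fmt `"fastq"` or `"fasta"`. Defaults to guessing from the file
#'   extension.
#' @return A data frame with columns `id`, `seq` (uppercase DNA) and `qual`
#'   (Sanger/+33-encoded quality string, `NA` for FASTA input). Row order
#'   follows the file.
#' @export
read_reads <- function(path, fmt = c("auto", "fastq", "fasta")) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (fmt == "fasta") {
    g <- read_fasta(path)
    return(data.frame(id = vapply(g, `[[`, "", "id"),
                      seq = vapply(g, `[[`, "", "seq"),
                      qual = NA_character_))
  }
  validate_fastq(path)
  set <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(set),
             seq = normalize_nt(as.character(set)),
             qual = as.character(S4Vectors::mcols(set)$qualities),
             row.names = NULL)
}

validate_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4)")
  }
  n <- length(lines) %/% 4L
  for (r in seq_len(n)) {
    o <- (r - 1L) * 4L
    if (!startsWith(lines[o + 1L], "@")) {
      stop("malformed FASTQ: line ", o + 1L, " does not start with '@'")
    }
    if (nchar(lines[o + 2L]) != nchar(lines[o + 4L])) {
      stop("malformed FASTQ: record at line ", o + 1L,
           " has sequence/quality length mismatch (",
           nchar(lines[o + 2L]), " vs ", nchar(lines[o + 4L]), ")")
    }
  }
  invisible(TRUE)
}

#' Write reads to FASTQ or FASTA
#'
#' Reads lacking quality strings are written with a constant Q30 quality
#' when `fmt = "fastq"`.
#'
#' @param reads Read data frame as returned by [read_reads()].
#' @param path Output path.
#' @param fmt `"fastq"` or `"fasta"`.
#' @export
write_reads <- function(reads, path, fmt = c("fastq", "fasta")) {
  fmt <- match.arg(fmt)
  set <- Biostrings::BStringSet(reads$seq)
  names(set) <- reads$id
  if (fmt == "fasta") {
    Biostrings::writeXStringSet(set, path, format = "fasta")
  } else {
    qual <- reads$qual
    missing <- is.na(qual)
    qual[missing] <- strrep("?", nchar(reads$seq[missing]))
    Biostrings::writeXStringSet(set, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual))
  }
  invisible(path)
}

#' Write a 5'-end profile to disk
#'
#' bedGraph output is 0-based half-open per the bedGraph standard (a single
#' base at 1-based position `p` covers `[p-1, p)`), one track per strand.
#' TSV output carries one row per nonzero position with columns
#' `position` (1-based), `strand`, `value`, preceded by `#`-prefixed header
#' lines recording the genome id, genome length, QC-read count and
#' normalization state, so that [read_profile()] restores the profile
#' exactly.
#'
#' @param profile A `five_prime_profile` (see [build_profile()]).
#' @param path Output path.
#' @param fmt `"tsv"` or `"bedGraph"`.
#' @export
write_profile <- function(profile, path, fmt = c("tsv", "bedGraph")) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(profile, "five_prime_profile"))
  if (!all(is.finite(profile$plus)) || !all(is.finite(profile$minus))) {
    stop("profile contains non-finite values")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (fmt == "bedGraph") {
    for (strand in c("+", "-")) {
      v <- if (strand == "+") profile$plus else profile$minus
      writeLines(sprintf(
        "track type=bedGraph name=\"%s 5p ends (%s)\"",
        profile$genome_id, strand), con)
      nz <- which(v != 0)
      if (length(nz)) {
        writeLines(sprintf("%s\t%d\t%d\t%.17g",
                           profile$genome_id, nz - 1L, nz, v[nz]), con)
      }
    }
  } else {
    writeLines(c(
      sprintf("# genome_id=%s", profile$genome_id),
      sprintf("# genome_length=%d", length(profile$plus)),
      sprintf("# n_qc=%.17g", profile$n_qc),
      sprintf("# normalized=%s", profile$normalized),
      "position\tstrand\tvalue"), con)
    for (strand in c("+", "-")) {
      v <- if (strand == "+") profile$plus else profile$minus
      nz <- which(v != 0)
      if (length(nz)) {
        writeLines(sprintf("%d\t%s\t%.17g", nz, strand, v[nz]), con)
      }
    }
  }
  invisible(path)
}

#' Read a TSV profile written by [write_profile()]
#'
#' @param path Path to a profile TSV.
#' @return A `five_prime_profile`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  meta <- function(key) {
    m <- sub(paste0("^# ", key, "="), "", hdr[grepl(paste0("^# ", key, "="), hdr)])
    if (length(m) != 1L) stop("profile header missing key '", key, "' in ", path)
    m
  }
  len <- as.integer(meta("genome_length"))
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           colClasses = c("integer", "character", "numeric"))
  plus <- numeric(len)
  minus <- numeric(len)
  p <- tab$strand == "+"
  plus[tab$position[p]] <- tab$value[p]
  minus[tab$position[!p]] <- tab$value[!p]
  new_profile(meta("genome_id"), plus, minus,
              n_qc = as.numeric(meta("n_qc")),
              normalized = as.logical(meta("normalized")))
}
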