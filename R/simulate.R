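#' Configuration for the synthetic small-RNA library generator
#'
#' The generator emulates short (16-50 nt) fragments cleaved from defined
#' genomic loci on either strand, optionally carrying templated
#' continuations, A-rich homopolymeric tails, random N-mer extensions,
#' chimeric attachments of a fixed nanomere, substitution/indel noise and
#' 3'-adapter remnants. One pseudo-random stream per run; a fixed seed
#' yields byte-identical libraries.
#'
#' @param seed Integer seed driving every random draw.
#' @param genome_length Genome size in bp (default 10000).
#' @param loci Data frame of planted loci with columns `pos` (1-based
#'   5'-end), `strand`, `frag_len`, `depth`, `ext_model` (one of `none`,
#'   `templated`, `homopolymer`, `random`, `chimera`) and `ext_len`
#'   (templated/random models; ignored otherwise).
#' @param substitution_rate Per-base substitution probability (default 0).
#' @param indel_rate Per-read probability of a single internal 1-base indel
#'   (default 0).
#' @param adapter_fraction Fraction of reads receiving a 3'-adapter remnant
#'   (`adapter_prefix` plus a random 0-5 nt tail; default 0).
#' @param adapter_prefix Remnant prefix (default `ATCACCGACTGCCCA`).
#' @param n_background Number of unmodified background fragments sampled
#'   from random genomic positions per library (default 0); these emulate
#'   the bulk of an ordinary library and stabilize per-million
#'   normalization.
#' @param background_length_range Length band for background fragments
#'   (default 16-30 nt).
#' @param homopolymer_composition Tail base probabilities for the
#'   homopolymer model (default 80% A / 20% C, an A-rich tail).
#' @param homopolymer_geom_p Geometric parameter for homopolymer tail
#'   length, `1 + rgeom(p)` capped at 10 nt (default 0.5).
#' @param chimera_seq Fixed attached nanomere (default `GCCAAGGCG`).
#' @param guarantee_divergent For the `random` model, resample any flank
#'   (length >= 4) that fails the divergence rule against the true genomic
#'   continuation (default `FALSE`).
#' @param embed Optional data frame (`seq`, `pos`) of literal sequences to
#'   plant in the genome (e.g. a known tRNA-derived 19-mer).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed, genome_length = 10000L, loci = NULL,
                       substitution_rate = 0, indel_rate = 0,
                       adapter_fraction = 0,
                       adapter_prefix = "ATCACCGACTGCCCA",
                       n_background = 0L,
                       background_length_range = c(16L, 30L),
                       homopolymer_composition = c(A = 0.8, C = 0.2),
                       homopolymer_geom_p = 0.5,
                       chimera_seq = "GCCAAGGCG",
                       guarantee_divergent = FALSE,
                       embed = NULL) {
  rates <- c(substitution_rate, indel_rate, adapter_fraction)
  stopifnot(all(rates >= 0), all(rates <= 1), genome_length >= 1)
  if (!is.null(loci)) {
    need <- c("pos", "strand", "frag_len", "depth", "ext_model")
    if (!all(need %in% names(loci))) {
      stop("loci must have columns ", paste(need, collapse = ", "))
    }
    if (!"ext_len" %in% names(loci)) loci$ext_len <- NA_integer_
    stopifnot(all(loci$depth >= 0),
              all(loci$pos >= 1), all(loci$pos <= genome_length),
              all(loci$ext_model %in%
                    c("none", "templated", "homopolymer", "random", "chimera")))
  }
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length), loci = loci,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 adapter_fraction = adapter_fraction,
                 adapter_prefix = normalize_nt(adapter_prefix),
                 n_background = as.integer(n_background),
                 background_length_range = as.integer(background_length_range),
                 homopolymer_composition = homopolymer_composition,
                 homopolymer_geom_p = homopolymer_geom_p,
                 chimera_seq = normalize_nt(chimera_seq),
                 guarantee_divergent = guarantee_divergent,
                 embed = embed),
            class = "sim_config")
}

#' Generate a toy genome
#'
#' Uniform-random A/C/G/T sequence of the configured length, deterministic
#' for a fixed seed, with optional literal embeddings at requested
#' positions (overlapping embeddings are an error).
#'
#' @param cfg A [sim_config()] object.
#' @return A [genome()] object with id `"sim_genome"`.
#' @export
make_genome <- function(cfg) {
  set.seed(cfg$seed)
  seq <- paste(sample(c("A", "C", "G", "T"), cfg$genome_length,
                      replace = TRUE), collapse = "")
  if (!is.null(cfg$embed) && nrow(cfg$embed) > 0L) {
    emb <- cfg$embed
    emb$seq <- normalize_nt(emb$seq)
    ivs <- cbind(emb$pos, emb$pos + nchar(emb$seq) - 1L)
    if (any(ivs[, 2] > cfg$genome_length)) stop("embedding exceeds genome end")
    if (nrow(ivs) > 1L) {
      o <- order(ivs[, 1])
      if (any(ivs[o, 1][-1] <= ivs[o, 2][-nrow(ivs)])) {
        stop("embedding overlap conflict")
      }
    }
    for (i in seq_len(nrow(emb))) {
      substr(seq, emb$pos[i], emb$pos[i] + nchar(emb$seq[i]) - 1L) <- emb$seq[i]
    }
  }
  genome("sim_genome", seq)
}

random_bases <- function(n, len, prob = NULL, alphabet = c("A", "C", "G", "T")) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
}

apply_noise <- function(seqs, sub_rate, indel_rate) {
  if (sub_rate == 0 && indel_rate == 0) {
    return(list(seqs = seqs, n_sub = integer(length(seqs)),
                n_indel = integer(length(seqs))))
  }
  alphabet <- c("A", "C", "G", "T")
  n_sub <- integer(length(seqs))
  n_indel <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    if (sub_rate > 0) {
      hit <- which(stats::runif(length(ch)) < sub_rate)
      for (j in hit) ch[j] <- sample(setdiff(alphabet, ch[j]), 1L)
      n_sub[i] <- length(hit)
    }
    if (indel_rate > 0 && stats::runif(1) < indel_rate && length(ch) > 2L) {
      at <- sample(2:(length(ch) - 1L), 1L)
      if (stats::runif(1) < 0.5) {
        ch <- append(ch, sample(alphabet, 1L), after = at)
      } else {
        ch <- ch[-at]
      }
      n_indel[i] <- 1L
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  list(seqs = seqs, n_sub = n_sub, n_indel = n_indel)
}

#' Simulate a small-RNA sequencing library with planted ground truth
#'
#' Each planted locus emits `round(depth * depth_factor)` reads: the
#' genomic fragment plus an extension drawn from the locus' model,
#' followed by optional substitution/indel noise and 3'-adapter remnants.
#' Background fragments (unmodified, random loci) are added per the
#' configuration. FASTQ qualities are constant Q30.
#'
#' @param cfg A [sim_config()] object.
#' @param genome The genome from [make_genome()] (or any [genome()]).
#' @param depth_factor Scalar or per-locus multiplier on `depth`, used to
#'   plant condition-dependent abundance differences (default 1).
#' @param seed Seed for this library (default `cfg$seed`); libraries from
#'   the same configuration are distinguished by their seeds.
#' @param prefix Read-id prefix (default `"read"`).
#' @return A list with `reads` (data frame `id`, `seq`, `qual`) and
#'   `truth` (one row per read: `id`, `locus`, `pos`, `strand`,
#'   `true_extension`, `true_category`, `has_adapter`, `n_sub`,
#'   `n_indel`).
#' @export
simulate_library <- function(cfg, genome, depth_factor = 1, seed = cfg$seed,
                             prefix = "read") {
  set.seed(seed)
  loci <- cfg$loci
  if (is.null(loci)) loci <- data.frame()
  if (nrow(loci) > 0L) {
    factors <- rep_len(depth_factor, nrow(loci))
  }
  seqs <- character(0)
  truth <- list()
  add <- function(seq, locus, pos, strand, ext, category) {
    data.frame(locus = locus, pos = pos, strand = strand,
               true_extension = ext, true_category = category,
               seq = seq)
  }
  for (i in seq_len(nrow(loci))) {
    n <- round(loci$depth[i] * factors[i])
    if (n <= 0L) next
    frag <- genomic_sequence(genome, loci$pos[i], loci$strand[i],
                             loci$frag_len[i])
    if (is.na(frag)) stop("locus ", i, " extends beyond the genome")
    model <- loci$ext_model[i]
    ext <- switch(
      model,
      none = rep("", n),
      templated = {
        cont <- genomic_continuation(genome, loci$pos[i], loci$strand[i],
                                     skip = loci$frag_len[i],
                                     len = loci$ext_len[i])
        if (grepl("-", cont, fixed = TRUE)) {
          stop("templated continuation at locus ", i, " runs off the genome")
        }
        rep(cont, n)
      },
      homopolymer = {
        lens <- pmin(1L + stats::rgeom(n, cfg$homopolymer_geom_p), 10L)
        vapply(lens, function(l) {
          paste(sample(names(cfg$homopolymer_composition), l, replace = TRUE,
                       prob = cfg$homopolymer_composition), collapse = "")
        }, character(1))
      },
      random = {
        l <- loci$ext_len[i]
        e <- random_bases(n, l)
        if (cfg$guarantee_divergent && l >= 4L) {
          cont <- genomic_continuation(genome, loci$pos[i], loci$strand[i],
                                       skip = loci$frag_len[i], len = l)
          bad <- which(!flank_diverges(e, cont))
          while (length(bad)) {
            e[bad] <- random_bases(length(bad), l)
            bad <- bad[!flank_diverges(e[bad], cont)]
          }
        }
        e
      },
      chimera = rep(cfg$chimera_seq, n))
    category <- switch(model,
                       none = rep("correct", n),
                       templated = rep("correct", n),
                       classify_extension(ext))
    truth[[length(truth) + 1L]] <- add(paste0(frag, ext), i, loci$pos[i],
                                       loci$strand[i],
                                       ifelse(category == "correct", "", ext),
                                       category)
  }
  if (cfg$n_background > 0L) {
    lens <- sample(seq(cfg$background_length_range[1],
                       cfg$background_length_range[2]),
                   cfg$n_background, replace = TRUE)
    strands <- sample(c("+", "-"), cfg$n_background, replace = TRUE)
    bg <- vapply(seq_len(cfg$n_background), function(j) {
      start <- sample.int(genome$length - lens[j] + 1L, 1L)
      pos5 <- if (strands[j] == "+") start else start + lens[j] - 1L
      genomic_sequence(genome, pos5, strands[j], lens[j])
    }, character(1))
    truth[[length(truth) + 1L]] <- data.frame(
      locus = NA_integer_, pos = NA_integer_, strand = strands,
      true_extension = "", true_category = "correct", seq = bg)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(locus = integer(), pos = integer(), strand = character(),
               true_extension = character(), true_category = character(),
               seq = character())
  noised <- apply_noise(truth$seq, cfg$substitution_rate, cfg$indel_rate)
  seqs <- noised$seqs
  has_adapter <- rep(FALSE, length(seqs))
  if (cfg$adapter_fraction > 0 && length(seqs)) {
    has_adapter <- stats::runif(length(seqs)) < cfg$adapter_fraction
    if (any(has_adapter)) {
      tails <- vapply(which(has_adapter), function(j) {
        paste(sample(c("A", "C", "G", "T"), sample(0:5, 1L), replace = TRUE),
              collapse = "")
      }, character(1))
      seqs[has_adapter] <- paste0(seqs[has_adapter], cfg$adapter_prefix, tails)
    }
  }
  ids <- sprintf("%s_%06d", prefix, seq_along(seqs))
  reads <- data.frame(id = ids, seq = seqs,
                      qual = strrep("?", nchar(seqs)))
  truth_out <- data.frame(id = ids, locus = truth$locus, pos = truth$pos,
                          strand = truth$strand,
                          true_extension = truth$true_extension,
                          true_category = truth$true_category,
                          has_adapter = has_adapter,
                          n_sub = noised$n_sub, n_indel = noised$n_indel)
  list(reads = reads, truth = truth_out)
}

#' Write a truth table as TSV
#'
#' The header records the seed so a run can be reproduced.
#'
#' @param truth Truth data frame from [simulate_library()].
#' @param path Output path.
#' @param seed Seed to record in the header.
#' @export
write_truth <- function(truth, path, seed = NA_integer_) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s", seed), con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
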