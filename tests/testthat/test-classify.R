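test_that("anchors are exact genomic prefixes with bounded length", {
  g <- random_genome(100, seed = 3)
  a <- anchor(g, 10, "+", 12)
  expect_equal(a$seq, substring(g$seq, 10, 21))
  am <- anchor(g, 60, "-", 14)
  expect_equal(am$seq, revcomp(substring(g$seq, 47, 60)))
  expect_error(anchor(g, 10, "+", 11), "outside configured bounds")
  expect_silent(anchor(g, 10, "+", 11, len_range = c(8, 14)))
})

test_that("anchored collection demands an exact 5' prefix", {
  g <- random_genome(100, seed = 3)
  a <- anchor(g, 10, "+", 12)
  mism <- a$seq
  substr(mism, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                substr(mism, 5, 5))[1]
  reads <- read_df(c(paste0(a$seq, "AACT"),   # collected
                     paste0(mism, "AACT"),    # anchor mismatch
                     substr(a$seq, 1, 11)))   # shorter than the anchor
  got <- collect_by_anchor(reads, a)
  expect_equal(got$id, "r001")
})

test_that("extension classification follows the length/distinct-letter rules", {
  expect_equal(classify_extension("AAG"), "nontemplate_addition")
  expect_equal(classify_extension("AAAAA"), "nontemplate_addition")
  expect_equal(classify_extension("ACACAC"), "nontemplate_addition")
  expect_equal(classify_extension("ACGT"), "chimera")
  expect_equal(classify_extension("GCCAAGGCG"), "chimera")
  expect_error(classify_extension(""), "empty extension")
})

test_that("extension classification matches the distinct-letter oracle up to 6-mers", {
  for (l in 1:6) {
    kmers <- all_kmers(l)
    got <- classify_extension(kmers)
    want <- vapply(kmers, classify_oracle, "", USE.NAMES = FALSE)
    expect_identical(got, want)
  }
  four <- table(classify_extension(all_kmers(4)))
  expect_equal(as.vector(four["nontemplate_addition"]), 88)
  expect_equal(as.vector(four["chimera"]), 168)
})

test_that("reads are classified against the genomic continuation", {
  fix <- t_continuation_genome()
  g <- fix$genome
  pos <- fix$positions[1]
  a <- anchor(g, pos, "+", 12)
  frag <- substring(g$seq, pos, pos + 18)      # 19-mer, then poly-T follows
  correct <- classify_read(frag, a, g)
  expect_equal(correct$category, "correct")
  expect_equal(correct$extension, "")

  ext <- classify_read(paste0(frag, "CG"), a, g)
  expect_equal(ext$category, "nontemplate_addition")
  expect_equal(ext$extension, "CG")

  chim <- classify_read(paste0(frag, "GCCAAGGCG"), a, g)
  expect_equal(chim$category, "chimera")
  expect_equal(chim$extension, "GCCAAGGCG")

  # internal substitution at offset 15 of a 19-mer, genomic elsewhere
  sub <- frag
  substr(sub, 15, 15) <- setdiff(c("A", "C", "G"), substr(sub, 15, 15))[1]
  mm <- classify_read(sub, a, g)
  expect_equal(mm$category, "mismatch")
  expect_equal(mm$n_mismatch, 1)

  # internal deletion at offset 15
  del <- paste0(substr(frag, 1, 14), substr(frag, 16, 19), "TT")
  dd <- classify_read(del, a, g)
  expect_equal(dd$category, "indel")
  expect_equal(dd$n_indel, 1)
})

test_that("a read with extension and internal mismatch counts once, records both", {
  fix <- t_continuation_genome()
  g <- fix$genome
  pos <- fix$positions[2]
  a <- anchor(g, pos, "+", 12)
  frag <- substring(g$seq, pos, pos + 18)
  both <- frag
  substr(both, 15, 15) <- setdiff(c("A", "C", "G"), substr(both, 15, 15))[1]
  rec <- classify_read(paste0(both, "GCCAAGGCG"), a, g)
  expect_equal(rec$category, "chimera")
  expect_equal(rec$n_mismatch, 1)
  expect_equal(rec$n_deviation_types, 2)
})

test_that("substitutions inside terminal triplets are absorbed, not mismatches", {
  fix <- t_continuation_genome()
  g <- fix$genome
  pos <- fix$positions[3]
  a <- anchor(g, pos, "+", 12)
  frag <- substring(g$seq, pos, pos + 18)
  tail_sub <- frag
  substr(tail_sub, 19, 19) <- setdiff(c("A", "C", "G"),
                                      substr(tail_sub, 19, 19))[1]
  rec <- classify_read(tail_sub, a, g)
  expect_equal(rec$n_mismatch, 0)
  expect_equal(rec$category, "nontemplate_addition")  # trailing non-match run
})

test_that("minus-strand loci classify identically to plus-strand loci", {
  set.seed(8)
  g0 <- random_genome(300)
  # continuation of the minus-strand locus reads as poly-T (A's upstream)
  seq <- g0$seq
  substr(seq, 162, 181) <- strrep("A", 20)
  g <- genome("toy", seq)
  a <- anchor(g, 200, "-", 12)
  frag <- revcomp(substring(g$seq, 182, 200))  # 19-mer with 5' end at 200
  rec <- classify_read(paste0(frag, "GCCAAGGCG"), a, g)
  expect_equal(rec$category, "chimera")
})

test_that("classification partitions collected reads across categories", {
  fix <- t_continuation_genome()
  g <- fix$genome
  pos <- fix$positions[4]
  a <- anchor(g, pos, "+", 12)
  frag <- substring(g$seq, pos, pos + 18)
  reads <- read_df(c(frag, paste0(frag, "A"), paste0(frag, "GCCAAGGCG"),
                     paste0(frag, "CC"), frag))
  recs <- classify_locus(reads, a, g)
  expect_equal(nrow(recs), 5)
  expect_equal(sum(table(recs$category)), nrow(recs))
  expect_true(all(recs$category %in% c("correct", "nontemplate_addition",
                                       "chimera", "indel", "mismatch")))
})

test_that("replicate frequency rules gate on 100-read and 80-read floors", {
  mk <- function(n_ext, n_total) {
    data.frame(read_id = sprintf("r%d", seq_len(n_total)),
               category = c(rep("nontemplate_addition", n_ext),
                            rep("correct", n_total - n_ext)),
               extension = c(rep("AA", n_ext), rep("", n_total - n_ext)),
               n_mismatch = 0L, n_indel = 0L,
               n_deviation_types = as.integer(
                 c(rep(1, n_ext), rep(0, n_total - n_ext))))
  }
  s1 <- summarize_frequencies(mk(30, 150), mk(60, 120))
  expect_equal(s1$policy, "mean_of_two")
  expect_equal(unname(s1$percentages["nontemplate_addition"]),
               (100 * 30 / 150 + 100 * 60 / 120) / 2)
  s2 <- summarize_frequencies(mk(30, 60), mk(10, 50))
  expect_equal(s2$policy, "pooled")
  expect_equal(unname(s2$percentages["nontemplate_addition"]),
               100 * 40 / 110)
  s3 <- summarize_frequencies(mk(5, 30), mk(5, 40))
  expect_equal(s3$policy, "ignored")
  expect_null(s3$percentages)
})

test_that("classification recovers planted deviation types on clean simulations", {
  fix <- t_continuation_genome(n_loci = 4, gap = 60, seed = 99)
  g <- fix$genome
  loci <- data.frame(pos = fix$positions, strand = "+", frag_len = 19L,
                     depth = 100L,
                     ext_model = c("none", "homopolymer", "random", "chimera"),
                     ext_len = c(NA, NA, 4L, NA))
  cfg <- sim_config(seed = 4242, genome_length = g$length, loci = loci,
                    guarantee_divergent = TRUE)
  lib <- simulate_library(cfg, g)
  n_checked <- 0L
  n_recovered <- 0L
  for (i in seq_len(nrow(loci))) {
    a <- anchor(g, loci$pos[i], "+", 12)
    ids <- lib$truth$id[!is.na(lib$truth$locus) & lib$truth$locus == i]
    reads <- lib$reads[lib$reads$id %in% ids, ]
    recs <- classify_locus(reads, a, g)
    truth <- lib$truth[match(recs$read_id, lib$truth$id), ]
    n_checked <- n_checked + nrow(recs)
    n_recovered <- n_recovered + sum(recs$category == truth$true_category)
  }
  expect_equal(n_checked, 400L)
  expect_gte(n_recovered / n_checked, 0.99)
})
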