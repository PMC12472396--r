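test_that("Shannon index matches closed forms", {
  expect_equal(shannon_index(c(x = 17)), 0)
  expect_equal(shannon_index(rep(1, 4)), log(4))
  expect_equal(shannon_index(rep(1, 64)), log(64))
  expect_equal(shannon_index(c(x = 2, y = 1, z = 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
  expect_error(shannon_index(numeric(0)), "empty")
})

test_that("Shannon index agrees with brute-force evaluation on random multisets", {
  set.seed(2024)
  for (i in 1:300) {
    counts <- sample(1:20, sample(1:30, 1), replace = TRUE)
    expect_equal(shannon_index(counts), shannon_oracle(counts),
                 tolerance = 1e-12)
  }
})

test_that("H is maximal for uniform counts and merging uniques never increases it", {
  set.seed(9)
  for (i in 1:50) {
    n <- sample(2:20, 1)
    counts <- sample(1:10, n, replace = TRUE)
    expect_lte(shannon_index(counts), log(n) + 1e-12)
    merged <- c(counts[1] + counts[2], counts[-(1:2)])
    expect_lte(shannon_index(merged), shannon_index(counts) + 1e-12)
  }
})

test_that("flank divergence requires at least 4 positional mismatches", {
  expect_true(flank_diverges("AAAA", "TTTT"))    # L=4, 0 matches
  expect_false(flank_diverges("AAAT", "TTTT"))   # L=4, 1 match
  expect_true(flank_diverges("AATTCC", "TTTTTT"))   # L=6, 2 matches allowed
  expect_false(flank_diverges("ATTTCC", "TTTTTT"))  # L=6, 3 matches
  expect_error(flank_diverges("AAAA", "TTT"), "lengths differ")
  expect_error(flank_diverges("AAA", "TTT"), "L >= 4")
})

test_that("a truncated continuation counts missing bases as mismatches", {
  g <- genome("g", paste0(strrep("C", 20), "ACGT"))
  # k-mer ending 2 bases from the genome end: continuation is "GT" + 2 pads
  cont <- termflex:::genomic_continuation(g, 3, "+", 20, 4)
  expect_equal(cont, "GT--")
  expect_true(flank_diverges("CACA", cont))   # 0 real matches + 2 pads
  expect_false(flank_diverges("GTCA", cont))  # 2 real matches > L-4
})

test_that("perfectly genomic reads and anchorless reads never qualify", {
  g <- random_genome(500, seed = 21)
  genomic <- substring(g$seq, 100, 119)                  # 20 = 16 + 4
  noanchor <- paste0(strrep("A", 8), strrep("C", 8), "GTGT")
  stopifnot(is.null(map_read(noanchor, g)))
  out <- randext_run(c(genomic, noanchor), g, k = 16, L = 4)
  expect_equal(nrow(out), 0)
})

test_that("a genomic k-mer with a divergent flank qualifies at its locus", {
  g <- random_genome(500, seed = 22)
  kmer <- substring(g$seq, 100, 115)
  cont <- substring(g$seq, 116, 119)
  flank <- chartr("ACGT", "CATG", cont)      # every base differs
  out <- randext_run(paste0(kmer, flank), g, k = 16, L = 4)
  expect_equal(out$pos, 100)
  expect_equal(out$strand, "+")
  expect_equal(out$n_reads, 1)
  expect_equal(out$H, 0)
})

test_that("reads are attributed to every occurrence passing divergence", {
  set.seed(77)
  kmer <- paste(sample(c("A", "C", "G"), 16, TRUE), collapse = "")
  # same k-mer at two loci with different continuations
  g <- genome("dup", paste0(strrep("T", 10), kmer, "AAAA", strrep("T", 30),
                            kmer, "GGGG", strrep("T", 10)))
  both <- paste0(kmer, "CCCC")   # diverges from AAAA and GGGG
  att <- attribute_read(both, g, k = 16, L = 4)
  expect_equal(sort(att$pos), c(11L, 61L))
  one <- paste0(kmer, "GGGG")    # matches locus 2's continuation exactly
  att1 <- attribute_read(one, g, k = 16, L = 4)
  expect_equal(att1$pos, 11L)
  run <- randext_run(both, g, k = 16, L = 4)
  expect_true(all(run$cross_contributed))
})

test_that("grid scan aggregates the per-position maximum H", {
  g <- random_genome(400, seed = 30)
  kmer16 <- substring(g$seq, 50, 65)
  flanks <- c("AAAA", "CCCC", "GGGG", "TTTT")
  cont <- substring(g$seq, 66, 69)
  flanks <- flanks[vapply(flanks, function(f) flank_diverges(f, cont), TRUE)]
  reads <- paste0(kmer16, rep(flanks, each = 2))
  single <- randext_run(reads, g, k = 16, L = 4)
  grid1 <- grid_scan(reads, g, k_range = 16, L_range = 4)
  expect_equal(grid1$max_H[grid1$pos == 50], single$H[single$pos == 50])
  grid <- grid_scan(reads, g, k_range = 13:16, L_range = 4:7)
  row <- grid[grid$pos == 50, ]
  expect_equal(nrow(row), 1)
  all_h <- unlist(lapply(4:7, function(L) {
    r <- randext_run(reads, g, k = 20 - L, L = L)
    r$H[r$pos == 50]
  }))
  expect_equal(row$max_H, max(all_h))
  expect_error(grid_scan(reads, g, k_range = integer(0)), "empty parameter grid")
})

test_that("raising the H threshold never enlarges the flagged set", {
  cfg <- sim_config(seed = 55, genome_length = 3000,
                    loci = data.frame(pos = c(500, 1500), strand = "+",
                                      frag_len = 16L, depth = c(60L, 15L),
                                      ext_model = "random", ext_len = 4L),
                    guarantee_divergent = TRUE)
  g <- make_genome(cfg)
  lib <- simulate_library(cfg, g)
  flagged <- vapply(c(0.5, 1.5, 2.5, 3.5), function(th) {
    sum(grid_scan(lib$reads, g, k_range = 16, L_range = 4,
                  h_threshold = th)$flagged)
  }, numeric(1))
  expect_true(all(diff(flagged) <= 0))
})

test_that("an empty read set yields an empty H profile", {
  g <- random_genome(100, seed = 2)
  expect_equal(nrow(grid_scan(character(0), g, 13:14, 4:5)), 0)
})
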