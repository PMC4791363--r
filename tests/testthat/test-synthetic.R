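test_that("simulate_genome hits its G+C target, deterministically", {
  sp <- population_spec("T1", gc_target = 0.44, genome_length = 2e5)
  g1 <- simulate_genome(sp, seed = 11)
  g2 <- simulate_genome(sp, seed = 11)
  expect_identical(g1$sequence, g2$sequence)
  expect_false(identical(g1$sequence, simulate_genome(sp, seed = 12)$sequence))
  # binomial sd of per-base G+C draw at 2e5 is ~0.0011; 3 sd plus margin
  expect_lt(abs(gc_content(g1$sequence) - 0.44), 0.005)
  # invariant band for L >= 1e5
  for (gc in c(0.29, 0.5, 0.6)) {
    g <- simulate_genome(population_spec("x", gc, 1e5), seed = 3)
    expect_lt(abs(gc_content(g$sequence) - gc), 0.01)
  }
  expect_error(population_spec("bad", 1.2, 1e5), "fraction")
  expect_error(simulate_genome(population_spec("s", 0.5, 5e3), 1), ">= 1e4")
})

test_that("k-mer bias detectably shifts word frequencies toward the bias", {
  spec0 <- population_spec("plain", 0.5, 5e4)
  bias <- c(AAAA = 4, CCCC = 4)
  spec1 <- population_spec("biased", 0.5, 5e4, kmer_bias = bias)
  f0 <- word_frequency(simulate_genome(spec0, 5)$sequence, k = 4)
  f1 <- word_frequency(simulate_genome(spec1, 5)$sequence, k = 4)
  expect_gt(f1[["AAAA"]], f0[["AAAA"]])
  expect_gt(f1[["CCCC"]], f0[["CCCC"]])
  # G+C stays on target despite the bias layer (symmetric bias)
  expect_lt(abs(gc_content(simulate_genome(spec1, 5)$sequence) - 0.5), 0.01)
})

test_that("diverge_pair plants the requested substitution load", {
  g <- simulate_genome(population_spec("a", 0.5, 1e5), 21)
  same <- diverge_pair(g, 1.0, 22)
  expect_identical(same$sequence, g$sequence)
  div <- diverge_pair(g, 0.96, 23)
  ident <- mean(strsplit(g$sequence, "")[[1]] ==
                  strsplit(div$sequence, "")[[1]])
  # 3 binomial sd at L = 1e5: 3 * sqrt(0.96 * 0.04 / 1e5) ~ 0.0019
  expect_lt(abs(ident - 0.96), 0.002)
  expect_error(diverge_pair(g, 0, 1), "target_identity")
})

test_that("fragment_and_cover cuts disjoint substrings with coverage", {
  g <- simulate_genome(population_spec("a", 0.5, 1e5), 31)
  ct <- fragment_and_cover(g, n_contigs = 10, min_len = 3000,
                           cov_mean = 3, seed = 32)
  expect_equal(nrow(ct), 10)
  expect_true(all(ct$length >= 3000))
  # non-overlapping in genome coordinates
  o <- order(ct$start)
  expect_true(all(ct$start[o][-1] >= (ct$start + ct$length)[o][-10]))
  # substrings of the source
  expect_identical(ct$sequence[1],
                   substring(g$sequence, ct$start[1],
                             ct$start[1] + ct$length[1] - 1))
  one <- fragment_and_cover(g, 1, 1e5, 2.5, seed = 1, cov_sd = 0)
  expect_identical(one$sequence[1], g$sequence)
  expect_equal(one$coverage[1], 2.5)
  expect_error(fragment_and_cover(g, 50, 3000, 3, 1), "infeasible")
})

test_that("simulate_reads reproduces abundances, lengths and exactness", {
  gs <- lapply(1:2, function(i)
    simulate_genome(population_spec(paste0("p", i), 0.45, 1e5), 40 + i))
  comm <- list(list(genome = gs[[1]], abundance = 0.8),
               list(genome = gs[[2]], abundance = 0.2))
  rd <- simulate_reads(comm, n_reads = 4000, len_mean = 820, len_sd = 120,
                       err_rate = 0, seed = 44)
  expect_equal(length(rd$reads), 4000)
  expect_lt(abs(mean(nchar(rd$reads)) - 820), 3 * 120 / sqrt(4000) + 2)
  # source counts within 3 binomial sd of 0.8/0.2 (equal genome lengths)
  n1 <- sum(rd$truth$source == "p1")
  expect_lt(abs(n1 - 3200), 3 * sqrt(4000 * 0.8 * 0.2) + 1)
  # err_rate = 0: every read is an exact substring of its source (strand-aware)
  idx <- sample(4000, 25)
  for (i in idx) {
    tr <- rd$truth[i, ]
    src <- gs[[match(tr$source, c("p1", "p2"))]]$sequence
    frag <- substring(src, tr$start, tr$start + tr$length - 1)
    obs <- rd$reads[[tr$read_id]]
    if (tr$strand == "-")
      obs <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(obs)))
    expect_identical(obs, frag)
  }
  expect_error(simulate_reads(list(), 10, seed = 1), "non-empty")
  expect_error(simulate_reads(comm, 10, err_rate = 0.5, seed = 1), "err_rate")
})

test_that("simulate_survey plants identities on the right side of 97%", {
  niches <- list(T1 = list(temp = c(75, 88), ph = c(7.4, 8.6)))
  sv <- simulate_survey(survey_spec(10, niches = niches), seed = 51)
  expect_equal(nrow(sv$sites), 10)
  for (s in seq_len(10)) {
    v <- sv$pools[[s]][[paste0(sv$sites$site_id[s], "_T1")]]
    id <- suppressWarnings(rrna_identity(sv$references[["T1"]], v))
    if (sv$sites$occ_T1[s]) expect_gt(id, 97) else expect_lt(id, 97)
  }
  expect_error(survey_spec(5, niches = list()), "niche")
  expect_error(
    survey_spec(5, niches = list(a = list(temp = c(60, 80), ph = c(7, 8)))),
    "outside")
})

test_that("proteome divergence plants the expected identity", {
  pa <- simulate_proteome(30, seed = 61)
  pb <- diverge_proteome(pa, 0.94, 62)
  ident <- mean(mapply(function(x, y)
    mean(strsplit(x, "")[[1]] == strsplit(y, "")[[1]]), pa, pb))
  expect_lt(abs(ident - 0.94), 0.01)
  expect_identical(nchar(pa), nchar(pb))
})

test_that("stage_seed derives distinct, stable per-stage seeds", {
  expect_identical(stage_seed(1, "reads"), stage_seed(1, "reads"))
  expect_false(stage_seed(1, "reads") == stage_seed(1, "contigs"))
  expect_true(stage_seed(2^30, "x") < 2^31)
})
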