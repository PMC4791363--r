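test_that("local_align reproduces hand-derived alignments", {
  h <- local_align("ACGTACGT", "ACGTTCGT")
  expect_equal(h$columns, 8)
  expect_equal(h$matches, 7)
  expect_equal(h$identity, 0.875)
  same <- local_align("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(same$identity, 1)
  expect_equal(same$columns, 10)
  expect_error(local_align("ACGT", "EFIL"), "alphabet")
  expect_error(local_align("", "ACGT"), "non-empty")
})

test_that("aligner agrees exactly with a plain-R exhaustive DP oracle", {
  withr::with_seed(201, {
    for (rep in 1:60) {
      if (rep %% 2 == 0) {
        a <- random_dna_str(sample(10:150, 1))
        b <- random_dna_str(sample(10:150, 1))
      } else {
        p <- homologous_pair(sample(40:150, 1), sample(40:150, 1),
                             core_len = 30)
        a <- p[1]; b <- p[2]
      }
      got <- local_align(a, b, match = 1, mismatch = -1, gap = -2)
      want <- sw_oracle(a, b, 1, -1, -2)
      expect_identical(got$score, want$score)
      expect_identical(got$columns, want$columns)
      expect_identical(got$matches, want$matches)
    }
  })
})

test_that("seeded path equals full DP when homology provides seeds", {
  withr::with_seed(202, {
    for (rep in 1:10) {
      p <- homologous_pair(600, 700, core_len = 300)
      full <- local_align(p[1], p[2], method = "full", gap = -2)
      seeded <- local_align(p[1], p[2], method = "seeded", gap = -2)
      expect_identical(seeded$score, full$score)
      expect_identical(seeded$matches, full$matches)
    }
  })
})

test_that("score matches Biostrings pairwiseAlignment on random pairs", {
  skip_if_not_installed("Biostrings")
  mat <- matrix(-1L, 5, 5,
                dimnames = list(c("A", "C", "G", "T", "N"),
                                c("A", "C", "G", "T", "N")))
  diag(mat)[1:4] <- 1L
  withr::with_seed(203, {
    for (rep in 1:15) {
      p <- homologous_pair(120, 120, core_len = 40)
      got <- local_align(p[1], p[2], match = 1, mismatch = -1, gap = -2)
      ref <- Biostrings::pairwiseAlignment(
        p[1], p[2], type = "local", substitutionMatrix = mat,
        gapOpening = 0, gapExtension = 2)
      expect_equal(got$score, Biostrings::score(ref))
    }
  })
})

test_that("AAI is 100 +/- 0 for identical proteomes and filters weak pairs", {
  pa <- simulate_proteome(40, len_range = c(120, 300), seed = 211)
  self <- pairwise_aai(pa, pa)
  expect_equal(self$mean, 100)
  expect_equal(self$sd, 0)
  expect_equal(self$n, 40)
  # a candidate pair at ~28% identity is excluded from n
  clean <- pa[1]
  weak <- diverge_proteome(pa[2], 0.28, 212)
  names(weak) <- "w1"
  r <- pairwise_aai(c(clean, pa[2]), c(clean, weak))
  kept_under_30 <- r$n
  expect_lte(kept_under_30, 2)
  expect_true(all(r$identities >= 30)) # no retained identity below the filter
  expect_error(pairwise_aai(character(), pa), "non-empty")
})

test_that("AAI recovers planted 6% proteome divergence", {
  pa <- simulate_proteome(60, len_range = c(150, 350), seed = 213)
  pb <- diverge_proteome(pa, 0.94, 214)
  r <- pairwise_aai(pa, pb)
  expect_gte(r$mean, 92); expect_lte(r$mean, 96)
  expect_equal(r$n, 60)
})

test_that("ANI is exact on self and tracks planted divergence within 1 point", {
  g <- simulate_genome(population_spec("g", 0.5, 2e5), 221)
  self <- pairwise_ani(g$sequence, g$sequence)
  expect_equal(self$mean, 100)
  expect_equal(self$sd, 0)
  expect_true(self$defined)
  for (p in c(0.05, 0.15)) {
    d <- diverge_pair(g, 1 - p, 222 + round(100 * p))
    r <- pairwise_ani(g$sequence, d$sequence)
    expect_lt(abs(r$mean - 100 * (1 - p)), 1)
  }
  # unrelated genomes retain too few fragments: undefined signal, not error
  other <- simulate_genome(population_spec("h", 0.5, 2e5), 223)
  r0 <- pairwise_ani(g$sequence, other$sequence)
  expect_false(r0$defined)
  expect_true(is.na(r0$mean))
})

test_that("ANI/AAI are symmetric within half a point", {
  g <- simulate_genome(population_spec("g", 0.5, 1e5), 231)
  d <- diverge_pair(g, 0.95, 232)
  r1 <- pairwise_ani(g$sequence, d$sequence)
  r2 <- pairwise_ani(d$sequence, g$sequence)
  expect_lt(abs(r1$mean - r2$mean), 0.5)
  pa <- simulate_proteome(30, seed = 233)
  pb <- diverge_proteome(pa, 0.9, 234)
  a1 <- pairwise_aai(pa, pb); a2 <- pairwise_aai(pb, pa)
  expect_lt(abs(a1$mean - a2$mean), 0.5)
})

test_that("rrna_identity reports planted 16S divergence symmetrically", {
  withr::with_seed(241, {
    ref <- random_dna_str(1400, 0.55)
    b <- strsplit(ref, "")[[1]]
    pos <- sample(11:1390, 28) # 2% substitutions away from the ends
    b[pos] <- unlist(list(A = "C", C = "G", G = "T", T = "A")[b[pos]])
    var2 <- paste(b, collapse = "")
  })
  expect_equal(rrna_identity(ref, ref), 100)
  id <- rrna_identity(ref, var2)
  expect_equal(id, 100 * (1400 - 28) / 1400, tolerance = 1e-6)
  expect_equal(rrna_identity(ref, var2), rrna_identity(var2, ref))
  expect_warning(rrna_identity(substring(ref, 1, 150), ref), "200")
})
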