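ref_genomes <- local({
  set.seed(101)
  list(binA = random_dna_str(2e4), binB = random_dna_str(2e4))
})

test_that("exact substring reads recruit to their bin at identity 1", {
  reads <- c(r1 = substring(ref_genomes$binA, 501, 1300),
             r2 = substring(ref_genomes$binB, 2001, 2800))
  asn <- recruit_reads(reads, ref_genomes)
  expect_equal(asn$bin, c("binA", "binB"))
  expect_equal(asn$identity, c(1, 1))
  expect_equal(asn$aligned_len, c(800L, 800L))
  # minus-strand reads recruit identically
  rc <- vapply(reads, function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))), character(1))
  asn2 <- recruit_reads(rc, ref_genomes)
  expect_equal(asn2$bin, c("binA", "binB"))
  expect_equal(asn2$identity, c(1, 1))
})

test_that("reads below the identity threshold or coverage floor are orphans", {
  withr::with_seed(102, {
    frag <- substring(ref_genomes$binA, 1001, 1800)
    b <- strsplit(frag, "")[[1]]
    pos <- sample(30:770, 120) # 15% substitutions away from the ends
    alt <- list(A = "C", C = "G", G = "T", T = "A")
    b[pos] <- unlist(alt[b[pos]])
    read85 <- paste(b, collapse = "")
    lowcov <- paste0(substring(ref_genomes$binA, 3001, 3150),
                     random_dna_str(350))
  })
  asn <- recruit_reads(c(r85 = read85, rlow = lowcov), ref_genomes)
  expect_equal(asn$bin, c("ORPHAN", "ORPHAN"))
  expect_lt(asn$identity[1], 0.9)
})

test_that("ties between bins are orphaned, and recruitment is monotone", {
  dup <- list(binA = ref_genomes$binA, binA2 = ref_genomes$binA)
  read <- substring(ref_genomes$binA, 101, 900)
  asn <- recruit_reads(c(r = read), dup)
  expect_equal(asn$bin, "ORPHAN")
  expect_equal(asn$identity, 1) # identity reported even for the tie orphan
  # raising min_identity never increases a non-orphan percentage
  withr::with_seed(103, {
    reads <- c(
      vapply(1:20, function(i) {
        st <- sample(1e4, 1)
        substring(ref_genomes$binA, st, st + 799)
      }, character(1)),
      vapply(1:20, function(i) {
        st <- sample(1e4, 1)
        frag <- substring(ref_genomes$binB, st, st + 799)
        b <- strsplit(frag, "")[[1]]
        pos <- sample(30:770, 56) # 7% divergence: above 0.90, below 0.95
        b[pos] <- unlist(list(A = "C", C = "G", G = "T", T = "A")[b[pos]])
        paste(b, collapse = "")
      }, character(1)))
    names(reads) <- paste0("r", seq_along(reads))
  })
  ab90 <- abundance_table(recruit_reads(reads, ref_genomes,
                                        min_identity = 0.90))
  ab95 <- abundance_table(recruit_reads(reads, ref_genomes,
                                        min_identity = 0.95))
  pct <- function(tab, bn) if (bn %in% tab$bin) tab$percent[tab$bin == bn] else 0
  for (bn in c("binA", "binB"))
    expect_lte(pct(ab95, bn), pct(ab90, bn))
  # the 7%-diverged reads recruit at 0.90 but not at 0.95
  expect_gt(pct(ab90, "binB"), 0)
  expect_equal(pct(ab95, "binB"), 0)
})

test_that("abundance_table percentages behave and sum to 100", {
  asn <- tibble::tibble(read_id = paste0("r", 1:100),
                        bin = c(rep("A", 80), rep("ORPHAN", 20)),
                        identity = 1, aligned_len = 800L)
  ab <- abundance_table(asn)
  expect_equal(ab$percent[ab$bin == "A"], 80)
  expect_equal(ab$percent[ab$bin == "ORPHAN"], 20)
  expect_equal(sum(ab$percent), 100)
  one <- abundance_table(tibble::tibble(read_id = "r", bin = "A",
                                        identity = 1, aligned_len = 1L))
  expect_equal(one$percent, c(100, 0))
  expect_error(abundance_table(asn[0, ]), "zero reads")
})

test_that("gc_histogram counts reads per bin with an ALL series", {
  g <- simulate_genome(population_spec("g44", 0.44, 1e5), 105)
  rd <- simulate_reads(list(list(genome = g, abundance = 1)), 400,
                       len_mean = 800, len_sd = 50, seed = 106)
  asn <- recruit_reads(rd$reads, list(g44 = g$sequence))
  h <- gc_histogram(rd$reads, asn, bin_width = 1)
  hg <- h[h$bin == "g44", ]
  expect_equal(sum(hg$count), sum(asn$bin == "g44"))
  expect_equal(sum(h$count[h$bin == "ALL"]), 400)
  mode_gc <- hg$gc_lower[which.max(hg$count)]
  expect_gte(mode_gc, 42); expect_lte(mode_gc, 46)
  expect_error(gc_histogram(rd$reads, asn, bin_width = 0), "positive")
})
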