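test_that("curate_references enforces the >= 16 of 18 rule with whitelist", {
  tables <- list(ok16 = MARKER_GENES_18[1:16],
                 full = MARKER_GENES_18,
                 short15 = MARKER_GENES_18[1:15],
                 rescued = MARKER_GENES_18[1:15])
  kept <- curate_references(tables, min_genes = 16, total = 18,
                            whitelist = "rescued")
  expect_setequal(kept, c("ok16", "full", "rescued"))
  expect_false("short15" %in% kept)
  long <- data.frame(genome = rep(c("a", "b"), c(18, 10)),
                     gene = c(MARKER_GENES_18, MARKER_GENES_18[1:10]))
  expect_equal(curate_references(long), "a")
})

test_that("concatenation tiles partitions and gap-fills missing taxa", {
  g1 <- c(A = strrep("Q", 100), B = strrep("Q", 100), C = strrep("K", 100))
  g2 <- c(A = strrep("M", 200), B = strrep("L", 200), D = strrep("M", 200))
  cc <- concatenate_partitions(list(beta = g2, alph = g1))
  expect_equal(ncol(cc$matrix), 300)
  expect_equal(cc$partitions$gene, c("alph", "beta")) # lexicographic order
  expect_equal(cc$partitions$start, c(0, 100))
  expect_equal(cc$partitions$end, c(100, 300))
  expect_true(all(cc$matrix["D", 1:100] == "-"))
  expect_true(all(cc$matrix["C", 101:300] == "-"))
  # informative columns: both partitions vary across taxa
  expect_equal(cc$informative, 300)
  allsame <- concatenate_partitions(list(g = c(A = "AAAA", B = "AAAA")))
  expect_equal(allsame$informative, 0)
  expect_error(concatenate_partitions(list(g = c(A = "AA", B = "AAA"))),
               "unequal")
})

test_that("column_weights follows the gap x conservation formula", {
  w <- column_weights(c(t1 = "AC-A", t2 = "AC-C", t3 = "AD-G", t4 = "A--T"))
  expect_equal(w, c(1, 0.5, 0, 0.25))
})

test_that("distance correction matches the closed form and its edge cases", {
  M <- rbind(a = rep("A", 100), b = c(rep("C", 10), rep("A", 90)))
  D <- protein_distance_matrix(M)
  expect_equal(D[1, 2], -(19 / 20) * log(1 - 20 * 0.1 / 19))
  expect_equal(D[2, 1], D[1, 2])
  expect_equal(diag(D), c(a = 0, b = 0))
  ident <- protein_distance_matrix(rbind(a = rep("A", 50), b = rep("A", 50)))
  expect_equal(ident[1, 2], 0)
  # saturation cap
  sat <- protein_distance_matrix(rbind(a = rep("A", 40), b = rep("C", 40)))
  expect_equal(sat[1, 2], 10)
  # nucleotide (Jukes-Cantor) correction constant
  Mn <- rbind(a = rep("A", 100), b = c(rep("C", 10), rep("A", 90)))
  Dn <- protein_distance_matrix(Mn, alphabet_size = 4)
  expect_equal(Dn[1, 2], -(3 / 4) * log(1 - 4 * 0.1 / 3))
  expect_error(protein_distance_matrix(
    rbind(a = c("A", "-"), b = c("-", "A"))), "comparable")
})

test_that("nj_tree recovers additive topologies and the 3-taxon closed form", {
  D4 <- matrix(c(0, 2, 5, 5, 2, 0, 5, 5, 5, 5, 0, 2, 5, 5, 2, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(D4)
  expect_equal(quartet_split(ape::cophenetic.phylo(tr)[LETTERS[1:4],
                                                       LETTERS[1:4]]),
               quartet_split(D4))
  # 3 taxa: closed-form branch lengths x=1, y=2, z=3
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  expect_setequal(round(t3$edge.length, 9), c(1, 2, 3))
  # taxon order never changes the topology
  perm <- sample(4)
  trp <- nj_tree(D4[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(trp)),
               structure(0, names = NULL), ignore_attr = TRUE)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

make_planted_alignment <- function(seed, n_col = 200, internal = 30) {
  withr::with_seed(seed, {
    aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
    base <- sample(aas, n_col, TRUE)
    mut <- function(row, k) {
      i <- sample(n_col, k)
      row[i] <- sample(aas, k, TRUE)
      row
    }
    groupAB <- mut(base, internal)
    mat <- rbind(A = mut(groupAB, 8), B = mut(groupAB, 8),
                 C = mut(base, 8), D = mut(base, 8), E = mut(base, 40))
    apply(mat, 1, paste, collapse = "")
  })
}

test_that("bootstrap supports are reproducible, bounded, and signal-driven", {
  aln <- make_planted_alignment(301)
  cc <- concatenate_partitions(list(gene1 = aln))
  b1 <- bootstrap_support(cc, n_reps = 60, seed = 5)
  b2 <- bootstrap_support(cc, n_reps = 60, seed = 5)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support$support >= 0 & b1$support$support <= 100))
  # the planted (A,B) clade has a long internal branch: full support
  ab_node <- ape::getMRCA(b1$tree, c("A", "B"))
  expect_equal(b1$support$support[b1$support$node == ab_node], 100)
  # star-like data: internal supports well below 100
  withr::with_seed(302, {
    aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
    base <- sample(aas, 150, TRUE)
    mut <- function(row, k) {
      i <- sample(150, k); row[i] <- sample(aas, k, TRUE); row
    }
    star <- apply(rbind(A = mut(base, 12), B = mut(base, 12),
                        C = mut(base, 12), D = mut(base, 12),
                        E = mut(base, 12)), 1, paste, collapse = "")
  })
  bs <- bootstrap_support(concatenate_partitions(list(g = star)),
                          n_reps = 60, seed = 6)
  internal <- bs$support$support[-1] # drop the root pseudo-node
  expect_true(any(internal < 90))
})

test_that("csi_scan measures indels between flanks and flags ambiguity", {
  sig <- csi_signature("gene", left = "KLM", right = "PQR", ref_span = 0)
  res <- csi_scan(c(ref = "AAKLMPQRWW", plus5 = "AAKLMWWWWWPQRWW",
                    gapped = "AAKLM--PQRWW", missing = "AAKLMWWW"), sig)
  expect_equal(res$indel_length[res$taxon == "ref"], 0L)
  expect_equal(res$indel_length[res$taxon == "plus5"], 5L)
  expect_equal(res$indel_length[res$taxon == "gapped"], 0L) # gaps not counted
  expect_equal(res$status[res$taxon == "missing"], "NOT_FOUND")
  expect_error(csi_scan(c(x = "KLMAPQRKLM"), sig), "ambiguous")
  expect_error(csi_signature("g", "", "PQR"), "non-empty")
})
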