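# Independent oracles used across the suite. These deliberately re-derive
# results with different code paths (plain R, closed forms, enumeration)
# from the implementations they check.

# Exhaustive Smith-Waterman DP in plain R: linear gap, same deterministic
# tie conventions as the package aligner (first maximal cell in row-major
# order; diagonal > up > left on ties). Returns score/columns/matches.
sw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1) # 0 stop, 1 diag, 2 up, 3 left
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- if (av[i] == bv[j]) match else mismatch
      diag <- H[i, j] + sub
      up <- H[i, j + 1] + gap
      left <- H[i + 1, j] + gap
      h <- diag; p <- 1L
      if (up > h) { h <- up; p <- 2L }
      if (left > h) { h <- left; p <- 3L }
      if (h <= 0) { h <- 0; p <- 0L }
      H[i + 1, j + 1] <- h
      P[i + 1, j + 1] <- p
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  cols <- 0; matches <- 0
  i <- bi; j <- bj
  while (i > 0 && j > 0 && P[i + 1, j + 1] != 0L) {
    p <- P[i + 1, j + 1]
    cols <- cols + 1
    if (p == 1L) {
      if (av[i] == bv[j]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (p == 2L) i <- i - 1 else j <- j - 1
  }
  list(score = as.integer(best), columns = as.integer(cols),
       matches = as.integer(matches))
}

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Four-point-condition split of a quartet: for additive distances the true
# split {x,y}|{z,w} is the pairing with the strictly smallest sum
# d(x,y) + d(z,w). Returns a canonical string encoding of the split.
quartet_split <- function(D4) {
  t <- rownames(D4)
  pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  sums <- vapply(pairings, function(p)
    D4[t[p[1]], t[p[2]]] + D4[t[p[3]], t[p[4]]], numeric(1))
  p <- pairings[[which.min(sums)]]
  paste(sort(c(paste(sort(t[p[1:2]]), collapse = ","),
               paste(sort(t[p[3:4]]), collapse = ","))), collapse = "|")
}

# All quartet splits induced by a tree's additive (cophenetic) distances.
tree_quartets <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  tips <- sort(rownames(D))
  combs <- utils::combn(tips, 4, simplify = FALSE)
  vapply(combs, function(q) quartet_split(D[q, q]), character(1))
}

# Planted-homology pair: two random sequences sharing one common segment.
homologous_pair <- function(len_a, len_b, core_len) {
  core <- random_dna_str(core_len)
  a <- paste0(random_dna_str(max(0, len_a - core_len)), core)
  b <- paste0(core, random_dna_str(max(0, len_b - core_len)))
  c(a, b)
}
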