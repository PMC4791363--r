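#' Construct a relatedness result
#'
#' Container for AAI / ANI / 16S identity summaries: the mean and standard
#' deviation (in percent) of the retained pairwise identities and the number
#' of retained comparisons. When too few comparisons survive the filters the
#' result is *undefined* (a signal, not an error): `defined` is `FALSE` and
#' the summary statistics are `NA`.
#'
#' @param metric one of `"AAI"`, `"ANI"`, `"RRNA_ID"`.
#' @param identities numeric vector of retained identities as fractions.
#' @param min_n minimum number of retained comparisons for a defined result.
#' @param params list of parameters to echo in the result.
#' @return An object of class `relatedness_result` with fields `metric`,
#'   `mean`, `sd`, `n`, `defined`, `params`.
#' @export
relatedness_result <- function(metric, identities, min_n = 1L, params = list()) {
  n <- length(identities)
  defined <- n >= min_n
  structure(list(
    metric = metric,
    mean = if (defined) mean(identities) * 100 else NA_real_,
    sd = if (defined) stats::sd(identities) * 100 else NA_real_,
    n = n, defined = defined, params = params,
    identities = identities * 100), class = "relatedness_result")
}

#' @export
print.relatedness_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<%s> %.1f +/- %.1f%% (n = %d retained comparisons)\n",
                x$metric, x$mean, x$sd, x$n))
  } else {
    cat(sprintf("<%s> undefined: only %d comparison(s) retained\n",
                x$metric, x$n))
  }
  invisible(x)
}

#' @noRd
.seqs_as_named_char <- function(x, prefix) {
  s <- .as_char_seq(x)
  if (length(s) == 0) return(s)
  if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == ""))
    names(s) <- paste0(prefix, seq_along(s))
  names(s) <- sub("\\s.*$", "", names(s))
  toupper(s)
}

#' Average amino-acid identity (AAI) between two proteomes
#'
#' Computes bidirectional best-hit protein pairs between two proteomes with
#' the seeded local aligner, then summarizes the percent identity of the
#' retained pairs. A hit pair is retained only if it passes three filters:
#' identity at least `min_identity`, the alignment covers at least
#' `min_subject_cov` of the subject protein's length, and the alignment is
#' at least `min_aln_len` columns long.
#'
#' "Similarity" in the first filter is implemented as percent identity,
#' the only reproducible reading without a fixed similarity grouping.
#'
#' @param proteome_a,proteome_b `AAStringSet` or named character vectors of
#'   protein sequences.
#' @param min_identity identity filter, fraction (default 0.30).
#' @param min_subject_cov minimum alignable fraction of the subject protein
#'   (default 0.70).
#' @param min_aln_len minimum alignment length in residues (default 100).
#' @param matrix protein substitution matrix (default BLOSUM62).
#' @param gap linear gap penalty (negative integer).
#' @param k,band,max_occ seeding parameters, see [local_align()].
#' @return A [relatedness_result()] with `metric = "AAI"`. Undefined (not an
#'   error) when no pair survives the filters.
#' @export
pairwise_aai <- function(proteome_a, proteome_b,
                         min_identity = 0.30, min_subject_cov = 0.70,
                         min_aln_len = 100L, matrix = NULL, gap = -8L,
                         k = 4L, band = 40L, max_occ = 64L) {
  if (length(proteome_a) == 0 || length(proteome_b) == 0)
    stop("both proteomes must be non-empty")
  A <- .seqs_as_named_char(proteome_a, "pA_")
  B <- .seqs_as_named_char(proteome_b, "pB_")
  S <- .protein_score_matrix(matrix)
  nA <- length(A); nB <- length(B)
  score <- idmat <- cols <- scov <- matrix(0, nA, nB)
  for (j in seq_len(nB)) {
    # force the seeded path: unrelated pairs share no seed and exit cheaply
    h <- .align_many_cpp(unname(A), B[[j]], .AA_ALPHABET, S, as.integer(gap),
                         as.integer(k), as.integer(band), 0, as.integer(max_occ))
    score[, j] <- h[, "score"]
    cols[, j] <- h[, "columns"]
    idmat[, j] <- ifelse(h[, "columns"] > 0, h[, "matches"] / h[, "columns"], 0)
    scov[, j] <- (h[, "send"] - h[, "sstart"]) / nchar(B[[j]])
  }
  # bidirectional best hits on the (symmetric-scoring) score matrix;
  # ties broken toward the lexicographically smaller partner id
  ordB <- order(names(B)); ordA <- order(names(A))
  best_b_of_a <- apply(score[, ordB, drop = FALSE], 1,
                       function(r) if (max(r) > 0) ordB[which.max(r)] else NA_integer_)
  best_a_of_b <- apply(score[ordA, , drop = FALSE], 2,
                       function(r) if (max(r) > 0) ordA[which.max(r)] else NA_integer_)
  keep_id <- numeric(0)
  for (i in seq_len(nA)) {
    j <- best_b_of_a[i]
    if (!is.na(j) && !is.na(best_a_of_b[j]) && best_a_of_b[j] == i &&
        idmat[i, j] >= min_identity && scov[i, j] >= min_subject_cov &&
        cols[i, j] >= min_aln_len) {
      keep_id <- c(keep_id, idmat[i, j])
    }
  }
  relatedness_result("AAI", keep_id, min_n = 1L,
                     params = list(min_identity = min_identity,
                                   min_subject_cov = min_subject_cov,
                                   min_aln_len = min_aln_len, gap = gap))
}

#' Average nucleotide identity (ANI) between two genomes
#'
#' Fragment-based ANI: the first genome is cut into windows of `window`
#' bases advanced by `step`; each fragment is locally aligned to the second
#' genome (both strands; the better-scoring strand is kept). A fragment is
#' retained when its alignment is at least `min_frag_len` columns long, its
#' identity is at least `min_identity`, and at least `min_frag_cov` of the
#' fragment is alignable. ANI is the mean (and sd) of retained fragment
#' identities; the result is undefined when fewer than `min_aln_n`
#' fragments are retained.
#'
#' @param genome_a,genome_b `DNAStringSet`/`DNAString` or character vectors
#'   (multiple contigs are concatenated with `N` spacers for the subject).
#' @param window fragment window length in bp (default 1000).
#' @param step fragment step size in bp (default 200).
#' @param min_frag_len minimum alignment length for a retained fragment
#'   (default 700 bp).
#' @param min_identity minimum fragment identity (default 0.70).
#' @param min_frag_cov minimum alignable fraction of the fragment
#'   (default 0.70).
#' @param min_aln_n minimum retained fragment count for a defined result
#'   (default 50).
#' @param match,mismatch,gap DNA scoring parameters.
#' @param k,band,max_occ seeding parameters, see [local_align()].
#' @return A [relatedness_result()] with `metric = "ANI"`.
#' @export
pairwise_ani <- function(genome_a, genome_b, window = 1000L, step = 200L,
                         min_frag_len = 700L, min_identity = 0.70,
                         min_frag_cov = 0.70, min_aln_n = 50L,
                         match = 1L, mismatch = -1L, gap = -3L,
                         k = 13L, band = 32L, max_occ = 64L) {
  a <- paste(toupper(.as_char_seq(genome_a)), collapse = strrep("N", 50))
  b <- paste(toupper(.as_char_seq(genome_b)), collapse = strrep("N", 50))
  if (nchar(a) == 0 || nchar(b) == 0) stop("both genomes must be non-empty")
  starts <- seq(1L, max(1L, nchar(a) - window + 1L), by = step)
  frags <- substring(a, starts, pmin(starts + window - 1L, nchar(a)))
  frags <- frags[nchar(frags) >= min_frag_len]
  if (length(frags) == 0) stop("genome_a yields no fragments of usable length")
  S <- .dna_score_matrix(match, mismatch)
  eval_hits <- function(h, flen) {
    id <- ifelse(h[, "columns"] > 0, h[, "matches"] / h[, "columns"], 0)
    cov <- (h[, "qend"] - h[, "qstart"]) / flen
    list(id = id, ok = h[, "columns"] >= min_frag_len & id >= min_identity &
           cov >= min_frag_cov, score = h[, "score"])
  }
  hf <- .align_many_cpp(frags, b, .DNA_ALPHABET, S, as.integer(gap),
                        as.integer(k), as.integer(band), 0, as.integer(max_occ))
  res <- eval_hits(hf, nchar(frags))
  retry <- which(!res$ok)
  if (length(retry) > 0) {
    rc <- vapply(frags[retry], revcomp, character(1), USE.NAMES = FALSE)
    hr <- .align_many_cpp(rc, b, .DNA_ALPHABET, S, as.integer(gap),
                          as.integer(k), as.integer(band), 0, as.integer(max_occ))
    rres <- eval_hits(hr, nchar(rc))
    better <- rres$score > res$score[retry]
    res$id[retry][better] <- rres$id[better]
    res$ok[retry][better] <- rres$ok[better]
  }
  relatedness_result("ANI", res$id[res$ok], min_n = min_aln_n,
                     params = list(window = window, step = step,
                                   min_frag_len = min_frag_len,
                                   min_identity = min_identity,
                                   min_frag_cov = min_frag_cov,
                                   min_aln_n = min_aln_n))
}

#' 16S rRNA gene identity between two sequences
#'
#' Percent identity (matches / alignment columns) over the optimal *global*
#' alignment of the two genes. Local alignment would be misleading here:
#' between unrelated genes it collapses onto a short perfect island and
#' reports spuriously high identity, while an occurrence threshold like
#' 97% is meant for full-length gene comparisons. Sequences shorter than
#' 200 bases trigger a warning (short fragments give unstable identities)
#' but are still compared.
#'
#' @param a,b nucleotide sequences (character or `XString`).
#' @param match,mismatch,gap alignment scoring parameters.
#' @return Identity as a percentage (scalar).
#' @export
rrna_identity <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  a <- toupper(.as_char_seq(a)); b <- toupper(.as_char_seq(b))
  if (nchar(a) < 200 || nchar(b) < 200)
    warning("sequence shorter than 200 bases; identity may be unstable")
  .check_alphabet(a, "dna"); .check_alphabet(b, "dna")
  hit <- .global_align_cpp(a, b, .DNA_ALPHABET,
                           .dna_score_matrix(match, mismatch),
                           as.integer(gap))
  if (hit$columns == 0) return(0)
  100 * hit$matches / hit$columns
}
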