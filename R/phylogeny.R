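#' The 18 concatenation marker genes
#'
#' Five universal (pheT, rplE, rplO, rpsK, rpsM) and thirteen
#' bacterial-specific single-copy housekeeping genes used for the
#' concatenated marker phylogeny.
#'
#' @format Character vector of 18 gene symbols.
#' @export
MARKER_GENES_18 <- c("pheT", "rplE", "rplO", "rpsK", "rpsM",
                     "clpX", "leuS", "ligA", "murD", "pnp", "pth", "pyrG",
                     "rplL", "rpoA", "rpoB", "rpoC", "secY", "serS")

#' Curate reference genomes by marker-gene count
#'
#' A reference genome is retained when it carries at least `min_genes` of
#' the `total` marker genes, or when it is explicitly whitelisted (the
#' escape hatch for a taxon one wants despite missing genes).
#'
#' @param marker_tables named list: genome -> character vector of marker
#'   genes present; or a long data frame with `genome` and `gene` columns.
#' @param min_genes retention threshold (default 16).
#' @param total total marker genes in the scheme (default 18).
#' @param whitelist genome labels retained regardless of count.
#' @return Character vector of retained genome labels.
#' @export
curate_references <- function(marker_tables, min_genes = 16L, total = 18L,
                              whitelist = character()) {
  if (total < min_genes) stop("total must be >= min_genes")
  if (is.data.frame(marker_tables))
    marker_tables <- split(marker_tables$gene, marker_tables$genome)
  counts <- vapply(marker_tables, function(g) length(unique(g)), integer(1))
  names(counts)[counts >= min_genes | names(counts) %in% whitelist]
}

#' @noRd
.aln_as_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  s <- .as_char_seq(aln)
  w <- unique(nchar(s))
  if (length(w) != 1)
    stop("aligned rows have unequal lengths")
  m <- do.call(rbind, strsplit(s, ""))
  rownames(m) <- names(s)
  m
}

#' Confidence weights for alignment columns
#'
#' A simple internal stand-in for external column-confidence tools: the
#' weight of a column is (fraction of non-gap rows) times (frequency of
#' the modal residue among non-gap rows), so gappy and ambiguously aligned
#' columns are down-weighted. All-gap columns get weight 0.
#'
#' @param aln an aligned gene: `AAStringSet`, named character vector of
#'   equal-length strings, or character matrix.
#' @return Numeric vector of per-column weights in `[0, 1]`.
#' @export
column_weights <- function(aln) {
  m <- .aln_as_matrix(aln)
  if (nrow(m) < 2) stop("at least 2 aligned rows are required")
  apply(m, 2, function(col) {
    res <- col[col != "-"]
    if (length(res) == 0) return(0)
    (length(res) / length(col)) * (max(table(res)) / length(res))
  })
}

#' Concatenate per-gene alignments into a partitioned supermatrix
#'
#' Genes are concatenated in lexicographic order of their labels; taxa
#' missing a gene are filled with gap characters across that partition.
#' Column confidence weights are taken from `weights` or computed with
#' [column_weights()]. Informative positions are columns with at least two
#' distinct non-gap states.
#'
#' @param per_gene_alignments named list: gene -> aligned sequences
#'   (`AAStringSet` or named character vector; rows within a gene must
#'   have equal lengths).
#' @param weights optional named list: gene -> per-column weights.
#' @return An object of class `concat_alignment`: `taxa`, `matrix`
#'   (character matrix, rows = taxa), `partitions` (tibble: `gene`,
#'   `start`, `end`, 0-based half-open), `weights` (per column),
#'   `informative` (count).
#' @export
concatenate_partitions <- function(per_gene_alignments, weights = NULL) {
  genes <- sort(names(per_gene_alignments))
  mats <- lapply(per_gene_alignments[genes], .aln_as_matrix)
  taxa <- sort(unique(unlist(lapply(mats, rownames))))
  if (is.null(taxa)) stop("alignments must carry taxon names")
  widths <- vapply(mats, ncol, integer(1))
  total <- sum(widths)
  M <- matrix("-", length(taxa), total, dimnames = list(taxa, NULL))
  wvec <- numeric(total)
  off <- 0L
  parts <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]; m <- mats[[i]]; w <- unname(widths[i])
    M[rownames(m), off + seq_len(w)] <- m
    gw <- if (!is.null(weights) && !is.null(weights[[g]])) weights[[g]] else
      column_weights(m)
    if (length(gw) != w) stop("weights length mismatch for gene ", g)
    wvec[off + seq_len(w)] <- gw
    parts[[i]] <- tibble::tibble(gene = g, start = off, end = off + w)
    off <- off + w
  }
  informative <- sum(apply(M, 2, function(col) {
    length(unique(col[col != "-"])) >= 2
  }))
  structure(list(taxa = taxa, matrix = M,
                 partitions = do.call(rbind, parts),
                 weights = wvec, informative = informative),
            class = "concat_alignment")
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat(sprintf("<concat_alignment> %d taxa, %d columns (%d informative), %d partitions\n",
              length(x$taxa), ncol(x$matrix), x$informative,
              nrow(x$partitions)))
  invisible(x)
}

#' Corrected pairwise distances from a concatenated alignment
#'
#' For each taxon pair, the (optionally weighted) proportion of differing
#' states p is computed over columns where both taxa are non-gap, then
#' corrected for multiple hits with the Poisson/Jukes-Cantor style formula
#' d = -((s-1)/s) ln(1 - s p / (s-1)), with s = 20 for amino acids and
#' s = 4 for nucleotides. Saturated pairs (p >= (s-1)/s) are capped at
#' `max_dist`.
#'
#' @param aln a `concat_alignment` (or a bare character matrix).
#' @param use_weights use the alignment's column weights (default TRUE).
#' @param alphabet_size 20 (protein, default) or 4 (nucleotide,
#'   Jukes-Cantor).
#' @param max_dist cap for saturated pairs (default 10).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
protein_distance_matrix <- function(aln, use_weights = TRUE,
                                    alphabet_size = 20, max_dist = 10) {
  M <- if (inherits(aln, "concat_alignment")) aln$matrix else
    .aln_as_matrix(aln)
  w <- if (inherits(aln, "concat_alignment") && use_weights) aln$weights else
    rep(1, ncol(M))
  n <- nrow(M)
  if (n < 2) stop("at least 2 taxa are required")
  s <- alphabet_size
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- M[i, ] != "-" & M[j, ] != "-"
      if (!any(ok) || sum(w[ok]) == 0)
        stop("taxa ", rownames(M)[i], " and ", rownames(M)[j],
             " share no comparable columns")
      p <- sum(w[ok] * (M[i, ok] != M[j, ok])) / sum(w[ok])
      d <- if (p >= (s - 1) / s) max_dist else
        -((s - 1) / s) * log(1 - s * p / (s - 1))
      D[i, j] <- D[j, i] <- min(d, max_dist)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}) with negative branch lengths
#' clamped at zero and taxa pre-sorted lexicographically so that the input
#' order never changes the result. Three taxa get the closed-form
#' three-point solution.
#'
#' @param distances symmetric distance matrix with labelled rows.
#' @return An `ape::phylo` tree (unrooted).
#' @export
nj_tree <- function(distances) {
  D <- as.matrix(distances)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distances must be symmetric")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  ord <- order(rownames(D))
  D <- D[ord, ord]
  n <- nrow(D)
  if (n < 3) stop("at least 3 taxa are required")
  if (n == 3) {
    l <- rownames(D)
    x <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    y <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    z <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f,%s:%f);",
                                        l[1], max(x, 0), l[2], max(y, 0),
                                        l[3], max(z, 0)))
    return(tr)
  }
  tr <- ape::nj(D)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Bootstrap support for a concatenated-alignment NJ tree
#'
#' Columns are resampled with replacement within each partition (gene);
#' each replicate is run through [protein_distance_matrix()] and
#' [nj_tree()], and the support of each internal edge of the original tree
#' is the percentage of replicates whose tree contains the same
#' bipartition.
#'
#' @param aln a `concat_alignment`.
#' @param n_reps number of bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param use_weights carry column weights with the resampled columns
#'   (default TRUE).
#' @param alphabet_size 20 (protein) or 4 (nucleotide).
#' @return A list with `tree` (the original-data tree, `node.label` set to
#'   supports) and `support` (tibble: internal `node`, `support` percent).
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L,
                              use_weights = TRUE, alphabet_size = 20) {
  stopifnot(inherits(aln, "concat_alignment"), n_reps >= 1)
  base_tree <- nj_tree(protein_distance_matrix(aln, use_weights,
                                               alphabet_size))
  part_cols <- lapply(seq_len(nrow(aln$partitions)), function(i)
    (aln$partitions$start[i] + 1L):aln$partitions$end[i])
  boot <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_reps), function(r) {
      cols <- unlist(lapply(part_cols, function(pc)
        sample(pc, length(pc), replace = TRUE)))
      rep_aln <- structure(list(taxa = aln$taxa,
                                matrix = aln$matrix[, cols, drop = FALSE],
                                partitions = aln$partitions,
                                weights = aln$weights[cols],
                                informative = NA_integer_),
                           class = "concat_alignment")
      nj_tree(protein_distance_matrix(rep_aln, use_weights, alphabet_size))
    })
  })
  counts <- ape::prop.clades(base_tree, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_reps
  base_tree$node.label <- formatC(support, format = "f", digits = 0)
  list(tree = base_tree,
       support = tibble::tibble(
         node = length(base_tree$tip.label) + seq_along(support),
         support = support))
}

#' Define a conserved signature indel (CSI)
#'
#' A CSI is located by two flanking motifs in the ungapped protein
#' sequence; the signature's `ref_span` is the residue count strictly
#' between the flanks in the reference state, so a scanned taxon's indel
#' length is its own between-flank residue count minus `ref_span`.
#'
#' @param gene gene label the signature lives in.
#' @param left,right flanking motifs (non-empty, exact residue strings).
#' @param ref_span reference residue count between the flanks (default 0).
#' @return An object of class `csi_signature`.
#' @export
csi_signature <- function(gene, left, right, ref_span = 0L) {
  if (nchar(left) == 0 || nchar(right) == 0)
    stop("flank motifs must be non-empty")
  structure(list(gene = gene, left = left, right = right,
                 ref_span = as.integer(ref_span)), class = "csi_signature")
}

#' Scan an alignment for a conserved signature indel
#'
#' For each taxon row, the gapless sequence is searched for the left and
#' right flank motifs; the indel length is the number of residues strictly
#' between them minus the signature's reference span. A missing flank
#' gives status `NOT_FOUND`; a flank matching more than once is an
#' ambiguity error.
#'
#' @param aln aligned gene (`AAStringSet` or named character vector).
#' @param signature a [csi_signature()].
#' @return Tibble with `taxon`, `status` (`"found"` / `"NOT_FOUND"`),
#'   `indel_length` (NA when not found).
#' @export
csi_scan <- function(aln, signature) {
  stopifnot(inherits(signature, "csi_signature"))
  s <- .as_char_seq(aln)
  if (is.null(names(s))) stop("alignment rows must carry taxon names")
  rows <- lapply(names(s), function(tx) {
    seq <- gsub("-", "", s[[tx]], fixed = TRUE)
    lpos <- gregexpr(signature$left, seq, fixed = TRUE)[[1]]
    rpos <- gregexpr(signature$right, seq, fixed = TRUE)[[1]]
    lhit <- lpos[lpos > 0]; rhit <- rpos[rpos > 0]
    if (length(lhit) > 1 || length(rhit) > 1)
      stop("flank matches more than once in taxon ", tx,
           "; signature is ambiguous")
    if (length(lhit) == 0 || length(rhit) == 0)
      return(tibble::tibble(taxon = tx, status = "NOT_FOUND",
                            indel_length = NA_integer_))
    between <- rhit - (lhit + nchar(signature$left))
    if (between < 0)
      return(tibble::tibble(taxon = tx, status = "NOT_FOUND",
                            indel_length = NA_integer_))
    tibble::tibble(taxon = tx, status = "found",
                   indel_length = as.integer(between - signature$ref_span))
  })
  do.call(rbind, rows)
}
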