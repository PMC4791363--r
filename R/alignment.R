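.DNA_ALPHABET <- "ACGT"
.AA_ALPHABET <- "ARNDCQEGHILKMFPSTWYVBZX"

#' @noRd
.dna_score_matrix <- function(match, mismatch) {
  n <- nchar(.DNA_ALPHABET) + 1L # extra row/column for unknown characters
  S <- matrix(as.integer(mismatch), n, n)
  diag(S)[seq_len(n - 1L)] <- as.integer(match)
  S[n, n] <- as.integer(mismatch) # N never matches N
  S
}

#' @noRd
.protein_score_matrix <- function(matrix = NULL) {
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  letters <- strsplit(.AA_ALPHABET, "")[[1]]
  stopifnot(all(letters %in% rownames(matrix)))
  S0 <- matrix[letters, letters]
  n <- length(letters) + 1L
  S <- matrix(as.integer(min(S0)), n, n)
  S[seq_len(n - 1L), seq_len(n - 1L)] <- as.integer(S0)
  S
}

#' @noRd
.check_alphabet <- function(seq, type) {
  ok <- if (type == "dna") "ACGTNRYSWKMBDHVU-" else
    paste0(.AA_ALPHABET, "U O*.-")
  bad <- setdiff(unique(strsplit(toupper(seq), "")[[1]]), strsplit(ok, "")[[1]])
  if (length(bad) > 0)
    stop("sequence contains characters not in the ", type, " alphabet: ",
         paste(utils::head(bad, 5), collapse = ""), call. = FALSE)
  invisible(TRUE)
}

#' Optimal local alignment of two sequences
#'
#' A Smith-Waterman local aligner with linear gap costs, used throughout the
#' package as the stand-in for BLAST-style searches: read recruitment, ANI
#' fragments, AAI best hits and 16S identity all go through it. Below a DP
#' size cutoff the exact full dynamic program is run; above it, shared
#' k-mers seed a best-diagonal banded dynamic program.
#'
#' Tie-breaking is fixed (first maximal cell in row-major order; on equal
#' scores the diagonal move is preferred over a gap in the subject, which is
#' preferred over a gap in the query), so results are deterministic.
#'
#' @param a,b query and subject sequences: character scalars or
#'   `Biostrings` `XString` objects. Both must be the same alphabet.
#' @param type `"dna"` or `"protein"`.
#' @param match,mismatch integer match/mismatch scores (DNA only).
#' @param gap linear gap penalty per gap column (negative integer).
#' @param matrix optional protein substitution matrix (default BLOSUM62,
#'   rows/columns named by one-letter amino-acid codes).
#' @param method `"auto"` (exact DP below `full_cutoff` cells, seeded
#'   above), `"full"`, or `"seeded"`.
#' @param k seed word size (default 11 for DNA, 4 for protein).
#' @param band half-width, in diagonals, of the banded extension.
#' @param full_cutoff DP-cell count below which `"auto"` runs the exact DP.
#' @param max_occ k-mers occurring more often than this in the subject are
#'   skipped when seeding (repeat masking).
#' @return An object of class `alignment_hit`: a list with `score`,
#'   `columns`, `matches`, `identity` (= matches / columns), 0-based
#'   half-open spans `qstart`/`qend` and `sstart`/`send`, and the `method`
#'   used. A score of 0 with 0 columns means no local similarity was found.
#' @examples
#' local_align("ACGTACGT", "ACGTTCGT")
#' @export
local_align <- function(a, b, type = c("dna", "protein"),
                        match = 1L, mismatch = -1L, gap = -2L, matrix = NULL,
                        method = c("auto", "full", "seeded"),
                        k = NULL, band = 50L, full_cutoff = 4e6,
                        max_occ = 64L) {
  type <- match.arg(type)
  method <- match.arg(method)
  a <- toupper(.as_char_seq(a)); b <- toupper(.as_char_seq(b))
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  .check_alphabet(a, type); .check_alphabet(b, type)
  if (type == "dna") {
    S <- .dna_score_matrix(match, mismatch)
    alphabet <- .DNA_ALPHABET
    k <- k %||% 11L
  } else {
    S <- .protein_score_matrix(matrix)
    alphabet <- .AA_ALPHABET
    k <- k %||% 4L
  }
  hit <- .align_pair_cpp(a, b, alphabet, S, as.integer(gap), method,
                         as.integer(k), as.integer(band), full_cutoff,
                         as.integer(max_occ))
  structure(hit, class = "alignment_hit")
}

#' @export
print.alignment_hit <- function(x, ...) {
  cat(sprintf(
    "<alignment_hit> score %d, %d columns, %d matches (identity %.3f), %s\n",
    x$score, x$columns, x$matches,
    if (x$columns > 0) x$matches / x$columns else NA_real_, x$method))
  cat(sprintf("  query [%d,%d)  subject [%d,%d)\n",
              x$qstart, x$qend, x$sstart, x$send))
  invisible(x)
}

#' Reverse complement of a DNA string
#' @param seq character scalar.
#' @return The reverse complement, as a character scalar.
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
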