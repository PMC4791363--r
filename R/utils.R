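#' Derive a stage-specific seed from a master seed
#'
#' All generators in the package take an explicit integer seed. When a whole
#' pipeline is driven from one master seed, each stage derives its own seed
#' deterministically from the master seed and the stage name, so adding or
#' reordering stages never silently changes another stage's random stream.
#'
#' @param master integer master seed.
#' @param stage character stage name, e.g. `"reads"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' stage_seed(1, "reads")
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) %% 1000003L) * 2017L + h * 7919L) %% 2147483646L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.as_char_seq <- function(x) {
  if (inherits(x, "XString") || inherits(x, "XStringSet")) return(as.character(x))
  nms <- names(x)
  out <- as.character(x)
  names(out) <- nms
  out
}

#' Write sequences to FASTA with coverage encoded in the description
#'
#' Contig coverage travels with the sequence as a `cov=<float>` token in the
#' FASTA description line, so contig sets round-trip through plain FASTA.
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output file path.
#' @param coverage optional numeric coverage per sequence (recycled names).
#' @return `path`, invisibly.
#' @export
write_fasta_cov <- function(seqs, path, coverage = NULL) {
  s <- Biostrings::DNAStringSet(.as_char_seq(seqs))
  nm <- names(seqs) %||% paste0("seq", seq_along(s))
  if (!is.null(coverage)) nm <- paste0(nm, " cov=", format(coverage, trim = TRUE))
  names(s) <- nm
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Read a contig FASTA, parsing coverage from the description line
#'
#' @param path FASTA file path.
#' @return A tibble with columns `contig_id`, `sequence`, `length`,
#'   `coverage` (`NA` when no `cov=` token is present).
#' @export
read_fasta_cov <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  full <- names(s)
  id <- sub("\\s.*$", "", full)
  cov <- suppressWarnings(as.numeric(sub(".*cov=([0-9eE.+-]+).*", "\\1", full)))
  cov[!grepl("cov=", full)] <- NA_real_
  tibble::tibble(contig_id = id, sequence = as.character(s),
                 length = Biostrings::width(s), coverage = cov)
}
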