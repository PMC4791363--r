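#' Construct a marker catalog
#'
#' A catalog is a named set of single-copy marker genes against which a
#' genome bin's annotation table is scored. Presence is binary per marker:
#' one annotated gene, even a partial fragment, counts.
#'
#' @param name catalog label.
#' @param markers character vector of marker labels (non-empty, unique).
#' @param mode `"at-least-one-partial"` (default) — any gene, partial or
#'   complete, establishes presence — or `"exhaustive"`.
#' @return An object of class `marker_catalog`.
#' @export
marker_catalog <- function(name, markers,
                           mode = c("at-least-one-partial", "exhaustive")) {
  mode <- match.arg(mode)
  markers <- unique(as.character(markers))
  if (length(markers) == 0) stop("a catalog must contain at least one marker")
  structure(list(name = name, markers = markers, mode = mode),
            class = "marker_catalog")
}

#' @export
print.marker_catalog <- function(x, ...) {
  cat(sprintf("<marker_catalog> %s: %d markers (%s)\n",
              x$name, length(x$markers), x$mode))
  invisible(x)
}

#' Default marker catalogs for completeness estimation
#'
#' Three single-copy catalogs of the conventional sizes — 21 tRNA
#' synthetase genes, 40 universal prokaryotic markers, 178 conserved
#' bacterial housekeeping genes. The 21 tRNA synthetase labels are real
#' gene symbols; the other two lists are editable placeholders shipped as
#' TSV resources (`inst/extdata/markers_*.tsv`): the published catalog
#' contents live in external references, so for real data supply your own
#' lists. The completeness computation is independent of the labels.
#'
#' @return Named list of three [marker_catalog()] objects:
#'   `trna21`, `univ40`, `bact178`.
#' @export
default_marker_catalogs <- function() {
  rd <- function(f) utils::read.delim(
    system.file("extdata", f, package = "thermopop"))$marker
  list(
    trna21 = marker_catalog("trna21", rd("markers_trna_synthetase_21.tsv")),
    univ40 = marker_catalog("univ40", rd("markers_universal_40.tsv")),
    bact178 = marker_catalog("bact178", rd("markers_bacterial_178.tsv")))
}

#' Fraction of a marker catalog detected in an annotation table
#'
#' A catalog marker counts as present when at least one annotated gene
#' (possibly flagged partial) carries its label. Annotation rows whose
#' marker label is not in the catalog are ignored.
#'
#' @param annotations data frame with a `marker` column (NA for
#'   non-marker genes); an optional logical `partial` column is accepted
#'   and does not affect presence.
#' @param catalog a [marker_catalog()].
#' @return Fraction in `[0, 1]`.
#' @export
marker_fraction <- function(annotations, catalog) {
  stopifnot(inherits(catalog, "marker_catalog"))
  if (is.null(annotations) || nrow(annotations) == 0) return(0)
  seen <- unique(stats::na.omit(annotations$marker))
  length(intersect(seen, catalog$markers)) / length(catalog$markers)
}

#' Assembly statistics for a genome bin
#'
#' @param contigs tibble with a `sequence` column (and optionally
#'   `contig_id`), or a `DNAStringSet` / character vector.
#' @param annotations optional annotation data frame; rows with
#'   `type == "coding"` are counted as coding genes.
#' @return List with `size_mbp`, `gc_pct`, `n_contigs`, `longest_kbp`,
#'   `coding_genes` (NA without annotations).
#' @export
assembly_stats <- function(contigs, annotations = NULL) {
  seqs <- if (is.data.frame(contigs)) contigs$sequence else
    .as_char_seq(contigs)
  if (length(seqs) == 0) stop("the bin must contain at least one contig")
  lens <- nchar(seqs)
  list(size_mbp = sum(lens) / 1e6,
       gc_pct = 100 * gc_content(paste(seqs, collapse = "")),
       n_contigs = length(seqs),
       longest_kbp = max(lens) / 1e3,
       coding_genes = if (is.null(annotations)) NA_integer_ else
         sum(annotations$type == "coding", na.rm = TRUE))
}

#' Three-catalog completeness report for a genome bin
#'
#' Scores the bin's annotations against exactly three marker catalogs and
#' reports each catalog fraction together with their unweighted arithmetic
#' mean as a percentage, plus assembly statistics. Annotation rows whose
#' marker label appears in none of the three catalogs trigger a single
#' warning and are ignored.
#'
#' @param contigs bin contigs (see [assembly_stats()]).
#' @param annotations annotation data frame with `marker` (and optionally
#'   `type`, `partial`) columns.
#' @param catalogs list of exactly three [marker_catalog()] objects
#'   (default [default_marker_catalogs()]).
#' @return An object of class `completeness_report`: `fractions` (named,
#'   per catalog), `mean_pct`, `stats`.
#' @export
completeness_report <- function(contigs, annotations,
                                catalogs = default_marker_catalogs()) {
  if (length(catalogs) != 3)
    stop("exactly three marker catalogs are required")
  all_markers <- unique(unlist(lapply(catalogs, `[[`, "markers")))
  seen <- unique(stats::na.omit(annotations$marker))
  unknown <- setdiff(seen, all_markers)
  if (length(unknown) > 0)
    warning(length(unknown), " annotated marker label(s) not in any catalog",
            " were ignored (e.g. ", unknown[1], ")")
  fr <- vapply(catalogs, function(cat) marker_fraction(annotations, cat),
               numeric(1))
  names(fr) <- vapply(catalogs, `[[`, character(1), "name")
  structure(list(fractions = fr, mean_pct = 100 * mean(fr),
                 stats = assembly_stats(contigs, annotations)),
            class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat("<completeness_report>\n")
  for (nm in names(x$fractions))
    cat(sprintf("  %-10s %.1f%%\n", nm, 100 * x$fractions[[nm]]))
  cat(sprintf("  mean       %.1f%%\n", x$mean_pct))
  cat(sprintf("  assembly: %.2f Mbp, G+C %.1f%%, %d contigs, longest %.1f kbp\n",
              x$stats$size_mbp, x$stats$gc_pct, x$stats$n_contigs,
              x$stats$longest_kbp))
  invisible(x)
}
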