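#' COG presence/absence matrix across genomes
#'
#' Columns are the sorted union of COG labels observed in any genome; an
#' entry is 1 when the genome carries at least one gene with that COG.
#'
#' @param annotations named list: genome -> character vector of COG labels;
#'   or a long data frame with `genome` and `cog` columns.
#' @return Binary integer matrix, genomes x COGs (rows sorted by genome
#'   label). A genome with no annotations gives an all-zero row with a
#'   warning.
#' @export
cog_matrix <- function(annotations) {
  if (is.data.frame(annotations)) {
    genomes <- sort(unique(annotations$genome))
    annotations <- lapply(stats::setNames(genomes, genomes), function(g)
      annotations$cog[annotations$genome == g])
  }
  if (length(annotations) < 2) stop("at least 2 genomes are required")
  if (anyDuplicated(names(annotations)))
    stop("duplicate genome labels")
  empty <- names(annotations)[lengths(annotations) == 0]
  if (length(empty) > 0)
    warning("genome(s) with no COG annotations: ",
            paste(empty, collapse = ", "))
  cogs <- sort(unique(unlist(annotations)))
  genomes <- sort(names(annotations))
  M <- matrix(0L, length(genomes), length(cogs),
              dimnames = list(genomes, cogs))
  for (g in genomes) M[g, unique(annotations[[g]])] <- 1L
  M
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS (global monotone regression) minimized by
#' iterative majorization, run from one classical metric-scaling start plus
#' `n_restarts` seeded random starts; the lowest-stress configuration is
#' returned. Deterministic given `seed`.
#'
#' Ties are treated as *secondary* by default: tied dissimilarities must
#' receive equal fitted distances. Under the primary (weak) treatment a
#' fully tied matrix — e.g. four mutually equidistant genomes — has stress
#' identically zero, which hides exactly the non-embeddable structure the
#' stress is meant to flag; `ties = "primary"` is still available.
#'
#' @param dist symmetric distance matrix (or `dist`) with zero diagonal.
#' @param dims embedding dimension (default 2).
#' @param n_restarts random restarts in addition to the metric start
#'   (default 20).
#' @param seed integer seed.
#' @param ties `"secondary"` (default) or `"primary"` treatment of tied
#'   dissimilarities.
#' @return An object of class `ordination_result`: `points` (n x dims),
#'   `stress` (Kruskal stress-1, in `[0, 1]`), `n_restarts`, `seed`,
#'   `dims`.
#' @export
nmds <- function(dist, dims = 2L, n_restarts = 20L, seed = 1L,
                 ties = c("secondary", "primary")) {
  ties <- match.arg(ties)
  D <- as.matrix(dist)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distances must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distances must have a zero diagonal")
  n <- nrow(D)
  if (n < dims + 2) stop("need at least dims + 2 points")
  d <- stats::as.dist(D)
  run1 <- function(y) vegan::monoMDS(d, y = y, k = dims, model = "global",
                                     weakties = (ties == "primary"),
                                     maxit = 1000, smin = 1e-12,
                                     sfgrmin = 1e-12, sratmax = 1 - 1e-9)
  best <- withr::with_seed(as.integer(seed), {
    y0 <- stats::cmdscale(d, k = dims)
    if (ncol(y0) < dims)
      y0 <- cbind(y0, matrix(0, n, dims - ncol(y0)))
    fit <- run1(y0)
    for (r in seq_len(n_restarts)) {
      cand <- run1(matrix(stats::rnorm(n * dims), n, dims))
      if (cand$stress < fit$stress) fit <- cand
    }
    fit
  })
  pts <- best$points
  rownames(pts) <- rownames(D)
  structure(list(points = pts, stress = best$stress,
                 n_restarts = n_restarts, seed = seed, dims = dims,
                 ties = ties), class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %d points in %d dims, stress %.4g (%d restarts, seed %d)\n",
              nrow(x$points), x$dims, x$stress, x$n_restarts, x$seed))
  invisible(x)
}

#' Define a metabolic pathway by its required gene set
#'
#' @param name pathway label.
#' @param genes character vector of required gene symbols (non-empty).
#' @return An object of class `pathway_definition`.
#' @export
pathway_definition <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop("a pathway needs at least one required gene")
  structure(list(name = name, genes = genes), class = "pathway_definition")
}

#' Bundled example pathway definitions
#'
#' Editable TSV resource (`inst/extdata/pathways.tsv`) with gene lists for
#' a few example pathways (glycolysis, oxidative TCA cycle, cobalamin
#' synthesis). Detection is annotation-table lookup by gene symbol; for
#' real data supply definitions matched to your annotation vocabulary.
#'
#' @param path TSV file with `pathway` and `gene` columns (default: the
#'   bundled resource).
#' @return Named list of [pathway_definition()] objects.
#' @export
read_pathway_definitions <- function(path = system.file("extdata",
                                                        "pathways.tsv",
                                                        package = "thermopop")) {
  df <- utils::read.delim(path)
  sp <- split(df$gene, df$pathway)
  lapply(stats::setNames(names(sp), names(sp)), function(nm)
    pathway_definition(nm, sp[[nm]]))
}

#' Fraction of a pathway's required genes present
#'
#' @param genes_present character vector of gene symbols annotated in a
#'   genome.
#' @param pathway a [pathway_definition()].
#' @return Fraction in `[0, 1]`.
#' @export
pathway_completeness <- function(genes_present, pathway) {
  stopifnot(inherits(pathway, "pathway_definition"))
  length(intersect(unique(genes_present), pathway$genes)) /
    length(pathway$genes)
}
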