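#' Call phylotype occurrence across survey sites
#'
#' For each site, the best 16S identity between the phylotype reference
#' gene and the site's sequence pool is computed with [rrna_identity()];
#' the call is positive only when the best identity *strictly exceeds* the
#' threshold (so exactly 97.0% against a 97 threshold is negative). An
#' empty pool gives a negative call with `NA` identity.
#'
#' @param reference phylotype 16S reference gene (character or `XString`,
#'   at least 200 bases).
#' @param pools named list: site id -> character vector of pool sequences
#'   (e.g. the `pools` element of [simulate_survey()] output).
#' @param threshold occurrence threshold in percent (default 97).
#' @param phylotype label recorded in the output (default `"phylotype"`).
#' @return Tibble with `site_id`, `phylotype`, `best_identity` (percent)
#'   and `positive` (logical).
#' @export
occurrence_call <- function(reference, pools, threshold = 97,
                            phylotype = "phylotype") {
  ref <- .as_char_seq(reference)
  if (nchar(ref) < 200) stop("reference must be at least 200 bases")
  rows <- lapply(names(pools), function(sid) {
    pool <- pools[[sid]]
    if (length(pool) == 0)
      return(tibble::tibble(site_id = sid, phylotype = phylotype,
                            best_identity = NA_real_, positive = FALSE))
    ids <- vapply(pool, function(s)
      suppressWarnings(rrna_identity(ref, s)), numeric(1), USE.NAMES = FALSE)
    best <- max(ids)
    tibble::tibble(site_id = sid, phylotype = phylotype,
                   best_identity = best, positive = best > threshold)
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic and chi-squared p-value (via
#' `stats::kruskal.test`), with an optional exact permutation p-value that
#' enumerates all distinct assignments of the pooled observations to the
#' group sizes (feasible for small samples; falls back to Monte Carlo with
#' a warning when the enumeration would exceed `max_enum` assignments).
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   non-empty, total n >= 3).
#' @param exact also compute the permutation p-value (default FALSE).
#' @param max_enum enumeration cap on the multinomial assignment count
#'   (default 2e5).
#' @param n_mc Monte Carlo permutations when enumeration is infeasible.
#' @param seed seed for the Monte Carlo fallback.
#' @return An object of class `rank_test_result`: `H`, `df`, `p_value`,
#'   `tie_corrected`, and (when `exact`) `p_exact` and `exact_method`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE, max_enum = 2e5,
                           n_mc = 1e4, seed = 1L) {
  if (length(groups) < 2) stop("at least 2 groups are required")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("total sample size must be >= 3")
  g <- factor(rep(seq_along(groups), sizes))
  kt <- stats::kruskal.test(x, g)
  out <- list(H = unname(kt$statistic), df = unname(kt$parameter),
              p_value = kt$p.value,
              tie_corrected = anyDuplicated(x) > 0)
  if (exact) {
    r <- rank(x)
    N <- length(x)
    ties <- table(r)
    tiecor <- 1 - sum(ties^3 - ties) / (N^3 - N)
    h_of <- function(assign) {
      sums <- vapply(split(r, factor(assign, levels = seq_along(sizes))),
                     sum, numeric(1))
      (12 / (N * (N + 1)) * sum(sums^2 / sizes) - 3 * (N + 1)) / tiecor
    }
    n_assign <- exp(lgamma(N + 1) - sum(lgamma(sizes + 1)))
    if (n_assign <= max_enum) {
      perms <- .enumerate_assignments(N, sizes)
      hs <- vapply(perms, h_of, numeric(1))
      out$p_exact <- mean(hs >= out$H - 1e-10)
      out$exact_method <- "enumeration"
    } else {
      warning("assignment count ", format(n_assign, digits = 3),
              " exceeds max_enum; using ", n_mc, " Monte Carlo permutations")
      hs <- withr::with_seed(as.integer(seed), {
        vapply(seq_len(n_mc), function(i) h_of(g[sample.int(N)]), numeric(1))
      })
      out$p_exact <- mean(hs >= out$H - 1e-10)
      out$exact_method <- "monte-carlo"
    }
  }
  structure(out, class = "rank_test_result")
}

# all distinct assignments of N positions to groups of the given sizes;
# returns a list of integer vectors of length N (group index per position)
#' @noRd
.enumerate_assignments <- function(N, sizes) {
  res <- list()
  assign <- integer(N)
  k <- length(sizes)
  rec <- function(avail, gi) {
    if (gi == k) {
      assign[avail] <<- gi
      res[[length(res) + 1]] <<- assign
      assign[avail] <<- 0L
      return(invisible())
    }
    for (p in utils::combn(avail, sizes[gi], simplify = FALSE)) {
      assign[p] <<- gi
      rec(setdiff(avail, p), gi + 1)
      assign[p] <<- 0L
    }
  }
  rec(seq_len(N), 1L)
  res
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("<rank_test_result> H = %.3f, df = %d, p = %.4g%s\n",
              x$H, x$df, x$p_value,
              if (x$tie_corrected) " (tie-corrected)" else ""))
  if (!is.null(x$p_exact))
    cat(sprintf("  permutation p = %.4g (%s)\n", x$p_exact, x$exact_method))
  invisible(x)
}

#' Pearson product-moment correlation with a two-sided p-value
#'
#' @param x,y numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return List with `r`, `p_value`, `df`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       df = unname(ct$parameter), n = length(x))
}

#' Test environmental distributions across phylotypes
#'
#' Joins occurrence calls with site metadata and runs a Kruskal-Wallis
#' test of the temperature (and pH) values of positive sites across
#' phylotypes — the question being whether the phylotypes occupy
#' distinguishable physicochemical niches.
#'
#' @param calls tibble of [occurrence_call()] rows for several phylotypes.
#' @param sites site metadata tibble with `site_id`, `temperature`, `ph`.
#' @return List with `temperature` and `ph` [kruskal_wallis()] results,
#'   and `positive_sites` (the joined tibble of positive calls).
#' @export
test_env_distributions <- function(calls, sites) {
  pos <- calls[calls$positive, , drop = FALSE]
  m <- merge(pos, sites, by = "site_id")
  if (length(unique(m$phylotype)) < 2)
    stop("need positive calls for at least 2 phylotypes")
  gt <- split(m$temperature, m$phylotype)
  gp <- split(m$ph, m$phylotype)
  list(temperature = kruskal_wallis(gt), ph = kruskal_wallis(gp),
       positive_sites = tibble::as_tibble(m))
}
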