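#' Specify a synthetic population
#'
#' A population spec bundles everything the generator needs to emit one
#' genome population of a synthetic hot-spring community: target G+C,
#' genome length, optional k-mer compositional bias, community abundance,
#' marker-catalog retention fractions (for completeness truth) and a COG
#' complement (for functional-profile truth).
#'
#' @param name population label.
#' @param gc_target target G+C fraction, in (0, 1).
#' @param genome_length genome length in bases (>= 1e4 for simulation).
#' @param abundance community abundance fraction (checked at community
#'   level, where abundances must sum to 1).
#' @param kmer_bias optional named numeric vector of relative weights for
#'   canonical k-mers; unlisted k-mers have weight 1.
#' @param marker_presence named numeric vector: marker-catalog name ->
#'   fraction of that catalog's markers retained, each in `[0, 1]`.
#' @param cog_set character vector of COG labels carried by the population.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(name, gc_target, genome_length, abundance = NA_real_,
                            kmer_bias = NULL, marker_presence = NULL,
                            cog_set = character()) {
  if (!is.numeric(gc_target) || gc_target <= 0 || gc_target >= 1)
    stop("gc_target must be a fraction in (0, 1)")
  if (genome_length < 1) stop("genome_length must be positive")
  if (!is.null(marker_presence) &&
      (any(marker_presence < 0) || any(marker_presence > 1)))
    stop("marker_presence fractions must be in [0, 1]")
  if (!is.null(kmer_bias) && (is.null(names(kmer_bias)) || any(kmer_bias < 0)))
    stop("kmer_bias must be a named non-negative numeric vector")
  structure(list(name = name, gc_target = gc_target,
                 genome_length = as.integer(genome_length),
                 abundance = abundance, kmer_bias = kmer_bias,
                 marker_presence = marker_presence, cog_set = cog_set),
            class = "population_spec")
}

#' @noRd
.random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# chunk propensity under a k-mer bias: product of the relative weights of
# all biased k-mer occurrences (unlisted k-mers weigh 1), in log space
#' @noRd
.chunk_kmer_score <- function(chunk, kmer_bias) {
  k <- nchar(names(kmer_bias)[1])
  n <- nchar(chunk)
  if (n < k) return(0)
  words <- substring(chunk, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  w <- kmer_bias[words]
  sum(log(w[!is.na(w)]))
}

#' Simulate a genome with controlled G+C and k-mer composition
#'
#' Bases are drawn i.i.d. with per-position G+C probability equal to
#' `gc_target`. When the spec carries a `kmer_bias`, the genome is built in
#' chunks: for each chunk several candidates are drawn and one is kept with
#' probability proportional to the product of its k-mers' relative weights
#' (importance resampling), so a weight-w k-mer ends up roughly w-fold
#' enriched per occurrence while G+C stays on target for symmetric biases.
#' Identical seeds give byte-identical genomes.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed.
#' @param catalogs marker catalogs used to materialize `marker_presence`
#'   into a concrete truth set (default [default_marker_catalogs()]).
#' @param chunk_len chunk length for the bias layer (bases).
#' @param max_tries candidate chunks drawn per resampling step.
#' @return An object of class `synthetic_genome`: list with `name`,
#'   `sequence`, `truth_markers`, `truth_cogs`, `gc_target`.
#' @export
simulate_genome <- function(spec, seed, catalogs = default_marker_catalogs(),
                            chunk_len = 200L, max_tries = 30L) {
  stopifnot(inherits(spec, "population_spec"))
  if (spec$genome_length < 1e4)
    stop("genome_length must be >= 1e4 for simulation")
  withr::with_seed(as.integer(seed), {
    L <- spec$genome_length
    if (is.null(spec$kmer_bias)) {
      sequence <- .random_dna(L, spec$gc_target)
    } else {
      # importance resampling per chunk: draw candidates and keep one with
      # probability proportional to the product of its k-mers' relative
      # weights, so a weight-w k-mer is ~w-fold enriched per occurrence
      n_chunks <- ceiling(L / chunk_len)
      chunks <- character(n_chunks)
      for (i in seq_len(n_chunks)) {
        len <- if (i == n_chunks) L - (n_chunks - 1L) * chunk_len else chunk_len
        cand <- vapply(seq_len(max_tries), function(t)
          .random_dna(len, spec$gc_target), character(1))
        lw <- vapply(cand, .chunk_kmer_score, numeric(1),
                     kmer_bias = spec$kmer_bias, USE.NAMES = FALSE)
        p <- exp(lw - max(lw))
        chunks[i] <- cand[sample.int(max_tries, 1, prob = p)]
      }
      sequence <- paste(chunks, collapse = "")
    }
    truth_markers <- character()
    if (!is.null(spec$marker_presence)) {
      for (cn in names(spec$marker_presence)) {
        cat_markers <- catalogs[[cn]]$markers
        n_keep <- round(spec$marker_presence[[cn]] * length(cat_markers))
        truth_markers <- c(truth_markers,
                           sort(sample(cat_markers, n_keep)))
      }
    }
    structure(list(name = spec$name, sequence = sequence,
                   truth_markers = unique(truth_markers),
                   truth_cogs = spec$cog_set, gc_target = spec$gc_target),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %s: %d bp, G+C %.3f (target %.3f)\n",
              x$name, nchar(x$sequence), gc_content(x$sequence), x$gc_target))
  invisible(x)
}

#' Derive a conspecific genome at a known nucleotide identity
#'
#' Emulates a pair of conspecific populations (e.g. the same species
#' recovered from two springs) by substituting each site independently with
#' probability `1 - target_identity`. Substitutions only, no indels, so the
#' true global identity is analytic and recoverable by alignment.
#'
#' @param genome a `synthetic_genome` (or character sequence).
#' @param target_identity expected global identity, in (0, 1].
#' @param seed integer seed.
#' @return A `synthetic_genome` named `<name>_div`.
#' @export
diverge_pair <- function(genome, target_identity, seed) {
  if (target_identity <= 0 || target_identity > 1)
    stop("target_identity must be in (0, 1]")
  seq <- if (inherits(genome, "synthetic_genome")) genome$sequence else
    .as_char_seq(genome)
  name <- if (inherits(genome, "synthetic_genome")) genome$name else "genome"
  withr::with_seed(as.integer(seed), {
    bases <- strsplit(seq, "")[[1]]
    hit <- which(stats::runif(length(bases)) < 1 - target_identity)
    if (length(hit) > 0) {
      alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"),
                   N = c("A", "C", "G"))
      row <- match(bases[hit], rownames(alt), nomatch = 5L)
      bases[hit] <- alt[cbind(row, sample.int(3L, length(hit),
                                              replace = TRUE))]
    }
    structure(list(name = paste0(name, "_div"),
                   sequence = paste(bases, collapse = ""),
                   truth_markers = if (inherits(genome, "synthetic_genome"))
                     genome$truth_markers else character(),
                   truth_cogs = if (inherits(genome, "synthetic_genome"))
                     genome$truth_cogs else character(),
                   gc_target = if (inherits(genome, "synthetic_genome"))
                     genome$gc_target else NA_real_),
              class = "synthetic_genome")
  })
}

#' Fragment a genome into covered contigs
#'
#' Cuts non-overlapping substrings out of a genome and attaches a coverage
#' value to each, emulating the contig length/coverage structure of a
#' low-coverage Sanger assembly (genome coverages of roughly 2-3.5x in the
#' communities this generator emulates).
#'
#' @param genome a `synthetic_genome` or character sequence.
#' @param n_contigs number of contigs to cut.
#' @param min_len minimum contig length (bases).
#' @param cov_mean mean fold-coverage assigned to contigs.
#' @param seed integer seed.
#' @param cov_sd standard deviation of per-contig coverage (default 0.4).
#' @return A tibble with `contig_id`, `sequence`, `length`, `coverage`,
#'   `source`, `start` (1-based position in the source genome).
#' @export
fragment_and_cover <- function(genome, n_contigs, min_len, cov_mean, seed,
                               cov_sd = 0.4) {
  seq <- if (inherits(genome, "synthetic_genome")) genome$sequence else
    .as_char_seq(genome)
  name <- if (inherits(genome, "synthetic_genome")) genome$name else "genome"
  L <- nchar(seq)
  if (n_contigs < 1 || min_len < 1) stop("n_contigs and min_len must be >= 1")
  if (n_contigs * min_len > L)
    stop("infeasible: n_contigs * min_len exceeds the genome length")
  withr::with_seed(as.integer(seed), {
    spare <- L - n_contigs * min_len
    u <- stats::runif(n_contigs)
    extra <- floor(0.8 * spare * u / max(sum(u), 1))
    lens <- min_len + extra
    gap_total <- L - sum(lens)
    g <- stats::runif(n_contigs + 1)
    gaps <- floor(gap_total * g / sum(g))
    starts <- cumsum(c(1L, lens + gaps[-(n_contigs + 1)]))[seq_len(n_contigs)]
    coverage <- pmax(0.2, stats::rnorm(n_contigs, cov_mean, cov_sd))
    tibble::tibble(
      contig_id = sprintf("%s_c%03d", name, seq_len(n_contigs)),
      sequence = substring(seq, starts, starts + lens - 1L),
      length = as.integer(lens), coverage = coverage,
      source = name, start = as.integer(starts))
  })
}

#' Simulate shotgun reads from a community
#'
#' Draws reads from community genomes in proportion to abundance times
#' genome length, with Sanger-like lengths (normal, truncated) and optional
#' substitution errors (no indels, so the truth identity of each read to
#' its source is analytic). Half the reads are reverse-complemented to
#' emulate random cloning orientation. A truth table is always returned so
#' downstream stages have an oracle.
#'
#' @param community list of `list(genome = , abundance = )` entries, where
#'   `genome` is a `synthetic_genome` or character sequence.
#' @param n_reads number of reads.
#' @param len_mean,len_sd read length distribution (default mean 820 bp,
#'   emulating Sanger shotgun reads).
#' @param err_rate per-base substitution error rate, in `[0, 0.3]`.
#' @param seed integer seed.
#' @return A list with `reads` (named character vector) and `truth`
#'   (tibble: `read_id`, `source`, `start`, `length`, `strand`).
#' @export
simulate_reads <- function(community, n_reads, len_mean = 820, len_sd = 120,
                           err_rate = 0, seed = 1L) {
  if (length(community) == 0) stop("community must be non-empty")
  if (err_rate < 0 || err_rate > 0.3) stop("err_rate must be in [0, 0.3]")
  seqs <- vapply(community, function(m)
    if (inherits(m$genome, "synthetic_genome")) m$genome$sequence else
      .as_char_seq(m$genome), character(1))
  nms <- vapply(seq_along(community), function(i) {
    g <- community[[i]]$genome
    if (inherits(g, "synthetic_genome")) g$name else paste0("genome", i)
  }, character(1))
  ab <- vapply(community, function(m) m$abundance, numeric(1))
  if (abs(sum(ab) - 1) > 1e-9) stop("abundances must sum to 1")
  lens <- nchar(seqs)
  withr::with_seed(as.integer(seed), {
    w <- ab * lens
    src <- sample(seq_along(seqs), n_reads, replace = TRUE, prob = w / sum(w))
    rl <- pmin(pmax(50L, as.integer(round(stats::rnorm(n_reads, len_mean,
                                                       len_sd)))),
               lens[src])
    start <- 1L + as.integer(floor(stats::runif(n_reads) * (lens[src] - rl + 1)))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    reads <- substring(seqs[src], start, start + rl - 1L)
    minus <- strand == "-"
    if (any(minus))
      reads[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[minus])))
    if (err_rate > 0) {
      alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
      for (i in seq_len(n_reads)) {
        nmut <- stats::rbinom(1, rl[i], err_rate)
        if (nmut == 0) next
        pos <- sample.int(rl[i], nmut)
        b <- strsplit(reads[i], "")[[1]]
        b[pos] <- vapply(b[pos], function(x) {
          j <- sample.int(3, 1)
          substr(alt[[x]], j, j)
        }, character(1), USE.NAMES = FALSE)
        reads[i] <- paste(b, collapse = "")
      }
    }
    ids <- sprintf("read%06d", seq_len(n_reads))
    names(reads) <- ids
    list(reads = reads,
         truth = tibble::tibble(read_id = ids, source = nms[src],
                                start = start, length = rl, strand = strand))
  })
}

#' Simulate a proteome
#'
#' Draws `n_proteins` random protein sequences with i.i.d. residues
#' (uniform over the 20 standard amino acids) and lengths uniform in
#' `len_range` — enough structure for best-hit identity statistics, which
#' depend only on planted divergence, not on realistic residue usage.
#'
#' @param n_proteins number of proteins.
#' @param len_range length range in residues (default 100-500, so every
#'   protein can pass a 100-residue alignment-length filter when intact).
#' @param seed integer seed.
#' @return Named character vector of protein sequences.
#' @export
simulate_proteome <- function(n_proteins, len_range = c(100L, 500L), seed) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  withr::with_seed(as.integer(seed), {
    lens <- sample(len_range[1]:len_range[2], n_proteins, replace = TRUE)
    prots <- vapply(lens, function(L)
      paste(sample(aas, L, replace = TRUE), collapse = ""), character(1))
    stats::setNames(prots, sprintf("prot%04d", seq_len(n_proteins)))
  })
}

#' Derive a diverged copy of a proteome at a known amino-acid identity
#'
#' Substitutes each residue independently with probability
#' `1 - target_identity` (uniform over the other 19 amino acids), so the
#' expected per-protein identity equals the target — the planted-divergence
#' scenario for AAI recovery.
#'
#' @param proteome named character vector of protein sequences.
#' @param target_identity expected identity, in (0, 1].
#' @param seed integer seed.
#' @return Named character vector, same names and lengths.
#' @export
diverge_proteome <- function(proteome, target_identity, seed) {
  if (target_identity <= 0 || target_identity > 1)
    stop("target_identity must be in (0, 1]")
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  withr::with_seed(as.integer(seed), {
    out <- vapply(proteome, function(p) {
      b <- strsplit(p, "")[[1]]
      hit <- which(stats::runif(length(b)) < 1 - target_identity)
      if (length(hit) > 0)
        b[hit] <- vapply(b[hit], function(x)
          sample(setdiff(aas, x), 1), character(1))
      paste(b, collapse = "")
    }, character(1))
    names(out) <- names(proteome)
    out
  })
}

#' Specify a synthetic site survey
#'
#' Describes a set of thermal-spring sites (temperature and pH drawn inside
#' global ranges) and, per phylotype, an occurrence niche: sites whose
#' temperature and pH fall inside the niche window carry a 16S variant
#' above the occurrence-identity threshold; sites outside carry only
#' variants below it.
#'
#' @param n_sites number of sites.
#' @param temp_range global temperature range, degrees C (default 70-90,
#'   the terrestrial thermal-spring window these phylotypes occupy).
#' @param ph_range global pH range (default 7-9, circumneutral springs).
#' @param niches named list: phylotype -> `list(temp = c(lo, hi),
#'   ph = c(lo, hi))`; windows must lie inside the global ranges.
#' @param identity_in within-niche 16S identity to the reference (fraction,
#'   must exceed the occurrence threshold; default 0.99).
#' @param identity_out out-of-niche identity (default 0.93, safely below a
#'   97% threshold).
#' @param gene_length 16S gene length (default 1400 bp).
#' @return An object of class `survey_spec`.
#' @export
survey_spec <- function(n_sites, temp_range = c(70, 90), ph_range = c(7, 9),
                        niches, identity_in = 0.99, identity_out = 0.93,
                        gene_length = 1400L) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (length(niches) == 0) stop("at least one phylotype niche is required")
  for (nm in names(niches)) {
    ni <- niches[[nm]]
    if (ni$temp[1] < temp_range[1] || ni$temp[2] > temp_range[2] ||
        ni$ph[1] < ph_range[1] || ni$ph[2] > ph_range[2])
      stop("niche window for ", nm, " lies outside the global ranges")
  }
  if (any(c(identity_in, identity_out) < 0) ||
      any(c(identity_in, identity_out) > 1))
    stop("identity parameters must be fractions in [0, 1]")
  structure(list(n_sites = as.integer(n_sites), temp_range = temp_range,
                 ph_range = ph_range, niches = niches,
                 identity_in = identity_in, identity_out = identity_out,
                 gene_length = as.integer(gene_length)),
            class = "survey_spec")
}

#' @noRd
.mutate_exact <- function(seq, n_sub, margin = 10L) {
  b <- strsplit(seq, "")[[1]]
  L <- length(b)
  pos <- sample((margin + 1L):(L - margin), n_sub)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  b[pos] <- vapply(b[pos], function(x) sample(alt[[x]], 1), character(1))
  paste(b, collapse = "")
}

#' Simulate a 16S survey across thermal-spring sites
#'
#' Draws site temperatures and pH uniformly inside the global ranges and
#' builds per-site 16S sequence pools. Inside a phylotype's niche the pool
#' contains a variant whose identity to that phylotype's reference gene is
#' `identity_in` (substitutions placed away from the sequence ends so the
#' alignment identity equals the planted value exactly); outside, only an
#' `identity_out` variant. Every pool also carries one unrelated background
#' sequence. Truth occupancy per site and phylotype is returned.
#'
#' @param spec a [survey_spec()].
#' @param seed integer seed.
#' @return A list with `sites` (tibble: `site_id`, `temperature`, `ph`, and
#'   one logical `occ_<phylotype>` truth column per phylotype), `pools`
#'   (list of named character vectors per site) and `references` (named
#'   character vector of per-phylotype reference genes).
#' @export
simulate_survey <- function(spec, seed) {
  stopifnot(inherits(spec, "survey_spec"))
  withr::with_seed(as.integer(seed), {
    L <- spec$gene_length
    refs <- vapply(names(spec$niches), function(nm) .random_dna(L, 0.55),
                   character(1))
    temp <- stats::runif(spec$n_sites, spec$temp_range[1], spec$temp_range[2])
    ph <- stats::runif(spec$n_sites, spec$ph_range[1], spec$ph_range[2])
    site_id <- sprintf("site%03d", seq_len(spec$n_sites))
    occ <- matrix(FALSE, spec$n_sites, length(spec$niches),
                  dimnames = list(site_id, names(spec$niches)))
    pools <- vector("list", spec$n_sites)
    names(pools) <- site_id
    for (s in seq_len(spec$n_sites)) {
      pool <- character(0)
      for (nm in names(spec$niches)) {
        ni <- spec$niches[[nm]]
        inside <- temp[s] >= ni$temp[1] && temp[s] <= ni$temp[2] &&
          ph[s] >= ni$ph[1] && ph[s] <= ni$ph[2]
        occ[s, nm] <- inside
        q <- if (inside) spec$identity_in else spec$identity_out
        v <- .mutate_exact(refs[[nm]], round((1 - q) * L))
        pool <- c(pool, stats::setNames(v, paste0(site_id[s], "_", nm)))
      }
      bg <- stats::setNames(.random_dna(L, 0.55), paste0(site_id[s], "_bg"))
      pools[[s]] <- c(pool, bg)
    }
    sites <- tibble::tibble(site_id = site_id, temperature = temp, ph = ph)
    for (nm in colnames(occ)) sites[[paste0("occ_", nm)]] <- unname(occ[, nm])
    list(sites = sites, pools = pools, references = refs)
  })
}
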