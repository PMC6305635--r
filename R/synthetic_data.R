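#' Simulate unphased diploid genotypes under Hardy-Weinberg equilibrium
#'
#' Each individual is formed by two independent haplotype draws from the
#' supplied frequency vector (random union of gametes), after which phase
#' is erased to site-wise allele counts -- the sampling model the EM
#' estimator assumes. Fully deterministic under the seed.
#'
#' @param freqs Named numeric vector (names are haplotype patterns in any
#'   accepted spelling) or a data.frame with columns `pattern`,
#'   `frequency`. Must be non-negative and sum to 1 within 0.005 (printed
#'   tables round); renormalised internally.
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed.
#' @param site_map Site map (defaults to the seven beta-globin sites when
#'   patterns have seven symbols, else generic labels).
#' @return A `genotype_matrix` of n rows, with the drawn (phased) haplotype
#'   pair per individual retained in the `truth` attribute.
#' @examples
#' g <- simulate_genotypes(c("+----++" = 0.6, "-------" = 0.4), n = 10, seed = 7)
#' @export
simulate_genotypes <- function(freqs, n, seed, site_map = NULL) {
  if (is.data.frame(freqs)) {
    freqs <- stats::setNames(freqs$frequency, freqs$pattern)
  }
  if (n < 1) stop("n must be >= 1")
  if (is.null(names(freqs)) || any(freqs < 0) ||
      abs(sum(freqs) - 1) > 0.005) {
    stop("freqs must be a named non-negative vector summing to 1")
  }
  L <- nchar(gsub("[[:space:]]", "", names(freqs)[1]))
  if (is.null(site_map)) {
    site_map <- if (L == 7) beta_globin_sites() else
      beta_globin_sites(paste0("s", seq_len(L)))
  }
  pats <- .canon(names(freqs), site_map)
  freqs <- freqs / sum(freqs)
  H <- do.call(rbind, lapply(strsplit(pats, ""), function(ch) as.integer(ch == "+")))
  set.seed(seed)
  draws <- sample.int(length(pats), 2 * n, replace = TRUE, prob = freqs)
  h1 <- draws[seq_len(n)]
  h2 <- draws[n + seq_len(n)]
  m <- H[h1, , drop = FALSE] + H[h2, , drop = FALSE]
  g <- genotype_matrix(m, site_map)
  attr(g, "truth") <- data.frame(individual = rownames(g),
                                 h1 = pats[h1], h2 = pats[h2],
                                 stringsAsFactors = FALSE)
  attr(g, "seed") <- seed
  g
}

#' Simulate mutation accumulation on a star genealogy
#'
#' Each of `n` lineages radiates independently from the root and accrues a
#' Poisson(`lambda`) number of site flips. By default mutated sites are
#' drawn without replacement within a lineage (infinite-sites
#' approximation, valid while the draw count is at most L), so the
#' observed Hamming distance to the root equals the true mutation count
#' and rho can be validated exactly against the truth. With
#' `recurrent = TRUE` -- or whenever a lineage draws more mutations than
#' there are sites -- sites are drawn with replacement and repeated hits
#' toggle (a back-mutation warning is issued).
#'
#' @param root Root haplotype pattern (any spelling).
#' @param n Number of chromosomes (lineages).
#' @param lambda Expected mutations per lineage (>= 0).
#' @param seed Integer seed.
#' @param L Haplotype length; defaults to the root's length. When larger
#'   than the root's length the root is padded with `-` sites (handy for
#'   near-infinite-sites simulation).
#' @param counts Optional integer vector of length `n` overriding the
#'   Poisson draws with fixed per-lineage mutation counts.
#' @param recurrent Force with-replacement site choice.
#' @return List with `haplotypes` (character vector of n observed
#'   patterns), `mutations` (true per-lineage counts), `root`, `seed`.
#' @examples
#' sim <- simulate_star("-------", n = 5, lambda = 2, seed = 3)
#' sim$mutations
#' @export
simulate_star <- function(root, n, lambda = NULL, seed = 1, L = NULL,
                          counts = NULL, recurrent = FALSE) {
  root_vec_raw <- parse_haplotype(root,
    beta_globin_sites(paste0("s", seq_len(nchar(gsub("[[:space:]]", "", root))))))
  if (is.null(L)) L <- length(root_vec_raw)
  if (L < length(root_vec_raw)) stop("L is shorter than the root haplotype")
  root_vec <- c(as.integer(root_vec_raw), rep(0L, L - length(root_vec_raw)))
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  if (is.null(counts)) {
    if (is.null(lambda) || lambda < 0) stop("lambda must be >= 0")
    counts <- stats::rpois(n, lambda)
  } else {
    stopifnot(length(counts) == n, all(counts >= 0))
    counts <- as.integer(counts)
  }
  warned <- FALSE
  haps <- vapply(seq_len(n), function(i) {
    k <- counts[i]
    h <- root_vec
    if (k > 0) {
      if (!recurrent && k <= L) {
        sites <- sample.int(L, k)
        h[sites] <- 1L - h[sites]
      } else {
        if (!warned) {
          warning("mutation count exceeds site count or recurrent = TRUE; ",
                  "drawing sites with replacement (back-mutation possible)")
          warned <<- TRUE
        }
        sites <- sample.int(L, k, replace = TRUE)
        for (s in sites) h[s] <- 1L - h[s]
      }
    }
    format_haplotype(h)
  }, character(1))
  list(haplotypes = haps, mutations = counts,
       root = format_haplotype(root_vec), seed = seed)
}

#' Write a star-simulation truth table
#'
#' Emits `lineage`, `true_mutations`, `observed_pattern` as TSV with the
#' seed recorded in a header comment, so simulated datasets are fully
#' reproducible from the file alone.
#'
#' @param sim Result of [simulate_star()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_star_truth <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d root=%s", sim$seed, sim$root), con)
  utils::write.table(
    data.frame(lineage = seq_along(sim$haplotypes),
               true_mutations = sim$mutations,
               observed_pattern = sim$haplotypes),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
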