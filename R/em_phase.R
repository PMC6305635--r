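#' EM settings for haplotype-frequency estimation
#'
#' @param tol Convergence tolerance on the absolute change in log-likelihood
#'   between iterations.
#' @param max_iter Iteration cap per restart.
#' @param restarts Number of starts: the first is the deterministic uniform
#'   start over the compatible-haplotype support, the rest are Dirichlet(1)
#'   draws. Multiple starts escape symmetric fixed points (e.g. the uniform
#'   saddle of a single double-heterozygote).
#' @param seed Seed controlling the random restarts.
#' @return A list of class `phase_config`.
#' @export
phase_config <- function(tol = 1e-8, max_iter = 10000L, restarts = 20L,
                         seed = 1L) {
  stopifnot(tol > 0, max_iter >= 1L, restarts >= 1L)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "phase_config")
}

#' Haplotype pairs compatible with an unphased genotype
#'
#' Enumerates every unordered pair of haplotypes whose site-wise allele
#' counts reproduce the genotype. A site with one `+` allele may phase
#' either way; a missing site is summed over all four ordered allele
#' configurations. A genotype heterozygous at k sites (none missing) has
#' max(1, 2^(k-1)) compatible pairs.
#'
#' @param g Integer vector of 0/1/2/NA allele counts (one genotype row).
#' @param site_map Site map fixing the haplotype length.
#' @return Character matrix with columns `h1`, `h2` of compact patterns,
#'   one row per unordered pair.
#' @examples
#' g <- c(2L, 0L, 0L, 0L, 0L, 2L, 2L)  # homozygous +----++
#' enumerate_compatible_pairs(g)
#' @export
enumerate_compatible_pairs <- function(g, site_map = beta_globin_sites()) {
  L <- length(site_map)
  if (length(g) != L) stop("genotype length does not match the site map")
  opts <- lapply(seq_len(L), function(i) {
    if (is.na(g[i])) list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
    else if (g[i] == 0L) list(c(0L, 0L))
    else if (g[i] == 2L) list(c(1L, 1L))
    else if (g[i] == 1L) list(c(0L, 1L), c(1L, 0L))
    else stop("genotype values must be 0, 1, 2 or NA")
  })
  idx <- expand.grid(lapply(opts, seq_along))
  pairs <- matrix(character(0), 0, 2, dimnames = list(NULL, c("h1", "h2")))
  seen <- character(0)
  for (r in seq_len(nrow(idx))) {
    a <- integer(L); b <- integer(L)
    for (i in seq_len(L)) {
      ab <- opts[[i]][[idx[r, i]]]
      a[i] <- ab[1]; b[i] <- ab[2]
    }
    pa <- format_haplotype(a); pb <- format_haplotype(b)
    if (.pkey(pa) > .pkey(pb)) { tmp <- pa; pa <- pb; pb <- tmp }
    key <- paste(pa, pb)
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      pairs <- rbind(pairs, c(pa, pb))
    }
  }
  colnames(pairs) <- c("h1", "h2")
  pairs
}

## Internal: collapse a genotype matrix to unique rows with counts and a
## flat pair table indexed into the compatible-haplotype support.
.pair_table <- function(g, site_map) {
  keys <- apply(unclass(g), 1, paste, collapse = ",")
  tab <- table(keys)
  uniq <- names(tab)
  counts <- as.numeric(tab)
  rows <- lapply(strsplit(uniq, ","), function(v) as.integer(ifelse(v == "NA", NA, v)))
  pair_list <- lapply(rows, enumerate_compatible_pairs, site_map = site_map)
  if (any(vapply(pair_list, nrow, 1L) == 0L)) {
    stop("an individual has no compatible haplotype pair")
  }
  support <- .psort(unique(unlist(pair_list)))
  pg <- rep(seq_along(pair_list), vapply(pair_list, nrow, 1L))
  flat <- do.call(rbind, pair_list)
  list(support = support, n_geno = length(uniq), counts = counts,
       pg = pg,
       pi = match(flat[, 1], support), pj = match(flat[, 2], support))
}

#' Log-likelihood of haplotype frequencies given unphased genotypes
#'
#' The Hardy-Weinberg multinomial likelihood summed over phase
#' configurations: for each individual the genotype probability is
#' `sum over compatible pairs of (2 - delta(h1, h2)) p(h1) p(h2)`. Returns
#' `-Inf` when some individual's every compatible pair has zero frequency.
#'
#' @param p Named numeric frequency vector (names are patterns in any
#'   accepted spelling); must sum to 1.
#' @param genotypes A `genotype_matrix`.
#' @param site_map Site map.
#' @return The log-likelihood, a single number (possibly `-Inf`).
#' @export
log_likelihood <- function(p, genotypes, site_map = beta_globin_sites()) {
  stopifnot(!is.null(names(p)), all(p >= 0))
  if (abs(sum(p) - 1) > 1e-6) stop("frequencies must sum to 1")
  names(p) <- .canon(names(p), site_map)
  pt <- .pair_table(genotypes, site_map)
  pv <- p[pt$support]
  pv[is.na(pv)] <- 0
  coef <- ifelse(pt$pi == pt$pj, 1, 2)
  pr <- as.numeric(rowsum(coef * pv[pt$pi] * pv[pt$pj], pt$pg))
  sum(pt$counts * log(pr))
}

## one EM run from a given start; returns frequencies, trace, convergence
.em_once <- function(p0, pt, tol, max_iter) {
  coef <- ifelse(pt$pi == pt$pj, 1, 2)
  two_n <- 2 * sum(pt$counts)
  p <- p0
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- coef * p[pt$pi] * p[pt$pj]
    s <- as.numeric(rowsum(w, pt$pg))
    if (any(s <= 0)) { trace <- c(trace, -Inf); break }
    ll <- sum(pt$counts * log(s))
    trace <- c(trace, ll)
    post <- w / s[pt$pg] * pt$counts[pt$pg]
    cnt <- numeric(length(p))
    acc <- rowsum(c(post, post), c(pt$pi, pt$pj))
    cnt[as.integer(rownames(acc))] <- acc
    p_new <- cnt / two_n
    if (it > 1L && abs(ll - trace[it - 1L]) < tol) {
      converged <- TRUE
      p <- p_new
      break
    }
    p <- p_new
  }
  list(p = p, loglik = trace[length(trace)], trace = trace,
       iterations = length(trace), converged = converged)
}

#' Estimate haplotype frequencies from unphased genotypes by EM
#'
#' Maximum-likelihood haplotype-frequency estimation under Hardy-Weinberg
#' equilibrium with unknown gametic phase. The E-step distributes each
#' individual over its compatible haplotype pairs with posterior weight
#' proportional to `(2 - delta) p(h1) p(h2)`; the M-step sets each
#' frequency to its expected chromosome count divided by 2n. Only
#' haplotypes compatible with at least one sampled individual enter the
#' support. The best restart by final log-likelihood is returned (first
#' occurrence wins ties); haplotypes whose fitted frequency falls below
#' 1e-12 are dropped and the remainder renormalised.
#'
#' @param genotypes A `genotype_matrix` with at least one row.
#' @param config A [phase_config()].
#' @param site_map Site map.
#' @return An object of class `em_result`: list with `frequencies`
#'   (data.frame `pattern`, `frequency`), `loglik`, `iterations`,
#'   `converged`, and `ll_trace` (per-iteration log-likelihood of the best
#'   restart, non-decreasing).
#' @examples
#' g <- simulate_genotypes(c("+----++" = 1), n = 5, seed = 1)
#' em_estimate(g)$frequencies
#' @export
em_estimate <- function(genotypes, config = phase_config(),
                        site_map = beta_globin_sites()) {
  if (nrow(genotypes) == 0L) stop("genotype sample is empty")
  pt <- .pair_table(genotypes, site_map)
  K <- length(pt$support)
  best <- NULL
  for (r in seq_len(config$restarts)) {
    if (r == 1L) {
      p0 <- rep(1 / K, K)
    } else {
      set.seed(config$seed + r)
      d <- stats::rexp(K)
      p0 <- d / sum(d)
    }
    run <- .em_once(p0, pt, config$tol, config$max_iter)
    if (is.null(best) || run$loglik > best$loglik + 1e-12) best <- run
  }
  keep <- best$p >= 1e-12
  p <- best$p[keep] / sum(best$p[keep])
  structure(list(
    frequencies = data.frame(pattern = pt$support[keep], frequency = p,
                             stringsAsFactors = FALSE, row.names = NULL),
    loglik = best$loglik, iterations = best$iterations,
    converged = best$converged, ll_trace = best$trace,
    config = config), class = "em_result")
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf("EM haplotype frequencies: %d haplotypes, logLik %.6f, %d iterations%s\n",
              nrow(x$frequencies), x$loglik, x$iterations,
              if (x$converged) "" else " (not converged)"))
  print(x$frequencies, ...)
  invisible(x)
}

#' Write EM frequencies as a one-population frequency TSV
#'
#' Emits columns `haplotype`, `pattern`, `frequency`, the single-population
#' analogue of the published frequency-table layout. Haplotypes are named
#' from `labels` where a pattern matches, else `H1`, `H2`, ... in
#' decreasing-frequency order.
#'
#' @param res An `em_result`.
#' @param path Output path.
#' @param labels Optional named character vector, pattern -> label.
#' @return `path`, invisibly.
#' @export
write_em_result <- function(res, path, labels = NULL) {
  fr <- res$frequencies[order(-res$frequencies$frequency,
                              .pkey(res$frequencies$pattern),
                              method = "radix"), ]
  nm <- unname(labels[fr$pattern])
  nm[is.na(nm)] <- paste0("H", which(is.na(nm)))
  df <- data.frame(haplotype = nm, pattern = fr$pattern,
                   frequency = fr$frequency, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
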