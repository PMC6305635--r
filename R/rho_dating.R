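#' Mutation-rate calibration
#'
#' Years of elapsed time represented by one mutation along a lineage. The
#' default, 20,180 years per mutation, is the human mtDNA control-region
#' calibration (np 16,090--16,365) used in the rho-dating literature.
#' It is exposed as a parameter because restriction-site haplotypes of a
#' nuclear cluster mutate at their own rate: substitute a locus-appropriate
#' value for absolute dates to be meaningful.
#'
#' @param years_per_mutation Positive number of years per mutation.
#' @return A number of class `calibration_rate`.
#' @export
calibration_rate <- function(years_per_mutation = 20180) {
  stopifnot(years_per_mutation > 0)
  structure(years_per_mutation, class = "calibration_rate")
}

#' Convert a rho or sigma value from mutational units to years
#'
#' Multiplies by the calibration rate and reports to 0.1 year, the
#' precision at which such ages are conventionally tabulated.
#'
#' @param x Non-negative value in mutational units (a rho statistic or its
#'   sigma standard error).
#' @param rate A [calibration_rate()].
#' @return Age (or age SD) in years.
#' @examples
#' convert_age(4)    # 80720
#' convert_age(0.5)  # 10090
#' @export
convert_age <- function(x, rate = calibration_rate()) {
  if (any(x < 0)) stop("mutational-unit values must be non-negative")
  round(x * as.numeric(rate), 1)
}

#' Time since demographic expansion from the mismatch mode
#'
#' The mismatch-distribution mode tau dates an expansion through
#' t = tau / (2u), with u the mutation rate per sequence per generation;
#' multiply by years per generation for an absolute date. Estimating tau
#' itself is outside this package's scope; this is the conversion only.
#'
#' @param tau Mismatch mode, in mutational units (>= 0).
#' @param u Mutation rate per sequence per generation (> 0).
#' @param generation_years Years per generation (default 1, i.e. result in
#'   generations).
#' @return Expansion time, in generations or years.
#' @examples
#' expansion_time(4.2, 0.05, generation_years = 25)
#' @export
expansion_time <- function(tau, u, generation_years = 1) {
  if (u <= 0) stop("mutation rate u must be positive")
  if (tau < 0) stop("tau must be non-negative")
  tau / (2 * u) * generation_years
}

#' Rooted genealogy container
#'
#' A rooted tree over haplotype nodes: one row per node with its parent,
#' the mutational length of the edge to the parent, the depth (mutational
#' distance from the root) and the sampled multiplicity (number of sampled
#' chromosomes carrying that haplotype; 0 for median vectors).
#'
#' @param nodes data.frame with columns `id`, `pattern`, `parent` (id, NA
#'   for the root), `edge_length`, `multiplicity`, `sampled`.
#' @return The validated data.frame with class `rooted_genealogy`; depths
#'   are (re)computed from the parent pointers.
#' @export
rooted_genealogy <- function(nodes) {
  need <- c("id", "pattern", "parent", "edge_length", "multiplicity", "sampled")
  stopifnot(all(need %in% names(nodes)))
  if (sum(is.na(nodes$parent)) != 1L) stop("exactly one root (parent NA) required")
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  if (any(nodes$multiplicity < 0)) stop("multiplicities must be >= 0")
  ok <- is.na(nodes$parent) | nodes$edge_length >= 1 |
    nodes$pattern == nodes$pattern[match(nodes$parent, nodes$id)]
  if (!all(ok)) stop("edges between distinct haplotypes must have length >= 1")
  depth <- stats::setNames(rep(NA_real_, nrow(nodes)), nodes$id)
  root <- nodes$id[is.na(nodes$parent)]
  depth[root] <- 0
  remaining <- setdiff(nodes$id, root)
  while (length(remaining)) {
    ready <- remaining[!is.na(depth[nodes$parent[match(remaining, nodes$id)]])]
    if (!length(ready)) stop("genealogy is not a single rooted tree")
    i <- match(ready, nodes$id)
    depth[ready] <- depth[nodes$parent[i]] + nodes$edge_length[i]
    remaining <- setdiff(remaining, ready)
  }
  nodes$depth <- as.numeric(depth[nodes$id])
  class(nodes) <- c("rooted_genealogy", "data.frame")
  nodes
}

#' Extract a rooted genealogy from a haplotype network
#'
#' Roots the network at a designated ancestral haplotype and returns the
#' shortest-path tree. In `"shortest-path"` mode each node's parent is
#' chosen deterministically among the neighbours realising its shortest
#' root distance: highest sampled frequency first, then lexicographically
#' smallest pattern. In `"all-shortest-paths-average"` mode the recorded
#' depth is the mean root distance over all shortest paths -- which, all
#' shortest paths having equal length by definition, coincides with the
#' shortest-path depth; the modes differ only in bookkeeping intent and
#' give identical ages.
#'
#' @param net A `haplo_network`.
#' @param root Root haplotype: a pattern (any spelling) or a node id
#'   present in the network.
#' @param mode Parent/depth bookkeeping mode (see above).
#' @return A `rooted_genealogy` whose multiplicities are the sampled node
#'   weights of the network.
#' @export
extract_tree <- function(net, root,
                         mode = c("shortest-path", "all-shortest-paths-average")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "haplo_network"))
  nodes <- net$nodes
  root_pat <- if (root %in% nodes$id) {
    nodes$pattern[match(root, nodes$id)]
  } else {
    tryCatch(.canon(root, net$params$site_map), error = function(e) root)
  }
  if (!(root_pat %in% nodes$pattern)) {
    stop(sprintf("root '%s' is not a node of the network", root))
  }
  g <- .as_igraph_raw(list(patterns = nodes$pattern, edges = net$edges))
  D <- igraph::distances(g, v = root_pat, weights = igraph::E(g)$length)[1, ]
  if (any(!is.finite(D))) stop("network is not connected")
  adj <- .adjacency(list(patterns = nodes$pattern, edges = net$edges))
  elen <- stats::setNames(net$edges$length,
                          paste(net$edges$from, net$edges$to))
  edge_len <- function(a, b) {
    v <- elen[paste(a, b)]
    if (is.na(v)) v <- elen[paste(b, a)]
    as.numeric(v)
  }
  wt <- stats::setNames(nodes$weight, nodes$pattern)
  parent <- stats::setNames(rep(NA_character_, nrow(nodes)), nodes$pattern)
  for (p in setdiff(nodes$pattern, root_pat)) {
    cands <- adj[[p]]
    cands <- cands[vapply(cands, function(q)
      isTRUE(all.equal(unname(D[q]) + edge_len(q, p), unname(D[p]))),
      logical(1))]
    if (!length(cands)) stop("no shortest-path parent found (internal error)")
    cands <- cands[order(-wt[cands], .pkey(cands), method = "radix")]
    parent[p] <- cands[1]
  }
  id_of <- stats::setNames(nodes$id, nodes$pattern)
  out <- data.frame(
    id = nodes$id, pattern = nodes$pattern,
    parent = ifelse(nodes$pattern == root_pat, NA_character_,
                    id_of[parent[nodes$pattern]]),
    edge_length = ifelse(nodes$pattern == root_pat, 0,
                         vapply(seq_len(nrow(nodes)), function(i) {
                           if (nodes$pattern[i] == root_pat) return(0)
                           edge_len(parent[nodes$pattern[i]], nodes$pattern[i])
                         }, numeric(1))),
    multiplicity = ifelse(nodes$sampled, nodes$weight, 0),
    sampled = nodes$sampled,
    stringsAsFactors = FALSE)
  gen <- rooted_genealogy(out)
  attr(gen, "mode") <- mode
  gen
}

## ids of the clade rooted at `node` (node included)
.clade <- function(tree, node) {
  out <- node
  repeat {
    kids <- tree$id[!is.na(tree$parent) & tree$parent %in% out &
                      !(tree$id %in% out)]
    if (!length(kids)) return(out)
    out <- c(out, kids)
  }
}

#' Rho and sigma age estimate for a node
#'
#' The rho statistic is the multiplicity-weighted arithmetic mean of the
#' mutational distance from the focal node to every sampled chromosome in
#' its clade (the node's own chromosomes count at distance 0). Its
#' standard error follows the branch formula
#' `sigma^2 = (1/n^2) * sum over clade branches of n_b^2 * l_b`, where
#' `n_b` is the number of sampled chromosomes below a branch and `l_b` its
#' mutational length. On a star genealogy this reduces to
#' `sigma^2 = rho / n`. Both are converted to years by the calibration
#' rate.
#'
#' @param tree A `rooted_genealogy`.
#' @param node Node id to date (often the root).
#' @param rate A [calibration_rate()].
#' @return A one-row data.frame of class `age_estimate`: `node`, `rho`,
#'   `sigma`, `years`, `years_sd`, `n` (sampled chromosomes used).
#' @examples
#' tr <- star_genealogy("---", c("+--", "-+-", "--+"))
#' rho_estimate(tr, "---")
#' @export
rho_estimate <- function(tree, node, rate = calibration_rate()) {
  stopifnot(inherits(tree, "rooted_genealogy"))
  if (!(node %in% tree$id)) stop(sprintf("node '%s' not in genealogy", node))
  clade <- .clade(tree, node)
  sub <- tree[match(clade, tree$id), ]
  n <- sum(sub$multiplicity)
  if (n <= 0) stop(sprintf("clade below '%s' contains no sampled chromosomes", node))
  d0 <- sub$depth[sub$id == node]
  rho <- sum(sub$multiplicity * (sub$depth - d0)) / n
  below <- vapply(sub$id, function(u)
    sum(sub$multiplicity[match(.clade(tree, u), sub$id)]), numeric(1))
  branches <- sub$id != node
  sigma2 <- sum(below[branches]^2 * sub$edge_length[branches]) / n^2
  sigma <- sqrt(sigma2)
  out <- data.frame(node = node, rho = rho, sigma = sigma,
                    years = convert_age(rho, rate),
                    years_sd = convert_age(sigma, rate),
                    n = n, stringsAsFactors = FALSE)
  class(out) <- c("age_estimate", "data.frame")
  out
}

#' Age estimates for every non-root sampled haplotype
#'
#' Two readings of "the age of a haplotype" are supported, because
#' published per-haplotype rho tables rarely state which genealogy each
#' value was computed on. `"descendant-rho"` applies [rho_estimate()] at
#' each node over its own clade (a leaf therefore gets rho 0).
#' `"root-path"` reports each node's mutational distance from the root as
#' its age, with `sigma = sqrt(depth)` (the branch formula along a single
#' lineage).
#'
#' @param tree A `rooted_genealogy`.
#' @param rate A [calibration_rate()].
#' @param mode `"descendant-rho"` or `"root-path"`.
#' @return data.frame with one row per non-root sampled haplotype:
#'   `haplotype`, `pattern`, `years`, `years_sd`, `rho`, `sigma`, `n`.
#'   Years are reported to 0.1, rho and sigma to 3 decimals.
#' @export
date_all_nodes <- function(tree, rate = calibration_rate(),
                           mode = c("descendant-rho", "root-path")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "rooted_genealogy"))
  root <- tree$id[is.na(tree$parent)]
  targets <- tree$id[tree$sampled & tree$id != root]
  rows <- lapply(targets, function(v) {
    if (mode == "descendant-rho") {
      est <- rho_estimate(tree, v, rate)
      rho <- round(est$rho, 3); sigma <- round(est$sigma, 3)
      n <- est$n
    } else {
      rho <- round(tree$depth[tree$id == v], 3)
      sigma <- round(sqrt(tree$depth[tree$id == v]), 3)
      n <- tree$multiplicity[tree$id == v]
    }
    # years derive from the printed-precision rho/sigma so the emitted
    # table is internally consistent (years / rho = rate to 0.1 year)
    data.frame(haplotype = v, pattern = tree$pattern[tree$id == v],
               years = convert_age(rho, rate),
               years_sd = convert_age(sigma, rate),
               rho = rho, sigma = sigma, n = n, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(haplotype = character(0), pattern = character(0),
               years = numeric(0), years_sd = numeric(0), rho = numeric(0),
               sigma = numeric(0), n = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "rate") <- as.numeric(rate)
  out
}

#' Star genealogy from a root and observed haplotypes
#'
#' Builds the rooted genealogy in which every distinct non-root haplotype
#' hangs directly off the root at its Hamming distance, with multiplicity
#' equal to how many chromosomes carry it. This is the genealogy a star
#' (sudden-expansion) model implies, and the natural input for validating
#' rho against simulated star samples.
#'
#' @param root Root pattern (any spelling).
#' @param haplotypes Character vector of observed chromosome patterns (one
#'   entry per chromosome; repeats allowed) or a matrix of 0/1 rows.
#' @param site_map Site map.
#' @return A `rooted_genealogy`.
#' @export
star_genealogy <- function(root, haplotypes, site_map = NULL) {
  if (is.matrix(haplotypes)) {
    pats <- apply(haplotypes, 1, function(r) format_haplotype(as.integer(r)))
    if (is.null(site_map)) site_map <- beta_globin_sites(paste0("s", seq_len(ncol(haplotypes))))
  } else {
    if (is.null(site_map)) {
      L <- nchar(gsub("[[:space:]]", "", root))
      site_map <- if (L == 7) beta_globin_sites() else
        beta_globin_sites(paste0("s", seq_len(L)))
    }
    pats <- .canon(haplotypes, site_map)
  }
  root_pat <- .canon(root, site_map)
  tab <- table(pats)
  pat <- names(tab)
  mult <- as.numeric(tab)
  wts <- rep(1, length(site_map))
  nodes <- data.frame(
    id = c(root_pat, setdiff(pat, root_pat)),
    pattern = c(root_pat, setdiff(pat, root_pat)),
    stringsAsFactors = FALSE)
  nodes$parent <- c(NA_character_, rep(root_pat, nrow(nodes) - 1L))
  nodes$edge_length <- vapply(nodes$pattern, .wdist, numeric(1),
                              pb = root_pat, weights = wts)
  nodes$multiplicity <- ifelse(nodes$pattern %in% pat,
                               mult[match(nodes$pattern, pat)], 0)
  nodes$multiplicity[is.na(nodes$multiplicity)] <- 0
  nodes$sampled <- nodes$multiplicity > 0
  rooted_genealogy(nodes)
}
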