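#' Parameters for network construction
#'
#' @param epsilon Non-negative integer tolerance on weighted distance. At 0
#'   the backbone is exactly the union of all minimum spanning trees; larger
#'   values admit longer alternative links and costlier median vectors,
#'   trading a sparser graph for more reticulation.
#' @param weights Positive integer weight per site (default all 1). Weights
#'   rescale the per-site cost of a mutation; topology under uniform weights
#'   is invariant to the common scale.
#' @param site_map Site map; `weights` must match its length.
#' @return A list of class `network_params`.
#' @export
network_params <- function(epsilon = 0L, weights = NULL,
                           site_map = beta_globin_sites()) {
  if (is.null(weights)) weights <- rep(1L, length(site_map))
  stopifnot(epsilon >= 0, all(weights > 0),
            length(weights) == length(site_map))
  structure(list(epsilon = as.integer(epsilon), weights = as.numeric(weights),
                 site_map = site_map), class = "network_params")
}

## Normalise any accepted haplotype-set input (freq_table, em_result,
## data.frame, character vector) to data.frame(label, pattern, weight) with
## distinct patterns, lexicographically sorted.
.hap_set <- function(x, site_map = beta_globin_sites()) {
  if (inherits(x, "freq_table")) {
    w <- rowSums(as.matrix(x[, populations(x), drop = FALSE]))
    df <- data.frame(label = x$label, pattern = x$pattern, weight = w,
                     stringsAsFactors = FALSE)
  } else if (inherits(x, "em_result")) {
    df <- data.frame(label = x$frequencies$pattern,
                     pattern = x$frequencies$pattern,
                     weight = x$frequencies$frequency,
                     stringsAsFactors = FALSE)
  } else if (is.character(x)) {
    if (length(x) == 0L) stop("haplotype set is empty")
    p <- .canon(x, site_map)
    df <- data.frame(label = if (is.null(names(x))) p else names(x),
                     pattern = p, weight = 1, stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    stopifnot("pattern" %in% names(x))
    df <- data.frame(
      label = if ("label" %in% names(x)) x$label else x$pattern,
      pattern = .canon(x$pattern, site_map),
      weight = if ("weight" %in% names(x)) x$weight else 1,
      stringsAsFactors = FALSE)
  } else stop("unsupported haplotype-set input")
  if (nrow(df) == 0L) stop("haplotype set is empty")
  agg <- stats::aggregate(weight ~ pattern, df, sum)
  agg$label <- df$label[match(agg$pattern, df$pattern)]
  agg <- agg[order(.pkey(agg$pattern), method = "radix"),
             c("label", "pattern", "weight")]
  rownames(agg) <- NULL
  agg
}

## weighted distance matrix over compact patterns
.dist_matrix <- function(patterns, weights) {
  n <- length(patterns)
  M <- matrix(0, n, n, dimnames = list(patterns, patterns))
  if (n < 2) return(M)
  bits <- do.call(rbind, lapply(strsplit(patterns, ""), function(ch) ch == "+"))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sum(weights[bits[i, ] != bits[j, ]])
    M[i, j] <- d; M[j, i] <- d
  }
  M
}

.new_network <- function(nodes, edges, params) {
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("haplotype network: %d nodes (%d sampled, %d median vectors), %d edges\n",
              nrow(x$nodes), sum(x$nodes$sampled), sum(!x$nodes$sampled),
              nrow(x$edges)))
  invisible(x)
}

## union-find
.uf_new <- function(n) seq_len(n)
.uf_find <- function(uf, i) { while (uf[i] != i) i <- uf[i]; i }

#' Minimum spanning network over a haplotype set
#'
#' The backbone of median-joining construction: processing weighted
#' Hamming-distance classes in increasing order, a link of length d is kept
#' when its endpoints are not already connected by links of length
#' < d - epsilon. With epsilon = 0 the result is the union of all minimum
#' spanning trees; it is always connected and contains an MST.
#'
#' @param haplotypes Haplotype set: a `freq_table`, an `em_result`, a
#'   character vector of patterns, or a data.frame with columns `pattern`
#'   and optionally `label`, `weight`.
#' @param params A [network_params()].
#' @return A `haplo_network`: list with `nodes` (id, pattern, sampled,
#'   weight) and `edges` (from, to, length, sites).
#' @examples
#' net <- minimum_spanning_network(c("--", "-+", "++"),
#'   params = network_params(site_map = beta_globin_sites(c("s1", "s2"))))
#' net$edges
#' @export
minimum_spanning_network <- function(haplotypes, params = network_params()) {
  hs <- .hap_set(haplotypes, params$site_map)
  net <- .msn_patterns(hs$pattern, params)
  .decorate_network(net, hs, params)
}

## MSN on bare pattern vectors; returns edges data.frame(from, to, length)
## with from < to lexicographically.
.msn_patterns <- function(patterns, params) {
  patterns <- .psort(unique(patterns))
  n <- length(patterns)
  edges <- data.frame(from = character(0), to = character(0),
                      length = numeric(0), stringsAsFactors = FALSE)
  if (n < 2) return(list(patterns = patterns, edges = edges))
  D <- .dist_matrix(patterns, params$weights)
  classes <- sort(unique(D[upper.tri(D)]))
  kept_i <- integer(0); kept_j <- integer(0); kept_d <- numeric(0)
  for (d in classes) {
    # components from kept links strictly shorter than d - epsilon
    uf <- .uf_new(n)
    low <- which(kept_d < d - params$epsilon)
    for (k in low) {
      ri <- .uf_find(uf, kept_i[k]); rj <- .uf_find(uf, kept_j[k])
      if (ri != rj) uf[ri] <- rj
    }
    idx <- which(upper.tri(D) & D == d, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      if (.uf_find(uf, i) != .uf_find(uf, j)) {
        kept_i <- c(kept_i, i); kept_j <- c(kept_j, j); kept_d <- c(kept_d, d)
      }
    }
  }
  list(patterns = patterns,
       edges = data.frame(from = patterns[kept_i], to = patterns[kept_j],
                          length = kept_d, stringsAsFactors = FALSE))
}

## attach sampled flags, weights, labels, differing-site annotations
.decorate_network <- function(raw, hs, params, median_names = NULL) {
  patterns <- raw$patterns
  sampled <- patterns %in% hs$pattern
  id <- character(length(patterns))
  id[sampled] <- hs$label[match(patterns[sampled], hs$pattern)]
  if (any(!sampled)) {
    mv <- patterns[!sampled]
    nm <- median_names[mv]
    nm[is.na(nm)] <- paste0("mv", seq_len(sum(is.na(nm))))
    id[!sampled] <- nm
  }
  nodes <- data.frame(id = id, pattern = patterns, sampled = sampled,
                      weight = ifelse(sampled,
                                      hs$weight[match(patterns, hs$pattern)], 0),
                      stringsAsFactors = FALSE)
  edges <- raw$edges
  site_names <- as.character(params$site_map)
  edges$sites <- vapply(seq_len(nrow(edges)), function(k) {
    a <- strsplit(edges$from[k], "")[[1]]
    b <- strsplit(edges$to[k], "")[[1]]
    paste(site_names[a != b], collapse = ",")
  }, character(1))
  .new_network(nodes, edges, params)
}

#' Median vector of three haplotypes
#'
#' For binary characters the quasi-median is the site-wise majority state
#' of the triple; it is the candidate Steiner point inserted during
#' median-joining construction.
#'
#' @param a,b,c Equal-length 0/1 haplotype vectors.
#' @return The majority haplotype as an integer 0/1 vector.
#' @examples
#' median_vector(c(0,0,0), c(0,1,1), c(1,1,0))
#' @export
median_vector <- function(a, b, c) {
  if (length(a) != length(b) || length(b) != length(c)) {
    stop("haplotype lengths differ")
  }
  as.integer((a + b + c) >= 2)
}

.median_pattern <- function(pa, pb, pc) {
  A <- strsplit(pa, "")[[1]] == "+"
  B <- strsplit(pb, "")[[1]] == "+"
  C <- strsplit(pc, "")[[1]] == "+"
  paste(ifelse((A + B + C) >= 2, "+", "-"), collapse = "")
}

#' Construct a median-joining network
#'
#' Iterates the Bandelt median-joining scheme: build the
#' epsilon-relaxed minimum spanning network over the current node set; for
#' every triple of mutually linked nodes form the (majority-rule) median
#' vector; among medians not yet present, add all whose connection cost
#' (summed weighted distance to the defining triple) is within epsilon of
#' the round's minimum; repeat until no median is added. Unsampled nodes
#' that end with degree <= 2 and lie on no shortest path between sampled
#' nodes are then pruned (lexicographically first, links rebuilt after each
#' deletion). Node order is made deterministic by lexicographic pattern
#' sorting throughout; median vectors are named `mv1`, `mv2`, ... in
#' insertion order.
#'
#' Frequency weights never affect topology; they annotate sampled nodes for
#' rendering and downstream dating multiplicities.
#'
#' @inheritParams minimum_spanning_network
#' @return A `haplo_network` (see [minimum_spanning_network()]).
#' @examples
#' sm <- beta_globin_sites(c("s1", "s2", "s3"))
#' mj_construct(c("---", "-++", "++-"), network_params(site_map = sm))
#' @export
mj_construct <- function(haplotypes, params = network_params()) {
  hs <- .hap_set(haplotypes, params$site_map)
  current <- hs$pattern
  median_names <- character(0)
  mv_counter <- 0L
  repeat {
    raw <- .msn_patterns(current, params)
    if (nrow(raw$edges) == 0L) break
    adj <- .adjacency(raw)
    cand <- list()
    pats <- raw$patterns
    for (i in seq_along(pats)) {
      ni <- adj[[pats[i]]]
      for (j in ni[.pkey(ni) > .pkey(pats[i])]) {
        common <- intersect(adj[[j]], ni)
        for (k in common[.pkey(common) > .pkey(j)]) {
          m <- .median_pattern(pats[i], j, k)
          if (m %in% current) next
          cost <- .wdist(m, pats[i], params$weights) +
            .wdist(m, j, params$weights) + .wdist(m, k, params$weights)
          if (is.null(cand[[m]]) || cost < cand[[m]]) cand[[m]] <- cost
        }
      }
    }
    if (length(cand) == 0L) break
    costs <- unlist(cand)
    add <- .psort(names(costs)[costs <= min(costs) + params$epsilon])
    nm <- paste0("mv", mv_counter + seq_along(add))
    names(nm) <- add
    median_names <- c(median_names, nm)
    mv_counter <- mv_counter + length(add)
    current <- .psort(c(current, add))
  }
  current <- .prune(current, hs$pattern, params)
  raw <- .msn_patterns(current, params)
  .decorate_network(raw, hs, params, median_names = median_names)
}

## adjacency list (pattern -> character vector of neighbours)
.adjacency <- function(raw) {
  adj <- stats::setNames(vector("list", length(raw$patterns)), raw$patterns)
  for (p in raw$patterns) adj[[p]] <- character(0)
  for (k in seq_len(nrow(raw$edges))) {
    a <- raw$edges$from[k]; b <- raw$edges$to[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

## delete obsolete unsampled nodes: degree <= 2 and on no sampled-sampled
## shortest path; one at a time (lexicographic), links rebuilt after each
.prune <- function(current, sampled, params) {
  repeat {
    raw <- .msn_patterns(current, params)
    uns <- setdiff(current, sampled)
    if (length(uns) == 0L) return(current)
    g <- .as_igraph_raw(raw)
    deg <- igraph::degree(g)
    D <- igraph::distances(g, weights = igraph::E(g)$length)
    smp <- intersect(current, sampled)
    victim <- NULL
    for (m in .psort(uns)) {
      if (deg[m] > 2) next
      on_path <- FALSE
      for (s in smp) {
        for (t in smp[smp > s]) {
          if (isTRUE(all.equal(D[s, m] + D[m, t], D[s, t]))) {
            on_path <- TRUE; break
          }
        }
        if (on_path) break
      }
      if (!on_path) { victim <- m; break }
    }
    if (is.null(victim)) return(current)
    current <- setdiff(current, victim)
  }
}

.as_igraph_raw <- function(raw) {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(raw$patterns)
  if (nrow(raw$edges)) {
    g <- igraph::add_edges(g, rbind(raw$edges$from, raw$edges$to),
                           length = raw$edges$length)
  }
  g
}

#' Convert a haplotype network to an igraph object
#'
#' @param net A `haplo_network`.
#' @return An undirected `igraph` graph with vertex attributes `pattern`,
#'   `sampled`, `weight` and edge attributes `length`, `sites`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "haplo_network"))
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(net$nodes$pattern,
                     label = net$nodes$id,
                     sampled = net$nodes$sampled,
                     weight = net$nodes$weight)
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to),
                           length = net$edges$length,
                           sites = net$edges$sites)
  }
  g
}

#' Export a haplotype network
#'
#' Writes the network as an edge-list TSV (`node_a`, `node_b`, `length`,
#' `sites_changed`), a Graphviz DOT file (sampled nodes drawn as circles
#' with diameter proportional to the square root of their frequency weight,
#' median vectors as small points, edges labelled with the differing
#' sites), or GraphML.
#'
#' @param net A `haplo_network`.
#' @param path Output path.
#' @param format One of `"tsv"`, `"dot"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "dot", "graphml")) {
  stopifnot(inherits(net, "haplo_network"))
  format <- match.arg(format)
  nodes <- net$nodes
  id_of <- stats::setNames(nodes$id, nodes$pattern)
  if (format == "tsv") {
    df <- data.frame(node_a = id_of[net$edges$from],
                     node_b = id_of[net$edges$to],
                     length = net$edges$length,
                     sites_changed = net$edges$sites,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "dot") {
    wmax <- max(nodes$weight, 1e-12)
    lines <- c("graph haplonet {", "  node [fixedsize=true];")
    for (r in seq_len(nrow(nodes))) {
      if (nodes$sampled[r]) {
        w <- 0.8 * nodes$weight[r] / wmax  # diameter proportional to frequency
        lines <- c(lines, sprintf(
          "  \"%s\" [shape=circle, width=%.3f, label=\"%s\"];",
          nodes$id[r], w, nodes$id[r]))
      } else {
        lines <- c(lines, sprintf(
          "  \"%s\" [shape=point, width=0.08, xlabel=\"%s\"];",
          nodes$id[r], nodes$id[r]))
      }
    }
    for (k in seq_len(nrow(net$edges))) {
      lines <- c(lines, sprintf(
        "  \"%s\" -- \"%s\" [label=\"%s\", len=%g];",
        id_of[net$edges$from[k]], id_of[net$edges$to[k]],
        net$edges$sites[k], net$edges$length[k]))
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}
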