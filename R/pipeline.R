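#' Pool population columns of a frequency table into one weighted set
#'
#' Pooled count per haplotype = sum over populations of frequency x
#' chromosome count; pooled frequencies are the renormalised counts. With
#' equal sizes (the default, used when per-population sample sizes are
#' unpublished) this is the unweighted mean of the population frequencies.
#'
#' @param ft A `freq_table`.
#' @param sizes Named numeric vector of chromosome counts per population;
#'   default equal weight 1 for every column. Every population with a
#'   nonzero column must have a size.
#' @return data.frame `label`, `pattern`, `count`, `frequency`.
#' @examples
#' pool_populations(table1_fixture())
#' @export
pool_populations <- function(ft, sizes = NULL) {
  stopifnot(inherits(ft, "freq_table"))
  pops <- populations(ft)
  vals <- as.matrix(ft[, pops, drop = FALSE])
  if (is.null(sizes)) sizes <- stats::setNames(rep(1, length(pops)), pops)
  nonzero <- pops[colSums(vals) > 0]
  missing <- setdiff(nonzero, names(sizes)[!is.na(sizes) & sizes > 0])
  if (length(missing)) {
    stop("no positive size supplied for population(s): ",
         paste(missing, collapse = ", "))
  }
  sz <- stats::setNames(rep(0, length(pops)), pops)
  sz[names(sizes)] <- sizes
  count <- as.numeric(vals %*% sz)
  data.frame(label = ft$label, pattern = ft$pattern, count = count,
             frequency = count / sum(count), stringsAsFactors = FALSE)
}

#' Run the full haplotype analysis pipeline
#'
#' Orchestrates the stages end to end: (optionally) EM haplotype-frequency
#' estimation from unphased genotypes, population pooling, median-joining
#' network construction, network export, genealogy extraction from the
#' designated ancestral root, and rho/sigma dating of every non-root
#' sampled haplotype. Exactly one of `frequency_table` or `genotypes` must
#' be supplied; a frequency table skips the EM stage (the published-table
#' path). All outputs are plain text and byte-identical across repeated
#' runs with the same inputs and seed.
#'
#' @param frequency_table A `freq_table`, or a path to one.
#' @param genotypes A `genotype_matrix`, or a path to a genotype TSV.
#' @param out_dir Output directory (created if needed).
#' @param root Ancestral root: pattern or label (default the all-minus
#'   haplotype of the site map).
#' @param rate A [calibration_rate()].
#' @param params A [network_params()].
#' @param phase A [phase_config()] (used only on the genotype path).
#' @param sizes Per-population chromosome counts for pooling (see
#'   [pool_populations()]).
#' @param tree_mode,dating_mode Passed to [extract_tree()] and
#'   [date_all_nodes()].
#' @param seed Integer seed recorded in the manifest and used for the EM
#'   restarts.
#' @return Invisibly, a list with the pooled set, network, genealogy, age
#'   table and the paths written: `frequencies.tsv`, `network.tsv`,
#'   `network.dot`, `network.graphml`, `ages.tsv`, `manifest.json`.
#' @examples
#' \donttest{
#' res <- run_pipeline(frequency_table = table1_fixture(),
#'                     out_dir = tempfile("hapnet"))
#' head(res$ages)
#' }
#' @export
run_pipeline <- function(frequency_table = NULL, genotypes = NULL,
                         out_dir, root = NULL,
                         rate = calibration_rate(),
                         params = network_params(),
                         phase = phase_config(),
                         sizes = NULL,
                         tree_mode = "shortest-path",
                         dating_mode = "descendant-rho",
                         seed = 1L) {
  if (is.null(frequency_table) == is.null(genotypes)) {
    stop("supply exactly one of frequency_table or genotypes")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  site_map <- params$site_map
  if (is.null(root)) root <- paste(rep("-", length(site_map)), collapse = "")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  em <- NULL
  if (!is.null(genotypes)) {
    g <- stage("read-genotypes", {
      if (is.character(genotypes)) read_genotypes(genotypes, site_map)
      else genotypes
    })
    em <- stage("em-phase", {
      cfg <- phase; cfg$seed <- as.integer(seed)
      em_estimate(g, cfg, site_map)
    })
    # nominal 100 chromosomes when no count accompanies EM frequencies
    pooled <- data.frame(label = em$frequencies$pattern,
                         pattern = em$frequencies$pattern,
                         count = em$frequencies$frequency * 100,
                         frequency = em$frequencies$frequency,
                         stringsAsFactors = FALSE)
  } else {
    ft <- stage("read-frequencies", {
      if (is.character(frequency_table)) {
        load_frequency_table(frequency_table, site_map)
      } else frequency_table
    })
    pooled <- stage("pool-populations", pool_populations(ft, sizes))
  }

  freq_path <- file.path(out_dir, "frequencies.tsv")
  utils::write.table(pooled, freq_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  net <- stage("mj-network", {
    mj_construct(data.frame(label = pooled$label, pattern = pooled$pattern,
                            weight = pooled$count,
                            stringsAsFactors = FALSE), params)
  })
  net_paths <- stage("export-network", {
    c(tsv = export_network(net, file.path(out_dir, "network.tsv"), "tsv"),
      dot = export_network(net, file.path(out_dir, "network.dot"), "dot"),
      graphml = export_network(net, file.path(out_dir, "network.graphml"),
                               "graphml"))
  })

  tree <- stage("extract-tree", extract_tree(net, root, tree_mode))
  ages <- stage("rho-dating", date_all_nodes(tree, rate, dating_mode))
  ages_path <- file.path(out_dir, "ages.tsv")
  con <- file(ages_path, "w")
  writeLines(sprintf("# root=%s rate=%g mode=%s tree_mode=%s",
                     root, as.numeric(rate), dating_mode, tree_mode), con)
  utils::write.table(ages, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  manifest <- list(
    package = "hapnet",
    version = as.character(utils::packageVersion("hapnet")),
    seed = as.integer(seed),
    root = root,
    rate_years_per_mutation = as.numeric(rate),
    epsilon = params$epsilon,
    site_weights = params$weights,
    sites = as.character(site_map),
    tree_mode = tree_mode,
    dating_mode = dating_mode,
    input = if (is.null(genotypes)) "frequency_table" else "genotypes",
    pooling_sizes = if (is.null(sizes)) "equal (assumed; none supplied)" else sizes,
    em = if (!is.null(em)) list(loglik = em$loglik, iterations = em$iterations,
                                converged = em$converged) else NULL,
    n_nodes = nrow(net$nodes), n_sampled = sum(net$nodes$sampled),
    n_median_vectors = sum(!net$nodes$sampled), n_edges = nrow(net$edges),
    outputs = c("frequencies.tsv", "ages.tsv", basename(unname(net_paths)),
                "manifest.json"))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(pooled = pooled, em = em, network = net, tree = tree,
                 ages = ages,
                 paths = c(frequencies = freq_path, net_paths,
                           ages = ages_path, manifest = manifest_path)))
}
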