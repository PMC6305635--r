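#' Build a haplotype frequency table
#'
#' A frequency table holds one row per distinct haplotype and one relative
#' frequency column per population, the layout in which RFLP haplotype
#' surveys are published. Columns are validated to sum to 1 within a
#' tolerance that accommodates the 3--4 significant digits such tables are
#' printed with; all-zero columns (population not typed for this haplotype
#' set) are permitted and skipped.
#'
#' @param labels Character vector of haplotype labels.
#' @param patterns Character vector of plus/minus patterns (any accepted
#'   spelling; stored in compact ASCII).
#' @param values Numeric matrix, rows = haplotypes, columns = populations.
#' @param site_map Site map fixing pattern length.
#' @param sum_tol Allowed deviation of a nonzero column sum from 1
#'   (default 0.005).
#' @return A `data.frame` of class `freq_table` with columns `label`,
#'   `pattern`, then one column per population; the site map is kept in the
#'   `site_map` attribute.
#' @export
frequency_table <- function(labels, patterns, values,
                            site_map = beta_globin_sites(),
                            sum_tol = 0.005) {
  patterns <- .canon(patterns, site_map)
  values <- as.matrix(values)
  if (length(labels) != length(patterns) || nrow(values) != length(patterns)) {
    stop("labels, patterns and value rows must align")
  }
  if (anyDuplicated(patterns)) {
    stop("duplicate haplotype pattern(s): ",
         paste(unique(patterns[duplicated(patterns)]), collapse = ", "))
  }
  if (any(values < 0 | values > 1)) stop("frequencies must lie in [0, 1]")
  sums <- colSums(values)
  bad <- which(sums > 0 & abs(sums - 1) > sum_tol)
  if (length(bad)) {
    stop("population column(s) do not sum to 1 within ", sum_tol, ": ",
         paste(sprintf("%s (%.4f)", colnames(values)[bad], sums[bad]),
               collapse = ", "))
  }
  out <- data.frame(label = as.character(labels), pattern = patterns,
                    values, check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "site_map") <- site_map
  class(out) <- c("freq_table", "data.frame")
  out
}

#' Read a haplotype frequency table from TSV
#'
#' Expects columns `label`, `pattern`, then one numeric column per
#' population. The pattern field may be compact (`-++-+++`) or spaced, with
#' Unicode or ASCII minus signs.
#'
#' @param path Path to a tab-separated file.
#' @inheritParams frequency_table
#' @return A validated `freq_table`.
#' @seealso [table1_fixture()] for the packaged world-population table.
#' @export
load_frequency_table <- function(path, site_map = beta_globin_sites(),
                                 sum_tol = 0.005) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 3L || !all(c("label", "pattern") %in% names(raw)[1:2])) {
    stop("expected columns: label, pattern, then population columns")
  }
  pops <- setdiff(names(raw), c("label", "pattern"))
  vals <- as.matrix(raw[, pops, drop = FALSE])
  storage.mode(vals) <- "double"
  frequency_table(raw$label, raw$pattern, vals, site_map, sum_tol)
}

#' Write a frequency table as TSV
#'
#' Patterns are emitted in compact ASCII so the file round-trips through
#' [load_frequency_table()] value-identically.
#'
#' @param ft A `freq_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(ft, path) {
  utils::write.table(as.data.frame(ft), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Population names of a frequency table
#' @param ft A `freq_table`.
#' @return Character vector of population column names.
#' @export
populations <- function(ft) setdiff(names(ft), c("label", "pattern"))

#' Published world-population haplotype frequency table
#'
#' The 21-haplotype x 8-population table of beta-globin gene-cluster RFLP
#' haplotype frequencies observed in carriers of the Hb D-Los Angeles
#' variant (Turkey, Iran, India, Thailand, Italia, Holland, Belgium,
#' Mexico), shipped verbatim as a plain-text fixture. Column sums deviate
#' from 1 by up to ~3e-4 because the source reports 3--4 significant digits.
#'
#' @return A `freq_table` with 21 rows and 8 population columns.
#' @examples
#' ft <- table1_fixture()
#' nrow(ft)
#' @export
table1_fixture <- function() {
  load_frequency_table(system.file("extdata", "table1_world.tsv",
                                   package = "hapnet", mustWork = TRUE))
}

#' Published haplotype age table
#'
#' The published age estimates for the same 21 haplotypes, rooted at the
#' ancestral all-minus haplotype (HAP10): years, year-scale SD, rho
#' statistic (mutational units) and sigma SD. The ancestral row carries NA
#' ages. Shipped as a plain-text fixture; used to check rate-calibration
#' conversions (years = rho x years-per-mutation).
#'
#' @return A `data.frame` with columns `label`, `pattern`, `years`,
#'   `years_sd`, `rho`, `sigma`.
#' @export
table2_fixture <- function() {
  utils::read.delim(system.file("extdata", "table2_ages.tsv",
                                package = "hapnet", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
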