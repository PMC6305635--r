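#' Unphased diploid genotype matrices
#'
#' Genotypes are held as an integer matrix with one row per individual and
#' one column per restriction site; each cell counts copies of the `+`
#' allele (0, 1 or 2), with `NA` for a missing call. Gametic phase is not
#' represented: a row says how many `+` alleles an individual carries at
#' each site, not which chromosome they sit on.
#'
#' @param x Matrix (or coercible) of 0/1/2/NA allele counts.
#' @param site_map Site map; must match the column count.
#' @return An integer matrix of class `genotype_matrix`.
#' @export
genotype_matrix <- function(x, site_map = beta_globin_sites()) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (ncol(x) != length(site_map)) {
    stop(sprintf("genotypes have %d sites, site map has %d",
                 ncol(x), length(site_map)))
  }
  if (!all(x %in% c(0L, 1L, 2L, NA))) {
    stop("genotype values must be 0, 1, 2 or NA")
  }
  colnames(x) <- as.character(site_map)
  if (is.null(rownames(x)) && nrow(x) > 0L) {
    rownames(x) <- paste0("ind", seq_len(nrow(x)))
  }
  class(x) <- c("genotype_matrix", class(x))
  x
}

#' Read unphased genotypes from TSV
#'
#' Expects a column `individual` followed by one column per site with
#' values `+/+`, `+/-` (or `-/+`), `-/-`, or `./.` for missing.
#'
#' @param path Path to a tab-separated genotype file.
#' @param site_map Site map naming and ordering the site columns.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, site_map = beta_globin_sites()) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (names(raw)[1] != "individual") stop("first column must be 'individual'")
  if (ncol(raw) - 1L != length(site_map)) {
    stop("site column count does not match the site map")
  }
  code <- function(v) {
    v <- gsub("−", "-", v)
    out <- rep(NA_integer_, length(v))
    out[v == "+/+"] <- 2L
    out[v %in% c("+/-", "-/+")] <- 1L
    out[v == "-/-"] <- 0L
    bad <- !(v %in% c("+/+", "+/-", "-/+", "-/-", "./."))
    if (any(bad)) stop("invalid genotype value(s): ",
                       paste(unique(v[bad]), collapse = ", "))
    out
  }
  m <- vapply(raw[-1], code, integer(nrow(raw)))
  if (nrow(raw) == 1L) m <- matrix(m, nrow = 1L)
  rownames(m) <- raw$individual
  genotype_matrix(m, site_map)
}

#' Write unphased genotypes as TSV
#' @param g A `genotype_matrix`.
#' @param path Output path.
#' @param header_comment Optional character vector written as leading
#'   `#`-comment lines (e.g. a simulation seed).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, header_comment = NULL) {
  sym <- function(v) {
    out <- rep("./.", length(v))
    out[!is.na(v) & v == 2L] <- "+/+"
    out[!is.na(v) & v == 1L] <- "+/-"
    out[!is.na(v) & v == 0L] <- "-/-"
    out
  }
  df <- data.frame(individual = rownames(g),
                   apply(unclass(g), 2, sym),
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
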