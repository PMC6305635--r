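#' Restriction-site map for the beta-globin gene cluster
#'
#' The seven polymorphic restriction sites conventionally scored across the
#' beta-globin gene cluster, in their fixed 5' to 3' order. This order defines
#' the index of every position in a haplotype vector; it is never reordered.
#'
#' @param sites Character vector of site labels (enzyme + locus). Defaults to
#'   the classical seven-site beta-globin map.
#' @return A character vector of class `site_map`; its length is the haplotype
#'   length L.
#' @examples
#' beta_globin_sites()
#' @export
beta_globin_sites <- function(sites = c(
  "HincII-5'eps", "HindIII-Ggamma", "HindIII-Agamma",
  "HincII-psibeta", "HincII-3'psibeta", "AvaII-beta", "HinfI-3'beta")) {
  sites <- as.character(sites)
  if (length(sites) < 1L) stop("a site map needs at least one site")
  if (anyDuplicated(sites)) stop("site labels must be unique")
  structure(sites, class = "site_map")
}

#' Parse a presence/absence haplotype pattern
#'
#' Converts the plus/minus notation used for restriction-site haplotypes
#' (e.g. `"- + + - + + +"`) into a binary vector, 1 for `+` (site present,
#' enzyme cuts) and 0 for `-`. The Unicode minus sign (U+2212), the ASCII
#' hyphen, and the digits `0`/`1` are all accepted; whitespace is ignored.
#'
#' @param text Pattern string with exactly `length(site_map)` symbols.
#' @param site_map A [beta_globin_sites()] site map fixing the haplotype
#'   length and site order.
#' @param label Optional haplotype label (e.g. `"HAP6"`) attached as the
#'   vector's `label` attribute.
#' @return Integer vector of 0/1 states, one per site.
#' @seealso [format_haplotype()] for the inverse.
#' @examples
#' parse_haplotype("- + + - + + +")
#' parse_haplotype("0110111")
#' @export
parse_haplotype <- function(text, site_map = beta_globin_sites(), label = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(gsub("[[:space:] ]+", "", text), "")[[1]]
  L <- length(site_map)
  if (length(chars) != L) {
    stop(sprintf("pattern '%s' has %d symbols, expected %d", text,
                 length(chars), L))
  }
  states <- integer(L)
  for (i in seq_len(L)) {
    states[i] <- switch(chars[i],
      "+" = 1L, "1" = 1L,
      "-" = 0L, "−" = 0L, "0" = 0L,
      stop(sprintf("invalid symbol '%s' at position %d of pattern '%s'",
                   chars[i], i, text)))
  }
  names(states) <- as.character(site_map)
  if (!is.null(label)) attr(states, "label") <- label
  states
}

#' Format a haplotype as a plus/minus pattern
#'
#' Always emits ASCII `+`/`-` regardless of the symbols parsed on input.
#'
#' @param states Integer 0/1 vector (a parsed haplotype).
#' @param collapse Separator between symbols; `""` gives the compact form
#'   used in file formats, `" "` the spaced display form.
#' @return A single pattern string.
#' @examples
#' format_haplotype(parse_haplotype("0110111"))
#' @export
format_haplotype <- function(states, collapse = "") {
  if (!all(states %in% c(0L, 1L))) stop("haplotype states must be 0 or 1")
  paste(ifelse(states == 1L, "+", "-"), collapse = collapse)
}

## canonical compact ASCII key for any pattern spelling; used as node/table id
.canon <- function(text, site_map = beta_globin_sites()) {
  vapply(text, function(s) format_haplotype(parse_haplotype(s, site_map)),
         character(1), USE.NAMES = FALSE)
}

#' Hamming distance between two haplotypes
#'
#' The number of restriction sites at which two haplotypes differ, i.e. the
#' minimum number of single-site mutations separating them. This is the edge
#' length (under unit site weights) everywhere in the network machinery.
#'
#' @param a,b Equal-length 0/1 vectors.
#' @return Non-negative integer count of differing positions.
#' @examples
#' hamming_distance(parse_haplotype("+----++"), parse_haplotype("-------"))
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("haplotype lengths differ (%d vs %d)", length(a), length(b)))
  }
  sum(a != b)
}

## Locale-independent ordering of compact patterns: '+' sorts before '-'
## (byte order), via a 0/1 digit key and radix sort. Every tie-prone step
## in the package orders patterns this way so output is identical across
## locales.
.pkey <- function(x) chartr("+-", "01", x)
.psort <- function(x) x[order(.pkey(x), method = "radix")]

## weighted Hamming distance on compact pattern strings
.wdist <- function(pa, pb, weights) {
  a <- strsplit(pa, "")[[1]]
  b <- strsplit(pb, "")[[1]]
  sum(weights[a != b])
}
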