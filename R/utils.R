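#' Normalize chromosome names
#'
#' Strips a case-insensitive \code{"chr"} prefix so that mixed dialects
#' ("16", "Chr16", "chr16") compare equal throughout the package.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalizeChrom(c("Chr16", "chr2", "16", "X"))
normalizeChrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}

#' Read a chromosome-length table
#'
#' Two-column TSV (chromosome, length in bp), no header required; a header
#' line whose second field is non-numeric is skipped. Chromosome names are
#' normalized with [normalizeChrom()]. Row order defines the canonical
#' chromosome sort order used for variant tables.
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of chromosome lengths, in file order.
#' @export
readChromTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "character"))
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df$length[1]))))
    df <- df[-1, , drop = FALSE]
  len <- as.numeric(df$length)
  if (anyNA(len) || any(len <= 0))
    stop("chromosome table: lengths must be positive numbers")
  stats::setNames(len, normalizeChrom(df$chrom))
}

# Canonical variant ordering: chromosome per the provided order (unknown
# chromosomes after known ones, alphabetically), then pos, ref, alt.
variantOrder <- function(chrom, pos, ref, alt, chromOrder = NULL) {
  chrom <- normalizeChrom(chrom)
  if (is.null(chromOrder) || !length(chromOrder)) {
    ckey <- chrom
  } else {
    idx <- match(chrom, normalizeChrom(chromOrder))
    idx[is.na(idx)] <- length(chromOrder) + 1L
    ckey <- sprintf("%09d%s", idx, chrom)
  }
  order(ckey, pos, ref, alt, method = "radix")
}

#' Convert genomic ranges to BED coordinates
#'
#' The single point where the package's internal 1-based closed interval
#' convention (GRanges) is converted to BED's 0-based half-open convention.
#'
#' @param gr A [GenomicRanges::GRanges] object.
#' @return A `data.frame` with columns `chrom`, `start` (0-based),
#'   `end` (exclusive), ready for BED export.
#' @export
grangesToBed <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Format a fraction as a percentage at two significant figures
#'
#' @param frac Numeric vector of fractions in \[0, 1\].
#' @return Character vector like `"0.61%"`, `"2.7%"`, `"0%"`.
#' @export
#' @examples
#' percentString(c(71 / 11712, 0))
percentString <- function(frac) {
  pct <- signif(100 * frac, 2)
  paste0(vapply(pct, function(p) format(p, scientific = FALSE, trim = TRUE),
                character(1)), "%")
}

#' Path to the bundled approximate cattle autosome table
#'
#' A convenience chromosome-length table for the 29 cattle autosomes with
#' lengths rounded to the 0.1-Mb scale (synthetic approximation, not an
#' assembly index). Suitable as an F_ROH denominator for demonstration
#' and simulation; analyses of real data should supply the exact
#' chromosome lengths of their reference assembly.
#'
#' @return Path to a two-column TSV readable by [readChromTable()].
#' @export
#' @examples
#' head(readChromTable(cattleAutosomesPath()))
cattleAutosomesPath <- function() {
  system.file("extdata", "cattle_autosomes_synthetic.tsv",
              package = "moiscan", mustWork = TRUE)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
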