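# Runs of homozygosity: consecutive-runs detection, shared regions across
# cases, and the genomic inbreeding coefficient F_ROH.
#
# Intervals are GRanges (1-based, closed) internally; conversion to BED's
# 0-based half-open convention happens only in grangesToBed().

#' ROH detection parameters (consecutive-runs method)
#'
#' @param min_snp Minimum number of homozygous markers in a run
#'   (default 20).
#' @param min_length Minimum run length in bp, first to last homozygous
#'   marker (default 50,000).
#' @param max_gap Maximum gap between consecutive markers inside a run,
#'   in bp (default 1,000,000).
#' @param max_opposite Maximum heterozygous calls tolerated inside a run
#'   (default 1).
#' @param max_missing Maximum missing calls tolerated inside a run
#'   (default 1).
#' @return Named list of class `moiscan_roh_params`.
#' @export
rohParams <- function(min_snp = 20, min_length = 50000, max_gap = 1e6,
                      max_opposite = 1, max_missing = 1) {
  stopifnot(min_snp >= 0, min_length > 0, max_gap >= 0,
            max_opposite >= 0, max_missing >= 0)
  structure(list(min_snp = min_snp, min_length = min_length,
                 max_gap = max_gap, max_opposite = max_opposite,
                 max_missing = max_missing), class = "moiscan_roh_params")
}

#' Extract a per-sample genotype track from a VariantTable
#'
#' @param x A [VariantTable-class].
#' @param sample Sample id.
#' @param stride Keep every `stride`-th marker per chromosome (default 1:
#'   all markers). Downsampling bounds runtime on dense WGS marker sets.
#' @return `data.frame` with columns `chrom`, `pos`, `geno`
#'   (0/1/2/NA), sorted by (chrom, pos).
#' @export
genotypeTrack <- function(x, sample, stride = 1L) {
  if (!sample %in% sampleIds(x)) stop("unknown sample: ", sample)
  v <- x@variants
  df <- data.frame(chrom = v$chrom, pos = v$pos, geno = x@geno[, sample],
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[, c("chrom", "pos")]), , drop = FALSE]
  if (stride > 1L) {
    keep <- unlist(lapply(split(seq_len(nrow(df)), df$chrom), function(i)
      i[seq(1L, length(i), by = stride)]), use.names = FALSE)
    df <- df[sort(keep), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Detect runs of homozygosity (consecutive-runs method)
#'
#' Scans each chromosome's ordered marker track for maximal runs of
#' consecutive homozygous calls (HOM_REF or HOM_ALT), tolerating up to
#' `max_opposite` heterozygous and `max_missing` missing calls per run
#' and inter-marker gaps up to `max_gap`. Run boundaries are trimmed to
#' the first and last homozygous marker. Runs are then filtered to
#' `min_snp` homozygous markers and `min_length` bp. Scanning is
#' left-greedy: a run starts at the earliest eligible homozygous marker
#' and extends as far right as the constraints allow; the scan resumes
#' after the constraint-violating marker, so emitted segments are
#' pairwise disjoint per (sample, chromosome).
#'
#' @param track Marker track as returned by [genotypeTrack()]: a
#'   `data.frame` with `chrom`, `pos` (sorted, unique per chromosome;
#'   hard error otherwise) and `geno` (0/1/2/NA).
#' @param params A [rohParams()].
#' @param sample_id Sample label stored on the output segments.
#' @return A [GenomicRanges::GRanges] of ROH segments with metadata
#'   columns `sample_id`, `n_snp` (homozygous markers), `n_het_inside`,
#'   `n_missing_inside`.
#' @export
detectRohConsecutive <- function(track, params = rohParams(),
                                 sample_id = NA_character_) {
  stopifnot(all(c("chrom", "pos", "geno") %in% names(track)))
  emptyGr <- GenomicRanges::GRanges(
    seqnames = character(0), ranges = IRanges::IRanges(),
    sample_id = character(0), n_snp = integer(0),
    n_het_inside = integer(0), n_missing_inside = integer(0))
  if (!nrow(track)) return(emptyGr)
  byChrom <- split(track, factor(track$chrom, levels = unique(track$chrom)))
  segs <- lapply(byChrom, function(tr) {
    pos <- tr$pos
    if (is.unsorted(pos, strictly = TRUE))
      stop("marker track must be sorted with unique positions per ",
           "chromosome (", tr$chrom[1], ")")
    g <- tr$geno
    isHom <- !is.na(g) & g != 1L
    isHet <- !is.na(g) & g == 1L
    isMiss <- is.na(g)
    n <- length(pos)
    out <- list()
    i <- 1L
    while (i <= n) {
      if (!isHom[i]) { i <- i + 1L; next }
      het <- 0L; miss <- 0L; lastHom <- i
      k <- i + 1L
      while (k <= n) {
        if (pos[k] - pos[k - 1L] > params$max_gap) break
        if (isHet[k]) {
          if (het + 1L > params$max_opposite) break
          het <- het + 1L
        } else if (isMiss[k]) {
          if (miss + 1L > params$max_missing) break
          miss <- miss + 1L
        } else lastHom <- k
        k <- k + 1L
      }
      nHom <- sum(isHom[i:lastHom])
      if (nHom >= params$min_snp &&
          pos[lastHom] - pos[i] + 1L >= params$min_length) {
        out[[length(out) + 1L]] <- c(pos[i], pos[lastHom], nHom,
                                     sum(isHet[i:lastHom]),
                                     sum(isMiss[i:lastHom]))
      }
      i <- k
    }
    if (!length(out)) return(NULL)
    m <- do.call(rbind, out)
    GenomicRanges::GRanges(
      seqnames = tr$chrom[1],
      ranges = IRanges::IRanges(start = m[, 1], end = m[, 2]),
      sample_id = sample_id, n_snp = as.integer(m[, 3]),
      n_het_inside = as.integer(m[, 4]),
      n_missing_inside = as.integer(m[, 5]))
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs)) return(emptyGr)
  suppressWarnings(do.call(c, unname(segs)))
}

# Put a list of GRanges on a common seqlevel universe so set operations
# do not warn about differing seqlevels.
harmonizeSeqlevels <- function(grl) {
  lv <- unique(unlist(lapply(grl, GenomeInfoDb::seqlevels)))
  lapply(grl, function(g) {
    GenomeInfoDb::seqlevels(g) <- lv
    g
  })
}

#' Shared homozygous regions across cases
#'
#' Intersects the ROH segment unions of all cases and keeps regions of at
#' least `min_shared_length` bp. Every case must contribute a (possibly
#' empty) segment list; zero cases is a hard error. The intersection is
#' commutative and associative in case order.
#'
#' @param roh_by_case Named list of [GenomicRanges::GRanges], one per
#'   case, as returned by [detectRohConsecutive()].
#' @param min_shared_length Minimum shared region length in bp
#'   (default 10,000: kb-sized regions).
#' @return A list with `regions` (a `GRanges` with a `supporting_cases`
#'   metadata column) and `total_bp` (sum of region widths).
#' @export
sharedHomozygousRegions <- function(roh_by_case, min_shared_length = 10000) {
  if (!length(roh_by_case)) stop("at least one case required")
  grl <- harmonizeSeqlevels(lapply(roh_by_case, GenomicRanges::reduce))
  shared <- Reduce(GenomicRanges::intersect, grl)
  shared <- shared[GenomicRanges::width(shared) >= min_shared_length]
  cases <- paste(names(roh_by_case), collapse = ",")
  if (length(shared))
    S4Vectors::mcols(shared)$supporting_cases <- cases
  else
    S4Vectors::mcols(shared)$supporting_cases <- character(0)
  list(regions = shared, total_bp = sum(GenomicRanges::width(shared)))
}

#' Genomic inbreeding coefficient F_ROH
#'
#' F_ROH(sample) = sum of autosomal ROH segment lengths / total autosome
#' length, with the denominator taken from the supplied chromosome-length
#' table. A ROH on a chromosome absent from the table is a hard error.
#'
#' @param roh_by_sample Named list of [GenomicRanges::GRanges] per sample.
#' @param chrom_lengths Named numeric vector of autosome lengths in bp
#'   (see [readChromTable()]).
#' @param group Sample ids over which the cohort mean and sample standard
#'   deviation are computed (default: all samples supplied).
#' @return A list with `per_sample` (`data.frame` of `sample`, `froh`),
#'   `mean` and `sd` over `group`.
#' @export
genomicInbreeding <- function(roh_by_sample, chrom_lengths,
                              group = names(roh_by_sample)) {
  total <- sum(chrom_lengths)
  froh <- vapply(roh_by_sample, function(gr) {
    chr <- normalizeChrom(as.character(GenomicRanges::seqnames(gr)))
    bad <- setdiff(unique(chr), names(chrom_lengths))
    if (length(bad))
      stop("ROH on chromosome(s) absent from the length table: ",
           paste(bad, collapse = ", "))
    sum(GenomicRanges::width(GenomicRanges::reduce(gr))) / total
  }, numeric(1))
  per <- data.frame(sample = names(roh_by_sample), froh = unname(froh),
                    stringsAsFactors = FALSE)
  sel <- per$froh[per$sample %in% group]
  list(per_sample = per, mean = mean(sel),
       sd = if (length(sel) > 1) stats::sd(sel) else NA_real_)
}

#' Export ROH segments or shared regions as BED
#'
#' BED uses 0-based half-open coordinates; conversion is centralized in
#' [grangesToBed()]. A fourth name column carries the sample id when
#' present.
#'
#' @param gr A [GenomicRanges::GRanges].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
exportRohBed <- function(gr, path) {
  bed <- grangesToBed(gr)
  mc <- S4Vectors::mcols(gr)
  if ("sample_id" %in% names(mc)) bed$name <- mc$sample_id
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
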