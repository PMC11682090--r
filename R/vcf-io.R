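# VCF input/output and normalization.
#
# Parsing of VCF files is delegated to vcfR; normalization (multiallelic
# splitting, genotype-class mapping, ANN parsing) is done here because its
# exact semantics drive every downstream filter.

#' Parse a VCF ANN INFO sub-field
#'
#' Parses the standard pipe-delimited, comma-separated functional
#' annotation sub-field ("Variant annotations in VCF format"). Ampersand
#' -joined effect terms are split into separate terms. HGVS strings are
#' preserved verbatim, never validated: published annotations occasionally
#' carry internally inconsistent genomic/cDNA notations and the parser must
#' not second-guess them.
#'
#' @param ann_value Raw ANN string (everything after `ANN=`), or `""`/`NA`.
#' @return `data.frame` with one row per annotation entry: `allele`,
#'   `gene_symbol`, `impact`, `hgvs_c`, `hgvs_p`, and a list-column
#'   `effect_terms` of character vectors. Zero rows for empty input.
#'   Entries with fewer than the 4 mandatory fields
#'   (allele, annotation, impact, gene name) are skipped with a warning.
#' @export
#' @examples
#' parseAnnField(
#'   "C|missense_variant|MODERATE|TOR3A|g1|transcript|t1|Coding|2/5|c.58G>T|p.Phe111Leu")
parseAnnField <- function(ann_value) {
  empty <- data.frame(allele = character(0), gene_symbol = character(0),
                      impact = character(0), hgvs_c = character(0),
                      hgvs_p = character(0), stringsAsFactors = FALSE)
  empty$effect_terms <- list()
  if (is.null(ann_value) || length(ann_value) == 0 || is.na(ann_value) ||
      !nzchar(ann_value))
    return(empty)
  entries <- strsplit(ann_value, ",", fixed = TRUE)[[1]]
  fields <- strsplit(entries, "|", fixed = TRUE)
  keep <- lengths(fields) >= 4L & vapply(fields, function(f)
    nzchar(f[2]), logical(1))
  if (any(!keep))
    warning(sum(!keep), " ANN entr(y/ies) with fewer than 4 fields skipped")
  fields <- fields[keep]
  if (!length(fields)) return(empty)
  pick <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else "", character(1))
  out <- data.frame(allele = pick(1), gene_symbol = pick(4),
                    impact = pick(3), hgvs_c = pick(10), hgvs_p = pick(11),
                    stringsAsFactors = FALSE)
  out$effect_terms <- strsplit(pick(2), "&", fixed = TRUE)
  out
}

# Map raw GT strings to genotype-class codes for the record carrying alt
# allele index `altIndex` (1-based among the site's alts).
#   both alleles == altIndex          -> 2 (HOM_ALT)
#   one allele == altIndex, other 0   -> 1 (HET)
#   both alleles 0                    -> 0 (HOM_REF)
#   anything else                     -> NA (MISSING): half-missing,
#     haploid/polyploid, out-of-range indices, and genotypes carrying a
#     different alt allele.
# Phased "|" and unphased "/" separators are equivalent (zygosity only).
classifyGenotypes <- function(gt, altIndex, nAlt) {
  out <- rep(NA_integer_, length(gt))
  gt[is.na(gt)] <- "."
  parts <- strsplit(gt, "[/|]")
  ok <- lengths(parts) == 2L
  a <- rep(NA_integer_, length(gt))
  b <- a
  a[ok] <- suppressWarnings(as.integer(vapply(parts[ok], `[`, "", 1L)))
  b[ok] <- suppressWarnings(as.integer(vapply(parts[ok], `[`, "", 2L)))
  bad_range <- !is.na(a) & !is.na(b) & (a > nAlt | b > nAlt | a < 0 | b < 0)
  a[bad_range] <- NA_integer_
  b[bad_range] <- NA_integer_
  known <- !is.na(a) & !is.na(b)
  out[known & a == altIndex & b == altIndex] <- 2L
  out[known & ((a == altIndex & b == 0L) | (a == 0L & b == altIndex))] <- 1L
  out[known & a == 0L & b == 0L] <- 0L
  out
}

#' Split a raw (possibly multiallelic) site into biallelic records
#'
#' For a site with k alternate alleles, emits one normalized record per
#' non-symbolic alt. For the record of alt j, a sample genotype is HOM_ALT
#' iff both alleles are j, HET iff exactly one allele is j and the other is
#' reference, HOM_REF iff both alleles are reference, and MISSING otherwise
#' (including genotypes carrying a different alt allele). ANN entries are
#' assigned to the record whose alt allele matches the entry's allele
#' field; entries matching no alt are kept on every record.
#'
#' @param site A list with elements `chrom`, `pos`, `ref`,
#'   `alt` (character vector of alt alleles), `qual_label`, `ann` (raw ANN
#'   string or `""`), and `gt` (named character vector of raw GT strings
#'   per sample).
#' @return A list of per-alt records; each record is a list with the same
#'   fields but a single `alt` and an integer `geno` vector
#'   (0/1/2/NA per sample).
#' @export
splitMultiallelic <- function(site) {
  alts <- site$alt
  symbolic <- !grepl("^[ACGT]+$", alts)
  if (any(symbolic)) {
    warning("dropping ", sum(symbolic), " symbolic alt allele(s) at ",
            site$chrom, ":", site$pos)
  }
  annEntries <- if (nzchar(site$ann %||% ""))
    strsplit(site$ann, ",", fixed = TRUE)[[1]] else character(0)
  annAllele <- vapply(annEntries, function(e)
    strsplit(e, "|", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  unmatched <- annEntries[!annAllele %in% alts]
  lapply(which(!symbolic), function(j) {
    own <- annEntries[annAllele == alts[j]]
    list(chrom = site$chrom, pos = site$pos, ref = site$ref,
         alt = alts[j], qual_label = site$qual_label,
         ann = paste(c(own, unmatched), collapse = ","),
         geno = stats::setNames(
           classifyGenotypes(site$gt, j, length(alts)), names(site$gt)))
  })
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Read an annotated multi-sample VCF into a VariantTable
#'
#' Reads a VCF (plain or bgzipped) with per-sample GT fields, splits
#' multiallelic sites, maps genotypes to zygosity classes, and maps the
#' FILTER column to a quality label (`PASS` -> PASS, `.` -> UNLABELED,
#' anything else -> FAIL). Chromosome names are normalized (a
#' case-insensitive `chr` prefix is stripped) and records are sorted by
#' (chromosome, position, ref, alt).
#'
#' @param vcf_path Path to the VCF file.
#' @param manifest A [CohortManifest-class]; every manifest sample must be
#'   present in the VCF header (hard error naming the first absent one).
#'   Genotypes are read for manifest samples only, in manifest order.
#' @param chromOrder Optional canonical chromosome order (e.g.
#'   `names(readChromTable(...))`). Defaults to numeric-aware sorting of
#'   the chromosomes observed.
#' @return A [VariantTable-class].
#' @export
readAnnotatedVcf <- function(vcf_path, manifest, chromOrder = NULL) {
  stopifnot(methods::is(manifest, "CohortManifest"))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  hdr_samples <- colnames(vcf@gt)[-1]
  want <- manifestTable(manifest)$sample
  absent <- setdiff(want, hdr_samples)
  if (length(absent))
    stop("manifest sample(s) absent from VCF header: ",
         paste(absent, collapse = ", "))
  n <- nrow(vcf@fix)
  if (is.null(n) || n == 0) {
    v <- data.frame(chrom = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    qual_label = character(0), ann = character(0),
                    stringsAsFactors = FALSE)
    g <- matrix(integer(0), nrow = 0, ncol = length(want),
                dimnames = list(NULL, want))
    return(VariantTable(v, g, chromOrder %||% character(0)))
  }
  fix <- vcf@fix
  gtRaw <- vcfR::extract.gt(vcf, element = "GT")
  gtRaw <- gtRaw[, want, drop = FALSE]
  if (is.null(dim(gtRaw))) gtRaw <- matrix(gtRaw, nrow = n,
                                           dimnames = list(NULL, want))
  ann <- vcfR::extract.info(vcf, element = "ANN")
  if (is.null(ann)) ann <- rep(NA_character_, n)
  filt <- fix[, "FILTER"]
  qual <- ifelse(is.na(filt) | filt == ".", "UNLABELED",
                 ifelse(filt == "PASS", "PASS", "FAIL"))

  # malformed GT summary: anything other than "." that is not two
  # [/|]-separated allele fields becomes MISSING with one warning
  uAll <- unique(as.vector(gtRaw))
  uAll[is.na(uAll)] <- "."
  badShape <- uAll[lengths(strsplit(uAll, "[/|]")) != 2L & uAll != "."]
  if (length(badShape)) {
    cnt <- sum(matrix(ifelse(is.na(gtRaw), ".", gtRaw) %in% badShape,
                      nrow = n))
    warning(cnt, " malformed GT value(s) set to MISSING")
  }

  isMulti <- grepl(",", fix[, "ALT"], fixed = TRUE)
  okBi <- !isMulti & grepl("^[ACGT]+$", fix[, "ALT"]) &
    grepl("^[ACGT]+$", fix[, "REF"])
  if (any(!isMulti & !okBi))
    warning("dropping ", sum(!isMulti & !okBi),
            " site(s) with symbolic or non-ACGT alleles")

  # biallelic fast path: classify the few unique GT strings once
  bi <- which(okBi)
  vBi <- NULL
  gBi <- NULL
  if (length(bi)) {
    gtBi <- gtRaw[bi, , drop = FALSE]
    u <- unique(as.vector(gtBi))
    code <- classifyGenotypes(ifelse(is.na(u), ".", u), 1L, 1L)
    gBi <- matrix(code[match(as.vector(gtBi), u)], nrow = length(bi),
                  dimnames = list(NULL, want))
    vBi <- data.frame(chrom = fix[bi, "CHROM"],
                      pos = as.integer(fix[bi, "POS"]),
                      ref = fix[bi, "REF"], alt = fix[bi, "ALT"],
                      qual_label = qual[bi],
                      ann = ifelse(is.na(ann[bi]), "", ann[bi]),
                      stringsAsFactors = FALSE)
  }

  # multiallelic sites: per-site split
  recs <- list()
  for (i in which(isMulti)) {
    site <- list(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
                 ref = fix[i, "REF"],
                 alt = strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]],
                 qual_label = qual[i], ann = ann[i] %||% "",
                 gt = gtRaw[i, ])
    recs <- c(recs, splitMultiallelic(site))
  }
  dropMultiBadRef <- vapply(recs, function(r)
    !grepl("^[ACGT]+$", r$ref), logical(1))
  if (any(dropMultiBadRef)) {
    warning("dropping ", sum(dropMultiBadRef),
            " split record(s) with non-ACGT REF")
    recs <- recs[!dropMultiBadRef]
  }
  if (length(recs)) {
    vMu <- data.frame(
      chrom = vapply(recs, `[[`, "", "chrom"),
      pos = vapply(recs, `[[`, 0L, "pos"),
      ref = vapply(recs, `[[`, "", "ref"),
      alt = vapply(recs, `[[`, "", "alt"),
      qual_label = vapply(recs, `[[`, "", "qual_label"),
      ann = vapply(recs, `[[`, "", "ann"),
      stringsAsFactors = FALSE)
    gMu <- do.call(rbind, lapply(recs, `[[`, "geno"))
    colnames(gMu) <- want
    v <- rbind(vBi, vMu)
    g <- rbind(gBi, gMu)
  } else {
    v <- vBi
    g <- gBi
  }
  if (is.null(v) || !nrow(v)) {
    v <- data.frame(chrom = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    qual_label = character(0), ann = character(0),
                    stringsAsFactors = FALSE)
    g <- matrix(integer(0), nrow = 0, ncol = length(want),
                dimnames = list(NULL, want))
    return(VariantTable(v, g, chromOrder %||% character(0)))
  }
  if (is.null(chromOrder))
    chromOrder <- defaultChromOrder(unique(normalizeChrom(v$chrom)))
  VariantTable(v, g, chromOrder)
}

# Numeric-aware chromosome ordering: 1, 2, ..., 10 before X, MT etc.
defaultChromOrder <- function(chroms) {
  num <- suppressWarnings(as.numeric(chroms))
  chroms[order(is.na(num), num, chroms)]
}

#' Write a VariantTable as VCF
#'
#' Emits a minimal VCF 4.2 file reproducing the normalized table: one
#' biallelic record per row, genotypes rendered as `0/0`, `0/1`, `1/1` or
#' `./.`, the ANN string in INFO, and the quality label in FILTER
#' (UNLABELED -> `.`). Reading the file back with [readAnnotatedVcf()]
#' yields a field-for-field identical table.
#'
#' @param x A [VariantTable-class].
#' @param path Output path (`.vcf`; plain text).
#' @return `path`, invisibly.
#' @export
writeVariantTableVcf <- function(x, path) {
  v <- x@variants
  g <- x@geno
  gtStr <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
  gtStr[!is.na(g) & g == 0L] <- "0/0"
  gtStr[!is.na(g) & g == 1L] <- "0/1"
  gtStr[!is.na(g) & g == 2L] <- "1/1"
  hdr <- c("##fileformat=VCFv4.2",
           "##FILTER=<ID=FAIL,Description=\"Failed quality label\">",
           paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=",
                  "\"Functional annotations: 'Allele|Annotation|",
                  "Annotation_Impact|Gene_Name|Gene_ID|Feature_Type|",
                  "Feature_ID|Transcript_BioType|Rank|HGVS.c|HGVS.p'\">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  filt <- ifelse(v$qual_label == "UNLABELED", ".",
                 ifelse(v$qual_label == "PASS", "PASS", "FAIL"))
  info <- ifelse(nzchar(v$ann), paste0("ANN=", v$ann), ".")
  body <- if (nrow(v)) {
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", filt, info, "GT",
          apply(gtStr, 1L, paste, collapse = "\t"), sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
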