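# Per-population genotype counts and variant-allele frequencies for a
# target variant, mirroring published occurrence tables
# (Var/Var, Ref/Var, Ref/Ref, allelic frequency per population).

findVariant <- function(x, key) {
  idx <- match(paste(normalizeChrom(key[1]), as.integer(key[2]),
                     key[3], key[4], sep = ":"), variantKeys(x))
  if (is.na(idx))
    stop("variant not found in table: ", paste(key, collapse = ":"))
  idx
}

#' Genotype counts for a variant in one population
#'
#' Counts genotype classes among the samples of one population. MISSING
#' genotypes are counted separately and excluded from frequency
#' denominators.
#'
#' @param x A [VariantTable-class].
#' @param key Variant key: character vector `c(chrom, pos, ref, alt)` or
#'   a single `"chrom:pos:ref:alt"` string. Unknown key is a hard error.
#' @param population Population label.
#' @param manifest A [CohortManifest-class].
#' @return A one-row `data.frame`: `population`, `n_var_var` (HOM_ALT),
#'   `n_ref_var` (HET), `n_ref_ref` (HOM_REF), `n_missing`.
#' @export
genotypeCounts <- function(x, key, population, manifest) {
  if (length(key) == 1L) key <- strsplit(key, ":", fixed = TRUE)[[1]]
  idx <- findVariant(x, key)
  m <- manifestTable(manifest)
  samples <- intersect(m$sample[m$population == population], sampleIds(x))
  g <- x@geno[idx, samples]
  data.frame(population = population,
             n_var_var = sum(g == 2L, na.rm = TRUE),
             n_ref_var = sum(g == 1L, na.rm = TRUE),
             n_ref_ref = sum(g == 0L, na.rm = TRUE),
             n_missing = sum(is.na(g)),
             stringsAsFactors = FALSE)
}

#' Variant-allele frequency from genotype counts
#'
#' frequency = (2 n_varvar + n_refvar) / (2 (n_varvar + n_refvar +
#' n_refref)). Missing genotypes are excluded from the denominator. The
#' percent string is rendered at two significant figures.
#'
#' @param counts A one-row `data.frame` as returned by
#'   [genotypeCounts()] (columns `n_var_var`, `n_ref_var`, `n_ref_ref`).
#' @return A list with `fraction` (numeric, `NA` when no sample was
#'   genotyped), `percent` (character like `"0.61%"`, `"NA"` when
#'   undefined) and `defined` (logical).
#' @export
#' @examples
#' alleleFrequency(data.frame(n_var_var = 0, n_ref_var = 71,
#'                            n_ref_ref = 5785))
alleleFrequency <- function(counts) {
  denom <- 2 * (counts$n_var_var + counts$n_ref_var + counts$n_ref_ref)
  if (denom == 0)
    return(list(fraction = NA_real_, percent = "NA", defined = FALSE))
  frac <- (2 * counts$n_var_var + counts$n_ref_var) / denom
  list(fraction = frac, percent = percentString(frac), defined = TRUE)
}

#' Population frequency table for a variant
#'
#' One row per population in the manifest: genotype counts plus the
#' allele frequency as fraction and two-significant-figure percent.
#'
#' @inheritParams genotypeCounts
#' @param populations Populations to tabulate (default: all in the
#'   manifest, in manifest order).
#' @return `data.frame` with columns `population`, `n_var_var`,
#'   `n_ref_var`, `n_ref_ref`, `n_missing`, `allele_freq_fraction`,
#'   `allele_freq_percent`.
#' @export
popFreqTable <- function(x, key, manifest,
                         populations = unique(manifestTable(manifest)$population)) {
  rows <- lapply(populations, function(p) {
    cnt <- genotypeCounts(x, key, p, manifest)
    af <- alleleFrequency(cnt)
    cnt$allele_freq_fraction <- af$fraction
    cnt$allele_freq_percent <- af$percent
    cnt
  })
  do.call(rbind, rows)
}

#' Scan for carriers of a variant
#'
#' Lists every sample that is not homozygous reference for the target
#' variant, with its population and genotype class, sorted by population
#' then sample.
#'
#' @inheritParams genotypeCounts
#' @return `data.frame` with columns `sample`, `population`, `genotype`
#'   (HET / HOM_ALT / MISSING).
#' @export
carrierScan <- function(x, key, manifest) {
  if (length(key) == 1L) key <- strsplit(key, ":", fixed = TRUE)[[1]]
  idx <- findVariant(x, key)
  m <- manifestTable(manifest)
  m <- m[m$sample %in% sampleIds(x), , drop = FALSE]
  g <- x@geno[idx, m$sample]
  lab <- ifelse(is.na(g), "MISSING", GT_LEVELS[g + 1L])
  keep <- lab != "HOM_REF"
  out <- data.frame(sample = m$sample[keep],
                    population = m$population[keep],
                    genotype = lab[keep], stringsAsFactors = FALSE)
  out <- out[order(out$population, out$sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}
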