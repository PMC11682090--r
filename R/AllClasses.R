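# Central S4 data containers.
#
# Genotype classes are stored as an integer matrix (variants x samples):
#   0 = HOM_REF, 1 = HET, 2 = HOM_ALT, NA = MISSING.
# For non-missing entries the integer code equals the alternate-allele
# dosage, which the filters exploit.

GT_LEVELS <- c("HOM_REF", "HET", "HOM_ALT")

MOI_LEVELS <- c("RECESSIVE_SHARED", "RECESSIVE_INDIVIDUAL", "DOMINANT_INDIVIDUAL")
STAGE_LEVELS <- c("ALL", "PRIVATE_TIER1", "PROTEIN_CHANGING", "POST_TIER2")
ROLE_LEVELS <- c("CASE", "TIER1_CONTROL", "TIER2_CONTROL")
QUAL_LEVELS <- c("PASS", "FAIL", "UNLABELED")

#' VariantTable: normalized multi-sample variant calls
#'
#' An ordered collection of normalized biallelic variant records.
#' Multiallelic input sites have been split (one record per alternate
#' allele), genotypes are mapped to zygosity classes, and records are
#' sorted by (chromosome, position, ref, alt) with chromosome order taken
#' from the chromosome table supplied at read time.
#'
#' @slot variants `data.frame` with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `qual_label` (PASS/FAIL/UNLABELED) and `ann` (raw
#'   ANN INFO sub-field string, possibly empty).
#' @slot geno Integer matrix, variants x samples; 0 = HOM_REF, 1 = HET,
#'   2 = HOM_ALT, NA = MISSING.
#' @slot chromOrder Character vector giving the canonical chromosome order.
#'
#' @seealso [readAnnotatedVcf()], [writeVariantTableVcf()]
#' @export
setClass("VariantTable",
         representation(variants = "data.frame",
                        geno = "matrix",
                        chromOrder = "character"))

setValidity("VariantTable", function(object) {
  v <- object@variants
  msgs <- character(0)
  need <- c("chrom", "pos", "ref", "alt", "qual_label", "ann")
  if (!all(need %in% names(v)))
    return(paste("variants must have columns:", paste(need, collapse = ", ")))
  if (nrow(v) != nrow(object@geno))
    msgs <- c(msgs, "geno rows must match variant rows")
  if (nrow(v)) {
    if (!all(grepl("^[ACGT]+$", v$ref)) || !all(grepl("^[ACGT]+$", v$alt)))
      msgs <- c(msgs, "ref and alt must be nonempty strings over {A,C,G,T}")
    if (any(grepl(",", v$alt, fixed = TRUE)))
      msgs <- c(msgs, "records must carry exactly one alt allele")
    g <- object@geno
    if (!all(g[!is.na(g)] %in% 0:2))
      msgs <- c(msgs, "genotype codes must be 0, 1, 2 or NA")
    ord <- variantOrder(v$chrom, v$pos, v$ref, v$alt, object@chromOrder)
    if (!identical(ord, seq_len(nrow(v))))
      msgs <- c(msgs, "records must be sorted by (chrom, pos, ref, alt)")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a VariantTable
#'
#' Low-level constructor; most users obtain tables from
#' [readAnnotatedVcf()]. Records are sorted on construction.
#'
#' @param variants `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `qual_label`, `ann`.
#' @param geno Integer genotype-class matrix (variants x samples) with
#'   sample names as column names.
#' @param chromOrder Optional canonical chromosome order.
#' @return A [VariantTable-class] object.
#' @export
VariantTable <- function(variants, geno, chromOrder = character(0)) {
  variants$chrom <- normalizeChrom(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  ord <- variantOrder(variants$chrom, variants$pos, variants$ref,
                      variants$alt, chromOrder)
  variants <- variants[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(variants) <- NULL
  rownames(geno) <- NULL
  methods::new("VariantTable", variants = variants, geno = geno,
               chromOrder = normalizeChrom(chromOrder))
}

#' @describeIn VariantTable-class Number of variant records.
#' @param x,object A `VariantTable`.
#' @export
nVariants <- function(x) nrow(x@variants)

#' Sample names of a VariantTable
#' @param x A [VariantTable-class].
#' @return Character vector of sample ids (column order of the genotype
#'   matrix).
#' @export
sampleIds <- function(x) colnames(x@geno)

#' Genotype-class matrix of a VariantTable
#' @param x A [VariantTable-class].
#' @param labels If `TRUE`, return a character matrix with labels
#'   HOM_REF/HET/HOM_ALT/MISSING instead of integer codes.
#' @return Integer (or character) matrix, variants x samples.
#' @export
genotypeMatrix <- function(x, labels = FALSE) {
  g <- x@geno
  if (!labels) return(g)
  lab <- matrix(GT_LEVELS[g + 1L], nrow = nrow(g), dimnames = dimnames(g))
  lab[is.na(g)] <- "MISSING"
  lab
}

#' Variant site table of a VariantTable
#' @param x A [VariantTable-class].
#' @return The per-record site `data.frame` (chrom, pos, ref, alt,
#'   qual_label, ann).
#' @export
variantInfo <- function(x) x@variants

#' Canonical variant keys
#' @param x A [VariantTable-class].
#' @return Character vector `"chrom:pos:ref:alt"`.
#' @export
variantKeys <- function(x) {
  v <- x@variants
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' Subset a VariantTable by record index
#' @param x A [VariantTable-class].
#' @param i Integer or logical index over records.
#' @return A [VariantTable-class] with the selected records.
#' @export
subsetVariants <- function(x, i) {
  methods::new("VariantTable",
               variants = {
                 v <- x@variants[i, , drop = FALSE]; rownames(v) <- NULL; v
               },
               geno = x@geno[i, , drop = FALSE],
               chromOrder = x@chromOrder)
}

setMethod("show", "VariantTable", function(object) {
  cat("VariantTable with", nVariants(object), "records and",
      ncol(object@geno), "samples\n")
  if (nVariants(object)) {
    v <- object@variants
    cat("  chromosomes:", paste(unique(v$chrom), collapse = ", "), "\n")
    cat("  quality labels:",
        paste(sprintf("%s=%d", names(table(v$qual_label)),
                      as.integer(table(v$qual_label))), collapse = " "), "\n")
  }
})

#' CohortManifest: sample roles and populations
#'
#' Assigns every sample a role (CASE, TIER1_CONTROL, TIER2_CONTROL) and a
#' population label. All filters are evaluated against this frame.
#'
#' @slot samples `data.frame` with columns `sample`, `role`, `population`.
#' @export
setClass("CohortManifest", representation(samples = "data.frame"))

setValidity("CohortManifest", function(object) {
  s <- object@samples
  if (!all(c("sample", "role", "population") %in% names(s)))
    return("manifest needs columns sample, role, population")
  if (anyDuplicated(s$sample))
    return("sample ids must be unique")
  if (!all(s$role %in% ROLE_LEVELS))
    return(paste("roles must be one of", paste(ROLE_LEVELS, collapse = ", ")))
  if (!any(s$role == "CASE"))
    return("manifest must contain at least one CASE")
  TRUE
})

#' Construct a CohortManifest
#'
#' @param sample Character vector of sample ids (unique).
#' @param role Character vector of roles: CASE, TIER1_CONTROL or
#'   TIER2_CONTROL.
#' @param population Character vector of population labels.
#' @return A [CohortManifest-class].
#' @export
CohortManifest <- function(sample, role, population) {
  methods::new("CohortManifest",
               samples = data.frame(sample = as.character(sample),
                                    role = as.character(role),
                                    population = as.character(population),
                                    stringsAsFactors = FALSE))
}

#' @describeIn CohortManifest-class Case sample ids.
#' @param x A `CohortManifest`.
#' @export
caseIds <- function(x) x@samples$sample[x@samples$role == "CASE"]

#' Tier-1 control sample ids
#' @param x A [CohortManifest-class].
#' @export
tier1Ids <- function(x) x@samples$sample[x@samples$role == "TIER1_CONTROL"]

#' Tier-2 control sample ids
#' @param x A [CohortManifest-class].
#' @export
tier2Ids <- function(x) x@samples$sample[x@samples$role == "TIER2_CONTROL"]

#' Manifest as a data.frame
#' @param x A [CohortManifest-class].
#' @export
manifestTable <- function(x) x@samples

setMethod("show", "CohortManifest", function(object) {
  s <- object@samples
  cat("CohortManifest:", nrow(s), "samples (",
      sum(s$role == "CASE"), "cases,",
      sum(s$role == "TIER1_CONTROL"), "tier-1 controls,",
      sum(s$role == "TIER2_CONTROL"), "tier-2 controls )\n")
  cat("  populations:", paste(unique(s$population), collapse = ", "), "\n")
})

#' Read / write a cohort manifest TSV
#'
#' Three-column TSV with header `sample`, `role`, `population`.
#'
#' @param path File path.
#' @return [readCohortManifest()] returns a [CohortManifest-class];
#'   [writeCohortManifest()] returns `path` invisibly.
#' @export
readCohortManifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  CohortManifest(df$sample, df$role, df$population)
}

#' @rdname readCohortManifest
#' @param manifest A [CohortManifest-class].
#' @export
writeCohortManifest <- function(manifest, path) {
  writeTsv(manifest@samples, path)
}

#' CandidateSet: variants surviving a filtering stage
#'
#' The set of variants surviving one stage of an MOI-stratified filter for
#' one case (or for all cases jointly under the shared recessive model).
#'
#' @slot caseId Sample id of the case, or `"ALL"` for the shared
#'   recessive filter.
#' @slot moi One of RECESSIVE_SHARED, RECESSIVE_INDIVIDUAL,
#'   DOMINANT_INDIVIDUAL.
#' @slot stage One of ALL, PRIVATE_TIER1, PROTEIN_CHANGING, POST_TIER2.
#' @slot table [VariantTable-class] holding the surviving records (all
#'   cohort genotype columns retained).
#' @export
setClass("CandidateSet",
         representation(caseId = "character", moi = "character",
                        stage = "character", table = "VariantTable"))

setValidity("CandidateSet", function(object) {
  if (!object@moi %in% MOI_LEVELS) return("invalid moi")
  if (!object@stage %in% STAGE_LEVELS) return("invalid stage")
  TRUE
})

#' @describeIn CandidateSet-class Number of surviving variants.
#' @param x A `CandidateSet`.
#' @export
nCandidates <- function(x) nVariants(x@table)

#' Variant table of a CandidateSet
#' @param x A [CandidateSet-class].
#' @export
candidateTable <- function(x) x@table

#' Stage and MOI accessors for CandidateSet
#' @param x A [CandidateSet-class].
#' @export
candidateStage <- function(x) x@stage

#' @rdname candidateStage
#' @export
candidateMoi <- function(x) x@moi

#' @rdname candidateStage
#' @export
candidateCase <- function(x) x@caseId

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet [case %s, %s, stage %s]: %d variants\n",
              object@caseId, object@moi, object@stage, nCandidates(object)))
})

#' FunnelReport: per-case filtering funnels
#'
#' The machine twin of per-case filtering funnel tables: for each
#' (case, mode of inheritance) the variant counts at the four stages and
#' the candidate gene symbols remaining at the final stage.
#'
#' @slot rows `data.frame` with columns `case_id`, `moi`, `n_all`,
#'   `n_private_tier1`, `n_protein_changing`, `n_post_tier2`, `genes`
#'   (comma-separated symbols, `"None"` when empty).
#' @export
setClass("FunnelReport", representation(rows = "data.frame"))

setValidity("FunnelReport", function(object) {
  r <- object@rows
  need <- c("case_id", "moi", "n_all", "n_private_tier1",
            "n_protein_changing", "n_post_tier2", "genes")
  if (!all(need %in% names(r)))
    return(paste("rows must have columns:", paste(need, collapse = ", ")))
  cnt <- as.matrix(r[, c("n_all", "n_private_tier1", "n_protein_changing",
                         "n_post_tier2")])
  if (nrow(cnt) && any(cnt[, -1, drop = FALSE] > cnt[, -4, drop = FALSE]))
    return("stage counts must be non-increasing along the funnel")
  TRUE
})

#' Funnel rows as a data.frame
#' @param x A [FunnelReport-class].
#' @export
funnelTable <- function(x) x@rows

setMethod("show", "FunnelReport", function(object) {
  cat("FunnelReport with", nrow(object@rows), "(case, MOI) rows\n")
  print(object@rows)
})
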