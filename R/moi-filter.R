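# Mode-of-inheritance stratified private-variant filtering.
#
# Three genetic models are screened:
#   RECESSIVE_SHARED      homozygous-alt in every case jointly
#   RECESSIVE_INDIVIDUAL  homozygous-alt in one case, other cases ignored
#   DOMINANT_INDIVIDUAL   alt carrier (het or hom-alt) in one case
# each evaluated first against tier-1 controls, then (after the
# protein-changing annotation filter) against the tier-2 global cohort.
#
# MISSING genotypes never count as carriers in controls; a MISSING case
# genotype excludes the variant for that case's filters (conservative on
# both sides).

#' Default protein-changing effect term set
#'
#' Sequence-ontology terms counted as protein changing by default:
#' missense, stop/start changes, frameshift, inframe indels, splice
#' donor/acceptor, and generic protein-altering. Configurable via
#' [filterConfig()].
#'
#' @return Character vector of effect terms.
#' @export
proteinChangingTerms <- function() {
  c("missense_variant", "stop_gained", "stop_lost", "start_lost",
    "frameshift_variant",
    "conservative_inframe_deletion", "disruptive_inframe_deletion",
    "conservative_inframe_insertion", "disruptive_inframe_insertion",
    "splice_acceptor_variant", "splice_donor_variant",
    "protein_altering_variant")
}

#' Filtering configuration
#'
#' Thresholds for the private-variant filters. "Private" under the
#' recessive models bounds homozygous-alt control carriers (default 0) but
#' leaves heterozygous control carriers unbounded by default: a recessive
#' candidate remains private while the allele segregates in carriers.
#' The dominant model bounds the total alternate-allele count across
#' controls (default 0: absent in all controls).
#'
#' @param protein_changing_terms Effect terms counted as protein changing.
#' @param recessive_max_control_het_tier1,recessive_max_control_het_tier2
#'   Maximum heterozygous carriers among tier-1 / tier-2 controls under
#'   the recessive models (`Inf` = unbounded, the default).
#' @param recessive_max_control_homalt_tier1,recessive_max_control_homalt_tier2
#'   Maximum homozygous-alt controls under the recessive models
#'   (default 0).
#' @param dominant_max_control_alt_alleles_tier1,dominant_max_control_alt_alleles_tier2
#'   Maximum total alternate-allele count across controls under the
#'   dominant model (default 0).
#' @param require_pass Only consider PASS variants (default `TRUE`).
#' @param include_unlabeled Also admit variants with no quality label
#'   when `require_pass` is `TRUE` (default `FALSE`).
#' @return Named list of class `moiscan_filter_config`.
#' @export
filterConfig <- function(protein_changing_terms = proteinChangingTerms(),
                         recessive_max_control_het_tier1 = Inf,
                         recessive_max_control_homalt_tier1 = 0,
                         dominant_max_control_alt_alleles_tier1 = 0,
                         recessive_max_control_het_tier2 = Inf,
                         recessive_max_control_homalt_tier2 = 0,
                         dominant_max_control_alt_alleles_tier2 = 0,
                         require_pass = TRUE,
                         include_unlabeled = FALSE) {
  thr <- c(recessive_max_control_het_tier1, recessive_max_control_homalt_tier1,
           dominant_max_control_alt_alleles_tier1,
           recessive_max_control_het_tier2, recessive_max_control_homalt_tier2,
           dominant_max_control_alt_alleles_tier2)
  if (any(thr < 0)) stop("filter thresholds must be >= 0")
  structure(list(
    protein_changing_terms = protein_changing_terms,
    recessive_max_control_het_tier1 = recessive_max_control_het_tier1,
    recessive_max_control_homalt_tier1 = recessive_max_control_homalt_tier1,
    dominant_max_control_alt_alleles_tier1 = dominant_max_control_alt_alleles_tier1,
    recessive_max_control_het_tier2 = recessive_max_control_het_tier2,
    recessive_max_control_homalt_tier2 = recessive_max_control_homalt_tier2,
    dominant_max_control_alt_alleles_tier2 = dominant_max_control_alt_alleles_tier2,
    require_pass = require_pass,
    include_unlabeled = include_unlabeled), class = "moiscan_filter_config")
}

qualityMask <- function(x, cfg) {
  q <- x@variants$qual_label
  if (!cfg$require_pass) return(rep(TRUE, length(q)))
  q == "PASS" | (cfg$include_unlabeled & q == "UNLABELED")
}

# Zygosity mask for the case side of each model. NA-safe: a MISSING case
# genotype yields FALSE.
zygosityMask <- function(x, manifest, moi, caseId) {
  g <- x@geno
  if (moi == "RECESSIVE_SHARED") {
    gc <- g[, caseIds(manifest), drop = FALSE]
    hit <- rowSums(gc == 2L) # NA if any case MISSING
    !is.na(hit) & hit == ncol(gc)
  } else {
    gi <- g[, caseId]
    if (moi == "RECESSIVE_INDIVIDUAL") !is.na(gi) & gi == 2L
    else !is.na(gi) & gi >= 1L
  }
}

# Control-threshold mask for one tier under one model.
controlMask <- function(x, controls, moi, cfg, tier) {
  if (!length(controls)) return(rep(TRUE, nVariants(x)))
  gC <- x@geno[, controls, drop = FALSE]
  if (moi == "DOMINANT_INDIVIDUAL") {
    thr <- cfg[[paste0("dominant_max_control_alt_alleles_", tier)]]
    rowSums(gC, na.rm = TRUE) <= thr
  } else {
    hetThr <- cfg[[paste0("recessive_max_control_het_", tier)]]
    homThr <- cfg[[paste0("recessive_max_control_homalt_", tier)]]
    rowSums(gC == 2L, na.rm = TRUE) <= homThr &
      rowSums(gC == 1L, na.rm = TRUE) <= hetThr
  }
}

checkCase <- function(manifest, case_id) {
  m <- manifestTable(manifest)
  if (!case_id %in% m$sample[m$role == "CASE"])
    stop("unknown case id (or sample is not a CASE): ", case_id)
}

newCandidateSet <- function(x, mask, caseId, moi, stage) {
  methods::new("CandidateSet", caseId = caseId, moi = moi, stage = stage,
               table = subsetVariants(x, which(mask)))
}

#' Recessive filter shared across all cases
#'
#' Returns variants homozygous for the alternate allele in every case
#' (a MISSING genotype in any case excludes the variant), with tier-1
#' control homozygous-alt and heterozygous carrier counts within the
#' configured thresholds.
#'
#' @param x A [VariantTable-class].
#' @param manifest A [CohortManifest-class] with at least one CASE.
#' @param cfg A [filterConfig()].
#' @return A [CandidateSet-class] at stage PRIVATE_TIER1 with
#'   `caseId = "ALL"`.
#' @export
filterRecessiveShared <- function(x, manifest, cfg = filterConfig()) {
  mask <- qualityMask(x, cfg) &
    zygosityMask(x, manifest, "RECESSIVE_SHARED", NULL) &
    controlMask(x, tier1Ids(manifest), "RECESSIVE_SHARED", cfg, "tier1")
  newCandidateSet(x, mask, "ALL", "RECESSIVE_SHARED", "PRIVATE_TIER1")
}

#' Recessive filter for an individual case
#'
#' Returns variants homozygous for the alternate allele in the given case,
#' with no tier-1 control homozygous-alt beyond the threshold and
#' heterozygous tier-1 carriers within the (default unbounded) threshold.
#' Other cases are ignored: each case is considered individually.
#'
#' @inheritParams filterRecessiveShared
#' @param case_id Sample id with role CASE (hard error otherwise).
#' @return A [CandidateSet-class] at stage PRIVATE_TIER1.
#' @export
filterRecessiveIndividual <- function(x, case_id, manifest,
                                      cfg = filterConfig()) {
  checkCase(manifest, case_id)
  mask <- qualityMask(x, cfg) &
    zygosityMask(x, manifest, "RECESSIVE_INDIVIDUAL", case_id) &
    controlMask(x, tier1Ids(manifest), "RECESSIVE_INDIVIDUAL", cfg, "tier1")
  newCandidateSet(x, mask, case_id, "RECESSIVE_INDIVIDUAL", "PRIVATE_TIER1")
}

#' Dominant filter for an individual case
#'
#' Returns variants where the given case carries the alternate allele
#' (heterozygous or homozygous) and the total alternate-allele count
#' across tier-1 controls is within the threshold (default 0: absent in
#' all controls).
#'
#' @inheritParams filterRecessiveIndividual
#' @return A [CandidateSet-class] at stage PRIVATE_TIER1.
#' @export
filterDominantIndividual <- function(x, case_id, manifest,
                                     cfg = filterConfig()) {
  checkCase(manifest, case_id)
  mask <- qualityMask(x, cfg) &
    zygosityMask(x, manifest, "DOMINANT_INDIVIDUAL", case_id) &
    controlMask(x, tier1Ids(manifest), "DOMINANT_INDIVIDUAL", cfg, "tier1")
  newCandidateSet(x, mask, case_id, "DOMINANT_INDIVIDUAL", "PRIVATE_TIER1")
}

# TRUE for records whose ANN carries >= 1 entry with an effect term in the
# configured set. A fast substring pre-screen is confirmed by parsing.
annProteinChanging <- function(ann, terms) {
  hit <- rep(FALSE, length(ann))
  if (!length(terms)) return(hit)
  pre <- grepl(paste(terms, collapse = "|"), ann)
  for (i in which(pre)) {
    entries <- parseAnnField(ann[i])
    hit[i] <- any(vapply(entries$effect_terms, function(tt)
      any(tt %in% terms), logical(1)))
  }
  hit
}

#' Protein-changing annotation filter
#'
#' Retains variants having at least one annotation entry whose effect
#' terms intersect the configured protein-changing term set.
#'
#' @param set A [CandidateSet-class] at stage PRIVATE_TIER1.
#' @param cfg A [filterConfig()].
#' @return A [CandidateSet-class] at stage PROTEIN_CHANGING.
#' @export
applyProteinChangingFilter <- function(set, cfg = filterConfig()) {
  if (candidateStage(set) != "PRIVATE_TIER1")
    stop("protein-changing filter expects a PRIVATE_TIER1 stage set, got ",
         candidateStage(set))
  x <- set@table
  keep <- annProteinChanging(x@variants$ann, cfg$protein_changing_terms)
  newCandidateSet(x, keep, set@caseId, set@moi, "PROTEIN_CHANGING")
}

#' Tier-2 (global cohort) filter
#'
#' Re-applies the carrier thresholds appropriate to the set's mode of
#' inheritance against tier-2 controls. Optionally writes a
#' machine-readable manual-review table (chrom, pos, ref, alt, case,
#' genotype, gene) of the surviving candidates in place of interactive
#' alignment inspection.
#'
#' @param set A [CandidateSet-class] at stage PROTEIN_CHANGING.
#' @param manifest A [CohortManifest-class].
#' @param cfg A [filterConfig()].
#' @param review_path Optional path for the manual-review TSV.
#' @return A [CandidateSet-class] at stage POST_TIER2.
#' @export
applyTier2Filter <- function(set, manifest, cfg = filterConfig(),
                             review_path = NULL) {
  if (candidateStage(set) != "PROTEIN_CHANGING")
    stop("tier-2 filter expects a PROTEIN_CHANGING stage set, got ",
         candidateStage(set))
  x <- set@table
  keep <- controlMask(x, tier2Ids(manifest), set@moi, cfg, "tier2")
  out <- newCandidateSet(x, keep, set@caseId, set@moi, "POST_TIER2")
  if (!is.null(review_path)) exportManualReview(out, manifest, review_path)
  out
}

#' Manual-review export for surviving candidates
#'
#' One row per (variant, case): chrom, pos, ref, alt, case, genotype
#' class, gene symbols. Stands in for interactive genome-browser
#' inspection with a machine-readable record.
#'
#' @param set A [CandidateSet-class].
#' @param manifest A [CohortManifest-class].
#' @param path Output TSV path.
#' @return The review `data.frame`, invisibly written to `path`.
#' @export
exportManualReview <- function(set, manifest, path) {
  x <- set@table
  cases <- if (set@caseId == "ALL") caseIds(manifest) else set@caseId
  v <- x@variants
  rows <- do.call(rbind, lapply(cases, function(cs) {
    g <- genotypeMatrix(x, labels = TRUE)[, cs]
    if (!nrow(v)) return(NULL)
    data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
               case = cs, genotype = g,
               gene = candidateGenes(x, collapse = TRUE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(chrom = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       case = character(0), genotype = character(0),
                       gene = character(0), stringsAsFactors = FALSE)
  writeTsv(rows, path)
  invisible(rows)
}

# Per-record gene symbols from ANN (unique, annotation order).
candidateGenes <- function(x, collapse = FALSE) {
  genes <- lapply(x@variants$ann, function(a) {
    e <- parseAnnField(a)
    unique(e$gene_symbol[nzchar(e$gene_symbol)])
  })
  if (collapse)
    vapply(genes, function(g)
      if (length(g)) paste(g, collapse = ",") else "None", character(1))
  else genes
}

#' Run the full four-stage funnel for one (case, MOI)
#'
#' Convenience wrapper chaining the stage filters:
#' ALL (quality + case-zygosity condition) -> PRIVATE_TIER1 (tier-1
#' carrier thresholds) -> PROTEIN_CHANGING -> POST_TIER2.
#'
#' @param x A [VariantTable-class].
#' @param manifest A [CohortManifest-class].
#' @param moi One of RECESSIVE_SHARED, RECESSIVE_INDIVIDUAL,
#'   DOMINANT_INDIVIDUAL.
#' @param case_id Case sample id; ignored (forced to `"ALL"`) for
#'   RECESSIVE_SHARED.
#' @param cfg A [filterConfig()].
#' @param review_path Optional manual-review TSV path (see
#'   [applyTier2Filter()]).
#' @return Named list of four [CandidateSet-class] objects:
#'   `all`, `private_tier1`, `protein_changing`, `post_tier2`.
#' @export
candidateFunnel <- function(x, manifest, moi,
                            case_id = NULL, cfg = filterConfig(),
                            review_path = NULL) {
  moi <- match.arg(moi, MOI_LEVELS)
  if (moi == "RECESSIVE_SHARED") {
    case_id <- "ALL"
  } else {
    checkCase(manifest, case_id)
  }
  maskAll <- qualityMask(x, cfg) & zygosityMask(x, manifest, moi, case_id)
  all <- newCandidateSet(x, maskAll, case_id, moi, "ALL")
  p1 <- switch(moi,
    RECESSIVE_SHARED = filterRecessiveShared(x, manifest, cfg),
    RECESSIVE_INDIVIDUAL = filterRecessiveIndividual(x, case_id, manifest, cfg),
    DOMINANT_INDIVIDUAL = filterDominantIndividual(x, case_id, manifest, cfg))
  pc <- applyProteinChangingFilter(p1, cfg)
  t2 <- applyTier2Filter(pc, manifest, cfg, review_path)
  list(all = all, private_tier1 = p1, protein_changing = pc, post_tier2 = t2)
}

#' Build a funnel report from stage sets
#'
#' @param funnels A list of four-stage funnels as returned by
#'   [candidateFunnel()] (each element a named list with `all`,
#'   `private_tier1`, `protein_changing`, `post_tier2`). A missing stage
#'   is a hard error.
#' @return A [FunnelReport-class] with one row per (case, MOI).
#' @export
buildFunnelReport <- function(funnels) {
  if (length(funnels) && methods::is(funnels[[1]], "CandidateSet"))
    funnels <- list(funnels)  # a single funnel was passed

  rows <- do.call(rbind, lapply(funnels, function(f) {
    miss <- setdiff(STAGE_LEVELS_NAMES, names(f))
    if (length(miss))
      stop("funnel missing stage(s): ", paste(miss, collapse = ", "))
    final <- f$post_tier2
    genes <- unique(unlist(candidateGenes(final@table)))
    data.frame(case_id = final@caseId, moi = final@moi,
               n_all = nCandidates(f$all),
               n_private_tier1 = nCandidates(f$private_tier1),
               n_protein_changing = nCandidates(f$protein_changing),
               n_post_tier2 = nCandidates(final),
               genes = if (length(genes)) paste(genes, collapse = ",")
                       else "None",
               stringsAsFactors = FALSE)
  }))
  methods::new("FunnelReport", rows = rows)
}

STAGE_LEVELS_NAMES <- c("all", "private_tier1", "protein_changing",
                        "post_tier2")

#' Write a funnel report TSV
#'
#' Column order mirrors published per-case filtering funnel tables:
#' case, MOI, all variants, private variants (tier-1), private
#' protein-changing variants, remaining variants after the global cohort,
#' candidate genes.
#'
#' @param report A [FunnelReport-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeFunnelTsv <- function(report, path) {
  writeTsv(funnelTable(report), path)
}
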