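# Evidence-based candidate classification.
#
# The classifier freezes a narrative application of the ACMG sequence
# variant interpretation guidelines into a deterministic three-rule
# cascade ("ACMG-lite"):
#   R1  no deleterious consensus, or gene not a disorder candidate
#       -> NOT_A_CANDIDATE
#   R2  homozygous-alt under a recessive model + deleterious consensus +
#       candidate gene -> LIKELY_PATHOGENIC
#   R3  heterozygous under the dominant model + deleterious consensus +
#       candidate gene + no segregation data -> UNCERTAIN_SIGNIFICANCE
# Residue conservation annotates the rationale but never changes the
# class (it is descriptive supporting evidence).

CLASS_LEVELS <- c("NOT_A_CANDIDATE", "UNCERTAIN_SIGNIFICANCE",
                  "LIKELY_PATHOGENIC")

#' Consensus over deleteriousness predictions
#'
#' DELETERIOUS iff at least one tool predicts deleterious;
#' NOT_DELETERIOUS iff at least one tool reported and none deleterious;
#' UNAVAILABLE otherwise (no tool reported).
#'
#' @param predictions `data.frame` with columns `tool` and `prediction`
#'   (DELETERIOUS / NEUTRAL / UNAVAILABLE), or a character vector of
#'   predictions. Zero rows allowed.
#' @return One of `"DELETERIOUS"`, `"NOT_DELETERIOUS"`, `"UNAVAILABLE"`.
#' @export
#' @examples
#' consensusDeleteriousness(c("NEUTRAL", "DELETERIOUS"))
consensusDeleteriousness <- function(predictions) {
  p <- if (is.data.frame(predictions)) predictions$prediction
       else as.character(predictions)
  p <- p[p != "UNAVAILABLE"]
  if (!length(p)) return("UNAVAILABLE")
  if (any(p == "DELETERIOUS")) "DELETERIOUS" else "NOT_DELETERIOUS"
}

#' Residue conservation across an aligned protein panel
#'
#' Fraction of non-gap sequences whose residue at the given alignment
#' column matches the reference (case-species) sequence. 1.0 means
#' complete conservation across the panel.
#'
#' @param alignment An [Biostrings::AAStringSet] of equal-length aligned
#'   sequences, or a path to an aligned FASTA file.
#' @param column 1-based alignment column of the affected residue.
#' @param ref Index (or name) of the reference sequence (default 1, the
#'   first sequence).
#' @return The conservation fraction in \[0, 1\], or `NA` (flagged
#'   unavailable) when the column is all gaps or the reference itself is
#'   gapped there.
#' @export
conservationFraction <- function(alignment, column, ref = 1L) {
  if (is.character(alignment) && length(alignment) == 1L)
    alignment <- Biostrings::readAAStringSet(alignment)
  w <- Biostrings::width(alignment)
  if (length(unique(w)) != 1L)
    stop("aligned sequences must all have equal length")
  if (column < 1L || column > w[1])
    stop("column ", column, " outside alignment of width ", w[1])
  res <- toupper(vapply(seq_along(alignment), function(i)
    as.character(Biostrings::subseq(alignment[[i]], column, column)),
    character(1)))
  gap <- res %in% c("-", ".")
  refRes <- res[[if (is.character(ref)) match(ref, names(alignment)) else ref]]
  if (all(gap) || refRes %in% c("-", ".")) return(NA_real_)
  sum(res[!gap] == refRes) / sum(!gap)
}

#' Assemble an evidence bundle for one candidate variant
#'
#' @param moi Mode of inheritance under which the variant survived
#'   filtering (RECESSIVE_SHARED, RECESSIVE_INDIVIDUAL,
#'   DOMINANT_INDIVIDUAL).
#' @param zygosity Genotype class in the case: `"HOM_ALT"` or `"HET"`
#'   (a `"HOM_REF"` case genotype is inconsistent and a hard error at
#'   classification).
#' @param predictions Deleteriousness predictions (see
#'   [consensusDeleteriousness()]).
#' @param conservation Conservation fraction in \[0, 1\] or `NA` when
#'   unavailable.
#' @param gene_is_candidate Is the affected gene a disorder candidate
#'   (function / associated phenotype / expression evidence)?
#'   User-supplied flag, not computed from databases.
#' @param gene_note Free-text evidence note for the gene flag.
#' @param allele_freq_global Global cohort allele frequency or `NA`.
#' @param segregation `"NONE"` when no family segregation data exist
#'   (the only value currently modelled).
#' @return Named list of class `moiscan_evidence`.
#' @export
evidenceBundle <- function(moi, zygosity, predictions = character(0),
                           conservation = NA_real_,
                           gene_is_candidate = FALSE, gene_note = "",
                           allele_freq_global = NA_real_,
                           segregation = "NONE") {
  moi <- match.arg(moi, MOI_LEVELS)
  structure(list(moi = moi, zygosity = zygosity,
                 predictions = predictions, conservation = conservation,
                 gene_is_candidate = gene_is_candidate,
                 gene_note = gene_note,
                 allele_freq_global = allele_freq_global,
                 segregation = segregation), class = "moiscan_evidence")
}

#' Classify a candidate variant from its evidence bundle
#'
#' Applies the deterministic rule cascade described in the package
#' vignette. The rationale lists every fired rule id, plus a
#' conservation note (`"CONSERVED_RESIDUE"`) when the conservation
#' fraction meets `conservation_note_min` (never affecting the class).
#'
#' @param bundle An [evidenceBundle()].
#' @param conservation_note_min Conservation fraction from which the
#'   supporting rationale note is added (default 0.9).
#' @return A list with `class` (LIKELY_PATHOGENIC /
#'   UNCERTAIN_SIGNIFICANCE / NOT_A_CANDIDATE) and `rationale`
#'   (character vector of fired rule ids).
#' @export
classifyCandidate <- function(bundle, conservation_note_min = 0.9) {
  stopifnot(inherits(bundle, "moiscan_evidence"))
  if (!bundle$zygosity %in% c("HOM_ALT", "HET"))
    stop("inconsistent evidence bundle: case zygosity ", bundle$zygosity)
  consensus <- consensusDeleteriousness(bundle$predictions)
  note <- if (!is.na(bundle$conservation) &&
              bundle$conservation >= conservation_note_min)
    "CONSERVED_RESIDUE" else character(0)
  if (consensus != "DELETERIOUS" || !isTRUE(bundle$gene_is_candidate)) {
    return(list(class = "NOT_A_CANDIDATE",
                rationale = c("R1_NO_DELETERIOUS_CONSENSUS_OR_GENE", note)))
  }
  recessive <- bundle$moi %in% c("RECESSIVE_SHARED", "RECESSIVE_INDIVIDUAL")
  if (recessive && bundle$zygosity == "HOM_ALT") {
    return(list(class = "LIKELY_PATHOGENIC",
                rationale = c("R2_RECESSIVE_HOMOZYGOUS_DELETERIOUS", note)))
  }
  if (bundle$moi == "DOMINANT_INDIVIDUAL" && bundle$zygosity == "HET" &&
      identical(bundle$segregation, "NONE")) {
    return(list(class = "UNCERTAIN_SIGNIFICANCE",
                rationale = c("R3_DOMINANT_HET_NO_SEGREGATION", note)))
  }
  # deleterious + candidate gene but zygosity/model combination outside
  # R2/R3 (e.g. het under a recessive model): not classifiable upward
  list(class = "NOT_A_CANDIDATE",
       rationale = c("R1_MODEL_ZYGOSITY_MISMATCH", note))
}

#' Classify a table of evidence bundles
#'
#' @param bundles Named list of [evidenceBundle()] objects (names are
#'   variant labels).
#' @param path Optional output TSV path (variant, class, rules fired,
#'   evidence summary).
#' @param ... Passed to [classifyCandidate()].
#' @return `data.frame` with columns `variant`, `class`, `rules`,
#'   `evidence`.
#' @export
classifyBundles <- function(bundles, path = NULL, ...) {
  rows <- do.call(rbind, lapply(names(bundles), function(nm) {
    b <- bundles[[nm]]
    res <- classifyCandidate(b, ...)
    data.frame(variant = nm, class = res$class,
               rules = paste(res$rationale, collapse = ";"),
               evidence = sprintf(
                 "moi=%s;zygosity=%s;consensus=%s;conservation=%s;gene=%s",
                 b$moi, b$zygosity, consensusDeleteriousness(b$predictions),
                 ifelse(is.na(b$conservation), "NA",
                        format(b$conservation, digits = 3)),
                 b$gene_note),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) writeTsv(rows, path)
  rows
}
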