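# Bundled study-shaped simulation preset.

#' Study-shaped simulation preset
#'
#' A bundled [simConfig()] emulating the structure of a seven-case
#' whole-genome screen with tiered controls:
#' \itemize{
#'   \item 7 cases, 120 tier-1 controls, and a tier-2 global cohort of
#'     430 genomes in four populations;
#'   \item one recessive-individual planting for case 7 (a missense
#'     variant in a torsin-family gene) with heterozygous tier-2
#'     carriers in three populations (71, 6 and 4 carriers) and none in
#'     tier 1 — the pattern of a recessive candidate that stays private
#'     in the homozygous state while the allele segregates in carriers;
#'   \item seven dominant plantings across cases 1-6, case 3 carrying
#'     two in distinct genes (a digenic pattern), each absent from all
#'     controls; six missense and one 12-bp inframe deletion;
#'   \item five homozygosity blocks shared by all seven cases totalling
#'     2.2 Mb, plus one private block per case on each chromosome so
#'     that the planted autozygous genome fraction per case is ~0.107.
#' }
#' Genome: two 50-Mb pseudo-autosomes with 100 markers/Mb; background
#' polymorphism: 400 variants with allele frequency uniform on
#' \[0.01, 0.5\].
#'
#' @return A [simConfig()] object.
#' @export
paperLikePreset <- function() {
  cases <- sprintf("case%d", 1:7)
  mb <- 1e6
  plantings <- list(
    plantedVariant("1", 1200123, "T", "C", "RECESSIVE_INDIVIDUAL",
                   cases = "case7",
                   control_het = c(swiss_holstein = 71,
                                   swiss_fleckvieh = 6, red_danish = 4),
                   gene = "TOR3A", effect_terms = "missense_variant",
                   hgvs_c = "c.58G>T", hgvs_p = "p.Phe111Leu"),
    plantedVariant("1", 2200211, "G", "A", "DOMINANT_INDIVIDUAL",
                   cases = "case1", gene = "MPEG1",
                   hgvs_c = "c.163C>T", hgvs_p = "p.Arg55Trp"),
    plantedVariant("1", 3200321, "G", "A", "DOMINANT_INDIVIDUAL",
                   cases = "case2", gene = "LHX8",
                   hgvs_c = "c.290C>T", hgvs_p = "p.Thr97Ile"),
    plantedVariant("2", 2500431, "CGCCCGAGCCCGA", "C",
                   "DOMINANT_INDIVIDUAL", cases = "case3", gene = "WHAMM",
                   effect_terms = "disruptive_inframe_deletion",
                   hgvs_c = "c.199_210delCCCGAGCCCGAG",
                   hgvs_p = "p.Pro67Glu70del"),
    plantedVariant("2", 3500541, "G", "A", "DOMINANT_INDIVIDUAL",
                   cases = "case3", gene = "NGRN",
                   hgvs_c = "c.328G>A", hgvs_p = "p.Gly110Ser"),
    plantedVariant("2", 4500651, "T", "C", "DOMINANT_INDIVIDUAL",
                   cases = "case4", gene = "TTN",
                   hgvs_c = "c.6374T>C", hgvs_p = "p.Ile2125Thr"),
    plantedVariant("1", 48200761, "G", "A", "DOMINANT_INDIVIDUAL",
                   cases = "case5", gene = "ATP1A1",
                   hgvs_c = "c.680C>T", hgvs_p = "p.Pro227Leu"),
    plantedVariant("1", 49000871, "G", "A", "DOMINANT_INDIVIDUAL",
                   cases = "case6", gene = "PCDH1",
                   hgvs_c = "c.3556C>T", hgvs_p = "p.Arg1186Cys"))

  shared <- data.frame(
    scope = "ALL_CASES",
    chrom = c("1", "1", "1", "2", "2"),
    start = c(5.0, 12.0, 20.0, 8.0, 15.0) * mb + 1,
    end = c(5.4, 12.5, 20.3, 8.6, 15.4) * mb,
    stringsAsFactors = FALSE)
  priv1 <- data.frame(
    scope = cases, chrom = "1",
    start = 24 * mb + (0:6) * 3.2 * mb + 1,
    end = 24 * mb + (0:6) * 3.2 * mb + 4.0 * mb,
    stringsAsFactors = FALSE)
  priv2 <- data.frame(
    scope = cases, chrom = "2",
    start = 22 * mb + (0:6) * 3.6 * mb + 1,
    end = 22 * mb + (0:6) * 3.6 * mb + 4.5 * mb,
    stringsAsFactors = FALSE)

  simConfig(n_cases = 7,
            n_tier1_controls = 120,
            tier2_populations = c(swiss_holstein = 150,
                                  swiss_fleckvieh = 100,
                                  red_danish = 80, other_breeds = 100),
            n_background_variants = 400,
            plantings = plantings,
            roh_blocks = rbind(shared, priv1, priv2),
            chrom_lengths = c(`1` = 5e7, `2` = 5e7),
            marker_density = 100)
}
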