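# End-to-end orchestration: read -> MOI funnels -> ROH -> population
# frequencies -> classification, with plain TSV/BED/JSON reports.

configHash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(obj), f)
  unname(tools::md5sum(f))
}

#' Run the full candidate-variant analysis
#'
#' Orchestrates the whole screen on one cohort: reads the VCF and
#' manifest, runs the three mode-of-inheritance funnels (recessive shared
#' across cases, recessive per case, dominant per case), detects runs of
#' homozygosity per case with shared regions and F_ROH, optionally
#' tabulates population frequencies for a target variant and classifies
#' supplied evidence bundles, and writes every report to `out_dir`.
#'
#' Reports written: `funnel_<moi>.tsv` per model;
#' `candidates_<moi>_<case>.vcf` and `review_<moi>_<case>.tsv` for every
#' non-empty final candidate set; `roh_<sample>.bed` per case;
#' `shared_regions.bed`; `froh.tsv` (per sample plus a cohort mean/SD
#' line); `popfreq.tsv` and `classification.tsv` when requested; and
#' `run.log` recording the configuration hash and applied defaults.
#' Rerunning with identical inputs overwrites with identical content.
#'
#' @param vcf_path Path to the annotated multi-sample VCF.
#' @param manifest_path Path to the manifest TSV (hard error, naming the
#'   file, if absent).
#' @param genome_path Path to the chromosome-length TSV.
#' @param out_dir Output directory.
#' @param cfg A [filterConfig()].
#' @param roh_params A [rohParams()].
#' @param stride Marker stride for ROH tracks (see [genotypeTrack()]).
#' @param min_shared_length Minimum shared homozygous region length (bp).
#' @param popfreq_variant Optional `"chrom:pos:ref:alt"` key to tabulate
#'   per-population frequencies for.
#' @param evidence Optional named list of [evidenceBundle()] objects to
#'   classify.
#' @return Invisibly, a list with the funnel reports (`funnels`,
#'   a [FunnelReport-class] per model), `roh` (per-case `GRanges`),
#'   `shared` (regions + total bp), `froh` (inbreeding result), and
#'   `paths`.
#' @export
runFullAnalysis <- function(vcf_path, manifest_path, genome_path, out_dir,
                            cfg = filterConfig(),
                            roh_params = rohParams(),
                            stride = 1L, min_shared_length = 10000,
                            popfreq_variant = NULL, evidence = NULL) {
  for (p in c(vcf_path, manifest_path, genome_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- readCohortManifest(manifest_path)
  chromLen <- readChromTable(genome_path)
  x <- readAnnotatedVcf(vcf_path, manifest, chromOrder = names(chromLen))
  cases <- caseIds(manifest)
  logLines <- c(
    sprintf("config_hash=%s", configHash(list(cfg, roh_params, stride,
                                              min_shared_length))),
    sprintf("n_variants=%d n_samples=%d n_cases=%d",
            nVariants(x), length(sampleIds(x)), length(cases)),
    sprintf("defaults: require_pass=%s stride=%d min_shared_length=%d",
            cfg$require_pass, as.integer(stride),
            as.integer(min_shared_length)))

  writeSets <- function(funnel, moi, caseLabel) {
    final <- funnel$post_tier2
    if (nCandidates(final) > 0) {
      writeVariantTableVcf(candidateTable(final), file.path(
        out_dir, sprintf("candidates_%s_%s.vcf", tolower(moi), caseLabel)))
      exportManualReview(final, manifest, file.path(
        out_dir, sprintf("review_%s_%s.tsv", tolower(moi), caseLabel)))
    }
    funnel
  }

  funnels <- list()
  shared_funnel <- writeSets(
    candidateFunnel(x, manifest, "RECESSIVE_SHARED", cfg = cfg),
    "RECESSIVE_SHARED", "all")
  funnels$recessive_shared <- buildFunnelReport(list(shared_funnel))
  recInd <- lapply(cases, function(cs) writeSets(
    candidateFunnel(x, manifest, "RECESSIVE_INDIVIDUAL", cs, cfg),
    "RECESSIVE_INDIVIDUAL", cs))
  funnels$recessive_individual <- buildFunnelReport(recInd)
  domInd <- lapply(cases, function(cs) writeSets(
    candidateFunnel(x, manifest, "DOMINANT_INDIVIDUAL", cs, cfg),
    "DOMINANT_INDIVIDUAL", cs))
  funnels$dominant_individual <- buildFunnelReport(domInd)
  for (nm in names(funnels))
    writeFunnelTsv(funnels[[nm]], file.path(out_dir,
                                            sprintf("funnel_%s.tsv", nm)))

  roh <- lapply(stats::setNames(cases, cases), function(cs) {
    gr <- detectRohConsecutive(genotypeTrack(x, cs, stride), roh_params,
                               sample_id = cs)
    exportRohBed(gr, file.path(out_dir, sprintf("roh_%s.bed", cs)))
    gr
  })
  shared <- sharedHomozygousRegions(roh, min_shared_length)
  exportRohBed(shared$regions, file.path(out_dir, "shared_regions.bed"))
  froh <- genomicInbreeding(roh, chromLen, group = cases)
  frohTab <- froh$per_sample
  writeTsv(frohTab, file.path(out_dir, "froh.tsv"))
  cat(sprintf("# cohort mean=%.6g sd=%.6g\n", froh$mean, froh$sd),
      file = file.path(out_dir, "froh.tsv"), append = TRUE)

  if (!is.null(popfreq_variant)) {
    writeTsv(popFreqTable(x, popfreq_variant, manifest),
             file.path(out_dir, "popfreq.tsv"))
  }
  if (!is.null(evidence)) {
    classifyBundles(evidence, path = file.path(out_dir,
                                               "classification.tsv"))
  }
  writeLines(logLines, file.path(out_dir, "run.log"))
  invisible(list(funnels = funnels, roh = roh, shared = shared,
                 froh = froh,
                 paths = list(out_dir = out_dir)))
}
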