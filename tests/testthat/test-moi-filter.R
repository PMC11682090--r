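# MOI-stratified private-variant filtering.

missenseAnn <- annPool()[2]
synonymousAnn <- annPool()[3]
inframeDelAnn <- annPool()[6]

test_that("shared recessive filter requires homozygosity in every case", {
  samples <- c("caseA", "caseB", "ctrl1", "ctrl2")
  mf <- simpleManifest(samples, c("CASE", "CASE", "TIER1_CONTROL",
                                  "TIER1_CONTROL"))
  g <- rbind(c(2L, 2L, 0L, 1L),   # hom in both cases, het control ok
             c(2L, 1L, 0L, 0L),   # one case het -> excluded
             c(2L, NA, 0L, 0L),   # one case missing -> excluded
             c(2L, 2L, 2L, 0L))   # control hom-alt -> excluded
  colnames(g) <- samples
  x <- tableFromCodes(g)
  res <- filterRecessiveShared(x, mf)
  expect_equal(nCandidates(res), 1L)
  expect_equal(variantInfo(candidateTable(res))$pos, 1000L)
  expect_equal(candidateCase(res), "ALL")
  expect_equal(candidateStage(res), "PRIVATE_TIER1")
  # empty table is an empty set, not an error
  expect_equal(nCandidates(filterRecessiveShared(subsetVariants(x, 0), mf)),
               0L)
})

test_that("individual recessive filter ignores other cases and tolerates control hets", {
  samples <- c("caseA", "caseB", "ctrl1", "ctrl2")
  mf <- simpleManifest(samples, c("CASE", "CASE", "TIER1_CONTROL",
                                  "TIER1_CONTROL"))
  g <- rbind(c(2L, 0L, 1L, 1L),   # hom in caseA, control HETs allowed
             c(2L, 2L, 0L, 0L),   # hom in other case too: still kept
             c(2L, 0L, 2L, 0L),   # control hom-alt -> excluded
             c(1L, 0L, 0L, 0L),   # caseA only het -> excluded
             c(NA, 0L, 0L, 0L))   # caseA missing -> excluded
  colnames(g) <- samples
  x <- tableFromCodes(g)
  res <- filterRecessiveIndividual(x, "caseA", mf)
  expect_equal(variantInfo(candidateTable(res))$pos, c(1000L, 2000L))
  expect_error(filterRecessiveIndividual(x, "ctrl1", mf), "ctrl1")
  expect_error(filterRecessiveIndividual(x, "nobody", mf), "nobody")
  # a configurable het cap makes the control-het variant drop out
  strict <- filterConfig(recessive_max_control_het_tier1 = 0)
  res2 <- filterRecessiveIndividual(x, "caseA", mf, strict)
  expect_equal(variantInfo(candidateTable(res2))$pos, 2000L)
})

test_that("dominant filter requires absence from all controls", {
  samples <- c("caseA", "caseB", "ctrl1")
  mf <- simpleManifest(samples, c("CASE", "CASE", "TIER1_CONTROL"))
  g <- rbind(c(1L, 0L, 0L),   # private het -> kept
             c(1L, 0L, 1L),   # het control carrier -> excluded
             c(2L, 0L, 0L),   # hom-alt case counts as carrier -> kept
             c(0L, 1L, 0L))   # carried by the other case only -> excluded
  colnames(g) <- samples
  x <- tableFromCodes(g)
  res <- filterDominantIndividual(x, "caseA", mf)
  expect_equal(variantInfo(candidateTable(res))$pos, c(1000L, 3000L))
  # other cases are not controls: caseB's variant is caseB's candidate
  resB <- filterDominantIndividual(x, "caseB", mf)
  expect_equal(variantInfo(candidateTable(resB))$pos, 4000L)
})

test_that("protein-changing filter keeps annotated consequence classes", {
  samples <- c("caseA", "ctrl1")
  mf <- simpleManifest(samples, c("CASE", "TIER1_CONTROL"))
  g <- matrix(c(1L, 0L, 1L, 0L, 1L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(NULL, samples))
  x <- tableFromCodes(g, ann = c(missenseAnn, synonymousAnn, inframeDelAnn))
  p1 <- filterDominantIndividual(x, "caseA", mf)
  pc <- applyProteinChangingFilter(p1)
  # missense and inframe deletion retained; synonymous-only removed
  expect_equal(variantInfo(candidateTable(pc))$pos, c(1000L, 3000L))
  expect_equal(candidateStage(pc), "PROTEIN_CHANGING")
  # stage precondition enforced
  expect_error(applyProteinChangingFilter(pc), "PRIVATE_TIER1")
})

test_that("tier-2 filter applies MOI-appropriate thresholds and empty tier-2 is identity", {
  samples <- c("caseA", "ctrl1", "w1", "w2")
  mf <- simpleManifest(samples, c("CASE", "TIER1_CONTROL",
                                  "TIER2_CONTROL", "TIER2_CONTROL"))
  g <- rbind(c(2L, 0L, 1L, 1L),   # tier-2 hets: allowed under recessive
             c(2L, 0L, 2L, 0L))   # tier-2 hom-alt: removed
  colnames(g) <- samples
  x <- tableFromCodes(g)
  pc <- applyProteinChangingFilter(filterRecessiveIndividual(x, "caseA", mf))
  t2 <- applyTier2Filter(pc, mf)
  expect_equal(variantInfo(candidateTable(t2))$pos, 1000L)
  expect_equal(candidateStage(t2), "POST_TIER2")
  # empty tier-2 cohort: output equals input
  mfNoT2 <- simpleManifest(samples, c("CASE", "TIER1_CONTROL",
                                      "TIER1_CONTROL", "TIER1_CONTROL"))
  x2 <- tableFromCodes(rbind(c(2L, 0L, 0L, 0L)))
  colnames(x2@geno) <- samples
  pc2 <- applyProteinChangingFilter(
    filterRecessiveIndividual(x2, "caseA", mfNoT2))
  expect_equal(nCandidates(applyTier2Filter(pc2, mfNoT2)),
               nCandidates(pc2))
})

test_that("a digenic case reports two final candidates in distinct genes", {
  samples <- c("caseA", "ctrl1", "w1")
  mf <- simpleManifest(samples, c("CASE", "TIER1_CONTROL", "TIER2_CONTROL"))
  annG1 <- "G|missense_variant|MODERATE|GENEX|g|t|u|Coding|1/1|c.1A>G|p.K1R"
  annG2 <- "G|missense_variant|MODERATE|GENEY|g|t|u|Coding|1/1|c.2A>G|p.K2R"
  g <- rbind(c(1L, 0L, 0L), c(1L, 0L, 0L))
  colnames(g) <- samples
  x <- tableFromCodes(g, ann = c(annG1, annG2))
  funnel <- candidateFunnel(x, mf, "DOMINANT_INDIVIDUAL", "caseA")
  expect_equal(nCandidates(funnel$post_tier2), 2L)
  report <- buildFunnelReport(list(funnel))
  expect_equal(funnelTable(report)$genes, "GENEX,GENEY")
})

test_that("funnel report counts stages, prints None for empty funnels, and demands all stages", {
  samples <- c("caseA", "ctrl1")
  mf <- simpleManifest(samples, c("CASE", "TIER1_CONTROL"))
  g <- matrix(c(0L, 0L), nrow = 1, dimnames = list(NULL, samples))
  x <- tableFromCodes(g)
  funnel <- candidateFunnel(x, mf, "DOMINANT_INDIVIDUAL", "caseA")
  rep0 <- funnelTable(buildFunnelReport(list(funnel)))
  expect_equal(unlist(rep0[1, c("n_all", "n_private_tier1",
                                "n_protein_changing", "n_post_tier2")],
                      use.names = FALSE), rep(0L, 4))
  expect_equal(rep0$genes, "None")
  expect_error(buildFunnelReport(list(funnel[-4])), "post_tier2")
})

test_that("filters match the brute-force oracle and funnels are monotone", {
  for (seed in 1:30) {
    rc <- randomCohort(seed)
    cfg <- randomFilterConfig(seed)
    cases <- caseIds(rc$manifest)
    for (moi in c("RECESSIVE_SHARED", "RECESSIVE_INDIVIDUAL",
                  "DOMINANT_INDIVIDUAL")) {
      cs <- if (moi == "RECESSIVE_SHARED") NULL else cases[1]
      funnel <- candidateFunnel(rc$x, rc$manifest, moi, cs, cfg)
      expect_equal(variantKeys(candidateTable(funnel$private_tier1)),
                   variantKeys(rc$x)[brutePrivateTier1(
                     rc$x, rc$manifest, moi, cs, cfg)])
      expect_equal(variantKeys(candidateTable(funnel$post_tier2)),
                   bruteFinalKeys(rc$x, rc$manifest, moi, cs, cfg))
      sizes <- vapply(funnel, nCandidates, 0L)
      expect_true(all(diff(sizes) <= 0))
      # nesting: later stages are subsets of earlier ones
      expect_true(all(variantKeys(candidateTable(funnel$post_tier2)) %in%
                        variantKeys(candidateTable(funnel$private_tier1))))
    }
  }
})
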