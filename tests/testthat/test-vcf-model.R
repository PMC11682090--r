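# Normalization of VCF input: genotype classes, multiallelic splitting,
# ANN parsing, ordering, round trip.

test_that("reading maps genotypes, quality labels and empty input correctly", {
  mf <- simpleManifest(c("s1", "s2", "s3", "s4"),
                       c("CASE", "TIER1_CONTROL", "TIER1_CONTROL",
                         "TIER2_CONTROL"))
  path <- vcfFixture(c("s1", "s2", "s3", "s4"), list(
    list(chrom = "1", pos = 100, ref = "A", alt = "G",
         gt = c("0/0", "0/1", "1/1", "./.")),
    list(chrom = "1", pos = 200, ref = "C", alt = "T", filter = ".",
         gt = c("0|1", "1|0", "0|0", "1|1")),
    list(chrom = "1", pos = 300, ref = "C", alt = "T", filter = "LowQual",
         gt = c("0/0", "0/0", "./1", "0/0"))))
  x <- readAnnotatedVcf(path, mf)
  expect_equal(nVariants(x), 3L)
  g <- genotypeMatrix(x)
  expect_equal(unname(g[1, ]), c(0L, 1L, 2L, NA))
  # phased separators are equivalent to unphased
  expect_equal(unname(g[2, ]), c(1L, 1L, 0L, 2L))
  # half-missing genotype is MISSING
  expect_true(is.na(g[3, "s3"]))
  expect_equal(variantInfo(x)$qual_label, c("PASS", "UNLABELED", "FAIL"))

  # empty VCF -> empty table
  empty <- vcfFixture(c("s1", "s2", "s3", "s4"), list())
  x0 <- suppressWarnings(readAnnotatedVcf(empty, mf))
  expect_equal(nVariants(x0), 0L)
  expect_equal(sampleIds(x0), c("s1", "s2", "s3", "s4"))

  # manifest sample absent from the header is a named hard error
  mfBad <- simpleManifest(c("s1", "ghost"), c("CASE", "TIER1_CONTROL"))
  expect_error(readAnnotatedVcf(path, mfBad), "ghost")
})

test_that("triallelic sites split into per-alt records matching the hand oracle", {
  # all 9 diploid combinations over alleles {0, 1, 2}, one per sample
  combos <- c("0/0", "0/1", "0/2", "1/1", "1/2", "2/2", "./.", "./1", "1/0")
  samples <- sprintf("s%d", seq_along(combos))
  mf <- simpleManifest(samples, c("CASE", rep("TIER1_CONTROL", 8)))
  path <- vcfFixture(samples, list(
    list(chrom = "1", pos = 500, ref = "A", alt = "C,T", gt = combos)))
  x <- readAnnotatedVcf(path, mf)
  expect_equal(nVariants(x), 2L)
  expect_equal(variantInfo(x)$alt, c("C", "T"))
  g <- genotypeMatrix(x)
  # hand-enumerated classes: HET requires the other allele to be REF;
  # any genotype carrying a different alt is MISSING
  expect_equal(unname(g[1, ]), c(0L, 1L, NA, 2L, NA, NA, NA, NA, 1L))
  expect_equal(unname(g[2, ]), c(0L, NA, 1L, NA, NA, 2L, NA, NA, NA))
})

test_that("splitMultiallelic obeys its per-alt genotype contract", {
  site <- list(chrom = "1", pos = 10L, ref = "A", alt = c("C", "T"),
               qual_label = "PASS", ann = "",
               gt = c(a = "0/1", b = "2/2", c = "0/2"))
  recs <- splitMultiallelic(site)
  expect_length(recs, 2L)
  expect_equal(unname(recs[[1]]$geno), c(1L, NA, NA))  # alt C
  expect_equal(unname(recs[[2]]$geno), c(NA, 2L, 1L))  # alt T
  # a genotype combining two different alts is MISSING on both records
  site$gt <- c(a = "1/2", b = "0/0", c = "0/0")
  recs <- splitMultiallelic(site)
  expect_true(is.na(recs[[1]]$geno[["a"]]))
  expect_true(is.na(recs[[2]]$geno[["a"]]))
  # biallelic input is an identity split
  bi <- list(chrom = "1", pos = 10L, ref = "A", alt = "C",
             qual_label = "PASS", ann = "", gt = c(a = "0/1"))
  expect_length(splitMultiallelic(bi), 1L)
  expect_equal(splitMultiallelic(bi)[[1]]$alt, "C")
  # symbolic alts are dropped with a warning
  sym <- list(chrom = "1", pos = 10L, ref = "A", alt = c("C", "<DEL>"),
              qual_label = "PASS", ann = "", gt = c(a = "0/1"))
  expect_warning(recs <- splitMultiallelic(sym), "symbolic")
  expect_length(recs, 1L)
})

test_that("splitting conserves alt-allele dosage for non-missing genotypes", {
  set.seed(42)
  for (rep in 1:50) {
    nAlt <- sample(1:3, 1)
    alleles <- 0:nAlt
    gt <- paste(sample(alleles, 5, replace = TRUE),
                sample(alleles, 5, replace = TRUE), sep = "/")
    names(gt) <- sprintf("s%d", 1:5)
    site <- list(chrom = "1", pos = 1L, ref = "A",
                 alt = c("C", "G", "T")[seq_len(nAlt)],
                 qual_label = "PASS", ann = "", gt = gt)
    recs <- splitMultiallelic(site)
    for (j in seq_len(nAlt)) {
      parts <- strsplit(gt, "/", fixed = TRUE)
      trueDosage <- vapply(parts, function(p) sum(as.integer(p) == j), 0L)
      got <- recs[[j]]$geno
      comparable <- !is.na(got)
      expect_equal(unname(got[comparable]),
                   unname(trueDosage[comparable]))
    }
  }
})

test_that("ANN parsing follows the annotation standard", {
  expect_equal(nrow(parseAnnField("")), 0L)
  one <- parseAnnField(paste0("C|missense_variant|MODERATE|TOR3A|g1|",
                              "transcript|t1|Coding|2/5|c.58G>T|p.Phe111Leu"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$gene_symbol, "TOR3A")
  expect_equal(one$impact, "MODERATE")
  expect_equal(one$effect_terms[[1]], "missense_variant")
  # HGVS strings preserved verbatim
  expect_equal(one$hgvs_c, "c.58G>T")
  expect_equal(one$hgvs_p, "p.Phe111Leu")
  # ampersand-joined terms split
  two <- parseAnnField("A|splice_donor_variant&intron_variant|HIGH|G2|x|y|z")
  expect_equal(two$effect_terms[[1]],
               c("splice_donor_variant", "intron_variant"))
  # short entries skipped with warning, others kept
  expect_warning(kept <- parseAnnField("A|b,C|missense_variant|MODERATE|G1"),
                 "skipped")
  expect_equal(nrow(kept), 1L)
})

test_that("tables are ordered by chromosome table order and round-trip", {
  mf <- simpleManifest(c("s1", "s2"), c("CASE", "TIER1_CONTROL"))
  path <- vcfFixture(c("s1", "s2"), list(
    list(chrom = "Chr2", pos = 50, ref = "T", alt = "A",
         gt = c("0/1", "0/0")),
    list(chrom = "10", pos = 5, ref = "G", alt = "C",
         gt = c("1/1", "0/1"),
         ann = "C|missense_variant|MODERATE|GX|g|t|u|Coding|1/1|c.1G>C|p.G1R"),
    list(chrom = "2", pos = 20, ref = "A", alt = "G",
         gt = c("0/0", "./."))))
  x <- readAnnotatedVcf(path, mf, chromOrder = c("2", "10"))
  # "Chr2" normalizes to "2"; chromosome order from the table, not lexical
  expect_equal(variantInfo(x)$chrom, c("2", "2", "10"))
  expect_equal(variantInfo(x)$pos, c(20L, 50L, 5L))
  out <- tempfile(fileext = ".vcf")
  writeVariantTableVcf(x, out)
  x2 <- readAnnotatedVcf(out, mf, chromOrder = c("2", "10"))
  expect_identical(variantInfo(x), variantInfo(x2))
  expect_identical(genotypeMatrix(x), genotypeMatrix(x2))
})
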