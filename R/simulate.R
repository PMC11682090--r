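# Seeded cohort simulator.
#
# Emits an annotated multi-sample VCF with three kinds of sites:
#   markers     dense common SNPs (no ANN) carrying the homozygosity
#               signal used for ROH detection
#   background  cohort-wide polymorphism under Hardy-Weinberg genotype
#               probabilities with per-variant allele frequency drawn
#               uniformly from a configured interval
#   plantings   MOI-consistent candidate variants stamped exactly as
#               configured (never randomised: different seeds change the
#               background, never the plantings)
# plus a sample manifest, a chromosome-length table, and a truth table
# recording every planting and homozygosity block.
#
# Inside a sample's planted ROH block every marker and background
# genotype of that sample is forced homozygous (as in a true autozygous
# segment); outside, genotypes follow Hardy-Weinberg draws.

#' Define a planted candidate variant
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles.
#' @param moi Mode of inheritance the planting is consistent with.
#' @param cases Case sample ids carrying the variant (HOM_ALT under the
#'   recessive models, HET under the dominant model).
#' @param control_het Named integer vector: population label -> number of
#'   heterozygous control carriers (assigned to the first samples of that
#'   population, deterministically). Must be empty/zero for dominant
#'   plantings ("absent in all controls").
#' @param gene Gene symbol stamped into the ANN field.
#' @param effect_terms Effect terms for the ANN field (joined by `&`).
#' @param impact ANN impact class.
#' @param hgvs_c,hgvs_p HGVS notations stamped verbatim.
#' @return Named list of class `moiscan_planting`.
#' @export
plantedVariant <- function(chrom, pos, ref, alt, moi, cases,
                           control_het = integer(0), gene,
                           effect_terms = "missense_variant",
                           impact = "MODERATE",
                           hgvs_c = "", hgvs_p = "") {
  moi <- match.arg(moi, MOI_LEVELS)
  if (moi == "DOMINANT_INDIVIDUAL" && sum(control_het) > 0)
    stop("dominant plantings must have zero control carriers")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = ref, alt = alt, moi = moi, cases = cases,
                 control_het = control_het, gene = gene,
                 effect_terms = effect_terms, impact = impact,
                 hgvs_c = hgvs_c, hgvs_p = hgvs_p),
            class = "moiscan_planting")
}

#' Simulation configuration
#'
#' @param n_cases Number of case genomes.
#' @param n_tier1_controls Tier-1 control cohort size.
#' @param tier2_populations Named integer vector: tier-2 population label
#'   -> size.
#' @param n_background_variants Number of background polymorphisms.
#' @param background_freq_range Interval for the per-variant background
#'   alternate-allele frequency, drawn uniformly (default
#'   `c(0.01, 0.5)`, a minimal neutral choice).
#' @param background_effect_probs Named probabilities over effect terms
#'   stamped on background variants.
#' @param background_fail_rate Fraction of background variants labelled
#'   FAIL instead of PASS.
#' @param plantings List of [plantedVariant()] objects.
#' @param roh_blocks `data.frame` with columns `scope` (a sample id or
#'   `"ALL_CASES"`), `chrom`, `start`, `end` (1-based inclusive bp).
#' @param chrom_lengths Named numeric vector of autosome lengths in bp.
#' @param marker_density Markers per Mb on the regular marker grid.
#' @param marker_freq_range Allele-frequency interval for markers.
#' @param case_population,tier1_population Population labels for cases
#'   and tier-1 controls.
#' @return Named list of class `moiscan_sim_config`.
#' @export
simConfig <- function(n_cases = 7,
                      n_tier1_controls = 120,
                      tier2_populations = c(swiss_holstein = 150,
                                            swiss_fleckvieh = 100,
                                            red_danish = 80,
                                            other_breeds = 100),
                      n_background_variants = 400,
                      background_freq_range = c(0.01, 0.5),
                      background_effect_probs = c(intron_variant = 0.5,
                                                  synonymous_variant = 0.3,
                                                  missense_variant = 0.2),
                      background_fail_rate = 0.02,
                      plantings = list(),
                      roh_blocks = data.frame(scope = character(0),
                                              chrom = character(0),
                                              start = numeric(0),
                                              end = numeric(0)),
                      chrom_lengths = c(`1` = 5e7, `2` = 5e7),
                      marker_density = 100,
                      marker_freq_range = c(0.05, 0.5),
                      case_population = "holstein_case",
                      tier1_population = "tier1_mixed") {
  stopifnot(n_cases >= 0, n_tier1_controls >= 0,
            all(tier2_populations >= 0), n_background_variants >= 0,
            marker_density >= 0)
  for (p in plantings) {
    if (!p$chrom %in% names(chrom_lengths) ||
        p$pos < 1 || p$pos > chrom_lengths[[p$chrom]])
      stop("planting outside chromosome bounds: ", p$chrom, ":", p$pos)
  }
  if (nrow(roh_blocks) &&
      any(roh_blocks$end > chrom_lengths[roh_blocks$chrom] |
          roh_blocks$start < 1))
    stop("ROH block outside chromosome bounds")
  structure(list(n_cases = n_cases, n_tier1_controls = n_tier1_controls,
                 tier2_populations = tier2_populations,
                 n_background_variants = n_background_variants,
                 background_freq_range = background_freq_range,
                 background_effect_probs = background_effect_probs,
                 background_fail_rate = background_fail_rate,
                 plantings = plantings, roh_blocks = roh_blocks,
                 chrom_lengths = chrom_lengths,
                 marker_density = marker_density,
                 marker_freq_range = marker_freq_range,
                 case_population = case_population,
                 tier1_population = tier1_population),
            class = "moiscan_sim_config")
}

simManifest <- function(config) {
  cases <- sprintf("case%d", seq_len(config$n_cases))
  t1 <- sprintf("t1_%03d", seq_len(config$n_tier1_controls))
  t2 <- unlist(lapply(names(config$tier2_populations), function(p)
    sprintf("%s_%03d", p, seq_len(config$tier2_populations[[p]]))),
    use.names = FALSE)
  t2pop <- rep(names(config$tier2_populations), config$tier2_populations)
  CohortManifest(
    sample = c(cases, t1, t2),
    role = c(rep("CASE", length(cases)),
             rep("TIER1_CONTROL", length(t1)),
             rep("TIER2_CONTROL", length(t2))),
    population = c(rep(config$case_population, length(cases)),
                   rep(config$tier1_population, length(t1)), t2pop))
}

annEntry <- function(alt, terms, impact, gene, hgvs_c = "", hgvs_p = "") {
  paste(alt, paste(terms, collapse = "&"), impact, gene, gene,
        "transcript", paste0(gene, ".t1"), "Coding", "1/1",
        hgvs_c, hgvs_p, sep = "|")
}

#' Simulate an annotated cohort
#'
#' Deterministic given `seed`: rerunning with the same configuration and
#' seed yields byte-identical output files. Different seeds change the
#' background polymorphism and marker genotypes but never the plantings.
#'
#' @param config A [simConfig()].
#' @param seed Integer RNG seed.
#' @param out_dir Output directory (created if needed). Files written:
#'   `cohort.vcf`, `cohort.tsv` (manifest), `autosomes.tsv`,
#'   `truth.json`.
#' @return Invisibly, a list with `paths` (named file paths), `manifest`
#'   (a [CohortManifest-class]) and `truth` (the truth table as a list).
#' @export
simulateCohort <- function(config, seed, out_dir) {
  stopifnot(inherits(config, "moiscan_sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))
  manifest <- simManifest(config)
  samples <- manifestTable(manifest)$sample
  ns <- length(samples)
  chroms <- names(config$chrom_lengths)

  plantKey <- vapply(config$plantings, function(p)
    paste0(p$chrom, ":", p$pos), character(1))

  # marker grid: regular spacing, dropped where a planting collides
  spacing <- if (config$marker_density > 0) 1e6 / config$marker_density else Inf
  mk <- do.call(rbind, lapply(chroms, function(ch) {
    if (!is.finite(spacing)) return(NULL)
    pos <- seq(from = round(spacing / 2), to = config$chrom_lengths[[ch]],
               by = round(spacing))
    data.frame(chrom = ch, pos = as.integer(pos), stringsAsFactors = FALSE)
  }))
  if (is.null(mk)) mk <- data.frame(chrom = character(0), pos = integer(0))
  collide <- paste0(mk$chrom, ":", mk$pos) %in% plantKey
  if (any(collide)) {
    message(sum(collide), " marker position(s) dropped (planting collision)")
    mk <- mk[!collide, , drop = FALSE]
  }

  # background positions: uniform, regenerated on any collision
  nbg <- config$n_background_variants
  taken <- c(plantKey, paste0(mk$chrom, ":", mk$pos))
  bgChrom <- character(nbg)
  bgPos <- integer(nbg)
  if (nbg > 0) {
    probs <- config$chrom_lengths / sum(config$chrom_lengths)
    for (i in seq_len(nbg)) {
      repeat {
        ch <- sample(chroms, 1L, prob = probs)
        p <- sample.int(config$chrom_lengths[[ch]], 1L)
        k <- paste0(ch, ":", p)
        if (!k %in% taken) break
        message("background position collision at ", k, "; regenerated")
      }
      bgChrom[i] <- ch
      bgPos[i] <- p
      taken <- c(taken, k)
    }
  }

  bases <- c("A", "C", "G", "T")
  bgRef <- sample(bases, nbg, replace = TRUE)
  bgAlt <- vapply(bgRef, function(r) sample(setdiff(bases, r), 1L),
                  character(1), USE.NAMES = FALSE)
  bgTerm <- if (nbg) sample(names(config$background_effect_probs), nbg,
                            replace = TRUE,
                            prob = config$background_effect_probs)
            else character(0)
  bgImpact <- c(intron_variant = "MODIFIER", synonymous_variant = "LOW",
                missense_variant = "MODERATE")[bgTerm]
  bgImpact[is.na(bgImpact)] <- "MODERATE"
  bgQual <- ifelse(stats::runif(nbg) < config$background_fail_rate,
                   "FAIL", "PASS")
  bgQ <- stats::runif(nbg, config$background_freq_range[1],
                      config$background_freq_range[2])

  nmk <- nrow(mk)
  mkQ <- stats::runif(nmk, config$marker_freq_range[1],
                      config$marker_freq_range[2])

  sites <- data.frame(
    kind = c(rep("marker", nmk), rep("background", nbg),
             rep("planting", length(config$plantings))),
    chrom = c(mk$chrom, bgChrom,
              vapply(config$plantings, `[[`, "", "chrom")),
    pos = c(mk$pos, bgPos,
            vapply(config$plantings, `[[`, 0L, "pos")),
    ref = c(rep("A", nmk), bgRef,
            vapply(config$plantings, `[[`, "", "ref")),
    alt = c(rep("G", nmk), bgAlt,
            vapply(config$plantings, `[[`, "", "alt")),
    qual = c(rep("PASS", nmk), bgQual,
             rep("PASS", length(config$plantings))),
    ann = c(rep("", nmk),
            if (nbg) annEntry(bgAlt, "", "", "") else character(0),
            vapply(config$plantings, function(p)
              annEntry(p$alt, p$effect_terms, p$impact, p$gene,
                       p$hgvs_c, p$hgvs_p), character(1))),
    q = c(mkQ, bgQ, rep(0, length(config$plantings))),
    stringsAsFactors = FALSE)
  # background ANN entries need per-variant term/gene
  if (nbg) {
    sites$ann[sites$kind == "background"] <- vapply(seq_len(nbg), function(i)
      annEntry(bgAlt[i], bgTerm[i], bgImpact[i], sprintf("BG%04d", i),
               "c.?", "p.?"), character(1))
  }

  # Hardy-Weinberg genotype draws (variants x samples)
  nsite <- nrow(sites)
  G <- matrix(stats::rbinom(nsite * ns, 2L, rep(sites$q, ns)),
              nrow = nsite, ncol = ns, dimnames = list(NULL, samples))

  # force homozygosity inside planted ROH blocks (markers + background)
  blocks <- config$roh_blocks
  caseSamples <- caseIds(manifest)
  if (nrow(blocks)) {
    for (b in seq_len(nrow(blocks))) {
      scope <- if (blocks$scope[b] == "ALL_CASES") caseSamples
               else blocks$scope[b]
      rows <- which(sites$kind != "planting" &
                      sites$chrom == blocks$chrom[b] &
                      sites$pos >= blocks$start[b] &
                      sites$pos <= blocks$end[b])
      if (!length(rows)) next
      q <- sites$q[rows]
      pHomAlt <- q^2 / (q^2 + (1 - q)^2)
      for (s in scope) {
        G[rows, s] <- ifelse(stats::runif(length(rows)) < pHomAlt, 2L, 0L)
      }
    }
  }

  # stamp plantings exactly (deterministic: no RNG draws)
  mtab <- manifestTable(manifest)
  for (j in seq_along(config$plantings)) {
    p <- config$plantings[[j]]
    row <- nmk + nbg + j
    G[row, ] <- 0L
    gtCase <- if (p$moi == "DOMINANT_INDIVIDUAL") 1L else 2L
    G[row, p$cases] <- gtCase
    for (pop in names(p$control_het)) {
      k <- p$control_het[[pop]]
      if (k == 0) next
      popSamples <- mtab$sample[mtab$population == pop &
                                  mtab$role != "CASE"]
      if (k > length(popSamples))
        stop("planting asks for ", k, " carriers in population ", pop,
             " of size ", length(popSamples))
      G[row, popSamples[seq_len(k)]] <- 1L
    }
  }

  ord <- variantOrder(sites$chrom, sites$pos, sites$ref, sites$alt, chroms)
  sites <- sites[ord, , drop = FALSE]
  G <- G[ord, , drop = FALSE]

  paths <- c(vcf = file.path(out_dir, "cohort.vcf"),
             manifest = file.path(out_dir, "cohort.tsv"),
             genome = file.path(out_dir, "autosomes.tsv"),
             truth = file.path(out_dir, "truth.json"))

  gtStr <- matrix(c("0/0", "0/1", "1/1")[G + 1L], nrow = nrow(G))
  gtStr[is.na(G)] <- "./."
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", chroms,
                   as.integer(config$chrom_lengths)),
           "##FILTER=<ID=FAIL,Description=\"Failed quality label\">",
           paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=",
                  "\"Functional annotations: 'Allele|Annotation|",
                  "Annotation_Impact|Gene_Name|Gene_ID|Feature_Type|",
                  "Feature_ID|Transcript_BioType|Rank|HGVS.c|HGVS.p'\">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  info <- ifelse(nzchar(sites$ann), paste0("ANN=", sites$ann), ".")
  gtCols <- do.call(paste, c(as.data.frame(gtStr, stringsAsFactors = FALSE),
                             sep = "\t"))
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                sites$qual, info, "GT", gtCols, sep = "\t")
  writeLines(c(hdr, body), paths[["vcf"]])
  writeCohortManifest(manifest, paths[["manifest"]])
  utils::write.table(
    data.frame(chrom = chroms, length = as.integer(config$chrom_lengths)),
    paths[["genome"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  planted_froh <- vapply(caseSamples, function(cs) {
    if (!nrow(blocks)) return(0)
    sel <- blocks$scope == "ALL_CASES" | blocks$scope == cs
    sum(blocks$end[sel] - blocks$start[sel] + 1) / sum(config$chrom_lengths)
  }, numeric(1))

  truth <- list(
    seed = as.integer(seed),
    n_samples = ns,
    plantings = lapply(config$plantings, function(p) list(
      key = paste(p$chrom, p$pos, p$ref, p$alt, sep = ":"),
      moi = p$moi, cases = p$cases, gene = p$gene,
      control_het = as.list(p$control_het),
      expected_stage = "POST_TIER2")),
    roh_blocks = lapply(seq_len(nrow(blocks)), function(b) list(
      scope = blocks$scope[b], chrom = blocks$chrom[b],
      start = blocks$start[b], end = blocks$end[b])),
    planted_froh = as.list(planted_froh))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, manifest = manifest, truth = truth))
}
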