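# Independent brute-force oracles and in-memory cohort generators.
# These re-derive every filter definition with explicit per-variant /
# per-sample loops (or per-window feasibility checks for ROH), sharing no
# code path with the package implementations they check.

# ---- random in-memory cohorts ------------------------------------------

annPool <- function() {
  c("",
    "A|missense_variant|MODERATE|GENE1|g|transcript|t|Coding|1/2|c.1A>G|p.K1R",
    "A|synonymous_variant|LOW|GENE2|g|transcript|t|Coding|1/2|c.3A>G|",
    "A|intron_variant|MODIFIER|GENE3|g|transcript|t|Coding||",
    "A|splice_donor_variant&intron_variant|HIGH|GENE4|g|transcript|t|Coding||",
    paste0("A|disruptive_inframe_deletion|MODERATE|GENE5|g|transcript|t|",
           "Coding|1/1|c.9_20del|p.P4_E7del"),
    paste0("A|missense_variant|MODERATE|GENE6|g|transcript|t|Coding|1/2|",
           "c.5C>T|p.A2V,A|intron_variant|MODIFIER|GENE6|g|transcript|t|||"))
}

randomCohort <- function(seed, max_var = 500, max_samp = 30) {
  set.seed(seed)
  nvar <- sample(20:min(150, max_var), 1)
  ncase <- sample(1:4, 1)
  nt1 <- sample(2:10, 1)
  nt2 <- sample(0:10, 1)
  samples <- c(sprintf("c%02d", seq_len(ncase)),
               sprintf("u%02d", seq_len(nt1)),
               if (nt2) sprintf("w%02d", seq_len(nt2)))
  manifest <- CohortManifest(
    sample = samples,
    role = c(rep("CASE", ncase), rep("TIER1_CONTROL", nt1),
             rep("TIER2_CONTROL", nt2)),
    population = sample(c("popA", "popB"), length(samples), replace = TRUE))
  g <- matrix(sample(c(0L, 1L, 2L, NA), nvar * length(samples),
                     replace = TRUE, prob = c(0.55, 0.2, 0.15, 0.1)),
              nrow = nvar, dimnames = list(NULL, samples))
  v <- data.frame(
    chrom = sample(c("1", "2"), nvar, replace = TRUE),
    pos = sample.int(1e6, nvar),
    ref = sample(c("A", "C", "G", "T"), nvar, replace = TRUE),
    alt = "N", qual_label = sample(c("PASS", "FAIL", "UNLABELED"), nvar,
                                   replace = TRUE, prob = c(0.85, .08, .07)),
    ann = sample(annPool(), nvar, replace = TRUE),
    stringsAsFactors = FALSE)
  v$alt <- vapply(v$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  v <- v[!duplicated(v[, c("chrom", "pos")]), , drop = FALSE]
  g <- g[seq_len(nrow(v)), , drop = FALSE]
  list(x = VariantTable(v, g, c("1", "2")), manifest = manifest)
}

randomFilterConfig <- function(seed) {
  set.seed(seed + 7777)
  filterConfig(
    recessive_max_control_het_tier1 = sample(c(0, 1, 2, Inf), 1),
    recessive_max_control_homalt_tier1 = sample(c(0, 1), 1),
    dominant_max_control_alt_alleles_tier1 = sample(c(0, 1), 1),
    recessive_max_control_het_tier2 = sample(c(0, 2, Inf), 1),
    recessive_max_control_homalt_tier2 = sample(c(0, 1), 1),
    dominant_max_control_alt_alleles_tier2 = sample(c(0, 1), 1),
    include_unlabeled = sample(c(TRUE, FALSE), 1))
}

# ---- brute-force MOI filter oracle -------------------------------------

bruteQualOk <- function(lbl, cfg) {
  if (!cfg$require_pass) return(TRUE)
  lbl == "PASS" || (cfg$include_unlabeled && lbl == "UNLABELED")
}

brutePrivateTier1 <- function(x, manifest, moi, case_id, cfg) {
  g <- genotypeMatrix(x)
  v <- variantInfo(x)
  m <- manifestTable(manifest)
  cases <- m$sample[m$role == "CASE"]
  t1 <- m$sample[m$role == "TIER1_CONTROL"]
  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    if (!bruteQualOk(v$qual_label[i], cfg)) next
    gi <- g[i, ]
    zyg <- switch(moi,
      RECESSIVE_SHARED = {
        ok <- TRUE
        for (cs in cases)
          if (is.na(gi[[cs]]) || gi[[cs]] != 2L) ok <- FALSE
        ok
      },
      RECESSIVE_INDIVIDUAL = !is.na(gi[[case_id]]) && gi[[case_id]] == 2L,
      DOMINANT_INDIVIDUAL = !is.na(gi[[case_id]]) && gi[[case_id]] >= 1L)
    if (!zyg) next
    het <- 0L; hom <- 0L; dos <- 0L
    for (s in t1) {
      gs <- gi[[s]]
      if (is.na(gs)) next
      if (gs == 1L) het <- het + 1L
      if (gs == 2L) hom <- hom + 1L
      dos <- dos + gs
    }
    keep[i] <- if (moi == "DOMINANT_INDIVIDUAL")
      dos <= cfg$dominant_max_control_alt_alleles_tier1
    else hom <= cfg$recessive_max_control_homalt_tier1 &&
      het <= cfg$recessive_max_control_het_tier1
  }
  keep
}

bruteProteinChanging <- function(ann, terms) {
  vapply(ann, function(a) {
    if (!nzchar(a)) return(FALSE)
    for (entry in strsplit(a, ",", fixed = TRUE)[[1]]) {
      f <- strsplit(entry, "|", fixed = TRUE)[[1]]
      if (length(f) < 4) next
      for (term in strsplit(f[2], "&", fixed = TRUE)[[1]])
        if (term %in% terms) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

bruteTier2 <- function(x, manifest, moi, cfg) {
  g <- genotypeMatrix(x)
  m <- manifestTable(manifest)
  t2 <- m$sample[m$role == "TIER2_CONTROL"]
  keep <- logical(nrow(g))
  for (i in seq_len(nrow(g))) {
    het <- 0L; hom <- 0L; dos <- 0L
    for (s in t2) {
      gs <- g[i, s]
      if (is.na(gs)) next
      if (gs == 1L) het <- het + 1L
      if (gs == 2L) hom <- hom + 1L
      dos <- dos + gs
    }
    keep[i] <- if (moi == "DOMINANT_INDIVIDUAL")
      dos <= cfg$dominant_max_control_alt_alleles_tier2
    else hom <= cfg$recessive_max_control_homalt_tier2 &&
      het <= cfg$recessive_max_control_het_tier2
  }
  keep
}

# Full-funnel brute oracle: final POST_TIER2 keys.
bruteFinalKeys <- function(x, manifest, moi, case_id, cfg) {
  keep <- brutePrivateTier1(x, manifest, moi, case_id, cfg) &
    bruteProteinChanging(variantInfo(x)$ann, cfg$protein_changing_terms) &
    bruteTier2(x, manifest, moi, cfg)
  variantKeys(x)[keep]
}

# ---- brute-force consecutive-runs ROH oracle ---------------------------

# Re-derives runs from per-window feasibility: from each scan position the
# earliest homozygous start is taken, the feasibility horizon is found from
# cumulative het/missing counts and gap violations, the window is trimmed
# to its last homozygous marker, and the scan resumes at the violation.
bruteRoh <- function(track, p) {
  out <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    pos <- tr$pos
    g <- tr$geno
    n <- length(pos)
    hom <- !is.na(g) & g != 1L
    het <- !is.na(g) & g == 1L
    mis <- is.na(g)
    cumHet <- cumsum(het)
    cumMis <- cumsum(mis)
    gapBad <- c(FALSE, diff(pos) > p$max_gap)
    cursor <- 1L
    repeat {
      starts <- which(hom)
      starts <- starts[starts >= cursor]
      if (!length(starts)) break
      s <- starts[1]
      viol <- n + 1L
      if (s < n) {
        j <- (s + 1L):n
        bad <- (cumHet[j] - cumHet[s]) > p$max_opposite |
          (cumMis[j] - cumMis[s]) > p$max_missing | gapBad[j]
        if (any(bad)) viol <- j[which(bad)[1]]
      }
      inWin <- s:(viol - 1L)
      lastHom <- max(inWin[hom[inWin]])
      nHom <- sum(hom[s:lastHom])
      if (nHom >= p$min_snp && pos[lastHom] - pos[s] + 1L >= p$min_length)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = pos[s], end = pos[lastHom], n_snp = nHom,
          stringsAsFactors = FALSE)
      cursor <- viol
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snp = integer(0)))
  do.call(rbind, out)
}

randomTrack <- function(seed, max_markers = 1000) {
  set.seed(seed)
  n <- sample(50:max_markers, 1)
  chrom <- sort(sample(c("1", "2"), n, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(i)
    sort(sample.int(5e6, length(i)))), use.names = FALSE)
  data.frame(chrom = chrom, pos = pos,
             geno = sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                           prob = c(0.45, 0.25, 0.2, 0.1)),
             stringsAsFactors = FALSE)
}

rohToDf <- function(gr) {
  ns <- S4Vectors::mcols(gr)$n_snp
  if (is.null(ns)) ns <- rep(NA_integer_, length(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             n_snp = ns,
             stringsAsFactors = FALSE)
}

# ---- sweep-line oracle for shared regions ------------------------------

# Interval intersection across cases by event sweep over per-case unions.
bruteShared <- function(roh_by_case, min_len) {
  ncase <- length(roh_by_case)
  dfs <- lapply(roh_by_case, rohToDf)
  chroms <- unique(unlist(lapply(dfs, `[[`, "chrom")))
  out <- list()
  for (ch in chroms) {
    ev <- list()
    for (d in dfs) {
      dch <- d[d$chrom == ch, , drop = FALSE]
      if (nrow(dch))
        ev[[length(ev) + 1L]] <- data.frame(
          pos = c(dch$start, dch$end + 1L),
          delta = rep(c(1L, -1L), each = nrow(dch)))
    }
    if (length(ev) < ncase) next  # some case has nothing on this chrom
    ev <- do.call(rbind, ev)
    ev <- stats::aggregate(delta ~ pos, ev, sum)
    ev <- ev[ev$delta != 0L, , drop = FALSE]  # no-op breakpoints
    ev <- ev[order(ev$pos), ]
    cov <- cumsum(ev$delta)
    full <- which(cov == ncase)
    for (k in full) {
      start <- ev$pos[k]
      end <- ev$pos[k + 1L] - 1L
      if (end - start + 1L >= min_len)
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = start,
                                              end = end)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}
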