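# Consecutive-runs ROH detection, shared regions, F_ROH.

test_that("basic runs: all-het tracks yield nothing, clean hom tracks one run", {
  p <- rohParams(min_snp = 20, min_length = 50000, max_gap = 1e6,
                 max_opposite = 1, max_missing = 1)
  allHet <- data.frame(chrom = "1", pos = seq(1000, by = 5000,
                                              length.out = 50),
                       geno = 1L)
  expect_length(detectRohConsecutive(allHet, p), 0L)
  # 100 consecutive hom markers over 500 kb -> exactly one segment
  hom <- data.frame(chrom = "1",
                    pos = seq(10000, by = 5000, length.out = 100),
                    geno = rep(c(0L, 2L), 50))
  gr <- detectRohConsecutive(hom, p, sample_id = "s")
  expect_length(gr, 1L)
  expect_equal(S4Vectors::mcols(gr)$n_snp, 100L)
  expect_equal(GenomicRanges::start(gr), 10000L)
  expect_equal(GenomicRanges::end(gr), 10000L + 99L * 5000L)
  # unsorted input is a hard error
  bad <- hom[c(2, 1, 3:100), ]
  expect_error(detectRohConsecutive(bad, p), "sorted")
})

test_that("run boundaries trim to homozygous markers and tolerances are enforced", {
  p <- rohParams(min_snp = 3, min_length = 10, max_gap = 1000,
                 max_opposite = 1, max_missing = 0)
  tr <- data.frame(chrom = "1",
                   pos = c(100, 200, 300, 400, 500, 600, 700),
                   geno = c(1L, 0L, 1L, 2L, 0L, 1L, 1L))
  gr <- detectRohConsecutive(tr, p)
  # run starts at first hom (200), absorbs one het, ends at last hom (500)
  expect_equal(GenomicRanges::start(gr), 200L)
  expect_equal(GenomicRanges::end(gr), 500L)
  expect_equal(S4Vectors::mcols(gr)$n_het_inside, 1L)
  # a gap beyond max_gap splits runs
  p2 <- rohParams(min_snp = 2, min_length = 10, max_gap = 150,
                  max_opposite = 0, max_missing = 0)
  tr2 <- data.frame(chrom = "1", pos = c(100, 200, 1000, 1100),
                    geno = 0L)
  gr2 <- detectRohConsecutive(tr2, p2)
  expect_length(gr2, 2L)
})

test_that("detection equals the window-feasibility brute oracle on random tracks", {
  for (seed in 1:40) {
    track <- randomTrack(seed, max_markers = 400)
    set.seed(seed + 999)
    p <- rohParams(min_snp = sample(2:6, 1),
                   min_length = sample(c(1e3, 1e4, 1e5), 1),
                   max_gap = sample(c(5e4, 2e5, 1e6), 1),
                   max_opposite = sample(0:2, 1),
                   max_missing = sample(0:2, 1))
    got <- rohToDf(detectRohConsecutive(track, p))
    want <- bruteRoh(track, p)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[, c("chrom", "start", "end", "n_snp")], want)
  }
})

test_that("segments are maximal and tightening parameters never adds ROH", {
  for (seed in 1:15) {
    track <- randomTrack(seed + 100, max_markers = 300)
    p <- rohParams(min_snp = 4, min_length = 5e3, max_gap = 5e5,
                   max_opposite = 1, max_missing = 1)
    gr <- detectRohConsecutive(track, p)
    df <- rohToDf(gr)
    for (ch in unique(df$chrom)) {
      tr <- track[track$chrom == ch, ]
      segs <- df[df$chrom == ch, ]
      hom <- !is.na(tr$geno) & tr$geno != 1L
      valid <- function(i, j) {
        if (!hom[i] || !hom[j]) return(FALSE)
        w <- tr$geno[i:j]
        sum(!is.na(w) & w == 1L) <= p$max_opposite &&
          sum(is.na(w)) <= p$max_missing &&
          all(diff(tr$pos[i:j]) <= p$max_gap)
      }
      for (k in seq_len(nrow(segs))) {
        i <- match(segs$start[k], tr$pos)
        j <- match(segs$end[k], tr$pos)
        # right-maximality: no homozygous extension to the right is valid
        right <- which(hom & seq_along(hom) > j)
        if (length(right)) expect_false(valid(i, right[1]))
      }
    }
    # monotonicity: stricter min_snp / min_length never increases output
    stricter <- rohParams(min_snp = 8, min_length = 2e4, max_gap = 5e5,
                          max_opposite = 1, max_missing = 1)
    gr2 <- detectRohConsecutive(track, stricter)
    expect_lte(length(gr2), length(gr))
    expect_lte(sum(GenomicRanges::width(gr2)),
               sum(GenomicRanges::width(gr)))
  }
})

test_that("shared regions are the cross-case intersection, order-invariant", {
  seg <- function(chrom, start, end, id = "x")
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                           sample_id = id, n_snp = 10L,
                           n_het_inside = 0L, n_missing_inside = 0L)
  a <- seg("1", 1000, 50000)
  # identical single segments intersect to themselves
  sh <- sharedHomozygousRegions(list(c1 = a, c2 = a),
                                min_shared_length = 1000)
  expect_equal(sh$total_bp, 49001)
  expect_length(sh$regions, 1L)
  # an empty case empties the intersection
  empty <- seg("1", 1, 1)[0]
  sh0 <- sharedHomozygousRegions(list(c1 = a, c2 = empty))
  expect_length(sh0$regions, 0L)
  expect_equal(sh0$total_bp, 0)
  expect_error(sharedHomozygousRegions(list()), "case")
  # random multi-case intersections equal the sweep-line oracle and are
  # commutative in case order
  for (seed in 1:25) {
    set.seed(seed)
    ncase <- sample(2:5, 1)
    rohs <- lapply(seq_len(ncase), function(i) {
      n <- sample(1:6, 1)
      start <- sort(sample.int(5e5, n)) * 10L
      width <- sample(1e4:2e5, n, replace = TRUE)
      GenomicRanges::reduce(seg("1", start, start + width))
    })
    names(rohs) <- sprintf("c%d", seq_len(ncase))
    minLen <- sample(c(1e3, 1e4, 5e4), 1)
    got <- sharedHomozygousRegions(rohs, minLen)
    gotDf <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(got$regions)),
      start = GenomicRanges::start(got$regions),
      end = GenomicRanges::end(got$regions), stringsAsFactors = FALSE)
    want <- bruteShared(rohs, minLen)
    rownames(gotDf) <- rownames(want) <- NULL
    expect_equal(gotDf, want[, c("chrom", "start", "end")])
    perm <- sample(ncase)
    expect_equal(sharedHomozygousRegions(rohs[perm], minLen)$total_bp,
                 got$total_bp)
  }
})

test_that("F_ROH is segment length over autosome length", {
  seg <- function(chrom, start, end)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  lens <- c(`1` = 1e8)
  expect_equal(genomicInbreeding(list(s = seg("1", 1, 1)[0]), lens)$
                 per_sample$froh, 0)
  expect_equal(genomicInbreeding(list(s = seg("1", 1, 1e8)), lens)$
                 per_sample$froh, 1)
  two <- c(seg("1", 1, 2e6), seg("1", 5e6, 5e6 + 3e6 - 1))
  expect_equal(genomicInbreeding(list(s = two), lens)$per_sample$froh, 0.05)
  # cohort mean and sd over the designated group
  res <- genomicInbreeding(list(a = seg("1", 1, 2e7), b = seg("1", 1, 4e7)),
                           lens)
  expect_equal(res$mean, 0.3)
  expect_equal(res$sd, stats::sd(c(0.2, 0.4)))
  # chromosome missing from the table is a hard error
  expect_error(genomicInbreeding(list(s = seg("9", 1, 100)), lens),
               "absent")
})
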