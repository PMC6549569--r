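test_that("reads group into families by position and barcode pair", {
  a <- make_family_records(2, rep("ACGTACGTAC", 2), qprefix = "a")
  b <- make_family_records(1, "ACGTACGTAC", umi1 = "GGGGGG", qprefix = "b")
  d <- make_family_records(1, "ACGTACGTAC", frag_start = 101L,
                           qprefix = "c")
  fams <- group_families(rbind(a, b, d))
  expect_equal(nrow(fams$families), 3L)
  expect_equal(sort(fams$families$size), c(1L, 1L, 2L))
  # every usable record belongs to exactly one family
  expect_false(anyNA(fams$records$family_id))
  expect_equal(nrow(fams$records), nrow(a) + nrow(b) + nrow(d))
})

test_that("unmapped and secondary records are excluded and counted", {
  a <- make_family_records(3, rep("ACGTACGTAC", 3))
  a$unmapped <- c(rep(FALSE, 5), TRUE)
  a$secondary <- c(TRUE, rep(FALSE, 5))
  fams <- group_families(a)
  expect_equal(unname(fams$excluded["unmapped"]), 1L)
  expect_equal(unname(fams$excluded["secondary"]), 1L)
  expect_equal(nrow(fams$records), 4L)
  a$umi1 <- NULL
  expect_error(group_families(a), "barcode")
})

test_that("consensus requires three reads and 90% agreement, inclusively", {
  expect_equal(call_sscs(rep("ACGTACGT", 3)), "ACGTACGT")
  expect_null(call_sscs(rep("ACGTACGT", 2)))
  # 9 of 10 As: 0.90 >= 0.90 calls A
  seqs <- c(rep("A", 9), "C")
  expect_equal(call_sscs(seqs), "A")
  # 8 of 10: 0.80 < 0.90 gives N
  expect_equal(call_sscs(c(rep("A", 8), "C", "C")), "N")
  # member Ns are excluded from the agreement denominator
  expect_equal(call_sscs(c("A", "A", "A", "N", "N")), "A")
  # a position that is all N stays N
  expect_equal(call_sscs(rep("NA", 3)), "NA")
  expect_error(call_sscs(character(0)), "empty")
})

test_that("consensus agrees with the brute-force tally oracle", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(1:20, 1)
    len <- sample(1:50, 1)
    fam <- random_family(n, len)
    expect_identical(call_sscs(fam), consensus_oracle(fam),
                     info = sprintf("case %d: n=%d len=%d", i, n, len))
  }
})

test_that("an agreeing read never flips a called base to N", {
  set.seed(202)
  for (i in 1:50) {
    fam <- random_family(sample(3:12, 1), sample(5:30, 1))
    cons <- call_sscs(fam)
    grown <- call_sscs(c(fam, cons))
    called <- strsplit(cons, "")[[1]] != "N"
    expect_true(all(strsplit(grown, "")[[1]][called] ==
                      strsplit(cons, "")[[1]][called]))
  }
})

test_that("end masking replaces five bases at either end, keeping length", {
  s <- strrep("ACGTG", 15)  # 75 bases
  m <- mask_ends(s, 5)
  expect_equal(nchar(m), 75L)
  expect_equal(substr(m, 1, 5), "NNNNN")
  expect_equal(substr(m, 71, 75), "NNNNN")
  expect_equal(substr(m, 6, 70), substr(s, 6, 70))
  expect_equal(mask_ends(s, 0), s)
  short <- mask_ends("ACGTACGT", 5)
  expect_equal(short, "NNNNNNNN")
  expect_true(is_all_n(short))
  expect_false(is_all_n(m))
})

test_that("mate overlap contributes one base per fragment position", {
  # mates over [100,110) and [105,115): 5 bp overlap, all agreeing
  recs <- make_family_records(
    3, rep("AAAAACCCCC", 3), rep("CCCCCGGGGG", 3),
    frag_start = 100L, frag_end = 115L)
  res <- run_consensus_pipeline(recs, mask_n = 0)
  expect_equal(nrow(res$fragments), 1L)
  expect_equal(res$fragments$bases, "AAAAACCCCCGGGGG")
  expect_equal(res$fragments$end - res$fragments$start, 15L)
})

test_that("overlap disagreement gives N; one-sided N defers to the call", {
  sscs <- data.table::data.table(
    family_id = 1L, mate = 1:2, chrom = "chr1",
    start = c(100L, 105L), end = c(110L, 115L),
    bases = c("AAAAACCCCC", "GCCCNGGGGG"),
    frag_start = 100L, frag_end = 115L, orientation = "F1R2",
    umi1 = "AAAAAA", umi2 = "CCCCCC", sample_id = "A", family_size = 3L)
  out <- collapse_mate_overlap(sscs)
  expect_equal(out$n_discordant, 0L)
  # pos 105: C vs G -> N; 106-108: agree C; 109: C vs N -> C
  expect_equal(out$fragments$bases, "AAAAANCCCCGGGGG")
})

test_that("discordant-chromosome fragments are dropped and counted", {
  sscs <- data.table::data.table(
    family_id = 1L, mate = 1:2, chrom = c("chr1", "chr2"),
    start = c(100L, 105L), end = c(110L, 115L),
    bases = c("AAAAACCCCC", "CCCCCGGGGG"),
    frag_start = 100L, frag_end = 115L, orientation = "F1R2",
    umi1 = "AAAAAA", umi2 = "CCCCCC", sample_id = "A", family_size = 3L)
  out <- collapse_mate_overlap(sscs)
  expect_equal(out$n_discordant, 1L)
  expect_equal(nrow(out$fragments), 0L)
})

test_that("disjoint mates concatenate their coverage with an N gap", {
  recs <- make_family_records(3, rep("AAAAA", 3), rep("GGGGG", 3),
                              frag_start = 100L, frag_end = 112L)
  res <- run_consensus_pipeline(recs, mask_n = 0)
  expect_equal(res$fragments$bases, "AAAAANNGGGGG")
})

test_that("tag-swap filter removes single-barcode matches at identical spans", {
  frags <- data.frame(
    chrom = "chr1", start = c(100L, 100L), end = c(250L, 250L),
    umi1 = c("AAAAAA", "AAAAAA"), umi2 = c("CCCCCC", "GGGGGG"),
    family_size = c(5L, 3L), sample_id = "A", stringsAsFactors = FALSE)
  out <- filter_tag_swaps(frags)
  expect_equal(out$n_removed, 1L)
  expect_equal(out$kept$family_size, 5L)
  expect_equal(out$kept$umi2, "CCCCCC")

  # both barcodes differ: both kept
  frags2 <- frags
  frags2$umi1 <- c("AAAAAA", "TTTTTT")
  expect_equal(filter_tag_swaps(frags2)$n_removed, 0L)

  # identical barcodes but end differs by 1: grouping is exact, both kept
  frags3 <- frags
  frags3$umi2 <- c("CCCCCC", "CCCCCC")
  frags3$end <- c(250L, 251L)
  expect_equal(filter_tag_swaps(frags3)$n_removed, 0L)
})

test_that("tag-swap filter is idempotent, shrinking, and chains transitively", {
  set.seed(7)
  n <- 40
  frags <- data.frame(
    chrom = "chr1", start = rep(c(100L, 300L), each = n / 2),
    end = rep(c(250L, 450L), each = n / 2),
    umi1 = sample(c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT"), n, TRUE),
    umi2 = sample(c("ACACAC", "GTGTGT", "CACACA", "TGTGTG"), n, TRUE),
    family_size = sample(1:10, n, TRUE), sample_id = "A",
    stringsAsFactors = FALSE)
  once <- filter_tag_swaps(frags)
  twice <- filter_tag_swaps(once$kept)
  expect_equal(twice$n_removed, 0L)
  expect_identical(as.data.frame(twice$kept), as.data.frame(once$kept))
  expect_lte(nrow(once$kept), nrow(frags))
  # every position group retains at least one representative
  before <- unique(paste(frags$chrom, frags$start, frags$end))
  after <- unique(paste(once$kept$chrom, once$kept$start, once$kept$end))
  expect_setequal(after, before)

  # transitive chain a-b (umi1), b-c (umi2) collapses to one survivor
  chain <- data.frame(
    chrom = "chr1", start = 1L, end = 100L,
    umi1 = c("AAAAAA", "AAAAAA", "TTTTTT"),
    umi2 = c("CCCCCC", "GGGGGG", "GGGGGG"),
    family_size = c(2L, 9L, 4L), sample_id = "A", stringsAsFactors = FALSE)
  out <- filter_tag_swaps(chain)
  expect_equal(out$n_removed, 2L)
  expect_equal(out$kept$family_size, 9L)
})

test_that("pipeline counts are conserved across stages", {
  set.seed(9)
  recs <- do.call(rbind, lapply(1:30, function(i) {
    n <- sample(1:6, 1)
    make_family_records(n, rep(random_family(1, 20, n_rate = 0), n),
                        umi1 = paste(sample(c("A","C","G","T"), 6, TRUE),
                                     collapse = ""),
                        umi2 = paste(sample(c("A","C","G","T"), 6, TRUE),
                                     collapse = ""),
                        frag_start = 100L + 30L * i,
                        qprefix = paste0("f", i, "_"))
  }))
  res <- run_consensus_pipeline(recs, mask_n = 2)
  m <- res$metrics
  expect_equal(m$families_in,
               m$families_below_min_size + m$families_umi_n +
                 m$families_inconsistent + m$families_consensused)
  expect_equal(m$fragments_out,
               m$families_consensused - m$fragments_discordant -
                 m$tag_swaps_removed)
})

test_that("families keyed on an N-containing UMI are omitted and counted", {
  good <- make_family_records(3, rep("ACGTACGTAC", 3), qprefix = "g")
  nn <- make_family_records(3, rep("ACGTACGTAC", 3), umi1 = "AANAAA",
                            frag_start = 200L, qprefix = "n")
  res <- run_consensus_pipeline(rbind(good, nn), mask_n = 0)
  expect_equal(res$metrics$families_umi_n, 1L)
  expect_equal(nrow(res$fragments), 1L)
})

test_that("panel pileup counts alt, other and N calls at covered sites", {
  frags <- data.frame(
    chrom = "chrS", start = c(490L, 495L, 498L, 480L),
    end = c(510L, 515L, 518L, 510L),
    bases = c(strrep("T", 20), strrep("A", 20), strrep("G", 20),
              strrep("N", 30)),
    umi1 = "AAAAAA", umi2 = "CCCCCC", family_size = 3L, sample_id = "A",
    stringsAsFactors = FALSE)
  pu <- pileup_panel(frags, make_pileup()[, c("chrom", "pos", "ref", "alt")])
  expect_equal(pu$depth, 4L)
  expect_equal(pu$alt_count, 1L)   # the T track
  expect_equal(pu$n_count, 1L)     # the N track
  expect_equal(pu$other_count, 1L) # the G track (site ref is A)
  pu0 <- pileup_panel(frags[0, ], make_pileup()[, c("chrom","pos","ref","alt")])
  expect_equal(pu0$depth, 0L)
})
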