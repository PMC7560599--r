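test_that("cohort metadata fixture parses with the published counts", {
  path <- system.file("extdata", "table1.tsv", package = "relapsevo")
  meta <- read_cohort_metadata(path)
  s <- cohort_metadata_summary(meta)
  expect_equal(s$n_patients, 80L)
  expect_equal(s$n_paired, 24L)
  expect_equal(s$n_t4_14, 38L)
  expect_equal(s$n_t11_14, 38L)
  expect_equal(s$n_t14_16, 4L)
  expect_true(all(meta$pathway %in% c("intensive", "nonintensive")))
  expect_true(all(is.na(meta$maintenance) |
                    meta$maintenance != "Missing"))
})

test_that("somatic indel filter applies support and germline-distance rules", {
  indels <- data.frame(
    sample_id = "S1", timepoint = "primary", chrom = "1",
    pos = c(100L, 500L, 900L, 1300L),
    ref = "A", alt = "AT", class = "indel",
    support_frac = c(0.15, 0.25, 0.50, NA),
    stringsAsFactors = FALSE)
  germ <- data.frame(chrom = "1", pos = c(110L, 511L),
                     stringsAsFactors = FALSE)
  expect_warning(out <- filter_somatic_indels(indels, germ),
                 "missing support_frac")
  # 0.15 support removed; pos 100 is exactly 10 bp from a germline indel
  # (removed anyway); pos 500 is 11 bp away with support 0.25 (kept)
  expect_equal(out$pos, c(500L, 900L))
  rej <- attr(out, "rejected")
  expect_setequal(rej$reject_reason[rej$pos == 1300L],
                  "missing support_frac")
  # boundary: distance exactly 10 excludes
  one <- indels[2, ]; one$pos <- 120L
  expect_equal(nrow(filter_somatic_indels(one, germ)), 0L)
  # idempotence
  out2 <- suppressWarnings(filter_somatic_indels(out, germ))
  expect_equal(out2$pos, out$pos)
})

test_that("SV consensus requires two callers and is order invariant", {
  sv <- function(p1, p2) data.frame(chrom1 = "3", pos1 = p1, chrom2 = "3",
                                    pos2 = p2, orientation = "+-",
                                    stringsAsFactors = FALSE)
  a <- rbind(sv(1000, 5000), sv(90000, 95000))
  b <- sv(1050, 5040)
  c <- sv(1010, 5010)
  expect_error(consensus_sv(list(a)), "two callers")
  out <- consensus_sv(list(a, b, c), tol_bp = 100)
  expect_equal(nrow(out), 1L)          # the singleton SV is excluded
  expect_equal(out$pos1, 1010)         # median of 1000, 1050, 1010
  expect_equal(out$n_callers, 3L)
  # identical SV in all three callers emitted once
  out3 <- consensus_sv(list(sv(7, 70), sv(7, 70), sv(7, 70)))
  expect_equal(nrow(out3), 1L)
  # permutation invariance over caller order
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(consensus_sv(list(a, b, c)[perm], tol_bp = 100), out)
  }
  # orientation mismatch breaks the match
  b2 <- b; b2$orientation <- "++"
  expect_equal(nrow(consensus_sv(list(a, b2), tol_bp = 100)), 0L)
})

test_that("nLOH consensus follows the two-of-three window rule", {
  cand <- data.frame(chrom = "4", start = 10e6, end = 20e6,
                     total_cn = 2L, minor_cn = 0L)
  nloh <- function(s, e) data.frame(chrom = "4", start = s, end = e,
                                    total_cn = 2L, minor_cn = 0L)
  expect_true(consensus_nloh(cand, list(nloh(11e6, 19e6),
                                        nloh(12e6, 18e6))))
  far <- nloh(41e6, 50e6)   # > 10 Mb past the candidate end
  expect_false(consensus_nloh(cand, list(far, far)))
  # one caller starting 9 Mb past the candidate end still overlaps
  expect_true(consensus_nloh(cand, list(far, nloh(29e6, 35e6))))
  bad <- cand; bad$minor_cn <- 1L
  expect_error(consensus_nloh(bad, list(far, far)), "nLOH")
})

test_that("promoter construction is strand aware with 651 bp span", {
  p <- build_promoter_region(10000L, "+", chrom = "1")
  expect_equal(c(p$start, p$end), c(9600L, 10250L))
  m <- build_promoter_region(10000L, "-", chrom = "1")
  expect_equal(c(m$start, m$end), c(9750L, 10400L))
  expect_equal(p$end - p$start + 1L, 651L)
  expect_equal(m$end - m$start + 1L, 651L)
  expect_warning(t <- build_promoter_region(300L, "+"), "truncated")
  expect_equal(t$start, 1L)
})

test_that("CRE interaction filter keeps score >= 5 and distance <= 1 Mb", {
  x <- data.frame(score = c(5.0, 4.99, 7, 6),
                  linear_distance = c(1e6, 5e5, 1e6 + 1, 2e5))
  out <- filter_cre_interactions(x)
  expect_equal(out$score, c(5.0, 6))
  # brute-force agreement on a randomized list
  set.seed(4)
  y <- data.frame(score = runif(50, 0, 10),
                  linear_distance = runif(50, 0, 2e6))
  expect_equal(nrow(filter_cre_interactions(y)),
               sum(y$score >= 5 & y$linear_distance <= 1e6))
  y$linear_distance[1] <- -5
  expect_warning(filter_cre_interactions(y), "negative")
})

test_that("gene-set disruption report flags mutation, loss and SV classes", {
  genes <- data.frame(gene = c("CRBN", "IKZF1"), chrom = c("3", "7"),
                      start = c(1e6, 5e6), end = c(1.1e6, 5.1e6),
                      stringsAsFactors = FALSE)
  empty <- gene_set_disruption_report(
    data.frame(sample_id = "S1", chrom = "9", pos = 1,
               stringsAsFactors = FALSE),
    NULL, NULL, genes)
  expect_equal(nrow(empty), 0L)
  segs <- data.frame(sample_id = "S2", chrom = "3", start = 0.9e6,
                     end = 1.2e6, total_cn = 1L, minor_cn = 0L,
                     stringsAsFactors = FALSE)
  svs <- data.frame(sample_id = "S3", chrom1 = "7", pos1 = 5.05e6,
                    chrom2 = "2", pos2 = 9e9, stringsAsFactors = FALSE)
  out <- gene_set_disruption_report(NULL, segs, svs, genes)
  expect_equal(out$disruption[out$sample_id == "S2"], "copy_loss")
  expect_equal(out$gene[out$sample_id == "S3"], "IKZF1")
  expect_equal(out$disruption[out$sample_id == "S3"], "sv")
})

test_that("segment validation enforces structural invariants", {
  seg <- data.frame(sample_id = "S1", timepoint = "primary", chrom = "1",
                    start = c(1, 50), end = c(100, 150),
                    total_cn = 2L, minor_cn = 1L, clonal_frac = 1)
  expect_error(validate_segments(seg), "overlapping")
  seg2 <- seg; seg2$start <- c(1, 101)
  expect_silent(validate_segments(seg2))
  seg3 <- seg2; seg3$minor_cn <- c(2L, 1L)
  expect_error(validate_segments(seg3), "minor_cn")
})
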