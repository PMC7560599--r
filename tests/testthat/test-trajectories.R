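test_that("diploid restriction keeps SNVs diploid at both timepoints", {
  segs <- rbind(
    data.frame(sample_id = "S1", timepoint = c("primary", "relapse"),
               chrom = "1", start = 1, end = 1e6, total_cn = 2L,
               minor_cn = 1L, clonal_frac = 1),
    data.frame(sample_id = "S1", timepoint = c("primary", "relapse"),
               chrom = "1", start = 1e6 + 1, end = 2e6,
               total_cn = c(3L, 3L), minor_cn = 1L, clonal_frac = 1),
    data.frame(sample_id = "S1", timepoint = c("primary", "relapse"),
               chrom = "2", start = 1, end = 1e6, total_cn = c(2L, 1L),
               minor_cn = c(1L, 0L), clonal_frac = 1))
  mut <- function(chrom, pos) data.frame(
    sample_id = "S1", timepoint = "primary", chrom = chrom, pos = pos,
    class = "SNV", context96 = 0L, ccf = 0.5, stringsAsFactors = FALSE)
  muts <- rbind(mut("1", 5e5),      # diploid both: kept
                mut("1", 1.5e6),    # gained region: excluded
                mut("2", 5e5),      # diploid primary only: excluded
                mut("3", 5e5))      # uncovered: excluded
  out <- filter_diploid_snvs(muts, segs)
  expect_equal(nrow(out), 1L)
  expect_equal(out$chrom, "1")
  # randomized agreement with a direct interval oracle
  set.seed(6)
  pos <- sample(1:2e6, 200)
  m2 <- mut("1", pos)
  keep_oracle <- pos <= 1e6
  expect_equal(sort(filter_diploid_snvs(m2, segs)$pos),
               sort(pos[keep_oracle]))
})

test_that("neutral-tail filter removes a planted 1/f tail", {
  set.seed(12)
  n_tail <- 600
  u <- runif(n_tail)
  f_tail <- 1 / (1 / 0.05 - u * (1 / 0.05 - 1 / 0.25))   # density ~ f^-2
  f_clonal <- pmin(1, pmax(0.3, rnorm(700, 0.55, 0.05)))
  f <- c(f_tail, f_clonal)
  keep <- neutral_tail_filter(f, seed = 3)
  expect_gte(mean(!keep[seq_len(n_tail)]), 0.8)     # tail removed
  expect_lte(mean(!keep[-seq_len(n_tail)]), 0.05)   # cluster kept
  # pure clonal cluster: nothing removed
  keep2 <- neutral_tail_filter(f_clonal, seed = 3)
  expect_true(all(keep2))
  expect_warning(neutral_tail_filter(runif(10, 0.3, 0.6)), "fewer than 50")
})

test_that("DP clustering recovers well-separated clone structures", {
  set.seed(7)
  pts <- rbind(
    cbind(ccf_primary = rnorm(250, 1, 0.02),
          ccf_relapse = rnorm(250, 1, 0.02)),
    cbind(ccf_primary = rnorm(250, 0.4, 0.02),
          ccf_relapse = rnorm(250, 0, 0.02)))
  pts <- as.data.frame(pmin(pmax(pts, 0), 1))
  fit <- cluster_ccf_2d(pts, seed = 2)
  big <- filter_clusters(fit$clusters, nrow(pts))
  expect_equal(nrow(big), 2L)
  centers <- big[order(big$ccf_primary), ]
  expect_lt(abs(centers$ccf_primary[1] - 0.4), 0.05)
  expect_lt(abs(centers$ccf_relapse[2] - 1.0), 0.05)
  # single blob collapses to one retained cluster
  one <- as.data.frame(cbind(ccf_primary = rnorm(300, 0.5, 0.02),
                             ccf_relapse = rnorm(300, 0.5, 0.02)))
  fit1 <- cluster_ccf_2d(one, seed = 2)
  expect_equal(nrow(filter_clusters(fit1$clusters, 300)), 1L)
  # row-permutation invariance of the recovered structure
  perm <- sample(nrow(pts))
  fit_p <- cluster_ccf_2d(pts[perm, ], seed = 2)
  big_p <- filter_clusters(fit_p$clusters, nrow(pts))
  expect_equal(nrow(big_p), 2L)
  expect_equal(sort(big_p$n_snvs), sort(big$n_snvs), tolerance = 0.05)
  expect_error(cluster_ccf_2d(pts[1:50, ]), "at least 100")
})

test_that("cluster size filters drop small or rare clusters", {
  cl <- data.frame(cluster_id = 1:3, ccf_primary = 0.5,
                   ccf_relapse = 0.5, n_snvs = c(99L, 150L, 150L))
  expect_equal(filter_clusters(cl[1, , drop = FALSE], 5000)$n_snvs,
               integer(0))
  expect_equal(nrow(filter_clusters(cl[2, , drop = FALSE], 20000)), 0L)
  expect_equal(nrow(filter_clusters(cl[3, , drop = FALSE], 10000)), 1L)
})

test_that("pattern rules fire in precedence order", {
  mk <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(ccf_primary = m[, 1], ccf_relapse = m[, 2], n_snvs = 300L)
  }
  expect_equal(classify_pattern(mk(1, 1, 0, 0.45))$pattern, 1L)
  expect_equal(classify_pattern(mk(1, 1, 0.35, 0.95, 0.3, 0))$pattern, 2L)
  expect_equal(classify_pattern(mk(1, 1, 0.4, 0, 0, 0.5))$pattern, 3L)
  expect_error(classify_pattern(mk(1, 1)[0, ]), "no retained")
})

test_that("shared-SNV fractions count relapse detection per cluster", {
  asg <- rep(c(1L, 2L, 3L), c(100, 50, 148))
  shared <- c(rep(TRUE, 100), rep(FALSE, 50),
              rep(c(TRUE, FALSE), c(37, 111)))
  out <- shared_snv_fraction(asg, shared)
  expect_equal(out$shared_fraction, c(1, 0, 0.25))
})
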