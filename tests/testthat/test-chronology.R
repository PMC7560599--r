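make_timed <- function(ccfs) {
  events <- data.frame(event_id = names(ccfs),
                       kind = "snv_driver",
                       n = vapply(ccfs, length, integer(1)),
                       mean_ccf = vapply(ccfs, mean, numeric(1)),
                       stringsAsFactors = FALSE)
  structure(list(events = events, ccfs = ccfs), class = "timed_events")
}

test_that("event selection enforces carrier and size thresholds", {
  meta <- data.frame(sample_id = paste0("S", 1:10),
                     elapsed_months = NA_real_,
                     hyperdiploid = c(TRUE, rep(FALSE, 9)),
                     stringsAsFactors = FALSE)
  gene_mut <- function(g, carriers) data.frame(
    sample_id = carriers, timepoint = "primary", chrom = "1",
    pos = 1e6, class = "SNV", context96 = 0L, ccf = 0.9, gene = g,
    stringsAsFactors = FALSE)
  muts <- rbind(gene_mut("FOUR", paste0("S", 2:5)),
                gene_mut("THREE", paste0("S", 2:4)),
                gene_mut("HDONLY", paste0("S", c(1, 2, 3, 4))))
  # 13q-loss-like event in 8 samples
  segs <- do.call(rbind, lapply(paste0("S", 2:9), function(s)
    data.frame(sample_id = s, timepoint = "primary", chrom = "13",
               start = 18000001L, end = 114000000L, total_cn = 1L,
               minor_cn = 0L, clonal_frac = 0.9,
               stringsAsFactors = FALSE)))
  timed <- select_timed_events(make_mini_bundle(muts, segs, meta))
  ids <- timed$events$event_id
  expect_true("FOUR" %in% ids)
  expect_false("THREE" %in% ids)        # only 3 carriers
  expect_true("13q_loss" %in% ids)
  # the hyperdiploid sample's carrier is dropped: FOUR has 3 non-HD
  # carriers only when S1 carried it; here all 4 carriers are non-HD
  expect_equal(timed$events$n[ids == "FOUR"], 4L)
  # small-arm events below 3 Mb are excluded
  tiny_genome <- data.frame(chrom = "1", length = 4000000L,
                            centromere = 2000000L,
                            stringsAsFactors = FALSE)
  tiny_segs <- do.call(rbind, lapply(paste0("S", 1:8), function(s)
    data.frame(sample_id = s, timepoint = "primary", chrom = "1",
               start = 1L, end = 1900000L, total_cn = 1L, minor_cn = 0L,
               clonal_frac = 0.9, stringsAsFactors = FALSE)))
  expect_error(
    select_timed_events(make_mini_bundle(muts[0, ], tiny_segs,
                                         meta[0, ], tiny_genome)),
    "no events")
})

test_that("ordering is by descending mean CCF with stable ties", {
  timed <- make_timed(list(b_event = c(0.5, 0.5), a_event = c(1, 1),
                           c_event = c(0.5, 0.5)))
  ord <- order_by_mean_ccf(timed)
  expect_equal(ord$events$event_id, c("a_event", "b_event", "c_event"))
  # invariant to input permutation
  timed2 <- make_timed(list(c_event = c(0.5, 0.5), a_event = c(1, 1),
                            b_event = c(0.5, 0.5)))
  expect_equal(order_by_mean_ccf(timed2)$events,
               ord$events)
})

test_that("clonality levels split on the studentized-range test", {
  # identical CCF vectors share a level
  same <- assign_clonality_levels(order_by_mean_ccf(make_timed(
    list(a = rep(0.8, 10), b = rep(0.8, 10)))))
  expect_equal(same$events$level, c(1L, 1L))
  # zero variance and a clear gap: infinite statistic, new level
  gap <- assign_clonality_levels(order_by_mean_ccf(make_timed(
    list(a = rep(1, 20), b = rep(0.2, 20)))))
  expect_equal(gap$events$level, c(1L, 2L))
  # three planted tiers at sigma 0.05 are recovered as three levels
  set.seed(41)
  tiers <- list(a1 = rnorm(20, 1, 0.05), a2 = rnorm(20, 1, 0.05),
                b1 = rnorm(20, 0.6, 0.05), b2 = rnorm(20, 0.6, 0.05),
                c1 = rnorm(20, 0.2, 0.05), c2 = rnorm(20, 0.2, 0.05))
  lev <- assign_clonality_levels(order_by_mean_ccf(make_timed(tiers)))
  expect_equal(max(lev$events$level), 3L)
  # monotone non-decreasing along the ordering
  expect_true(all(diff(lev$events$level) >= 0))
})

test_that("basic bootstrap interval is exact on degenerate input", {
  expect_equal(unname(bootstrap_ci(rep(1, 30), seed = 2)), c(1, 1))
  expect_equal(unname(bootstrap_ci(0.7)), c(0.7, 0.7))
  set.seed(10)
  x <- rbeta(40, 5, 2)
  ci <- bootstrap_ci(x, seed = 3)
  expect_lte(ci["ci_low"], mean(x))
  expect_gte(ci["ci_high"], mean(x))
  expect_identical(bootstrap_ci(x, seed = 3), ci)   # deterministic
})
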