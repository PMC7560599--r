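arms <- arm_table()

seg_row <- function(s, tp, chrom, start, end, total, minor, cf = 1) {
  data.frame(sample_id = s, timepoint = tp, chrom = chrom, start = start,
             end = end, total_cn = total, minor_cn = minor,
             clonal_frac = cf, stringsAsFactors = FALSE)
}

test_that("arm events follow the 50% coverage rule", {
  a13q <- arms[arms$arm == "13q", ]
  len <- a13q$end - a13q$start + 1
  # 95% of 13q at total CN 1: loss
  segs <- seg_row("S1", "primary", "13", a13q$start,
                  a13q$start + floor(0.95 * len), 1L, 0L, 0.8)
  ev <- call_arm_events(segs, arms)
  expect_equal(ev$state[ev$arm == "13q"], "loss")
  expect_equal(ev$ccf[ev$arm == "13q"], 0.8)
  # 40% gain coverage: neutral (no event emitted)
  segs2 <- seg_row("S1", "primary", "13", a13q$start,
                   a13q$start + floor(0.40 * len), 3L, 1L)
  expect_equal(nrow(call_arm_events(segs2, arms)), 0L)
  # mixed profile agrees with brute-force length accounting
  segs3 <- rbind(
    seg_row("S1", "primary", "13", a13q$start,
            a13q$start + floor(0.30 * len), 1L, 0L),
    seg_row("S1", "primary", "13", a13q$start + floor(0.30 * len) + 1,
            a13q$start + floor(0.85 * len), 2L, 0L))
  # nLOH covers 55% of the arm (>= 50%), loss only 30%
  ev3 <- call_arm_events(segs3, arms)
  expect_equal(ev3$state[ev3$arm == "13q"], "nLOH")
})

test_that("hyperdiploid classification needs two 90%-amplified autosomes", {
  g <- synthetic_genome()
  chr9 <- g[g$chrom == "9", ]; chr15 <- g[g$chrom == "15", ]
  both <- rbind(
    seg_row("S1", "primary", "9", 1, floor(0.95 * chr9$length), 3L, 1L),
    seg_row("S1", "primary", "15", 1, floor(0.92 * chr15$length), 3L, 1L))
  expect_true(classify_hyperdiploid(both, g))
  expect_false(classify_hyperdiploid(both[1, ], g))
  boundary <- rbind(both[1, ],
                    seg_row("S1", "primary", "15", 1,
                            floor(0.89 * chr15$length), 3L, 1L))
  expect_false(classify_hyperdiploid(boundary, g))
})

test_that("frequency-change test matches exact sign-flip enumeration", {
  pair_ids <- paste0("P", 1:8)
  relapse_ev <- data.frame(sample_id = pair_ids, timepoint = "relapse",
                           arm = "17p", state = "loss", ccf = 1,
                           span_bp = 1, stringsAsFactors = FALSE)
  r <- arm_frequency_change_test(relapse_ev, pair_ids, "17p", "loss",
                                 n_perm = 10000, seed = 21)
  expect_equal(r$observed_stat, 8L)
  exact <- signflip_oracle(rep(1L, 8))       # 2 / 2^8
  expect_equal(exact, 2 / 256)
  mc_se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(r$p_empirical - exact), 3 * mc_se + 1 / 10001)
  # mixed gains and losses, random case vs enumeration
  set.seed(31)
  d <- sample(c(-1L, 0L, 1L), 10, replace = TRUE,
              prob = c(0.2, 0.3, 0.5))
  ev <- do.call(rbind, lapply(seq_along(d), function(i) {
    if (d[i] == 1L) data.frame(sample_id = paste0("Q", i),
                               timepoint = "relapse", arm = "1q",
                               state = "gain", ccf = 1, span_bp = 1)
    else if (d[i] == -1L) data.frame(sample_id = paste0("Q", i),
                                     timepoint = "primary", arm = "1q",
                                     state = "gain", ccf = 1, span_bp = 1)
    else NULL
  }))
  r2 <- arm_frequency_change_test(ev, paste0("Q", 1:10), "1q", "gain",
                                  n_perm = 10000, seed = 5)
  if (abs(sum(d)) >= 2) {
    exact2 <- signflip_oracle(d)
    expect_lt(abs(r2$p_empirical - exact2),
              3 * sqrt(exact2 * (1 - exact2) / 10000) + 1 / 10001)
  }
  # net change in a single tumour is not tested
  one <- arm_frequency_change_test(relapse_ev[1, ], pair_ids[1:4],
                                   "17p", "loss", n_perm = 100)
  expect_true(is.na(one$p_empirical))
  # identical profiles: net 0, below the two-tumour filter
  zero <- arm_frequency_change_test(relapse_ev[0, ], pair_ids, "17p",
                                    "loss", n_perm = 100)
  expect_equal(zero$observed_stat, 0L)
  expect_true(is.na(zero$p_empirical))
})

test_that("arm-relocation test matches the binomial tail", {
  expect_equal(instability_localization_test(0, 0)$p_empirical, 1)
  r1 <- instability_localization_test(1, 1, n_perm = 10000, seed = 3)
  e1 <- 1 / 44
  expect_lt(abs(r1$p_empirical - e1), 3 * sqrt(e1 * (1 - e1) / 1e4) + 1e-4)
  r2 <- instability_localization_test(2, 10, n_perm = 10000, seed = 3)
  e2 <- 1 - pbinom(1, 10, 1 / 44)
  expect_lt(abs(r2$p_empirical - e2), 3 * sqrt(e2 * (1 - e2) / 1e4) + 1e-4)
})

test_that("progression counting spots nLOH-to-LOH style changes", {
  ev <- rbind(
    data.frame(sample_id = "P1", timepoint = "primary", arm = "11q",
               state = "nLOH", ccf = 1, span_bp = 1),
    data.frame(sample_id = "P1", timepoint = "relapse", arm = "11q",
               state = "loss", ccf = 1, span_bp = 1),
    data.frame(sample_id = "P2", timepoint = "primary", arm = "1q",
               state = "gain", ccf = 1, span_bp = 1),
    data.frame(sample_id = "P2", timepoint = "relapse", arm = "1q",
               state = "amp", ccf = 1, span_bp = 1),
    # loss -> gain is a different axis, not a progression
    data.frame(sample_id = "P3", timepoint = "primary", arm = "6q",
               state = "loss", ccf = 1, span_bp = 1),
    data.frame(sample_id = "P3", timepoint = "relapse", arm = "6q",
               state = "gain", ccf = 1, span_bp = 1))
  prog <- count_arm_progressions(ev, paste0("P", 1:3))
  expect_equal(attr(prog, "n_total"), 2L)
  expect_equal(prog$k[prog$arm == "11q"], 1L)
  expect_equal(prog$k[prog$arm == "1q"], 1L)
  expect_equal(prog$k[prog$arm == "6q"], 0L)
})
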