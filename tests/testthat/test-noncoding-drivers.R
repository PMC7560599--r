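test_that("background rates divide genome context counts", {
  # one sample, 960 mutations spread evenly over 96 contexts of 1e6 bases
  muts <- data.frame(sample_id = "S1", timepoint = "primary", chrom = "1",
                     pos = seq_len(960), class = "SNV",
                     context96 = rep(0:95, each = 10),
                     stringsAsFactors = FALSE)
  model <- fit_background(muts, rep(1e6, 96))
  expect_equal(unname(model$rate["S1", ]), rep(1e-5, 96))
  expect_equal(model$rt_factor, rep(1, 5))
  # doubling counts doubles rates exactly (linearity)
  model2 <- fit_background(rbind(muts, muts), rep(1e6, 96))
  expect_equal(model2$rate, model$rate * 2)
})

test_that("region hit probability matches the closed-form product", {
  model <- structure(list(
    rate = matrix(1e-3, 1, 96, dimnames = list("S1", NULL)),
    rt_factor = rep(1, 5)), class = "background_model")
  cc <- as.numeric(stats::rmultinom(1, 651, rep(1 / 96, 96)))
  p <- region_mutation_prob(cc, model)
  expect_equal(unname(p[1, 1]), 1 - 0.999^651, tolerance = 1e-10)
  # all-zero rates give zero probability
  model0 <- model; model0$rate[] <- 0
  expect_equal(unname(region_mutation_prob(cc, model0)[1, 1]), 0)
  # monotone nondecreasing in every site rate
  model_hi <- model; model_hi$rate[] <- 2e-3
  expect_gt(unname(region_mutation_prob(cc, model_hi)[1, 1]), unname(p[1, 1]))
  expect_error(region_mutation_prob(rep(0, 96), model), "zero eligible")
})

test_that("Poisson-binomial tail is exact", {
  expect_equal(poisson_binomial_tail(c(0.3, 0.7), 0), 1)
  expect_equal(poisson_binomial_tail(c(0.1, 0.2), 1), 0.28)
  expect_equal(poisson_binomial_tail(c(0.5, 0.5, 0.5), 2), 0.5)
  expect_equal(poisson_binomial_tail(c(0.1, 0.2), 3), 0)
  set.seed(11)
  for (i in 1:25) {
    n <- sample(1:8, 1)
    ps <- runif(n)
    k <- sample(0:n, 1)
    expect_equal(poisson_binomial_tail(ps, k), pb_tail_oracle(ps, k),
                 tolerance = 1e-12)
  }
})

test_that("clustering permutation test detects positional hotspots", {
  # all distinct positions: S = 0, p = 1
  p1 <- clustering_test(1:5, paste0("T", 1:5), 1000, n_perm = 200,
                        seed = 1)
  expect_equal(p1, 1)
  # five mutations at one position in a 1000-bp region
  p2 <- clustering_test(rep(17L, 5), paste0("T", 1:5), 1000,
                        n_perm = 1000, seed = 1)
  expect_equal(p2, 1 / 1001)
  expect_gte(p2, 1 / 1001)
  # fewer than three mutated tumours: unavailable
  expect_true(is.na(clustering_test(c(5L, 5L), c("T1", "T2"), 1000)))
})

test_that("Fisher combination has its closed form and properties", {
  expect_equal(fisher_combine(1, 1), 1)
  x <- -2 * (log(0.05) + log(0.05))
  expect_equal(fisher_combine(0.05, 0.05), exp(-x / 2) * (1 + x / 2))
  expect_equal(fisher_combine(0.05, 0.05), 0.0175, tolerance = 1e-2)
  for (p in c(0.001, 0.05, 0.5, 0.99))
    expect_gte(fisher_combine(p, 1), p)
  expect_warning(fisher_combine(0, 0.5), "clamped")
})

test_that("BH q-values follow the step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(2)
  p <- runif(20)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in p
  expect_equal(q, stats::p.adjust(p, "BH"))
})

test_that("driver calling applies exclusion rules by region kind", {
  regions <- data.frame(
    region_id = c("P1", "C1", "P2", "ORF1", "UTR1", "IMM"),
    kind = c("promoter", "CRE", "promoter", "ORF", "UTR",
             "immune_hypermutated"),
    chrom = "5",
    start = c(1000L, 3000L, 5000L, 1300L, 3300L, 4900L),
    end = c(1650L, 3999L, 5650L, 1400L, 3400L, 5100L),
    rt_bin = 1L, stringsAsFactors = FALSE)
  cc <- matrix(rep(stats::rmultinom(1, 651, rep(1 / 96, 96)), 6),
               nrow = 6, byrow = TRUE)
  model <- structure(list(
    rate = matrix(1e-4, 3, 96, dimnames = list(paste0("T", 1:3), NULL)),
    rt_factor = rep(1, 5)), class = "background_model")
  mut <- function(pos, s) data.frame(
    sample_id = s, timepoint = "primary", chrom = "5", pos = pos,
    class = "SNV", context96 = 0L, stringsAsFactors = FALSE)
  # P1: three tumours, but one mutation inside the ORF (excluded)
  muts <- rbind(mut(1100, "T1"), mut(1200, "T2"), mut(1350, "T3"),
                # C1: mutations inside the UTR are excluded for CREs
                mut(3350, "T1"), mut(3500, "T2"),
                # P2 overlaps the immune locus: not tested at all
                mut(5200, "T1"))
  res <- call_noncoding_drivers(muts, regions, model, n_perm = 100,
                                seed = 1, context_counts = cc)
  expect_setequal(res$region_id, c("P1", "C1"))
  expect_equal(res$k[res$region_id == "P1"], 2L)   # ORF mutation dropped
  expect_equal(res$k[res$region_id == "C1"], 1L)   # UTR mutation dropped
  expect_false(any(res$reported))
  # no mutations: empty result
  empty <- call_noncoding_drivers(muts[0, ], regions, model,
                                  context_counts = cc)
  expect_equal(nrow(empty), 0L)
})
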