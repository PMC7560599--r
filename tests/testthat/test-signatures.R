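test_that("NMF reconstructs low-rank count structure", {
  set.seed(5)
  W0 <- cbind(as.numeric(synthetic_sbs_catalog()[, "SBS2"]),
              as.numeric(synthetic_sbs_catalog()[, "SBS8"]))
  H0 <- matrix(runif(2 * 12, 50, 400), 2, 12)
  V <- t(W0 %*% H0)
  fit <- extract_signatures_nmf(V, k = 2, seed = 3, n_iter = 1500)
  # objective is monotone non-increasing
  expect_true(all(diff(fit$objective) <= 1e-6))
  # reconstruction error is small relative to the total count
  recon <- fit$signatures %*% t(fit$loadings)
  expect_lt(sum(abs(t(V) - recon)) / sum(V), 0.02)
  # single-signature data recovered at k = 1
  V1 <- t(sapply(1:8, function(i)
    sample_contexts(c(1, 0, 0, 0, 0, 0), 3000, seed = i)))
  fit1 <- extract_signatures_nmf(V1, k = 1, seed = 2, n_iter = 500)
  expect_gt(cosine_similarity(fit1$signatures[, 1],
                              synthetic_sbs_catalog()[, "SBS2"]), 0.99)
  expect_error(extract_signatures_nmf(V1, k = 50), "out of range")
})

test_that("cosine similarity has its closed form", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("catalog assignment is strict at the 0.75 threshold", {
  cat2 <- cbind(A = c(1, 0, 0), B = c(0, 1, 0))
  exact <- cbind(D1 = c(1, 0, 0))
  expect_equal(assign_to_catalog(exact, cat2)$assigned, "A")
  # construct a query with cosine exactly 0.75 to A
  q <- cbind(D1 = c(0.75, 0, sqrt(1 - 0.75^2)))
  out <- assign_to_catalog(q, cat2)
  expect_true(is.na(out$assigned))
  expect_equal(out$cosine, 0.75)
  # noisy copy still assigned
  set.seed(8)
  noisy <- synthetic_sbs_catalog()[, "SBS13"] + runif(96, 0, 0.003)
  out2 <- assign_to_catalog(cbind(D1 = noisy), synthetic_sbs_catalog())
  expect_equal(out2$assigned, "SBS13")
})

test_that("exposure refitting recovers mixtures and prunes small weights", {
  cat96 <- synthetic_sbs_catalog()
  # counts drawn exactly from one signature
  e1 <- refit_exposures(round(cat96[, "SBS2"] * 5000), cat96)
  expect_equal(unname(e1["SBS2"]), 1, tolerance = 0.02)
  # 50/50 mix of two near-disjoint signatures at n = 5000
  mix <- sample_contexts(c(0.5, 0, 0, 0, 0.5, 0), 5000, cat96, seed = 4)
  e2 <- refit_exposures(mix, cat96)
  expect_equal(unname(e2["SBS2"]), 0.5, tolerance = 0.06)
  expect_equal(unname(e2["SBS13"]), 0.5, tolerance = 0.06)
  # a 3% component is pruned to zero
  mix3 <- round(5000 * (0.57 * cat96[, "SBS2"] + 0.40 * cat96[, "SBS8"] +
                          0.03 * cat96[, "SBS13"]))
  e3 <- refit_exposures(mix3, cat96[, c("SBS2", "SBS8", "SBS13")])
  expect_equal(unname(e3["SBS13"]), 0)
  expect_equal(sum(e3), 1)
  expect_error(refit_exposures(mix3, cat96[, 0]), "empty catalog")
})

test_that("group combination conserves mass and rejects SBS3", {
  e <- c(SBS2 = 0.1, SBS5 = 0.2, SBS8 = 0.1, SBS9 = 0.05, SBS13 = 0.15,
         SBS40 = 0.1)
  g <- combine_groups(e)
  expect_equal(g$aid_apobec, 0.3)
  expect_equal(g$flat, 0.4)
  expect_equal(g$aid_apobec + g$flat + g$other, g$total)
  zero <- combine_groups(c(SBS5 = 0.6, SBS8 = 0.4))
  expect_equal(zero$aid_apobec, 0)
  expect_error(combine_groups(c(SBS3 = 0.5, SBS5 = 0.5)), "SBS3")
})

test_that("paired signature chi-square matches the textbook statistic", {
  same <- paired_signature_chisq(c(A = 50, B = 50), c(A = 100, B = 100))
  expect_equal(same, 1)
  p <- paired_signature_chisq(c(A = 50, B = 50), c(A = 90, B = 10))
  oracle <- stats::chisq.test(rbind(c(50, 50), c(90, 10)),
                              correct = FALSE)
  expect_equal(p, oracle$p.value)
  expect_equal(unname(oracle$statistic), 38.0952381, tolerance = 1e-6)
  # invariance to signature ordering
  p_perm <- paired_signature_chisq(c(B = 50, A = 50), c(B = 10, A = 90))
  expect_equal(p_perm, p)
  w <- testthat::capture_warnings(
    paired_signature_chisq(c(A = 500, B = 0, C = 1),
                           c(A = 480, B = 1, C = 0)))
  expect_true(any(grepl("merging", w)))
})

test_that("burden/APOBEC Fisher test matches the exact oracle", {
  concord <- burden_apobec_association(rep(c(TRUE, FALSE), each = 12),
                                       rep(c(TRUE, FALSE), each = 12))
  oracle <- stats::fisher.test(matrix(c(12, 0, 0, 12), 2))$p.value
  expect_equal(concord, oracle)
  # independent-looking table: large p
  indep <- burden_apobec_association(rep(c(TRUE, FALSE), 8),
                                     rep(c(TRUE, TRUE, FALSE, FALSE), 4))
  expect_gt(indep, 0.5)
  # symmetry under swapping the two indicators
  a <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  b <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(burden_apobec_association(a, b),
               burden_apobec_association(b, a))
})

test_that("Spearman association handles monotone and degenerate input", {
  x <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  out <- apobec_vs_time(x, 1:5)
  expect_equal(out$rho, -1)
  expect_error(apobec_vs_time(x[1:3], 1:3), "at least 4")
  expect_warning(res <- apobec_vs_time(rep(0.5, 5), 1:5), "constant")
  expect_true(is.na(res$rho))
  # random permutations give small |rho| on average
  set.seed(9)
  rhos <- replicate(200, apobec_vs_time(sample(24), 1:24)$rho)
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("C>G transversion fraction counts the second class", {
  m <- function(ctx) data.frame(class = rep("SNV", length(ctx)),
                                context96 = ctx,
                                stringsAsFactors = FALSE)
  expect_equal(cg_transversion_fraction(m(16:31)), 1)
  expect_equal(cg_transversion_fraction(m(seq(0, 95, by = 16))), 1 / 6)
  expect_equal(cg_transversion_fraction(m(c(rep(20L, 25),
                                            rep(40L, 175)))), 0.125)
  expect_true(is.na(cg_transversion_fraction(m(integer(0)))))
})
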