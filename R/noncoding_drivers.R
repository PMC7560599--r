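#' @title Noncoding driver discovery
#' @name noncoding_drivers
#' @description
#' Recurrently mutated promoters and cis-regulatory elements (CREs) are
#' identified by combining two per-region tests: (i) a mutational
#' recurrence test under a Poisson-binomial model whose per-sample
#' region-hit probabilities account for tumour identity, trinucleotide
#' context and replication timing, and (ii) a positional-clustering
#' permutation test on the number of mutations sharing a nucleotide
#' position. Per-region p-values are combined with Fisher's method and
#' adjusted with the Benjamini-Hochberg FDR procedure (significance at
#' Q < 0.05); only regions mutated in at least three tumours are
#' reported, and regions overlapping immune-hypermutated loci are
#' excluded.
NULL

#' Fit the per-sample background mutation model
#'
#' For each sample and trinucleotide substitution channel, the background
#' rate is the genome-wide count of channel mutations in that sample
#' divided by the genome-wide count of eligible bases providing the
#' channel's context. A multiplicative replication-timing adjustment is
#' estimated by binning the timing track into `n_bins` quantile bins
#' (weighted by track length) and taking observed/expected mutation
#' share per bin, normalised to a weighted mean of one.
#'
#' @param mutations Mutation table (SNVs are used; `sample_id`,
#'   `context96`, `chrom`, `pos`).
#' @param genome_context_counts Numeric vector of length 96: eligible
#'   genome bases per context channel.
#' @param rt_track Replication timing track (`chrom`, `start`, `end`,
#'   `timing`) or NULL for no timing adjustment.
#' @param n_bins Number of timing bins (default 5, quintiles).
#' @return Object of class `background_model`: list with `rate`
#'   (samples x 96 matrix), `rt_factor` (length `n_bins`, all 1 when no
#'   track is given), and `rt_bins` (the binned track).
#' @export
fit_background <- function(mutations, genome_context_counts,
                           rt_track = NULL, n_bins = 5L) {
  stopifnot(length(genome_context_counts) == 96L)
  snv <- mutations[mutations$class == "SNV" & !is.na(mutations$context96),
                   , drop = FALSE]
  samples <- sort(unique(snv$sample_id))
  if (!length(samples)) stop("no SNVs to fit the background model")
  counts <- matrix(0, nrow = length(samples), ncol = 96L,
                   dimnames = list(samples, NULL))
  tab <- table(factor(snv$sample_id, levels = samples),
               factor(snv$context96, levels = 0:95))
  counts[] <- as.numeric(tab)
  empty <- genome_context_counts == 0
  if (any(empty & colSums(counts) > 0))
    warning("mutations observed in context channels with zero eligible ",
            "bases; their rates are set to 0")
  denom <- ifelse(genome_context_counts > 0, genome_context_counts, Inf)
  rate <- sweep(counts, 2L, denom, "/")

  rt_factor <- rep(1, n_bins)
  rt_bins <- NULL
  if (!is.null(rt_track)) {
    rt_bins <- bin_rt_track(rt_track, n_bins)
    bin_of_mut <- lookup_rt_bin(rt_bins, snv$chrom, snv$pos)
    len <- tapply(as.numeric(rt_bins$end - rt_bins$start + 1),
                  rt_bins$bin, sum)
    len <- as.numeric(len[as.character(seq_len(n_bins))])
    len[is.na(len)] <- 0
    obs <- tabulate(bin_of_mut, nbins = n_bins)
    expd <- len / sum(len) * sum(obs)
    rt_factor <- ifelse(expd > 0, obs / expd, 1)
    # weighted mean 1 over eligible bases
    rt_factor <- rt_factor / sum(rt_factor * len / sum(len))
  }
  structure(list(rate = rate, rt_factor = rt_factor, rt_bins = rt_bins,
                 samples = samples),
            class = "background_model")
}

# Assign quantile bins (1..n_bins) to a timing track, weighting by length.
bin_rt_track <- function(rt_track, n_bins) {
  o <- order(rt_track$timing)
  len <- as.numeric(rt_track$end - rt_track$start + 1)
  cum <- cumsum(len[o]) / sum(len)
  bin_sorted <- pmin(n_bins, floor(cum * n_bins - 1e-12) + 1L)
  bin <- integer(nrow(rt_track))
  bin[o] <- bin_sorted
  out <- rt_track
  out$bin <- bin
  out
}

# Timing bin of genomic positions via the binned track.
lookup_rt_bin <- function(rt_bins, chrom, pos) {
  bin <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    tr <- rt_bins[rt_bins$chrom == ch, , drop = FALSE]
    if (!nrow(tr)) next
    idx <- chrom == ch
    i <- findInterval(pos[idx], tr$start)
    ok <- i >= 1L & pos[idx] <= tr$end[pmax(i, 1L)]
    bin[idx][ok] <- tr$bin[i[ok]]
  }
  bin[is.na(bin)] <- 1L
  bin
}

#' Per-sample probability that a region carries at least one mutation
#'
#' For sample j, `p_j = 1 - prod_i (1 - min(1, rate[j, c(i)] * f_b))`
#' over the eligible bases i of the region, where `c(i)` is the base's
#' context channel and `f_b` the replication-timing factor of the
#' region's bin. Regions are summarised by their context composition, so
#' the product is computed channel-wise.
#'
#' @param context_counts Numeric vector of length 96 (eligible bases per
#'   channel in the region) or a regions x 96 matrix.
#' @param model A `background_model`.
#' @param rt_bin Timing bin of the region(s); scalar or vector.
#' @return Matrix samples x regions of hit probabilities (a vector input
#'   returns a one-column matrix).
#' @export
region_mutation_prob <- function(context_counts, model, rt_bin = 1L) {
  if (is.null(dim(context_counts)))
    context_counts <- matrix(context_counts, nrow = 1L)
  stopifnot(ncol(context_counts) == 96L)
  if (any(rowSums(context_counts) == 0))
    stop("region with zero eligible bases")
  nr <- nrow(context_counts)
  rt_bin <- rep_len(rt_bin, nr)
  out <- matrix(NA_real_, nrow = nrow(model$rate), ncol = nr,
                dimnames = list(rownames(model$rate), NULL))
  for (b in unique(rt_bin)) {
    f <- model$rt_factor[b]
    site <- pmin(model$rate * f, 1)               # samples x 96
    logq <- log1p(-pmin(site, 1 - 1e-15))
    idx <- which(rt_bin == b)
    out[, idx] <- 1 - exp(logq %*% t(context_counts[idx, , drop = FALSE]))
  }
  out
}

#' Exact upper tail of a Poisson-binomial count
#'
#' P(X >= k) for X the sum of independent Bernoulli(p_j) indicators,
#' computed exactly by dynamic programming over samples (numerically
#' stable for thousands of samples; no normal approximation).
#'
#' @param ps Vector of success probabilities in \[0, 1\].
#' @param k Integer threshold, 0 <= k; `k > length(ps)` returns 0.
#' @return P(X >= k).
#' @export
poisson_binomial_tail <- function(ps, k) {
  stopifnot(all(ps >= 0 & ps <= 1), k >= 0)
  n <- length(ps)
  if (k == 0) return(1)
  if (k > n) return(0)
  pmf <- c(1, numeric(n))
  for (p in ps) {
    pmf <- c(pmf * (1 - p), 0)[seq_len(n + 1L)] +
      c(0, pmf * p)[seq_len(n + 1L)]
  }
  sum(pmf[(k + 1L):(n + 1L)])
}

#' Positional clustering permutation test
#'
#' Statistic S = (number of mutations) - (number of distinct mutated
#' positions) in the region. Under the null each mutation's position is
#' redrawn uniformly over the region's positions, preserving per-tumour
#' mutation counts; the p-value is `(1 + #\{S* >= S_obs\}) / (n_perm + 1)`.
#' Computed only for regions mutated in at least three tumours;
#' otherwise `NA` is returned and the combined test falls back to the
#' recurrence p-value alone.
#'
#' @param positions Mutated positions (one entry per mutation).
#' @param sample_ids Tumour of each mutation (same length).
#' @param region_length Number of eligible positions in the region.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return p-value, or `NA_real_` for regions mutated in < 3 tumours.
#' @export
clustering_test <- function(positions, sample_ids, region_length,
                            n_perm = 10000L, seed = 1L) {
  if (length(unique(sample_ids)) < 3L) return(NA_real_)
  m <- length(positions)
  s_obs <- m - length(unique(positions))
  set.seed(seed)
  draws <- matrix(sample.int(region_length, m * n_perm, replace = TRUE),
                  nrow = n_perm)
  s_null <- m - apply(draws, 1L, function(r) length(unique(r)))
  (1 + sum(s_null >= s_obs)) / (n_perm + 1)
}

#' Combine recurrence and clustering p-values with Fisher's method
#'
#' `X = -2 (ln p1 + ln p2)` referred to a chi-square with 4 degrees of
#' freedom; the upper tail has the closed form `exp(-X/2) (1 + X/2)`.
#' Zero inputs are clamped to the smallest positive double with a
#' warning.
#'
#' @param p_rec,p_clust p-values in (0, 1\].
#' @return Combined p-value.
#' @export
fisher_combine <- function(p_rec, p_clust) {
  ps <- c(p_rec, p_clust)
  if (any(ps == 0)) {
    warning("zero p-value clamped to machine minimum")
    ps[ps == 0] <- .Machine$double.xmin
  }
  x <- -2 * sum(log(ps))
  exp(-x / 2) * (1 + x / 2)
}

#' Benjamini-Hochberg q-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as the named
#' step of the driver pipeline.
#'
#' @param pvals Numeric p-values.
#' @return q-values, order-preserving and monotone in p.
#' @export
bh_fdr <- function(pvals) stats::p.adjust(pvals, method = "BH")

#' Call recurrently mutated promoters and CREs
#'
#' Runs the full per-region driver test. Mutation exclusions by region
#' kind: promoter tests drop mutations overlapping ORF regions; CRE
#' tests drop mutations overlapping ORF or UTR regions. Regions
#' overlapping immune-hypermutated loci are excluded from testing
#' altogether. For each remaining region the number of mutated tumours
#' k, the Poisson-binomial recurrence tail at k, the clustering
#' permutation p (regions mutated in >= 3 tumours), the Fisher-combined
#' p (falling back to the recurrence p when clustering is unavailable)
#' and the BH q-value over all tested regions are reported. A region is
#' flagged `reported` iff k >= 3.
#'
#' @param mutations Mutation table (primary-timepoint SNVs are tested).
#' @param regions Region catalog (kinds "promoter"/"CRE" are tested;
#'   kinds "ORF", "UTR" and "immune_hypermutated" drive exclusions). The
#'   catalog must carry a `regions x 96` context composition as
#'   `attr(regions, "context_counts")` and an `rt_bin` column (or see
#'   `context_counts`/`rt_bin` arguments).
#' @param model `background_model` from [fit_background()].
#' @param n_perm Permutations for the clustering test.
#' @param seed Integer seed.
#' @param context_counts Optional regions x 96 matrix overriding the
#'   attribute.
#' @param rt_bin Optional vector of per-region timing bins.
#' @param timepoint Timepoint tested (default "primary").
#' @return data.frame with `region_id`, `kind`, `k`, `p_rec`, `p_clust`,
#'   `p_combined`, `q_value`, `reported`.
#' @export
call_noncoding_drivers <- function(mutations, regions, model,
                                   n_perm = 10000L, seed = 1L,
                                   context_counts = NULL, rt_bin = NULL,
                                   timepoint = "primary") {
  if (is.null(context_counts))
    context_counts <- attr(regions, "context_counts")
  if (is.null(rt_bin)) rt_bin <- regions$rt_bin
  tested_kind <- regions$kind %in% c("promoter", "CRE")
  excl <- regions[regions$kind %in% c("ORF", "UTR", "immune_hypermutated"),
                  , drop = FALSE]
  tested <- which(tested_kind)
  if (!length(tested) || is.null(mutations) || !nrow(mutations))
    return(data.frame(region_id = character(), kind = character(),
                      k = integer(), p_rec = numeric(),
                      p_clust = numeric(), p_combined = numeric(),
                      q_value = numeric(), reported = logical(),
                      stringsAsFactors = FALSE))
  # drop regions overlapping immune hypermutated loci
  imm <- excl[excl$kind == "immune_hypermutated", , drop = FALSE]
  if (nrow(imm)) {
    overlaps_immune <- vapply(tested, function(i) {
      any(imm$chrom == regions$chrom[i] & imm$start <= regions$end[i] &
            imm$end >= regions$start[i])
    }, logical(1))
    tested <- tested[!overlaps_immune]
  }
  snv <- mutations[mutations$class == "SNV" &
                     mutations$timepoint == timepoint, , drop = FALSE]
  orf <- excl[excl$kind == "ORF", , drop = FALSE]
  utr <- excl[excl$kind == "UTR", , drop = FALSE]
  in_any <- function(muts, regs) {
    if (!nrow(regs) || !nrow(muts)) return(rep(FALSE, nrow(muts)))
    hit <- rep(FALSE, nrow(muts))
    for (j in seq_len(nrow(regs)))
      hit <- hit | (muts$chrom == regs$chrom[j] &
                      muts$pos >= regs$start[j] & muts$pos <= regs$end[j])
    hit
  }
  probs <- region_mutation_prob(context_counts[tested, , drop = FALSE],
                                model, rt_bin[tested])
  res <- vector("list", length(tested))
  for (ii in seq_along(tested)) {
    i <- tested[ii]
    inreg <- snv[snv$chrom == regions$chrom[i] &
                   snv$pos >= regions$start[i] &
                   snv$pos <= regions$end[i], , drop = FALSE]
    if (nrow(inreg)) {
      drop <- in_any(inreg, orf)
      if (regions$kind[i] == "CRE") drop <- drop | in_any(inreg, utr)
      inreg <- inreg[!drop, , drop = FALSE]
    }
    k <- length(unique(inreg$sample_id))
    p_rec <- poisson_binomial_tail(probs[, ii], k)
    p_clust <- NA_real_
    if (k >= 3L) {
      rl <- regions$end[i] - regions$start[i] + 1L
      p_clust <- clustering_test(inreg$pos, inreg$sample_id, rl,
                                 n_perm = n_perm, seed = seed + ii)
    }
    p_comb <- if (is.na(p_clust)) p_rec else fisher_combine(p_rec, p_clust)
    res[[ii]] <- data.frame(region_id = regions$region_id[i],
                            kind = regions$kind[i], k = k, p_rec = p_rec,
                            p_clust = p_clust, p_combined = p_comb,
                            reported = k >= 3L, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_combined)
  out[, c("region_id", "kind", "k", "p_rec", "p_clust", "p_combined",
          "q_value", "reported")]
}
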