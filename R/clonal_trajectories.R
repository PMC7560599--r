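#' @title Clonal evolution patterns from 2-D CCF clustering
#' @name clonal_trajectories
#' @description
#' For each primary/relapse tumour pair, SNVs restricted to diploid
#' regions are embedded in the (primary CCF, relapse CCF) plane, likely
#' neutral-tail mutations are removed, the point cloud is clustered
#' with a Dirichlet-process mixture of bivariate Gaussians (collapsed
#' Gibbs sampler), small clusters are filtered, and the pair is
#' classified into one of three clonal-evolution patterns: Pattern 1
#' (dominant clone persists, new clone appears), Pattern 2 (a primary
#' subclone expands to dominate the relapse), Pattern 3 (primary clones
#' disappear, new clones emerge).
NULL

#' Restrict SNVs to regions diploid at both timepoints
#'
#' Keeps SNVs whose position is covered by a segment with total copy
#' number 2 and minor copy number 1 at both the primary and the relapse
#' timepoint of the sample. SNVs at positions not covered by segments
#' at both timepoints are excluded.
#'
#' @param mutations SNV rows of one sample pair (both timepoints).
#' @param segments Segment rows of the same sample (both timepoints).
#' @return The diploid subset of `mutations`.
#' @export
filter_diploid_snvs <- function(mutations, segments) {
  snv <- mutations[mutations$class == "SNV", , drop = FALSE]
  if (!nrow(snv)) return(snv)
  ok_tp <- function(tp) {
    seg <- segments[segments$timepoint == tp & segments$total_cn == 2 &
                      segments$minor_cn == 1, , drop = FALSE]
    idx <- split(seg[order(seg$start), c("start", "end")], seg$chrom)
    in_regions(idx, snv$chrom, snv$pos)
  }
  snv[ok_tp("primary") & ok_tp("relapse"), , drop = FALSE]
}

#' Remove likely neutral-tail mutations before clustering
#'
#' Fits a two-component mixture by EM to frequencies in (0, 1\]: a
#' truncated Pareto (power-law) tail with density proportional to
#' `f^-(1+alpha)` on \[`f_min`, `tail_max`\] — the analytic shape of
#' passenger mutations under neutral growth — against a Beta component
#' for clonal/subclonal clusters. Points with posterior probability
#' above 0.5 for the tail component are excluded. With fewer than 50
#' points no filtering is attempted (pass-through with a warning).
#' Re-filtering the kept set is not guaranteed to be a no-op (the
#' mixture is refit), and idempotence is deliberately not claimed.
#'
#' @param f Frequencies (CCF or VAF) in (0, 1\].
#' @param f_min Lower detection bound of the tail (default 0.05).
#' @param tail_max Upper support of the tail (default 0.25).
#' @param seed Integer seed (EM initialisation).
#' @param max_iter EM iterations (default 200).
#' @return Logical keep-mask over `f`.
#' @export
neutral_tail_filter <- function(f, f_min = 0.05, tail_max = 0.25,
                                seed = 1L, max_iter = 200L) {
  stopifnot(all(f > 0 & f <= 1))
  n <- length(f)
  if (n < 50L) {
    warning("fewer than 50 points; neutral-tail filtering skipped")
    return(rep(TRUE, n))
  }
  set.seed(seed)
  in_tail_support <- f >= f_min & f <= tail_max
  # truncated Pareto log-density on [f_min, tail_max]
  dtail <- function(x, alpha) {
    norm <- (f_min^(-alpha) - tail_max^(-alpha)) / alpha
    ifelse(x >= f_min & x <= tail_max,
           x^(-(1 + alpha)) / norm, 0)
  }
  alpha <- 1
  ab <- c(2, 2)
  w <- if (any(in_tail_support))
    0.5 * mean(in_tail_support) else 0.01
  for (it in seq_len(max_iter)) {
    d1 <- w * dtail(f, alpha)
    d2 <- (1 - w) * stats::dbeta(f, ab[1L], ab[2L])
    r <- d1 / pmax(d1 + d2, .Machine$double.xmin)
    w_new <- mean(r)
    # weighted MLE of the truncated Pareto index (1-D optimisation)
    if (sum(r) > 1e-8) {
      nll <- function(a) {
        norm <- (f_min^(-a) - tail_max^(-a)) / a
        -sum(r * (-(1 + a) * log(pmax(f, f_min)) - log(norm)))
      }
      alpha_new <- stats::optimize(nll, c(0.05, 10))$minimum
    } else alpha_new <- alpha
    # weighted method-of-moments Beta fit
    wr <- 1 - r
    mu <- sum(wr * f) / sum(wr)
    v <- sum(wr * (f - mu)^2) / sum(wr)
    v <- min(v, mu * (1 - mu) * 0.99)
    if (v > 1e-8) {
      common <- mu * (1 - mu) / v - 1
      ab_new <- c(mu * common, (1 - mu) * common)
    } else ab_new <- ab
    conv <- abs(w_new - w) < 1e-8 && abs(alpha_new - alpha) < 1e-6
    w <- min(max(w_new, 1e-6), 1 - 1e-6)
    alpha <- alpha_new
    ab <- pmax(ab_new, 0.05)
    if (conv) break
  }
  d1 <- w * dtail(f, alpha)
  d2 <- (1 - w) * stats::dbeta(f, ab[1L], ab[2L])
  post <- d1 / pmax(d1 + d2, .Machine$double.xmin)
  post <= 0.5
}

#' Dirichlet-process clustering of mutations in 2-D CCF space
#'
#' Collapsed Gibbs sampler for a Dirichlet-process mixture of bivariate
#' Gaussians (concentration `alpha`, conjugate Normal-Inverse-Gamma
#' base measure per dimension; 500 sweeps with 250 burn-in by default).
#' The point-estimate partition minimises the posterior expected
#' pairwise-assignment (Dahl least-squares) loss over the stored
#' posterior samples; cluster centres are the mean CCFs of the assigned
#' points, clipped to the unit square.
#'
#' @param points data.frame/matrix with columns `ccf_primary`,
#'   `ccf_relapse`; at least 100 points.
#' @param seed Integer seed.
#' @param alpha DP concentration (default 1).
#' @param n_sweeps,burn_in,thin Gibbs schedule (defaults 500/250/5).
#' @param prior Base-measure hyperparameters: list with `m0` (location,
#'   0.5), `k0` (location strength, 0.05), `a0`/`b0` (variance shape
#'   and scale, 3 and 0.02 — prior cluster s.d. around 0.1).
#' @return List of class `ccf_clustering`: `clusters` data.frame
#'   (`cluster_id`, `ccf_primary`, `ccf_relapse`, `n_snvs`,
#'   `frac_total`) and the per-point `assignment`.
#' @export
cluster_ccf_2d <- function(points, seed = 1L, alpha = 1,
                           n_sweeps = 500L, burn_in = 250L, thin = 5L,
                           prior = list(m0 = 0.5, k0 = 0.05, a0 = 3,
                                        b0 = 0.02)) {
  x <- points[, "ccf_primary"]
  y <- points[, "ccf_relapse"]
  if (length(x) < 100L)
    stop("2-D CCF clustering requires at least 100 points")
  set.seed(seed)
  fit <- dp_gibbs_cluster(as.numeric(x), as.numeric(y), alpha,
                          as.integer(n_sweeps), as.integer(burn_in),
                          as.integer(thin), prior$m0, prior$k0,
                          prior$a0, prior$b0)
  z <- fit$assignment
  ids <- sort(unique(z))
  clusters <- data.frame(
    cluster_id = ids,
    ccf_primary = clip01(vapply(ids, function(c) mean(x[z == c]),
                                numeric(1))),
    ccf_relapse = clip01(vapply(ids, function(c) mean(y[z == c]),
                                numeric(1))),
    n_snvs = vapply(ids, function(c) sum(z == c), integer(1)),
    stringsAsFactors = FALSE)
  clusters$frac_total <- clusters$n_snvs / length(x)
  structure(list(clusters = clusters, assignment = z),
            class = "ccf_clustering")
}

#' Retain clusters that are large enough to interpret
#'
#' Keeps clusters with at least `min_snvs` SNVs and at least
#' `min_frac` of the pair's total mutations.
#'
#' @param clusters Cluster data.frame (`n_snvs` column).
#' @param total_n Total mutation count of the pair.
#' @param min_snvs,min_frac Thresholds (defaults 100 and 0.01).
#' @return Filtered cluster data.frame.
#' @export
filter_clusters <- function(clusters, total_n, min_snvs = 100L,
                            min_frac = 0.01) {
  keep <- clusters$n_snvs >= min_snvs &
    clusters$n_snvs / total_n >= min_frac
  clusters[keep, , drop = FALSE]
}

#' Classify a pair's clonal evolution pattern from its CCF clusters
#'
#' A cluster is "present" at a timepoint when its CCF is at least
#' `delta`. Rules, in precedence order: Pattern 2 when some cluster
#' sits at the vertical top and horizontal centre (primary CCF between
#' `delta` and `subclonal_hi`, relapse CCF at least `clonal_thr`) — a
#' subclone that expanded to dominate the relapse; otherwise Pattern 1
#' when no primary-present cluster disappears (all keep relapse CCF at
#' least `delta`) and some relapse-only cluster exists; otherwise
#' Pattern 3. Pattern 2 takes precedence because subclonal expansion is
#' typically accompanied by branching (Pattern-3-like gain/loss of
#' minor clones).
#'
#' @param clusters Retained cluster data.frame with `ccf_primary`,
#'   `ccf_relapse`.
#' @param delta Presence threshold (default 0.10).
#' @param clonal_thr Relapse-clonal threshold for Pattern 2 (default
#'   0.80).
#' @param subclonal_hi Upper primary-subclonal bound for Pattern 2
#'   (default 0.60).
#' @return List of class `pattern_call`: `pattern` (1, 2 or 3) and
#'   `evidence` (character rule firings).
#' @export
classify_pattern <- function(clusters, delta = 0.10, clonal_thr = 0.80,
                             subclonal_hi = 0.60) {
  if (!nrow(clusters)) stop("no retained clusters to classify")
  cp <- clusters$ccf_primary
  cr <- clusters$ccf_relapse
  evidence <- character(0)
  p2 <- cp >= delta & cp <= subclonal_hi & cr >= clonal_thr
  if (any(p2)) {
    evidence <- sprintf("subclone (%.2f) expands to relapse-clonal (%.2f)",
                        cp[p2][1L], cr[p2][1L])
    out <- list(pattern = 2L, evidence = evidence)
    class(out) <- "pattern_call"
    return(out)
  }
  primary_present <- cp >= delta
  persists <- cr[primary_present] >= delta
  relapse_only <- cp < delta & cr >= delta
  if (all(persists) && any(relapse_only)) {
    evidence <- c("no primary cluster disappears",
                  sprintf("new relapse cluster at CCF %.2f",
                          cr[relapse_only][1L]))
    out <- list(pattern = 1L, evidence = evidence)
  } else {
    if (!all(persists))
      evidence <- sprintf("primary cluster (%.2f) disappears at relapse",
                          cp[primary_present][!persists][1L])
    if (any(relapse_only))
      evidence <- c(evidence,
                    sprintf("new relapse cluster at CCF %.2f",
                            cr[relapse_only][1L]))
    out <- list(pattern = 3L, evidence = evidence)
  }
  class(out) <- "pattern_call"
  out
}

#' Fraction of a cluster's SNVs detected at relapse
#'
#' @param assignment Per-SNV cluster assignment.
#' @param shared Logical per SNV: detected at relapse.
#' @return data.frame `cluster_id`, `shared_fraction` (`NA` for empty
#'   clusters).
#' @export
shared_snv_fraction <- function(assignment, shared) {
  ids <- sort(unique(assignment))
  data.frame(cluster_id = ids,
             shared_fraction = vapply(ids, function(c) {
               idx <- assignment == c
               if (!any(idx)) return(NA_real_)
               mean(shared[idx])
             }, numeric(1)))
}

# Join one pair's primary and relapse SNV rows into 2-D CCF points.
build_pair_points <- function(mutations, sample_id) {
  snv <- mutations[mutations$sample_id == sample_id &
                     mutations$class == "SNV", , drop = FALSE]
  key <- paste(snv$chrom, snv$pos, snv$alt, sep = ":")
  pri <- snv$timepoint == "primary"
  kp <- key[pri]; kr <- key[!pri]
  all_keys <- unique(c(kp, kr))
  cp <- rep(0, length(all_keys))
  cr <- rep(0, length(all_keys))
  cp[match(kp, all_keys)] <- snv$ccf[pri]
  cr[match(kr, all_keys)] <- snv$ccf[!pri]
  data.frame(key = all_keys, ccf_primary = cp, ccf_relapse = cr,
             stringsAsFactors = FALSE)
}

#' Classify clonal evolution patterns for every pair in a cohort
#'
#' Runs the full trajectory pipeline for each matched pair: diploid-SNV
#' restriction, 2-D point construction (undetected SNVs carry CCF 0 at
#' the missing timepoint), neutral-tail exclusion, DP clustering,
#' cluster filtering, pattern classification and shared-SNV fractions.
#' Large point clouds are subsampled to `max_points` for the sampler.
#'
#' @param bundle A `cohort_bundle`.
#' @param seed Integer seed.
#' @param max_points Subsampling bound for the Gibbs sampler (default
#'   2000).
#' @param ... Passed to [classify_pattern()].
#' @return data.frame per pair: `sample_id`, `pattern`, `n_snvs`,
#'   `n_clusters`; cluster tables in `attr(, "clusters")`.
#' @export
run_trajectories <- function(bundle, seed = 1L, max_points = 2000L,
                             ...) {
  meta <- bundle$metadata
  pair_ids <- meta$sample_id[!is.na(meta$elapsed_months)]
  out <- vector("list", length(pair_ids))
  cluster_tabs <- list()
  for (i in seq_along(pair_ids)) {
    s <- pair_ids[i]
    muts <- bundle$mutations[bundle$mutations$sample_id == s, ,
                             drop = FALSE]
    segs <- bundle$segments[bundle$segments$sample_id == s, ,
                            drop = FALSE]
    dip <- filter_diploid_snvs(muts, segs)
    pts <- build_pair_points(dip, s)
    pos <- pmax(pts$ccf_primary, pts$ccf_relapse)
    ok <- pos > 0
    pts <- pts[ok, , drop = FALSE]
    keep <- neutral_tail_filter(pmax(pts$ccf_primary, pts$ccf_relapse),
                                seed = seed + i)
    pts <- pts[keep, , drop = FALSE]
    set.seed(seed + 1000L + i)
    if (nrow(pts) > max_points)
      pts <- pts[sample.int(nrow(pts), max_points), , drop = FALSE]
    cl <- cluster_ccf_2d(pts, seed = seed + 2000L + i)
    retained <- filter_clusters(cl$clusters, nrow(pts))
    call <- classify_pattern(retained, ...)
    shared <- shared_snv_fraction(cl$assignment, pts$ccf_relapse > 0)
    tab <- merge(cl$clusters, shared, by = "cluster_id")
    tab$retained <- tab$cluster_id %in% retained$cluster_id
    cluster_tabs[[s]] <- tab
    out[[i]] <- data.frame(sample_id = s, pattern = call$pattern,
                           n_snvs = nrow(pts),
                           n_clusters = nrow(retained),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "clusters") <- cluster_tabs
  res
}
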