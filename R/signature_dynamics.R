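#' @title Mutational-signature dynamics
#' @name signature_dynamics
#' @description
#' De novo extraction of single-base-substitution signatures by
#' non-negative matrix factorisation (multiplicative updates minimising
#' generalised Kullback-Leibler divergence), cosine-similarity
#' assignment of de novo spectra to a catalog (threshold 0.75),
#' non-negative least-squares refitting of per-sample exposures over
#' the assigned catalog subset (pruning contributions below 6%),
#' group combination (AID/APOBEC = SBS2+9+13; flat = SBS5+8+40, SBS3
#' excluded from the model), and the paired relapse-dynamics
#' statistics: chi-square comparison of paired exposure profiles,
#' Fisher test for the burden/APOBEC association, Spearman correlation
#' of relapse-specific APOBEC contribution with time to relapse, and
#' the C>G transversion fraction.
NULL

#' De novo signature extraction by NMF (multiplicative updates)
#'
#' Factorises a samples-by-96 count matrix `V ~ t(W H)` with
#' multiplicative updates minimising the generalised KL divergence.
#' Signature columns are normalised to simplexes (scale absorbed into
#' the loadings). Deterministic given `seed`; the objective is
#' non-increasing over iterations.
#'
#' @param counts Samples x 96 non-negative count matrix.
#' @param k Number of signatures (1 <= k <= min(dim)).
#' @param seed Integer seed for the random initialisation.
#' @param n_iter Update iterations (default 2000).
#' @return List: `signatures` (96 x k, columns sum to 1), `loadings`
#'   (samples x k), `objective` (per-iteration KL divergence).
#' @export
extract_signatures_nmf <- function(counts, k, seed = 1L,
                                   n_iter = 2000L) {
  V <- t(as.matrix(counts))                     # 96 x S
  if (any(V < 0)) stop("counts must be non-negative")
  if (k > min(dim(V)) || k < 1) stop("k out of range")
  set.seed(seed)
  eps <- 1e-10
  W <- matrix(stats::runif(96 * k, 0.1, 1), 96, k)
  H <- matrix(stats::runif(k * ncol(V), 0.1, 1), k, ncol(V))
  obj <- numeric(n_iter)
  kl <- function(V, WH) {
    pos <- V > 0
    sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
  }
  for (it in seq_len(n_iter)) {
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / pmax(matrix(rowSums(H)[col(W)],
                                               96, k), eps)
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / pmax(matrix(colSums(W)[row(H)],
                                               k, ncol(V)), eps)
    obj[it] <- kl(V, W %*% H + eps)
  }
  scale <- colSums(W)
  W <- sweep(W, 2L, scale, "/")
  H <- H * scale
  rownames(W) <- context96_labels()
  list(signatures = W, loadings = t(H), objective = obj)
}

#' Cosine similarity of two spectra
#'
#' @param a,b Non-zero numeric vectors of equal length.
#' @return `sum(a*b) / (||a|| ||b||)`.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Assign de novo signatures to catalog signatures
#'
#' Each de novo spectrum maps to its best-cosine catalog signature iff
#' the similarity strictly exceeds the threshold; otherwise it remains
#' unassigned.
#'
#' @param denovo 96 x k matrix of de novo spectra.
#' @param catalog 96 x K catalog.
#' @param threshold Assignment threshold (default 0.75, strict `>`).
#' @return data.frame `denovo`, `assigned` (catalog id or `NA`),
#'   `cosine`.
#' @export
assign_to_catalog <- function(denovo, catalog, threshold = 0.75) {
  stopifnot(nrow(denovo) == nrow(catalog))
  res <- lapply(seq_len(ncol(denovo)), function(j) {
    sims <- apply(catalog, 2L, cosine_similarity, b = denovo[, j])
    best <- which.max(sims)
    data.frame(denovo = colnames(denovo)[j] %||% paste0("D", j),
               assigned = if (sims[best] > threshold)
                 colnames(catalog)[best] else NA_character_,
               cosine = unname(sims[best]), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Refit signature exposures by non-negative least squares
#'
#' Regresses the normalised 96-channel spectrum on the catalog columns
#' under non-negativity, then iteratively drops signatures whose
#' normalised weight falls below `min_contrib` and refits until stable.
#' Weights are renormalised to sum 1.
#'
#' @param counts96 96-vector of mutation counts (sum > 0).
#' @param catalog 96 x K catalog subset (the signatures extracted de
#'   novo).
#' @param min_contrib Minimum retained contribution (default 0.06).
#' @return Named exposure vector over the catalog columns (zeros for
#'   pruned signatures), summing to 1.
#' @export
refit_exposures <- function(counts96, catalog, min_contrib = 0.06) {
  if (is.null(dim(catalog)) || ncol(catalog) == 0)
    stop("empty catalog subset")
  if (sum(counts96) <= 0) stop("counts must sum to a positive number")
  x <- counts96 / sum(counts96)
  active <- colnames(catalog)
  repeat {
    A <- catalog[, active, drop = FALSE]
    w <- pracma::lsqnonneg(A, x)$x
    if (sum(w) == 0) {
      w <- rep(1 / length(active), length(active))
    } else w <- w / sum(w)
    drop <- active[w < min_contrib]
    if (!length(drop) || length(active) - length(drop) < 1L) break
    active <- setdiff(active, drop)
  }
  out <- stats::setNames(numeric(ncol(catalog)), colnames(catalog))
  out[active] <- w
  out
}

#' Combine exposures into AID/APOBEC and flat groups
#'
#' Sums AID/APOBEC signatures (SBS2, SBS9, SBS13) and the flat-profile
#' signatures (SBS5, SBS8, SBS40); any remaining exposure is reported
#' as `other`. SBS3 must not be present (it is excluded from the model
#' as inactive in myeloma); supplying it is an error. Group masses plus
#' `other` conserve the total exactly.
#'
#' @param exposures Named exposure vector or samples x K matrix.
#' @return data.frame with `aid_apobec`, `flat`, `other`, `total`.
#' @export
combine_groups <- function(exposures) {
  if (is.null(dim(exposures)))
    exposures <- matrix(exposures, nrow = 1L,
                        dimnames = list(NULL, names(exposures)))
  if ("SBS3" %in% colnames(exposures))
    stop("SBS3 must not be in the exposure model")
  apo <- intersect(c("SBS2", "SBS9", "SBS13"), colnames(exposures))
  flat <- intersect(c("SBS5", "SBS8", "SBS40"), colnames(exposures))
  aid_apobec <- rowSums(exposures[, apo, drop = FALSE])
  flat_sum <- rowSums(exposures[, flat, drop = FALSE])
  total <- rowSums(exposures)
  data.frame(aid_apobec = aid_apobec, flat = flat_sum,
             other = total - aid_apobec - flat_sum, total = total)
}

#' Chi-square comparison of paired signature profiles
#'
#' Pearson chi-square on the 2 x K table of signature-attributed
#' mutation counts at primary and relapse. Signature categories whose
#' expected count falls below 1 are merged (smallest first) with a
#' warning.
#'
#' @param primary_counts,relapse_counts Named per-signature counts.
#' @return p-value.
#' @export
paired_signature_chisq <- function(primary_counts, relapse_counts) {
  stopifnot(identical(names(primary_counts), names(relapse_counts)))
  tab <- rbind(primary = primary_counts, relapse = relapse_counts)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  repeat {
    if (ncol(tab) < 2L) return(1)
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expd >= 1)) break
    warning("merging smallest signature categories (expected count < 1)")
    o <- order(colSums(tab))
    merged <- tab[, o[1L]] + tab[, o[2L]]
    tab <- cbind(tab[, -o[1:2], drop = FALSE], merged)
  }
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}

#' Fisher exact test for burden/APOBEC concordance at relapse
#'
#' Two-sided Fisher exact test on the 2 x 2 table of per-pair
#' indicators: mutational burden increased at relapse vs AID/APOBEC
#' contribution increased at relapse.
#'
#' @param burden_up,apobec_up Logical vectors (one entry per pair).
#' @return p-value.
#' @export
burden_apobec_association <- function(burden_up, apobec_up) {
  stopifnot(length(burden_up) == length(apobec_up),
            length(burden_up) >= 1L)
  tab <- table(factor(burden_up, levels = c(FALSE, TRUE)),
               factor(apobec_up, levels = c(FALSE, TRUE)))
  stats::fisher.test(tab)$p.value
}

#' Spearman correlation of relapse APOBEC contribution with time
#'
#' Spearman rank correlation (ties mid-ranked) between the AID/APOBEC
#' contribution of relapse-specific mutations and the elapsed time to
#' relapse.
#'
#' @param apobec_share Per-pair relapse-specific AID/APOBEC share.
#' @param elapsed_months Per-pair time to relapse.
#' @return List `rho`, `p`; `NA` values (with a warning) when either
#'   vector is constant.
#' @export
apobec_vs_time <- function(apobec_share, elapsed_months) {
  stopifnot(length(apobec_share) == length(elapsed_months))
  if (length(apobec_share) < 4L) stop("need at least 4 pairs")
  if (stats::sd(apobec_share) == 0 || stats::sd(elapsed_months) == 0) {
    warning("constant input; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(apobec_share, elapsed_months,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Fraction of C>G transversions among SNVs
#'
#' The share of SNVs in the pyrimidine-strand C>G substitution class
#' among all six classes.
#'
#' @param mutations Mutation table (SNVs with `context96` are used).
#' @return Fraction in \[0, 1\], or `NA` when there are no SNVs.
#' @export
cg_transversion_fraction <- function(mutations) {
  ctx <- mutations$context96[mutations$class == "SNV" &
                               !is.na(mutations$context96)]
  if (!length(ctx)) return(NA_real_)
  mean(context96_class(ctx) == 1L)
}

# per-sample/timepoint 96-channel counts from a mutation table
context_count_matrix <- function(mutations, timepoint) {
  snv <- mutations[mutations$class == "SNV" &
                     mutations$timepoint == timepoint &
                     !is.na(mutations$context96), , drop = FALSE]
  samples <- sort(unique(snv$sample_id))
  m <- table(factor(snv$sample_id, levels = samples),
             factor(snv$context96, levels = 0:95))
  out <- matrix(as.numeric(m), nrow = length(samples),
                dimnames = list(samples, context96_labels()))
  out
}

# relapse rows absent from the primary table at the same chrom/pos/alt
relapse_specific_mutations <- function(mutations, sample_id) {
  mu <- mutations[mutations$sample_id == sample_id &
                    mutations$class == "SNV", , drop = FALSE]
  keyp <- with(mu[mu$timepoint == "primary", ],
               paste(chrom, pos, alt, sep = ":"))
  rel <- mu[mu$timepoint == "relapse", , drop = FALSE]
  keyr <- paste(rel$chrom, rel$pos, rel$alt, sep = ":")
  rel[!(keyr %in% keyp), , drop = FALSE]
}

#' Signature dynamics across a paired cohort
#'
#' End-to-end signature analysis of a cohort bundle: de novo NMF
#' extraction on the primary genomes, cosine assignment to the bundled
#' catalog, per-sample exposure refitting over the assigned subset for
#' primary, relapse and relapse-specific mutation sets, group
#' combination, and the paired statistics (chi-square per pair, Fisher
#' burden/APOBEC association, Spearman APOBEC-vs-time, C>G fractions).
#'
#' @param bundle A `cohort_bundle`.
#' @param k Signatures to extract de novo (default 4).
#' @param seed Integer seed.
#' @param nmf_iter NMF iterations (default 800).
#' @return List: `assignments`, `exposures` (long data.frame),
#'   `pair_stats`, `spearman`, `fisher_p`.
#' @export
run_signature_dynamics <- function(bundle, k = 4L, seed = 1L,
                                   nmf_iter = 800L) {
  catalog <- bundle$catalog
  prim_counts <- context_count_matrix(bundle$mutations, "primary")
  nmf <- extract_signatures_nmf(prim_counts, k = k, seed = seed,
                                n_iter = nmf_iter)
  colnames(nmf$signatures) <- paste0("D", seq_len(k))
  asg <- assign_to_catalog(nmf$signatures, catalog)
  used <- unique(stats::na.omit(asg$assigned))
  if (!length(used)) used <- colnames(catalog)
  sub <- catalog[, used, drop = FALSE]
  refit_tp <- function(counts, timepoint) {
    do.call(rbind, lapply(rownames(counts), function(s) {
      e <- refit_exposures(counts[s, ], sub)
      data.frame(sample_id = s, timepoint = timepoint,
                 signature = names(e), exposure = as.numeric(e),
                 stringsAsFactors = FALSE)
    }))
  }
  expo <- rbind(refit_tp(prim_counts, "primary"),
                refit_tp(context_count_matrix(bundle$mutations,
                                              "relapse"), "relapse"))
  meta <- bundle$metadata
  pair_ids <- meta$sample_id[!is.na(meta$elapsed_months)]
  stats_rows <- list()
  rs_share <- rep(NA_real_, length(pair_ids))
  burden_up <- apo_up <- rep(NA, length(pair_ids))
  for (i in seq_along(pair_ids)) {
    s <- pair_ids[i]
    mu <- bundle$mutations[bundle$mutations$sample_id == s &
                             bundle$mutations$class == "SNV", ,
                           drop = FALSE]
    np <- sum(mu$timepoint == "primary")
    nr <- sum(mu$timepoint == "relapse")
    ep <- expo$exposure[expo$sample_id == s &
                          expo$timepoint == "primary"]
    er <- expo$exposure[expo$sample_id == s &
                          expo$timepoint == "relapse"]
    names(ep) <- names(er) <- used
    p_chisq <- paired_signature_chisq(round(ep * np), round(er * nr))
    rs <- relapse_specific_mutations(bundle$mutations, s)
    cnt_rs <- tabulate(rs$context96 + 1L, nbins = 96L)
    e_rs <- refit_exposures(cnt_rs, sub)
    rs_share[i] <- combine_groups(e_rs)$aid_apobec
    burden_up[i] <- nr > np
    apo_up[i] <- combine_groups(er)$aid_apobec >
      combine_groups(ep)$aid_apobec
    stats_rows[[i]] <- data.frame(
      sample_id = s, n_primary = np, n_relapse = nr,
      chisq_p = p_chisq, relapse_specific_apobec = rs_share[i],
      cg_fraction_primary = cg_transversion_fraction(
        mu[mu$timepoint == "primary", ]),
      cg_fraction_relapse_specific = cg_transversion_fraction(rs),
      stringsAsFactors = FALSE)
  }
  pair_stats <- do.call(rbind, stats_rows)
  elapsed <- meta$elapsed_months[match(pair_ids, meta$sample_id)]
  sp <- apobec_vs_time(rs_share, elapsed)
  fp <- burden_apobec_association(burden_up, apo_up)
  list(assignments = asg, exposures = expo, pair_stats = pair_stats,
       spearman = sp, fisher_p = fp)
}
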