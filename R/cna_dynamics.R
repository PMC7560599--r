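#' @title Arm-level copy-number dynamics at relapse
#' @name cna_dynamics
#' @description
#' Aggregates allele-specific segments into arm-level events over the 44
#' autosomal chromosome-arm loci and runs the two paired permutation
#' tests for relapse copy-number dynamics: a condition-label swap test
#' for changes in arm event frequency between primary and relapse, and
#' an arm-relocation test for whether additional relapse CNAs localise
#' to pre-existing unstable arms more often than expected among the 44
#' arms.
NULL

arm_state_levels <- c("neutral", "gain", "amp", "nLOH", "loss",
                      "deep_loss")

# severity used for "additional CNA at a pre-existing unstable region":
# gains progress gain -> amp; losses progress nLOH -> loss -> deep_loss.
arm_state_severity <- c(neutral = 0, gain = 1, amp = 2, nLOH = 1,
                        loss = 2, deep_loss = 3)

#' Call arm-level copy-number events from segments
#'
#' For each sample, timepoint and chromosome arm, segments are clipped
#' to the arm and classified per base: `amp` (total CN >= 4), `gain`
#' (total CN 3), `deep_loss` (total CN 0), `loss` (total CN 1), `nLOH`
#' (total CN 2, minor 0), else neutral (against a diploid baseline; the
#' simulated cohort is non-hyperdiploid). The arm state is the class
#' covering at least 50% of the arm length (precedence by severity when
#' tied), else neutral. The event CCF is the clonal fraction of the
#' largest qualifying segment and `span_bp` its clipped length.
#'
#' @param segments Segment data.frame.
#' @param arms Arm table from [arm_table()].
#' @return data.frame `sample_id`, `timepoint`, `arm`, `state`, `ccf`,
#'   `span_bp`; one row per non-neutral (sample, timepoint, arm) plus
#'   none for neutral arms.
#' @export
call_arm_events <- function(segments, arms = arm_table()) {
  classify <- function(total, minor) {
    ifelse(total >= 4, "amp",
      ifelse(total == 3, "gain",
        ifelse(total == 0, "deep_loss",
          ifelse(total == 1, "loss",
            ifelse(total == 2 & minor == 0, "nLOH", "neutral")))))
  }
  out <- list()
  key <- interaction(segments$sample_id, segments$timepoint, drop = TRUE)
  for (grp in split(segments, key)) {
    for (a in seq_len(nrow(arms))) {
      seg <- grp[grp$chrom == arms$chrom[a], , drop = FALSE]
      if (!nrow(seg)) next
      s <- pmax(seg$start, arms$start[a])
      e <- pmin(seg$end, arms$end[a])
      keep <- s <= e
      if (!any(keep)) next
      seg <- seg[keep, , drop = FALSE]
      len <- (e - s + 1)[keep]
      cls <- classify(seg$total_cn, seg$minor_cn)
      arm_len <- arms$end[a] - arms$start[a] + 1
      cover <- tapply(len, factor(cls, levels = arm_state_levels), sum)
      cover[is.na(cover)] <- 0
      cand <- names(cover)[cover >= 0.5 * arm_len & names(cover) != "neutral"]
      if (!length(cand)) next
      state <- cand[which.max(arm_state_severity[cand])]
      qual <- which(cls == state)
      big <- qual[which.max(len[qual])]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = grp$sample_id[1L], timepoint = grp$timepoint[1L],
        arm = arms$arm[a], state = state,
        ccf = seg$clonal_frac[big], span_bp = sum(len[qual]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), timepoint = character(),
                      arm = character(), state = character(),
                      ccf = numeric(), span_bp = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify a sample as hyperdiploid
#'
#' A chromosome counts as amplified when at least 90% of its length is
#' covered by gain segments (total CN > 2); a sample is hyperdiploid
#' when at least two autosomes are amplified.
#'
#' @param segments Segments of one sample (one timepoint).
#' @param genome Genome table with chromosome lengths.
#' @return Logical scalar.
#' @export
classify_hyperdiploid <- function(segments, genome = synthetic_genome()) {
  amplified <- 0L
  for (i in seq_len(nrow(genome))) {
    seg <- segments[segments$chrom == genome$chrom[i] &
                      segments$total_cn > 2, , drop = FALSE]
    if (!nrow(seg)) next
    covered <- sum(pmin(seg$end, genome$length[i]) -
                     pmax(seg$start, 1) + 1)
    if (covered >= 0.9 * genome$length[i]) amplified <- amplified + 1L
  }
  amplified >= 2L
}

#' Paired permutation test for arm event frequency change
#'
#' For a given arm and event state, the statistic is the net frequency
#' change `sum_pairs I(event at relapse) - I(event at primary)`. Under
#' the null each pair's condition labels are swapped independently with
#' probability 1/2 (flipping the sign of its term); the two-sided
#' empirical p-value is `(1 + #\{|net*| >= |net|\}) / (n_perm + 1)`.
#' Arms with a net change in fewer than two tumours are not tested
#' (`p_empirical = NA`), mirroring the reporting rule.
#'
#' @param paired_events Arm events (from [call_arm_events()]) for
#'   matched pairs: both timepoints present for every `sample_id`.
#' @param pair_ids Character vector of the paired sample ids (defines
#'   the pairs; every id must have rows possible at both timepoints).
#' @param arm,state Arm label and event state tested.
#' @param n_perm Number of label swaps (default 10000).
#' @param seed Integer seed.
#' @return data.frame `arm`, `state`, `observed_stat`, `p_empirical`,
#'   `n_perm`.
#' @export
arm_frequency_change_test <- function(paired_events, pair_ids, arm,
                                      state, n_perm = 10000L, seed = 1L) {
  has <- function(tp) pair_ids %in% paired_events$sample_id[
    paired_events$timepoint == tp & paired_events$arm == arm &
      paired_events$state == state]
  d <- as.integer(has("relapse")) - as.integer(has("primary"))
  obs <- sum(d)
  if (abs(obs) < 2L)
    return(data.frame(arm = arm, state = state, observed_stat = obs,
                      p_empirical = NA_real_, n_perm = as.integer(n_perm),
                      stringsAsFactors = FALSE))
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE),
                  nrow = n_perm)
  net <- as.numeric(signs %*% d)
  p <- (1 + sum(abs(net) >= abs(obs))) / (n_perm + 1)
  data.frame(arm = arm, state = state, observed_stat = obs,
             p_empirical = p, n_perm = as.integer(n_perm),
             stringsAsFactors = FALSE)
}

#' Arm-relocation permutation test for localised instability
#'
#' Tests whether additional relapse CNAs localise to a given arm more
#' often than expected if each additional event had instead landed
#' uniformly on one of the 44 autosomal arm loci. The statistic is the
#' number of additional-CNA events on the tested arm; the empirical
#' p-value is `(1 + #\{count* >= k\}) / (n_perm + 1)`.
#'
#' @param k Observed additional-CNA events on the tested arm.
#' @param n_total Total additional-CNA events across tumours.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param n_arms Number of arm loci (default 44).
#' @return data.frame `observed_stat`, `p_empirical`, `n_perm`.
#' @export
instability_localization_test <- function(k, n_total, n_perm = 10000L,
                                          seed = 1L, n_arms = 44L) {
  stopifnot(k <= n_total)
  if (n_total == 0L)
    return(data.frame(observed_stat = 0L, p_empirical = 1,
                      n_perm = as.integer(n_perm)))
  set.seed(seed)
  draws <- matrix(sample.int(n_arms, n_total * n_perm, replace = TRUE),
                  nrow = n_perm)
  cnt <- rowSums(draws == 1L)
  p <- (1 + sum(cnt >= k)) / (n_perm + 1)
  data.frame(observed_stat = as.integer(k), p_empirical = p,
             n_perm = as.integer(n_perm))
}

#' Count additional relapse CNAs at pre-existing unstable arms
#'
#' An "additional CNA at a pre-existing unstable region" is an arm that
#' is altered at primary and whose state progresses at relapse (severity
#' strictly increases along the same axis: nLOH to LOH, LOH to complete
#' deletion, gain to further gain).
#'
#' @param paired_events Arm events for matched pairs (both timepoints).
#' @param pair_ids Paired sample ids.
#' @return data.frame `arm`, `k` (progression events on the arm); plus
#'   `attr(, "n_total")` — total progression events.
#' @export
count_arm_progressions <- function(paired_events, pair_ids) {
  arms <- arm_table()$arm
  ev <- list()
  for (s in pair_ids) {
    pri <- paired_events[paired_events$sample_id == s &
                           paired_events$timepoint == "primary", ,
                         drop = FALSE]
    rel <- paired_events[paired_events$sample_id == s &
                           paired_events$timepoint == "relapse", ,
                         drop = FALSE]
    for (a in intersect(pri$arm, rel$arm)) {
      sp <- pri$state[pri$arm == a][1L]
      sr <- rel$state[rel$arm == a][1L]
      gain_axis <- c("gain", "amp")
      loss_axis <- c("nLOH", "loss", "deep_loss")
      same_axis <- (sp %in% gain_axis && sr %in% gain_axis) ||
        (sp %in% loss_axis && sr %in% loss_axis)
      if (same_axis && arm_state_severity[sr] > arm_state_severity[sp])
        ev[[length(ev) + 1L]] <- a
    }
  }
  ev <- unlist(ev)
  k <- vapply(arms, function(a) sum(ev == a), integer(1))
  out <- data.frame(arm = arms, k = as.integer(k),
                    stringsAsFactors = FALSE)
  attr(out, "n_total") <- length(ev)
  out
}

#' Scan all arm/state combinations for relapse frequency change
#'
#' Convenience wrapper running [arm_frequency_change_test()] over every
#' (arm, state) combination observed in the paired events, plus the
#' arm-relocation test for every arm with observed progression events.
#'
#' @param bundle A `cohort_bundle`.
#' @param n_perm Permutations per test.
#' @param seed Integer seed.
#' @return List with `frequency_change` and `localization` data.frames.
#' @export
run_cna_tests <- function(bundle, n_perm = 10000L, seed = 1L) {
  meta <- bundle$metadata
  pair_ids <- meta$sample_id[!is.na(meta$elapsed_months)]
  segs <- bundle$segments[bundle$segments$sample_id %in% pair_ids, ,
                          drop = FALSE]
  ev <- call_arm_events(segs, arm_table(bundle$genome))
  combos <- unique(ev[, c("arm", "state")])
  fc <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
    arm_frequency_change_test(ev, pair_ids, combos$arm[i],
                              combos$state[i], n_perm = n_perm,
                              seed = seed + i)))
  prog <- count_arm_progressions(ev, pair_ids)
  n_total <- attr(prog, "n_total")
  loc <- do.call(rbind, lapply(which(prog$k > 0), function(i) {
    r <- instability_localization_test(prog$k[i], n_total,
                                       n_perm = n_perm, seed = seed + i)
    cbind(arm = prog$arm[i], r, stringsAsFactors = FALSE)
  }))
  list(frequency_change = fc, localization = loc)
}
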