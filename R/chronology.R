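#' @title Chronology of mutational events
#' @name chronology
#' @description
#' Orders driver SNVs and large-scale copy-number events in relative
#' time from cancer cell fractions (CCFs): events are ranked by mean CCF
#' (highest = earliest), consecutive events are compared with Tukey's
#' studentized-range test in a stepwise walk to delimit discrete
#' clonality levels, and each event's mean CCF receives a basic-
#' bootstrap 95% confidence interval.
NULL

#' Select events eligible for chronological timing
#'
#' SNV events are driver genes mutated in at least four samples; CNA
#' events are autosomal arm-level events spanning at least 3 Mb present
#' in at least eight samples. Samples flagged hyperdiploid in the
#' metadata are excluded. The per-sample CCF of a CNA event is the
#' clonal fraction of the qualifying segment covering the majority of
#' the arm.
#'
#' @param bundle A `cohort_bundle` (or a list with `mutations`,
#'   `segments`, `metadata`, `genome`).
#' @param min_snv_carriers,min_cna_carriers Carrier thresholds
#'   (defaults 4 and 8).
#' @param min_cna_mb Minimum CNA span in Mb (default 3).
#' @return A `timed_events` object: list with `events` (event_id, kind,
#'   n, mean_ccf) and `ccfs` (named list of per-sample CCF vectors).
#' @export
select_timed_events <- function(bundle, min_snv_carriers = 4L,
                                min_cna_carriers = 8L, min_cna_mb = 3) {
  meta <- bundle$metadata
  excluded <- if ("hyperdiploid" %in% names(meta))
    meta$sample_id[meta$hyperdiploid] else character(0)
  muts <- bundle$mutations
  muts <- muts[muts$timepoint == "primary" & !is.na(muts$gene) &
                 !(muts$sample_id %in% excluded), , drop = FALSE]
  ccfs <- list()
  if (nrow(muts)) {
    for (g in unique(muts$gene)) {
      mg <- muts[muts$gene == g, , drop = FALSE]
      v <- tapply(mg$ccf, mg$sample_id, mean)
      if (length(v) >= min_snv_carriers)
        ccfs[[g]] <- as.numeric(v)
    }
  }
  kinds <- rep("snv_driver", length(ccfs))
  segs <- bundle$segments
  segs <- segs[segs$timepoint == "primary" &
                 !(segs$sample_id %in% excluded), , drop = FALSE]
  if (nrow(segs)) {
    arm_ev <- call_arm_events(segs, arm_table(bundle$genome))
    arm_ev <- arm_ev[arm_ev$state != "neutral" &
                       arm_ev$span_bp >= min_cna_mb * 1e6, , drop = FALSE]
    if (nrow(arm_ev)) {
      arm_ev$event <- paste0(arm_ev$arm, "_", arm_ev$state)
      for (e in unique(arm_ev$event)) {
        ae <- arm_ev[arm_ev$event == e, , drop = FALSE]
        if (nrow(ae) >= min_cna_carriers) {
          ccfs[[e]] <- ae$ccf
          kinds <- c(kinds, "cna")
        }
      }
    }
  }
  if (!length(ccfs)) stop("no events meet the carrier thresholds")
  events <- data.frame(event_id = names(ccfs), kind = kinds,
                       n = vapply(ccfs, length, integer(1)),
                       mean_ccf = vapply(ccfs, mean, numeric(1)),
                       stringsAsFactors = FALSE)
  rownames(events) <- NULL
  structure(list(events = events, ccfs = ccfs), class = "timed_events")
}

#' Order timed events by mean CCF
#'
#' Descending mean CCF (clonal first); ties broken lexicographically by
#' event id, so the ordering is invariant to input permutation.
#'
#' @param timed A `timed_events` object.
#' @return The same object with `events` (and `ccfs`) reordered.
#' @export
order_by_mean_ccf <- function(timed) {
  ev <- timed$events
  if (!nrow(ev)) stop("no events to order")
  o <- order(-ev$mean_ccf, ev$event_id)
  timed$events <- ev[o, , drop = FALSE]
  rownames(timed$events) <- NULL
  timed$ccfs <- timed$ccfs[timed$events$event_id]
  timed
}

#' Assign discrete clonality levels along the CCF ordering
#'
#' Walks the descending-CCF ordering and compares each consecutive pair
#' of events with the Tukey studentized-range test (Tukey-Kramer
#' standard error from the pooled within-event variance; the number of
#' groups is the total number of events and the degrees of freedom are
#' the pooled residual df). A new clonality level starts whenever the
#' adjusted p-value falls below `alpha`; otherwise the event inherits
#' the current level. Events with zero pooled variance and a positive
#' mean difference separate levels (infinite statistic). Levels are
#' contiguous from 1 and never decrease along the ordering.
#'
#' @param timed An ordered `timed_events` object (see
#'   [order_by_mean_ccf()]).
#' @param alpha Significance threshold (default 0.05).
#' @return The object with a `level` column added to `events`.
#' @export
assign_clonality_levels <- function(timed, alpha = 0.05) {
  ev <- timed$events
  k <- nrow(ev)
  ns <- ev$n
  means <- ev$mean_ccf
  ss <- vapply(timed$ccfs, function(x) sum((x - mean(x))^2), numeric(1))
  df <- sum(ns) - k
  s2 <- if (df > 0) sum(ss) / df else 0
  level <- integer(k)
  level[1L] <- 1L
  if (k > 1L) for (i in 2L:k) {
    diff <- means[i - 1L] - means[i]
    if (s2 <= 0 || df <= 0) {
      p <- if (diff > 0) 0 else 1
    } else {
      se <- sqrt(s2 / 2 * (1 / ns[i - 1L] + 1 / ns[i]))
      q <- diff / se
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    }
    level[i] <- level[i - 1L] + (p < alpha)
  }
  timed$events$level <- level
  timed
}

#' Basic bootstrap confidence interval for a mean CCF
#'
#' The basic (reflected percentile) bootstrap interval
#' `(2*m - q_0.975, 2*m - q_0.025)` of the bootstrap distribution of the
#' mean, clipped to \[0, 1\]. Deterministic given `seed`; a single
#' observation yields the degenerate point interval.
#'
#' @param ccfs Numeric CCF vector.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @return Named numeric `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(ccfs, n_boot = 1000L, seed = 1L) {
  m <- mean(ccfs)
  n <- length(ccfs)
  if (n == 1L) return(c(ci_low = m, ci_high = m))
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  boots <- rowMeans(matrix(ccfs[idx], nrow = n_boot))
  q <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  ci <- c(2 * m - q[2L], 2 * m - q[1L])
  ci <- pmin(1, pmax(0, ci))
  c(ci_low = ci[1L], ci_high = ci[2L])
}

#' Full chronology pipeline
#'
#' Selects eligible events, orders them by mean CCF, assigns clonality
#' levels and attaches basic-bootstrap confidence intervals.
#'
#' @param bundle A `cohort_bundle`.
#' @param alpha Level-splitting threshold.
#' @param n_boot Bootstrap iterations.
#' @param seed Integer seed.
#' @param ... Passed to [select_timed_events()].
#' @return data.frame: `event_id`, `kind`, `n`, `mean_ccf`, `ci_low`,
#'   `ci_high`, `level`, ordered from earliest (highest CCF).
#' @export
run_chronology <- function(bundle, alpha = 0.05, n_boot = 1000L,
                           seed = 1L, ...) {
  timed <- assign_clonality_levels(
    order_by_mean_ccf(select_timed_events(bundle, ...)), alpha = alpha)
  ev <- timed$events
  cis <- t(vapply(seq_len(nrow(ev)), function(i)
    bootstrap_ci(timed$ccfs[[i]], n_boot = n_boot, seed = seed + i),
    numeric(2)))
  ev$ci_low <- cis[, 1L]
  ev$ci_high <- cis[, 2L]
  ev[, c("event_id", "kind", "n", "mean_ccf", "ci_low", "ci_high",
         "level")]
}
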