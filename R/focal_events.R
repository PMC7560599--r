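#' @title Kataegis and chromothripsis rule checks
#' @name focal_events
#' @description
#' Rule-based detection of localised hypermutation (kataegis) foci and
#' of chromothripsis-criteria flags: kataegis foci are maximal runs of
#' six or more consecutive substitutions with mean inter-mutation
#' distance at most 1 kb, outside immune-hypermutated loci;
#' chromothripsis is flagged on a chromosome showing at least four
#' adjacent segments oscillating between two total-copy-number states
#' together with at least six interleaved structural variants. Instead
#' of a manual-curation step, the evidence fields (run length,
#' interleaved SV count) are emitted for review.
NULL

#' Call kataegis foci on one sample
#'
#' Scans each chromosome's sorted SNV positions for maximal runs of at
#' least `min_mutations` consecutive mutations whose mean
#' inter-mutation distance is at most `max_mean_imd`; runs are grown
#' greedily while the mean constraint holds, so reported foci are
#' disjoint and not extendable. Runs overlapping excluded regions
#' (immune-hypermutated loci) are dropped.
#'
#' @param snvs SNV rows of one sample (`chrom`, `pos`).
#' @param excluded_regions Regions to exclude (`chrom`, `start`,
#'   `end`) or NULL.
#' @param min_mutations Minimum run length (default 6).
#' @param max_mean_imd Maximum mean inter-mutation distance in bp
#'   (default 1000).
#' @return data.frame `chrom`, `start`, `end`, `n_mutations`,
#'   `mean_imd`.
#' @export
call_kataegis <- function(snvs, excluded_regions = NULL,
                          min_mutations = 6L, max_mean_imd = 1000) {
  out <- list()
  for (ch in unique(snvs$chrom)) {
    pos <- sort(unique(snvs$pos[snvs$chrom == ch]))
    n <- length(pos)
    i <- 1L
    while (i <= n) {
      # grow the run while the mean inter-mutation distance holds
      j <- i
      while (j < n &&
             (pos[j + 1L] - pos[i]) / (j + 1L - i) <= max_mean_imd)
        j <- j + 1L
      if (j - i + 1L >= min_mutations) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = pos[i], end = pos[j],
          n_mutations = j - i + 1L,
          mean_imd = (pos[j] - pos[i]) / (j - i),
          stringsAsFactors = FALSE)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_mutations = integer(),
                      mean_imd = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  if (!is.null(excluded_regions) && nrow(excluded_regions)) {
    drop <- vapply(seq_len(nrow(res)), function(i)
      any(excluded_regions$chrom == res$chrom[i] &
            excluded_regions$start <= res$end[i] &
            excluded_regions$end >= res$start[i]), logical(1))
    res <- res[!drop, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Longest two-state copy-number oscillation run
#'
#' Length of the longest run of adjacent segments alternating between
#' exactly two total-copy-number values (each segment must differ from
#' its neighbour and equal the segment two back). Fewer than two
#' segments return the segment count.
#'
#' @param total_cn Ordered total copy numbers of adjacent,
#'   non-overlapping segments on one chromosome.
#' @return Integer run length.
#' @export
oscillation_run <- function(total_cn) {
  n <- length(total_cn)
  if (n < 2L) return(n)
  best <- 1L
  run <- 1L
  for (i in 2L:n) {
    extends <- total_cn[i] != total_cn[i - 1L] &&
      (run < 2L || total_cn[i] == total_cn[i - 2L])
    run <- if (extends) run + 1L else
      if (total_cn[i] != total_cn[i - 1L]) 2L else 1L
    best <- max(best, run)
  }
  best
}

# SVs (as intrachromosomal breakpoint intervals) that cross at least one
# other SV: overlap without nesting.
interleaved_sv_count <- function(starts, ends) {
  n <- length(starts)
  if (n < 2L) return(0L)
  crossed <- rep(FALSE, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a1 <- min(starts[i], ends[i]); a2 <- max(starts[i], ends[i])
    b1 <- min(starts[j], ends[j]); b2 <- max(starts[j], ends[j])
    cross <- (a1 < b1 && b1 < a2 && a2 < b2) ||
      (b1 < a1 && a1 < b2 && b2 < a2)
    if (cross) crossed[i] <- crossed[j] <- TRUE
  }
  sum(crossed)
}

#' Flag chromothripsis criteria on one chromosome
#'
#' Flags a chromosome when its segments contain an oscillation run of
#' at least `min_run` adjacent segments between two total-copy-number
#' states and at least `min_interleaved` structural variants whose
#' breakpoint intervals overlap at least one other SV without nesting,
#' restricted to the oscillating region extended by `flank_bp`.
#' Evidence fields are returned for manual review.
#'
#' @param segments Ordered segments of one sample on `chrom`.
#' @param svs Intrachromosomal SVs (`chrom1 == chrom2 == chrom`) with
#'   `pos1`, `pos2`.
#' @param chrom Chromosome tested.
#' @param min_run,min_interleaved Criteria thresholds (defaults 4 and
#'   6).
#' @param flank_bp Flank around the oscillating region (default 1 Mb).
#' @return data.frame `chrom`, `oscillating_run_len`,
#'   `n_interleaved_svs`, `flagged`.
#' @export
flag_chromothripsis <- function(segments, svs, chrom, min_run = 4L,
                                min_interleaved = 6L, flank_bp = 1e6) {
  seg <- segments[segments$chrom == chrom, , drop = FALSE]
  seg <- seg[order(seg$start), , drop = FALSE]
  run_len <- oscillation_run(seg$total_cn)
  # locate the longest oscillating window to restrict the SV count
  lo <- -Inf; hi <- Inf
  if (nrow(seg) >= 2L && run_len >= 2L) {
    cn <- seg$total_cn
    best <- c(1L, 1L)
    run <- 1L
    for (i in 2L:nrow(seg)) {
      extends <- cn[i] != cn[i - 1L] &&
        (run < 2L || cn[i] == cn[i - 2L])
      run <- if (extends) run + 1L else if (cn[i] != cn[i - 1L]) 2L else 1L
      if (run > best[2L] - best[1L] + 1L) best <- c(i - run + 1L, i)
    }
    lo <- seg$start[best[1L]] - flank_bp
    hi <- seg$end[best[2L]] + flank_bp
  }
  n_inter <- 0L
  if (!is.null(svs) && nrow(svs)) {
    sv <- svs[svs$chrom1 == chrom & svs$chrom2 == chrom, , drop = FALSE]
    keep <- pmin(sv$pos1, sv$pos2) >= lo & pmax(sv$pos1, sv$pos2) <= hi
    sv <- sv[keep, , drop = FALSE]
    n_inter <- interleaved_sv_count(sv$pos1, sv$pos2)
  }
  data.frame(chrom = chrom, oscillating_run_len = run_len,
             n_interleaved_svs = as.integer(n_inter),
             flagged = run_len >= min_run & n_inter >= min_interleaved,
             stringsAsFactors = FALSE)
}
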