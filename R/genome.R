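#' Bundled synthetic autosome table
#'
#' Returns a table of the 22 autosomes with approximate hg38-scale lengths
#' and centromere midpoints (values rounded to the megabase). This is a
#' synthetic stand-in genome used by the cohort simulator and by arm-level
#' copy-number aggregation; it is not a reference assembly and carries no
#' sequence.
#'
#' @return A data.frame with columns `chrom` (character, "1".."22"),
#'   `length` and `centromere` (integer base pairs, 1-based).
#' @export
synthetic_genome <- function() {
  len_mb <- c(249, 242, 198, 190, 182, 171, 159, 145, 138, 134, 135, 133,
              114, 107, 102, 90, 83, 80, 59, 64, 47, 51)
  cen_mb <- c(123, 93, 91, 50, 48, 60, 60, 45, 43, 40, 53, 36, 18, 17, 19,
              37, 25, 18, 26, 28, 12, 15)
  data.frame(chrom = as.character(1:22),
             length = as.integer(len_mb * 1e6),
             centromere = as.integer(cen_mb * 1e6),
             stringsAsFactors = FALSE)
}

#' Autosomal chromosome-arm table
#'
#' Splits each autosome of a genome table at its centromere, yielding the
#' 44 arm loci (22 autosomes, p and q) used by arm-level event calling and
#' the arm-relocation permutation test.
#'
#' @param genome A genome table as returned by [synthetic_genome()].
#' @return A data.frame with columns `arm` ("1p".."22q"), `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @export
arm_table <- function(genome = synthetic_genome()) {
  p <- data.frame(arm = paste0(genome$chrom, "p"), chrom = genome$chrom,
                  start = 1L, end = genome$centromere,
                  stringsAsFactors = FALSE)
  q <- data.frame(arm = paste0(genome$chrom, "q"), chrom = genome$chrom,
                  start = genome$centromere + 1L, end = genome$length,
                  stringsAsFactors = FALSE)
  out <- rbind(p, q)
  out[order(match(out$chrom, genome$chrom), out$start), , drop = FALSE]
}

#' Deterministic replication-timing track for the synthetic genome
#'
#' Builds a bedGraph-like table of replication timing over fixed windows.
#' Timing is a smooth deterministic function of genomic position (a phase-
#' shifted sinusoid per chromosome, scaled to \[0, 1\], higher = earlier
#' replication), which gives the simulator and the background mutation
#' model a shared, reproducible covariate with genuine spatial structure.
#'
#' @param genome Genome table, see [synthetic_genome()].
#' @param window_bp Window size in base pairs (default 10 Mb).
#' @return data.frame with `chrom`, `start`, `end`, `timing`.
#' @export
synthetic_rt_track <- function(genome = synthetic_genome(),
                               window_bp = 1e7) {
  rows <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq(1L, len, by = window_bp)
    ends <- pmin(starts + window_bp - 1L, len)
    mid <- (starts + ends) / 2
    timing <- (1 + sin(2 * pi * mid / 9.7e7 + i)) / 2
    data.frame(chrom = genome$chrom[i], start = starts, end = ends,
               timing = timing, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Trinucleotide substitution channel labels
#'
#' The 96 single-base-substitution channels in the fixed order used
#' throughout the package: six pyrimidine-strand substitution classes
#' (C>A, C>G, C>T, T>A, T>C, T>G), each with the 16 flanking-base
#' combinations in alphabetical order. Channel index `i` (0-based, as
#' stored in the `context96` mutation column) corresponds to label
#' `context96_labels()[i + 1]`.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
context96_labels <- function() {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(96)
  k <- 1L
  for (cl in classes) {
    for (l in bases) {
      for (r in bases) {
        out[k] <- paste0(l, "[", cl, "]", r)
        k <- k + 1L
      }
    }
  }
  out
}

# Substitution class (0..5) of a 0-based channel index.
context96_class <- function(context96) context96 %/% 16L

# (ref, alt) nucleotides for a 0-based channel index, pyrimidine strand.
context96_ref_alt <- function(context96) {
  cls <- context96_class(context96)
  ref <- ifelse(cls < 3L, "C", "T")
  alt <- c("A", "G", "T", "A", "C", "G")[cls + 1L]
  cbind(ref = ref, alt = alt)
}
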