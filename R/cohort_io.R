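#' @title Cohort tables: readers, writers and consensus filters
#' @name cohort_io
#' @description
#' Tabular input/output for the per-sample tables consumed by every
#' analysis stage (mutations, copy-number segments, regions, cohort
#' metadata), together with the variant- and segment-level consensus and
#' filtering rules that precede analysis: somatic indel filtering,
#' structural-variant consensus across callers, copy-neutral LOH
#' consensus, promoter construction, CRE interaction filtering and the
#' CRBN/IMiD gene-set disruption report.
#'
#' All coordinates are 1-based inclusive. BED-style inputs (0-based
#' half-open) must be converted on read; [read_regions()] does this for
#' BED files.
NULL

mutation_columns <- c("sample_id", "timepoint", "chrom", "pos", "ref",
                      "alt", "class", "context96", "ccf", "support_frac",
                      "pop_af")

segment_columns <- c("sample_id", "timepoint", "chrom", "start", "end",
                     "total_cn", "minor_cn", "clonal_frac")

#' Read or write a somatic mutation table
#'
#' Mutation tables are TSV with one row per somatic SNV/indel call and
#' columns `sample_id`, `timepoint` ("primary"/"relapse"), `chrom`, `pos`
#' (1-based), `ref`, `alt`, `class` ("SNV"/"indel"), `context96` (0-95
#' trinucleotide substitution channel, SNVs only), `ccf`, `support_frac`,
#' `pop_af`. Missing values are empty or `NA`.
#'
#' @param path File path.
#' @param x Mutation data.frame (for the writer).
#' @return `read_mutations` returns a validated data.frame.
#' @export
read_mutations <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  validate_mutations(x)
}

#' @rdname read_mutations
#' @export
write_mutations <- function(x, path) {
  utils::write.table(x[, intersect(mutation_columns, names(x))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a mutation table against its invariants
#'
#' Checks: positions >= 1; SNVs have single-base `ref != alt`; `context96`
#' in 0..95 and only set for SNVs; `ccf` within \[0, 1\] when present.
#'
#' @param x Mutation data.frame.
#' @return `x`, invisibly validated (errors on violation).
#' @export
validate_mutations <- function(x) {
  need <- c("sample_id", "timepoint", "chrom", "pos", "class")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("mutation table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(x$pos < 1)) stop("mutation positions must be >= 1")
  if (!all(x$timepoint %in% c("primary", "relapse")))
    stop("timepoint must be 'primary' or 'relapse'")
  snv <- x$class == "SNV"
  if (any(snv) && ("ref" %in% names(x))) {
    bad <- snv & (nchar(x$ref) != 1L | nchar(x$alt) != 1L | x$ref == x$alt)
    if (any(bad, na.rm = TRUE)) stop("SNVs must have single-base ref != alt")
  }
  if ("context96" %in% names(x)) {
    ctx <- x$context96[snv]
    if (any(!is.na(ctx) & (ctx < 0 | ctx > 95)))
      stop("context96 out of range 0..95")
    if (any(!is.na(x$context96[!snv])))
      stop("context96 is defined only for SNVs")
  }
  if ("ccf" %in% names(x)) {
    cc <- x$ccf
    if (any(!is.na(cc) & (cc < 0 | cc > 1))) stop("ccf outside [0, 1]")
  }
  x
}

#' Read or write an allele-specific copy-number segment table
#'
#' Segments are TSV with columns `sample_id`, `timepoint`, `chrom`,
#' `start`, `end` (1-based inclusive), `total_cn`, `minor_cn`,
#' `clonal_frac`. Segments of one sample/chromosome must not overlap.
#'
#' @param path File path.
#' @param x Segment data.frame (writer).
#' @return `read_segments` returns a validated data.frame.
#' @export
read_segments <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  validate_segments(x)
}

#' @rdname read_segments
#' @export
write_segments <- function(x, path) {
  utils::write.table(x[, intersect(segment_columns, names(x))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_segments
#' @export
validate_segments <- function(x) {
  miss <- setdiff(segment_columns[1:7], names(x))
  if (length(miss)) stop("segment table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(x$start > x$end)) stop("segment start > end")
  if (any(x$total_cn < 0 | x$minor_cn < 0)) stop("negative copy number")
  if (any(x$minor_cn > ceiling(x$total_cn / 2)))
    stop("minor_cn exceeds ceiling(total_cn / 2)")
  key <- interaction(x$sample_id, x$timepoint, x$chrom, drop = TRUE)
  for (grp in split(x, key)) {
    if (nrow(grp) < 2L) next
    o <- order(grp$start)
    if (any(grp$start[o][-1L] <= grp$end[o][-nrow(grp)]))
      stop("overlapping segments within one sample/chromosome")
  }
  x
}

#' Read genomic regions (TSV or BED-like) into 1-based coordinates
#'
#' Accepts a TSV with columns `region_id`, `kind` (promoter, CRE,
#' immune_hypermutated, ORF, UTR), `chrom`, `start`, `end` and optional
#' `linked_gene`. With `bed = TRUE` the `start` column is interpreted as
#' 0-based half-open (BED convention) and shifted to 1-based inclusive.
#'
#' @param path File path.
#' @param bed Logical; input uses BED coordinate convention.
#' @return data.frame of regions, 1-based inclusive.
#' @export
read_regions <- function(path, bed = FALSE) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  if (bed) x$start <- x$start + 1L
  if (any(x$end < x$start)) stop("region end < start")
  x
}

#' Read a cohort metadata table (demographics and treatment)
#'
#' Parses a TSV mirroring the cohort summary table: `sample_id`,
#' `karyotype` (e.g. "4;14", "11;14", "14;16", "4;14/HD"), `sex`, `age`,
#' `elapsed_months` (time to relapse; `NA` when no matched relapse
#' sample exists), `induction`, `maintenance`, `pathway`. On read,
#' `maintenance == "Missing"` becomes `NA` and pathway spelling variants
#' ("Non-intensive", "Nonintensive") are normalised to
#' "intensive"/"nonintensive". A `purity` column is optional; values at
#' or below 0.3 trigger a warning (the cohort rule requires purity in
#' excess of 30%), not an error, so that edge cases remain testable.
#'
#' @param path File path.
#' @return data.frame with normalised columns.
#' @export
read_cohort_metadata <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  x$maintenance[!is.na(x$maintenance) & x$maintenance == "Missing"] <- NA
  x$pathway <- tolower(gsub("-", "", x$pathway))
  if (!all(x$pathway %in% c("intensive", "nonintensive")))
    stop("pathway must normalise to intensive/nonintensive")
  if ("purity" %in% names(x) &&
      any(!is.na(x$purity) & x$purity <= 0.3))
    warning("sample purity at or below 0.3 (cohort rule expects > 30%)")
  x
}

#' Headline counts from a cohort metadata table
#'
#' @param meta Metadata data.frame from [read_cohort_metadata()].
#' @return Named list: `n_patients`, `n_paired` (rows with a non-missing
#'   `elapsed_months`, i.e. a matched relapse), and per-karyotype counts
#'   `n_t4_14` (prefix match, so "4;14/HD" counts), `n_t11_14`,
#'   `n_t14_16`.
#' @export
cohort_metadata_summary <- function(meta) {
  list(n_patients = nrow(meta),
       n_paired = sum(!is.na(meta$elapsed_months)),
       n_t4_14 = sum(startsWith(meta$karyotype, "4;14")),
       n_t11_14 = sum(startsWith(meta$karyotype, "11;14")),
       n_t14_16 = sum(startsWith(meta$karyotype, "14;16")))
}

#' Filter somatic indels by read support and germline proximity
#'
#' Keeps indels supported by at least 20% of overlapping tumour reads and
#' farther than 10 bp from any germline indel ("within ten base pairs" is
#' read conservatively: distance <= 10 excludes the call). Records with a
#' missing `support_frac` are rejected with a reported reason rather than
#' silently dropped. Input order is preserved; the filter is idempotent.
#'
#' @param indels Mutation data.frame rows of class "indel" with a
#'   `support_frac` column.
#' @param germline_indels data.frame with `chrom` and `pos` of germline
#'   indels (1-based).
#' @param min_support Minimum tumour read support fraction (default 0.20).
#' @param max_germline_dist Distance at or below which a germline indel
#'   excludes the call (default 10 bp).
#' @return Filtered data.frame; rejected records (with reasons) are
#'   attached as `attr(, "rejected")`.
#' @export
filter_somatic_indels <- function(indels, germline_indels,
                                  min_support = 0.20,
                                  max_germline_dist = 10) {
  if (nrow(indels) == 0L) return(indels)
  no_support <- is.na(indels$support_frac)
  if (any(no_support))
    warning(sum(no_support),
            " indel record(s) rejected: missing support_frac")
  gdist <- rep(Inf, nrow(indels))
  if (!is.null(germline_indels) && nrow(germline_indels) > 0L) {
    for (i in seq_len(nrow(indels))) {
      same <- germline_indels$chrom == indels$chrom[i]
      if (any(same))
        gdist[i] <- min(abs(germline_indels$pos[same] - indels$pos[i]))
    }
  }
  keep <- !no_support & indels$support_frac >= min_support &
    gdist > max_germline_dist
  out <- indels[keep, , drop = FALSE]
  rejected <- indels[!keep, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reject_reason <- ifelse(
      no_support[!keep], "missing support_frac",
      ifelse(!is.na(indels$support_frac[!keep]) &
               indels$support_frac[!keep] < min_support,
             "support_frac below threshold", "near germline indel"))
  }
  attr(out, "rejected") <- rejected
  out
}

#' Consensus structural variants across callers
#'
#' Emits an SV iff at least two callers report both breakpoints within
#' `tol_bp` with matching chromosomes and orientation; emitted
#' coordinates are the medians over the supporting callers. The result is
#' independent of caller ordering.
#'
#' @param calls Named list (>= 2 elements) of per-caller data.frames with
#'   columns `chrom1`, `pos1`, `chrom2`, `pos2`, `orientation`.
#' @param tol_bp Breakpoint matching tolerance in bp (default 200; the
#'   merge window is a package choice, callers do not agree on one).
#' @return data.frame of consensus SVs (`chrom1`, `pos1`, `chrom2`,
#'   `pos2`, `orientation`, `n_callers`), sorted by coordinates.
#' @export
consensus_sv <- function(calls, tol_bp = 200) {
  if (length(calls) < 2L)
    stop("consensus requires call sets from at least two callers")
  all_sv <- do.call(rbind, lapply(seq_along(calls), function(i) {
    x <- calls[[i]]
    if (nrow(x)) x$caller <- i
    x
  }))
  if (is.null(all_sv) || nrow(all_sv) == 0L)
    return(data.frame(chrom1 = character(), pos1 = numeric(),
                      chrom2 = character(), pos2 = numeric(),
                      orientation = character(), n_callers = integer(),
                      stringsAsFactors = FALSE))
  n <- nrow(all_sv)
  # union-find over pairwise breakpoint matches
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (all_sv$chrom1[i] == all_sv$chrom1[j] &&
        all_sv$chrom2[i] == all_sv$chrom2[j] &&
        all_sv$orientation[i] == all_sv$orientation[j] &&
        abs(all_sv$pos1[i] - all_sv$pos1[j]) <= tol_bp &&
        abs(all_sv$pos2[i] - all_sv$pos2[j]) <= tol_bp) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  rows <- lapply(groups, function(idx) {
    g <- all_sv[idx, , drop = FALSE]
    if (length(unique(g$caller)) < 2L) return(NULL)
    data.frame(chrom1 = g$chrom1[1L], pos1 = stats::median(g$pos1),
               chrom2 = g$chrom2[1L], pos2 = stats::median(g$pos2),
               orientation = g$orientation[1L],
               n_callers = length(unique(g$caller)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(chrom1 = character(), pos1 = numeric(),
                      chrom2 = character(), pos2 = numeric(),
                      orientation = character(), n_callers = integer(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$chrom1, out$pos1, out$chrom2, out$pos2), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus check for a copy-neutral LOH segment
#'
#' A candidate nLOH segment (total copy number 2, minor allele 0) is
#' retained iff at least one of two additional callers reports an nLOH
#' segment on the same chromosome overlapping the candidate extended by
#' `window_mb` megabases on each side (candidate caller + one support =
#' two of three callers). When both supporting callers are discordant the
#' segment is excluded from downstream analysis.
#'
#' @param candidate One-row segment data.frame with `chrom`, `start`,
#'   `end`, `total_cn` (must be 2), `minor_cn` (must be 0).
#' @param supports List of two segment data.frames from the other
#'   callers.
#' @param window_mb Overlap window in megabases (default 10).
#' @return Logical scalar.
#' @export
consensus_nloh <- function(candidate, supports, window_mb = 10) {
  if (nrow(candidate) != 1L)
    stop("candidate must be a single segment")
  if (candidate$total_cn != 2L || candidate$minor_cn != 0L)
    stop("candidate is not an nLOH segment (need total_cn 2, minor_cn 0)")
  if (length(supports) != 2L)
    stop("exactly two supporting caller segment lists are required")
  w <- window_mb * 1e6
  lo <- candidate$start - w
  hi <- candidate$end + w
  for (s in supports) {
    if (is.null(s) || nrow(s) == 0L) next
    hit <- s$chrom == candidate$chrom & s$total_cn == 2L &
      s$minor_cn == 0L & s$start <= hi & s$end >= lo
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Build a promoter region around a transcription start site
#'
#' Promoters span 400 bp upstream and 250 bp downstream of the TSS,
#' oriented by strand; 1-based inclusive, length 651 bp. A TSS within
#' 400 bp of the chromosome start is truncated at position 1 with a
#' warning.
#'
#' @param tss TSS position (1-based).
#' @param strand "+" or "-".
#' @param chrom Chromosome label (carried through).
#' @param gene Linked gene symbol (carried through, optional).
#' @return One-row region data.frame of kind "promoter".
#' @export
build_promoter_region <- function(tss, strand, chrom = NA_character_,
                                  gene = NA_character_) {
  stopifnot(length(tss) == 1L, strand %in% c("+", "-"))
  if (strand == "+") {
    start <- tss - 400L; end <- tss + 250L
  } else {
    start <- tss - 250L; end <- tss + 400L
  }
  if (start < 1L) {
    warning("promoter truncated at chromosome start (tss <= 400)")
    start <- 1L
  }
  data.frame(region_id = paste0("promoter:", gene, ":", chrom, ":", tss),
             kind = "promoter", chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             linked_gene = gene, stringsAsFactors = FALSE)
}

#' Filter promoter-CRE interactions by distance and interaction score
#'
#' Keeps interactions with CHiCAGO-style score >= 5 and linear distance
#' <= 1 Mb (both boundaries inclusive). Records with a negative distance
#' are rejected with a warning.
#'
#' @param interactions data.frame with `score` and `linear_distance`.
#' @param min_score,max_distance Thresholds (defaults 5 and 1e6).
#' @return Filtered data.frame (order preserved).
#' @export
filter_cre_interactions <- function(interactions, min_score = 5,
                                    max_distance = 1e6) {
  bad <- interactions$linear_distance < 0
  if (any(bad))
    warning(sum(bad), " interaction(s) rejected: negative linear distance")
  keep <- !bad & interactions$score >= min_score &
    interactions$linear_distance <= max_distance
  interactions[keep, , drop = FALSE]
}

#' Per-sample disruption report for a curated gene set
#'
#' Flags, per sample, each gene of a curated set (e.g. the CRBN/IMiD
#' response genes) disrupted by a mutation inside the gene body, a
#' copy-number loss (segment with total copy number < 2 overlapping the
#' gene), or a structural-variant breakpoint falling within the gene.
#' The mutation table is assumed already restricted to consequential
#' (e.g. nonsynonymous) calls.
#'
#' @param mutations Mutation data.frame (`sample_id`, `chrom`, `pos`).
#' @param segments Segment data.frame.
#' @param svs SV data.frame (`sample_id`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2`) or NULL.
#' @param gene_set data.frame with `gene`, `chrom`, `start`, `end`.
#' @return data.frame `sample_id`, `gene`, `disruption` in
#'   ("mutation", "copy_loss", "sv"); zero rows when nothing is
#'   disrupted.
#' @export
gene_set_disruption_report <- function(mutations, segments, svs,
                                       gene_set) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(gene_set)))
  out <- list()
  for (i in seq_len(nrow(gene_set))) {
    g <- gene_set[i, ]
    if (!is.null(mutations) && nrow(mutations)) {
      hit <- mutations$chrom == g$chrom & mutations$pos >= g$start &
        mutations$pos <= g$end
      for (s in unique(mutations$sample_id[hit]))
        out[[length(out) + 1L]] <- data.frame(
          sample_id = s, gene = g$gene, disruption = "mutation",
          stringsAsFactors = FALSE)
    }
    if (!is.null(segments) && nrow(segments)) {
      hit <- segments$chrom == g$chrom & segments$total_cn < 2 &
        segments$start <= g$end & segments$end >= g$start
      for (s in unique(segments$sample_id[hit]))
        out[[length(out) + 1L]] <- data.frame(
          sample_id = s, gene = g$gene, disruption = "copy_loss",
          stringsAsFactors = FALSE)
    }
    if (!is.null(svs) && nrow(svs)) {
      hit <- (svs$chrom1 == g$chrom & svs$pos1 >= g$start &
                svs$pos1 <= g$end) |
        (svs$chrom2 == g$chrom & svs$pos2 >= g$start & svs$pos2 <= g$end)
      for (s in unique(svs$sample_id[hit]))
        out[[length(out) + 1L]] <- data.frame(
          sample_id = s, gene = g$gene, disruption = "sv",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), gene = character(),
                      disruption = character(), stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}
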