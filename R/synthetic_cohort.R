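#' @title Synthetic cohort generator
#' @name synthetic_cohort
#' @description
#' Generates complete synthetic cohorts — mutation tables with
#' trinucleotide-context and replication-timing structure, planted
#' recurrently mutated regions with positional hotspots, clonal
#' structures realising three primary/relapse evolution patterns,
#' arm-level copy-number states with relapse-enriched changes, and
#' mutational-signature exposures with a planted negative correlation
#' between relapse APOBEC activity and time to relapse — together with a
#' machine-readable ground truth, so every downstream pipeline stage is
#' testable without controlled-access sequencing data.
NULL

# deterministic per-stage seeds derived from one global seed
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65536 * 32749 + k * 7919) %% 2147483647)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Synthetic single-base-substitution signature catalog
#'
#' A deterministic 96 x 6 catalog of SBS-like spectra constructed in
#' code (it is synthetic, not the COSMIC catalog): SBS2 (APOBEC C>T at
#' TpC), SBS13 (APOBEC C>G at TpC), SBS9 (broad T-mutation profile),
#' SBS5 (flat), SBS8 (flat, C>A enriched) and SBS40 (flat, T-class
#' tilted). The three flat spectra are deliberately given distinct tilts
#' so that exposure refitting is identifiable. Columns sum to 1.
#'
#' @return 96 x 6 matrix, rownames [context96_labels()], colnames the
#'   signature ids.
#' @export
synthetic_sbs_catalog <- function() {
  labs <- context96_labels()
  sig <- matrix(0, 96, 6, dimnames = list(labs, c("SBS2", "SBS5", "SBS8",
                                                  "SBS9", "SBS13", "SBS40")))
  tpc <- function(class0) class0 * 16L + 3L * 4L + 1:4  # T[.]A,C,G,T (1-based)
  # SBS2: C>T at TpC
  s <- rep(0.0007, 96); s[tpc(2L)] <- c(0.32, 0.22, 0.12, 0.28)
  sig[, "SBS2"] <- s / sum(s)
  # SBS13: C>G at TpC
  s <- rep(0.0007, 96); s[tpc(1L)] <- c(0.30, 0.20, 0.14, 0.30)
  sig[, "SBS13"] <- s / sum(s)
  # SBS9: broad profile over T>A / T>C with flank preference
  s <- rep(0.002, 96)
  s[49:64] <- 0.020 + 0.010 * sin(seq_len(16))      # T>A block
  s[65:80] <- 0.028 + 0.012 * cos(seq_len(16))      # T>C block
  sig[, "SBS9"] <- s / sum(s)
  # SBS5: flat with a gentle wiggle, leaning C>T
  s <- 1 + 0.3 * sin(seq_len(96) / 5); s[33:48] <- s[33:48] * 1.8
  sig[, "SBS5"] <- s / sum(s)
  # SBS8: flat, strongly C>A enriched
  s <- rep(0.45, 96); s[1:16] <- 5.0; s[17:32] <- 0.9
  sig[, "SBS8"] <- s / sum(s)
  # SBS40: flat, tilted toward T>A / T>G channels
  s <- rep(0.30, 96); s[81:96] <- 2.0; s[49:64] <- 1.4; s[65:80] <- 0.9
  sig[, "SBS40"] <- s / sum(s)
  sig
}

#' Simulation configuration
#'
#' Builds and validates the configuration for [generate_cohort()]. The
#' defaults are the study conditions emulated by the package: 80
#' patients, 24 with a matched relapse; karyotypes in 38:38:4
#' proportions (t(4;14), t(11;14), t(14;16)); negative-binomial
#' per-tumour SNV burdens; 1-4 clones per tumour; paired tumours
#' realising evolution patterns 1/2/3 in 3:4:17 proportions; planted
#' driver regions at a 5-fold rate with positional hotspots; arm-level
#' copy-number states with a relapse-enriched 17p deletion and
#' progression at 11q/14q; and signature exposures with a Gaussian-
#' copula-planted Spearman correlation of -0.43 between relapse-specific
#' APOBEC contribution and time to relapse (the planting default mirrors
#' the association strength the model is meant to recover; it is not a
#' truth claim about new data).
#'
#' @param n_patients,n_paired Cohort sizes (defaults 80 and 24).
#' @param karyotype_probs Named proportions for karyotype assignment.
#' @param clones_range Range of clone numbers for unpaired tumours.
#' @param burden_mean,burden_disp Negative-binomial SNV burden per
#'   primary tumour (mean and size/overdispersion).
#' @param relapse_new_frac Expected relapse-specific mutations as a
#'   fraction of the primary burden (drives the higher relapse burden).
#' @param eligible_genome_bp Eligible genome size used for context
#'   denominators.
#' @param context_background 96-simplex of genome context composition
#'   (default: derived deterministically from the catalog mean).
#' @param rt_effect Monotone multiplier over the 5 replication-timing
#'   bins (normalised internally to weighted mean 1).
#' @param n_regions Number of candidate noncoding regions in the
#'   catalog.
#' @param n_drivers,driver_multiplier,hotspot_fraction Planted driver
#'   regions: how many, their rate multiplier, and the fraction of their
#'   mutations placed on a single hotspot position.
#' @param pattern_mix Proportions of Patterns 1/2/3 among paired
#'   tumours.
#' @param ccf_sigma CCF measurement noise (truncated Gaussian, clipped
#'   to \[0, 1\]).
#' @param chron_sigma CCF spread of planted chronology events.
#' @param exposure_alpha Dirichlet concentration for per-sample
#'   signature exposures.
#' @param apobec_time_rho Target Spearman correlation planted between
#'   relapse-specific APOBEC share and elapsed months.
#' @param indel_frac Fraction of calls emitted as indels.
#' @param n_kataegis Kataegis foci planted across the cohort.
#' @param seed Global integer seed.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 80L, n_paired = 24L,
                       karyotype_probs = c("4;14" = 38, "11;14" = 38,
                                           "14;16" = 4) / 80,
                       clones_range = c(1L, 4L),
                       burden_mean = 5000, burden_disp = 10,
                       relapse_new_frac = 0.50,
                       eligible_genome_bp = 1e8,
                       context_background = NULL,
                       rt_effect = c(0.6, 0.8, 1.0, 1.2, 1.4),
                       n_regions = 500L, n_drivers = 10L,
                       driver_multiplier = 5, hotspot_fraction = 0.5,
                       pattern_mix = c(3, 4, 17) / 24,
                       ccf_sigma = 0.05, chron_sigma = 0.10,
                       exposure_alpha = c(SBS2 = 6, SBS5 = 10, SBS8 = 5,
                                          SBS9 = 5, SBS13 = 6, SBS40 = 5),
                       apobec_time_rho = -0.43,
                       indel_frac = 0.02, n_kataegis = 2L,
                       seed = 1L) {
  if (n_paired > n_patients) stop("n_paired exceeds n_patients")
  if (abs(sum(karyotype_probs) - 1) > 1e-9)
    stop("karyotype_probs must sum to 1")
  if (abs(sum(pattern_mix) - 1) > 1e-9) stop("pattern_mix must sum to 1")
  if (hotspot_fraction < 0 || hotspot_fraction > 1)
    stop("hotspot_fraction must lie in [0, 1]")
  if (driver_multiplier < 1) stop("driver_multiplier must be >= 1")
  if (any(diff(rt_effect) < 0)) stop("rt_effect must be monotone")
  if (is.null(context_background)) {
    w <- rowMeans(synthetic_sbs_catalog())
    context_background <- (0.5 * w + 0.5 / 96)
    context_background <- context_background / sum(context_background)
  }
  if (abs(sum(context_background) - 1) > 1e-9)
    stop("context_background must be a simplex")
  structure(list(n_patients = as.integer(n_patients),
                 n_paired = as.integer(n_paired),
                 karyotype_probs = karyotype_probs,
                 clones_range = as.integer(clones_range),
                 burden_mean = burden_mean, burden_disp = burden_disp,
                 relapse_new_frac = relapse_new_frac,
                 eligible_genome_bp = eligible_genome_bp,
                 context_background = context_background,
                 rt_effect = rt_effect, n_regions = as.integer(n_regions),
                 n_drivers = as.integer(n_drivers),
                 driver_multiplier = driver_multiplier,
                 hotspot_fraction = hotspot_fraction,
                 pattern_mix = pattern_mix, ccf_sigma = ccf_sigma,
                 chron_sigma = chron_sigma,
                 exposure_alpha = exposure_alpha,
                 apobec_time_rho = apobec_time_rho,
                 indel_frac = indel_frac,
                 n_kataegis = as.integer(n_kataegis),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Clone CCFs realising one evolution pattern
#'
#' Returns the clone template (primary CCF, relapse CCF, lineage weight)
#' for the requested clonal-evolution pattern, before measurement noise:
#' Pattern 1 — the dominant primary clone survives unchanged and a new
#' clone appears at relapse; Pattern 2 — a primary subclone expands to
#' become the dominant relapse clone (with branching: another subclone
#' is lost); Pattern 3 — primary subclones disappear and new clones
#' emerge at relapse. Every template retains the founding clone at
#' (1, 1): treatment never eradicates it. The templates satisfy the
#' [classify_pattern()] rules exactly.
#'
#' @param pattern 1, 2 or 3.
#' @return data.frame with `clone`, `ccf_primary`, `ccf_relapse`,
#'   `weight` (weights sum to 1).
#' @export
plant_pattern_clones <- function(pattern) {
  stopifnot(pattern %in% 1:3)
  out <- switch(as.character(pattern),
    "1" = data.frame(ccf_primary = c(1, 0), ccf_relapse = c(1, 0.45),
                     weight = c(0.70, 0.30)),
    "2" = data.frame(ccf_primary = c(1, 0.35, 0.30),
                     ccf_relapse = c(1, 0.95, 0),
                     weight = c(0.45, 0.30, 0.25)),
    "3" = data.frame(ccf_primary = c(1, 0.40, 0),
                     ccf_relapse = c(1, 0, 0.50),
                     weight = c(0.50, 0.25, 0.25)))
  out$clone <- seq_len(nrow(out))
  out[, c("clone", "ccf_primary", "ccf_relapse", "weight")]
}

#' Draw trinucleotide-context counts from signature exposures
#'
#' Multinomial draw of `n` mutation contexts from the spectrum
#' `catalog %*% exposures`.
#'
#' @param exposures Exposure simplex over the catalog columns.
#' @param n Number of mutations.
#' @param catalog 96 x K signature catalog (columns are simplexes).
#' @param seed Optional integer seed.
#' @return Integer 96-vector of channel counts summing to `n`.
#' @export
sample_contexts <- function(exposures, n,
                            catalog = synthetic_sbs_catalog(),
                            seed = NULL) {
  stopifnot(length(exposures) == ncol(catalog))
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(integer(96))
  p <- as.numeric(catalog %*% (exposures / sum(exposures)))
  as.integer(stats::rmultinom(1, n, p))
}

#' Simulate one primary/relapse pair's CCF point cloud
#'
#' Draws per-SNV (primary CCF, relapse CCF) points around the clone
#' template of a pattern, with truncated-Gaussian noise clipped to
#' \[0, 1\]. Used to exercise the 2-D clustering and pattern
#' classification path in isolation.
#'
#' @param pattern 1, 2 or 3.
#' @param n_per_clone Points per clone (default 300).
#' @param sigma CCF noise standard deviation (0 = noise free).
#' @param seed Integer seed.
#' @return data.frame `ccf_primary`, `ccf_relapse`, `clone` (truth).
#' @export
simulate_pair_points <- function(pattern, n_per_clone = 300L,
                                 sigma = 0.05, seed = 1L) {
  set.seed(seed)
  tmpl <- plant_pattern_clones(pattern)
  n <- nrow(tmpl) * n_per_clone
  clone <- rep(tmpl$clone, each = n_per_clone)
  x <- clip01(rep(tmpl$ccf_primary, each = n_per_clone) +
                stats::rnorm(n, 0, sigma))
  y <- clip01(rep(tmpl$ccf_relapse, each = n_per_clone) +
                stats::rnorm(n, 0, sigma))
  data.frame(ccf_primary = x, ccf_relapse = y, clone = clone)
}

# default arm-level event rates: primary prevalence, relapse dynamics
default_arm_rates <- function() {
  data.frame(
    arm = c("13q", "21q", "1q", "1p", "22q", "17p", "11q", "14q",
            "6q", "8p"),
    state = c("loss", "gain", "gain", "loss", "loss", "loss", "nLOH",
              "nLOH", "loss", "loss"),
    p_primary = c(0.73, 0.15, 0.45, 0.35, 0.35, 0.10, 0.15, 0.15,
                  0.12, 0.12),
    relapse_delta = c(0, 0, 0, 0, 0, 0.35, 0, 0, 0, 0),
    progression_rate = c(0, 0, 0, 0, 0, 0, 0.5, 0.5, 0, 0),
    mean_cf = c(0.95, 0.98, 0.55, 0.50, 0.70, 0.70, 0.80, 0.80,
                0.60, 0.65),
    stringsAsFactors = FALSE)
}

# default planted chronology: driver genes with true mean CCF tiers
default_chronology_genes <- function() {
  data.frame(
    gene = c("CCND1", "MAX", "PRKD2", "DIS3", "NRAS", "KRAS", "IRF4",
             "FGFR3", "TP53", "TET2", "ATM", "XBP1"),
    chrom = c("11", "14", "19", "13", "1", "12", "6", "4", "17", "4",
              "11", "22"),
    # loci placed outside the candidate-region band (chrom 2-12, < 80 Mb)
    # and outside the synthetic immune-hypermutated loci
    pos = c(118.0e6, 65.0e6, 46.7e6, 72.7e6, 114.7e6, 110.0e6, 0.4e6,
            1.8e6, 7.6e6, 105.2e6, 108.2e6, 28.7e6),
    mean_ccf = c(0.98, 0.95, 0.92, 0.88, 0.85, 0.70, 0.62, 0.55, 0.50,
                 0.42, 0.35, 0.30),
    n_carriers = c(24L, 12L, 10L, 20L, 18L, 22L, 12L, 14L, 12L, 10L,
                   9L, 8L),
    stringsAsFactors = FALSE)
}

# fast membership test against non-overlapping sorted regions (per chrom)
make_region_index <- function(regions) {
  split(regions[order(regions$start), c("start", "end")], regions$chrom)
}

in_regions <- function(index, chrom, pos) {
  hit <- rep(FALSE, length(pos))
  for (ch in names(index)) {
    idx <- which(chrom == ch)
    if (!length(idx)) next
    tr <- index[[ch]]
    i <- findInterval(pos[idx], tr$start)
    hit[idx] <- i >= 1L & pos[idx] <= tr$end[pmax(i, 1L)]
  }
  hit
}

#' Generate a synthetic cohort with ground truth
#'
#' Produces a `cohort_bundle` (metadata, mutation table, segment table,
#' region catalog with context composition, replication-timing track,
#' signature catalog, genome table, genome context counts) and a
#' `ground_truth` object recording every planted effect. Deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with elements `bundle` and `truth`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  genome <- synthetic_genome()
  rt_track <- synthetic_rt_track(genome)
  rt_bins <- bin_rt_track(rt_track, 5L)
  catalog <- synthetic_sbs_catalog()
  genome_context_counts <- config$context_background *
    config$eligible_genome_bp

  ## ---- stage 1: metadata, patterns, copula ------------------------------
  set.seed(stage_seed(config$seed, 1L))
  n <- config$n_patients
  ids <- sprintf("S%03d", seq_len(n))
  kcount <- floor(config$karyotype_probs * n)
  while (sum(kcount) < n) {
    i <- which.max(config$karyotype_probs * n - kcount)
    kcount[i] <- kcount[i] + 1L
  }
  karyotype <- sample(rep(names(kcount), kcount))
  paired <- sort(sample(n, config$n_paired))
  hd <- sample(setdiff(seq_len(n), paired), 1L)
  karyotype[hd] <- paste0(karyotype[hd], "/HD")
  # Gaussian copula linking elapsed time and relapse APOBEC share
  rho_s <- config$apobec_time_rho
  r <- 2 * sin(pi * rho_s / 6)
  z1 <- stats::rnorm(config$n_paired)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(config$n_paired)
  elapsed <- rep(NA_real_, n)
  elapsed[paired] <- round(stats::qlnorm(stats::pnorm(z1), log(17), 0.45), 2)
  apobec_share <- stats::qbeta(stats::pnorm(z2), 2.5, 3.5)
  pat_count <- floor(config$pattern_mix * config$n_paired)
  while (sum(pat_count) < config$n_paired) {
    i <- which.max(config$pattern_mix * config$n_paired - pat_count)
    pat_count[i] <- pat_count[i] + 1L
  }
  pattern <- rep(NA_integer_, n)
  pattern[paired] <- sample(rep(1:3, pat_count))
  metadata <- data.frame(
    sample_id = ids, karyotype = karyotype,
    sex = sample(c("Male", "Female"), n, replace = TRUE, prob = c(.6, .4)),
    age = sample(36:82, n, replace = TRUE),
    elapsed_months = elapsed,
    induction = sample(c("CTD", "CTDa", "RCD", "RCDa", "CCRD"), n, TRUE,
                       prob = c(.3, .22, .2, .2, .08)),
    maintenance = sample(c(NA, "No", "Lenalidomide"), n, TRUE,
                         prob = c(.5, .3, .2)),
    pathway = sample(c("intensive", "nonintensive"), n, TRUE,
                     prob = c(.55, .45)),
    purity = round(stats::runif(n, 0.5, 0.95), 3),
    hyperdiploid = seq_len(n) == hd,
    stringsAsFactors = FALSE)

  ## ---- stage 2: signature exposures -------------------------------------
  set.seed(stage_seed(config$seed, 2L))
  K <- length(config$exposure_alpha)
  expo_primary <- t(vapply(seq_len(n),
                           function(i) rdirichlet1(config$exposure_alpha),
                           numeric(K)))
  dimnames(expo_primary) <- list(ids, names(config$exposure_alpha))
  apo <- c("SBS2", "SBS9", "SBS13")
  expo_new <- expo_primary[paired, , drop = FALSE]
  for (j in seq_along(paired)) {
    e <- expo_new[j, ]
    w_in <- e[apo] / sum(e[apo])
    w_out <- e[setdiff(colnames(expo_new), apo)]
    w_out <- w_out / sum(w_out)
    e[apo] <- apobec_share[j] * w_in
    e[setdiff(colnames(expo_new), apo)] <- (1 - apobec_share[j]) * w_out
    expo_new[j, ] <- e
  }

  ## ---- stage 3: region catalog ------------------------------------------
  set.seed(stage_seed(config$seed, 3L))
  nr <- config$n_regions
  kind <- rep("promoter", nr)
  kind[seq_len(nr) %% 10 == 0] <- "CRE"
  rlen <- ifelse(kind == "promoter", 651L, 1000L)
  reg_chrom <- as.character(rep(2:12, length.out = nr))
  slot <- stats::ave(seq_len(nr), reg_chrom, FUN = seq_along)
  reg_start <- 2e6 + (slot - 1L) * 4e5
  regions <- data.frame(
    region_id = sprintf("R%04d", seq_len(nr)), kind = kind,
    chrom = reg_chrom, start = as.integer(reg_start),
    end = as.integer(reg_start + rlen - 1L),
    linked_gene = sprintf("GENE%04d", seq_len(nr)),
    stringsAsFactors = FALSE)
  mid <- (regions$start + regions$end) / 2
  regions$rt_bin <- lookup_rt_bin(rt_bins, regions$chrom, mid)
  regions$hotspot_pos <- regions$start +
    as.integer(floor(stats::runif(nr) * rlen))
  context_counts <- t(vapply(rlen, function(L)
    as.numeric(stats::rmultinom(1, L, config$context_background)),
    numeric(96)))
  driver_idx <- if (config$n_drivers > 0)
    sort(sample(nr, config$n_drivers)) else integer(0)
  regions$multiplier <- 1
  regions$multiplier[driver_idx] <- config$driver_multiplier
  # immune hypermutated loci (synthetic IG-like loci)
  immune <- data.frame(
    region_id = c("IGH_like", "IGK_like", "IGL_like"),
    kind = "immune_hypermutated",
    chrom = c("14", "2", "22"),
    start = as.integer(c(105e6, 89e6, 22e6)),
    end = as.integer(c(106e6, 90e6, 23e6)),
    linked_gene = NA_character_, rt_bin = NA_integer_,
    hotspot_pos = NA_integer_, multiplier = NA_real_,
    stringsAsFactors = FALSE)
  all_regions <- rbind(regions, immune)
  attr(all_regions, "context_counts") <- context_counts
  reg_index <- make_region_index(regions)

  ## ---- stage 4: mutations ------------------------------------------------
  set.seed(stage_seed(config$seed, 4L))
  rt_len <- as.numeric(rt_bins$end - rt_bins$start + 1)
  bin_len <- vapply(1:5, function(b) sum(rt_len[rt_bins$bin == b]),
                    numeric(1))
  rt_f <- config$rt_effect / sum(config$rt_effect * bin_len / sum(bin_len))
  win_w <- rt_len * rt_f[rt_bins$bin]
  draw_positions <- function(m) {
    row <- sample.int(nrow(rt_bins), m, replace = TRUE, prob = win_w)
    pos <- rt_bins$start[row] +
      floor(stats::runif(m) * rt_len[row])
    chrom <- rt_bins$chrom[row]
    bad <- in_regions(reg_index, chrom, pos)
    tries <- 0L
    while (any(bad) && tries < 10L) {
      m2 <- sum(bad)
      row2 <- sample.int(nrow(rt_bins), m2, replace = TRUE, prob = win_w)
      pos[bad] <- rt_bins$start[row2] + floor(stats::runif(m2) * rt_len[row2])
      chrom[bad] <- rt_bins$chrom[row2]
      bad <- in_regions(reg_index, chrom, pos)
      tries <- tries + 1L
    }
    list(chrom = chrom, pos = pos)
  }
  mut_rows <- function(sample_id, timepoint, ctx, ccf, gene = NA) {
    m <- length(ctx)
    loc <- draw_positions(m)
    ra <- context96_ref_alt(ctx)
    data.frame(sample_id = sample_id, timepoint = timepoint,
               chrom = loc$chrom, pos = loc$pos, ref = ra[, 1L],
               alt = ra[, 2L], class = "SNV", context96 = ctx,
               ccf = ccf, support_frac = NA_real_, pop_af = 0,
               gene = gene, stringsAsFactors = FALSE)
  }
  expand_contexts <- function(cnt) {
    ctx <- rep.int(0:95, cnt)
    if (length(ctx) <= 1L) return(ctx)
    sample(ctx)
  }
  burden <- pmax(500L, stats::rnbinom(n, mu = config$burden_mean,
                                      size = config$burden_disp))
  all_muts <- vector("list", n)
  pair_j <- match(seq_len(n), paired)
  for (i in seq_len(n)) {
    spec_i <- as.numeric(catalog %*% expo_primary[i, ])
    Ni <- burden[i]
    if (is.na(pair_j[i])) {
      k <- sample(seq(config$clones_range[1], config$clones_range[2]), 1L)
      ccfs <- c(1, stats::runif(k - 1L, 0.2, 0.7))
      w <- rdirichlet1(rep(2, k))
      clone <- sample.int(k, Ni, replace = TRUE, prob = w)
      ctx <- expand_contexts(stats::rmultinom(1, Ni, spec_i)[, 1L])
      ccf <- clip01(ccfs[clone] + stats::rnorm(Ni, 0, config$ccf_sigma))
      all_muts[[i]] <- mut_rows(ids[i], "primary", ctx, ccf)
    } else {
      j <- pair_j[i]
      tmpl <- plant_pattern_clones(pattern[i])
      clone <- sample.int(nrow(tmpl), Ni, replace = TRUE,
                          prob = tmpl$weight * (tmpl$ccf_primary > 0))
      ctx <- expand_contexts(stats::rmultinom(1, Ni, spec_i)[, 1L])
      loc <- draw_positions(Ni)
      ra <- context96_ref_alt(ctx)
      ccf_p <- clip01(tmpl$ccf_primary[clone] +
                        stats::rnorm(Ni, 0, config$ccf_sigma))
      prim <- data.frame(sample_id = ids[i], timepoint = "primary",
                         chrom = loc$chrom, pos = loc$pos,
                         ref = ra[, 1L], alt = ra[, 2L], class = "SNV",
                         context96 = ctx, ccf = ccf_p,
                         support_frac = NA_real_, pop_af = 0,
                         gene = NA_character_, stringsAsFactors = FALSE)
      shared <- tmpl$ccf_relapse[clone] > 0
      rel_shared <- prim[shared, , drop = FALSE]
      rel_shared$timepoint <- "relapse"
      rel_shared$ccf <- clip01(tmpl$ccf_relapse[clone[shared]] +
                                 stats::rnorm(sum(shared), 0,
                                              config$ccf_sigma))
      # relapse-specific mutations: relapse-present clones, relapse spectrum
      n_new <- stats::rpois(1, config$relapse_new_frac * Ni)
      w_new <- tmpl$weight * (tmpl$ccf_relapse > 0)
      clone_new <- sample.int(nrow(tmpl), n_new, replace = TRUE,
                              prob = w_new)
      spec_new <- as.numeric(catalog %*% expo_new[j, ])
      ctx_new <- expand_contexts(stats::rmultinom(1, n_new, spec_new)[, 1L])
      rel_new <- mut_rows(ids[i], "relapse", ctx_new,
                          clip01(tmpl$ccf_relapse[clone_new] +
                                   stats::rnorm(n_new, 0,
                                                config$ccf_sigma)))
      all_muts[[i]] <- rbind(prim, rel_shared, rel_new)
    }
  }
  mutations <- do.call(rbind, all_muts)

  ## planted region mutations (driver channel; null regions get rate x1)
  set.seed(stage_seed(config$seed, 5L))
  spec_mat <- expo_primary %*% t(catalog)              # samples x 96
  rate_true <- sweep(spec_mat * burden, 2L, genome_context_counts, "/")
  lam <- (rate_true %*% t(context_counts)) *
    rep(rt_f[regions$rt_bin], each = n) * rep(regions$multiplier, each = n)
  hits <- matrix(stats::rpois(length(lam), lam), nrow = n)
  hit_idx <- which(hits > 0, arr.ind = TRUE)
  reg_rows <- vector("list", nrow(hit_idx))
  if (nrow(hit_idx)) for (h in seq_len(nrow(hit_idx))) {
    s <- hit_idx[h, 1L]; rgi <- hit_idx[h, 2L]
    m <- hits[s, rgi]
    pctx <- rate_true[s, ] * context_counts[rgi, ]
    ctx <- expand_contexts(stats::rmultinom(1, m, pctx)[, 1L])
    hf <- if (regions$multiplier[rgi] > 1) config$hotspot_fraction else 0
    on_hot <- stats::runif(m) < hf
    pos <- ifelse(on_hot, regions$hotspot_pos[rgi],
                  regions$start[rgi] +
                    floor(stats::runif(m) *
                            (regions$end[rgi] - regions$start[rgi] + 1L)))
    ra <- context96_ref_alt(ctx)
    reg_rows[[h]] <- data.frame(sample_id = ids[s], timepoint = "primary",
                                chrom = regions$chrom[rgi], pos = pos,
                                ref = ra[, 1L], alt = ra[, 2L],
                                class = "SNV", context96 = ctx,
                                ccf = clip01(stats::runif(m, 0.3, 1)),
                                support_frac = NA_real_, pop_af = 0,
                                gene = NA_character_,
                                stringsAsFactors = FALSE)
  }
  reg_rows <- do.call(rbind, reg_rows)
  if (!is.null(reg_rows)) mutations <- rbind(mutations, reg_rows)

  ## planted chronology driver-gene mutations
  set.seed(stage_seed(config$seed, 6L))
  genes <- default_chronology_genes()
  gene_rows <- vector("list", nrow(genes))
  non_hd <- setdiff(seq_len(n), hd)
  for (g in seq_len(nrow(genes))) {
    carriers <- sample(non_hd, min(genes$n_carriers[g], length(non_hd)))
    ccf <- pmin(1, pmax(0.02, stats::rnorm(length(carriers),
                                           genes$mean_ccf[g],
                                           config$chron_sigma)))
    ctx <- sample(0:95, length(carriers), replace = TRUE)
    ra <- context96_ref_alt(ctx)
    gene_rows[[g]] <- data.frame(
      sample_id = ids[carriers], timepoint = "primary",
      chrom = genes$chrom[g],
      pos = as.integer(genes$pos[g] + seq_along(carriers)),
      ref = ra[, 1L], alt = ra[, 2L], class = "SNV", context96 = ctx,
      ccf = ccf, support_frac = NA_real_, pop_af = 0,
      gene = genes$gene[g], stringsAsFactors = FALSE)
  }
  mutations <- rbind(mutations, do.call(rbind, gene_rows))

  ## indels
  set.seed(stage_seed(config$seed, 7L))
  n_ind <- stats::rbinom(n, burden, config$indel_frac)
  ind_rows <- lapply(seq_len(n), function(i) {
    m <- n_ind[i]
    if (!m) return(NULL)
    loc <- draw_positions(m)
    data.frame(sample_id = ids[i], timepoint = "primary",
               chrom = loc$chrom, pos = loc$pos, ref = "A", alt = "AT",
               class = "indel", context96 = NA_integer_,
               ccf = clip01(stats::runif(m, 0.2, 1)),
               support_frac = round(stats::runif(m, 0.25, 1), 3),
               pop_af = 0, gene = NA_character_, stringsAsFactors = FALSE)
  })
  mutations <- rbind(mutations, do.call(rbind, ind_rows))

  ## kataegis foci (APOBEC-flavoured clustered substitutions)
  set.seed(stage_seed(config$seed, 8L))
  kat_truth <- NULL
  if (config$n_kataegis > 0) {
    kat_rows <- lapply(seq_len(config$n_kataegis), function(k) {
      s <- sample(n, 1L)
      ch <- sample(genome$chrom, 1L)
      start <- floor(stats::runif(1, 2e7, 4e7))
      while (any(in_regions(reg_index, rep(ch, 20L),
                            start + seq(0, 1.9e4, by = 1e3))))
        start <- floor(stats::runif(1, 2e7, 4e7))
      m <- 6L + stats::rpois(1, 3)
      pos <- start + cumsum(c(0, 50 + stats::rgeom(m - 1L, 1 / 80)))
      ctx <- sample(c(44:47, 28:31), m, replace = TRUE)  # T[C>T]N, T[C>G]N
      ra <- context96_ref_alt(ctx)
      data.frame(sample_id = ids[s], timepoint = "primary", chrom = ch,
                 pos = as.integer(pos), ref = ra[, 1L], alt = ra[, 2L],
                 class = "SNV", context96 = ctx, ccf = 0.9,
                 support_frac = NA_real_, pop_af = 0,
                 gene = NA_character_, stringsAsFactors = FALSE)
    })
    kat_truth <- do.call(rbind, lapply(kat_rows, function(x)
      data.frame(sample_id = x$sample_id[1L], chrom = x$chrom[1L],
                 start = min(x$pos), end = max(x$pos), n = nrow(x),
                 stringsAsFactors = FALSE)))
    mutations <- rbind(mutations, do.call(rbind, kat_rows))
  }
  rownames(mutations) <- NULL

  ## ---- stage 5: copy-number segments -------------------------------------
  set.seed(stage_seed(config$seed, 9L))
  arm_rates <- default_arm_rates()
  arms <- arm_table(genome)
  seg_list <- list()
  arm_states <- list()
  state_cn <- list(gain = c(3L, 1L), amp = c(4L, 1L), loss = c(1L, 0L),
                   deep_loss = c(0L, 0L), nLOH = c(2L, 0L),
                   neutral = c(2L, 1L))
  build_segments <- function(sample_id, timepoint, st, cf) {
    rows <- lapply(seq_len(nrow(arms)), function(a) {
      s0 <- arms$start[a]; e0 <- arms$end[a]
      if (st[a] == "neutral")
        return(data.frame(sample_id = sample_id, timepoint = timepoint,
                          chrom = arms$chrom[a], start = s0, end = e0,
                          total_cn = 2L, minor_cn = 1L, clonal_frac = 1,
                          stringsAsFactors = FALSE))
      cut <- s0 + floor(0.95 * (e0 - s0))
      cn <- state_cn[[st[a]]]
      rbind(
        data.frame(sample_id = sample_id, timepoint = timepoint,
                   chrom = arms$chrom[a], start = s0, end = cut,
                   total_cn = cn[1L], minor_cn = cn[2L],
                   clonal_frac = cf[a], stringsAsFactors = FALSE),
        data.frame(sample_id = sample_id, timepoint = timepoint,
                   chrom = arms$chrom[a], start = cut + 1L, end = e0,
                   total_cn = 2L, minor_cn = 1L, clonal_frac = 1,
                   stringsAsFactors = FALSE))
    })
    do.call(rbind, rows)
  }
  for (i in seq_len(n)) {
    st <- rep("neutral", nrow(arms))
    cf <- rep(1, nrow(arms))
    names(st) <- arms$arm
    for (a in seq_len(nrow(arm_rates))) {
      if (stats::runif(1) < arm_rates$p_primary[a]) {
        st[arm_rates$arm[a]] <- arm_rates$state[a]
        cf[match(arm_rates$arm[a], arms$arm)] <-
          min(1, max(0.05, stats::rnorm(1, arm_rates$mean_cf[a], 0.1)))
      }
    }
    bg <- stats::runif(nrow(arms)) < 0.02
    st[bg & st == "neutral"] <-
      sample(c("gain", "loss"), sum(bg & st == "neutral"), replace = TRUE)
    if (i == hd) {  # hyperdiploid: whole-chromosome gains of 9 and 15
      st[c("9p", "9q", "15p", "15q")] <- "gain"
      cf[match(c("9p", "9q", "15p", "15q"), arms$arm)] <- 1
    }
    seg_list[[length(seg_list) + 1L]] <-
      build_segments(ids[i], "primary", st, cf)
    arm_states[[ids[i]]] <- st
    if (!is.na(pair_j[i])) {
      str <- st
      cfr <- cf
      for (a in seq_len(nrow(arm_rates))) {
        arm <- arm_rates$arm[a]
        if (str[arm] == "neutral" &&
            stats::runif(1) < arm_rates$relapse_delta[a]) {
          str[arm] <- arm_rates$state[a]
          cfr[match(arm, arms$arm)] <-
            min(1, max(0.05, stats::rnorm(1, arm_rates$mean_cf[a], 0.1)))
        }
        if (str[arm] == "nLOH" && arm_rates$progression_rate[a] > 0 &&
            stats::runif(1) < arm_rates$progression_rate[a])
          str[arm] <- "loss"                       # nLOH -> LOH
      }
      churn <- stats::runif(nrow(arms)) < 0.02
      str[churn & str == "neutral"] <-
        sample(c("gain", "loss"), sum(churn & str == "neutral"),
               replace = TRUE)
      seg_list[[length(seg_list) + 1L]] <-
        build_segments(ids[i], "relapse", str, cfr)
    }
  }
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL

  bundle <- structure(list(
    metadata = metadata, mutations = mutations, segments = segments,
    regions = all_regions, rt_track = rt_track, catalog = catalog,
    genome = genome, genome_context_counts = genome_context_counts,
    config = config), class = "cohort_bundle")
  truth <- structure(list(
    driver_regions = data.frame(region_id = regions$region_id,
                                is_driver = regions$multiplier > 1,
                                multiplier = regions$multiplier,
                                stringsAsFactors = FALSE),
    exposures_primary = expo_primary,
    exposures_relapse_specific = expo_new,
    apobec = data.frame(sample_id = ids[paired],
                        apobec_share = apobec_share,
                        elapsed_months = elapsed[paired],
                        stringsAsFactors = FALSE),
    patterns = data.frame(sample_id = ids[paired],
                          pattern = pattern[paired],
                          stringsAsFactors = FALSE),
    chronology_genes = genes,
    arm_rates = arm_rates,
    kataegis = kat_truth,
    burden = data.frame(sample_id = ids, burden = burden,
                        stringsAsFactors = FALSE)), class = "ground_truth")
  list(bundle = bundle, truth = truth)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Synthetic cohort bundle:", nrow(x$metadata), "patients (",
      sum(!is.na(x$metadata$elapsed_months)), "paired ),",
      nrow(x$mutations), "mutation rows,", nrow(x$segments),
      "segments,", sum(x$regions$kind %in% c("promoter", "CRE")),
      "candidate regions\n")
  invisible(x)
}
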