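#' Per-site nucleotide diversity from allele counts
#'
#' For a biallelic site with `c0` reference and `c1` alternate haplotypes
#' observed (n = c0 + c1 sampled haplotypes), nucleotide diversity is the
#' proportion of the n(n-1)/2 unordered haplotype pairs that differ:
#' pi = c0 * c1 / choose(n, 2). This is the unbiased per-site heterozygosity
#' used by VCFtools' `--site-pi`/`--window-pi`.
#'
#' @param c0,c1 Non-negative integer vectors of reference and alternate
#'   haplotype counts (recycled to common length).
#' @return Numeric vector of per-site pi values in \[0, 1\].
#' @examples
#' site_pi(2, 2)   # 4 of 6 pairs differ
#' site_pi(4, 0)   # monomorphic
#' @export
site_pi <- function(c0, c1) {
  n <- c0 + c1
  if (any(n < 2)) abort("site_pi is undefined for fewer than 2 haplotypes")
  (c0 * c1) / (n * (n - 1) / 2)
}

#' Summarise genotype calls into per-site diversity records
#'
#' Collapses a (filtered) `vcf_calls` tibble to one row per site with allele
#' counts over non-missing diploid calls and per-site pi. Sites where fewer
#' than two haplotypes remain (fewer than one non-missing diploid call) are
#' skipped; the number skipped is attached as `attr(, "n_skipped")` .
#'
#' @param calls A `vcf_calls` tibble, normally from [filter_variants()].
#' @return A tibble with columns `chrom`, `pos`, `n_hap` (2 x non-missing
#'   calls), `c_ref`, `c_alt`, `pi_site`.
#' @export
site_diversity <- function(calls) {
  key <- paste(calls$chrom, calls$pos, sep = "\r")
  sid <- match(key, unique(key))
  first <- !duplicated(sid)
  n_ref <- (!is.na(calls$gt1) & calls$gt1 == 0L) + (!is.na(calls$gt2) & calls$gt2 == 0L)
  n_alt <- (!is.na(calls$gt1) & calls$gt1 == 1L) + (!is.na(calls$gt2) & calls$gt2 == 1L)
  agg <- rowsum(cbind(c_ref = n_ref, c_alt = n_alt), sid, reorder = FALSE)
  sites <- tibble(
    chrom = calls$chrom[first],
    pos = calls$pos[first],
    n_hap = as.integer(agg[, "c_ref"] + agg[, "c_alt"]),
    c_ref = as.integer(agg[, "c_ref"]),
    c_alt = as.integer(agg[, "c_alt"])
  )
  ok <- sites$n_hap >= 2L
  out <- sites %>%
    filter(ok) %>%
    mutate(pi_site = site_pi(.data$c_ref, .data$c_alt))
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Windowed nucleotide diversity
#'
#' Sums per-site pi over non-overlapping windows of `window_size` base pairs
#' (1-based, inclusive: \[1, W\], \[W+1, 2W\], ... per chromosome) and divides
#' by the full window length, so unobserved positions contribute zero --
#' VCFtools `--window-pi` semantics. Windows containing no site are not
#' emitted.
#'
#' @param sites Per-site tibble from [site_diversity()], sorted by
#'   (`chrom`, `pos`).
#' @param window_size Window width in base pairs (default 10 kb).
#' @return A tibble with columns `chrom`, `bin_start`, `bin_end`,
#'   `n_variants`, `pi` (per-bp rate).
#' @export
windowed_pi <- function(sites, window_size = 10000) {
  if (window_size < 1) abort("`window_size` must be a positive integer")
  if (nrow(sites) > 1) {
    o <- order(sites$chrom, sites$pos)
    if (!identical(o, seq_len(nrow(sites)))) {
      abort("ordering error: `sites` must be sorted by (chrom, pos)")
    }
  }
  sites %>%
    mutate(bin = (.data$pos - 1L) %/% window_size) %>%
    group_by(.data$chrom, .data$bin) %>%
    summarise(
      n_variants = dplyr::n(),
      pi = sum(.data$pi_site) / window_size,
      .groups = "drop"
    ) %>%
    mutate(
      bin_start = .data$bin * as.integer(window_size) + 1L,
      bin_end = .data$bin_start + as.integer(window_size) - 1L
    ) %>%
    select("chrom", "bin_start", "bin_end", "n_variants", "pi")
}

#' Count polymorphic SNPs
#'
#' A site is polymorphic within a group when both alleles are observed among
#' that group's non-missing calls (0 < c_alt < n_hap).
#'
#' @param sites Per-site tibble from [site_diversity()].
#' @return Integer count.
#' @export
count_polymorphic <- function(sites) {
  sum(sites$c_alt > 0L & sites$c_alt < sites$n_hap)
}

#' Percent of a diversity metric lost between two timepoints
#'
#' @param v_day1 Baseline value (must be positive).
#' @param v_day7 Later value.
#' @return `100 * (v_day1 - v_day7) / v_day1`.
#' @examples
#' percent_loss(480932, 452687)  # 5.87% of SNPs lost
#' @export
percent_loss <- function(v_day1, v_day7) {
  if (any(v_day1 <= 0)) abort("`v_day1` must be positive")
  100 * (v_day1 - v_day7) / v_day1
}

#' Relative excess of loss in one condition over another
#'
#' Expresses how much larger the high-condition percent loss is than the low-
#' condition one, as a percentage of the latter (e.g. 18.61% vs 10.12% loss
#' is an ~84% excess).
#'
#' @param pct_high,pct_low Percent-loss values; `pct_low` must be positive.
#' @return `100 * (pct_high - pct_low) / pct_low`.
#' @export
excess_loss <- function(pct_high, pct_low) {
  if (any(pct_low <= 0)) abort("`pct_low` must be positive")
  100 * (pct_high - pct_low) / pct_low
}

#' Per-group diversity summaries and loss statistics
#'
#' Builds the headline report for a 2 x 2 day-by-condition design: per-group
#' mean window pi and polymorphic-SNP counts, percent lost through time
#' within each condition (for both metrics), the relative excess of the
#' high-condition pi loss, and pooled overall figures (mean pi over all
#' emitted windows; number of distinct sites polymorphic in at least one
#' group).
#'
#' @param sites Per-site tibble (as [site_diversity()] output) with added
#'   `day` (1 or 7) and `condition` (`"low"`/`"high"`) columns.
#' @param windows Window tibble (as [windowed_pi()] output) with the same two
#'   grouping columns.
#' @return An object of class `diversity_report`: a list with elements
#'   `groups` (tibble: day, condition, mean_pi, n_polymorphic, n_windows),
#'   `loss` (tibble: metric, low, high percent lost), `excess_loss_pct`, and
#'   `overall` (list with `pi` and `n_snps`).
#' @export
group_summaries <- function(sites, windows) {
  need <- tidyr::expand_grid(day = c(1, 7), condition = c("low", "high"))
  have <- distinct(windows, .data$day, .data$condition)
  missing_grp <- dplyr::anti_join(need, have, by = c("day", "condition"))
  if (nrow(missing_grp) > 0) {
    abort(sprintf(
      "configuration error: missing group(s): %s",
      paste(sprintf("day %s / %s", missing_grp$day, missing_grp$condition),
            collapse = ", ")))
  }

  win_sum <- windows %>%
    group_by(.data$day, .data$condition) %>%
    summarise(mean_pi = mean(.data$pi), n_windows = dplyr::n(), .groups = "drop")
  snp_sum <- sites %>%
    group_by(.data$day, .data$condition) %>%
    summarise(
      n_polymorphic = sum(.data$c_alt > 0L & .data$c_alt < .data$n_hap),
      .groups = "drop"
    )
  groups <- left_join(win_sum, snp_sum, by = c("day", "condition")) %>%
    mutate(n_polymorphic = dplyr::coalesce(.data$n_polymorphic, 0L)) %>%
    select("day", "condition", "mean_pi", "n_polymorphic", "n_windows") %>%
    arrange(.data$day, .data$condition)

  pick <- function(col, d, cond) {
    groups[[col]][groups$day == d & groups$condition == cond]
  }
  loss <- tibble(
    metric = c("mean_pi", "n_snps"),
    low = c(percent_loss(pick("mean_pi", 1, "low"), pick("mean_pi", 7, "low")),
            percent_loss(pick("n_polymorphic", 1, "low"), pick("n_polymorphic", 7, "low"))),
    high = c(percent_loss(pick("mean_pi", 1, "high"), pick("mean_pi", 7, "high")),
             percent_loss(pick("n_polymorphic", 1, "high"), pick("n_polymorphic", 7, "high")))
  )
  pi_low <- loss$low[loss$metric == "mean_pi"]
  excess <- if (pi_low > 0) excess_loss(loss$high[loss$metric == "mean_pi"], pi_low) else NA_real_

  poly_sites <- sites %>%
    filter(.data$c_alt > 0L, .data$c_alt < .data$n_hap) %>%
    distinct(.data$chrom, .data$pos)
  overall <- list(pi = mean(windows$pi), n_snps = nrow(poly_sites))

  structure(
    list(groups = groups, loss = loss, excess_loss_pct = excess,
         overall = overall),
    class = "diversity_report"
  )
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("Nucleotide diversity by treatment group\n")
  g <- x$groups
  for (d in unique(g$day)) {
    cat(sprintf("  Day %d:\n", as.integer(d)))
    for (cond in c("low", "high")) {
      row <- g[g$day == d & g$condition == cond, ]
      cat(sprintf("    %-4s pCO2: mean pi %.5g  SNPs %d  windows %d\n",
                  cond, row$mean_pi, row$n_polymorphic, row$n_windows))
    }
  }
  cat("Percent lost through time (day 1 -> day 7):\n")
  cat(sprintf("    mean pi : low %.2f%%  high %.2f%%\n",
              x$loss$low[1], x$loss$high[1]))
  cat(sprintf("    SNPs    : low %.2f%%  high %.2f%%\n",
              x$loss$low[2], x$loss$high[2]))
  cat(sprintf("  Excess pi loss, high vs low: %.1f%%\n", x$excess_loss_pct))
  cat(sprintf("  Overall: mean pi %.5g over all windows, %d polymorphic SNPs\n",
              x$overall$pi, x$overall$n_snps))
  invisible(x)
}

#' @rdname group_summaries
#' @param x A `diversity_report`.
#' @param ... Unused.
#' @method tidy diversity_report
#' @export
tidy.diversity_report <- function(x, ...) {
  x$groups
}

#' @rdname group_summaries
#' @method glance diversity_report
#' @export
glance.diversity_report <- function(x, ...) {
  tibble(
    pct_loss_pi_low = x$loss$low[x$loss$metric == "mean_pi"],
    pct_loss_pi_high = x$loss$high[x$loss$metric == "mean_pi"],
    pct_loss_snps_low = x$loss$low[x$loss$metric == "n_snps"],
    pct_loss_snps_high = x$loss$high[x$loss$metric == "n_snps"],
    excess_loss_pct = x$excess_loss_pct,
    overall_pi = x$overall$pi,
    overall_n_snps = x$overall$n_snps
  )
}

#' Write a window table in VCFtools --window-pi column layout
#'
#' @param windows Tibble from [windowed_pi()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_windows_tsv <- function(windows, path) {
  out <- windows %>%
    select(CHROM = "chrom", BIN_START = "bin_start", BIN_END = "bin_end",
           N_VARIANTS = "n_variants", PI = "pi")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
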