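#' Configuration for the synthetic selective-mortality cohort simulator
#'
#' Describes a 2 x 2 larval-rearing design: replicate population pools
#' sampled at two developmental days under two pCO2 conditions, with
#' viability selection acting only in the high-pCO2 arm. Defaults mirror the
#' emulated study design: seven replicate population pools of ~1000 larvae,
#' four treatment groups, one diploid genotype call per pool.
#'
#' @param n_populations Replicate population pools per group (default 7).
#' @param n_sites Number of biallelic loci simulated.
#' @param n_chromosomes Number of chromosomes loci are spread across.
#' @param window_span Chromosome length in bp; loci get uniform positions in
#'   `1..window_span`.
#' @param n0 Larvae per pool at day 1 (default 1000).
#' @param n7 Survivors per pool at day 7 (default 250).
#' @param selected_fraction Proportion of loci under viability selection in
#'   the high-pCO2 arm.
#' @param s Selection coefficient (genotype fitnesses 1 + s, 1 + h s, 1).
#' @param h Dominance of the favored allele (default 0.5, genic selection).
#' @param freq_alpha,freq_beta Beta prior parameters for ancestral alternate-
#'   allele frequencies. The default Beta(0.5, 0.5) is mildly U-shaped,
#'   approximating a folded site-frequency spectrum in which rare variants
#'   predominate.
#' @param prob_favor_minor Probability that the favored allele at a selected
#'   locus is the minor allele, so selection can either restore or remove
#'   variation (default 0.5).
#' @param mean_depth Mean sequencing depth per pool genotype (Poisson rate).
#' @param seq_error Per-read sequencing error rate.
#' @param seed Master seed; all randomness in [simulate_cohorts()] flows from
#'   it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 7,
                       n_sites = 20000,
                       n_chromosomes = 20,
                       window_span = 1e5,
                       n0 = 1000,
                       n7 = 250,
                       selected_fraction = 0.1,
                       s = 0.1,
                       h = 0.5,
                       freq_alpha = 0.5,
                       freq_beta = 0.5,
                       prob_favor_minor = 0.5,
                       mean_depth = 80,
                       seq_error = 0.005,
                       seed = NULL) {
  if (!(selected_fraction >= 0 && selected_fraction <= 1)) {
    abort("`selected_fraction` must be in [0, 1]")
  }
  if (s < 0) abort("`s` must be non-negative")
  if (!(n7 > 0 && n7 <= n0)) abort("need 0 < n7 <= n0")
  if (mean_depth <= 0) abort("`mean_depth` must be positive")
  if (!(seq_error >= 0 && seq_error < 0.5)) abort("`seq_error` must be in [0, 0.5)")
  if (freq_alpha <= 0 || freq_beta <= 0) abort("Beta prior parameters must be positive")
  if (n_sites > n_chromosomes * window_span) {
    abort("more sites than available positions")
  }
  structure(
    list(
      n_populations = n_populations, n_sites = n_sites,
      n_chromosomes = n_chromosomes, window_span = window_span,
      n0 = n0, n7 = n7,
      selected_fraction = selected_fraction, s = s, h = h,
      freq_alpha = freq_alpha, freq_beta = freq_beta,
      prob_favor_minor = prob_favor_minor,
      mean_depth = mean_depth, seq_error = seq_error, seed = seed
    ),
    class = "sim_config"
  )
}

#' Draw ancestral allele frequencies and locus positions
#'
#' Loci are assigned near-evenly to chromosomes with uniform distinct
#' positions, and ancestral alternate-allele frequencies are i.i.d.
#' Beta(`freq_alpha`, `freq_beta`) draws.
#'
#' @param config A [sim_config()].
#' @param .set_seed Seed R's RNG from `config$seed` first (set `FALSE` when
#'   the caller manages the stream).
#' @return A tibble sorted by (`chrom`, `pos`) with columns `chrom`, `pos`,
#'   `p0`.
#' @export
draw_ancestral_frequencies <- function(config = sim_config(), .set_seed = TRUE) {
  if (.set_seed && !is.null(config$seed)) set.seed(config$seed)
  chrom_id <- sort(sample.int(config$n_chromosomes, config$n_sites, replace = TRUE))
  chrom <- sprintf("chr%02d", chrom_id)
  pos <- unlist(lapply(split(seq_along(chrom_id), chrom_id), function(idx) {
    sort(sample.int(config$window_span, length(idx), replace = FALSE))
  }), use.names = FALSE)
  tibble(
    chrom = chrom,
    pos = as.integer(pos),
    p0 = rbeta(config$n_sites, config$freq_alpha, config$freq_beta)
  )
}

#' One generation of viability selection on an allele frequency
#'
#' Deterministic (infinite-population) update for a favored allele A with
#' genotype fitnesses w_AA = 1 + s, w_Aa = 1 + h s, w_aa = 1:
#' p' = (p^2 (1+s) + p (1-p) (1+hs)) / wbar.
#'
#' @param p Frequency of the favored allele (vectorized).
#' @param s Selection coefficient (>= 0).
#' @param h Dominance coefficient.
#' @return Updated frequency vector.
#' @examples
#' selection_update(0.5, s = 0.2, h = 0.5)  # 0.575 / 1.1
#' @export
selection_update <- function(p, s, h = 0.5) {
  w_bar <- p^2 * (1 + s) + 2 * p * (1 - p) * (1 + h * s) + (1 - p)^2
  (p^2 * (1 + s) + p * (1 - p) * (1 + h * s)) / w_bar
}

#' Emulate diploid genotyping of a pooled library
#'
#' Reproduces the data shape of one diploid GT:DP:GQ call per pooled library:
#' depth is Poisson(`mean_depth`); alternate-read count is binomial with
#' success probability q(1 - e) + (1 - q)e; the call is the maximum-
#' likelihood diploid genotype over alternate-allele fractions {e, 1/2,
#' 1 - e} (ties broken toward the heterozygote); GQ is the Phred-scaled
#' likelihood ratio of best to second-best genotype, capped at 99. Zero depth
#' yields a missing call.
#'
#' @param q Pool alternate-allele frequency (vectorized).
#' @param mean_depth Poisson mean depth.
#' @param seq_error Per-read error rate `e`.
#' @return A tibble with columns `gt1`, `gt2`, `dp`, `gq` (one row per
#'   element of `q`).
#' @export
emulate_genotyping <- function(q, mean_depth, seq_error) {
  m <- length(q)
  d <- rpois(m, mean_depth)
  p_alt_read <- q * (1 - seq_error) + (1 - q) * seq_error
  k <- rbinom(m, d, p_alt_read)

  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  af <- c(seq_error, 0.5, 1 - seq_error)
  ll <- cbind(
    xlogy(k, af[1]) + xlogy(d - k, 1 - af[1]),
    xlogy(k, af[2]) + xlogy(d - k, 1 - af[2]),
    xlogy(k, af[3]) + xlogy(d - k, 1 - af[3])
  )
  hom_best <- pmax(ll[, 1], ll[, 3])
  is_het <- ll[, 2] >= hom_best          # ties go to the heterozygote
  is_alt_hom <- !is_het & ll[, 3] > ll[, 1]
  gt1 <- integer(m)
  gt1[is_alt_hom] <- 1L
  gt2 <- as.integer(is_het | is_alt_hom)

  best <- pmax(ll[, 2], hom_best)
  # runner-up: for a het call the best homozygote; for a homozygous call
  # the better of the het and the other homozygote
  other_hom <- ll[, 3]
  other_hom[is_alt_hom] <- ll[is_alt_hom, 1]
  second <- pmax(ll[, 2], other_hom)
  second[is_het] <- hom_best[is_het]
  gq <- pmin(99L, as.integer(round(10 * (best - second) / log(10))))

  miss <- d == 0L
  gt1[miss] <- NA_integer_
  gt2[miss] <- NA_integer_
  gq[miss] <- 0L
  tibble(gt1 = gt1, gt2 = gt2, dp = as.integer(d), gq = gq)
}

group_table <- function() {
  tibble(
    group = c("D1-400", "D1-900", "D7-400", "D7-900"),
    day = c(1, 1, 7, 7),
    condition = c("low", "high", "low", "high")
  )
}

#' Simulate the four-group selective-mortality cohort experiment
#'
#' Generates, for each replicate population pool: day-1 pool allele
#' frequencies as binomial samples of 2 n0 gametes from the ancestral
#' frequency (independently per arm, as separate replicate cultures); day-7
#' frequencies by binomial survival drift down to n7 individuals, preceded in
#' the high-pCO2 arm by one [selection_update()] at the selected loci (the
#' favored allele is the minor allele with probability `prob_favor_minor`).
#' Each pool frequency is then genotyped with [emulate_genotyping()], giving
#' four `vcf_calls` tables with one diploid column per pool.
#'
#' @param config A [sim_config()].
#' @return An object of class `divloss_sim`: list with `calls` (named list of
#'   four `vcf_calls` tibbles: D1-400, D1-900, D7-400, D7-900), `truth`
#'   (per-locus tibble: chrom, pos, p0, selected, favored_is_alt, plus mean
#'   realized day-7 frequency per arm), `freqs` (list of n_sites x
#'   n_populations matrices of realized pool frequencies per group), `groups`
#'   (group/day/condition table), and `config`.
#' @examples
#' sim <- simulate_cohorts(sim_config(n_sites = 200, n_chromosomes = 2, seed = 1))
#' names(sim$calls)
#' @export
simulate_cohorts <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  loci <- draw_ancestral_frequencies(config, .set_seed = FALSE)
  n <- config$n_sites
  npop <- config$n_populations

  selected <- stats::runif(n) < config$selected_fraction
  minor_is_alt <- loci$p0 < 0.5
  favor_minor <- stats::runif(n) < config$prob_favor_minor
  favored_is_alt <- ifelse(favor_minor, minor_is_alt, !minor_is_alt)

  draw_pool <- function(p) rbinom(length(p), 2L * config$n0, p) / (2 * config$n0)
  drift <- function(q) rbinom(length(q), 2L * config$n7, q) / (2 * config$n7)
  select_alt_freq <- function(q) {
    # apply the update on the favored allele's frequency at selected loci
    upd <- ifelse(favored_is_alt,
                  selection_update(q, config$s, config$h),
                  1 - selection_update(1 - q, config$s, config$h))
    ifelse(selected, upd, q)
  }

  groups <- group_table()
  freqs <- list()
  for (g in seq_len(nrow(groups))) {
    qmat <- matrix(0, n, npop)
    for (j in seq_len(npop)) {
      q1 <- draw_pool(loci$p0)
      qmat[, j] <- if (groups$day[g] == 1) {
        q1
      } else if (groups$condition[g] == "low") {
        drift(q1)
      } else {
        drift(select_alt_freq(q1))
      }
    }
    freqs[[groups$group[g]]] <- qmat
  }

  pops <- sprintf("pop%d", seq_len(npop))
  calls <- lapply(groups$group, function(gname) {
    qmat <- freqs[[gname]]
    # record-major layout: all pools of locus 1, then locus 2, ...
    q_flat <- as.vector(t(qmat))
    geno <- emulate_genotyping(q_flat, config$mean_depth, config$seq_error)
    out <- tibble(
      chrom = rep(loci$chrom, each = npop),
      pos = rep(loci$pos, each = npop),
      id = ".", ref = "A", alt = "C", qual = ".", filter = ".", info = ".",
      n_alleles = 2L, is_indel = FALSE,
      sample = rep(pops, times = n),
      gt1 = geno$gt1, gt2 = geno$gt2, dp = geno$dp, gq = geno$gq
    )
    new_vcf_calls(out, samples = pops, source = sprintf("simulated:%s", gname))
  })
  names(calls) <- groups$group

  truth <- loci %>%
    mutate(
      selected = selected,
      favored_is_alt = favored_is_alt,
      freq_d1_low = rowMeans(freqs[["D1-400"]]),
      freq_d1_high = rowMeans(freqs[["D1-900"]]),
      freq_d7_low = rowMeans(freqs[["D7-400"]]),
      freq_d7_high = rowMeans(freqs[["D7-900"]])
    )

  structure(
    list(calls = calls, truth = truth, freqs = freqs, groups = groups,
         config = config),
    class = "divloss_sim"
  )
}

#' Write a simulated cohort to disk
#'
#' Emits one VCF per treatment group (via [write_vcf()]), a per-locus truth
#' TSV, and a JSON echo of the configuration including the seed.
#'
#' @param sim A `divloss_sim` from [simulate_cohorts()].
#' @param dir Output directory (created if needed).
#' @return A named character vector of the VCF paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "divloss_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(sim$calls), function(g) {
    p <- file.path(dir, paste0(g, ".vcf"))
    write_vcf(sim$calls[[g]], p)
    p
  }, character(1))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(paths)
}

#' @export
print.divloss_sim <- function(x, ...) {
  cat(sprintf(
    "<divloss_sim> %d loci x %d pools x 4 groups (selected fraction %.3g, s = %.3g)\n",
    x$config$n_sites, x$config$n_populations,
    x$config$selected_fraction, x$config$s))
  invisible(x)
}
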