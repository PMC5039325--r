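#' Run the full diversity-loss analysis
#'
#' Orchestrates the whole method on a four-group day x pCO2 design: read each
#' group's VCF (or take pre-parsed call tables), apply the genotype and site
#' filters, compute per-site and windowed pi, build the per-group summary and
#' percent-loss report, and assess day / condition / interaction effects with
#' the permutation ANOVA on log window pi.
#'
#' @param groups Either a `divloss_sim` object from [simulate_cohorts()], or
#'   a tibble with columns `group`, `day` (1/7), `condition` ("low"/"high")
#'   and one of `vcf` (file paths) or `calls` (list-column of `vcf_calls`
#'   tibbles).
#' @param filter A [filter_config()].
#' @param window_size Window width in bp (default 10 kb).
#' @param B Number of permutations (default 10000).
#' @param seed Seed for the permutation stream.
#' @param out_dir Optional output directory; when given, writes a Table-1
#'   style TSV, a full-precision JSON summary, per-group window TSVs
#'   (VCFtools `--window-pi` column layout), per-group filter logs, the
#'   permutation density TSV, and a run log.
#' @return An object of class `divloss_run`: list with `report`
#'   (`diversity_report`), `perm` (`perm_anova`), `windows`, `sites`,
#'   `filter_summary`, `n_excluded_windows`, and the run settings.
#' @examples
#' sim <- simulate_cohorts(sim_config(n_sites = 500, n_chromosomes = 2, seed = 1))
#' res <- run_pipeline(sim, B = 100, seed = 1)
#' res$report
#' @export
run_pipeline <- function(groups, filter = filter_config(),
                         window_size = 10000, B = 10000, seed = NULL,
                         out_dir = NULL) {
  if (inherits(groups, "divloss_sim")) {
    groups <- groups$groups %>%
      mutate(calls = unname(groups$calls[.data$group]))
  }
  if (!is.data.frame(groups) || !all(c("group", "day", "condition") %in% names(groups))) {
    abort("`groups` must be a divloss_sim or a table with group/day/condition")
  }
  if (nrow(groups) != 4) {
    abort(sprintf("configuration error: need exactly 4 groups, got %d", nrow(groups)))
  }
  need <- tidyr::expand_grid(day = c(1, 7), condition = c("low", "high"))
  if (nrow(dplyr::anti_join(need, groups, by = c("day", "condition"))) > 0) {
    abort("configuration error: groups must cover the 2x2 day x condition design")
  }
  if (window_size < 1) abort("`window_size` must be positive")
  if (B < 1) abort("`B` must be at least 1")

  per_group <- purrr::map(seq_len(nrow(groups)), function(i) {
    calls <- if ("calls" %in% names(groups)) {
      groups$calls[[i]]
    } else {
      read_vcf(groups$vcf[i])
    }
    kept <- filter_variants(calls, filter)
    sites <- site_diversity(kept)
    wins <- windowed_pi(sites, window_size)
    list(
      sites = mutate(sites, group = groups$group[i], day = groups$day[i],
                     condition = groups$condition[i]),
      windows = mutate(wins, group = groups$group[i], day = groups$day[i],
                       condition = groups$condition[i]),
      filter_summary = tibble(
        group = groups$group[i],
        n_sites_in = nrow(distinct(calls, .data$chrom, .data$pos)),
        n_sites_kept = nrow(sites),
        n_sites_dropped = nrow(filter_log(kept)) + attr(sites, "n_skipped")
      ),
      filter_log = mutate(filter_log(kept), group = groups$group[i])
    )
  })

  sites <- bind_rows(purrr::map(per_group, "sites"))
  windows <- bind_rows(purrr::map(per_group, "windows"))
  filter_summary <- bind_rows(purrr::map(per_group, "filter_summary"))

  report <- group_summaries(sites, windows)
  obs <- log_transform_windows(windows)
  perm <- permutation_anova(obs, B = B, seed = seed)

  res <- structure(
    list(
      report = report,
      perm = perm,
      windows = windows,
      sites = sites,
      filter_summary = filter_summary,
      filter_logs = bind_rows(purrr::map(per_group, "filter_log")),
      n_excluded_windows = attr(obs, "n_excluded"),
      window_size = window_size,
      B = B,
      seed = seed,
      filter = filter
    ),
    class = "divloss_run"
  )
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' Write the report bundle of a pipeline run
#'
#' @param res A `divloss_run` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(res, out_dir) {
  stopifnot(inherits(res, "divloss_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # Table-1 style presentation table (rounded only here)
  g <- res$report$groups
  t1 <- tibble(
    section = c(rep("day1", 2), rep("day7", 2), rep("percent_lost", 2)),
    metric = rep(c("mean_pi", "n_snps"), 3),
    low = c(g$mean_pi[g$day == 1 & g$condition == "low"],
            g$n_polymorphic[g$day == 1 & g$condition == "low"],
            g$mean_pi[g$day == 7 & g$condition == "low"],
            g$n_polymorphic[g$day == 7 & g$condition == "low"],
            round(res$report$loss$low, 2)),
    high = c(g$mean_pi[g$day == 1 & g$condition == "high"],
             g$n_polymorphic[g$day == 1 & g$condition == "high"],
             g$mean_pi[g$day == 7 & g$condition == "high"],
             g$n_polymorphic[g$day == 7 & g$condition == "high"],
             round(res$report$loss$high, 2))
  )
  write.table(t1, file.path(out_dir, "table1.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  for (grp in unique(res$windows$group)) {
    write_windows_tsv(
      filter(res$windows, .data$group == grp),
      file.path(out_dir, sprintf("windows_%s.tsv", grp))
    )
  }
  if (nrow(res$filter_logs) > 0) {
    write.table(res$filter_logs, file.path(out_dir, "filter_log.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  export_density(res$perm, file.path(out_dir, "permutation_density.tsv"))

  summary <- list(
    settings = list(
      window_size = res$window_size, B = res$B, seed = res$seed,
      filter = unclass(res$filter)
    ),
    groups = res$report$groups,
    percent_lost = res$report$loss,
    excess_loss_pct = res$report$excess_loss_pct,
    overall = res$report$overall,
    permutation = list(
      B = res$perm$B,
      empirical = res$perm$empirical,
      excluded_zero_pi_windows = res$n_excluded_windows
    ),
    filter_summary = res$filter_summary
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, dataframe = "rows")

  log_lines <- c(
    sprintf("divloss %s | R %s", as.character(utils::packageVersion("divloss")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("seed=%s window=%d B=%d", res$seed %||% "NULL",
            res$window_size, res$B),
    sprintf("group %s: %d sites in, %d kept, %d dropped",
            res$filter_summary$group, res$filter_summary$n_sites_in,
            res$filter_summary$n_sites_kept, res$filter_summary$n_sites_dropped),
    sprintf("zero-pi windows excluded from ANOVA: %d", res$n_excluded_windows)
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.divloss_run <- function(x, ...) {
  print(x$report)
  cat("\n")
  print(x$perm)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `divloss_run`.
#' @param ... Unused.
#' @method tidy divloss_run
#' @export
tidy.divloss_run <- function(x, ...) {
  tidy(x$report)
}

#' @rdname run_pipeline
#' @method glance divloss_run
#' @export
glance.divloss_run <- function(x, ...) {
  dplyr::bind_cols(glance(x$report), glance(x$perm))
}

#' Window pi distributions by treatment group
#'
#' @param object A `divloss_run`.
#' @param ... Unused.
#' @return A ggplot object: log10 window pi densities per group.
#' @method autoplot divloss_run
#' @export
autoplot.divloss_run <- function(object, ...) {
  df <- filter(object$windows, .data$pi > 0)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = log10(.data$pi), colour = .data$condition,
                 linetype = factor(.data$day))
  ) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "log10 window pi", colour = "pCO2", linetype = "day") +
    ggplot2::theme_minimal()
}
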