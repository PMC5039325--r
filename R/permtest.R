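#' Log-transform window diversity for ANOVA
#'
#' Window pi is strongly right-skewed; the significance procedure therefore
#' models natural-log pi. Windows with pi = 0 (possible when every variant in
#' a window is monomorphic within the group) cannot be transformed; they are
#' excluded and counted in `attr(, "n_excluded")`.
#'
#' The log base only shifts values by a constant factor, which cannot change
#' any ANOVA F or p value; natural log is used.
#'
#' @param windows Window tibble (see [windowed_pi()]) with `day` and
#'   `condition` columns.
#' @return A tibble of window observations: `value` (log pi), `day`,
#'   `condition`.
#' @export
log_transform_windows <- function(windows) {
  keep <- windows$pi > 0
  out <- tibble(
    value = log(windows$pi[keep]),
    day = windows$day[keep],
    condition = windows$condition[keep]
  )
  attr(out, "n_excluded") <- sum(!keep)
  out
}

# 2x2 design matrix with treatment coding, term order
# intercept, day, condition, day:condition (sequential SS order).
design_2x2 <- function(day, condition) {
  d <- as.numeric(day == 7)
  co <- as.numeric(condition == "high")
  cbind(intercept = 1, day = d, condition = co, `day:condition` = d * co)
}

validate_observations <- function(obs) {
  if (!all(c("value", "day", "condition") %in% names(obs))) {
    abort("observations need columns `value`, `day`, `condition`")
  }
  if (!all(obs$day %in% c(1, 7))) abort("`day` must be 1 or 7")
  if (!all(obs$condition %in% c("low", "high"))) {
    abort("`condition` must be 'low' or 'high'")
  }
  if (!all(is.finite(obs$value))) abort("`value` must be finite")
  cells <- table(factor(obs$day, c(1, 7)), factor(obs$condition, c("low", "high")))
  if (any(cells == 0)) {
    abort("degenerate design: every day x condition cell needs at least one observation")
  }
  if (nrow(obs) <= 4) {
    abort("degenerate design: no residual degrees of freedom")
  }
  invisible(obs)
}

# Sequential (Type I) sums of squares for the 2x2 model via one QR
# factorization. Returns list(ss = c(day, condition, day:condition),
# rss, df_res); y may be a matrix (one column per permutation).
anova_ss_2x2 <- function(qr_x, y) {
  y <- as.matrix(y)
  qty <- qr.qty(qr_x, y)
  ss <- qty[2:4, , drop = FALSE]^2
  rss <- colSums(y^2) - colSums(qty[1:4, , drop = FALSE]^2)
  rss <- pmax(rss, 0)
  list(ss = ss, rss = rss, df_res = nrow(y) - 4L)
}

#' Two-way fixed-effects ANOVA on window observations
#'
#' Fits the 2 x 2 model value ~ day + condition + day:condition with
#' sequential (Type I) sums of squares in that order -- the convention of
#' base R's `anova(lm(...))`, which an analysis scripted in R would have
#' used. Because window counts differ between groups (unbalanced design),
#' term order matters; the sequential order day, condition, interaction is
#' the default throughout the package.
#'
#' @param obs Observation tibble from [log_transform_windows()].
#' @return A tibble of class `anova2x2` with one row per term (`day`,
#'   `condition`, `day:condition`, `Residuals`) and columns `df`, `sumsq`,
#'   `meansq`, `statistic`, `p.value`.
#' @export
two_way_anova <- function(obs) {
  validate_observations(obs)
  x <- design_2x2(obs$day, obs$condition)
  qr_x <- qr(x)
  if (qr_x$rank < 4L) abort("degenerate design: model matrix is rank deficient")
  fit <- anova_ss_2x2(qr_x, obs$value)
  tot <- sum((obs$value - mean(obs$value))^2)
  if (fit$rss <= 1e-12 * max(tot, 1e-300) || tot == 0) {
    abort("degenerate design: zero residual variance")
  }
  ms_res <- fit$rss / fit$df_res
  f <- fit$ss[, 1] / ms_res
  out <- tibble(
    term = c("day", "condition", "day:condition", "Residuals"),
    df = c(1L, 1L, 1L, fit$df_res),
    sumsq = c(fit$ss[, 1], fit$rss),
    meansq = c(fit$ss[, 1], ms_res),
    statistic = c(f, NA_real_),
    p.value = c(pf(f, 1, fit$df_res, lower.tail = FALSE), NA_real_)
  )
  class(out) <- c("anova2x2", class(out))
  out
}

#' Permutation two-way ANOVA on window diversity
#'
#' The significance procedure for the day x condition design: fit the
#' observed ANOVA, then shuffle the response values across all windows of the
#' entire dataset `B` times (labels keep their original multiset; values are
#' permuted without replacement), refit the ANOVA each round, and report per
#' factor the empirical p -- the proportion of permuted rounds whose p value
#' is strictly smaller than the observed one (equivalently, whose F is
#' larger, since the degrees of freedom are fixed). An empirical p of 0 is
#' reported as "< 1/B".
#'
#' @param obs Observation tibble from [log_transform_windows()].
#' @param B Number of permutations (default 10000).
#' @param seed Integer seed making the permutation stream reproducible.
#' @param compare Rank permuted rounds by `"p"` value (default) or by `"F"`
#'   statistic; with fixed df the two orderings agree.
#' @param estimator `"strict"` (default) counts strictly smaller permuted p
#'   values; `"add_one"` uses the conservative (k + 1) / (B + 1) estimator.
#' @param .permutations Optional n x B integer matrix of permutation indices,
#'   overriding random generation (testing hook).
#' @return An object of class `perm_anova`: list with `observed` (the
#'   [two_way_anova()] table), `empirical` (tibble: term, p_observed,
#'   p_empirical, p_label), `perm_p` and `perm_F` (B x 3 matrices), `B`,
#'   `seed`, `n_obs`, `estimator`, `compare`.
#' @export
permutation_anova <- function(obs, B = 10000, seed = NULL,
                              compare = c("p", "F"),
                              estimator = c("strict", "add_one"),
                              .permutations = NULL) {
  compare <- match.arg(compare)
  estimator <- match.arg(estimator)
  if (B < 1) abort("`B` must be at least 1")
  observed <- two_way_anova(obs)  # errors on degenerate designs first
  n <- nrow(obs)
  x <- design_2x2(obs$day, obs$condition)
  qr_x <- qr(x)

  if (is.null(.permutations)) {
    if (!is.null(seed)) set.seed(seed)
    perm <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
  } else {
    perm <- .permutations
    if (nrow(perm) != n || ncol(perm) != B) {
      abort("`.permutations` must be an n x B index matrix")
    }
  }
  y_perm <- matrix(obs$value[perm], nrow = n, ncol = B)
  fit <- anova_ss_2x2(qr_x, y_perm)
  f_perm <- t(fit$ss) / (fit$rss / fit$df_res)  # B x 3
  colnames(f_perm) <- c("day", "condition", "day:condition")
  p_perm <- pf(f_perm, 1, fit$df_res, lower.tail = FALSE)

  obs_p <- observed$p.value[1:3]
  obs_f <- observed$statistic[1:3]
  hits <- if (compare == "p") {
    colSums(sweep(p_perm, 2, obs_p, "<"))
  } else {
    colSums(sweep(f_perm, 2, obs_f, ">"))
  }
  hits <- unname(hits)
  emp <- if (estimator == "strict") hits / B else (hits + 1) / (B + 1)
  label <- ifelse(emp == 0, sprintf("< %g", 1 / B), formatC(emp, digits = 4, format = "g"))

  structure(
    list(
      observed = observed,
      empirical = tibble(
        term = c("day", "condition", "day:condition"),
        p_observed = obs_p,
        p_empirical = emp,
        p_label = label
      ),
      perm_p = p_perm,
      perm_F = f_perm,
      B = B,
      seed = seed,
      n_obs = n,
      estimator = estimator,
      compare = compare
    ),
    class = "perm_anova"
  )
}

#' @export
print.perm_anova <- function(x, ...) {
  cat(sprintf("Permutation two-way ANOVA (B = %d, n = %d windows)\n",
              x$B, x$n_obs))
  e <- x$empirical
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-14s observed p = %.4g   empirical p %s\n",
                e$term[i], e$p_observed[i],
                if (e$p_empirical[i] == 0) e$p_label[i] else sprintf("= %s", e$p_label[i])))
  }
  invisible(x)
}

#' @rdname permutation_anova
#' @param x A `perm_anova` object.
#' @param ... Unused.
#' @method tidy perm_anova
#' @export
tidy.perm_anova <- function(x, ...) {
  x$empirical
}

#' @rdname permutation_anova
#' @method glance perm_anova
#' @export
glance.perm_anova <- function(x, ...) {
  e <- x$empirical
  tibble(
    B = x$B,
    n_obs = x$n_obs,
    p_day = e$p_empirical[e$term == "day"],
    p_condition = e$p_empirical[e$term == "condition"],
    p_interaction = e$p_empirical[e$term == "day:condition"]
  )
}

#' Export permutation densities for plotting
#'
#' Writes one row per permutation per factor (`term`, `p_observed`,
#' `p_permuted`), enough to redraw the permutation-density figure and to
#' recompute every empirical p exactly.
#'
#' @param result A `perm_anova` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_density <- function(result, path) {
  stopifnot(inherits(result, "perm_anova"))
  terms <- colnames(result$perm_p)
  if (length(terms) == 0 || result$B < 1) abort("empty permutation result")
  out <- tibble(
    term = rep(terms, each = result$B),
    p_observed = rep(result$empirical$p_observed, each = result$B),
    p_permuted = as.vector(result$perm_p)
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Density plot of the permutation null per factor
#'
#' One density panel per factor of the permuted p values, with a vertical
#' line at the observed p value.
#'
#' @param object A `perm_anova` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perm_anova
#' @export
autoplot.perm_anova <- function(object, ...) {
  df <- tibble(
    term = rep(colnames(object$perm_p), each = object$B),
    p_permuted = as.vector(object$perm_p)
  )
  obs <- object$empirical
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_permuted)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(
      data = obs,
      ggplot2::aes(xintercept = .data$p_observed),
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "permuted ANOVA p value", y = "density") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.perm_anova
#' @export
plot_permutation_density <- function(object, ...) autoplot.perm_anova(object, ...)
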