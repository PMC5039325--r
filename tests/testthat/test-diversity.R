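# Independent oracle: pi as the mean over all explicitly enumerated unordered
# haplotype pairs of the indicator "alleles differ".
pairwise_pi_oracle <- function(c0, c1) {
  haps <- c(rep(0, c0), rep(1, c1))
  pairs <- utils::combn(length(haps), 2)
  mean(haps[pairs[1, ]] != haps[pairs[2, ]])
}

test_that("site_pi equals exhaustive haplotype-pair enumeration", {
  expect_equal(site_pi(4, 0), 0)
  expect_equal(site_pi(2, 2), 4 / 6)
  expect_equal(site_pi(1, 3), 3 / 6)
  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:20, 1)
    c1 <- sample(0:n, 1)
    expect_equal(site_pi(n - c1, c1), pairwise_pi_oracle(n - c1, c1),
                 tolerance = 1e-12)
  }
  expect_error(site_pi(1, 0), "2 haplotypes")
})

test_that("site_diversity counts alleles over non-missing calls only", {
  p <- write_mini_vcf(
    list(
      list(pos = 5, ref = "A", alt = "C",
           calls = c("0/1:60:30", "./.:60:30", "1/1:60:30")),
      list(pos = 6, ref = "A", alt = "C",
           calls = c("./.:60:30", "./.:60:30", "./.:60:30"))
    ),
    samples = paste0("s", 1:3)
  )
  sites <- site_diversity(read_vcf(p))
  expect_equal(nrow(sites), 1)            # all-missing site skipped
  expect_equal(attr(sites, "n_skipped"), 1)
  expect_equal(sites$n_hap, 4L)
  expect_equal(sites$c_alt, 3L)
  expect_equal(sites$pi_site, site_pi(1, 3))
})

test_that("windowed_pi bins 1-based inclusive windows and divides by W", {
  sites <- tibble::tibble(
    chrom = "chr1", pos = 5000L, n_hap = 4L, c_ref = 2L, c_alt = 2L,
    pi_site = site_pi(2, 2)
  )
  w <- windowed_pi(sites, 10000)
  expect_equal(w$bin_start, 1L)
  expect_equal(w$bin_end, 10000L)
  expect_equal(w$n_variants, 1L)
  expect_equal(w$pi, (4 / 6) / 10000, tolerance = 1e-12)

  # boundary: 10000 belongs to the first window, 10001 to the second
  s2 <- tibble::tibble(
    chrom = "chr1", pos = c(10000L, 10001L), n_hap = 4L,
    c_ref = 2L, c_alt = 2L, pi_site = site_pi(2, 2)
  )
  w2 <- windowed_pi(s2, 10000)
  expect_equal(w2$bin_start, c(1L, 10001L))
  expect_equal(w2$n_variants, c(1L, 1L))

  # windows without sites are not emitted; unsorted input is rejected
  expect_equal(nrow(windowed_pi(s2[0, ], 10000)), 0)
  expect_error(windowed_pi(s2[2:1, ], 10000), "ordering")
})

test_that("window pi totals conserve summed site pi", {
  set.seed(21)
  sites <- tibble::tibble(
    chrom = rep(c("chrA", "chrB"), c(300, 200)),
    pos = c(sort(sample.int(9e4, 300)), sort(sample.int(9e4, 200))),
    c_ref = sample(0:14, 500, replace = TRUE)
  ) |>
    dplyr::mutate(c_alt = 14L - c_ref, n_hap = 14L,
                  pi_site = site_pi(c_ref, c_alt))
  w <- windowed_pi(sites, 10000)
  expect_equal(sum(w$pi * 10000), sum(sites$pi_site), tolerance = 1e-12)
  expect_equal(sum(w$n_variants), nrow(sites))
})

test_that("removing or silencing polymorphism never increases window pi", {
  set.seed(22)
  sites <- tibble::tibble(
    chrom = "chr1", pos = sort(sample.int(10000, 50)),
    c_ref = sample(1:13, 50, replace = TRUE)
  ) |>
    dplyr::mutate(c_alt = 14L - c_ref, n_hap = 14L,
                  pi_site = site_pi(c_ref, c_alt))
  w_full <- windowed_pi(sites, 10000)$pi
  for (drop in sample(50, 10)) {
    expect_lte(windowed_pi(sites[-drop, ], 10000)$pi, w_full)
    mono <- sites
    mono$c_ref[drop] <- 14L
    mono$c_alt[drop] <- 0L
    mono$pi_site[drop] <- 0
    expect_lte(windowed_pi(mono, 10000)$pi, w_full)
  }
})

test_that("count_polymorphic requires both alleles within the group", {
  sites <- tibble::tibble(
    chrom = "c", pos = 1:3, n_hap = c(4L, 4L, 6L),
    c_ref = c(4L, 2L, 0L), c_alt = c(0L, 2L, 6L),
    pi_site = c(0, site_pi(2, 2), 0)
  )
  expect_equal(count_polymorphic(sites), 1L)
  expect_equal(count_polymorphic(sites[0, ]), 0L)
})

test_that("percent_loss reproduces the published SNP-count arithmetic", {
  expect_equal(round(percent_loss(480932, 452687), 2), 5.87)
  expect_equal(round(percent_loss(497167, 456671), 2), 8.15)
  expect_equal(percent_loss(3, 3), 0)
  expect_equal(percent_loss(10, 12), -20)            # gains are negative loss
  expect_equal(percent_loss(480932 * 3, 452687 * 3),  # scale invariance
               percent_loss(480932, 452687), tolerance = 1e-12)
  expect_error(percent_loss(0, 5), "positive")
})

test_that("excess_loss expresses relative extra loss", {
  expect_equal(excess_loss(18.61, 10.12), 100 * (18.61 - 10.12) / 10.12)
  expect_equal(round(excess_loss(18.61, 10.12)), 84)
  expect_equal(excess_loss(10, 10), 0)
  expect_equal(excess_loss(20, 10), 100)
  expect_error(excess_loss(5, 0), "positive")
})

test_that("group_summaries matches a brute-force recomputation", {
  sim <- simulate_cohorts(small_sim_config(seed = 5))
  per_group <- purrr::map(seq_len(4), function(i) {
    kept <- filter_variants(sim$calls[[i]])
    sites <- site_diversity(kept)
    wins <- windowed_pi(sites, 10000)
    list(
      sites = dplyr::mutate(sites, day = sim$groups$day[i],
                            condition = sim$groups$condition[i]),
      windows = dplyr::mutate(wins, day = sim$groups$day[i],
                              condition = sim$groups$condition[i])
    )
  })
  sites <- dplyr::bind_rows(purrr::map(per_group, "sites"))
  windows <- dplyr::bind_rows(purrr::map(per_group, "windows"))
  rep_ <- group_summaries(sites, windows)

  # brute force, independently of the report code
  for (i in seq_len(4)) {
    g <- per_group[[i]]
    row <- rep_$groups[rep_$groups$day == sim$groups$day[i] &
                       rep_$groups$condition == sim$groups$condition[i], ]
    expect_equal(row$mean_pi, mean(g$windows$pi), tolerance = 1e-12)
    expect_equal(row$n_polymorphic,
                 sum(g$sites$c_alt > 0 & g$sites$c_alt < g$sites$n_hap))
    expect_equal(row$n_windows, nrow(g$windows))
  }
  pick <- function(col, d, cond) {
    rep_$groups[[col]][rep_$groups$day == d & rep_$groups$condition == cond]
  }
  expect_equal(rep_$loss$low[rep_$loss$metric == "mean_pi"],
               percent_loss(pick("mean_pi", 1, "low"), pick("mean_pi", 7, "low")))
  expect_equal(rep_$loss$high[rep_$loss$metric == "n_snps"],
               percent_loss(pick("n_polymorphic", 1, "high"),
                            pick("n_polymorphic", 7, "high")))
  expect_equal(rep_$overall$pi, mean(windows$pi), tolerance = 1e-12)

  gl <- glance(rep_)
  expect_equal(gl$pct_loss_pi_low, rep_$loss$low[1])
  expect_equal(tidy(rep_), rep_$groups)
})

test_that("degenerate group configurations are rejected or trivial", {
  sites <- tidyr::expand_grid(day = c(1, 7), condition = c("low", "high")) |>
    dplyr::mutate(chrom = "c", pos = dplyr::row_number(), n_hap = 4L,
                  c_ref = 2L, c_alt = 2L, pi_site = site_pi(2, 2))
  windows <- sites |>
    dplyr::mutate(bin_start = 1L, bin_end = 10000L, n_variants = 1L,
                  pi = pi_site / 10000)
  # identical day-1 and day-7 values -> zero loss everywhere
  r <- group_summaries(sites, windows)
  expect_equal(r$loss$low, c(0, 0))
  expect_equal(r$loss$high, c(0, 0))
  # a missing group is a configuration error
  expect_error(group_summaries(sites[sites$day == 1, ],
                               windows[windows$day == 1, ]),
               "configuration error")
})

test_that("window TSV uses the --window-pi column layout", {
  w <- tibble::tibble(chrom = "chr1", bin_start = 1L, bin_end = 10000L,
                      n_variants = 2L, pi = 1e-4)
  f <- tempfile(fileext = ".tsv")
  write_windows_tsv(w, f)
  got <- utils::read.delim(f)
  expect_equal(names(got), c("CHROM", "BIN_START", "BIN_END", "N_VARIANTS", "PI"))
  expect_equal(got$PI, 1e-4)
})
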