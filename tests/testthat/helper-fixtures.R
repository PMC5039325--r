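# Shared fixture builders. Everything is generated in code; the only file
# fixture is the packaged 12-record toy VCF (inst/extdata/toy12.vcf).

toy_vcf_path <- function() {
  system.file("extdata", "toy12.vcf", package = "divloss")
}

# Hand-enumerated truth for the toy VCF under the default filter set:
# 200 indel (ALT "AT"), 300 multiallelic, 400 two DP=49 calls -> 5/7 present,
# 500 two GQ=19 calls -> 5/7 present, 1000 indel (REF "AT"). Everything else
# passes (600 has one DP=10 call and 800 one ./. call: 6/7 = 0.857 >= 0.8).
toy_surviving_pos <- c(100L, 600L, 700L, 800L, 900L, 1100L, 1200L)

# Minimal VCF text from a call-level spec: `records` is a list of lists with
# pos, ref, alt and a character vector of sample fields ("GT:DP:GQ").
write_mini_vcf <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(records, function(r) {
    paste(c(r$chrom %||% "chr1", r$pos, ".", r$ref, r$alt, ".", ".", ".",
            r$format %||% "GT:DP:GQ", r$calls), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tibble of window observations for the 2x2 ANOVA with given cell sizes.
make_observations <- function(n_per_cell = c(10, 10, 10, 10), seed = 1,
                              means = c(0, 0, 0, 0), sd = 1) {
  set.seed(seed)
  cells <- tidyr::expand_grid(day = c(1, 7), condition = c("low", "high"))
  purrr::map_dfr(seq_len(4), function(i) {
    tibble::tibble(
      value = stats::rnorm(n_per_cell[i], means[i], sd),
      day = cells$day[i],
      condition = cells$condition[i]
    )
  })
}

small_sim_config <- function(seed = 1, ...) {
  sim_config(n_sites = 800, n_chromosomes = 4, n_populations = 7,
             window_span = 5e4, seed = seed, ...)
}
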