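#' Genotype- and site-level filter settings
#'
#' Bundles the thresholds applied to a multi-sample VCF before diversity
#' estimation: a per-genotype depth/quality mask and per-site allele-count,
#' indel and missingness rules. Defaults reproduce a standard VCFtools-style
#' filter set (`--minDP 50 --minGQ 20 --max-missing 0.8 --min-alleles 2
#' --max-alleles 2 --remove-indels`); all thresholds are inclusive, matching
#' VCFtools behaviour (depth 50 and GQ 20 pass; 80% present passes).
#'
#' @param min_depth Minimum read depth for a genotype call to be kept.
#' @param max_missing_kept_fraction Minimum fraction of samples that must have
#'   a non-missing call after masking for the site to be kept (the VCFtools
#'   `--max-missing` convention, where 1 means no missing data allowed).
#' @param min_alleles,max_alleles Allowed total number of alleles (REF + ALT)
#'   at a site. The defaults keep biallelic sites only; multiallelic sites are
#'   dropped, not decomposed.
#' @param min_gq Minimum Phred-scaled genotype quality (GQ 20 is approximately
#'   99% call confidence).
#' @param drop_indels Drop sites where any allele is longer than one base.
#' @param depth_mode `"genotype"` (default) applies `min_depth` as a
#'   per-genotype mask, like VCFtools `--minDP`; `"site_mean"` instead drops
#'   whole sites whose mean depth across non-missing calls is below
#'   `min_depth`, like `--min-meanDP`.
#'
#' @return A list of class `"filter_config"`.
#' @examples
#' filter_config()
#' filter_config(min_depth = 20, depth_mode = "site_mean")
#' @export
filter_config <- function(min_depth = 50,
                          max_missing_kept_fraction = 0.8,
                          min_alleles = 2,
                          max_alleles = 2,
                          min_gq = 20,
                          drop_indels = TRUE,
                          depth_mode = c("genotype", "site_mean")) {
  depth_mode <- match.arg(depth_mode)
  if (!(max_missing_kept_fraction > 0 && max_missing_kept_fraction <= 1)) {
    abort("`max_missing_kept_fraction` must be in (0, 1].")
  }
  if (min_alleles > max_alleles) {
    abort("`min_alleles` must not exceed `max_alleles`.")
  }
  if (min_depth < 0 || min_gq < 0) {
    abort("`min_depth` and `min_gq` must be non-negative.")
  }
  structure(
    list(
      min_depth = min_depth,
      max_missing_kept_fraction = max_missing_kept_fraction,
      min_alleles = min_alleles,
      max_alleles = max_alleles,
      min_gq = min_gq,
      drop_indels = drop_indels,
      depth_mode = depth_mode
    ),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  cat(sprintf("  min depth        : %s (%s)\n", x$min_depth, x$depth_mode))
  cat(sprintf("  min GQ           : %s\n", x$min_gq))
  cat(sprintf("  min present frac : %s\n", x$max_missing_kept_fraction))
  cat(sprintf("  alleles          : %s..%s\n", x$min_alleles, x$max_alleles))
  cat(sprintf("  drop indels      : %s\n", x$drop_indels))
  invisible(x)
}
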