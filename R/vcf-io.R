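#' Read a multi-sample VCF into a long tibble of genotype calls
#'
#' Parses a VCF v4.x file carrying per-genotype GT (required) plus optional DP
#' and GQ subfields into one row per site x sample. Only the fields the
#' diversity pipeline consumes are interpreted; the remaining fixed columns
#' (ID, QUAL, FILTER, INFO) are carried through verbatim so a read/write
#' round trip preserves body lines byte for byte.
#'
#' Missing genotypes (`./.` or `.`) become `NA` allele columns. Absent or `.`
#' DP/GQ subfields are recorded as 0, so they fail any positive threshold in
#' [mask_genotypes()] -- the conservative reading when quality cannot be
#' verified.
#'
#' @param path Path to an uncompressed VCF file.
#' @return A tibble of class `vcf_calls` with columns `chrom`, `pos`, `id`,
#'   `ref`, `alt` (comma-joined ALT field), `qual`, `filter`, `info`,
#'   `n_alleles` (REF + ALTs), `is_indel`, `sample`, `gt1`, `gt2` (allele
#'   indices, `NA` when missing), `dp`, `gq`. Sample names (in header order)
#'   are in `attr(, "samples")`.
#' @seealso [write_vcf()], [mask_genotypes()], [filter_variants()]
#' @examples
#' vcf <- system.file("extdata", "toy12.vcf", package = "divloss")
#' calls <- read_vcf(vcf)
#' dplyr::count(calls, is_indel)
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  lines <- readLines(path)
  is_meta <- startsWith(lines, "##")
  hdr_idx <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_idx) != 1L) {
    abort(sprintf("malformed VCF header in %s: expected exactly one #CHROM line", path))
  }
  hdr <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10L || !identical(hdr[9], "FORMAT")) {
    abort(sprintf("malformed VCF header (line %d): need FORMAT and at least one sample column", hdr_idx))
  }
  samples <- hdr[-(1:9)]
  n_fields <- length(hdr)

  body_idx <- setdiff(seq_along(lines), c(which(is_meta), hdr_idx))
  body_idx <- body_idx[nzchar(lines[body_idx])]
  if (length(body_idx) == 0L) {
    return(new_vcf_calls(empty_calls_tibble(), samples = samples, source = path))
  }

  sp <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  lens <- lengths(sp)
  if (any(lens != n_fields)) {
    bad <- body_idx[which(lens != n_fields)[1]]
    abort(sprintf("format error at line %d: expected %d tab-separated fields, found %d",
                  bad, n_fields, lens[which(lens != n_fields)[1]]))
  }
  m <- matrix(unlist(sp, use.names = FALSE), ncol = n_fields, byrow = TRUE)

  n_rec <- nrow(m)
  n_smp <- length(samples)
  alt_raw <- m[, 5]
  alt_list <- strsplit(alt_raw, ",", fixed = TRUE)
  n_alts <- ifelse(alt_raw == ".", 0L, lengths(alt_list))
  is_indel <- nchar(m[, 4]) != 1L |
    vapply(alt_list, function(a) any(a != "." & nchar(a) != 1L), logical(1))

  fmt_keys <- strsplit(m[, 9], ":", fixed = TRUE)
  gt_pos <- vapply(fmt_keys, function(k) match("GT", k), integer(1))
  if (anyNA(gt_pos)) {
    abort(sprintf("format error at line %d: FORMAT lacks GT", body_idx[which(is.na(gt_pos))[1]]))
  }
  dp_pos <- vapply(fmt_keys, function(k) match("DP", k), integer(1))
  gq_pos <- vapply(fmt_keys, function(k) match("GQ", k), integer(1))

  gmat <- m[, 10:(9 + n_smp), drop = FALSE]
  gsp <- strsplit(as.vector(gmat), ":", fixed = TRUE)  # column-major: sample varies slowest
  rec_of <- rep.int(seq_len(n_rec), n_smp)

  pick <- function(pos_by_rec) {
    idx <- pos_by_rec[rec_of]
    out <- rep(NA_character_, length(gsp))
    ok <- !is.na(idx) & idx <= lengths(gsp)
    out[ok] <- mapply(function(x, i) x[[i]], gsp[ok], idx[ok], USE.NAMES = FALSE)
    out
  }
  gt_str <- pick(gt_pos)
  dp_str <- pick(dp_pos)
  gq_str <- pick(gq_pos)

  gt_ok <- grepl("^(\\.|[0-9]+)[/|](\\.|[0-9]+)$", gt_str) | gt_str == "."
  if (any(!gt_ok | is.na(gt_str))) {
    bad_call <- which(!gt_ok | is.na(gt_str))[1]
    abort(sprintf("format error at line %d: cannot parse genotype field %s",
                  body_idx[rec_of[bad_call]],
                  if (is.na(gt_str[bad_call])) "(missing GT)" else sQuote(gt_str[bad_call])))
  }
  a1 <- sub("^(\\.|[0-9]+)[/|].*$", "\\1", gt_str)
  a2 <- sub("^.*[/|](\\.|[0-9]+)$", "\\1", gt_str)
  a1[gt_str == "."] <- "."
  a2[gt_str == "."] <- "."
  gt1 <- suppressWarnings(as.integer(a1))
  gt2 <- suppressWarnings(as.integer(a2))
  # missing genotype <=> both alleles missing
  half <- xor(is.na(gt1), is.na(gt2))
  gt1[half] <- NA_integer_
  gt2[half] <- NA_integer_

  to_int0 <- function(x, what) {
    miss <- is.na(x) | x == "."
    v <- suppressWarnings(as.integer(x))
    bad <- !miss & is.na(v)
    if (any(bad)) {
      b <- which(bad)[1]
      abort(sprintf("format error at line %d: non-numeric %s value %s",
                    body_idx[rec_of[b]], what, sQuote(x[b])))
    }
    v[miss] <- 0L
    v
  }
  dp <- to_int0(dp_str, "DP")
  gq <- to_int0(gq_str, "GQ")

  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) {
    abort(sprintf("format error at line %d: non-numeric POS", body_idx[which(is.na(pos))[1]]))
  }

  # record-major rows: grouped by record, samples in header order
  rec_rep <- rep(seq_len(n_rec), each = n_smp)
  cell <- (rep(seq_len(n_smp), times = n_rec) - 1L) * n_rec + rec_rep  # column-major index
  out <- tibble(
    chrom = m[rec_rep, 1],
    pos = pos[rec_rep],
    id = m[rec_rep, 3],
    ref = m[rec_rep, 4],
    alt = alt_raw[rec_rep],
    qual = m[rec_rep, 6],
    filter = m[rec_rep, 7],
    info = m[rec_rep, 8],
    n_alleles = 1L + n_alts[rec_rep],
    is_indel = is_indel[rec_rep],
    sample = samples[rep(seq_len(n_smp), times = n_rec)],
    gt1 = gt1[cell],
    gt2 = gt2[cell],
    dp = dp[cell],
    gq = gq[cell]
  )
  new_vcf_calls(out, samples = samples, source = path)
}

empty_calls_tibble <- function() {
  tibble(
    chrom = character(), pos = integer(), id = character(), ref = character(),
    alt = character(), qual = character(), filter = character(),
    info = character(), n_alleles = integer(), is_indel = logical(),
    sample = character(), gt1 = integer(), gt2 = integer(),
    dp = integer(), gq = integer()
  )
}

new_vcf_calls <- function(x, samples, source = NA_character_) {
  structure(x,
    class = c("vcf_calls", class(tibble())),
    samples = samples, source = source
  )
}

#' Write genotype calls back to a VCF file
#'
#' Emits a VCF v4.2 file with a `GT:DP:GQ` FORMAT for every record, preserving
#' record order and the fixed columns carried by [read_vcf()]. Missing calls
#' are written as `./.`.
#'
#' @param calls A `vcf_calls` tibble (see [read_vcf()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  samples <- attr(calls, "samples")
  if (is.null(samples)) samples <- unique(calls$sample)
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  if (nrow(calls) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  gt <- ifelse(is.na(calls$gt1), "./.", paste0(calls$gt1, "/", calls$gt2))
  field <- paste(gt, calls$dp, calls$gq, sep = ":")
  # records keep first-appearance order; samples in header order within record
  key <- paste(calls$chrom, calls$pos, sep = "\r")
  rec <- match(key, unique(key))
  smp <- match(calls$sample, samples)
  n_rec <- max(rec)
  fm <- matrix("./.:0:0", nrow = n_rec, ncol = length(samples))
  fm[cbind(rec, smp)] <- field
  first <- !duplicated(rec)
  fixed <- cbind(calls$chrom[first], calls$pos[first], calls$id[first],
                 calls$ref[first], calls$alt[first], calls$qual[first],
                 calls$filter[first], calls$info[first], "GT:DP:GQ")
  body <- apply(cbind(fixed, fm), 1, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Mask low-confidence genotype calls
#'
#' Sets to missing any genotype whose depth or Phred-scaled quality falls
#' below the configured thresholds; thresholds are inclusive, so DP 50 and
#' GQ 20 pass the defaults. Depth masking is skipped when
#' `config$depth_mode == "site_mean"` (the site-level rule is then applied by
#' [site_passes()]). DP and GQ values themselves are retained.
#'
#' @param calls A `vcf_calls` tibble.
#' @param config A [filter_config()].
#' @return `calls` with sub-threshold genotypes set to `NA`.
#' @export
mask_genotypes <- function(calls, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  low <- calls$gq < config$min_gq
  if (config$depth_mode == "genotype") low <- low | calls$dp < config$min_depth
  calls$gt1[low] <- NA_integer_
  calls$gt2[low] <- NA_integer_
  calls
}

#' Site-level filter decisions
#'
#' Evaluates, per site, the allele-count, indel and missingness rules on calls
#' that have already been masked with [mask_genotypes()]. A site passes when
#' it is not an indel, carries exactly the allowed number of alleles (two, by
#' default), and at least `max_missing_kept_fraction` of its genotypes are
#' non-missing. With `depth_mode = "site_mean"` a mean-depth rule replaces the
#' per-genotype depth mask.
#'
#' @inheritParams mask_genotypes
#' @return A tibble with one row per site: `chrom`, `pos`, `pass` and, for
#'   failing sites, the first `reason` that applied (`indel`,
#'   `allele_count`, `low_mean_depth`, `missingness`).
#' @export
site_passes <- function(calls, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  key <- paste(calls$chrom, calls$pos, sep = "\r")
  sid <- match(key, unique(key))
  first <- !duplicated(sid)
  agg <- rowsum(
    cbind(n_calls = 1, n_present = !is.na(calls$gt1), depth = calls$dp),
    sid, reorder = FALSE
  )
  sites <- tibble(
    chrom = calls$chrom[first],
    pos = calls$pos[first],
    is_indel = calls$is_indel[first],
    n_alleles = calls$n_alleles[first],
    n_calls = agg[, "n_calls"],
    n_present = agg[, "n_present"],
    mean_depth = agg[, "depth"] / agg[, "n_calls"]
  )
  reason <- rep(NA_character_, nrow(sites))
  if (config$drop_indels) reason[sites$is_indel] <- "indel"
  bad_alleles <- sites$n_alleles < config$min_alleles |
    sites$n_alleles > config$max_alleles
  reason[is.na(reason) & bad_alleles] <- "allele_count"
  if (config$depth_mode == "site_mean") {
    reason[is.na(reason) & sites$mean_depth < config$min_depth] <- "low_mean_depth"
  }
  too_missing <- sites$n_present / sites$n_calls < config$max_missing_kept_fraction
  reason[is.na(reason) & too_missing] <- "missingness"
  tibble(
    chrom = sites$chrom, pos = sites$pos,
    pass = is.na(reason), reason = reason
  )
}

#' Apply the full genotype + site filter set
#'
#' Convenience wrapper chaining [mask_genotypes()] and [site_passes()]:
#' masks low-confidence genotypes, drops failing sites, and attaches a filter
#' log. Applying it twice gives the same result as applying it once.
#'
#' @inheritParams mask_genotypes
#' @return The filtered `vcf_calls` tibble. The dropped sites and their
#'   reasons are available via [filter_log()].
#' @examples
#' vcf <- system.file("extdata", "toy12.vcf", package = "divloss")
#' kept <- filter_variants(read_vcf(vcf))
#' filter_log(kept)
#' @export
filter_variants <- function(calls, config = filter_config()) {
  masked <- mask_genotypes(calls, config)
  verdict <- site_passes(masked, config)
  keep <- verdict[verdict$pass, c("chrom", "pos")]
  out <- dplyr::semi_join(masked, keep, by = c("chrom", "pos"))
  log <- verdict %>%
    filter(!.data$pass) %>%
    select("chrom", "pos", reason_dropped = "reason")
  out <- new_vcf_calls(out, samples = attr(calls, "samples"),
                       source = attr(calls, "source"))
  attr(out, "filter_log") <- log
  out
}

#' Retrieve the filter log attached by [filter_variants()]
#'
#' @param calls A filtered `vcf_calls` tibble.
#' @return A tibble with columns `chrom`, `pos`, `reason_dropped`.
#' @export
filter_log <- function(calls) {
  log <- attr(calls, "filter_log")
  if (is.null(log)) {
    log <- tibble(chrom = character(), pos = integer(),
                  reason_dropped = character())
  }
  log
}

#' Write a filter log as TSV
#'
#' @param calls A filtered `vcf_calls` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_log <- function(calls, path) {
  write.table(filter_log(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
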