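#' Read a per-mutation VAF table from TSV or VCF
#'
#' TSV mode expects columns `chrom`, `pos`, `alt_count`, `depth` (header
#' required; extra columns ignored); `vaf` is computed as
#' `alt_count / depth`. VCF mode keeps PASS single-nucleotide variants whose
#' positions fall inside the intervals of a BED file of high-quality diploid
#' segments (BED is 0-based half-open, VCF 1-based: a variant at a BED
#' interval's `end` coordinate is excluded), and reads `alt_count`/`depth`
#' from the first sample's `AD` field.
#'
#' Malformed rows (negative counts, `alt_count > depth`, non-numeric
#' fields) are dropped with a per-row report; if more than `max_bad_frac` of
#' rows are bad the whole file is rejected.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param diploid_bed BED file path (required for VCF mode).
#' @param purity Sample purity in `(0, 1]`.
#' @param mean_depth Mean sequencing depth; defaults to the mean of `depth`.
#' @param min_alt_reads Call threshold (default 2).
#' @param max_bad_frac Maximum tolerated fraction of malformed rows.
#' @return A `vaf_sample` with provenance `"empirical"`.
#' @export
read_vaf_input <- function(path, format = c("tsv", "vcf"),
                           diploid_bed = NULL, purity = 1,
                           mean_depth = NULL, min_alt_reads = 2L,
                           max_bad_frac = 0.01) {
  format <- match.arg(format)
  stop_unless(file.exists(path), sprintf("file not found: %s", path))
  df <- if (format == "tsv") {
    read_vaf_tsv(path)
  } else {
    stop_unless(!is.null(diploid_bed), "VCF mode requires `diploid_bed`")
    read_vaf_vcf(path, diploid_bed)
  }
  bad <- !is.finite(df$alt_count) | !is.finite(df$depth) |
    df$alt_count < 0 | df$depth < df$alt_count | df$depth <= 0
  if (any(bad)) {
    warn(sprintf("%d malformed row(s) dropped (e.g. row %d)", sum(bad),
                 which(bad)[1]))
    if (mean(bad) > max_bad_frac) {
      abort(sprintf("%.1f%% of rows malformed (> %.1f%% allowed)",
                    100 * mean(bad), 100 * max_bad_frac))
    }
    df <- df[!bad, , drop = FALSE]
  }
  vaf_sample(alt_count = df$alt_count, depth = df$depth, chrom = df$chrom,
             pos = df$pos, mean_depth = mean_depth, purity = purity,
             min_alt_reads = min_alt_reads, provenance = "empirical")
}

read_vaf_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "pos", "alt_count", "depth")
  stop_unless(all(need %in% names(df)),
              paste("TSV must have columns:", paste(need, collapse = ", ")))
  tibble(chrom = as.character(df$chrom), pos = as.numeric(df$pos),
         alt_count = suppressWarnings(as.numeric(df$alt_count)),
         depth = suppressWarnings(as.numeric(df$depth)))
}

read_vaf_vcf <- function(path, bed_path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF input requires the vcfR package")
  }
  bed <- read_bed(bed_path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  is_snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE)
  is_pass <- fix$FILTER %in% c("PASS", ".") | is.na(fix$FILTER)
  pos <- as.numeric(fix$POS)
  # BED is 0-based half-open, VCF 1-based; a variant whose 1-based position
  # equals the interval's end coordinate is excluded (half-open convention)
  in_bed <- vapply(seq_len(nrow(fix)), function(i) {
    b <- bed[bed$chrom == fix$CHROM[i], , drop = FALSE]
    any(pos[i] > b$start & pos[i] < b$end)
  }, logical(1))
  keep <- which(is_snv & is_pass & in_bed)
  ad <- unname(vcfR::extract.gt(v, element = "AD")[, 1])
  parts <- strsplit(ad[keep], ",", fixed = TRUE)
  ref_n <- vapply(parts, function(x) suppressWarnings(as.numeric(x[1])),
                  numeric(1))
  alt_n <- vapply(parts, function(x) suppressWarnings(as.numeric(x[2])),
                  numeric(1))
  tibble(chrom = fix$CHROM[keep], pos = pos[keep], alt_count = alt_n,
         depth = ref_n + alt_n)
}

read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  stop_unless(ncol(df) >= 3, "BED needs at least 3 columns")
  tibble(chrom = as.character(df[[1]]), start = as.numeric(df[[2]]),
         end = as.numeric(df[[3]]))
}

#' Write / read a VAF sample as TSV
#'
#' Columns `chrom`, `pos`, `alt_count`, `depth`, `vaf` (coordinates are
#' synthetic placeholders for simulated data).
#'
#' @param sample A `vaf_sample`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vaf_tsv <- function(sample, path) {
  readr::write_tsv(as_tibble(sample), path, progress = FALSE)
  invisible(path)
}

#' Serialize a simulated pair batch as JSON lines
#'
#' One record per tumour: parameters, labels and the observed mutation
#' table; paired records share a `pair_id`.
#'
#' @param pairs List of [generate_pair()] results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_jsonl <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(pairs)) {
    for (arm in c("selected", "neutral")) {
      rec <- list(
        pair_id = i, arm = arm,
        labels = unclass(pairs[[i]][[arm]]$labels),
        mean_depth = attr(pairs[[i]][[arm]]$sample, "mean_depth"),
        purity = attr(pairs[[i]][[arm]]$sample, "purity"),
        mutations = as.data.frame(
          pairs[[i]][[arm]]$sample[, c("alt_count", "depth", "vaf")])
      )
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 8), con)
    }
  }
  invisible(path)
}

#' Write / read an evolution report as JSON
#'
#' The report round-trips: `read_report(write_report(x))` reproduces the
#' calls, posterior draws, cluster labels and QC flags.
#'
#' @param report An `evolution_report` from [run_estimate()].
#' @param path Output path.
#' @return `path` invisibly (`write_report`); a list (`read_report`).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evolution_report"))
  out <- list(
    mode = report$call$mode,
    n_subclones = report$call$n_subclones,
    p_selection = posterior_to_list(report$call$p_sel),
    p_n_subclones = lapply(report$call$p_nsub, posterior_to_list),
    subclone_frequencies = lapply(report$frequencies, posterior_to_list),
    clusters = as.data.frame(report$clusters),
    qc = report$qc,
    metadata = report$metadata
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

posterior_to_list <- function(s) {
  list(mean = s$mean, eti_lower = s$eti_lower, eti_upper = s$eti_upper,
       level = s$level, draws = s$draws)
}
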