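# Readers and writers: allele-count TSV, minimal pooled VCF, BED regions,
# population TSV and the YAML run configuration.

counts_cols <- function() {
  c("chrom", "pos_bp", "id", "ref", "alt",
    "high_ref", "high_alt", "low_ref", "low_alt")
}

#' Read pooled allele counts
#'
#' Reads per-SNP reference/alternate read counts for two contrasting pools,
#' either from the package's TSV dialect (columns CHROM, POS, ID, REF, ALT,
#' HIGH_REF, HIGH_ALT, LOW_REF, LOW_ALT; POS 1-based) or from a minimal
#' biallelic VCF whose two samples carry AD (allelic depth) fields, high pool
#' first. Multiallelic VCF records are skipped with a warning naming their
#' count.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return Pool-count tibble as produced by [sample_pool_reads()].
#' @export
read_allele_counts <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste("no such file:", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") read_counts_tsv(path) else read_counts_vcf(path)
}

read_counts_tsv <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           CHROM = readr::col_character(),
                           POS = readr::col_double(),
                           ID = readr::col_character(),
                           REF = readr::col_character(),
                           ALT = readr::col_character(),
                           HIGH_REF = readr::col_double(),
                           HIGH_ALT = readr::col_double(),
                           LOW_REF = readr::col_double(),
                           LOW_ALT = readr::col_double()
                         ))
  need <- c("CHROM", "POS", "ID", "REF", "ALT",
            "HIGH_REF", "HIGH_ALT", "LOW_REF", "LOW_ALT")
  if (!all(need %in% names(raw))) {
    abort(paste("TSV header must contain:", paste(need, collapse = ", ")))
  }
  counts <- raw |>
    select(chrom = "CHROM", pos_bp = "POS", id = "ID", ref = "REF",
           alt = "ALT", high_ref = "HIGH_REF", high_alt = "HIGH_ALT",
           low_ref = "LOW_REF", low_alt = "LOW_ALT") |>
    mutate(chrom = suppressWarnings(as.integer(.data$chrom)))
  bad <- which(counts$high_ref < 0 | counts$high_alt < 0 |
                 counts$low_ref < 0 | counts$low_alt < 0 |
                 is.na(counts$pos_bp))
  if (length(bad)) {
    abort(sprintf("malformed counts at data line %d of %s", bad[1], path))
  }
  counts
}

read_counts_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% character(0))
  if (any(multi)) {
    warn(sprintf("skipped %d multiallelic record(s)", sum(multi)))
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (ncol(ad) != 2) abort("expected exactly two pooled samples in the VCF")
  keep <- !multi
  split_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    list(ref = as.integer(vapply(parts, `[`, "", 1)),
         alt = as.integer(vapply(parts, `[`, "", 2)))
  }
  hi <- split_ad(ad[keep, 1])
  lo <- split_ad(ad[keep, 2])
  tibble(
    chrom = suppressWarnings(as.integer(gsub("^chr", "", fix$CHROM[keep]))),
    pos_bp = as.numeric(fix$POS[keep]),
    id = fix$ID[keep],
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    high_ref = hi$ref, high_alt = hi$alt,
    low_ref = lo$ref, low_alt = lo$alt
  )
}

#' Write pooled allele counts
#'
#' Writes the TSV dialect read back by [read_allele_counts()], or a minimal
#' biallelic VCF with two pooled samples carrying AD fields (high pool
#' first). Both round-trip losslessly.
#'
#' @param counts Pool-count tibble.
#' @param path Output file.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(counts, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!all(counts_cols() %in% names(counts))) {
    abort(paste("`counts` must have columns:", paste(counts_cols(), collapse = ", ")))
  }
  if (format == "tsv") {
    out <- counts |>
      select(CHROM = "chrom", POS = "pos_bp", ID = "id", REF = "ref",
             ALT = "alt", HIGH_REF = "high_ref", HIGH_ALT = "high_alt",
             LOW_REF = "low_ref", LOW_ALT = "low_alt")
    readr::write_tsv(out, path)
  } else {
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=anthomap",
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "high_pool", "low_pool", sep = "\t")
    )
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.\tAD\t%d,%d\t%d,%d",
                    counts$chrom, as.integer(counts$pos_bp), counts$id,
                    counts$ref, counts$alt,
                    counts$high_ref, counts$high_alt,
                    counts$low_ref, counts$low_alt)
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Write candidate regions as BED
#'
#' Converts internal 1-based inclusive intervals to BED's 0-based half-open
#' convention (`start - 1`, `end`). The name field carries the exceedance
#' level and the score is `1000 * |peak delta|`, clipped to `[0, 1000]`.
#'
#' @param regions Region tibble from [call_regions()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- "track name=anthomap_regions"
  if (nrow(regions) > 0) {
    lines <- c(lines, sprintf(
      "chr%s\t%d\t%d\t%s\t%d",
      regions$chrom,
      as.integer(regions$start_bp) - 1L,
      as.integer(regions$end_bp),
      paste0("P", regions$level),
      pmin(1000L, pmax(0L, as.integer(round(1000 * abs(regions$peak_delta)))))
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED regions file back to internal coordinates
#'
#' @param path BED file written by [write_regions_bed()].
#' @return Region tibble with 1-based inclusive `start_bp`, `end_bp`.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = integer(), start_bp = numeric(), end_bp = numeric(),
                  peak_delta = numeric(), n_windows = integer(),
                  level = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    chrom = as.integer(gsub("^chr", "", vapply(parts, `[`, "", 1))),
    start_bp = as.numeric(vapply(parts, `[`, "", 2)) + 1,
    end_bp = as.numeric(vapply(parts, `[`, "", 3)),
    peak_delta = as.numeric(vapply(parts, `[`, "", 5)) / 1000,
    n_windows = NA_integer_,
    level = as.numeric(sub("^P", "", vapply(parts, `[`, "", 4)))
  )
}

#' Write a population as TSV
#'
#' One row per individual: id, latent score, colour class, then the 0/1/2
#' red-parent allele dosage at every locus.
#'
#' @param pop An `anthomap_pop`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_population_tsv <- function(pop, path) {
  out <- pop$phenotype |>
    select("id", "latent", "colour_class") |>
    left_join(dosages(pop), by = "id")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a run configuration
#'
#' Loads a YAML configuration with blocks `seed`, `architecture`, `map`,
#' `simulation` and `scan`, fills defaults for anything omitted and
#' validates numeric ranges.
#'
#' @param path YAML file.
#' @return Named list with validated entries.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  cfg <- yaml::read_yaml(path) %||% list()
  defaults <- list(
    seed = 1L,
    simulation = list(n_f2 = 218L, n_family = 300L, pool_size = 50L,
                      mean_depth = 50, dispersion = 10, error_rate = 0.002,
                      score_noise_sd = 1.0),
    scan = list(min_depth = 10L, window_bp = 2e7, step_bp = 5e6,
                min_snps = 5L, min_consecutive = 3L, n_reps = 10000L,
                levels = c(0.05, 0.01)),
    map = list(n_markers = 200L, cm_per_mb = 0.5)
  )
  cfg <- utils::modifyList(defaults, cfg)
  sim <- cfg$simulation
  if (sim$mean_depth <= 0) abort("simulation.mean_depth must be positive")
  if (sim$error_rate < 0 || sim$error_rate >= 0.5) {
    abort("simulation.error_rate must be in [0, 0.5)")
  }
  if (sim$pool_size < 1) abort("simulation.pool_size must be >= 1")
  if (cfg$scan$window_bp < cfg$scan$step_bp || cfg$scan$step_bp <= 0) {
    abort("scan.window_bp >= scan.step_bp > 0 required")
  }
  cfg
}
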