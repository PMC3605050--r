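#' Read a per-population frequency table into cline datasets
#'
#' The table (TSV by default, CSV by file extension) has one row per
#' population with required columns `population` and `distance_km` (alias
#' `distance`), and per-locus data in one of two dialects:
#'
#' * count dialect: paired columns `<locus>_n` and `<locus>_k`;
#' * frequency dialect: a column `<locus>_freq` together with a shared
#'   per-population `n` column, from which `k = round(freq * n)`; rows
#'   where `freq * n` was not an integer are recorded in the `rounded`
#'   attribute.
#'
#' @param path File path.
#' @return A long tibble with columns `locus`, `population`, `distance`,
#'   `n`, `k`, ready for [fit_clines()]. Attribute `rounded` lists any
#'   frequency-dialect rounding.
#' @export
read_frequency_table <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  raw <- reader(path, show_col_types = FALSE)
  if ("distance" %in% names(raw) && !"distance_km" %in% names(raw)) {
    raw <- dplyr::rename(raw, distance_km = "distance")
  }
  missing_cols <- setdiff(c("population", "distance_km"), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("frequency table is missing required column(s): ",
                 paste0("`", missing_cols, "`", collapse = ", "), "."))
  }
  nk_loci <- unique(sub("_n$", "", grep("_n$", names(raw), value = TRUE)))
  nk_loci <- nk_loci[paste0(nk_loci, "_k") %in% names(raw)]
  fr_loci <- sub("_freq$", "", grep("_freq$", names(raw), value = TRUE))
  if (length(nk_loci) == 0 && length(fr_loci) == 0) {
    abort("no locus columns found (expected `<locus>_n`/`<locus>_k` pairs or `<locus>_freq`).")
  }
  if (length(fr_loci) > 0 && !"n" %in% names(raw)) {
    abort("frequency-dialect columns need a per-population `n` column to form counts.")
  }

  rounded <- tibble(locus = character(), population = character(),
                    line = integer())
  pieces <- list()
  for (lc in nk_loci) {
    n <- raw[[paste0(lc, "_n")]]
    k <- raw[[paste0(lc, "_k")]]
    bad <- which(is.na(n) | is.na(k) | k < 0 | k > n)
    if (length(bad) > 0) {
      abort(paste0("locus `", lc, "`: k must satisfy 0 <= k <= n; violated on line ",
                   paste(bad + 1L, collapse = ", "),
                   " (population ", paste(raw$population[bad], collapse = ", "),
                   ")."))
    }
    pieces[[lc]] <- tibble(locus = lc, population = raw$population,
                           distance = raw$distance_km,
                           n = as.integer(n), k = as.integer(k))
  }
  for (lc in fr_loci) {
    fr <- raw[[paste0(lc, "_freq")]]
    n <- raw$n
    bad <- which(is.na(fr) | fr < 0 | fr > 1 | is.na(n))
    if (length(bad) > 0) {
      abort(paste0("locus `", lc, "`: frequencies must lie in [0, 1] with n present; violated on line ",
                   paste(bad + 1L, collapse = ", "), "."))
    }
    k <- round(fr * n)
    off <- which(abs(fr * n - k) > 1e-8)
    if (length(off) > 0) {
      rounded <- dplyr::bind_rows(
        rounded, tibble(locus = lc, population = raw$population[off],
                        line = as.integer(off + 1L)))
    }
    pieces[[lc]] <- tibble(locus = lc, population = raw$population,
                           distance = raw$distance_km,
                           n = as.integer(n), k = as.integer(k))
  }
  out <- dplyr::bind_rows(pieces)
  attr(out, "rounded") <- rounded
  out
}

#' Write cline datasets as a wide frequency table
#'
#' Inverse of [read_frequency_table()]'s count dialect: one row per
#' population, columns `population`, `distance_km`, then `<locus>_n` /
#' `<locus>_k` pairs in locus order. Stable column and row order makes the
#' files diffable, and writing then re-reading then re-writing is
#' byte-identical.
#'
#' @param data Long tibble with columns `locus`, `population`, `distance`,
#'   `n`, `k` (as produced by [simulate_zone()] or
#'   [read_frequency_table()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(data, path) {
  data <- as_tibble(data)
  needed <- c("locus", "population", "distance", "n", "k")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  wide <- data |>
    dplyr::select(dplyr::all_of(needed)) |>
    tidyr::pivot_wider(names_from = "locus", values_from = c("n", "k"),
                       names_glue = "{locus}_{.value}") |>
    dplyr::rename(distance_km = "distance")
  loci <- unique(data$locus)
  ord <- c("population", "distance_km",
           as.vector(rbind(paste0(loci, "_n"), paste0(loci, "_k"))))
  readr::write_tsv(wide[, ord], path)
  invisible(path)
}

#' Read a genotype panel from TSV
#'
#' Expects columns `id`, `population`, `group`, then one column per locus
#' with genotypes coded either as dosages (0/1/2) or as `RR`/`RY`/`YY`
#' (focal-allele homozygote / heterozygote / other homozygote). Missing
#' genotypes may be `NA`, empty, or `.`.
#'
#' @param path File path.
#' @return A genotype panel tibble with numeric dosage locus columns.
#' @export
read_genotype_panel <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing_cols <- setdiff(c("id", "population", "group"), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("genotype panel is missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  loci <- setdiff(names(raw), c("id", "population", "group"))
  code <- c(RR = 2, RY = 1, YR = 1, YY = 0,
            `2` = 2, `1` = 1, `0` = 0)
  for (lc in loci) {
    v <- toupper(trimws(raw[[lc]]))
    v[v %in% c("", ".", "NA")] <- NA
    bad <- setdiff(unique(v[!is.na(v)]), names(code))
    if (length(bad) > 0) {
      abort(paste0("locus `", lc, "`: unrecognized genotype code(s): ",
                   paste(bad, collapse = ", "),
                   " (expected RR/RY/YY or 0/1/2)."))
    }
    raw[[lc]] <- unname(code[v])
  }
  raw
}

#' Read a genotype panel from a VCF
#'
#' Optional ingestion path for biallelic SNPs. Genotypes are converted to
#' focal-allele dosage per sample and joined to a sample map supplying
#' population and group labels. By default the focal ("R") allele is the
#' REF allele; use `r_allele = "alt"` when the reference sample belongs to
#' the other ecotype.
#'
#' Requires the suggested package `vcfR`.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param sample_map Data frame with columns `id` (sample names as in the
#'   VCF), `population`, `group`.
#' @param r_allele Which VCF allele counts as the focal allele.
#' @return A genotype panel tibble.
#' @export
read_genotype_vcf <- function(path, sample_map,
                              r_allele = c("ref", "alt")) {
  r_allele <- match.arg(r_allele)
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF ingestion requires the `vcfR` package.")
  }
  sample_map <- as_tibble(sample_map)
  missing_cols <- setdiff(c("id", "population", "group"), names(sample_map))
  if (length(missing_cols) > 0) {
    abort(paste0("`sample_map` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- vcfR::is.biallelic(vcf)
  if (!all(biallelic)) vcf <- vcf[biallelic, ]
  gt <- vcfR::extract.gt(vcf)
  ids <- vcfR::getID(vcf)
  ids[is.na(ids) | ids == "."] <- paste0(
    vcfR::getCHROM(vcf), "_", vcfR::getPOS(vcf))[is.na(ids) | ids == "."]
  rownames(gt) <- ids
  alt_dose <- function(g) {
    ifelse(is.na(g), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a) {
             a <- suppressWarnings(as.numeric(a))
             if (anyNA(a)) NA_real_ else sum(a > 0)
           }, numeric(1)))
  }
  dose <- apply(gt, 2, alt_dose)
  if (is.null(dim(dose))) dose <- matrix(dose, nrow = 1,
                                         dimnames = list(ids, colnames(gt)))
  if (r_allele == "ref") dose <- 2 - dose
  panel <- as_tibble(t(dose))
  panel$id <- colnames(gt)
  dplyr::inner_join(sample_map, panel, by = "id")
}
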