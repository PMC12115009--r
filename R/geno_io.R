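#' Read a genotype matrix from VCF or CSV
#'
#' VCF genotypes are read from the GT field with dosages counting the ALT
#' allele (`0/0` -> 0, `0/1` -> 1, `1/1` -> 2, `./.` -> missing). The CSV
#' dosage dialect is comma-separated with a header row of marker IDs, the
#' first column holding individual IDs, and missing coded `NA`.
#'
#' @param path file path.
#' @param format `"vcf"` or `"csv"` (default guessed from the extension).
#' @param map optional marker map data frame for CSV input.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "csv"), map = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "csv"
  if (!file.exists(path))
    sp_stop(sprintf("file not found: %s", path), "selfpred_io_error")
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_csv(path, map)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0)
    sp_stop(sprintf("no GT records parsed from %s", path), "selfpred_parse_error")
  # count ALT alleles irrespective of phasing separator
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  dos[ok] <- as.numeric(a1[ok]) + as.numeric(a2[ok])
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  marker <- fix$ID
  marker[is.na(marker) | marker == "."] <-
    paste0(fix$CHROM, "_", fix$POS)[is.na(marker) | marker == "."]
  rownames(dos) <- marker
  map <- data.frame(marker = marker, chrom = fix$CHROM,
                    pos_bp = as.numeric(fix$POS))
  genotype_matrix(t(dos), map)
}

read_genotypes_csv <- function(path, map = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    sp_stop(sprintf("dosage CSV %s has no marker columns", path), "selfpred_parse_error")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    sp_stop("duplicate individual ids in dosage CSV", "selfpred_validation_error")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(m, 2, function(x) all(is.na(x) | grepl("^[0-9.]+$", x))))[1]
    sp_stop(sprintf("non-numeric dosage values in column %d of %s", bad + 1, path),
            "selfpred_parse_error")
  }
  rownames(m) <- ids
  genotype_matrix(m, map)
}

#' Write a genotype matrix
#'
#' @param g a [genotype_matrix()] (integer dosages required for VCF output).
#' @param path output file.
#' @param format `"csv"` or `"vcf"`.
#' @export
write_genotypes <- function(g, path, format = c("csv", "vcf")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(id = g$individual_ids, g$dosage, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    d <- g$dosage
    if (any(!is.na(d) & d != round(d)))
      sp_stop("VCF output requires integer dosages (write before imputation)",
              "selfpred_validation_error")
    map <- g$map %||% data.frame(marker = g$marker_ids, chrom = 1L,
                                 pos_bp = seq_along(g$marker_ids))
    gt_code <- c("0/0", "0/1", "1/1")
    lines <- c("##fileformat=VCFv4.2",
               "##source=selfpred",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$individual_ids), collapse = "\t"))
    body <- vapply(seq_along(g$marker_ids), function(j) {
      dj <- d[, j]
      gt <- ifelse(is.na(dj), "./.", gt_code[dj + 1])
      paste(c(map$chrom[j], map$pos_bp[j], g$marker_ids[j], "A", "T", ".",
              "PASS", ".", "GT", gt), collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), path)
  }
  invisible(path)
}

#' SNP quality control
#'
#' Removes markers with minor allele frequency strictly below `maf_min` or
#' call rate strictly below `callrate_min` (boundary values are retained),
#' after first removing individuals with more than `ind_missing_max` missing
#' calls. A marker failing both filters is attributed to the MAF filter.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min MAF threshold (default 0.05).
#' @param callrate_min call-rate threshold (default 0.95).
#' @param ind_missing_max individual-level missingness ceiling (default 0.95).
#' @return list with elements `genotypes` (filtered) and `report` (class
#'   `qc_report`): marker/individual counts and per-filter id lists.
#' @export
qc_filter <- function(g, maf_min = 0.05, callrate_min = 0.95,
                      ind_missing_max = 0.95) {
  d <- g$dosage
  ind_miss <- rowMeans(is.na(d))
  drop_ind <- g$individual_ids[ind_miss > ind_missing_max]
  if (length(drop_ind)) d <- d[setdiff(rownames(d), drop_ind), , drop = FALSE]

  freq <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  callrate <- colMeans(!is.na(d))
  fail_maf <- is.na(maf) | maf < maf_min
  fail_cr <- callrate < callrate_min & !fail_maf
  keep <- !(fail_maf | fail_cr)
  report <- structure(list(
    n_markers_in = ncol(g$dosage),
    n_removed_maf = sum(fail_maf),
    n_removed_callrate = sum(fail_cr),
    n_markers_out = sum(keep),
    n_individuals_in = nrow(g$dosage),
    n_removed_individuals = length(drop_ind),
    removed_maf = colnames(d)[fail_maf],
    removed_callrate = colnames(d)[fail_cr],
    removed_individuals = drop_ind,
    maf_min = maf_min, callrate_min = callrate_min,
    ind_missing_max = ind_missing_max), class = "qc_report")
  if (!any(keep))
    warning("qc_filter removed every marker", call. = FALSE)
  out <- genotype_matrix(d[, keep, drop = FALSE],
                         if (is.null(g$map)) NULL else
                           g$map[match(colnames(d)[keep], g$map$marker), ])
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("<qc_report> %d markers in; %d removed (MAF < %.3g), ",
                     "%d removed (call rate < %.3g); %d out. ",
                     "%d of %d individuals removed (> %.0f%% missing).\n"),
              x$n_markers_in, x$n_removed_maf, x$maf_min,
              x$n_removed_callrate, x$callrate_min, x$n_markers_out,
              x$n_removed_individuals, x$n_individuals_in,
              100 * x$ind_missing_max))
  invisible(x)
}

#' Mean-impute missing dosages
#'
#' Each missing dosage is replaced by twice the marker's counted-allele
#' frequency (the column mean of non-missing entries), which preserves
#' column means and is the standard preparation for VanRaden-type matrices.
#'
#' @param g a [genotype_matrix()].
#' @return A [genotype_matrix()] with real-valued dosages and no missing
#'   entries.
#' @export
impute_mean <- function(g) {
  d <- g$dosage
  if (!anyNA(d)) return(g)
  allmiss <- which(colSums(!is.na(d)) == 0)
  if (length(allmiss))
    sp_stop(sprintf("marker(s) with all entries missing cannot be imputed: %s",
                    paste(head(colnames(d)[allmiss], 5), collapse = ", ")),
            "selfpred_validation_error")
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  genotype_matrix(d, g$map)
}

#' Read/write helper tables (pedigree, phenotypes, marker map)
#'
#' CSV round-trip helpers for the remaining study tables.
#'
#' @param path file path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$sire[df$sire %in% c("", "NA", "0")] <- NA
  df$dam[df$dam %in% c("", "NA", "0")] <- NA
  pedigree(df)
}

#' @rdname table_io
#' @param ped a [pedigree()].
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @param trait trait column name.
#' @export
read_phenotypes <- function(path, trait = "dbh_cm") {
  phenotype_table(utils::read.csv(path, stringsAsFactors = FALSE), trait = trait)
}

#' @rdname table_io
#' @param ph a [phenotype_table()].
#' @export
write_phenotypes <- function(ph, path) {
  utils::write.csv(as.data.frame(ph), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
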