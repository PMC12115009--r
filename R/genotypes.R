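#' Genotype matrix container
#'
#' Holds an individuals-by-markers dosage matrix (counted-allele dosages 0/1/2,
#' `NA` for missing calls), an optional marker map (chromosome, physical
#' position) and the per-marker counted-allele frequency computed from
#' non-missing entries. Imputed matrices (see [impute_mean()]) may hold
#' real-valued dosages.
#'
#' @param dosage numeric matrix, rows = individuals, columns = markers.
#'   Row and column names are used as individual and marker identifiers.
#' @param map optional data frame with columns `marker`, `chrom`, `pos_bp`.
#' @return An object of class `genotype_matrix` with elements `dosage`,
#'   `map`, `allele_freq`, `individual_ids`, `marker_ids`.
#' @export
genotype_matrix <- function(dosage, map = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("IND", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("M", seq_len(ncol(dosage)))
  if (anyDuplicated(rownames(dosage)))
    sp_stop("duplicate individual ids in genotype matrix", "selfpred_validation_error")
  if (anyDuplicated(colnames(dosage)))
    sp_stop("duplicate marker ids in genotype matrix", "selfpred_validation_error")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2))
    sp_stop("dosages must lie in [0, 2]", "selfpred_validation_error")
  if (!is.null(map)) {
    map <- as.data.frame(map)
    stopifnot(all(c("marker", "chrom", "pos_bp") %in% names(map)))
    map <- map[match(colnames(dosage), map$marker), , drop = FALSE]
    rownames(map) <- NULL
  }
  obj <- list(
    dosage = dosage,
    map = map,
    allele_freq = colMeans(dosage, na.rm = TRUE) / 2,
    individual_ids = rownames(dosage),
    marker_ids = colnames(dosage)
  )
  class(obj) <- "genotype_matrix"
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dosage
  miss <- mean(is.na(d))
  cat(sprintf("<genotype_matrix> %d individuals x %d markers (%.2f%% missing)\n",
              nrow(d), ncol(d), 100 * miss))
  if (!is.null(x$map))
    cat(sprintf("  map: %d chromosomes\n", length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# Subset individuals and/or markers, keeping map and frequencies consistent.
subset_genotypes <- function(g, individuals = NULL, markers = NULL) {
  d <- g$dosage
  if (!is.null(individuals)) d <- d[individuals, , drop = FALSE]
  if (!is.null(markers)) d <- d[, markers, drop = FALSE]
  map <- g$map
  if (!is.null(map)) map <- map[match(colnames(d), map$marker), , drop = FALSE]
  genotype_matrix(d, map)
}

#' Pedigree container
#'
#' @param records data frame with columns `id`, `sire`, `dam` (unknown parents
#'   coded `NA`). Selfed individuals have `sire == dam`. An optional `cohort`
#'   column is preserved.
#' @return An object of class `pedigree`: the records reordered so that
#'   parents precede offspring, with the derived order retained.
#' @export
pedigree <- function(records) {
  ped <- as.data.frame(records)
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  if (anyDuplicated(ped$id))
    sp_stop("duplicate ids in pedigree", "selfpred_pedigree_error")
  for (col in c("sire", "dam")) {
    known <- !is.na(ped[[col]])
    if (any(known & !(ped[[col]] %in% ped$id)))
      sp_stop(sprintf("pedigree column '%s' refers to unlisted individuals", col),
              "selfpred_pedigree_error")
  }
  ped <- topo_sort_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn topological sort; cycles reported with an offending individual.
topo_sort_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  parents <- cbind(idx[ped$sire], idx[ped$dam])
  indeg <- rowSums(!is.na(parents))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in parents[i, ]) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  order <- integer(0)
  ready <- which(indeg == 0)
  while (length(ready)) {
    i <- ready[1]; ready <- ready[-1]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0) ready <- c(ready, ch)
    }
  }
  if (length(order) < n) {
    stuck <- ped$id[setdiff(seq_len(n), order)][1]
    sp_stop(sprintf("pedigree contains a cycle involving '%s'", stuck),
            "selfpred_pedigree_error")
  }
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Phenotype table
#'
#' @param df data frame with columns `id`, `block` and a trait column
#'   (default `dbh_cm`, in cm). Unphenotyped individuals (e.g. orchard
#'   candidates) carry `NA` trait values.
#' @param trait name of the trait column.
#' @return A validated data frame of class `phenotype_table`.
#' @export
phenotype_table <- function(df, trait = "dbh_cm") {
  df <- as.data.frame(df)
  stopifnot(all(c("id", "block", trait) %in% names(df)))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    sp_stop("at most one phenotype record per id", "selfpred_validation_error")
  attr(df, "trait") <- trait
  class(df) <- c("phenotype_table", "data.frame")
  df
}
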