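#' Pairwise linkage disequilibrium
#'
#' For all same-chromosome marker pairs within `max_distance_bp`, computes
#' the composite (unphased, genotypic) `r^2` as the squared Pearson
#' correlation of dosage vectors; optionally the gametic disequilibrium
#' coefficient `D` from EM-estimated haplotype frequencies. Monomorphic
#' markers and markers below `min_maf` are excluded (counted in the
#' `"n_skipped"` attribute).
#'
#' @param g a [genotype_matrix()] with a marker map.
#' @param max_distance_bp maximum pair distance (default `Inf`).
#' @param min_maf minimum MAF for a marker to enter pairs (default 0.05).
#' @param with_D also estimate `D` by the two-locus EM algorithm.
#' @return data frame of class `ld_pair_table`: `marker_i`, `marker_j`,
#'   `chrom`, `distance_bp`, `r2` (and `D` when requested).
#' @export
ld_pairs <- function(g, max_distance_bp = Inf, min_maf = 0.05,
                     with_D = FALSE) {
  if (is.null(g$map))
    sp_stop("ld_pairs requires a marker map", "selfpred_validation_error")
  d <- g$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  usable <- which(!is.na(maf) & maf >= min_maf &
                    apply(d, 2, function(x) stats::sd(x, na.rm = TRUE) > 0))
  n_skipped <- ncol(d) - length(usable)
  out <- list()
  for (ch in unique(g$map$chrom)) {
    cols <- intersect(which(g$map$chrom == ch), usable)
    if (length(cols) < 2) next
    sub <- d[, cols, drop = FALSE]
    pos <- g$map$pos_bp[cols]
    cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    ij <- which(upper.tri(cc), arr.ind = TRUE)
    dist <- abs(pos[ij[, 2]] - pos[ij[, 1]])
    keep <- dist <= max_distance_bp
    ij <- ij[keep, , drop = FALSE]
    if (!nrow(ij)) next
    tab <- data.frame(marker_i = colnames(sub)[ij[, 1]],
                      marker_j = colnames(sub)[ij[, 2]],
                      chrom = ch, distance_bp = dist[keep],
                      r2 = cc[ij]^2, stringsAsFactors = FALSE)
    if (with_D)
      tab$D <- mapply(function(a, b) em_haplotype_D(sub[, a], sub[, b]),
                      ij[, 1], ij[, 2])
    out[[length(out) + 1]] <- tab
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(marker_i = character(0), marker_j = character(0),
               chrom = integer(0), distance_bp = numeric(0), r2 = numeric(0))
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  class(res) <- c("ld_pair_table", "data.frame")
  res
}

# Two-locus EM for haplotype frequency p(AB) from unphased dosages;
# D = p(AB) - p(A) p(B).
em_haplotype_D <- function(x, y, max_iter = 100, tol = 1e-10) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  pA <- mean(x) / 2
  pB <- mean(y) / 2
  pAB <- pA * pB
  amb <- x == 1 & y == 1  # double heterozygotes: phase ambiguous
  # AB-haplotype count is determined for every other genotype pair
  cAB <- vapply(seq_len(n), function(i) {
    xi <- x[i]; yi <- y[i]
    if (xi == 1 && yi == 1) return(NA_real_)  # ambiguous
    # determined: number of AB haplotypes in the two chromosomes
    if (xi == 2) return(yi)           # both carry A: AB count = yi
    if (yi == 2) return(xi)
    if (xi == 0 || yi == 0) return(0)
    return(min(xi, yi))               # unreachable for biallelic dosages
  }, numeric(1))
  for (it in seq_len(max_iter)) {
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
    denom <- pAB * pab + pAb * paB
    frac <- if (denom > 0) pAB * pab / denom else 0.5
    nAB <- sum(cAB, na.rm = TRUE) + sum(amb) * frac
    pAB_new <- nAB / (2 * n)
    if (abs(pAB_new - pAB) < tol) { pAB <- pAB_new; break }
    pAB <- pAB_new
  }
  pAB - pA * pB
}

#' LD decay curve
#'
#' Bins pair distances and reports the mean `r^2` per bin.
#'
#' @param pairs an `ld_pair_table` from [ld_pairs()].
#' @param bin_width_bp bin width in base pairs.
#' @return data frame `(bin_mid_bp, mean_r2, n_pairs)`; empty bins between
#'   occupied ones are reported with `n_pairs = 0` and `NA` mean.
#' @export
ld_decay_curve <- function(pairs, bin_width_bp) {
  if (!nrow(pairs))
    sp_stop("empty LD pair table", "selfpred_validation_error")
  bin <- floor(pairs$distance_bp / bin_width_bp)
  bins <- seq(0, max(bin))
  agg <- data.frame(
    bin_mid_bp = (bins + 0.5) * bin_width_bp,
    mean_r2 = vapply(bins, function(b) {
      v <- pairs$r2[bin == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    n_pairs = vapply(bins, function(b) sum(bin == b), numeric(1)))
  agg
}

#' Plot an LD decay curve
#'
#' @param curve output of [ld_decay_curve()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_ld_decay <- function(curve, ...) {
  ok <- curve$n_pairs > 0
  graphics::plot(curve$bin_mid_bp[ok] / 1e3, curve$mean_r2[ok], type = "b",
                 xlab = "distance (kb)", ylab = expression(mean ~ r^2),
                 main = "LD decay", ...)
  invisible(curve)
}

#' Select the most polymorphic markers
#'
#' Markers ranked by expected heterozygosity `2pq` (descending), ties broken
#' by MAF (descending) then marker id; the top `n` are returned.
#'
#' @param g a [genotype_matrix()].
#' @param n number of markers to keep (default 723, a typical
#'   parentage-panel size).
#' @return a [genotype_matrix()] restricted to the selected markers.
#' @export
select_informative_markers <- function(g, n = 723) {
  if (n > length(g$marker_ids))
    sp_stop("n exceeds the number of markers", "selfpred_validation_error")
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  he <- 2 * p * (1 - p)
  maf <- pmin(p, 1 - p)
  ord <- order(-he, -maf, g$marker_ids)
  subset_genotypes(g, markers = g$marker_ids[ord[seq_len(n)]])
}

# Mendelian transition probability table: P(g_o | g_m, g_f) for dosages
# 0/1/2; parent with dosage g transmits the counted allele w.p. g/2.
mendelian_T <- local({
  Ttab <- array(0, c(3, 3, 3))
  for (gm in 0:2) for (gf in 0:2) {
    a <- gm / 2; b <- gf / 2
    Ttab[1, gm + 1, gf + 1] <- (1 - a) * (1 - b)
    Ttab[2, gm + 1, gf + 1] <- a * (1 - b) + b * (1 - a)
    Ttab[3, gm + 1, gf + 1] <- a * b
  }
  Ttab
})

# Per-locus likelihood components for the LOD with known mother:
# numerator (1-e) T(g_o | g_m, g_c) + e HWE(g_o); denominator replaces the
# candidate by a random father drawn from the allele frequencies.
lod_components <- function(go, gm, gc, p, e) {
  ok <- !is.na(go) & !is.na(gm) & !is.na(gc)
  # genotype calls index the Mendelian lookup table, so integral dosages
  go <- round(go[ok]); gm <- round(gm[ok]); gc <- round(gc[ok]); p <- p[ok]
  hwe <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)[cbind(seq_along(go), go + 1)]
  num <- (1 - e) * mendelian_T[cbind(go + 1, gm + 1, gc + 1)] + e * hwe
  # random father transmits counted allele w.p. p
  a <- gm / 2
  t_rand <- cbind((1 - a) * (1 - p),
                  a * (1 - p) + p * (1 - a),
                  a * p)[cbind(seq_along(go), go + 1)]
  den <- (1 - e) * t_rand + e * hwe
  list(num = num, den = den)
}

#' Paternity LOD score with known mother
#'
#' `LOD = sum_markers log P(g_o | g_m, g_c, e) / P(g_o | g_m, random
#' father)`, with Mendelian transition probabilities mixed with the
#' genotyping error rate `e` (an erroneous call is a draw from the marker's
#' Hardy-Weinberg genotype distribution). Markers missing in any of the
#' three genotypes are skipped. With `e = 0` an excluding candidate yields
#' `-Inf`.
#'
#' @param g a [genotype_matrix()] (typically from
#'   [select_informative_markers()]).
#' @param offspring,mother,candidate individual ids.
#' @param error_rate assumed genotyping error rate (default 0.05).
#' @return the LOD score (natural log).
#' @export
paternity_lod <- function(g, offspring, mother, candidate,
                          error_rate = 0.05) {
  d <- g$dosage
  for (id in c(offspring, mother, candidate))
    if (!id %in% rownames(d))
      sp_stop(sprintf("unknown id '%s'", id), "selfpred_lookup_error")
  p <- colMeans(d, na.rm = TRUE) / 2
  comp <- lod_components(d[offspring, ], d[mother, ], d[candidate, ], p,
                         error_rate)
  sum(log(comp$num)) - sum(log(comp$den))
}

#' Assign paternity by the Delta statistic
#'
#' For each offspring with known mother, computes the LOD of every candidate
#' father, the Delta statistic (difference between the top two LODs), and an
#' assignment: `selfed` when the best candidate is the mother herself,
#' `crossed` otherwise, `unassigned` when Delta falls below the significance
#' threshold. Confidence is `relaxed` at `delta_relaxed` and `strict` at
#' `delta_strict` (optional).
#'
#' @param g a [genotype_matrix()] holding offspring and candidates.
#' @param offspring_ids offspring to test.
#' @param mothers named character vector or single-column mapping,
#'   `mothers[offspring_id]` = known seed parent.
#' @param candidate_ids candidate fathers (must include the mothers).
#' @param error_rate assumed genotyping error rate.
#' @param delta_relaxed Delta threshold for assignment (e.g. from
#'   [delta_threshold()]; default 0 assigns every top candidate).
#' @param delta_strict optional higher-confidence threshold (`NA` disables).
#' @return data frame of class `paternity_result`: `offspring_id`,
#'   `known_mother`, `best_candidate`, `lod_best`, `lod_second`, `delta`,
#'   `assignment`, `confidence`.
#' @export
assign_paternity <- function(g, offspring_ids, mothers, candidate_ids,
                             error_rate = 0.05, delta_relaxed = 0,
                             delta_strict = NA) {
  d <- g$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  res <- lapply(offspring_ids, function(o) {
    mo <- mothers[[o]]
    lods <- vapply(candidate_ids, function(cand) {
      comp <- lod_components(d[o, ], d[mo, ], d[cand, ], p, error_rate)
      sum(log(comp$num)) - sum(log(comp$den))
    }, numeric(1))
    ord <- order(-lods, candidate_ids)
    best <- candidate_ids[ord[1]]
    lod_best <- lods[ord[1]]
    lod_second <- if (length(lods) > 1) lods[ord[2]] else -Inf
    delta <- lod_best - lod_second
    conf <- if (!is.na(delta_strict) && delta >= delta_strict) "strict"
            else if (delta >= delta_relaxed) "relaxed" else "none"
    assignment <- if (conf == "none") "unassigned"
                  else if (best == mo) "selfed" else "crossed"
    data.frame(offspring_id = o, known_mother = mo, best_candidate = best,
               lod_best = lod_best, lod_second = lod_second, delta = delta,
               assignment = assignment, confidence = conf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("paternity_result", "data.frame")
  out
}

#' Simulated significance threshold for the Delta statistic
#'
#' Simulates offspring of known parents drawn from the candidate pool
#' (genotyping error applied), computes each replicate's Delta and whether
#' its top candidate is the true father, and sets `delta_critical` to the
#' smallest Delta at which the assignments exceeding it reach the requested
#' success rate (a Cervus-style criterion).
#'
#' @param g a [genotype_matrix()] of the candidates (marker subset).
#' @param candidate_ids candidate parents.
#' @param confidence_level required proportion of correct assignments
#'   (default 0.80).
#' @param n_replicates simulation replicates (default 10000).
#' @param error_rate genotyping error rate (default 0.05).
#' @param seed simulation seed.
#' @return list of class `delta_threshold`: the inputs plus
#'   `delta_critical` and the realized `success_rate` above it.
#' @export
delta_threshold <- function(g, candidate_ids = g$individual_ids,
                            confidence_level = 0.80, n_replicates = 10000,
                            error_rate = 0.05, seed = 1) {
  if (length(candidate_ids) < 2) {
    warning("degenerate candidate pool: threshold 0", call. = FALSE)
    return(structure(list(confidence_level = confidence_level,
                          n_replicates = n_replicates, error_rate = error_rate,
                          delta_critical = 0, success_rate = NA_real_),
                     class = "delta_threshold"))
  }
  set.seed(derive_seed(seed, "paternity"))
  d <- g$dosage[candidate_ids, , drop = FALSE]
  if (anyNA(d)) d <- impute_mean(genotype_matrix(d, g$map))$dosage
  d <- round(d)
  m <- ncol(d)
  p <- colMeans(d) / 2
  nc <- length(candidate_ids)

  mo_idx <- sample.int(nc, n_replicates, replace = TRUE)
  fa_idx <- sample.int(nc, n_replicates, replace = TRUE)
  # offspring genotypes: one allele from each true parent, then error
  gm_mat <- d[mo_idx, , drop = FALSE]
  gf_mat <- d[fa_idx, , drop = FALSE]
  go <- matrix(rbinom(n_replicates * m, 1, gm_mat / 2) +
                 rbinom(n_replicates * m, 1, gf_mat / 2),
               n_replicates, m)
  if (error_rate > 0) {
    err <- matrix(runif(n_replicates * m) < error_rate, n_replicates, m)
    if (any(err)) {
      hw0 <- matrix((1 - p)^2, n_replicates, m, byrow = TRUE)
      hw1 <- matrix(2 * p * (1 - p), n_replicates, m, byrow = TRUE)
      u <- matrix(runif(n_replicates * m), n_replicates, m)
      redraw <- (u > hw0) + (u > hw0 + hw1)
      go[err] <- redraw[err]
    }
  }
  scores <- replicate_lods(go, gm_mat, d, p, error_rate)
  top2 <- t(apply(scores, 1, function(s) {
    o <- order(-s)
    c(o[1], s[o[1]], if (length(s) > 1) s[o[2]] else -Inf)
  }))
  delta <- top2[, 2] - top2[, 3]
  correct <- top2[, 1] == fa_idx

  ord <- order(-delta)
  cum_correct <- cumsum(correct[ord])
  rate <- cum_correct / seq_along(ord)
  ok <- which(rate >= confidence_level)
  if (length(ok)) {
    kmax <- max(ok)
    delta_critical <- if (kmax == length(ord)) 0 else delta[ord][kmax]
    success <- rate[kmax]
  } else {
    delta_critical <- Inf
    success <- rate[1]
  }
  structure(list(confidence_level = confidence_level,
                 n_replicates = n_replicates, error_rate = error_rate,
                 delta_critical = max(delta_critical, 0),
                 success_rate = success), class = "delta_threshold")
}

# LOD of every candidate for every simulated offspring, vectorized over
# replicates x markers through the Mendelian lookup table.
replicate_lods <- function(go, gm_mat, cand_dos, p, e) {
  n_rep <- nrow(go); m <- ncol(go); nc <- nrow(cand_dos)
  hwe_tab <- rbind((1 - p)^2, 2 * p * (1 - p), p^2)  # 3 x m
  hwe <- matrix(hwe_tab[cbind(as.vector(go) + 1, rep(seq_len(m), each = n_rep))],
                n_rep, m)
  a <- gm_mat / 2
  pm <- matrix(p, n_rep, m, byrow = TRUE)
  t_rand <- (go == 0) * (1 - a) * (1 - pm) +
    (go == 1) * (a * (1 - pm) + pm * (1 - a)) +
    (go == 2) * a * pm
  log_den <- rowSums(log((1 - e) * t_rand + e * hwe))
  scores <- matrix(0, n_rep, nc)
  base_idx <- go + 1 + 3 * gm_mat
  for (k in seq_len(nc)) {
    gc <- matrix(cand_dos[k, ], n_rep, m, byrow = TRUE)
    tv <- matrix(mendelian_T[base_idx + 9 * gc], n_rep, m)
    scores[, k] <- rowSums(log((1 - e) * tv + e * hwe)) - log_den
  }
  scores
}

#' Selfing summary from paternity assignments
#'
#' Accepts either a per-offspring `paternity_result` table or a per-family
#' count table (columns `family`/`genotype`, `n_selfed`, `n_crossed`,
#' optionally `n_unassigned`). Returns per-family and overall counts and
#' proportions (percentages to 2 decimals).
#'
#' @param results paternity results or family counts.
#' @return list of class `selfing_summary`: `per_family` data frame and
#'   `overall` (total, n_selfed, n_crossed, n_unassigned, pct_selfed,
#'   pct_crossed).
#' @export
classify_offspring <- function(results) {
  if (all(c("n_selfed", "n_crossed") %in% names(results))) {
    fam <- as.data.frame(results)
    famcol <- intersect(c("family", "genotype"), names(fam))[1]
    per_family <- data.frame(
      family = as.character(fam[[famcol]]),
      n_selfed = fam$n_selfed, n_crossed = fam$n_crossed,
      n_unassigned = fam$n_unassigned %||% rep(0, nrow(fam)),
      stringsAsFactors = FALSE)
  } else {
    stopifnot(inherits(results, "paternity_result") ||
                all(c("known_mother", "assignment") %in% names(results)))
    per_family <- do.call(rbind, lapply(split(results, results$known_mother),
      function(d) data.frame(
        family = d$known_mother[1],
        n_selfed = sum(d$assignment == "selfed"),
        n_crossed = sum(d$assignment == "crossed"),
        n_unassigned = sum(d$assignment == "unassigned"),
        stringsAsFactors = FALSE)))
    rownames(per_family) <- NULL
  }
  per_family$n_total <- per_family$n_selfed + per_family$n_crossed +
    per_family$n_unassigned
  per_family$pct_selfed <- round(100 * per_family$n_selfed /
                                   pmax(per_family$n_total, 1), 2)
  total <- sum(per_family$n_total)
  overall <- list(total = total,
                  n_selfed = sum(per_family$n_selfed),
                  n_crossed = sum(per_family$n_crossed),
                  n_unassigned = sum(per_family$n_unassigned),
                  pct_selfed = round(100 * sum(per_family$n_selfed) / total, 2),
                  pct_crossed = round(100 * sum(per_family$n_crossed) / total, 2))
  structure(list(per_family = per_family, overall = overall),
            class = "selfing_summary")
}

#' @export
print.selfing_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<selfing_summary> %d offspring: %d selfed (%.2f%%), %d crossed (%.2f%%), %d unassigned\n",
              o$total, o$n_selfed, o$pct_selfed, o$n_crossed, o$pct_crossed,
              o$n_unassigned))
  invisible(x)
}

#' Stacked-bar plot of per-family selfing proportions
#'
#' @param summary a `selfing_summary`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_selfing_summary <- function(summary, ...) {
  pf <- summary$per_family
  m <- t(as.matrix(pf[, c("n_selfed", "n_crossed", "n_unassigned")]))
  colnames(m) <- pf$family
  graphics::barplot(m, legend.text = c("selfed", "crossed", "unassigned"),
                    las = 2, main = "Selfed vs crossed offspring per family",
                    ...)
  invisible(summary)
}
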