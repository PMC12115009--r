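#' Simulation configuration
#'
#' Defines the synthetic population the generator produces: a set of clonal
#' parents crossed to themselves (selfing) or to another parent, genotyped at
#' linked biallelic markers, with a polygenic additive + dominance trait
#' measured on a randomized complete block design. Defaults emulate a
#' commercial Eucalyptus selfing program: 28 parents yielding 1-33 offspring
#' each, a ~62% selfing rate, ~10,000 SNPs, a DBH-like trait with mean
#' 12.25 cm and SD 4.18 cm on 30 blocks, and 62 unphenotyped orchard
#' candidates.
#'
#' @param n_parents number of founder (parent) clones.
#' @param offspring_per_parent integer range `c(min, max)`; each parent's
#'   offspring count is drawn uniformly from this range.
#' @param selfing_rate probability an offspring is selfed.
#' @param n_markers,n_chromosomes,chrom_length_bp marker panel layout.
#' @param adjacent_ld_rho correlation in `[0, 1)` between adjacent founder
#'   haplotype alleles (first-order Markov LD).
#' @param maf_floor minimum founder allele frequency.
#' @param h2_additive,d2_dominance narrow-sense heritability and dominance
#'   variance proportion of the trait; their sum must be < 1.
#' @param trait_mean,trait_sd trait mean and phenotypic SD (cm).
#' @param n_blocks,block_sd number of field blocks and SD of block effects (cm).
#' @param outlier_rate probability a field record is replaced by an extreme
#'   low value (exercises winsorization).
#' @param genotyping_error_rate probability a called genotype is replaced by a
#'   draw from the marker's Hardy-Weinberg genotype distribution.
#' @param missing_rate probability a genotype call is missing.
#' @param n_qtl number of causal markers (`NULL` = all markers causal,
#'   i.e. fully polygenic).
#' @param n_orchard number of offspring flagged as unphenotyped orchard
#'   candidates.
#' @param seed integer seed; identical configs reproduce identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_parents = 28L,
                       offspring_per_parent = c(1L, 33L),
                       selfing_rate = 0.62,
                       n_markers = 10000L,
                       n_chromosomes = 11L,
                       chrom_length_bp = 5e7,
                       adjacent_ld_rho = 0.5,
                       maf_floor = 0.05,
                       h2_additive = 0.4,
                       d2_dominance = 0.1,
                       trait_mean = 12.25,
                       trait_sd = 4.18,
                       n_blocks = 30L,
                       block_sd = 1.0,
                       outlier_rate = 0.02,
                       genotyping_error_rate = 0.01,
                       missing_rate = 0.02,
                       n_qtl = NULL,
                       n_orchard = 62L,
                       seed = 1L) {
  cfg <- list(n_parents = n_parents, offspring_per_parent = offspring_per_parent,
              selfing_rate = selfing_rate, n_markers = n_markers,
              n_chromosomes = n_chromosomes, chrom_length_bp = chrom_length_bp,
              adjacent_ld_rho = adjacent_ld_rho, maf_floor = maf_floor,
              h2_additive = h2_additive, d2_dominance = d2_dominance,
              trait_mean = trait_mean, trait_sd = trait_sd,
              n_blocks = n_blocks, block_sd = block_sd,
              outlier_rate = outlier_rate,
              genotyping_error_rate = genotyping_error_rate,
              missing_rate = missing_rate, n_qtl = n_qtl,
              n_orchard = n_orchard, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  for (f in c("n_parents", "n_markers", "n_chromosomes", "n_blocks"))
    if (!is_count(cfg[[f]])) config_error(f, "must be a count >= 1")
  opp <- cfg$offspring_per_parent
  if (length(opp) != 2 || !is_count(opp[1]) || !is_count(opp[2]) || opp[1] > opp[2])
    config_error("offspring_per_parent", "must be an increasing integer range [min, max]")
  for (f in c("selfing_rate", "outlier_rate", "genotyping_error_rate", "missing_rate"))
    if (!is_prob(cfg[[f]])) config_error(f, "must be a probability in [0, 1]")
  if (!is_prob(cfg$maf_floor) || cfg$maf_floor >= 0.5)
    config_error("maf_floor", "must lie in [0, 0.5)")
  if (!(is.numeric(cfg$adjacent_ld_rho) && cfg$adjacent_ld_rho >= 0 && cfg$adjacent_ld_rho < 1))
    config_error("adjacent_ld_rho", "must lie in [0, 1)")
  if (!(cfg$h2_additive >= 0 && cfg$h2_additive < 1))
    config_error("h2_additive", "must lie in [0, 1)")
  if (!(cfg$d2_dominance >= 0 && cfg$d2_dominance < 1))
    config_error("d2_dominance", "must lie in [0, 1)")
  if (cfg$h2_additive + cfg$d2_dominance >= 1)
    config_error("h2_additive", "plus d2_dominance must be < 1")
  if (cfg$chrom_length_bp < 1) config_error("chrom_length_bp", "must be >= 1")
  if (cfg$trait_sd <= 0) config_error("trait_sd", "must be > 0")
  if (cfg$block_sd < 0) config_error("block_sd", "must be >= 0")
  if (!is.null(cfg$n_qtl) && !is_count(cfg$n_qtl))
    config_error("n_qtl", "must be NULL or a count >= 1")
  if (!(is.numeric(cfg$n_orchard) && cfg$n_orchard >= 0 && cfg$n_orchard == floor(cfg$n_orchard)))
    config_error("n_orchard", "must be a non-negative integer")
  if (length(cfg$seed) != 1 || !is.finite(cfg$seed))
    config_error("seed", "must be a single finite number")
  invisible(cfg)
}

# Marker map: markers split evenly across chromosomes, sorted uniform positions.
make_marker_map <- function(cfg) {
  per <- rep(cfg$n_markers %/% cfg$n_chromosomes, cfg$n_chromosomes)
  extra <- cfg$n_markers %% cfg$n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  chrom <- rep(seq_len(cfg$n_chromosomes), per)
  pos <- unlist(lapply(per, function(m) sort(round(runif(m, 1, cfg$chrom_length_bp)))))
  data.frame(marker = sprintf("M%05d", seq_len(cfg$n_markers)),
             chrom = chrom, pos_bp = pos)
}

#' Simulate founder (parent) genotypes
#'
#' Founder haplotypes are drawn per chromosome from a latent Gaussian AR(1)
#' process with lag-one correlation `adjacent_ld_rho`, thresholded at each
#' locus so the allele's marginal frequency equals a target drawn uniformly
#' from `[maf_floor, 1 - maf_floor]` -- a first-order Markov chain on alleles
#' whose adjacent-locus correlation is the configured knob. Loci that come
#' out monomorphic in the founder sample are redrawn independently so every
#' marker is usable downstream.
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()] of the parents, with founder haplotypes kept
#'   in the `"haplotypes"` attribute for [simulate_progeny()].
#' @export
simulate_founders <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "simulate"))
  map <- make_marker_map(config)
  n_hap <- 2L * config$n_parents
  hap <- matrix(0L, n_hap, config$n_markers)
  target_p <- runif(config$n_markers, config$maf_floor, 1 - config$maf_floor)
  rho <- config$adjacent_ld_rho
  for (ch in unique(map$chrom)) {
    cols <- which(map$chrom == ch)
    z <- matrix(0, n_hap, length(cols))
    z[, 1] <- rnorm(n_hap)
    if (length(cols) > 1) {
      for (j in 2:length(cols))
        z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * rnorm(n_hap)
    }
    hap[, cols] <- (z < matrix(qnorm(target_p[cols]), n_hap, length(cols),
                               byrow = TRUE)) + 0L
  }
  # redraw loci monomorphic in the sample (breaks LD only at those columns)
  for (pass in 1:20) {
    mono <- which(colSums(hap) == 0L | colSums(hap) == n_hap)
    if (!length(mono)) break
    for (j in mono) hap[, j] <- rbinom(n_hap, 1L, target_p[j])
  }
  dos <- hap[seq(1, n_hap, by = 2), , drop = FALSE] +
         hap[seq(2, n_hap, by = 2), , drop = FALSE]
  rownames(dos) <- sprintf("P%02d", seq_len(config$n_parents))
  colnames(dos) <- map$marker
  g <- genotype_matrix(dos, map)
  attr(g, "haplotypes") <- hap
  attr(g, "target_freq") <- target_p
  g
}

# One gamete from a parent's two haplotypes: Haldane model, 100 cM per
# chromosome mapped linearly onto chrom_length_bp (Poisson(1) crossovers).
make_gamete <- function(hapA, hapB, map_split, chrom_len) {
  gam <- integer(length(hapA))
  for (ch in seq_along(map_split)) {
    cols <- map_split[[ch]]$cols
    pos <- map_split[[ch]]$pos
    nxo <- rpois(1, 1)
    xo <- if (nxo > 0) sort(runif(nxo, 0, chrom_len)) else numeric(0)
    seg <- findInterval(pos, xo)
    start <- sample.int(2L, 1L)
    use_a <- ((seg + start) %% 2L) == 0L
    gam[cols] <- ifelse(use_a, hapA[cols], hapB[cols])
  }
  gam
}

#' Simulate progeny by selfing and outcrossing
#'
#' Each parent yields a uniform number of offspring in
#' `offspring_per_parent`; each offspring is selfed with probability
#' `selfing_rate`, otherwise sired by a uniformly drawn other parent.
#' Meiosis follows the Haldane no-interference model with 100 cM per
#' chromosome. True genotypes, breeding values and dominance deviations are
#' recorded before genotyping errors (HWE-redraw model) and missingness are
#' applied, so ground truth is exact.
#'
#' @param founders output of [simulate_founders()].
#' @param config the same [sim_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()] of parents
#'   and offspring, observed calls), `pedigree` (a [pedigree()]), and `truth`
#'   (class `sim_truth`: `true_breeding_values`, `true_dominance_values`,
#'   `marker_effects`, `dominance_effects`, `realized_h2`, `parent_of`,
#'   `true_dosage`).
#' @export
simulate_progeny <- function(founders, config) {
  validate_sim_config(config)
  if (config$n_parents < 2 && config$selfing_rate < 1)
    config_error("n_parents", "must be >= 2 when selfing_rate < 1")
  set.seed(derive_seed(config$seed, "simulate") + 1L)
  hap <- attr(founders, "haplotypes")
  if (is.null(hap))
    sp_stop("founders must come from simulate_founders()", "selfpred_validation_error")
  map <- founders$map
  chrom_len <- config$chrom_length_bp
  map_split <- lapply(split(seq_len(nrow(map)), map$chrom),
                      function(ix) list(cols = ix, pos = map$pos_bp[ix]))
  parents <- founders$individual_ids
  np <- length(parents)

  rng <- seq(config$offspring_per_parent[1], config$offspring_per_parent[2])
  n_off_per <- rng[sample.int(length(rng), np, replace = TRUE)]
  mothers <- rep(seq_len(np), n_off_per)
  n_off <- length(mothers)
  selfed <- runif(n_off) < config$selfing_rate
  fathers <- integer(n_off)
  for (i in seq_len(n_off)) {
    fathers[i] <- if (selfed[i]) mothers[i] else {
      cand <- setdiff(seq_len(np), mothers[i])
      cand[sample.int(length(cand), 1L)]
    }
  }

  off_dos <- matrix(0L, n_off, config$n_markers)
  for (i in seq_len(n_off)) {
    m <- mothers[i]; f <- fathers[i]
    gm <- make_gamete(hap[2 * m - 1, ], hap[2 * m, ], map_split, chrom_len)
    gf <- make_gamete(hap[2 * f - 1, ], hap[2 * f, ], map_split, chrom_len)
    off_dos[i, ] <- gm + gf
  }
  off_ids <- sprintf("O%04d", seq_len(n_off))
  rownames(off_dos) <- off_ids
  colnames(off_dos) <- map$marker

  true_dos <- rbind(founders$dosage, off_dos)
  all_ids <- rownames(true_dos)

  # trait architecture on true dosages
  p <- colMeans(true_dos) / 2
  qtl <- if (is.null(config$n_qtl)) seq_len(config$n_markers) else
    sort(sample.int(config$n_markers, config$n_qtl))
  alpha <- numeric(config$n_markers)
  alpha[qtl] <- rnorm(length(qtl))
  Zc <- sweep(true_dos, 2, 2 * p)
  bv <- drop(Zc %*% alpha)
  var_bv_target <- config$h2_additive * config$trait_sd^2
  if (var_bv_target > 0 && stats::var(bv) > 0) {
    sc <- sqrt(var_bv_target / stats::var(bv))
    alpha <- alpha * sc; bv <- bv * sc
  } else {
    alpha[] <- 0; bv[] <- 0
  }
  delta <- numeric(config$n_markers)
  dv <- numeric(length(all_ids))
  if (config$d2_dominance > 0) {
    delta[qtl] <- rnorm(length(qtl))
    W <- dominance_design(true_dos, p)
    dv <- drop(W %*% delta)
    var_dv_target <- config$d2_dominance * config$trait_sd^2
    if (stats::var(dv) > 0) {
      sc <- sqrt(var_dv_target / stats::var(dv))
      delta <- delta * sc; dv <- dv * sc
    }
  }
  sigma_e2 <- config$trait_sd^2 * (1 - config$h2_additive - config$d2_dominance)
  realized_h2 <- if (stats::var(bv) + stats::var(dv) + sigma_e2 > 0)
    stats::var(bv) / (stats::var(bv) + stats::var(dv) + sigma_e2) else 0

  # observed calls: genotyping error then missingness
  obs <- true_dos
  if (config$genotyping_error_rate > 0) {
    err <- matrix(runif(length(obs)) < config$genotyping_error_rate,
                  nrow(obs), ncol(obs))
    if (any(err)) {
      for (j in which(colSums(err) > 0)) {
        rows <- which(err[, j])
        obs[rows, j] <- sample(0:2, length(rows), replace = TRUE,
                               prob = c((1 - p[j])^2, 2 * p[j] * (1 - p[j]), p[j]^2))
      }
    }
  }
  if (config$missing_rate > 0) {
    miss <- matrix(runif(length(obs)) < config$missing_rate, nrow(obs), ncol(obs))
    obs[miss] <- NA_real_
  }

  ped <- pedigree(data.frame(
    id = c(parents, off_ids),
    sire = c(rep(NA_character_, np), parents[fathers]),
    dam = c(rep(NA_character_, np), parents[mothers]),
    cohort = c(rep("parent", np), rep("offspring", n_off)),
    stringsAsFactors = FALSE))

  truth <- structure(list(
    true_breeding_values = setNames(bv, all_ids),
    true_dominance_values = setNames(dv, all_ids),
    marker_effects = setNames(alpha, map$marker),
    dominance_effects = setNames(delta, map$marker),
    realized_h2 = realized_h2,
    sigma_e2 = sigma_e2,
    qtl = map$marker[qtl],
    parent_of = data.frame(id = off_ids, dam = parents[mothers],
                           sire = parents[fathers], selfed = selfed,
                           stringsAsFactors = FALSE),
    true_dosage = true_dos), class = "sim_truth")

  list(genotypes = genotype_matrix(obs, map), pedigree = ped, truth = truth)
}

# Classical dominance design: entries (-2p^2, 2pq, -2q^2) for dosages (0,1,2).
dominance_design <- function(dos, p) {
  q <- 1 - p
  W <- matrix(0, nrow(dos), ncol(dos), dimnames = dimnames(dos))
  for (code in 0:2) {
    vals <- switch(as.character(code),
                   "0" = -2 * p^2, "1" = 2 * p * q, "2" = -2 * q^2)
    idx <- which(dos == code, arr.ind = TRUE)
    if (nrow(idx)) W[idx] <- vals[idx[, 2]]
  }
  W
}

#' Simulate phenotypes on a randomized complete block design
#'
#' Field individuals (all but the last `n_orchard` offspring) are assigned to
#' blocks round-robin; the phenotype is
#' `mean + block effect + breeding value + dominance deviation + residual`,
#' with residual variance set so the realized narrow-sense heritability
#' matches `h2_additive`. With probability `outlier_rate` a record is
#' replaced by an extreme low value. Orchard individuals get `NA` phenotypes.
#'
#' @param progeny result of [simulate_progeny()] (or its `genotypes` element).
#' @param truth the `sim_truth` from [simulate_progeny()].
#' @param config the same [sim_config()].
#' @return A [phenotype_table()] covering every individual; attribute
#'   `"orchard_ids"` lists the unphenotyped candidates.
#' @export
simulate_phenotypes <- function(progeny, truth, config) {
  validate_sim_config(config)
  g <- if (inherits(progeny, "genotype_matrix")) progeny else progeny$genotypes
  set.seed(derive_seed(config$seed, "simulate") + 2L)
  ids <- g$individual_ids
  n <- length(ids)
  is_off <- grepl("^O", ids)
  n_orch <- min(config$n_orchard, sum(is_off))
  orchard <- if (n_orch > 0) utils::tail(ids[is_off], n_orch) else character(0)
  field <- setdiff(ids, orchard)

  block_eff <- rnorm(config$n_blocks, 0, config$block_sd)
  block <- setNames(rep(NA_integer_, n), ids)
  block[field] <- rep(seq_len(config$n_blocks), length.out = length(field))
  # orchard individuals carry a nominal block label for table completeness
  block[orchard] <- 1L

  bv <- truth$true_breeding_values[ids]
  dv <- truth$true_dominance_values[ids]
  e <- rnorm(n, 0, sqrt(truth$sigma_e2))
  y <- config$trait_mean + block_eff[block] + bv + dv + e
  # extreme low outliers in the lower tail only
  out <- runif(n) < config$outlier_rate
  y[out] <- config$trait_mean - (4 + stats::rexp(sum(out))) * config$trait_sd
  y[ids %in% orchard] <- NA_real_

  ph <- phenotype_table(data.frame(id = ids, block = block, dbh_cm = y,
                                   stringsAsFactors = FALSE))
  attr(ph, "orchard_ids") <- orchard
  attr(ph, "n_outliers") <- sum(out & !(ids %in% orchard))
  ph
}

#' Simulate a complete study population
#'
#' Convenience wrapper chaining [simulate_founders()], [simulate_progeny()]
#' and [simulate_phenotypes()].
#'
#' @param config a [sim_config()].
#' @return list with `founders`, `genotypes`, `pedigree`, `phenotypes`,
#'   `truth`, `config`.
#' @export
simulate_population <- function(config = sim_config()) {
  fo <- simulate_founders(config)
  pr <- simulate_progeny(fo, config)
  ph <- simulate_phenotypes(pr$genotypes, pr$truth, config)
  list(founders = fo, genotypes = pr$genotypes, pedigree = pr$pedigree,
       phenotypes = ph, truth = pr$truth, config = config)
}
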