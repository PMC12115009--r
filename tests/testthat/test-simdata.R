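test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(n_parents = 0), "n_parents",
               class = "selfpred_config_error")
  expect_error(sim_config(selfing_rate = 1.2), "selfing_rate",
               class = "selfpred_config_error")
  expect_error(sim_config(h2_additive = 0.6, d2_dominance = 0.5),
               "h2_additive", class = "selfpred_config_error")
  expect_error(sim_config(adjacent_ld_rho = 1), "adjacent_ld_rho",
               class = "selfpred_config_error")
  expect_error(sim_config(n_parents = 1, selfing_rate = 0.5) |>
                 simulate_founders() |>
                 simulate_progeny(sim_config(n_parents = 1, selfing_rate = 0.5)),
               class = "selfpred_config_error")
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_parents = 6, offspring_per_parent = c(4, 6),
                    n_markers = 150, n_chromosomes = 2, n_blocks = 4,
                    n_orchard = 3, seed = 99)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$genotypes$dosage, p2$genotypes$dosage)
  expect_identical(as.data.frame(p1$phenotypes), as.data.frame(p2$phenotypes))
  expect_identical(p1$truth$true_breeding_values, p2$truth$true_breeding_values)
  expect_identical(serialize(p1$pedigree, NULL), serialize(p2$pedigree, NULL))
})

test_that("founder LD increases with the adjacent correlation parameter", {
  mk <- function(rho) {
    g <- simulate_founders(sim_config(n_parents = 50, n_markers = 2000,
                                      n_chromosomes = 4,
                                      adjacent_ld_rho = rho, seed = 5))
    # adjacent-pair dosage r2 per chromosome
    by_chr <- split(seq_len(nrow(g$map)), g$map$chrom)
    r2 <- unlist(lapply(by_chr, function(ix) {
      d <- g$dosage[, ix]
      diag(stats::cor(d[, -ncol(d)], d[, -1]))^2
    }))
    mean(r2, na.rm = TRUE)
  }
  r_hi <- mk(0.9); r_lo <- mk(0.1); r_null <- mk(0)
  expect_gt(r_hi, r_lo)
  # independence case: mean adjacent r2 close to the 1/n null expectation
  expect_lt(r_null, 0.05)
})

test_that("selfing produces sire == dam at the configured rate", {
  cfg <- sim_config(n_parents = 28, offspring_per_parent = c(19, 19),
                    selfing_rate = 1, n_markers = 100, n_chromosomes = 2,
                    seed = 3)
  pr <- simulate_progeny(simulate_founders(cfg), cfg)
  off <- pr$pedigree[!is.na(pr$pedigree$sire), ]
  expect_true(all(off$sire == off$dam))

  cfg2 <- sim_config(n_parents = 28, offspring_per_parent = c(19, 19),
                     selfing_rate = 0.62, n_markers = 100, n_chromosomes = 2,
                     seed = 17)
  pr2 <- simulate_progeny(simulate_founders(cfg2), cfg2)
  sel <- pr2$truth$parent_of$selfed
  n_off <- length(sel)
  ci <- qbinom(c(0.005, 0.995), n_off, 0.62)
  expect_gte(sum(sel), ci[1])
  expect_lte(sum(sel), ci[2])
})

test_that("selfed offspring of homozygous loci are identically homozygous", {
  cfg <- sim_config(n_parents = 4, offspring_per_parent = c(10, 10),
                    selfing_rate = 1, n_markers = 200, n_chromosomes = 2,
                    genotyping_error_rate = 0, missing_rate = 0, seed = 21)
  pr <- simulate_progeny(simulate_founders(cfg), cfg)
  dos <- pr$truth$true_dosage
  po <- pr$truth$parent_of
  for (i in seq_len(nrow(po))) {
    parent <- dos[po$dam[i], ]
    child <- dos[po$id[i], ]
    hom <- parent %in% c(0, 2)
    expect_identical(unname(child[hom]), unname(parent[hom]))
  }
})

test_that("progeny allele frequencies track founder frequencies", {
  cfg <- sim_config(n_parents = 10, offspring_per_parent = c(60, 60),
                    n_markers = 300, n_chromosomes = 3,
                    genotyping_error_rate = 0, missing_rate = 0, seed = 8)
  fo <- simulate_founders(cfg)
  pr <- simulate_progeny(fo, cfg)
  off_ids <- grep("^O", rownames(pr$truth$true_dosage), value = TRUE)
  f_found <- colMeans(fo$dosage) / 2
  f_prog <- colMeans(pr$truth$true_dosage[off_ids, ]) / 2
  expect_lt(mean(abs(f_prog - f_found)), 0.05)
  expect_gt(stats::cor(f_prog, f_found), 0.95)
})

test_that("one selfing generation yields pedigree inbreeding F = 0.5", {
  pop <- small_pop()
  A <- build_A(pop$pedigree)
  selfed <- pop$truth$parent_of$id[pop$truth$parent_of$selfed]
  expect_true(length(selfed) > 0)
  expect_equal(unname(diag(A$values)[selfed]), rep(1.5, length(selfed)))
})

test_that("phenotype signal follows the configured heritability", {
  # no genetic signal: breeding values are identically zero
  cfg0 <- sim_config(n_parents = 6, offspring_per_parent = c(10, 10),
                     h2_additive = 0, d2_dominance = 0, n_markers = 150,
                     n_chromosomes = 2, n_orchard = 0, seed = 4)
  pop0 <- simulate_population(cfg0)
  expect_equal(unname(stats::sd(pop0$truth$true_breeding_values)), 0)
  expect_gt(stats::var(pop0$phenotypes$dbh_cm, na.rm = TRUE), 0)

  # near-total heritability: phenotype is almost the breeding value
  cfg1 <- sim_config(n_parents = 20, offspring_per_parent = c(25, 25),
                     h2_additive = 0.95, d2_dominance = 0, block_sd = 0,
                     outlier_rate = 0, n_markers = 400, n_chromosomes = 3,
                     n_orchard = 0, seed = 12)
  pop1 <- simulate_population(cfg1)
  ph <- pop1$phenotypes
  ok <- !is.na(ph$dbh_cm)
  r <- stats::cor(ph$dbh_cm[ok], pop1$truth$true_breeding_values[ph$id[ok]])
  expect_gt(r^2, 0.9)
})

test_that("lower-tail outliers are injected at the configured rate", {
  cfg <- sim_config(n_parents = 20, offspring_per_parent = c(30, 30),
                    outlier_rate = 0.05, n_markers = 100, n_chromosomes = 2,
                    n_orchard = 0, seed = 6)
  pop <- simulate_population(cfg)
  n_out <- attr(pop$phenotypes, "n_outliers")
  n <- sum(!is.na(pop$phenotypes$dbh_cm))
  ci <- qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(n_out, ci[1])
  expect_lte(n_out, ci[2])
  # outliers sit in the lower tail only
  y <- pop$phenotypes$dbh_cm
  expect_lt(min(y, na.rm = TRUE), cfg$trait_mean - 3.9 * cfg$trait_sd)
})

test_that("orchard individuals are unphenotyped and flagged", {
  pop <- small_pop()
  orch <- attr(pop$phenotypes, "orchard_ids")
  expect_length(orch, pop$config$n_orchard)
  expect_true(all(is.na(pop$phenotypes$dbh_cm[pop$phenotypes$id %in% orch])))
})
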