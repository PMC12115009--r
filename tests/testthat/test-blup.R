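test_that("MME solutions match the dense GLS oracle on random fixtures", {
  for (s in 1:6) {
    fx <- random_mixed_fixture(n = c(12, 18, 21, 24, 27, 30)[s], seed = 100 + s)
    fit <- fit_mixed(fx$pheno, fx$K, max_iter = 2000)
    or <- gls_blup_oracle(fx$y, stats::model.matrix(~ fx$block),
                          fx$K$values, seq_along(fx$y),
                          fit$varcomp[["additive"]], fit$varcomp[["residual"]])
    expect_lt(max(abs(unname(fit$gebv) - unname(or$u))), 1e-6)
    expect_lt(max(abs(unname(fit$beta_hat) - unname(or$beta))), 1e-6)
  }
})

test_that("GEBVs equal the direct ridge-type solve at a fixed variance ratio", {
  fx <- random_mixed_fixture(n = 20, seed = 7)
  fit <- fit_mixed(fx$pheno, fx$K)
  s2a <- fit$varcomp[["additive"]]; s2e <- fit$varcomp[["residual"]]
  lambda <- s2e / s2a
  X <- stats::model.matrix(~ fx$block)
  # direct MME solve: u = (Z'Z + lambda K^-1)^-1 Z'(y - X beta)
  Kinv <- solve(fx$K$values)
  u_direct <- solve(diag(20) + lambda * Kinv,
                    fx$y - drop(X %*% fit$beta_hat))
  expect_lt(max(abs(unname(fit$gebv) - u_direct)), 1e-5)
})

test_that("constant phenotypes drive the additive variance to the boundary", {
  fx <- random_mixed_fixture(n = 15, seed = 3)
  ph <- fx$pheno
  ph$dbh_cm <- 7.5
  fit <- suppressWarnings(fit_mixed(ph, fx$K))
  expect_lt(fit$varcomp[["additive"]], 1e-6)
  expect_lt(max(abs(fit$gebv)), 1e-6)
})

test_that("REML log-likelihood is non-decreasing across EM iterations", {
  fx <- random_mixed_fixture(n = 25, seed = 11)
  fit <- fit_mixed(fx$pheno, fx$K)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))

  pop <- small_pop()
  fit2 <- fit_gblup(pop$phenotypes, pop$genotypes)
  expect_true(all(diff(fit2$loglik_trace) > -1e-6))
  expect_true(fit2$converged)
})

test_that("GEBVs are shrunken contractions of the fixed-effect residuals", {
  # the BLUP operator s2a K V^-1 has spectral norm < 1 in the kinship
  # eigenbasis, so the GEBV vector is strictly shorter than the residual
  for (s in 1:4) {
    fx <- random_mixed_fixture(n = 20, seed = 200 + s)
    fit <- fit_mixed(fx$pheno, fx$K)
    X <- stats::model.matrix(~ fx$block)
    r <- fx$y - drop(X %*% fit$beta_hat)
    expect_lt(sqrt(sum(fit$gebv^2)), sqrt(sum(r^2)))
    # and each GEBV stays well inside the data range
    expect_lt(max(abs(fit$gebv)), diff(range(fx$y)))
  }
})

test_that("ABLUP and GBLUP agree when given the same kinship", {
  fx <- random_mixed_fixture(n = 20, seed = 5)
  fa <- fit_ablup(fx$pheno, kinship = fx$K)
  fg <- fit_gblup(fx$pheno, kinship = fx$K)
  expect_lt(max(abs(fa$gebv - fg$gebv)), 1e-6)
  expect_equal(fa$varcomp, fg$varcomp, tolerance = 1e-8)
})

test_that("HBLUP equals GBLUP when everyone is genotyped and blend is 0", {
  pop <- small_pop()
  fg <- fit_gblup(pop$phenotypes, pop$genotypes)
  fh <- fit_hblup(pop$phenotypes, pop$pedigree, pop$genotypes, blend = 0)
  expect_lt(max(abs(fh$gebv[names(fg$gebv)] - fg$gebv)), 1e-6)
})

test_that("the dominance variance stays near zero on purely additive data", {
  hits <- 0
  n_rep <- 6
  for (s in 1:n_rep) {
    pop <- fixture_pop(n_parents = 10, offspring_per_parent = c(18, 22),
                       n_markers = 500, n_chromosomes = 3, h2_additive = 0.4,
                       d2_dominance = 0, outlier_rate = 0, n_orchard = 0,
                       missing_rate = 0, seed = 300 + s)
    fit <- suppressWarnings(fit_gblup_ad(pop$phenotypes, pop$genotypes,
                                         max_iter = 300))
    vc <- fit$varcomp
    if (vc[["dominance"]] < 0.15 * sum(vc, na.rm = TRUE)) hits <- hits + 1
  }
  expect_gte(hits, ceiling(n_rep / 2) + 1)
})

test_that("unphenotyped individuals get ranked GEBV predictions", {
  pop <- small_pop()
  fit <- fit_gblup(pop$phenotypes, pop$genotypes)
  orch <- attr(pop$phenotypes, "orchard_ids")
  tab <- predict_unphenotyped(fit)
  expect_setequal(tab$id, setdiff(names(fit$gebv), fit$obs_ids))
  expect_true(all(orch %in% tab$id))
  expect_equal(tab$rank, seq_len(nrow(tab)))
  expect_true(all(diff(tab$gebv) <= 1e-12))
  expect_error(predict_unphenotyped(fit, "nobody"),
               class = "selfpred_lookup_error")
})

test_that("ties in GEBV are ranked by id lexicographic order", {
  fake <- structure(list(gebv = c(b = 1, c = 1, a = 1), obs_ids = character(0),
                         model = "gblup"), class = "gs_fit")
  tab <- predict_unphenotyped(fake, c("b", "c", "a"))
  expect_equal(tab$id, c("a", "b", "c"))
  expect_equal(tab$rank, 1:3)
})

test_that("an orchard clone identical to a trained individual shares its GEBV", {
  pop <- small_pop()
  gi <- impute_mean(pop$genotypes)
  top_id <- pop$phenotypes$id[which.max(pop$phenotypes$dbh_cm)]
  d <- rbind(gi$dosage, clone = gi$dosage[top_id, ])
  rownames(d) <- c(rownames(gi$dosage), "clone")
  fit <- fit_gblup(pop$phenotypes, genotype_matrix(d, gi$map))
  expect_equal(unname(fit$gebv["clone"]), unname(fit$gebv[top_id]),
               tolerance = 1e-8)
})

test_that("heritability is recovered on a moderately sized simulation", {
  pop <- fixture_pop(n_parents = 16, offspring_per_parent = c(22, 28),
                     n_markers = 800, n_chromosomes = 4, h2_additive = 0.4,
                     d2_dominance = 0, outlier_rate = 0, n_orchard = 0,
                     seed = 77)
  fit <- fit_gblup(pop$phenotypes, pop$genotypes)
  expect_gt(fit$h2_hat, 0.15)
  expect_lt(fit$h2_hat, 0.65)
})
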