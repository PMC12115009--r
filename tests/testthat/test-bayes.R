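# small shared fixture: 60 individuals x 40 markers, moderate signal
bayes_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(314)
      n <- 60; m <- 40
      p <- runif(m, 0.15, 0.85)
      dos <- sapply(p, function(pp) rbinom(n, 2, pp))
      dimnames(dos) <- list(sprintf("i%03d", 1:n), sprintf("m%03d", 1:m))
      eff <- rnorm(m, 0, 0.15)
      y <- 12 + drop(scale(dos, scale = FALSE) %*% eff) + rnorm(n, 0, 1)
      cache <<- list(
        g = genotype_matrix(dos),
        ph = phenotype_table(data.frame(id = rownames(dos),
                                        block = rep(1:3, length.out = n),
                                        dbh_cm = y)))
    }
    cache
  }
})

test_that("a null phenotype yields null posterior marker effects", {
  fx <- bayes_fixture()
  ph0 <- fx$ph
  ph0$dbh_cm <- 0
  fit <- fit_bayes(fx$g, ph0, bayes_prior("brr"),
                   mcmc_settings(3000, 500, 5, seed = 1))
  eff <- fit$posterior$marker_effect_means
  sds <- fit$posterior$marker_effect_sds
  expect_true(all(abs(eff) <= 3 * pmax(sds, 1e-8)))
  expect_lt(max(abs(fit$gebv)), 0.5)
})

test_that("BayesB/C with pi fixed at 1 force all effects to exactly zero", {
  fx <- bayes_fixture()
  for (m in c("bayesb", "bayesc")) {
    fit <- fit_bayes(fx$g, fx$ph,
                     bayes_prior(m, pi = 1, estimate_pi = FALSE),
                     mcmc_settings(1000, 200, 2, seed = 2))
    expect_identical(max(abs(fit$posterior$marker_effect_means)), 0)
    expect_identical(max(fit$posterior$inclusion_prob), 0)
    expect_lt(max(abs(fit$gebv - mean(fit$gebv))), 1e-12)
  }
})

test_that("chains are reproducible under a seed and stable across seeds", {
  fx <- bayes_fixture()
  f1 <- fit_bayes(fx$g, fx$ph, bayes_prior("bayesa"),
                  mcmc_settings(4000, 1000, 5, seed = 9))
  f2 <- fit_bayes(fx$g, fx$ph, bayes_prior("bayesa"),
                  mcmc_settings(4000, 1000, 5, seed = 9))
  expect_identical(f1$posterior$marker_effect_means,
                   f2$posterior$marker_effect_means)
  expect_identical(f1$posterior$chains$sigma2_e, f2$posterior$chains$sigma2_e)

  f3 <- fit_bayes(fx$g, fx$ph, bayes_prior("bayesa"),
                  mcmc_settings(4000, 1000, 5, seed = 10))
  # posterior means agree across seeds within Monte-Carlo error
  se <- function(f) stats::sd(f$posterior$chains$sigma2_e) /
    sqrt(selfpred:::ess(f$posterior$chains$sigma2_e))
  mc_se <- sqrt(se(f1)^2 + se(f3)^2)
  expect_lt(abs(f1$posterior$sigma2_e - f3$posterior$sigma2_e), 4 * mc_se)
  expect_gt(stats::cor(f1$gebv, f3$gebv), 0.95)
})

test_that("BayesC with pi = 0 reduces to Bayesian ridge regression", {
  fx <- bayes_fixture()
  fc <- fit_bayes(fx$g, fx$ph,
                  bayes_prior("bayesc", pi = 0, estimate_pi = FALSE),
                  mcmc_settings(8000, 2000, 5, seed = 4))
  fr <- fit_bayes(fx$g, fx$ph, bayes_prior("brr"),
                  mcmc_settings(8000, 2000, 5, seed = 4))
  expect_true(all(fc$posterior$inclusion_prob == 1))
  expect_gt(stats::cor(fc$gebv, fr$gebv), 0.99)
})

test_that("BayesB concentrates inclusion probability on causal markers", {
  p_causal <- c(); p_null <- c()
  for (s in 1:3) {
    pop <- fixture_pop(n_parents = 12, offspring_per_parent = c(20, 25),
                       n_markers = 600, n_chromosomes = 3, h2_additive = 0.5,
                       d2_dominance = 0, n_qtl = 8, outlier_rate = 0,
                       n_orchard = 0, missing_rate = 0, seed = 400 + s)
    fit <- fit_bayes(pop$genotypes, pop$phenotypes, bayes_prior("bayesb"),
                     mcmc_settings(2500, 500, 5, seed = s))
    ip <- fit$posterior$inclusion_prob
    causal <- names(ip) %in% pop$truth$qtl
    p_causal <- c(p_causal, ip[causal])
    p_null <- c(p_null, sample(ip[!causal], 50))
  }
  wt <- stats::wilcox.test(p_causal, p_null, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("marker-based scoring is consistent with training GEBVs", {
  fx <- bayes_fixture()
  fit <- fit_bayes(fx$g, fx$ph, bayes_prior("bl"),
                   mcmc_settings(3000, 500, 5, seed = 6))
  tab <- gebv_from_markers(fit, fx$g)
  expect_equal(setNames(tab$gebv, tab$id)[names(fit$gebv)], fit$gebv,
               tolerance = 1e-12)

  # duplicate of a training individual scores identically
  d <- rbind(fx$g$dosage, dup = fx$g$dosage[1, ])
  rownames(d) <- c(rownames(fx$g$dosage), "dup")
  tab2 <- gebv_from_markers(fit, genotype_matrix(d))
  g2 <- setNames(tab2$gebv, tab2$id)
  expect_equal(unname(g2["dup"]), unname(g2[rownames(fx$g$dosage)[1]]))

  # an individual sitting exactly at the training centring has GEBV 0
  centre_row <- matrix(fit$posterior$centres, 1,
                       dimnames = list("cent", names(fit$posterior$centres)))
  tab3 <- gebv_from_markers(fit, genotype_matrix(rbind(d, cent = centre_row)))
  expect_equal(tab3$gebv[tab3$id == "cent"], 0, tolerance = 1e-12)

  # marker mismatch is a hard alignment error
  gbad <- genotype_matrix(fx$g$dosage[, 1:10])
  expect_error(gebv_from_markers(fit, gbad), class = "selfpred_alignment_error")
})
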