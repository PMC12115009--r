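#' Prior configuration for the Bayesian whole-genome regressions
#'
#' Marker effects are modelled with model-specific priors: a common Gaussian
#' variance (BRR), per-marker scaled-inverse-chi-square variances (BayesA),
#' a point mass at zero with probability `pi` plus per-marker variances
#' (BayesB), a point mass plus a common variance (BayesC), or a Laplace
#' prior via its normal-exponential scale mixture (BL). Scale
#' hyperparameters left `NULL` are solved at fit time from the heuristic
#' that markers explain `r2` of the phenotypic variance a priori.
#'
#' @param model one of `"brr"`, `"bayesa"`, `"bayesb"`, `"bayesc"`, `"bl"`.
#' @param nu_beta,S_beta degrees of freedom and scale of the marker-variance
#'   prior.
#' @param nu_e,S_e degrees of freedom and scale of the residual-variance
#'   prior.
#' @param pi prior probability of a NULL marker effect (BayesB/C).
#' @param estimate_pi sample `pi` (BayesC default) with a
#'   `Beta(pi_a, pi_b)` prior.
#' @param pi_a,pi_b Beta hyperparameters for `pi`.
#' @param lambda_shape,lambda_rate Gamma hyperparameters for the BL penalty
#'   `lambda^2` (`lambda_rate = NULL` is solved from `r2` at fit time).
#' @param r2 prior proportion of variance attributed to markers.
#' @return list of class `bayes_prior`.
#' @export
bayes_prior <- function(model, nu_beta = 5, S_beta = NULL, nu_e = 5,
                        S_e = NULL, pi = NULL, estimate_pi = NULL,
                        pi_a = 1, pi_b = 9, lambda_shape = 1.1,
                        lambda_rate = NULL, r2 = 0.5) {
  model <- normalize_model_name(model)
  if (!model %in% c("brr", "bayesa", "bayesb", "bayesc", "bl"))
    config_error("model", sprintf("'%s' is not a Bayesian model", model))
  pi <- pi %||% switch(model, bayesb = 0.99, bayesc = 0.99, 0)
  estimate_pi <- estimate_pi %||% (model == "bayesc")
  if (nu_beta <= 0) config_error("nu_beta", "must be > 0")
  if (nu_e <= 0) config_error("nu_e", "must be > 0")
  if (!is_prob(pi)) config_error("pi", "must be a probability in [0, 1]")
  if (!is.null(S_beta) && S_beta <= 0) config_error("S_beta", "must be > 0")
  if (!is.null(S_e) && S_e <= 0) config_error("S_e", "must be > 0")
  if (lambda_shape <= 0) config_error("lambda_shape", "must be > 0")
  if (!is.null(lambda_rate) && lambda_rate <= 0)
    config_error("lambda_rate", "must be > 0")
  if (pi_a <= 0 || pi_b <= 0) config_error("pi_a", "and pi_b must be > 0")
  structure(list(model = model, nu_beta = nu_beta, S_beta = S_beta,
                 nu_e = nu_e, S_e = S_e, pi = pi, estimate_pi = estimate_pi,
                 pi_a = pi_a, pi_b = pi_b, lambda_shape = lambda_shape,
                 lambda_rate = lambda_rate, r2 = r2), class = "bayes_prior")
}

#' MCMC settings
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in discarded initial iterations (< `n_iter`).
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param seed chain seed.
#' @return list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 20000L, burn_in = 2000L, thin = 5L,
                          seed = 1L) {
  if (!is_count(n_iter)) config_error("n_iter", "must be a count >= 1")
  if (burn_in < 0 || burn_in >= n_iter)
    config_error("burn_in", "must satisfy 0 <= burn_in < n_iter")
  if (!is_count(thin)) config_error("thin", "must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_settings")
}

# Solve default scales from the r2 heuristic on the phenotypic variance.
resolve_prior_scales <- function(prior, Xc, y) {
  vy <- stats::var(y)
  if (vy == 0) vy <- 1
  sum_var_x <- sum(apply(Xc, 2, stats::var))
  if (sum_var_x == 0) sum_var_x <- 1
  frac_in <- if (prior$model %in% c("bayesb", "bayesc")) max(1 - prior$pi, 0.01) else 1
  mode_b <- prior$r2 * vy / (sum_var_x * frac_in)
  if (is.null(prior$S_beta))
    prior$S_beta <- mode_b * (prior$nu_beta + 2) / prior$nu_beta
  if (is.null(prior$S_e))
    prior$S_e <- (1 - prior$r2) * vy * (prior$nu_e + 2) / prior$nu_e
  if (is.null(prior$lambda_rate)) {
    mode_l2 <- max(2 * (1 - prior$r2) / prior$r2 * sum_var_x / vy, 1e-4)
    prior$lambda_rate <- max(prior$lambda_shape - 1, 0.1) / mode_l2
  }
  prior
}

#' Fit a Bayesian whole-genome regression by Gibbs sampling
#'
#' The phenotype is pre-adjusted for the fixed effects (intercept + blocks)
#' by OLS, dosages are centred per marker, and marker effects are sampled
#' from their single-site full conditionals (see [bayes_prior()] for the
#' model-specific priors). Posterior summaries are means over post-burn-in
#' thinned samples; GEBVs (`Xc %*% effect_mean`) are returned for every
#' individual in the genotype matrix, including unphenotyped ones.
#'
#' @param g a [genotype_matrix()] (imputed automatically if needed).
#' @param pheno a [phenotype_table()].
#' @param prior a [bayes_prior()].
#' @param mcmc an [mcmc_settings()].
#' @param fixed one-sided fixed-effects formula (default `~ block`).
#' @param trait trait column name.
#' @param sample_mu also sample an intercept inside the chain (default
#'   FALSE: the OLS pre-adjustment already centres the response).
#' @param fix_var fix `sigma_beta^2`/`sigma_e^2` at `fixed_sb2`/`fixed_se2`
#'   (degenerate priors; used for closed-form validation).
#' @param fixed_sb2,fixed_se2 the fixed variances when `fix_var = TRUE`.
#' @return A `gs_fit`/`gs_bayes` object whose `posterior` element holds
#'   per-marker effect means/SDs, inclusion probabilities, variance
#'   chains and effective sample sizes.
#' @export
fit_bayes <- function(g, pheno, prior, mcmc = mcmc_settings(),
                      fixed = ~block, trait = NULL, sample_mu = FALSE,
                      fix_var = FALSE, fixed_sb2 = 1, fixed_se2 = 1) {
  if (is.null(g)) config_error("genotypes", "are required for Bayesian models")
  stopifnot(inherits(prior, "bayes_prior"), inherits(mcmc, "mcmc_settings"))
  trait <- trait %||% (attr(pheno, "trait") %||% "dbh_cm")
  g <- impute_mean(g)
  ph <- as.data.frame(pheno)
  obs <- ph[!is.na(ph[[trait]]) & ph$id %in% g$individual_ids, , drop = FALSE]
  if (nrow(obs) < 2)
    sp_stop("need at least 2 phenotyped genotyped individuals",
            "selfpred_validation_error")
  obs$block <- factor(obs$block)

  # OLS pre-adjustment for intercept + blocks
  tl <- attr(stats::terms(fixed), "term.labels")
  ols_form <- if (length(tl)) stats::reformulate(tl, response = trait) else
    stats::as.formula(paste(trait, "~ 1"))
  ols <- stats::lm(ols_form, data = obs)
  y_adj <- stats::residuals(ols)

  centres <- colMeans(g$dosage[obs$id, , drop = FALSE])
  Xc_train <- sweep(g$dosage[obs$id, , drop = FALSE], 2, centres)
  prior <- resolve_prior_scales(prior, Xc_train, y_adj)

  model_code <- match(prior$model, c("brr", "bayesa", "bayesb", "bayesc", "bl")) - 1L
  set.seed(derive_seed(mcmc$seed, "mcmc"))
  raw <- gibbs_wgr_cpp(Xc_train, y_adj, model_code,
                       mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                       prior$nu_beta, prior$S_beta, prior$nu_e, prior$S_e,
                       prior$pi, prior$estimate_pi, prior$pi_a, prior$pi_b,
                       prior$lambda_shape, prior$lambda_rate,
                       fix_var, fixed_sb2, fixed_se2, sample_mu)

  eff <- setNames(raw$effect_mean, g$marker_ids)
  Xc_all <- sweep(g$dosage, 2, centres)
  gebv <- drop(Xc_all %*% eff) + raw$mu_mean
  names(gebv) <- g$individual_ids
  fitted_obs <- stats::fitted(ols) + gebv[obs$id]
  posterior <- list(
    marker_effect_means = eff,
    marker_effect_sds = setNames(raw$effect_sd, g$marker_ids),
    inclusion_prob = setNames(raw$inclusion_prob, g$marker_ids),
    sigma2_beta = mean(raw$chain_sb2),
    sigma2_e = mean(raw$chain_se2),
    pi_posterior = if (prior$estimate_pi) mean(raw$chain_pi) else NULL,
    lambda2_posterior = if (prior$model == "bl") mean(raw$chain_lambda2) else NULL,
    chains = list(sigma2_e = raw$chain_se2, sigma2_beta = raw$chain_sb2),
    diagnostics = c(ess_sigma2_e = ess(raw$chain_se2),
                    ess_sigma2_beta = ess(raw$chain_sb2)),
    n_samples = raw$n_samples,
    centres = centres, mu_mean = raw$mu_mean)

  structure(list(
    model = prior$model,
    beta_hat = stats::coef(ols),
    gebv = gebv, dominance_values = NULL,
    varcomp = c(additive = NA_real_, dominance = NA_real_,
                residual = posterior$sigma2_e),
    h2_hat = NA_real_,
    loglik = NA_real_, loglik_trace = NULL,
    converged = TRUE, n_iter = mcmc$n_iter,
    fitted = setNames(fitted_obs, obs$id),
    residuals = setNames(obs[[trait]] - fitted_obs, obs$id),
    obs_ids = obs$id, trait = trait, fixed = fixed,
    terms = stats::terms(ols), xlev = ols$xlevels,
    x_cols = names(stats::coef(ols)),
    kinship_kind = NA_character_,
    posterior = posterior, prior = prior, mcmc = mcmc,
    method = "Gibbs"), class = c("gs_bayes", "gs_fit"))
}

#' Score individuals from posterior marker effects
#'
#' @param fit a `gs_bayes` fit.
#' @param g a [genotype_matrix()] over the same marker set (centred with the
#'   training constants).
#' @return ranked GEBV table as in [predict_unphenotyped()].
#' @export
gebv_from_markers <- function(fit, g) {
  stopifnot(inherits(fit, "gs_bayes"))
  post <- fit$posterior
  missing <- setdiff(names(post$marker_effect_means), g$marker_ids)
  extra <- setdiff(g$marker_ids, names(post$marker_effect_means))
  if (length(missing) || length(extra))
    sp_stop(sprintf("marker sets differ (missing: %s; extra: %s)",
                    paste(head(missing, 3), collapse = ","),
                    paste(head(extra, 3), collapse = ",")),
            "selfpred_alignment_error")
  g <- impute_mean(g)
  Xc <- sweep(g$dosage[, names(post$marker_effect_means), drop = FALSE], 2,
              post$centres)
  gebv <- drop(Xc %*% post$marker_effect_means) + post$mu_mean
  names(gebv) <- g$individual_ids
  ord <- order(-gebv, g$individual_ids)
  data.frame(id = g$individual_ids[ord], gebv = unname(gebv[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' @export
print.gs_bayes <- function(x, ...) {
  cat(sprintf("<gs_bayes> model=%s, %d phenotyped, %d markers, %d kept samples\n",
              x$model, length(x$obs_ids),
              length(x$posterior$marker_effect_means), x$posterior$n_samples))
  cat(sprintf("  posterior means: sigma2_beta=%.4g sigma2_e=%.4g%s\n",
              x$posterior$sigma2_beta, x$posterior$sigma2_e,
              if (!is.null(x$posterior$pi_posterior))
                sprintf(" pi=%.3f", x$posterior$pi_posterior) else ""))
  cat(sprintf("  ESS: sigma2_e=%.0f sigma2_beta=%.0f\n",
              x$posterior$diagnostics[["ess_sigma2_e"]],
              x$posterior$diagnostics[["ess_sigma2_beta"]]))
  invisible(x)
}
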