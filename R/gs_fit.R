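#' Fit a genomic-selection model
#'
#' Central fitting front-end covering the four frequentist kinship models
#' (`"ablup"`, `"gblup"`, `"gblup_ad"`, `"hblup"`; EM-REML) and the five
#' Bayesian whole-genome regressions (`"brr"`, `"bayesa"`, `"bayesb"`,
#' `"bayesc"`, `"bl"`; Gibbs sampling). The formula gives the trait and the
#' fixed effects, e.g. `dbh_cm ~ block`; the intercept is always included.
#'
#' @param formula model formula, `trait ~ fixed effects`.
#' @param data a [phenotype_table()] (or data frame with `id` column).
#' @param model one of the nine model names above (`"gblup-ad"`, `"lasso"`
#'   accepted as aliases).
#' @param genotypes a [genotype_matrix()] (needed for the genomic and
#'   Bayesian models; imputed automatically if it has missing calls).
#' @param pedigree a [pedigree()] (needed for `ablup` and `hblup`).
#' @param kinship optionally a prebuilt `relationship_matrix` to use
#'   directly (overrides `genotypes`/`pedigree` for single-kinship models).
#' @param dominance optional prebuilt dominance matrix for `gblup_ad`.
#' @param prior a [bayes_prior()] for the Bayesian models (defaults filled
#'   from the model name).
#' @param mcmc an [mcmc_settings()] for the Bayesian models.
#' @param blend,tau,omega H-matrix construction parameters (see [build_H()]).
#' @param ... passed on to [fit_mixed()] (e.g. `max_iter`, `tol`).
#' @return An object of class `gs_fit` (Bayesian fits also inherit
#'   `gs_bayes`), with methods `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot` and `simulate`.
#' @examples
#' pop <- simulate_population(sim_config(n_parents = 6,
#'   offspring_per_parent = c(4, 8), n_markers = 200, n_chromosomes = 2,
#'   n_blocks = 5, n_orchard = 4, seed = 42))
#' fit <- gs_fit(dbh_cm ~ block, data = pop$phenotypes, model = "gblup",
#'               genotypes = pop$genotypes)
#' fit
#' head(predict(fit, ranked = TRUE))
#' @export
gs_fit <- function(formula, data, model = "gblup", genotypes = NULL,
                   pedigree = NULL, kinship = NULL, dominance = NULL,
                   prior = NULL, mcmc = mcmc_settings(),
                   blend = 0.05, tau = 1, omega = 1, ...) {
  model <- normalize_model_name(model)
  trait <- all.vars(formula)[1]
  tl <- attr(stats::terms(formula), "term.labels")
  fixed <- if (length(tl)) stats::reformulate(tl) else ~1
  ph <- if (inherits(data, "phenotype_table")) data else
    phenotype_table(data, trait = trait)

  if (model %in% c("ablup", "gblup", "gblup_ad", "hblup")) {
    fit <- switch(model,
      ablup = fit_ablup(ph, pedigree = pedigree, kinship = kinship,
                        fixed = fixed, trait = trait, ...),
      gblup = fit_gblup(ph, genotypes = genotypes, kinship = kinship,
                        fixed = fixed, trait = trait, ...),
      gblup_ad = fit_gblup_ad(ph, genotypes = genotypes, kinship = kinship,
                              dominance = dominance, fixed = fixed,
                              trait = trait, ...),
      hblup = fit_hblup(ph, pedigree = pedigree, genotypes = genotypes,
                        fixed = fixed, trait = trait, blend = blend,
                        tau = tau, omega = omega, ...))
    fit$model <- model
    fit
  } else {
    prior <- prior %||% bayes_prior(model)
    if (normalize_model_name(prior$model) != model)
      config_error("prior", sprintf("is for model '%s', not '%s'",
                                    prior$model, model))
    fit_bayes(genotypes, ph, prior = prior, mcmc = mcmc, fixed = fixed,
              trait = trait)
  }
}

normalize_model_name <- function(model) {
  m <- tolower(gsub("[-_ ]", "", model))
  map <- c(ablup = "ablup", gblup = "gblup", gblupad = "gblup_ad",
           hblup = "hblup", brr = "brr", bayesa = "bayesa", bayesb = "bayesb",
           bayesc = "bayesc", bl = "bl", bayeslasso = "bl", lasso = "bl",
           bayesianlasso = "bl")
  if (!m %in% names(map))
    config_error("model", sprintf("'%s' unknown; valid: %s", model,
                                  paste(unique(map), collapse = ", ")))
  unname(map[m])
}

#' Frequentist model wrappers
#'
#' Thin wrappers binding the appropriate relationship matrices into
#' [fit_mixed()]: pedigree A for ABLUP, VanRaden G for GBLUP, G plus the
#' dominance matrix for additive-dominant GBLUP, and the single-step H for
#' HBLUP.
#'
#' @param pheno a [phenotype_table()].
#' @param pedigree a [pedigree()].
#' @param genotypes a [genotype_matrix()].
#' @param kinship,dominance prebuilt matrices (built from the inputs when
#'   omitted).
#' @param genotyped_ids ids treated as genotyped when building H.
#' @param blend,tau,omega see [build_H()].
#' @param ... passed to [fit_mixed()].
#' @name blup_wrappers
NULL

#' @rdname blup_wrappers
#' @export
fit_ablup <- function(pheno, pedigree = NULL, kinship = NULL, ...) {
  if (is.null(kinship)) {
    if (is.null(pedigree))
      config_error("pedigree", "is required for ABLUP")
    kinship <- build_A(pedigree)
  }
  fit <- fit_mixed(pheno, kinship, ...)
  fit$model <- "ablup"
  fit
}

#' @rdname blup_wrappers
#' @export
fit_gblup <- function(pheno, genotypes = NULL, kinship = NULL, ...) {
  if (is.null(kinship)) {
    if (is.null(genotypes))
      config_error("genotypes", "are required for GBLUP")
    kinship <- build_G(impute_mean(genotypes))
  }
  fit <- fit_mixed(pheno, kinship, ...)
  fit$model <- "gblup"
  fit
}

#' @rdname blup_wrappers
#' @export
fit_gblup_ad <- function(pheno, genotypes = NULL, kinship = NULL,
                         dominance = NULL, ...) {
  if (is.null(kinship) || is.null(dominance)) {
    if (is.null(genotypes))
      config_error("genotypes", "are required for additive-dominant GBLUP")
    gi <- impute_mean(genotypes)
    if (is.null(kinship)) kinship <- build_G(gi)
    if (is.null(dominance)) dominance <- build_D(gi)
  }
  fit <- fit_mixed(pheno, kinship, dominance = dominance, ...)
  fit$model <- "gblup_ad"
  fit
}

#' @rdname blup_wrappers
#' @export
fit_hblup <- function(pheno, pedigree = NULL, genotypes = NULL,
                      genotyped_ids = NULL, blend = 0.05, tau = 1,
                      omega = 1, ...) {
  if (is.null(pedigree) || is.null(genotypes))
    config_error("pedigree", "and genotypes are both required for HBLUP")
  A <- build_A(pedigree)
  G <- build_G(impute_mean(genotypes))
  genotyped_ids <- genotyped_ids %||% intersect(A$ids, G$ids)
  H <- build_H(A, G, genotyped_ids, tau = tau, omega = omega, blend = blend)
  fit <- fit_mixed(pheno, H, ...)
  fit$model <- "hblup"
  fit
}

#' Rank unphenotyped individuals by GEBV
#'
#' @param fit a `gs_fit`.
#' @param ids individuals to rank (must be known to the fit); defaults to
#'   every id without a phenotype record in the training data.
#' @return data frame `(id, gebv, rank)`; rank 1 is the largest GEBV, ties
#'   broken by id in lexicographic order.
#' @export
predict_unphenotyped <- function(fit, ids = NULL) {
  gebv <- fit$gebv
  ids <- ids %||% setdiff(names(gebv), fit$obs_ids)
  unknown <- setdiff(ids, names(gebv))
  if (length(unknown))
    sp_stop(sprintf("unknown id(s): %s", paste(head(unknown, 5), collapse = ", ")),
            "selfpred_lookup_error")
  g <- gebv[ids]
  ord <- order(-g, ids)
  out <- data.frame(id = ids[ord], gebv = unname(g[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf("<gs_fit> model=%s (%s), %d phenotyped, %d total ids\n",
              x$model, x$method, length(x$obs_ids), length(x$gebv)))
  if (!is.null(x$varcomp)) {
    vc <- x$varcomp[!is.na(x$varcomp)]
    cat("  varcomp:", paste(sprintf("%s=%.4g", names(vc), vc), collapse = ", "),
        sprintf(" h2=%.3f\n", x$h2_hat))
    cat(sprintf("  REML loglik %.3f, %s in %d iterations\n", x$loglik,
                if (x$converged) "converged" else "NOT converged", x$n_iter))
  }
  invisible(x)
}

#' @export
summary.gs_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.gs_fit")
}

#' @export
print.summary.gs_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nFixed effects:\n")
  print(round(f$beta_hat, 4))
  cat("\nGEBV summary (all ids):\n")
  print(summary(f$gebv))
  invisible(x)
}

#' @export
coef.gs_fit <- function(object, ...) object$beta_hat

#' @export
fitted.gs_fit <- function(object, ...) object$fitted

#' @export
residuals.gs_fit <- function(object, ...) object$residuals

#' Predict from a fitted genomic-selection model
#'
#' @param object a `gs_fit`.
#' @param newdata optional data frame with `id` (and fixed-effect columns
#'   for `type = "response"`).
#' @param type `"gebv"` (additive genetic value), `"genetic"` (additive +
#'   dominance where fitted) or `"response"` (fixed effects + genetic value).
#' @param ranked return a ranked table as in [predict_unphenotyped()].
#' @param ... unused.
#' @export
predict.gs_fit <- function(object, newdata = NULL, type = c("gebv", "genetic",
                           "response"), ranked = FALSE, ...) {
  type <- match.arg(type)
  ids <- if (is.null(newdata)) names(object$gebv) else as.character(newdata$id)
  unknown <- setdiff(ids, names(object$gebv))
  if (length(unknown))
    sp_stop(sprintf("unknown id(s): %s", paste(head(unknown, 5), collapse = ", ")),
            "selfpred_lookup_error")
  g <- object$gebv[ids]
  if (type %in% c("genetic", "response") && !is.null(object$dominance_values))
    g <- g + object$dominance_values[ids]
  if (type == "response") {
    if (is.null(newdata))
      sp_stop("newdata required for type = 'response'", "selfpred_validation_error")
    nd <- newdata
    nd$block <- factor(nd$block, levels = object$xlev$block %||%
                         unique(as.character(nd$block)))
    Xn <- stats::model.matrix(stats::delete.response(object$terms), nd,
                              xlev = object$xlev)
    Xn <- Xn[, object$x_cols, drop = FALSE]
    g <- drop(Xn %*% object$beta_hat[object$x_cols]) + g
    names(g) <- ids
  }
  if (ranked) {
    ord <- order(-g, ids)
    return(data.frame(id = ids[ord], gebv = unname(g[ord]),
                      rank = seq_along(ord), stringsAsFactors = FALSE))
  }
  g
}

#' @export
plot.gs_fit <- function(x, ...) {
  graphics::plot(x$fitted, x$fitted + x$residuals,
                 xlab = "fitted", ylab = "observed",
                 main = sprintf("%s: observed vs fitted", x$model), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate phenotypes from a fitted frequentist model
#'
#' Draws new phenotype vectors for the training individuals from the fitted
#' model, `y* = X beta + u* + e*` with `u* ~ N(0, K sigma_a2)` approximated
#' by resampling the estimated variance components.
#'
#' @param object a frequentist `gs_fit`.
#' @param nsim number of replicates.
#' @param seed optional seed.
#' @param ... unused.
#' @export
simulate.gs_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$obs_ids)
  mu <- object$fitted  # conditional mean given the fitted genetic values
  sig_e <- sqrt(object$varcomp[["residual"]])
  out <- as.data.frame(replicate(nsim, mu + rnorm(n, 0, sig_e)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$obs_ids
  out
}
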