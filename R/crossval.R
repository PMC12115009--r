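#' One-sided lower winsorization
#'
#' Values strictly below the empirical `percentile` quantile (linear
#' interpolation between order statistics, R's default type 7 rule) are
#' replaced by that quantile; the upper tail is untouched. `NA` values are
#' preserved.
#'
#' @param y numeric trait vector.
#' @param percentile lower-tail proportion in (0, 1), default 0.05.
#' @export
winsorize_lower <- function(y, percentile = 0.05) {
  if (!length(y)) sp_stop("empty vector", "selfpred_validation_error")
  if (!(is.numeric(percentile) && length(percentile) == 1 &&
        percentile > 0 && percentile < 1))
    config_error("percentile", "must lie strictly in (0, 1)")
  q <- stats::quantile(y, percentile, na.rm = TRUE, names = FALSE, type = 7)
  y[!is.na(y) & y < q] <- q
  y
}

#' Cross-validation metrics
#'
#' Predictive capacity is the Pearson correlation between predicted and
#' observed values (sample n-1 convention); MSE is the mean squared
#' difference; R2 is `1 - SSres/SStot` with the total sum of squares about
#' the observed mean of the validation set (negative values allowed).
#'
#' @param y_hat,y predicted and observed values of equal length.
#' @name cv_metrics
NULL

#' @rdname cv_metrics
#' @export
predictive_capacity <- function(y_hat, y) {
  stopifnot(length(y_hat) == length(y))
  if (length(y) < 2)
    sp_stop("need at least 2 observations", "selfpred_validation_error")
  if (stats::sd(y_hat) == 0 || stats::sd(y) == 0)
    sp_stop("predictive capacity undefined: zero variance",
            "selfpred_metric_error")
  stats::cov(y_hat, y) / (stats::sd(y_hat) * stats::sd(y))
}

#' @rdname cv_metrics
#' @export
mean_squared_error <- function(y_hat, y) {
  stopifnot(length(y_hat) == length(y), length(y) >= 1)
  mean((y_hat - y)^2)
}

#' @rdname cv_metrics
#' @export
r_squared <- function(y_hat, y) {
  stopifnot(length(y_hat) == length(y))
  if (length(y) < 2)
    sp_stop("need at least 2 observations", "selfpred_validation_error")
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0)
    sp_stop("R2 undefined: zero total variance", "selfpred_metric_error")
  1 - sum((y - y_hat)^2) / sstot
}

#' k-fold cross-validation of genomic-selection models
#'
#' The phenotyped response is winsorized once (lower 5th percentile) before
#' fold splitting; ids are shuffled under `seed` and dealt round-robin into
#' `k` folds (sizes differ by at most 1). Relationship matrices are built
#' once on all individuals and only held-out phenotypes are masked in each
#' fold; held-out predictions are fixed-effect estimates plus genetic
#' values. Metrics are computed per fold and aggregated as mean and SD
#' across folds.
#'
#' @param models character vector of model names (see [gs_fit()]).
#' @param data a list with `phenotypes`, and `genotypes` and/or `pedigree`
#'   as the models require (e.g. the output of [simulate_population()]).
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param winsor_percentile lower-tail winsorization proportion (`NULL`
#'   disables).
#' @param mcmc [mcmc_settings()] for any Bayesian models.
#' @param blend,tau,omega passed to [build_H()] for `hblup`.
#' @param trait trait column name.
#' @param ... passed to [fit_mixed()].
#' @return object of class `cv_report`: `per_fold` (model, fold, pc, mse,
#'   r2), `aggregate` (mean and SD per metric), `fold_assignment`, `seed`,
#'   `failures`.
#' @export
kfold_cv <- function(models, data, k = 10, seed = 1,
                     winsor_percentile = 0.05, mcmc = mcmc_settings(),
                     blend = 0.05, tau = 1, omega = 1, trait = "dbh_cm",
                     ...) {
  models <- vapply(models, normalize_model_name, character(1))
  ph <- as.data.frame(data$phenotypes)
  if (!is.null(winsor_percentile))
    ph[[trait]] <- winsorize_lower(ph[[trait]], winsor_percentile)
  obs_ids <- ph$id[!is.na(ph[[trait]])]
  if (length(obs_ids) < k)
    sp_stop("fewer phenotyped individuals than folds", "selfpred_validation_error")
  set.seed(derive_seed(seed, "cv"))
  shuffled <- sample(obs_ids)
  fold_of <- setNames(rep(seq_len(k), length.out = length(shuffled)), shuffled)

  # matrices built once over all individuals
  need_G <- any(models %in% c("gblup", "gblup_ad", "hblup"))
  need_A <- any(models %in% c("ablup", "hblup"))
  gi <- if (!is.null(data$genotypes)) impute_mean(data$genotypes) else NULL
  G <- if (need_G && !is.null(gi)) build_G(gi) else NULL
  D <- if ("gblup_ad" %in% models && !is.null(gi)) build_D(gi) else NULL
  A <- if (need_A && !is.null(data$pedigree)) build_A(data$pedigree) else NULL
  H <- if ("hblup" %in% models) {
    if (is.null(A) || is.null(G))
      config_error("data", "hblup needs both pedigree and genotypes")
    build_H(A, G, intersect(A$ids, G$ids), tau = tau, omega = omega,
            blend = blend)
  } else NULL

  per_fold <- list()
  failures <- list()
  for (model in unique(models)) {
    bayes <- model %in% c("brr", "bayesa", "bayesb", "bayesc", "bl")
    for (fold in seq_len(k)) {
      test_ids <- names(fold_of)[fold_of == fold]
      ph_train <- ph
      ph_train[[trait]][ph_train$id %in% test_ids] <- NA_real_
      res <- tryCatch({
        fit <- if (bayes) {
          fit_bayes(data$genotypes, phenotype_table(ph_train, trait),
                    prior = bayes_prior(model), mcmc = mcmc, trait = trait)
        } else {
          kin <- switch(model, ablup = A, gblup = G, gblup_ad = G, hblup = H)
          if (is.null(kin)) config_error("data", sprintf("missing inputs for %s", model))
          fit_mixed(phenotype_table(ph_train, trait), kin,
                    dominance = if (model == "gblup_ad") D else NULL,
                    trait = trait, ...)
        }
        nd <- ph[ph$id %in% test_ids, c("id", "block")]
        y_hat <- predict(fit, newdata = nd, type = "response")
        y_obs <- ph[[trait]][match(nd$id, ph$id)]
        data.frame(model = model, fold = fold,
                   pc = predictive_capacity(y_hat, y_obs),
                   mse = mean_squared_error(y_hat, y_obs),
                   r2 = r_squared(y_hat, y_obs),
                   stringsAsFactors = FALSE)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          list(model = model, fold = fold, message = conditionMessage(res))
      } else per_fold[[length(per_fold) + 1]] <- res
    }
  }
  per_fold <- if (length(per_fold)) do.call(rbind, per_fold) else
    data.frame(model = character(0), fold = integer(0), pc = numeric(0),
               mse = numeric(0), r2 = numeric(0))
  agg <- do.call(rbind, lapply(split(per_fold, per_fold$model), function(d) {
    data.frame(model = d$model[1],
               pc_mean = mean(d$pc), pc_sd = stats::sd(d$pc),
               mse_mean = mean(d$mse), mse_sd = stats::sd(d$mse),
               r2_mean = mean(d$r2), r2_sd = stats::sd(d$r2),
               n_folds = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(per_fold = per_fold, aggregate = agg,
                 fold_assignment = fold_of, seed = seed, k = k,
                 winsor_percentile = winsor_percentile,
                 quantile_convention = "type 7 (linear interpolation)",
                 failures = failures,
                 complete = length(failures) == 0), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV, seed %s%s\n", x$k, x$seed,
              if (x$complete) "" else sprintf(" (%d fold failures)",
                                              length(x$failures))))
  print(comparison_report(x), digits = 4)
  invisible(x)
}

#' Model-comparison table
#'
#' Models sorted by mean predictive capacity (descending, ties broken
#' alphabetically), reporting PC, MSE and R2 as mean +/- SD across folds.
#'
#' @param cv a `cv_report`.
#' @return data frame with one row per model, best first.
#' @export
comparison_report <- function(cv) {
  agg <- cv$aggregate
  if (!nrow(agg)) return(agg)
  agg <- agg[order(-agg$pc_mean, agg$model), , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg
}
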