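# EM-REML engine for the kinship-based mixed models.
#
# Model: y = X beta + u (+ v) + e with u ~ N(0, K1 sigma_a^2),
# v ~ N(0, K2 sigma_d^2), e ~ N(0, I sigma_e^2). Variance components by
# EM-REML with optional Aitken acceleration (accepted only when it does not
# decrease the REML log-likelihood, so the monotonicity guarantee of EM is
# preserved). Single-kinship fits run in the eigenbasis of the observed
# kinship block, where every EM iteration is O(n p^2).

#' Fit a kinship mixed model by EM-REML
#'
#' Fits `trait ~ fixed` with one (or, with `dominance`, two) correlated
#' random genetic effects. Variance components are estimated by EM-REML
#' (tolerance `tol` on the relative change, at most `max_iter` iterations,
#' components clamped at 1e-8); BLUEs/BLUPs come from the mixed-model
#' equations at the REML estimates. Breeding values are returned for every
#' id in the kinship matrix, including unphenotyped individuals (the orchard
#' prediction case).
#'
#' @param pheno a [phenotype_table()] (rows with `NA` trait are treated as
#'   unphenotyped).
#' @param kinship a `relationship_matrix` covering at least all phenotyped ids.
#' @param dominance optional second `relationship_matrix` (additive-dominant
#'   model).
#' @param fixed one-sided formula for the fixed effects (default `~ block`;
#'   the intercept is always included).
#' @param trait trait column name.
#' @param max_iter,tol EM-REML iteration cap and relative-change tolerance.
#' @param aitken use Aitken acceleration (default TRUE).
#' @return An object of class `gs_fit`; see [gs_fit()].
#' @export
fit_mixed <- function(pheno, kinship, dominance = NULL, fixed = ~block,
                      trait = NULL, max_iter = 500L, tol = 1e-6,
                      aitken = TRUE) {
  trait <- trait %||% (attr(pheno, "trait") %||% "dbh_cm")
  ph <- as.data.frame(pheno)
  ids_all <- kinship$ids
  obs <- ph[!is.na(ph[[trait]]), , drop = FALSE]
  if (nrow(obs) < 2)
    sp_stop("need at least 2 phenotyped individuals", "selfpred_validation_error")
  missing_ids <- setdiff(obs$id, ids_all)
  if (length(missing_ids))
    sp_stop(sprintf("phenotyped ids absent from kinship: %s",
                    paste(head(missing_ids, 5), collapse = ", ")),
            "selfpred_validation_error")
  obs$block <- factor(obs$block)
  y <- obs[[trait]]
  n <- length(y)

  trm <- stats::terms(fixed)
  mf <- stats::model.frame(trm, obs, na.action = stats::na.pass)
  X <- stats::model.matrix(trm, mf)
  # drop aliased columns so the design is full rank after reference-level drop
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  xlev <- stats::.getXlevels(trm, mf)

  oidx <- match(obs$id, ids_all)
  K1 <- kinship$values
  K1oo <- K1[oidx, oidx, drop = FALSE]

  fit <- if (is.null(dominance)) {
    reml_em_single(y, X, K1oo, max_iter, tol, aitken)
  } else {
    if (!all(obs$id %in% dominance$ids))
      sp_stop("phenotyped ids absent from dominance matrix",
              "selfpred_validation_error")
    K2oo <- dominance$values[match(obs$id, dominance$ids),
                             match(obs$id, dominance$ids), drop = FALSE]
    reml_em_two(y, X, K1oo, K2oo, max_iter, tol, aitken)
  }

  Py <- fit$Py  # P y in the original observation basis
  gebv <- drop(fit$sigma_a2 * K1[, oidx, drop = FALSE] %*% Py)
  names(gebv) <- ids_all
  dom_vals <- NULL
  if (!is.null(dominance)) {
    K2 <- dominance$values
    didx <- match(obs$id, dominance$ids)
    dom_vals <- drop(fit$sigma_d2 * K2[, didx, drop = FALSE] %*% Py)
    names(dom_vals) <- dominance$ids
  }
  beta <- drop(fit$beta)
  names(beta) <- colnames(X)
  fitted_obs <- drop(X %*% fit$beta) + gebv[obs$id] +
    if (is.null(dom_vals)) 0 else dom_vals[obs$id]
  varcomp <- c(additive = fit$sigma_a2,
               dominance = if (is.null(dominance)) NA_real_ else fit$sigma_d2,
               residual = fit$sigma_e2)
  h2 <- fit$sigma_a2 / sum(varcomp, na.rm = TRUE)
  structure(list(
    model = if (is.null(dominance)) paste0(tolower(kinship$kind), "blup")
            else "gblup_ad",
    beta_hat = beta, gebv = gebv, dominance_values = dom_vals,
    varcomp = varcomp, h2_hat = h2,
    loglik = fit$loglik, loglik_trace = fit$trace,
    converged = fit$converged, n_iter = fit$n_iter,
    fitted = setNames(fitted_obs, obs$id),
    residuals = setNames(y - fitted_obs, obs$id),
    obs_ids = obs$id, trait = trait, fixed = fixed,
    terms = trm, xlev = xlev, x_cols = colnames(X),
    kinship_kind = kinship$kind,
    method = "EM-REML"), class = "gs_fit")
}

# Single random effect, eigenbasis implementation.
reml_em_single <- function(y, X, K, max_iter, tol, aitken) {
  n <- length(y)
  eg <- eigen(symmetrize(K), symmetric = TRUE)
  d <- pmax(eg$values, 1e-8)  # ridge-stabilized spectrum
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1  # degenerate (constant) response
  th <- c(a = vy / 2, e = vy / 2)
  step <- function(th) {
    w <- th[1] * d + th[2]
    Xw <- Xt / w
    XtWX <- crossprod(Xt, Xw)
    B <- solve(XtWX)
    beta <- B %*% crossprod(Xw, yt)
    r <- yt - drop(Xt %*% beta)
    Py <- r / w
    yPKPy <- sum(d * Py^2)
    yPPy <- sum(Py^2)
    trPK <- sum(d / w) - sum(B * crossprod(Xw, d * Xw))
    trP <- sum(1 / w) - sum(B * crossprod(Xw, Xw))
    ll <- -0.5 * (sum(log(w)) + determinant(XtWX, logarithm = TRUE)$modulus +
                    sum(r * Py))
    list(th_new = pmax(c(th[1] + th[1]^2 * (yPKPy - trPK) / n,
                         th[2] + th[2]^2 * (yPPy - trP) / n), 1e-8),
         loglik = as.numeric(ll), beta = beta, Py = Py)
  }
  run_em(th, step, max_iter, tol, aitken, finish = function(th, st) {
    list(sigma_a2 = unname(th[1]), sigma_e2 = unname(th[2]),
         beta = st$beta, Py = drop(U %*% st$Py))
  })
}

# Two correlated random effects (additive + dominance), dense implementation.
reml_em_two <- function(y, X, K1, K2, max_iter, tol, aitken) {
  n <- length(y)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  th <- c(a = vy / 3, d = vy / 3, e = vy / 3)
  I_n <- diag(n)
  step <- function(th) {
    V <- th[1] * K1 + th[2] * K2 + th[3] * I_n
    ch <- tryCatch(chol(V), error = function(e)
      chol(V + 1e-6 * mean(diag(V)) * I_n))
    Vinv <- chol2inv(ch)
    XtVX <- crossprod(X, Vinv %*% X)
    B <- solve(XtVX)
    VX <- Vinv %*% X
    P <- Vinv - VX %*% B %*% t(VX)
    Py <- drop(P %*% y)
    upd <- function(sig, K) {
      KPy <- drop(K %*% Py)
      max(sig + sig^2 * (sum(Py * KPy) - sum(P * K)) / n, 1e-8)
    }
    ll <- -0.5 * (2 * sum(log(diag(ch))) +
                    determinant(XtVX, logarithm = TRUE)$modulus + sum(y * Py))
    list(th_new = c(upd(th[1], K1), upd(th[2], K2),
                    max(th[3] + th[3]^2 * (sum(Py^2) - sum(diag(P))) / n, 1e-8)),
         loglik = as.numeric(ll),
         beta = B %*% crossprod(X, drop(Vinv %*% y)), Py = Py)
  }
  run_em(th, step, max_iter, tol, aitken, finish = function(th, st) {
    list(sigma_a2 = unname(th[1]), sigma_d2 = unname(th[2]),
         sigma_e2 = unname(th[3]), beta = st$beta, Py = st$Py)
  })
}

# Shared EM driver: plain EM updates plus guarded Aitken extrapolation.
run_em <- function(th, step, max_iter, tol, aitken, finish) {
  trace <- numeric(0)
  hist <- list()
  converged <- FALSE
  st <- step(th)
  for (it in seq_len(max_iter)) {
    th_new <- st$th_new
    trace <- c(trace, st$loglik)
    hist <- c(hist, list(th))
    if (aitken && length(hist) >= 3 && it %% 3 == 0) {
      t1 <- hist[[length(hist) - 2]]; t2 <- hist[[length(hist) - 1]]; t3 <- th
      den <- (t3 - t2) - (t2 - t1)
      acc <- ifelse(abs(den) > 1e-12, t3 - (t3 - t2)^2 / den, th_new)
      acc <- pmax(acc, 1e-8)
      st_acc <- step(acc)
      if (is.finite(st_acc$loglik) && st_acc$loglik >= st$loglik) {
        th_new <- acc
        st_next <- st_acc
      } else st_next <- NULL
    } else st_next <- NULL
    rel <- max(abs(th_new - th) / pmax(abs(th), 1e-12))
    ll_prev <- st$loglik
    th <- th_new
    st <- if (is.null(st_next)) step(th) else st_next
    # stop on parameter stability, or on a stationary REML objective (a
    # boundary component keeps creeping multiplicatively long after the
    # likelihood has flattened)
    if (rel < tol ||
        abs(st$loglik - ll_prev) < 1e-9 * (1 + abs(st$loglik))) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("EM-REML did not converge in %d iterations", max_iter),
            call. = FALSE)
  out <- finish(th, st)
  out$loglik <- st$loglik
  out$trace <- c(trace, st$loglik)
  out$converged <- converged
  out$n_iter <- length(trace)
  out
}
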