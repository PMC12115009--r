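# Independent oracles and shared fixtures for the test suite. The oracles
# deliberately use different algorithms from the package code paths they
# check (gene dropping vs the tabular method, dense GLS vs the eigenbasis
# REML solver, sort-based quantiles vs stats::quantile).

# -- gene-dropping kinship oracle ---------------------------------------
# Founders get unique allele labels; alleles are dropped through the
# pedigree n_drops times; the additive relationship is estimated as twice
# the probability that random alleles from i and j are identical by descent.
gene_drop_A <- function(ped, n_drops = 1e5, seed = 1) {
  set.seed(seed)
  ped <- as.data.frame(ped)
  n <- nrow(ped)
  ids <- ped$id
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  a1 <- matrix(0L, n_drops, n)
  a2 <- matrix(0L, n_drops, n)
  next_allele <- 1L
  for (i in seq_len(n)) {
    if (is.na(si[i]) || is.na(di[i])) {
      a1[, i] <- next_allele; a2[, i] <- next_allele + 1L
      next_allele <- next_allele + 2L
    } else {
      pick1 <- runif(n_drops) < 0.5
      a1[, i] <- ifelse(pick1, a1[, si[i]], a2[, si[i]])
      pick2 <- runif(n_drops) < 0.5
      a2[, i] <- ifelse(pick2, a1[, di[i]], a2[, di[i]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    f <- mean((a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
                (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])) / 4
    A[i, j] <- A[j, i] <- 2 * f
  }
  A
}

# -- dense GLS / BLUP oracle --------------------------------------------
# Direct V-inverse solve of the mixed model at given variance components:
# beta = (X' V^-1 X)^-1 X' V^-1 y,  u = s2a * K[, obs] V^-1 (y - X beta).
gls_blup_oracle <- function(y, X, K_full, obs_idx, s2a, s2e) {
  Koo <- K_full[obs_idx, obs_idx, drop = FALSE]
  V <- s2a * Koo + s2e * diag(length(y))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  u <- s2a * K_full[, obs_idx, drop = FALSE] %*% Vi %*% r
  list(beta = drop(beta), u = drop(u))
}

# -- sort-based type-7 quantile oracle ----------------------------------
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

# -- closed-form ridge oracle (BRR with fixed variances) ----------------
ridge_oracle <- function(X, y, lambda) {
  drop(solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, y)))
}

# -- cached simulated populations ---------------------------------------
.pop_cache <- new.env(parent = emptyenv())
fixture_pop <- function(..., seed = 1) {
  key <- paste(deparse(list(..., seed = seed)), collapse = "")
  key <- paste0("k", sum(utf8ToInt(key)), nchar(key))
  if (is.null(.pop_cache[[key]]))
    .pop_cache[[key]] <- simulate_population(sim_config(..., seed = seed))
  .pop_cache[[key]]
}

# small default population used across tests
small_pop <- function(seed = 1) {
  fixture_pop(n_parents = 8, offspring_per_parent = c(6, 10), n_markers = 300,
              n_chromosomes = 3, n_blocks = 5, n_orchard = 4,
              missing_rate = 0.02, seed = seed)
}

# random PD kinship + phenotype fixture for oracle tests
random_mixed_fixture <- function(n, seed) {
  set.seed(seed)
  m <- 60
  dos <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)[rep(seq_len(m), each = n)]),
                n, m)
  dimnames(dos) <- list(sprintf("i%02d", seq_len(n)), sprintf("m%02d", seq_len(m)))
  K <- build_G(genotype_matrix(dos))$values + diag(0.05, n)
  L <- chol(K)
  u <- drop(t(L) %*% rnorm(n))
  block <- factor(rep(1:3, length.out = n))
  y <- 10 + as.numeric(block) * 0.5 + u + rnorm(n, 0, 1)
  ph <- phenotype_table(data.frame(id = rownames(dos), block = block,
                                   dbh_cm = y))
  list(K = relationship_matrix(K, "G"), pheno = ph, y = y, block = block)
}
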