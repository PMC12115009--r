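#' Relationship matrix container
#'
#' @param values symmetric numeric matrix with id dimnames.
#' @param kind one of `"A"`, `"G"`, `"D"`, `"H"`.
#' @return object of class `relationship_matrix` with `ids`, `values`, `kind`.
#' @export
relationship_matrix <- function(values, kind = c("A", "G", "D", "H")) {
  kind <- match.arg(kind)
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-10)))
    sp_stop("relationship matrix is not symmetric", "selfpred_matrix_error")
  values <- symmetrize(values)
  structure(list(ids = rownames(values), values = values, kind = kind),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("<relationship_matrix kind=%s> %d ids, mean diagonal %.3f\n",
              x$kind, length(x$ids), mean(diag(x$values))))
  invisible(x)
}

#' Pedigree numerator relationship matrix (A)
#'
#' Tabular (recursive) method with inbreeding: for individual `i` with
#' parents `s`, `d`, `a_ii = 1 + a_sd / 2` and
#' `a_ij = (a_js + a_jd) / 2` for earlier `j`. Unknown parents are treated
#' as unrelated and non-inbred. One generation of selfing from a non-inbred
#' parent gives F = 0.5 (diagonal 1.5).
#'
#' @param ped a [pedigree()] (or data frame coercible to one).
#' @return A `relationship_matrix` of kind `"A"`; per-individual inbreeding
#'   coefficients are `diag - 1`.
#' @export
build_A <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  n <- nrow(ped)
  ids <- ped$id
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      as_ <- if (is.na(s)) rep(0, i - 1L) else A[j, s]
      ad_ <- if (is.na(d)) rep(0, i - 1L) else A[j, d]
      A[j, i] <- A[i, j] <- (as_ + ad_) / 2
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else A[s, d] / 2
  }
  relationship_matrix(A, "A")
}

#' Genomic relationship matrix (G), VanRaden method 1
#'
#' `Z = M - 2p` (dosages centred at twice the counted-allele frequency of
#' the analysed sample) and `G = Z Z' / (2 * sum(p_j (1 - p_j)))`.
#'
#' @param g an imputed [genotype_matrix()] (no missing dosages).
#' @return A `relationship_matrix` of kind `"G"`.
#' @export
build_G <- function(g) {
  d <- g$dosage
  if (anyNA(d))
    sp_stop("build_G requires imputed dosages (see impute_mean)",
            "selfpred_validation_error")
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    sp_stop("all markers monomorphic: VanRaden denominator is zero",
            "selfpred_matrix_error")
  Z <- sweep(d, 2, 2 * p)
  relationship_matrix(tcrossprod(Z) / denom, "G")
}

#' Genomic dominance matrix (D), classical parameterization
#'
#' Dominance design entries `(-2p^2, 2pq, -2q^2)` for dosages `(0, 1, 2)`
#' (centred under Hardy-Weinberg), and `D = W W' / sum((2 p_j q_j)^2)`.
#'
#' @param g an imputed [genotype_matrix()].
#' @return A `relationship_matrix` of kind `"D"`.
#' @export
build_D <- function(g) {
  d <- g$dosage
  if (anyNA(d))
    sp_stop("build_D requires imputed dosages (see impute_mean)",
            "selfpred_validation_error")
  p <- colMeans(d) / 2
  q <- 1 - p
  denom <- sum((2 * p * q)^2)
  if (denom <= 0)
    sp_stop("all markers monomorphic: dominance denominator is zero",
            "selfpred_matrix_error")
  # piecewise-linear interpolation through the classical codes, exact at
  # integer dosages; real-valued entries only arise from mean imputation
  W <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  for (j in seq_along(p)) {
    x <- d[, j]
    w0 <- -2 * p[j]^2; w1 <- 2 * p[j] * q[j]; w2 <- -2 * q[j]^2
    lo <- pmax(0, pmin(1, x))       # weight path 0 -> 1
    hi <- pmax(0, pmin(1, x - 1))   # weight path 1 -> 2
    W[, j] <- w0 * (1 - lo) + w1 * (lo - hi) + w2 * hi
  }
  relationship_matrix(tcrossprod(W) / denom, "D")
}

#' Single-step hybrid relationship matrix (H)
#'
#' Blends the genomic matrix with the corresponding pedigree block
#' (`G* = (1 - blend) G + blend A22`) and propagates the genomic correction
#' to non-genotyped relatives through the pedigree (Legarra/Christensen
#' construction). With `tau`/`omega` different from 1 the matrix is formed
#' through its inverse, `H^-1 = A^-1 + [0, 0; 0, tau G*^-1 - omega A22^-1]`.
#'
#' @param A pedigree `relationship_matrix` over all individuals.
#' @param G genomic `relationship_matrix` over the genotyped subset.
#' @param genotyped_ids ids of the genotyped individuals (must be in `A`).
#' @param tau,omega scaling weights on `G*^-1` and `A22^-1` (default 1).
#' @param blend proportion of `A22` mixed into `G` (default 0.05).
#' @return A `relationship_matrix` of kind `"H"` over all ids in `A`.
#' @export
build_H <- function(A, G, genotyped_ids = G$ids, tau = 1, omega = 1,
                    blend = 0.05) {
  if (!all(genotyped_ids %in% A$ids))
    sp_stop("genotyped_ids must all be present in A", "selfpred_validation_error")
  if (!all(genotyped_ids %in% G$ids))
    sp_stop("genotyped_ids must all be present in G", "selfpred_validation_error")
  Av <- A$values
  g2 <- match(genotyped_ids, rownames(Av))
  g1 <- setdiff(seq_len(nrow(Av)), g2)
  A22 <- Av[g2, g2, drop = FALSE]
  Gs <- (1 - blend) * G$values[genotyped_ids, genotyped_ids, drop = FALSE] +
    blend * A22
  Delta <- Gs - A22
  H <- Av
  if (tau == 1 && omega == 1) {
    if (length(g1)) {
      A22inv <- tryCatch(solve(A22), error = function(e)
        sp_stop("A22 is singular; consider a larger blend", "selfpred_matrix_error"))
      A12 <- Av[g1, g2, drop = FALSE]
      P <- A12 %*% A22inv
      H[g1, g1] <- H[g1, g1] + P %*% Delta %*% t(P)
      H[g1, g2] <- H[g1, g2] + P %*% Delta
      H[g2, g1] <- t(H[g1, g2])
    }
    H[g2, g2] <- H[g2, g2] + Delta
  } else {
    inv <- function(M, what) tryCatch(solve(M), error = function(e)
      sp_stop(sprintf("%s is singular; consider a larger blend", what),
              "selfpred_matrix_error"))
    Hinv <- inv(Av, "A")
    Hinv[g2, g2] <- Hinv[g2, g2] + tau * inv(Gs, "G*") - omega * inv(A22, "A22")
    H <- inv(Hinv, "H^-1")
  }
  relationship_matrix(symmetrize(H), "H")
}
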