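# Internal numerical helpers shared across modules.

# log(sum(exp(x))) along rows of a matrix, guarded against -Inf rows
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(m - mx)))
  out[bad] <- -Inf
  out
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# Gauss-Hermite nodes/weights (physicists' convention: weight exp(-x^2)).
# Cached per node count; pracma does the quadrature-rule construction.
gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(n) {
  key <- as.character(n)
  if (is.null(gh_cache[[key]])) gh_cache[[key]] <- pracma::gaussHermite(n)
  gh_cache[[key]]
}

# 2x2 symmetric pd matrix <-> log-Cholesky vector (l11, l21, l22),
# diagonal entries on log scale so any real vector maps to a pd matrix
logchol_to_cov <- function(v) {
  L <- matrix(c(exp(v[1L]), v[2L], 0, exp(v[3L])), 2L, 2L)
  L %*% t(L)
}

cov_to_logchol <- function(B) {
  L <- t(chol(B))
  c(log(L[1L, 1L]), L[2L, 1L], log(L[2L, 2L]))
}

# linear predictor alpha' w for covariate rows (sex, addiction, age)
covariate_lp <- function(coef, sex, addiction, age) {
  coef[1L] * sex + coef[2L] * addiction + coef[3L] * age
}

`%||%` <- function(a, b) if (is.null(a)) b else a
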