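# Shared fixtures and independent oracles (kept free of the package's own
# fitting code paths).

GENO <- c("LL", "HL", "HH")

# residual_phenotypes table from a named numeric vector
res_phen <- function(values, ids = names(values)) {
  structure(data.frame(id = ids, residual = unname(values),
                       stringsAsFactors = FALSE),
            class = c("residual_phenotypes", "data.frame"))
}

# genotype matrix from per-marker call vectors
geno_matrix <- function(..., ids = NULL) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  if (is.null(ids)) ids <- sprintf("id%03d", seq_len(nrow(m)))
  rownames(m) <- ids
  class(m) <- c("genotype_matrix", class(m))
  m
}

# iid multinomial genotype calls at intercross (1/4, 1/2, 1/4) frequencies
draw_calls <- function(n, loci) {
  m <- matrix(sample(GENO, n * length(loci), replace = TRUE,
                     prob = c(0.25, 0.5, 0.25)),
              n, length(loci), dimnames = list(sprintf("id%05d", seq_len(n)),
                                               loci))
  class(m) <- c("genotype_matrix", class(m))
  m
}

# Brute-force least-squares oracle: minimum-norm solution and RSS via SVD
# pseudo-inverse (independent of the package's QR path).
pinv_fit <- function(X, y, tol = 1e-10) {
  s <- svd(X)
  keep <- s$d > tol * max(s$d)
  beta <- s$v[, keep, drop = FALSE] %*%
    ((t(s$u[, keep, drop = FALSE]) %*% y) / s$d[keep])
  list(beta = drop(beta), rss = sum((y - X %*% beta)^2), rank = sum(keep))
}

oracle_nested_f <- function(y, X_red, X_full) {
  f_full <- pinv_fit(X_full, y)
  f_red <- pinv_fit(X_red, y)
  n <- length(y)
  dfn <- f_full$rank - f_red$rank
  dfd <- n - f_full$rank
  if (dfn <= 0 || dfd <= 0) return(0)
  num <- (f_red$rss - f_full$rss) / dfn
  den <- f_full$rss / dfd
  eps <- 1e-10 * max(f_red$rss, 1)
  if (den <= eps / dfd) return(if (num > eps) Inf else 0)
  max(num / den, 0)
}

# Full two-locus design matrices from call vectors
two_locus_design <- function(cA, cB) {
  a1 <- c(LL = -1, HL = 0, HH = 1)[cA]
  d1 <- as.numeric(cA == "HL")
  a2 <- c(LL = -1, HL = 0, HH = 1)[cB]
  d2 <- as.numeric(cB == "HL")
  list(full = cbind(1, a1, d1, a2, d2, a1 * a2, a1 * d2, d1 * a2, d1 * d2),
       marginal = cbind(1, a1, d1, a2, d2))
}
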