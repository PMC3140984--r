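# Two-locus epistatic model fits, 1D/2D marker scans, bootstrap-averaged
# profiles, and permutation-derived study-wide thresholds.

# Additive-term F statistics for all markers at once, for one or many
# phenotype vectors. Y: n x P matrix (columns = phenotype vectors, e.g.
# permutations); A: n x m additive-coding matrix (NA allowed per marker).
# Returns an m x P matrix of F statistics (monomorphic markers -> 0).
.f_stats_multi <- function(Y, A) {
  M <- !is.na(A)
  X0 <- A
  X0[!M] <- 0
  n <- colSums(M)
  Sx <- colSums(X0)
  Sxx <- colSums(X0^2)
  SyM <- crossprod(M, Y)
  Syy <- crossprod(M, Y^2)
  Sxy <- crossprod(X0, Y)
  sxx <- Sxx - Sx^2 / pmax(n, 1)
  sxy <- Sxy - (Sx / pmax(n, 1)) * SyM
  syy <- Syy - SyM^2 / pmax(n, 1)
  poly <- sxx > 1e-12
  ssr <- sxy^2 / ifelse(poly, sxx, Inf)
  rss <- pmax(syy - ssr, 0)
  df2 <- pmax(n - 2, 0)
  eps <- 1e-10 * pmax(syy, 1)
  Fm <- ssr * (df2 / pmax(rss, .Machine$double.xmin))
  Fm[rss <= eps & ssr > eps] <- Inf
  Fm[ssr <= eps] <- 0
  Fm[!poly | df2 == 0] <- 0
  Fm
}

# Least-squares RSS and rank via pivoted QR.
.qr_fit <- function(X, yv) {
  q <- qr(X)
  list(q = q, rank = q$rank, rss = sum(qr.resid(q, yv)^2))
}

.nested_f <- function(rss_red, rank_red, rss_full, rank_full, n) {
  dfn <- rank_full - rank_red
  dfd <- n - rank_full
  if (dfn <= 0 || dfd <= 0) return(0)
  num <- (rss_red - rss_full) / dfn
  den <- rss_full / dfd
  eps <- 1e-10 * max(rss_red, 1)
  if (den <= eps / dfd) {
    if (num > eps) return(Inf) else return(0)
  }
  max(num / den, 0)
}

#' Fit the two-locus epistatic model at a marker pair
#'
#' Least squares of the (residualized) phenotype on marginal additive and
#' dominance terms of both loci plus the four product interaction terms
#' (additive-by-additive, additive-by-dominance, dominance-by-additive,
#' dominance-by-dominance). Additive coding HH = +1, HL = 0, LL = -1;
#' dominance HL = 1. Two nested F tests are reported: full model against the
#' marginal-only model (the interaction-improvement statistic) and against
#' the intercept-only model.
#'
#' @param y A `residual_phenotypes` table.
#' @param locusA,locusB Marker ids (columns of `g`).
#' @param g A `genotype_matrix` (discrete predictors, the default mode), or,
#'   with `predictors = "continuous"`, a `line_origin_matrix` whose raw
#'   contrast is the additive predictor and `1 - |contrast|` the dominance
#'   predictor.
#' @param min_n Minimum complete-case sample size.
#' @param predictors `"discrete"` or `"continuous"`.
#' @return Object of class `two_locus_fit`: `coefficients` (a1, d1, a2, d2,
#'   aa, ad, da, dd and intercept), `F_full_vs_marginal`, `F_full_vs_null`,
#'   `df_resid`, `n`, `aliased` (names of rank-deficient terms, fitted with
#'   minimum-norm/zero coefficients).
#' @export
fit_two_locus <- function(y, locusA, locusB, g, min_n = 30,
                          predictors = c("discrete", "continuous")) {
  predictors <- match.arg(predictors)
  for (l in c(locusA, locusB)) {
    if (!l %in% colnames(g)) stop("locus not present in matrix: ", l)
  }
  yv <- align_phenotypes(y, g)
  if (predictors == "discrete") {
    a1 <- additive_code(g[, locusA]); d1 <- dominance_code(g[, locusA])
    a2 <- additive_code(g[, locusB]); d2 <- dominance_code(g[, locusB])
  } else {
    c1 <- as.numeric(g[, locusA]); c2 <- as.numeric(g[, locusB])
    a1 <- c1; d1 <- 1 - abs(c1); a2 <- c2; d2 <- 1 - abs(c2)
  }
  cc <- stats::complete.cases(yv, a1, d1, a2, d2)
  n <- sum(cc)
  if (n < min_n) {
    stop("only ", n, " complete observations at ", locusA, " x ", locusB,
         " (minimum ", min_n, ")")
  }
  yv <- yv[cc]; a1 <- a1[cc]; d1 <- d1[cc]; a2 <- a2[cc]; d2 <- d2[cc]
  Xf <- cbind(`(Intercept)` = 1, a1 = a1, d1 = d1, a2 = a2, d2 = d2,
              aa = a1 * a2, ad = a1 * d2, da = d1 * a2, dd = d1 * d2)
  ff <- .qr_fit(Xf, yv)
  fm <- .qr_fit(Xf[, 1:5, drop = FALSE], yv)
  rss0 <- sum((yv - mean(yv))^2)
  beta <- qr.coef(ff$q, yv)
  aliased <- names(beta)[is.na(beta)]
  beta[is.na(beta)] <- 0
  structure(list(
    coefficients = beta,
    F_full_vs_marginal = .nested_f(fm$rss, fm$rank, ff$rss, ff$rank, n),
    F_full_vs_null = .nested_f(rss0, 1L, ff$rss, ff$rank, n),
    df_resid = n - ff$rank,
    rss_full = ff$rss, rss_marginal = fm$rss, rss_null = rss0,
    rank_full = ff$rank, rank_marginal = fm$rank,
    n = n, loci = c(locusA, locusB), aliased = aliased,
    predictors = predictors
  ), class = "two_locus_fit")
}

#' Two-dimensional epistasis scan and per-segment marker selection
#'
#' Fits the two-locus epistatic model for every between-segment marker pair
#' and, per segment, selects the marker whose largest
#' full-versus-marginal-model F statistic over all its pairings is highest
#' ("strongest support for interactions"). Ties break to the lowest marker
#' index.
#'
#' @inheritParams fit_two_locus
#' @param map A `marker_map` covering the columns of `g` (at least 2
#'   segments).
#' @return `data.frame` of class `selected_markers` with one row per segment
#'   (`segment`, `marker_id`, `score`); the full pair table (marker1,
#'   marker2, `F_full_vs_marginal`, `n`) is attached as attribute `"pairs"`.
#' @export
scan_2d <- function(y, g, map, min_n = 30) {
  map <- map[map$marker_id %in% colnames(g), , drop = FALSE]
  segs <- unique(map$segment)
  if (length(segs) < 2L) stop("scan_2d needs markers from at least 2 segments")
  ids <- map$marker_id
  yv <- align_phenotypes(y, g)
  A <- additive_code(g[, ids, drop = FALSE])
  D <- dominance_code(g[, ids, drop = FALSE])
  m <- length(ids)
  score <- rep(-Inf, m)
  pr <- utils::combn(m, 2L)
  keep <- map$segment[pr[1L, ]] != map$segment[pr[2L, ]]
  pr <- pr[, keep, drop = FALSE]
  pairs <- data.frame(marker1 = ids[pr[1L, ]], marker2 = ids[pr[2L, ]],
                      F_full_vs_marginal = NA_real_, n = NA_integer_,
                      stringsAsFactors = FALSE)
  for (p in seq_len(ncol(pr))) {
    i <- pr[1L, p]; j <- pr[2L, p]
    a1 <- A[, i]; d1 <- D[, i]; a2 <- A[, j]; d2 <- D[, j]
    cc <- stats::complete.cases(yv, a1, d1, a2, d2)
    n <- sum(cc)
    pairs$n[p] <- n
    if (n < min_n) next
    Xf <- cbind(1, a1[cc], d1[cc], a2[cc], d2[cc],
                (a1 * a2)[cc], (a1 * d2)[cc], (d1 * a2)[cc], (d1 * d2)[cc])
    ff <- .qr_fit(Xf, yv[cc])
    fm <- .qr_fit(Xf[, 1:5, drop = FALSE], yv[cc])
    fstat <- .nested_f(fm$rss, fm$rank, ff$rss, ff$rank, n)
    pairs$F_full_vs_marginal[p] <- fstat
    score[i] <- max(score[i], fstat)
    score[j] <- max(score[j], fstat)
  }
  sel <- do.call(rbind, lapply(segs, function(s) {
    k <- which(map$segment == s)
    if (length(k) == 1L) {
      best <- k
    } else {
      best <- k[which.max(score[k])]  # first max = lowest marker index
    }
    data.frame(segment = s, marker_id = ids[best],
               score = if (is.finite(score[best])) score[best] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  attr(sel, "pairs") <- pairs
  class(sel) <- c("selected_markers", "data.frame")
  sel
}

#' One-dimensional additive QTL scan
#'
#' Per-marker F statistic of the additive term (sex and generation are
#' handled by prior residualization of the phenotype). Monomorphic markers
#' get statistic 0 and are flagged.
#'
#' @param y A `residual_phenotypes` table.
#' @param markers Marker ids, in map order.
#' @param g A `genotype_matrix`.
#' @return `data.frame` of class `scan_profile`: `marker`, `F`, `n`,
#'   `monomorphic`.
#' @export
scan_1d <- function(y, markers, g) {
  if (length(markers) == 0L) stop("markers must be non-empty")
  missing_m <- setdiff(markers, colnames(g))
  if (length(missing_m) > 0L) {
    stop("marker(s) not in matrix: ", paste(missing_m, collapse = ", "))
  }
  yv <- align_phenotypes(y, g)
  ok <- !is.na(yv)
  A <- additive_code(g[ok, markers, drop = FALSE])
  Fv <- .f_stats_multi(matrix(yv[ok], ncol = 1L), A)[, 1L]
  M <- !is.na(A)
  X0 <- A; X0[!M] <- 0
  nm <- colSums(M)
  sxx <- colSums(X0^2) - colSums(X0)^2 / pmax(nm, 1)
  out <- data.frame(marker = markers, F = Fv, n = nm,
                    monomorphic = sxx <= 1e-12, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("scan_profile", "data.frame")
  out
}

#' Bootstrap-averaged one-dimensional scan
#'
#' Resamples individuals with replacement to the original sample size,
#' recomputes the one-dimensional scan on every bootstrap replicate, and
#' averages the per-marker statistics across replicates.
#'
#' @inheritParams scan_1d
#' @param B Number of bootstrap replicates (default 200).
#' @param seed Optional integer seed.
#' @param min_n Minimum number of individuals (refuses smaller strata).
#' @param indices_fun Resampling hook mainly for testing: a
#'   `function(n)` returning the row indices of one replicate (default:
#'   sample with replacement).
#' @return `data.frame` of class `scan_profile` with the bootstrap-averaged
#'   `F` per marker (`B` recorded as an attribute).
#' @export
bootstrap_scan <- function(y, markers, g, B = 200, seed = NULL, min_n = 30,
                           indices_fun = NULL) {
  stopifnot(B >= 1)
  with_seed_maybe(seed)
  yv <- align_phenotypes(y, g)
  ok <- !is.na(yv)
  if (sum(ok) < min_n) {
    stop("stratum of size ", sum(ok), " below minimum ", min_n)
  }
  A <- additive_code(g[ok, markers, drop = FALSE])
  yv <- yv[ok]
  n <- length(yv)
  if (is.null(indices_fun)) {
    indices_fun <- function(n) sample.int(n, n, replace = TRUE)
  }
  acc <- matrix(0, length(markers), B)
  for (b in seq_len(B)) {
    idx <- indices_fun(n)
    acc[, b] <- .f_stats_multi(matrix(yv[idx], ncol = 1L),
                               A[idx, , drop = FALSE])[, 1L]
  }
  out <- data.frame(marker = markers, F = rowMeans(acc),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "B") <- B
  class(out) <- c("scan_profile", "data.frame")
  out
}

#' Permutation-derived study-wide significance threshold for 1D scans
#'
#' Genotype rows are permuted against the (phenotype, sex, generation)
#' tuples -- because the phenotype is residualized on sex and generation
#' beforehand, this is realized by permuting the phenotype vector, which
#' keeps the phenotype/fixed-factor pairing intact while breaking the
#' genotype-phenotype link. The maximal marker statistic of each permuted
#' scan is recorded and the threshold is the empirical `1 - alpha` quantile
#' (type 7) of those maxima.
#'
#' @inheritParams scan_1d
#' @param N Number of permutations (default 1000; at least 100).
#' @param alpha Study-wide significance level in `(0, 1]` (default 0.05).
#' @param seed Optional integer seed.
#' @param chunk Permutations evaluated per matrix block.
#' @return List of class `permutation_threshold`: `threshold`, `alpha`, `N`,
#'   `maxima` (the `N` max statistics).
#' @export
permutation_threshold <- function(y, markers, g, N = 1000, alpha = 0.05,
                                  seed = NULL, chunk = 250L) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (N < 100) stop("at least 100 permutations are required")
  with_seed_maybe(seed)
  yv <- align_phenotypes(y, g)
  ok <- !is.na(yv)
  A <- additive_code(g[ok, markers, drop = FALSE])
  yv <- yv[ok]
  n <- length(yv)
  maxima <- numeric(N)
  done <- 0L
  while (done < N) {
    nb <- min(chunk, N - done)
    Y <- vapply(seq_len(nb), function(i) yv[sample.int(n)], numeric(n))
    Fm <- .f_stats_multi(Y, A)
    maxima[done + seq_len(nb)] <- apply(Fm, 2L, max)
    done <- done + nb
  }
  structure(list(
    threshold = unname(stats::quantile(maxima, 1 - alpha, type = 7)),
    alpha = alpha, N = N, maxima = maxima
  ), class = "permutation_threshold")
}

# Study-wide permutation threshold for the pair-interaction statistic
# (max over marker pairs of F full-vs-marginal). Used by the pipeline to
# declare pairs "interacting".
.pair_interaction_threshold <- function(yv, g, pairs, N = 1000, alpha = 0.05,
                                        min_n = 30) {
  n_all <- length(yv)
  Y <- vapply(seq_len(N), function(i) yv[sample.int(n_all)], numeric(n_all))
  maxF <- rep(0, N)
  for (p in seq_len(nrow(pairs))) {
    a1 <- additive_code(g[, pairs$marker1[p]])
    d1 <- dominance_code(g[, pairs$marker1[p]])
    a2 <- additive_code(g[, pairs$marker2[p]])
    d2 <- dominance_code(g[, pairs$marker2[p]])
    cc <- stats::complete.cases(yv, a1, d1, a2, d2)
    n <- sum(cc)
    if (n < min_n) next
    Xf <- cbind(1, a1, d1, a2, d2, a1 * a2, a1 * d2, d1 * a2,
                d1 * d2)[cc, , drop = FALSE]
    qf <- qr(Xf)
    qm <- qr(Xf[, 1:5, drop = FALSE])
    Yc <- Y[cc, , drop = FALSE]
    rss_f <- colSums(qr.resid(qf, Yc)^2)
    rss_m <- colSums(qr.resid(qm, Yc)^2)
    dfn <- qf$rank - qm$rank
    dfd <- n - qf$rank
    if (dfn <= 0 || dfd <= 0) next
    Fp <- ((rss_m - rss_f) / dfn) / (rss_f / dfd)
    maxF <- pmax(maxF, Fp)
  }
  unname(stats::quantile(maxF, 1 - alpha, type = 7))
}
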