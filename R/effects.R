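# Stratified additive-effect estimation, one-sided strata comparison,
# network-level summaries, and the k-level decomposition of multi-locus
# effects.

#' Additive effect of a marker within a conditioning stratum
#'
#' Least-squares slope of the residualized weight on the additive coding
#' (HH = +1, HL = 0, LL = -1) among the individuals of one stratum, with the
#' standard error from the fit.
#'
#' @param stratum An `ail_stratum` (see [make_strata()]).
#' @param marker Marker id whose effect is estimated.
#' @param y A `residual_phenotypes` table.
#' @param g A `genotype_matrix`.
#' @return Object of class `effect_estimate`: `locus`, `stratum` (descriptor
#'   string), `a` (g), `se` (g), `n`.
#' @export
stratified_additive_effect <- function(stratum, marker, y, g) {
  stopifnot(inherits(stratum, "ail_stratum"))
  if (!marker %in% colnames(g)) stop("marker not in matrix: ", marker)
  if (stratum$n < stratum$min_size) {
    stop("stratum ", stratum$locus, ".", stratum$class, " of size ",
         stratum$n, " below minimum ", stratum$min_size)
  }
  rows <- match(stratum$ids, rownames(g))
  if (anyNA(rows)) stop("stratum ids missing from genotype matrix")
  x <- additive_code(g[rows, marker])
  yv <- align_phenotypes(y, g[rows, , drop = FALSE])
  cc <- stats::complete.cases(x, yv)
  x <- x[cc]; yv <- yv[cc]
  n <- length(x)
  if (n < 3L || stats::var(x) <= 1e-12) {
    stop("no contrast: marker ", marker, " is monomorphic (or nearly empty) ",
         "within stratum ", stratum$locus, ".", stratum$class)
  }
  fit <- stats::lm(yv ~ x)
  sm <- summary(fit)$coefficients
  structure(list(locus = marker,
                 stratum = paste0(stratum$locus, ".", stratum$class),
                 a = unname(sm["x", "Estimate"]),
                 se = unname(sm["x", "Std. Error"]),
                 n = n),
            class = "effect_estimate")
}

#' One-sided comparison of stratified additive effects
#'
#' Wald test on the difference of two independent effect estimates:
#' z = (a_HH - a_LL) / sqrt(SE_HH^2 + SE_LL^2), with the one-sided p oriented
#' by `direction`. The emulated study never names its test and some of its
#' printed p-values are inconsistent with this choice; a permutation
#' alternative is available via `compare_strata_effects_perm()`.
#'
#' @param eHH,eLL `effect_estimate` objects (or lists with `a` and `se`).
#' @param direction `"HH>LL"` (default) or `"HH<LL"`.
#' @return Object of class `strata_comparison`: `a_HH`, `a_LL`, `se_HH`,
#'   `se_LL`, `direction`, `z`, `one_sided_p`.
#' @export
compare_strata_effects <- function(eHH, eLL, direction = c("HH>LL", "HH<LL")) {
  direction <- match.arg(direction)
  se <- sqrt(eHH$se^2 + eLL$se^2)
  diffa <- eHH$a - eLL$a
  if (se <= 0) {
    p <- if (abs(diffa) <= 0) 0.5 else if (xor(diffa > 0, direction == "HH>LL")) 1 else 0
    z <- if (diffa == 0) 0 else sign(diffa) * Inf
  } else {
    z <- diffa / se
    p <- if (direction == "HH>LL") stats::pnorm(z, lower.tail = FALSE)
         else stats::pnorm(z)
  }
  structure(list(a_HH = eHH$a, a_LL = eLL$a, se_HH = eHH$se, se_LL = eLL$se,
                 direction = direction, z = z, one_sided_p = p),
            class = "strata_comparison")
}

#' Permutation alternative to the Wald strata comparison
#'
#' Re-randomizes stratum labels over the pooled individuals and recomputes
#' the difference of within-stratum additive effects; the one-sided p is the
#' empirical exceedance probability of the observed difference.
#'
#' @inheritParams stratified_additive_effect
#' @param strata A two-element list (`HH`, `LL`) of `ail_stratum` objects at
#'   one conditioning locus.
#' @param direction `"HH>LL"` or `"HH<LL"`.
#' @param N Number of label permutations.
#' @param seed Optional integer seed.
#' @return A `strata_comparison` with `one_sided_p` from the permutation
#'   null (`method = "permutation"`).
#' @export
compare_strata_effects_perm <- function(strata, marker, y, g,
                                        direction = c("HH>LL", "HH<LL"),
                                        N = 1000, seed = NULL) {
  direction <- match.arg(direction)
  with_seed_maybe(seed)
  eHH <- stratified_additive_effect(strata$HH, marker, y, g)
  eLL <- stratified_additive_effect(strata$LL, marker, y, g)
  obs <- eHH$a - eLL$a
  ids <- c(strata$HH$ids, strata$LL$ids)
  nHH <- strata$HH$n
  rows <- match(ids, rownames(g))
  x <- additive_code(g[rows, marker])
  yv <- align_phenotypes(y, g[rows, , drop = FALSE])
  slope <- function(sel) {
    xx <- x[sel]; yy <- yv[sel]
    cc <- stats::complete.cases(xx, yy)
    if (sum(cc) < 3L || stats::var(xx[cc]) <= 1e-12) return(NA_real_)
    stats::cov(xx[cc], yy[cc]) / stats::var(xx[cc])
  }
  nulls <- vapply(seq_len(N), function(i) {
    idx <- sample.int(length(ids))
    slope(idx[seq_len(nHH)]) - slope(idx[-seq_len(nHH)])
  }, numeric(1))
  nulls <- nulls[!is.na(nulls)]
  p <- if (direction == "HH>LL") (sum(nulls >= obs) + 1) / (length(nulls) + 1)
       else (sum(nulls <= obs) + 1) / (length(nulls) + 1)
  out <- compare_strata_effects(eHH, eLL, direction)
  out$one_sided_p <- p
  out$method <- "permutation"
  out
}

#' Network-level summary of stratified effects
#'
#' Sums the HH- and LL-stratum additive effects over the supplied locus
#' pairs, forms their ratio, and expresses each sum as a percentage of the
#' founder-line difference (defaults 1522 g and 181 g) and optionally in
#' phenotypic-SD units.
#'
#' @param effects `data.frame` (or list of pairs) with columns/elements
#'   `a_HH` and `a_LL`, one row per stratified effect.
#' @param line_means Length-2 vector `(HWS mean, LWS mean)` in grams.
#' @param sd_ref Optional phenotypic SD (g) for sigma_P scaling.
#' @return Object of class `network_summary`: `sum_a_HH`, `sum_a_LL`,
#'   `ratio` (NA-flagged when the LL sum is 0), `pct_HH`, `pct_LL`, and
#'   (given `sd_ref`) `sigma_HH`, `sigma_LL`.
#' @export
network_summary <- function(effects, line_means = c(1522, 181), sd_ref = NULL) {
  if (is.list(effects) && !is.data.frame(effects)) {
    effects <- data.frame(a_HH = vapply(effects, function(e) e$a_HH %||% e$HH$a,
                                        numeric(1)),
                          a_LL = vapply(effects, function(e) e$a_LL %||% e$LL$a,
                                        numeric(1)))
  }
  if (nrow(effects) == 0L) stop("effects list must be non-empty")
  stopifnot(length(line_means) == 2L)
  sHH <- sum(effects$a_HH)
  sLL <- sum(effects$a_LL)
  denom <- line_means[1L] - line_means[2L]
  ratio <- if (abs(sLL) <= .Machine$double.eps * 100) NA_real_ else sHH / sLL
  out <- list(sum_a_HH = sHH, sum_a_LL = sLL, ratio = ratio,
              ratio_defined = !is.na(ratio),
              pct_HH = 100 * sHH / denom, pct_LL = 100 * sLL / denom,
              line_means = line_means)
  if (!is.null(sd_ref)) {
    out$sigma_HH <- sHH / sd_ref
    out$sigma_LL <- sLL / sd_ref
  }
  structure(out, class = "network_summary")
}

#' k-level decomposition of three-locus effects
#'
#' Attributes the total effect of a locus triplet to its members at
#' increasing interaction order k: at k = 1 each locus contributes its own
#' marginal effect; at k = 2 each locus contributes the average over its two
#' pairs of half the pair span (each locus of a pair is assumed to carry
#' half the pair's effect); at k = 3 each locus contributes a third of the
#' triplet span. Totals are the exact sums of the attributions (rounding
#' only at report time).
#'
#' @param marginals Named numeric vector of length 3: marginal effect (g)
#'   per locus.
#' @param pair_spans Named numeric vector of length 3 with names
#'   `"A:B"`, `"A:C"`, `"B:C"` (locus names as in `marginals`): span (g) of
#'   each pair's genotype-class means (highest minus lowest).
#' @param triplet_span Span (g) of the 27 triplet genotype-class means.
#' @return `data.frame` of class `k_decomposition` with rows k = 1, 2, 3:
#'   one attribution column per locus plus `total`.
#' @export
k_level_decomposition <- function(marginals, pair_spans, triplet_span) {
  if (length(marginals) != 3L) stop("exactly three loci are required")
  loci <- names(marginals)
  if (is.null(loci)) loci <- c("L1", "L2", "L3")
  expected <- c(paste(loci[1], loci[2], sep = ":"),
                paste(loci[1], loci[3], sep = ":"),
                paste(loci[2], loci[3], sep = ":"))
  if (is.null(names(pair_spans))) {
    if (length(pair_spans) != 3L) stop("three pair spans are required")
    names(pair_spans) <- expected
  }
  miss <- setdiff(expected, names(pair_spans))
  if (length(miss) > 0L) {
    stop("missing pair span for pair(s): ", paste(miss, collapse = ", "))
  }
  stopifnot(length(triplet_span) == 1L)
  k2 <- vapply(seq_along(loci), function(i) {
    own <- expected[vapply(strsplit(expected, ":", fixed = TRUE),
                           function(p) loci[i] %in% p, logical(1))]
    mean(pair_spans[own] / 2)
  }, numeric(1))
  k3 <- rep(triplet_span / 3, 3L)
  out <- data.frame(k = 1:3, rbind(unname(marginals), k2, k3),
                    total = c(sum(marginals), sum(k2), sum(k3)),
                    row.names = NULL)
  names(out)[2:4] <- loci
  class(out) <- c("k_decomposition", "data.frame")
  out
}

#' Span of genotype-class means
#'
#' Difference between the highest and lowest (non-missing) corrected
#' genotype-class means of a pair or triplet map -- the "pair span" /
#' "triplet span" consumed by [k_level_decomposition()].
#'
#' @param m A `genotype_class_map` (see [genotype_class_means()]).
#' @return Span in grams.
#' @export
genotype_span <- function(m) {
  v <- m$mean[!is.na(m$mean)]
  if (length(v) < 2L) stop("fewer than 2 populated classes")
  max(v) - min(v)
}
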