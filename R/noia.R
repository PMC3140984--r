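# Genotype-phenotype maps: model-free class means over HH-counts and the
# parametric orthogonal-effects (NOIA "statistical model") map, plus their
# comparison as an indicator of higher-order interactions.

# Per-locus NOIA statistical-scale columns (additive, dominance) given the
# observed genotype frequencies; rows ordered LL, HL, HH. The columns have
# zero mean and are mutually orthogonal under those frequencies; at ideal
# F2 frequencies (1/4, 1/2, 1/4) they reduce to the classical orthogonal
# codings (-1,0,1) and (-1/2,1/2,-1/2).
.noia_scaling <- function(freq, locus = "?") {
  freq <- freq[GENO_LEVELS]
  if (anyNA(freq) || any(freq <= 0)) {
    stop("locus ", locus,
         " has a zero-frequency genotype class; orthogonal scaling undefined")
  }
  pLL <- freq[["LL"]]; pHL <- freq[["HL"]]; pHH <- freq[["HH"]]
  xa <- c(0, 1, 2) - (pHL + 2 * pHH)
  D <- pLL + pHH - (pLL - pHH)^2
  xd <- c(-2 * pHL * pHH, 4 * pLL * pHH, -2 * pLL * pHL) / D
  m <- cbind(a = xa, d = xd)
  rownames(m) <- GENO_LEVELS
  m
}

# Effect terms up to the requested interaction order: reference "r",
# per-locus a./d., and all pairwise products (aa, ad, da, dd).
.noia_terms <- function(loci, order = 2) {
  stopifnot(order %in% c(1, 2))
  terms <- list(list(name = "r", comp = character(0)))
  for (l in loci) {
    terms <- c(terms, list(list(name = paste0("a.", l),
                                comp = stats::setNames("a", l)),
                           list(name = paste0("d.", l),
                                comp = stats::setNames("d", l))))
  }
  if (order >= 2 && length(loci) >= 2) {
    pr <- utils::combn(loci, 2)
    for (p in seq_len(ncol(pr))) {
      i <- pr[1, p]; j <- pr[2, p]
      for (ci in c("a", "d")) for (cj in c("a", "d")) {
        terms <- c(terms, list(list(
          name = paste0(ci, cj, ".", i, ":", j),
          comp = stats::setNames(c(ci, cj), c(i, j))
        )))
      }
    }
  }
  terms
}

# Design matrix: one row per genotype row of `calls` (character matrix with
# columns = loci), one column per term.
.noia_design <- function(calls, scalings, terms) {
  n <- nrow(calls)
  idx <- lapply(colnames(calls), function(l) match(calls[, l], GENO_LEVELS))
  names(idx) <- colnames(calls)
  X <- matrix(1, n, length(terms))
  colnames(X) <- vapply(terms, `[[`, character(1), "name")
  for (t in seq_along(terms)) {
    comp <- terms[[t]]$comp
    for (l in names(comp)) {
      X[, t] <- X[, t] * scalings[[l]][idx[[l]], comp[[l]]]
    }
  }
  X
}

#' Fit the orthogonal (NOIA statistical) multi-locus effect model
#'
#' Builds per-locus additive/dominance predictors scaled to the observed
#' genotype frequencies (so effect estimates are mutually orthogonal even
#' away from ideal F2 frequencies), forms all pairwise interaction products,
#' and fits the residualized phenotype by least squares.
#'
#' @param g A `genotype_matrix`.
#' @param y A `residual_phenotypes` table.
#' @param loci Marker ids to model jointly.
#' @param order Interaction order: 1 (marginal only) or 2 (default: marginal
#'   plus all pairwise interactions).
#' @return Object of class `noia_effects`: `effects` (named vector),
#'   `se`, `freqs` (3 x L genotype-frequency matrix), `loci`, `order`, `n`.
#' @export
noia_fit <- function(g, y, loci, order = 2) {
  missing_l <- setdiff(loci, colnames(g))
  if (length(missing_l) > 0L) {
    stop("loci not in matrix: ", paste(missing_l, collapse = ", "))
  }
  calls <- unclass(g)[, loci, drop = FALSE]
  yv <- align_phenotypes(y, g)
  cc <- stats::complete.cases(calls) & !is.na(yv)
  calls <- calls[cc, , drop = FALSE]
  yv <- yv[cc]
  n <- nrow(calls)
  freqs <- vapply(loci, function(l) {
    tab <- table(factor(calls[, l], GENO_LEVELS)) / n
    as.numeric(tab)
  }, numeric(3))
  rownames(freqs) <- GENO_LEVELS
  scalings <- lapply(loci, function(l) .noia_scaling(freqs[, l], l))
  names(scalings) <- loci
  terms <- .noia_terms(loci, order)
  X <- .noia_design(calls, scalings, terms)
  fit <- stats::lm(yv ~ X - 1)
  sm <- summary(fit)$coefficients
  eff <- stats::coef(fit)
  names(eff) <- colnames(X)
  eff[is.na(eff)] <- 0
  se <- rep(NA_real_, length(eff))
  names(se) <- names(eff)
  se[sub("^X", "", rownames(sm))] <- sm[, "Std. Error"]
  structure(list(effects = eff, se = se, freqs = freqs, loci = loci,
                 order = order, n = n),
            class = "noia_effects")
}

#' Transform orthogonal effects into a full genotype-phenotype map
#'
#' Applies the linear NOIA "transformation": the fitted effect vector is
#' mapped onto expected phenotypes (genotype values) for all `3^L`
#' multi-locus genotypes.
#'
#' @param e A `noia_effects` object (or one with the same fields).
#' @return `data.frame` of class `gp_map_parametric` with one column per
#'   locus plus `value` (g); effect provenance, frequencies and model order
#'   are carried as attributes.
#' @export
noia_to_gp_map <- function(e) {
  loci <- e$loci
  grid <- expand.grid(stats::setNames(rep(list(GENO_LEVELS), length(loci)),
                                      loci),
                      stringsAsFactors = FALSE)
  scalings <- lapply(loci, function(l) .noia_scaling(e$freqs[, l], l))
  names(scalings) <- loci
  terms <- .noia_terms(loci, e$order)
  tn <- vapply(terms, `[[`, character(1), "name")
  if (!setequal(tn, names(e$effects))) {
    stop("effect vector does not match the declared loci/model order")
  }
  S <- .noia_design(as.matrix(grid), scalings, terms)
  out <- cbind(grid, value = as.numeric(S %*% e$effects[colnames(S)]))
  attr(out, "freqs") <- e$freqs
  attr(out, "loci") <- loci
  attr(out, "order") <- e$order
  attr(out, "effects") <- e$effects
  class(out) <- c("gp_map_parametric", "data.frame")
  out
}

#' Recover orthogonal effects from a genotype-phenotype map
#'
#' Inverse of [noia_to_gp_map()]: weighted least squares of the genotype
#' values on the NOIA design, weighting each multi-locus genotype by the
#' product of its per-locus frequencies. For maps generated from an effect
#' vector of the same model order the round trip is exact.
#'
#' @param map A `gp_map_parametric` (or any map with locus columns, a
#'   `value` column, and a `freqs` attribute).
#' @param order Model order of the recovered effects.
#' @return A `noia_effects` object (no standard errors).
#' @export
noia_map_to_effects <- function(map, order = attr(map, "order") %||% 2) {
  loci <- attr(map, "loci")
  freqs <- attr(map, "freqs")
  if (is.null(loci) || is.null(freqs)) {
    stop("map must carry loci and frequency attributes")
  }
  scalings <- lapply(loci, function(l) .noia_scaling(freqs[, l], l))
  names(scalings) <- loci
  terms <- .noia_terms(loci, order)
  calls <- as.matrix(map[, loci, drop = FALSE])
  S <- .noia_design(calls, scalings, terms)
  w <- rep(1, nrow(calls))
  for (l in loci) w <- w * freqs[calls[, l], l]
  fit <- stats::lm.wfit(S, map$value, w)
  eff <- fit$coefficients
  eff[is.na(eff)] <- 0
  names(eff) <- colnames(S)
  structure(list(effects = eff, se = rep(NA_real_, length(eff)),
                 freqs = freqs, loci = loci, order = order, n = nrow(calls)),
            class = "noia_effects")
}

#' Model-free genotype-phenotype map over HH-counts
#'
#' Individuals with complete calls at the hub and radial loci, and
#' homozygous (HH or LL) at the hub, are grouped by (hub genotype, number of
#' radial loci at which they are HH homozygous). Heterozygous radial calls
#' count toward the "not HH" side. With four radial loci this yields the
#' 10 canonical classes; class means below the minimum size are reported as
#' missing (not zero).
#'
#' @param g A `genotype_matrix`.
#' @param y A `residual_phenotypes` table.
#' @param radial_loci Marker ids of the radial loci.
#' @param hub Marker id of the hub (conditioning) locus.
#' @param min_class_n Minimum class size for reporting a mean (default 3).
#' @return `data.frame` of class `gp_map_model_free`: `hub_genotype`,
#'   `n_hh`, `mean` (g), `sem` (g), `n`.
#' @export
model_free_gp_map <- function(g, y, radial_loci, hub, min_class_n = 3) {
  loci <- c(hub, radial_loci)
  missing_l <- setdiff(loci, colnames(g))
  if (length(missing_l) > 0L) {
    stop("loci not in matrix: ", paste(missing_l, collapse = ", "))
  }
  calls <- unclass(g)[, loci, drop = FALSE]
  yv <- align_phenotypes(y, g)
  keep <- stats::complete.cases(calls) & !is.na(yv) &
    calls[, hub] %in% c("HH", "LL")
  calls <- calls[keep, , drop = FALSE]
  yv <- yv[keep]
  n_hh <- rowSums(calls[, radial_loci, drop = FALSE] == "HH")
  R <- length(radial_loci)
  grid <- expand.grid(hub_genotype = c("LL", "HH"), n_hh = 0:R,
                      stringsAsFactors = FALSE)
  key <- paste(calls[, hub], n_hh)
  f <- factor(key, levels = paste(grid$hub_genotype, grid$n_hh))
  n <- as.integer(table(f))
  sums <- tapply(yv, f, sum, default = 0)
  ssq <- tapply(yv, f, function(z) sum(z^2), default = 0)
  mu <- ifelse(n > 0, sums / n, NA_real_)
  sdv <- ifelse(n > 1, sqrt(pmax(ssq - n * mu^2, 0) / (n - 1)), NA_real_)
  out <- data.frame(grid, mean = ifelse(n >= min_class_n, mu, NA_real_),
                    sem = ifelse(n >= max(min_class_n, 2), sdv / sqrt(n),
                                 NA_real_),
                    n = n, row.names = NULL)
  attr(out, "hub") <- hub
  attr(out, "radial_loci") <- radial_loci
  attr(out, "n_used") <- length(yv)
  class(out) <- c("gp_map_model_free", "data.frame")
  out
}

#' Observed-minus-expected class means as a higher-order indicator
#'
#' Collapses a parametric (second-order NOIA) genotype-phenotype map onto
#' the model-free HH-count classes -- weighting each multi-locus genotype by
#' the product of its per-locus frequencies -- and subtracts it from the
#' observed class means. Because third-order terms are deliberately absent
#' from the parametric fit, systematic nonzero differences indicate
#' higher-order interactions. The expected map is treated as fixed, so the
#' reported sem is the observed class sem.
#'
#' @param observed A `gp_map_model_free`.
#' @param expected A `gp_map_parametric` over the same hub and radial loci.
#' @return `data.frame`: `hub_genotype`, `n_hh`, `observed`, `expected`,
#'   `diff`, `sem`, `n`.
#' @export
higher_order_indicator <- function(observed, expected) {
  hub <- attr(observed, "hub")
  radial <- attr(observed, "radial_loci")
  loci <- attr(expected, "loci")
  if (!setequal(c(hub, radial), loci)) {
    stop("non-overlapping class sets: observed map loci (", hub, ", ",
         paste(radial, collapse = ", "), ") differ from parametric map loci (",
         paste(loci, collapse = ", "), ")")
  }
  freqs <- attr(expected, "freqs")
  calls <- as.matrix(expected[, loci, drop = FALSE])
  w <- rep(1, nrow(calls))
  for (l in loci) w <- w * freqs[calls[, l], l]
  keep <- calls[, hub] %in% c("HH", "LL")
  n_hh <- rowSums(calls[, radial, drop = FALSE] == "HH")
  key <- paste(calls[, hub], n_hh)[keep]
  ew <- tapply(expected$value[keep] * w[keep], key, sum) /
    tapply(w[keep], key, sum)
  okey <- paste(observed$hub_genotype, observed$n_hh)
  out <- data.frame(observed[, c("hub_genotype", "n_hh")],
                    observed = observed$mean,
                    expected = as.numeric(ew[okey]),
                    sem = observed$sem, n = observed$n, row.names = NULL)
  out$diff <- out$observed - out$expected
  out
}
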