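# Pair/triplet genotype-class means, plane extraction, within-plane
# variances, and the R_p max/min plane-variance ratio for capacitating
# third-order epistasis.

#' Corrected phenotypic means for all two- or three-locus genotype classes
#'
#' @param g A `genotype_matrix`.
#' @param y A `residual_phenotypes` table.
#' @param loci 2 or 3 marker ids; individuals missing a call at any of them
#'   are excluded.
#' @param min_cell_n Minimum individuals per class for a reported mean
#'   (default 3); smaller classes keep their count but are flagged missing.
#' @return `data.frame` of class `genotype_class_map` with one row per class
#'   (9 or 27): one call column per locus, `n`, `mean` (g), `sem` (g).
#' @export
genotype_class_means <- function(g, y, loci, min_cell_n = 3) {
  L <- length(loci)
  if (!L %in% c(2L, 3L)) stop("loci must name 2 or 3 markers")
  missing_l <- setdiff(loci, colnames(g))
  if (length(missing_l) > 0L) {
    stop("loci not in matrix: ", paste(missing_l, collapse = ", "))
  }
  calls <- unclass(g)[, loci, drop = FALSE]
  yv <- align_phenotypes(y, g)
  cc <- stats::complete.cases(calls) & !is.na(yv)
  calls <- calls[cc, , drop = FALSE]
  yv <- yv[cc]
  grid <- expand.grid(stats::setNames(rep(list(GENO_LEVELS), L), loci),
                      stringsAsFactors = FALSE)
  lev <- do.call(paste, c(grid, sep = ":"))
  f <- factor(do.call(paste, c(as.data.frame(calls), sep = ":")), levels = lev)
  n <- as.integer(table(f))
  if (sum(n > 0L) < 2L) stop("fewer than 2 populated genotype classes")
  sums <- tapply(yv, f, sum, default = 0)
  ssq <- tapply(yv, f, function(z) sum(z^2), default = 0)
  mu <- ifelse(n > 0, sums / n, NA_real_)
  sdv <- ifelse(n > 1, sqrt(pmax(ssq - n * mu^2, 0) / pmax(n - 1, 1)),
                NA_real_)
  out <- data.frame(grid, n = n,
                    mean = ifelse(n >= min_cell_n, mu, NA_real_),
                    sem = ifelse(n >= max(min_cell_n, 2L), sdv / sqrt(n),
                                 NA_real_),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "loci") <- loci
  attr(out, "min_cell_n") <- min_cell_n
  attr(out, "n_used") <- length(yv)
  class(out) <- c("genotype_class_map", "data.frame")
  out
}

#' Split a triplet class map into conditioning-locus planes
#'
#' The 27 three-locus classes are partitioned into three planes of nine
#' cells sharing one genotype (LL, HL or HH) at the conditioning locus, and
#' each plane's variance over its populated cell means is computed.
#'
#' @param m A triplet `genotype_class_map`.
#' @param conditioning_locus One of the map's loci.
#' @param min_cells Minimum populated cells (of 9) for a defined plane
#'   variance (default 5).
#' @param weight `"none"` (default: unweighted sample variance, divisor
#'   n-1) or `"count"` (cell-count-weighted, unbiased).
#' @return Object of class `plane_set`: `conditioning_locus`, `planes`
#'   (list of the three 9-cell data frames), `variances` (named LL/HL/HH,
#'   `NA` when undefined), `n_populated`.
#' @export
extract_planes <- function(m, conditioning_locus, min_cells = 5,
                           weight = c("none", "count")) {
  weight <- match.arg(weight)
  loci <- attr(m, "loci")
  if (length(loci) != 3L) stop("plane extraction needs a triplet map")
  if (!conditioning_locus %in% loci) {
    stop("conditioning locus ", conditioning_locus, " not among map loci")
  }
  planes <- lapply(stats::setNames(GENO_LEVELS, GENO_LEVELS), function(cl) {
    m[m[[conditioning_locus]] == cl, , drop = FALSE]
  })
  variances <- vapply(planes, function(p) {
    v <- p$mean[!is.na(p$mean)]
    if (length(v) < min_cells) return(NA_real_)
    if (weight == "none") return(stats::var(v))
    w <- p$n[!is.na(p$mean)]
    cw <- stats::cov.wt(matrix(v, ncol = 1), wt = w / sum(w),
                        method = "unbiased")
    as.numeric(cw$cov)
  }, numeric(1))
  structure(list(conditioning_locus = conditioning_locus, planes = planes,
                 variances = variances,
                 n_populated = vapply(planes, function(p) sum(!is.na(p$mean)),
                                      integer(1)),
                 weight = weight, min_cells = min_cells),
            class = "plane_set")
}

#' Plane-variance ratio R_p
#'
#' R_p is the ratio of the largest to the smallest defined within-plane
#' variance of a conditioning locus. A zero minimum variance makes the ratio
#' unbounded; such results are flagged `undefined-infinite` rather than
#' assigned a pseudo-number, since the scale of the ratio is dominated by
#' the smallest variance.
#'
#' @param p A `plane_set`.
#' @return Object of class `rp_result`: `conditioning_locus`, `variances`,
#'   `rp` (`>= 1` when valid, `Inf` when flagged), `valid`, `reason`.
#' @export
rp_ratio <- function(p) {
  stopifnot(inherits(p, "plane_set"))
  v <- p$variances
  defined <- !is.na(v)
  if (!any(defined)) stop("all plane variances are missing")
  if (sum(defined) < 2L) {
    stop("fewer than 2 planes with a defined variance")
  }
  vd <- v[defined]
  mn <- min(vd)
  mx <- max(vd)
  if (mn <= 1e-12 * max(mx, 1)) {
    res <- list(conditioning_locus = p$conditioning_locus, variances = v,
                rp = Inf, valid = FALSE, reason = "undefined-infinite")
  } else {
    res <- list(conditioning_locus = p$conditioning_locus, variances = v,
                rp = mx / mn, valid = TRUE, reason = NA_character_)
  }
  structure(res, class = "rp_result")
}

#' Exhaustive triplet R_p scan
#'
#' Enumerates all locus triplets among the candidates; for each triplet the
#' 27 corrected class means are computed once and R_p is evaluated for each
#' of the three conditioning choices (so `C(k,3) * 3` values for k candidate
#' loci). Triplets or planes with insufficient data are flagged and the scan
#' continues. Optionally, a permutation null (phenotypes permuted against
#' the genotype triplets) yields an empirical exceedance per value -- an
#' addition beyond the original analysis, which left significance testing of
#' R_p open.
#'
#' @inheritParams genotype_class_means
#' @inheritParams extract_planes
#' @param candidate_loci At least 3 marker ids.
#' @param null_perms Number of phenotype permutations for the optional
#'   empirical null (0 = none).
#' @param seed Optional integer seed (used for the permutation null).
#' @return `data.frame` of class `rp_scan` sorted by decreasing `rp`:
#'   `locus1..3`, `conditioning_locus`, `var_LL/HL/HH`, `rp`, `valid`,
#'   `reason`, and `null_exceedance` when permutations were requested.
#' @export
rp_scan <- function(g, y, candidate_loci, min_cell_n = 3, min_cells = 5,
                    weight = c("none", "count"), null_perms = 0, seed = NULL) {
  weight <- match.arg(weight)
  if (length(candidate_loci) < 3L) stop("at least 3 candidate loci required")
  with_seed_maybe(seed)
  trips <- utils::combn(candidate_loci, 3L)
  rows <- list()
  maps <- list()
  for (t in seq_len(ncol(trips))) {
    loci <- trips[, t]
    m <- tryCatch(genotype_class_means(g, y, loci, min_cell_n = min_cell_n),
                  error = function(e) e)
    for (cond in loci) {
      if (inherits(m, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus1 = loci[1], locus2 = loci[2], locus3 = loci[3],
          conditioning_locus = cond, var_LL = NA_real_, var_HL = NA_real_,
          var_HH = NA_real_, rp = NA_real_, valid = FALSE,
          reason = conditionMessage(m), stringsAsFactors = FALSE)
        next
      }
      res <- tryCatch(rp_ratio(extract_planes(m, cond, min_cells = min_cells,
                                              weight = weight)),
                      error = function(e) e)
      if (inherits(res, "error")) {
        v <- rep(NA_real_, 3)
        rows[[length(rows) + 1L]] <- data.frame(
          locus1 = loci[1], locus2 = loci[2], locus3 = loci[3],
          conditioning_locus = cond, var_LL = v[1], var_HL = v[2],
          var_HH = v[3], rp = NA_real_, valid = FALSE,
          reason = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          locus1 = loci[1], locus2 = loci[2], locus3 = loci[3],
          conditioning_locus = cond, var_LL = res$variances[["LL"]],
          var_HL = res$variances[["HL"]], var_HH = res$variances[["HH"]],
          rp = res$rp, valid = res$valid, reason = res$reason,
          stringsAsFactors = FALSE)
      }
    }
    maps[[t]] <- m
  }
  out <- do.call(rbind, rows)
  if (null_perms > 0) {
    obs_rp <- out$rp
    exceed <- rep(0L, nrow(out))
    yv <- align_phenotypes(y, g)
    for (b in seq_len(null_perms)) {
      perm <- sample.int(length(yv))
      yp <- data.frame(id = rownames(g), residual = yv[perm],
                       stringsAsFactors = FALSE)
      k <- 0L
      for (t in seq_len(ncol(trips))) {
        loci <- trips[, t]
        mP <- tryCatch(genotype_class_means(g, yp, loci,
                                            min_cell_n = min_cell_n),
                       error = function(e) e)
        for (cond in loci) {
          k <- k + 1L
          if (inherits(mP, "error") || is.na(obs_rp[k])) next
          rpP <- tryCatch(rp_ratio(extract_planes(mP, cond,
                                                  min_cells = min_cells,
                                                  weight = weight))$rp,
                          error = function(e) NA_real_)
          if (!is.na(rpP) && rpP >= obs_rp[k]) exceed[k] <- exceed[k] + 1L
        }
      }
    }
    out$null_exceedance <- ifelse(is.na(obs_rp), NA_real_,
                                  (exceed + 1) / (null_perms + 1))
  }
  out <- out[order(out$rp, decreasing = TRUE, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rp_scan", "data.frame")
  out
}
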