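# Contrast discretization, fixed-effect residualization, and
# conditioning-locus strata.

#' Discretize line-origin contrasts into genotype calls
#'
#' Contrasts above `hi` are called HH, below `lo` LL, otherwise HL; missing
#' contrasts become `NA`. The default +-0.4 thresholds are conservative: the
#' HL interval is wider than the homozygote intervals to avoid falsely
#' assigned homozygotes, and boundary values land in HL (strict
#' inequalities).
#'
#' @param m A `line_origin_matrix` (or any numeric matrix/vector with values
#'   in `[-1, 1]`).
#' @param hi,lo Homozygote thresholds, `-1 <= lo < hi <= 1`.
#' @return Character matrix (or vector) of calls in `{"HH","HL","LL",NA}`,
#'   class `genotype_matrix` for matrix input.
#' @export
discretize_contrasts <- function(m, hi = 0.4, lo = -0.4) {
  if (lo >= hi) stop("thresholds must satisfy lo < hi")
  if (hi > 1 || lo < -1) stop("thresholds must lie within [-1, 1]")
  x <- unclass(m)
  rng <- range(x, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -1 || rng[2] > 1)) {
    stop("contrast values outside [-1, 1]")
  }
  calls <- ifelse(is.na(x), NA_character_,
                  ifelse(x > hi, "HH", ifelse(x < lo, "LL", "HL")))
  if (is.matrix(x)) {
    calls <- matrix(calls, nrow = nrow(x), dimnames = dimnames(x))
    class(calls) <- c("genotype_matrix", class(calls))
  }
  calls
}

#' Residualize phenotypes for sex and generation
#'
#' Each individual's weight is expressed as the deviation from the mean of
#' its sex-by-generation class, so class means of the residuals are zero.
#' Classes of size one get residual 0 (with a warning).
#'
#' @param p A `phenotype_table` with columns `id`, `weight56`, `sex`,
#'   `generation` (a `residual` column is re-centered if already present).
#' @return `data.frame` of class `residual_phenotypes` with columns `id`,
#'   `residual`, `sex`, `generation`.
#' @export
correct_phenotypes <- function(p) {
  need <- c("id", "sex", "generation")
  if (!all(need %in% names(p))) {
    stop("phenotype table must have columns id, weight56, sex, generation")
  }
  w <- if ("residual" %in% names(p)) p$residual else p$weight56
  if (is.null(w)) stop("phenotype table must have a weight56 column")
  cls <- interaction(p$sex, p$generation, drop = TRUE)
  sizes <- table(cls)
  if (any(sizes == 1L)) {
    warning(sum(sizes == 1L),
            " sex-by-generation class(es) of size 1; residual set to 0")
  }
  res <- w - stats::ave(w, cls, FUN = function(z) mean(z, na.rm = TRUE))
  res[is.na(res)] <- NA_real_
  out <- data.frame(id = p$id, residual = res, sex = p$sex,
                    generation = p$generation, stringsAsFactors = FALSE)
  class(out) <- c("residual_phenotypes", "data.frame")
  out
}

#' Conditioning-locus strata
#'
#' Splits the individuals into the HH and LL homozygote strata at a
#' conditioning locus; heterozygotes and missing calls belong to neither.
#'
#' @param g A `genotype_matrix`.
#' @param locus Marker id (column of `g`).
#' @param min_size Minimum stratum size downstream scans will accept
#'   (recorded on the stratum; empty/small strata are returned with a
#'   warning, and refused by the scan/estimation functions).
#' @return List with elements `HH` and `LL`, each of class `ail_stratum`:
#'   `locus`, `class`, `ids`, `n`, `min_size`.
#' @export
make_strata <- function(g, locus, min_size = 30) {
  if (!locus %in% colnames(g)) stop("locus not present in matrix: ", locus)
  calls <- g[, locus]
  out <- lapply(c(HH = "HH", LL = "LL"), function(cl) {
    ids <- rownames(g)[!is.na(calls) & calls == cl]
    structure(list(locus = locus, class = cl, ids = ids, n = length(ids),
                   min_size = min_size),
              class = "ail_stratum")
  })
  for (cl in names(out)) {
    if (out[[cl]]$n == 0L) {
      warning("empty ", cl, " stratum at ", locus)
    }
  }
  out
}

#' Strata for a batch of conditioning loci
#'
#' @param g A `genotype_matrix`.
#' @param loci Marker ids.
#' @inheritParams make_strata
#' @return Flat named list of `ail_stratum` objects (`<locus>.HH`,
#'   `<locus>.LL`), two per conditioning locus.
#' @export
make_all_strata <- function(g, loci, min_size = 30) {
  out <- list()
  for (locus in loci) {
    s <- make_strata(g, locus, min_size = min_size)
    out[[paste0(locus, ".HH")]] <- s$HH
    out[[paste0(locus, ".LL")]] <- s$LL
  }
  out
}
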