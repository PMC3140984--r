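# Shared genotype codings and small helpers.

# Genotype class levels, ordered by high-line (HWS) allele count.
GENO_LEVELS <- c("LL", "HL", "HH")

.ADD_CODE <- c(LL = -1, HL = 0, HH = 1)

#' Additive coding of genotype calls
#'
#' Maps line-origin genotype calls to the additive predictor used throughout:
#' HH = +1, HL = 0, LL = -1 (HWS allele count minus 1). `NA` propagates.
#'
#' @param calls Character vector or matrix of calls in `{"HH","HL","LL",NA}`.
#' @return Numeric vector or matrix of the same shape.
#' @export
additive_code <- function(calls) {
  out <- unname(.ADD_CODE[calls])
  if (is.matrix(calls)) {
    out <- matrix(out, nrow = nrow(calls), dimnames = dimnames(calls))
  }
  out
}

#' Dominance coding of genotype calls
#'
#' HL = 1, homozygotes = 0. `NA` propagates.
#'
#' @inheritParams additive_code
#' @return Numeric vector or matrix of the same shape.
#' @export
dominance_code <- function(calls) {
  out <- ifelse(is.na(calls), NA_real_, as.numeric(calls == "HL"))
  if (is.matrix(calls)) {
    out <- matrix(out, nrow = nrow(calls), dimnames = dimnames(calls))
  }
  out
}

# Align a residual-phenotype table to the rows of a genotype/contrast matrix.
# Returns a numeric vector in rownames(m) order.
align_phenotypes <- function(y, m) {
  ids <- rownames(m)
  if (is.null(ids)) stop("genotype matrix has no individual ids (rownames)")
  idx <- match(ids, y$id)
  if (anyNA(idx)) {
    stop(
      "individuals missing from phenotype table: ",
      paste(utils::head(ids[is.na(idx)], 5L), collapse = ", ")
    )
  }
  yv <- y$residual
  if (is.null(yv)) yv <- y$weight56
  yv[idx]
}

# set.seed wrapper that tolerates NULL (use current RNG stream).
with_seed_maybe <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
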