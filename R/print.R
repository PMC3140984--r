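# Compact print methods for the core result objects.

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Additive effect of %s in stratum %s: a = %.1f +- %.1f g (n = %d)\n",
              x$locus, x$stratum, x$a, x$se, x$n))
  invisible(x)
}

#' @export
print.strata_comparison <- function(x, ...) {
  cat(sprintf("a(HH) = %.1f +- %.1f g vs a(LL) = %.1f +- %.1f g\n",
              x$a_HH, x$se_HH, x$a_LL, x$se_LL))
  cat(sprintf("one-sided P[a(%s)] = %.3f%s\n",
              x$direction, x$one_sided_p,
              if (!is.null(x$method)) paste0(" (", x$method, ")") else ""))
  invisible(x)
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("Sum of additive effects: HH %.1f g, LL %.1f g (ratio %s)\n",
              x$sum_a_HH, x$sum_a_LL,
              if (x$ratio_defined) sprintf("%.1f", x$ratio) else "undefined"))
  cat(sprintf("Percent of founder-line difference: HH %.0f%%, LL %.0f%%\n",
              x$pct_HH, x$pct_LL))
  if (!is.null(x$sigma_HH)) {
    cat(sprintf("In phenotypic SD units: HH %.1f, LL %.1f sigma_P\n",
                x$sigma_HH, x$sigma_LL))
  }
  invisible(x)
}

#' @export
print.two_locus_fit <- function(x, ...) {
  cat(sprintf("Two-locus epistatic fit: %s x %s (n = %d)\n",
              x$loci[1], x$loci[2], x$n))
  print(round(x$coefficients, 3))
  cat(sprintf("F (full vs marginal) = %.3f; F (full vs null) = %.3f\n",
              x$F_full_vs_marginal, x$F_full_vs_null))
  if (length(x$aliased) > 0L) {
    cat("aliased terms:", paste(x$aliased, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.rp_result <- function(x, ...) {
  v <- paste(sprintf("%s %.1f", names(x$variances), x$variances),
             collapse = ", ")
  cat(sprintf("R_p at %s: %s (plane variances: %s)\n",
              x$conditioning_locus,
              if (x$valid) sprintf("%.2f", x$rp) else x$reason, v))
  invisible(x)
}
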