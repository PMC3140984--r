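# Data ingestion/validation, analysis configuration, and the end-to-end
# pipeline tying the stages together.

#' Analysis configuration
#'
#' All defaults equal the emulated study's stated values: discretization
#' thresholds +-0.4, 200 bootstrap replicates, 1000 permutations at 95%
#' study-wide confidence, founder line means 1522 g and 181 g.
#'
#' @param thresholds Length-2 `(lo, hi)` homozygote thresholds.
#' @param bootstrap_B Bootstrap replicates for averaged 1D scans.
#' @param perms_N Permutations for 1D study-wide thresholds.
#' @param pair_perms_N Permutations for the pair-interaction threshold
#'   (defaults to `perms_N`).
#' @param alpha Study-wide significance level.
#' @param min_stratum Minimum stratum / complete-case size for scans.
#' @param min_cell_n Minimum individuals per genotype class mean.
#' @param min_cells_per_plane Minimum populated cells for a plane variance.
#' @param line_means Founder line means (HWS, LWS) in grams.
#' @param rp_candidates Maximum loci entering the triplet R_p scan.
#' @param do_stratified_scans Run bootstrap-averaged stratified 1D scans in
#'   the pipeline.
#' @param seed Integer seed governing the whole pipeline.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(thresholds = c(-0.4, 0.4), bootstrap_B = 200,
                            perms_N = 1000, pair_perms_N = perms_N,
                            alpha = 0.05, min_stratum = 30, min_cell_n = 3,
                            min_cells_per_plane = 5,
                            line_means = c(1522, 181), rp_candidates = 6,
                            do_stratified_scans = TRUE, seed = 1) {
  if (thresholds[1] >= thresholds[2] || thresholds[1] < -1 ||
      thresholds[2] > 1) {
    stop("thresholds must satisfy -1 <= lo < hi <= 1")
  }
  if (bootstrap_B < 1) stop("bootstrap_B must be >= 1")
  if (perms_N < 100 || pair_perms_N < 100) {
    stop("permutation counts must be >= 100")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (min_stratum < 3) stop("min_stratum must be >= 3")
  structure(list(schema_version = 1L, thresholds = thresholds,
                 bootstrap_B = bootstrap_B, perms_N = perms_N,
                 pair_perms_N = pair_perms_N, alpha = alpha,
                 min_stratum = min_stratum, min_cell_n = min_cell_n,
                 min_cells_per_plane = min_cells_per_plane,
                 line_means = line_means, rp_candidates = rp_candidates,
                 do_stratified_scans = do_stratified_scans,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the documented defaults.
#'
#' @param path YAML file.
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$schema_version <- NULL
  known <- setdiff(names(formals(analysis_config)), "...")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, vals)
}

#' Write a synthetic dataset to delimited text files
#'
#' Emits `contrasts.csv` (id + one column per marker), `phenotypes.csv`,
#' `pedigree.csv` and `marker_map.csv` under `dir`.
#'
#' @param d An `ail_dataset` (see [simulate_ail()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(d, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm <- data.frame(id = rownames(d$contrasts),
                   unclass(d$contrasts)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(cm, file.path(dir, "contrasts.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(d$phenotypes),
                   file.path(dir, "phenotypes.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(d$pedigree),
                   file.path(dir, "pedigree.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(d$map), file.path(dir, "marker_map.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load and validate a dataset from delimited text files
#'
#' @param paths Named list/vector with entries `contrasts`, `phenotypes`,
#'   and optionally `pedigree` and `map` (CSV paths as written by
#'   [write_dataset()]).
#' @param config An [analysis_config()] (for range checks).
#' @return Validated list of class `ail_dataset` (without architecture).
#' @export
load_dataset <- function(paths, config = analysis_config()) {
  for (p in c("contrasts", "phenotypes")) {
    if (is.null(paths[[p]])) stop("paths must include '", p, "'")
    if (!file.exists(paths[[p]])) stop("file not found: ", paths[[p]])
  }
  cm <- utils::read.csv(paths$contrasts, check.names = FALSE,
                        stringsAsFactors = FALSE)
  ids <- as.character(cm$id)
  if (anyDuplicated(ids)) {
    stop("duplicated individual ids in contrast matrix: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  }
  contrasts <- as.matrix(cm[, setdiff(names(cm), "id"), drop = FALSE])
  rownames(contrasts) <- ids
  bad <- which(!is.na(contrasts) & abs(contrasts) > 1, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("contrast value outside [-1, 1] at individual '",
         ids[bad[1, 1]], "', marker '", colnames(contrasts)[bad[1, 2]],
         "' (", nrow(bad), " offending cell(s))")
  }
  phen <- utils::read.csv(paths$phenotypes, stringsAsFactors = FALSE)
  unknown <- setdiff(phen$id, ids)
  if (length(unknown) > 0L) {
    stop("phenotype row(s) with unknown id: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  missing_ph <- setdiff(ids, phen$id)
  if (length(missing_ph) > 0L) {
    stop("individual(s) missing from phenotype table: ",
         paste(utils::head(missing_ph, 5), collapse = ", "))
  }
  class(phen) <- c("phenotype_table", "data.frame")
  ped <- NULL
  if (!is.null(paths$pedigree) && file.exists(paths$pedigree)) {
    ped <- utils::read.csv(paths$pedigree, stringsAsFactors = FALSE)
    class(ped) <- c("ail_pedigree", "data.frame")
  }
  map <- NULL
  if (!is.null(paths$map) && file.exists(paths$map)) {
    map <- utils::read.csv(paths$map, stringsAsFactors = FALSE)
    if (!setequal(map$marker_id, colnames(contrasts))) {
      stop("marker columns do not match the marker map")
    }
    map <- map[match(colnames(contrasts), map$marker_id), , drop = FALSE]
    class(map) <- c("marker_map", "data.frame")
  }
  class(contrasts) <- c("line_origin_matrix", class(contrasts))
  message("loaded dataset: ", length(ids), " individuals, ",
          ncol(contrasts), " markers, ",
          length(unique(phen$generation)), " generations")
  structure(list(pedigree = ped, map = map, contrasts = contrasts,
                 phenotypes = phen),
            class = "ail_dataset")
}

#' Run the full epistasis-analysis pipeline
#'
#' Stage order mirrors the emulated study: residualize and discretize;
#' two-dimensional scan to select one marker per segment; pair-interaction
#' tests against a permutation threshold; conditioning strata and
#' stratified additive effects with a network summary; (optionally)
#' bootstrap-averaged stratified 1D scans with study-wide thresholds;
#' model-free and parametric genotype-phenotype maps around the inferred
#' hub; and the exhaustive triplet R_p scan. A machine-readable manifest
#' (config, seed, versions) accompanies the outputs.
#'
#' @param d An `ail_dataset`.
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV/JSON (deterministically for a fixed config and seed).
#' @return List of class `ail_report` with elements `selected_markers`,
#'   `pairs`, `interaction_threshold`, `interacting_pairs`,
#'   `strata_effects`, `network_summary`, `stratified_scans`, `gp_map_free`,
#'   `noia`, `gp_map_parametric`, `higher_order`, `rp`, `manifest`.
#' @export
run_pipeline <- function(d, config = analysis_config(), out_dir = NULL) {
  stopifnot(inherits(d, "ail_dataset"), inherits(config, "analysis_config"))
  set.seed(config$seed)
  report <- list()
  persist <- function() {
    if (!is.null(out_dir)) .write_report(report, out_dir, config)
  }
  stage <- function(name, expr) {
    message("[", name, "] ...")
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      persist()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message("[", name, "] done (", round(proc.time()[["elapsed"]] - t0, 2),
            " s)")
    out
  }

  yres <- stage("residualize", correct_phenotypes(d$phenotypes))
  gmat <- stage("discretize",
                discretize_contrasts(d$contrasts, hi = config$thresholds[2],
                                     lo = config$thresholds[1]))
  sel <- stage("scan2d", scan_2d(yres, gmat, d$map,
                                 min_n = config$min_stratum))
  report$selected_markers <- sel

  ip <- stage("interactions", {
    ids <- sel$marker_id
    pr <- utils::combn(length(ids), 2L)
    pairs <- data.frame(marker1 = ids[pr[1, ]], marker2 = ids[pr[2, ]],
                        stringsAsFactors = FALSE)
    pairs$F_full_vs_marginal <- vapply(seq_len(nrow(pairs)), function(k) {
      tryCatch(fit_two_locus(yres, pairs$marker1[k], pairs$marker2[k], gmat,
                             min_n = config$min_stratum)$F_full_vs_marginal,
               error = function(e) NA_real_)
    }, numeric(1))
    yv <- align_phenotypes(yres, gmat)
    thr <- .pair_interaction_threshold(yv, gmat, pairs,
                                       N = config$pair_perms_N,
                                       alpha = config$alpha,
                                       min_n = config$min_stratum)
    pairs$interacting <- !is.na(pairs$F_full_vs_marginal) &
      pairs$F_full_vs_marginal > thr
    list(pairs = pairs, threshold = thr)
  })
  report$pairs <- ip$pairs
  report$interaction_threshold <- ip$threshold
  report$interacting_pairs <- ip$pairs[ip$pairs$interacting, , drop = FALSE]

  report$strata_effects <- stage("strata-effects", {
    ipairs <- report$interacting_pairs
    rows <- list()
    for (k in seq_len(nrow(ipairs))) {
      for (ori in 1:2) {
        tested <- ipairs[[ori]][k]
        conditioning <- ipairs[[3 - ori]][k]
        st <- suppressWarnings(make_strata(gmat, conditioning,
                                           min_size = config$min_stratum))
        est <- tryCatch({
          eHH <- stratified_additive_effect(st$HH, tested, yres, gmat)
          eLL <- stratified_additive_effect(st$LL, tested, yres, gmat)
          dir <- if (eHH$a >= eLL$a) "HH>LL" else "HH<LL"
          cmpr <- compare_strata_effects(eHH, eLL, dir)
          data.frame(tested = tested, conditioning = conditioning,
                     a_HH = eHH$a, se_HH = eHH$se, n_HH = eHH$n,
                     a_LL = eLL$a, se_LL = eLL$se, n_LL = eLL$n,
                     direction = dir, one_sided_p = cmpr$one_sided_p,
                     stringsAsFactors = FALSE)
        }, error = function(e) NULL)
        if (!is.null(est)) rows[[length(rows) + 1L]] <- est
      }
    }
    if (length(rows) > 0L) do.call(rbind, rows) else
      data.frame(tested = character(0))
  })

  report$network_summary <- stage("network-summary", {
    se <- report$strata_effects
    if (nrow(se) > 0L) {
      additive <- se[se$direction == "HH>LL", , drop = FALSE]
      if (nrow(additive) > 0L) {
        network_summary(additive[, c("a_HH", "a_LL")],
                        line_means = config$line_means,
                        sd_ref = stats::sd(align_phenotypes(yres, gmat)))
      } else NULL
    } else NULL
  })

  hub <- NULL
  partners <- character(0)
  if (nrow(report$interacting_pairs) > 0L) {
    cnt <- sort(table(c(report$interacting_pairs$marker1,
                        report$interacting_pairs$marker2)),
                decreasing = TRUE)
    hub <- names(cnt)[1L]
    ipp <- report$interacting_pairs
    partners <- unique(c(ipp$marker2[ipp$marker1 == hub],
                         ipp$marker1[ipp$marker2 == hub]))
  }
  report$hub <- hub

  report$stratified_scans <- if (config$do_stratified_scans && !is.null(hub)) {
    stage("stratified-scans", {
      conds <- unique(c(hub, partners))
      out <- list()
      for (cl in conds) {
        st <- suppressWarnings(make_strata(gmat, cl,
                                           min_size = config$min_stratum))
        others <- d$map$marker_id[d$map$segment !=
                                    d$map$segment[d$map$marker_id == cl]]
        for (which_st in c("HH", "LL")) {
          s <- st[[which_st]]
          if (s$n < config$min_stratum) next
          gsub_ <- gmat[s$ids, , drop = FALSE]
          prof <- bootstrap_scan(yres, others, gsub_, B = config$bootstrap_B,
                                 min_n = config$min_stratum)
          thr <- permutation_threshold(yres, others, gsub_,
                                       N = config$perms_N,
                                       alpha = config$alpha)
          prof$above_threshold <- prof$F > thr$threshold
          attr(prof, "threshold") <- thr$threshold
          out[[paste0(cl, ".", which_st)]] <- prof
        }
      }
      out
    })
  } else NULL

  if (!is.null(hub) && length(partners) >= 2L) {
    radial <- utils::head(partners, 4L)
    report$gp_map_free <- stage("gp-map-free",
      model_free_gp_map(gmat, yres, radial, hub,
                        min_class_n = config$min_cell_n))
    report$noia <- stage("noia", noia_fit(gmat, yres, c(hub, radial)))
    report$gp_map_parametric <- stage("noia-transform",
                                      noia_to_gp_map(report$noia))
    report$higher_order <- stage("higher-order",
      higher_order_indicator(report$gp_map_free, report$gp_map_parametric))
  }

  report$rp <- stage("triplet-rp", {
    ord <- order(sel$score, decreasing = TRUE)
    cand <- unique(c(hub, partners, sel$marker_id[ord]))
    cand <- utils::head(cand[!is.na(cand)], config$rp_candidates)
    rp_scan(gmat, yres, cand, min_cell_n = config$min_cell_n,
            min_cells = config$min_cells_per_plane)
  })

  report$manifest <- list(
    package = "ailnet",
    package_version = as.character(utils::packageVersion("ailnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    n_individuals = nrow(d$contrasts),
    n_markers = ncol(d$contrasts),
    hub = hub
  )
  class(report) <- "ail_report"
  if (!is.null(out_dir)) .write_report(report, out_dir, config)
  report
}

.write_report <- function(report, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    if (!is.null(x)) {
      utils::write.csv(as.data.frame(x), file.path(out_dir, name),
                       row.names = FALSE)
    }
  }
  wcsv(report$selected_markers, "selected_markers.csv")
  wcsv(report$pairs, "pairs.csv")
  wcsv(report$strata_effects, "strata_effects.csv")
  wcsv(report$gp_map_free, "gp_map_free.csv")
  wcsv(report$gp_map_parametric, "gp_map_parametric.csv")
  wcsv(report$higher_order, "higher_order.csv")
  wcsv(report$rp, "rp_scan.csv")
  if (!is.null(report$stratified_scans)) {
    for (nm in names(report$stratified_scans)) {
      wcsv(report$stratified_scans[[nm]], paste0("scan_", nm, ".csv"))
    }
  }
  if (!is.null(report$noia)) {
    wcsv(data.frame(term = names(report$noia$effects),
                    estimate = unname(report$noia$effects),
                    se = unname(report$noia$se)), "noia_effects.csv")
  }
  if (!is.null(report$network_summary)) {
    jsonlite::write_json(unclass(report$network_summary),
                         file.path(out_dir, "network_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(report$manifest)) {
    jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(out_dir)
}
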