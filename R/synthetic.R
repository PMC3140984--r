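# Synthetic advanced intercross line (AIL): pedigree construction,
# gene-dropping of line-origin haplotypes, epistatic genotype-phenotype
# architectures, and phenotype simulation.

# The nine QTL segments under study, with their physical bounds (Mb).
.SEGMENT_TABLE <- data.frame(
  segment = c("Growth1", "Growth2", "Growth3", "Growth4", "Growth6",
              "Growth7", "Growth8", "Growth9", "Growth12"),
  start_mb = c(169.6, 47.9, 124.3, 24.0, 1.3, 85.5, 33.7, 10.9, 7.1),
  stop_mb  = c(181.1, 65.5, 133.6, 68.0, 13.5, 88.8, 39.1, 35.5, 13.9),
  stringsAsFactors = FALSE
)

#' Pedigree specification for an advanced intercross line
#'
#' The defaults describe the study design emulated throughout the package:
#' reciprocal founder matings between a high-weight-selected (HWS) and a
#' low-weight-selected (LWS) chicken line (10 HWS males x 22 LWS females and
#' 8 LWS males x 19 HWS females, 59 founders in total), followed by eight
#' intercross generations of sizes 100, 100, 300, 100, 100, 100, 100 and 400.
#'
#' @param founders Named counts `hws_males`, `lws_females`, `lws_males`,
#'   `hws_females`.
#' @param generation_sizes Named (or positional, labelled `F1..Fk`) offspring
#'   counts per intercross generation. May be empty (founders only).
#' @return An object of class `ail_pedigree_spec`.
#' @export
ail_pedigree_spec <- function(founders = c(hws_males = 10, lws_females = 22,
                                           lws_males = 8, hws_females = 19),
                              generation_sizes = c(F1 = 100, F2 = 100, F3 = 300,
                                                   F4 = 100, F5 = 100, F6 = 100,
                                                   F7 = 100, F8 = 400)) {
  need <- c("hws_males", "lws_females", "lws_males", "hws_females")
  if (!all(need %in% names(founders))) {
    stop("founders must name counts: ", paste(need, collapse = ", "))
  }
  if (any(founders[need] <= 0)) stop("all founder counts must be > 0")
  k <- length(generation_sizes)
  if (k > 0) {
    if (any(generation_sizes <= 0)) stop("all generation sizes must be > 0")
    if (is.null(names(generation_sizes))) {
      names(generation_sizes) <- paste0("F", seq_len(k))
    }
    if (!identical(names(generation_sizes), paste0("F", seq_len(k)))) {
      stop("generations must be labelled F1..Fk contiguously")
    }
  }
  structure(list(founders = founders[need], generation_sizes = generation_sizes,
                 mating_scheme = "random-within-generation"),
            class = "ail_pedigree_spec")
}

#' Build an AIL pedigree
#'
#' Founders (generation F0) are drawn from the two lines; F1 individuals come
#' from reciprocal between-line matings; later generations mate randomly
#' within the preceding generation. Sexes are assigned in (near) balance.
#'
#' @param spec An [ail_pedigree_spec()].
#' @param seed Optional integer seed.
#' @return A `data.frame` of class `ail_pedigree` with columns `id`, `sire`,
#'   `dam`, `generation`, `sex` and (founders only) `line` (`"H"`/`"L"`).
#' @export
build_pedigree <- function(spec = ail_pedigree_spec(), seed = NULL) {
  stopifnot(inherits(spec, "ail_pedigree_spec"))
  with_seed_maybe(seed)
  f <- spec$founders
  n0 <- sum(f)
  founder <- data.frame(
    id = sprintf("F0_%03d", seq_len(n0)),
    sire = NA_character_, dam = NA_character_,
    generation = "F0",
    sex = rep(c("M", "F", "M", "F"), times = f),
    line = rep(c("H", "L", "L", "H"), times = f),
    stringsAsFactors = FALSE
  )
  ped <- founder
  prev <- founder
  for (gen in names(spec$generation_sizes)) {
    n <- spec$generation_sizes[[gen]]
    if (gen == "F1") {
      # reciprocal between-line founder matings
      hm <- founder$id[founder$sex == "M" & founder$line == "H"]
      lf <- founder$id[founder$sex == "F" & founder$line == "L"]
      lm <- founder$id[founder$sex == "M" & founder$line == "L"]
      hf <- founder$id[founder$sex == "F" & founder$line == "H"]
      cross <- sample(c(1L, 2L), n, replace = TRUE)
      sire <- ifelse(cross == 1L, sample(hm, n, replace = TRUE),
                     sample(lm, n, replace = TRUE))
      dam <- ifelse(cross == 1L, sample(lf, n, replace = TRUE),
                    sample(hf, n, replace = TRUE))
    } else {
      males <- prev$id[prev$sex == "M"]
      females <- prev$id[prev$sex == "F"]
      if (length(males) == 0L) {
        stop("no available male parents for generation ", gen)
      }
      if (length(females) == 0L) {
        stop("no available female parents for generation ", gen)
      }
      sire <- sample(males, n, replace = TRUE)
      dam <- sample(females, n, replace = TRUE)
    }
    off <- data.frame(
      id = sprintf("%s_%04d", gen, seq_len(n)),
      sire = sire, dam = dam, generation = gen,
      sex = sample(rep(c("M", "F"), length.out = n)),
      line = NA_character_,
      stringsAsFactors = FALSE
    )
    ped <- rbind(ped, off)
    prev <- off
  }
  class(ped) <- c("ail_pedigree", "data.frame")
  ped
}

#' Default marker map over the nine QTL segments
#'
#' Markers are evenly spaced over each segment's physical bounds; genetic
#' positions default to 1 cM per Mb (the real map is denser than 1 cM between
#' markers but per-marker genetic positions are not published).
#'
#' @param markers_per_segment Markers per segment (default 5; the real assay
#'   used 384 markers over the nine segments, which is unnecessary for the
#'   simulated analyses and slows the exhaustive two-dimensional scan).
#' @return A `data.frame` of class `marker_map` with columns `segment`,
#'   `marker`, `mb`, `cm`, `marker_id`.
#' @export
default_marker_map <- function(markers_per_segment = 5) {
  k <- as.integer(markers_per_segment)
  stopifnot(k >= 1)
  rows <- lapply(seq_len(nrow(.SEGMENT_TABLE)), function(i) {
    s <- .SEGMENT_TABLE[i, ]
    mb <- if (k == 1) (s$start_mb + s$stop_mb) / 2 else
      seq(s$start_mb, s$stop_mb, length.out = k)
    data.frame(segment = s$segment, marker = seq_len(k), mb = mb, cm = mb,
               marker_id = paste0(s$segment, ".", seq_len(k)),
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  class(map) <- c("marker_map", "data.frame")
  map
}

# Marker id at the middle of a segment (used for default architecture loci).
middle_marker <- function(map, segment) {
  ids <- map$marker_id[map$segment == segment]
  if (length(ids) == 0L) stop("segment not in map: ", segment)
  ids[ceiling(length(ids) / 2)]
}

#' Gene-drop line-origin genotypes through an AIL pedigree
#'
#' Each founder carries two chromosomes fixed for its line of origin.
#' Meiosis recombines within each segment using the Haldane map function
#' (r = (1 - exp(-2d/100))/2 for d in cM); segments segregate independently.
#' The emitted per-marker contrast is the HWS-allele count minus the
#' LWS-allele count, scaled to [-1, 1] (so HH = +1, HL = 0, LL = -1 for
#' exact line origins).
#'
#' @param ped An `ail_pedigree`.
#' @param map A `marker_map` with genetic positions (`cm`).
#' @param seed Optional integer seed.
#' @param blur Standard deviation of optional truncated-Gaussian noise added
#'   to the true contrasts, emulating line-origin estimation uncertainty
#'   (0 = exact contrasts).
#' @param return_haplotypes If `TRUE`, attach the paternal/maternal origin
#'   matrices as attribute `"haplotypes"` (for Mendelian checking).
#' @return Numeric matrix (individuals x markers) of class
#'   `line_origin_matrix`, values in `[-1, 1]`.
#' @export
simulate_genotypes <- function(ped, map, seed = NULL, blur = 0,
                               return_haplotypes = FALSE) {
  stopifnot(inherits(ped, "data.frame"), inherits(map, "data.frame"))
  if (is.null(map$cm) || anyNA(map$cm)) {
    bad <- if (is.null(map$cm)) map$marker_id else map$marker_id[is.na(map$cm)]
    stop("marker(s) with undefined genetic position: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  with_seed_maybe(seed)
  n <- nrow(ped)
  m <- nrow(map)
  H1 <- matrix(NA_integer_, n, m)  # paternal-origin chromosome (1 = HWS)
  H2 <- matrix(NA_integer_, n, m)  # maternal-origin chromosome
  rownames(H1) <- rownames(H2) <- ped$id
  is_founder <- is.na(ped$sire)
  if (any(is_founder)) {
    fl <- ped$line[is_founder]
    if (anyNA(fl)) stop("founders must carry a line label (H/L)")
    H1[is_founder, ] <- as.integer(fl == "H")
    H2[is_founder, ] <- as.integer(fl == "H")
  }
  seg_cols <- split(seq_len(m), factor(map$segment, unique(map$segment)))
  seg_r <- lapply(seg_cols, function(idx) {
    d <- diff(map$cm[idx])
    (1 - exp(-2 * d / 100)) / 2
  })
  # one recombinant gamete per (offspring, parent) pair
  make_gametes <- function(P1, P2) {
    no <- nrow(P1)
    G <- matrix(NA_integer_, no, ncol(P1))
    for (s in seq_along(seg_cols)) {
      idx <- seg_cols[[s]]
      r <- seg_r[[s]]
      cur <- stats::rbinom(no, 1L, 0.5)
      G[, idx[1L]] <- ifelse(cur == 0L, P1[, idx[1L]], P2[, idx[1L]])
      if (length(idx) > 1L) {
        for (j in 2L:length(idx)) {
          sw <- stats::rbinom(no, 1L, r[j - 1L])
          cur <- (cur + sw) %% 2L
          G[, idx[j]] <- ifelse(cur == 0L, P1[, idx[j]], P2[, idx[j]])
        }
      }
    }
    G
  }
  for (gen in setdiff(unique(ped$generation), "F0")) {
    rows <- which(ped$generation == gen)
    si <- match(ped$sire[rows], ped$id)
    di <- match(ped$dam[rows], ped$id)
    if (anyNA(si) || anyNA(di)) stop("unknown parent id in generation ", gen)
    H1[rows, ] <- make_gametes(H1[si, , drop = FALSE], H2[si, , drop = FALSE])
    H2[rows, ] <- make_gametes(H1[di, , drop = FALSE], H2[di, , drop = FALSE])
  }
  contrasts <- H1 + H2 - 1
  storage.mode(contrasts) <- "double"
  colnames(contrasts) <- map$marker_id
  if (blur > 0) {
    x <- as.vector(contrasts)
    lo <- stats::pnorm((-1 - x) / blur)
    hi <- stats::pnorm((1 - x) / blur)
    z <- stats::qnorm(lo + stats::runif(length(x)) * (hi - lo))
    contrasts <- matrix(pmin(1, pmax(-1, x + blur * z)), n, m,
                        dimnames = dimnames(contrasts))
  }
  class(contrasts) <- c("line_origin_matrix", class(contrasts))
  if (return_haplotypes) attr(contrasts, "haplotypes") <- list(paternal = H1,
                                                               maternal = H2)
  contrasts
}

#' Construct a genotype-phenotype architecture from a value map
#'
#' @param loci Character vector of marker ids the architecture acts on.
#' @param value_map Numeric array of dim `rep(3, L)` with dimnames
#'   `c("LL","HL","HH")` per locus: genotypic value (g) of every multi-locus
#'   genotype.
#' @param preset Label recorded for provenance.
#' @param params Parameter list recorded for provenance.
#' @return Object of class `gp_architecture`.
#' @export
gp_architecture <- function(loci, value_map, preset = "custom", params = list()) {
  L <- length(loci)
  stopifnot(L >= 1)
  if (!is.array(value_map) && L == 1L) value_map <- array(value_map, 3L)
  if (!identical(dim(value_map), rep(3L, L))) {
    stop("value_map must have dim rep(3, ", L, ")")
  }
  if (!all(is.finite(value_map))) stop("value_map must be finite everywhere")
  dimnames(value_map) <- stats::setNames(rep(list(GENO_LEVELS), L), loci)
  structure(list(loci = loci, value_map = value_map, preset = preset,
                 params = params),
            class = "gp_architecture")
}

#' Built-in epistatic architecture presets
#'
#' Three-locus presets (first locus is the hub/conditioning locus):
#' \describe{
#'   \item{flat}{no genetic effects.}
#'   \item{hub_only}{hub additive effect only; the three hub planes are flat
#'     and parallel.}
#'   \item{additive3}{all three loci additive and non-interacting; planes are
#'     translates of each other.}
#'   \item{pairwise_no_hub}{loci 2 and 3 interact with each other (but not
#'     with the hub); planes remain exact translates.}
#'   \item{capacitating}{loci 2 and 3 have effects (additive plus synergistic
#'     epistasis) only on the hub-HH plane; hub-HL/LL planes are flat.}
#' }
#' Five-locus preset:
#' \describe{
#'   \item{radial_network}{one hub and four radial loci; the phenotype
#'     increases stepwise with the number of HH radial genotypes, but only in
#'     the hub-HH background (capacitation released by the hub).}
#' }
#'
#' Default effect sizes are calibrated to the body-weight scale of the
#' emulated study: within-hub-HH-stratum additive effects of ~40-50 g per
#' released locus (`radial_a = 50`; `radial_step = 85`, whose stratified
#' additive slope is `radial_step/2`), a hub additive effect of 25 g
#' (suppressed-background effects ~20 g), and a synergy of 28 g chosen so
#' the best-minus-worst three-locus genotype span is ~200 g.
#'
#' @param preset One of the preset names above.
#' @param loci Marker ids (hub first); defaults to generic names.
#' @param hub_a Additive effect (g) of the hub locus.
#' @param radial_a Additive effect (g) of each non-hub locus where released.
#' @param synergy Additive-by-additive synergy (g) between non-hub loci.
#' @param radial_step Per-HH-radial-genotype step (g) in `radial_network`.
#' @return A [gp_architecture()].
#' @export
make_architecture <- function(preset = c("flat", "hub_only", "additive3",
                                         "pairwise_no_hub", "capacitating",
                                         "radial_network"),
                              loci = NULL, hub_a = 25, radial_a = 50,
                              synergy = 28, radial_step = 85) {
  preset <- match.arg(preset)
  L <- if (preset == "radial_network") 5L else 3L
  if (is.null(loci)) loci <- c("hub", paste0("radial", seq_len(L - 1L)))
  if (length(loci) != L) stop("preset ", preset, " needs ", L, " loci")
  grid <- expand.grid(stats::setNames(rep(list(GENO_LEVELS), L), loci),
                      stringsAsFactors = FALSE)
  A <- additive_code(as.matrix(grid))
  hubHH <- as.numeric(grid[[1L]] == "HH")
  values <- switch(preset,
    flat = rep(0, nrow(grid)),
    hub_only = hub_a * A[, 1L],
    additive3 = hub_a * A[, 1L] + radial_a * (A[, 2L] + A[, 3L]),
    pairwise_no_hub = hub_a * A[, 1L] + radial_a * (A[, 2L] + A[, 3L]) +
      synergy * A[, 2L] * A[, 3L],
    capacitating = hub_a * A[, 1L] +
      hubHH * (radial_a * (A[, 2L] + A[, 3L]) + synergy * A[, 2L] * A[, 3L]),
    radial_network = hub_a * A[, 1L] +
      hubHH * radial_step * rowSums(A[, -1L, drop = FALSE] == 1)
  )
  gp_architecture(loci, array(values, rep(3L, L)), preset = preset,
                  params = list(hub_a = hub_a, radial_a = radial_a,
                                synergy = synergy, radial_step = radial_step))
}

#' Genotypic value of each individual under an architecture
#'
#' @param arch A [gp_architecture()].
#' @param calls Character matrix of genotype calls whose columns include
#'   `arch$loci`.
#' @return Numeric vector of genotypic values (g); `NA` where any involved
#'   call is missing.
#' @export
evaluate_architecture <- function(arch, calls) {
  missing_loci <- setdiff(arch$loci, colnames(calls))
  if (length(missing_loci) > 0L) {
    stop("architecture references marker(s) absent from the matrix: ",
         paste(missing_loci, collapse = ", "))
  }
  idx <- matrix(match(calls[, arch$loci, drop = FALSE], GENO_LEVELS),
                ncol = length(arch$loci))
  out <- rep(NA_real_, nrow(idx))
  ok <- stats::complete.cases(idx)
  out[ok] <- arch$value_map[idx[ok, , drop = FALSE]]
  out
}

#' Simulate 56-day body weights from genotypes and an architecture
#'
#' weight = baseline + genotypic value + sex effect + generation effect +
#' Gaussian noise. Contrasts at the architecture loci are discretized at the
#' standard +-0.4 thresholds before the genotype-value lookup.
#'
#' @param geno A `line_origin_matrix`.
#' @param ped The `ail_pedigree` the matrix was simulated from (supplies sex
#'   and generation).
#' @param arch A [gp_architecture()].
#' @param sex_effect Male-minus-female weight difference (g); default 100.
#' @param generation_effects Optional named vector of per-generation shifts (g).
#' @param noise_sd Residual standard deviation (g); default 127, the F8
#'   phenotypic SD reported for the emulated pedigree.
#' @param baseline Population baseline weight (g); default 851, the founder
#'   line midpoint (1522 + 181)/2.
#' @param seed Optional integer seed.
#' @return `data.frame` of class `phenotype_table` with columns `id`,
#'   `weight56`, `sex`, `generation`.
#' @export
simulate_phenotypes <- function(geno, ped, arch, sex_effect = 100,
                                generation_effects = NULL, noise_sd = 127,
                                baseline = 851, seed = NULL) {
  stopifnot(inherits(arch, "gp_architecture"))
  with_seed_maybe(seed)
  absent <- setdiff(arch$loci, colnames(geno))
  if (length(absent) > 0L) {
    stop("architecture references marker(s) absent from the matrix: ",
         paste(absent, collapse = ", "))
  }
  calls <- discretize_contrasts(geno[, arch$loci, drop = FALSE])
  gval <- evaluate_architecture(arch, calls)
  if (anyNA(gval)) {
    warning("missing genotype call at an architecture locus for ",
            sum(is.na(gval)), " individual(s); their weights are NA")
  }
  idx <- match(rownames(geno), ped$id)
  if (anyNA(idx)) stop("genotype matrix contains ids absent from the pedigree")
  sexv <- ped$sex[idx]
  genv <- ped$generation[idx]
  gshift <- if (is.null(generation_effects)) 0 else {
    s <- generation_effects[genv]
    s[is.na(s)] <- 0
    as.numeric(s)
  }
  w <- baseline + gval + ifelse(sexv == "M", sex_effect / 2, -sex_effect / 2) +
    gshift + stats::rnorm(length(gval), 0, noise_sd)
  out <- data.frame(id = rownames(geno), weight56 = w, sex = sexv,
                    generation = genv, stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' One-call synthetic AIL dataset
#'
#' Builds the default pedigree, gene-drops genotypes over the default marker
#' map, instantiates an architecture preset on its default loci (hub =
#' mid-Growth9 marker; radial loci from Growth2/Growth4/Growth6/Growth12),
#' and simulates phenotypes. A single seed governs pedigree, meiosis and
#' noise, in that documented order.
#'
#' @inheritParams simulate_phenotypes
#' @inheritParams simulate_genotypes
#' @param preset Architecture preset name (see [make_architecture()]).
#' @param spec Pedigree specification.
#' @param markers_per_segment Markers per segment for the default map.
#' @param arch Optional explicit [gp_architecture()] overriding `preset`.
#' @param seed Integer seed for the whole simulation.
#' @param ... Passed to [make_architecture()].
#' @return List of class `ail_dataset`: `pedigree`, `map`, `contrasts`,
#'   `phenotypes`, `architecture`.
#' @export
simulate_ail <- function(preset = "radial_network", spec = ail_pedigree_spec(),
                         markers_per_segment = 5, noise_sd = 127, blur = 0,
                         sex_effect = 100, generation_effects = NULL,
                         arch = NULL, seed = NULL, ...) {
  with_seed_maybe(seed)
  ped <- build_pedigree(spec)
  map <- default_marker_map(markers_per_segment)
  geno <- simulate_genotypes(ped, map, blur = blur)
  if (is.null(arch)) {
    loci <- if (preset == "radial_network") {
      c(middle_marker(map, "Growth9"), middle_marker(map, "Growth2"),
        middle_marker(map, "Growth4"), middle_marker(map, "Growth6"),
        middle_marker(map, "Growth12"))
    } else {
      c(middle_marker(map, "Growth9"), middle_marker(map, "Growth4"),
        middle_marker(map, "Growth12"))
    }
    arch <- make_architecture(preset, loci = loci, ...)
  }
  phen <- simulate_phenotypes(geno, ped, arch, sex_effect = sex_effect,
                              generation_effects = generation_effects,
                              noise_sd = noise_sd)
  structure(list(pedigree = ped, map = map, contrasts = geno,
                 phenotypes = phen, architecture = arch),
            class = "ail_dataset")
}
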