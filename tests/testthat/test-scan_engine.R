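test_that("two-locus fits agree with the SVD pseudo-inverse oracle", {
  set.seed(101)
  for (rep in 1:12) {
    # enumerated 9-cell designs with random (possibly zero) cell counts
    counts <- if (rep <= 6) sample(0:4, 9, replace = TRUE) + 1 else
      sample(0:3, 9, replace = TRUE)  # later reps may drop cells entirely
    cells <- expand.grid(A = GENO, B = GENO, stringsAsFactors = FALSE)
    cA <- rep(cells$A, counts)
    cB <- rep(cells$B, counts)
    n <- length(cA)
    if (n < 12) next
    y <- rnorm(n, sd = 10)
    g <- geno_matrix(A = cA, B = cB)
    fit <- fit_two_locus(res_phen(setNames(y, rownames(g))), "A", "B", g,
                         min_n = 10)
    d <- two_locus_design(cA, cB)
    expect_equal(fit$F_full_vs_marginal, oracle_nested_f(y, d$marginal, d$full),
                 tolerance = 1e-8)
    f0 <- oracle_nested_f(y, matrix(1, n, 1), d$full)
    expect_equal(fit$F_full_vs_null, f0, tolerance = 1e-8)
    if (length(fit$aliased) == 0L) {
      expect_equal(unname(fit$coefficients), unname(pinv_fit(d$full, y)$beta),
                   tolerance = 1e-8)
    }
  }
})

test_that("two-locus fit handles degenerate and noiseless inputs", {
  cells <- expand.grid(A = GENO, B = GENO, stringsAsFactors = FALSE)
  cA <- rep(cells$A, 4)
  cB <- rep(cells$B, 4)
  g <- geno_matrix(A = cA, B = cB)

  y0 <- res_phen(setNames(rep(0, nrow(g)), rownames(g)))
  f0 <- fit_two_locus(y0, "A", "B", g, min_n = 10)
  expect_true(all(f0$coefficients == 0))
  expect_equal(f0$F_full_vs_marginal, 0)
  expect_equal(f0$F_full_vs_null, 0)

  a <- additive_code(cA) * additive_code(cB)
  yaa <- res_phen(setNames(10 * a, rownames(g)))
  faa <- fit_two_locus(yaa, "A", "B", g, min_n = 10)
  expect_equal(unname(faa$coefficients["aa"]), 10, tolerance = 1e-10)
  expect_equal(max(abs(faa$coefficients[setdiff(names(faa$coefficients),
                                                "aa")])), 0, tolerance = 1e-10)
  expect_true(is.infinite(faa$F_full_vs_marginal))

  yadd <- res_phen(setNames(7 * additive_code(cA), rownames(g)))
  fadd <- fit_two_locus(yadd, "A", "B", g, min_n = 10)
  expect_equal(fadd$F_full_vs_marginal, 0)

  # a locus with no heterozygotes aliases its dominance terms
  cB2 <- rep(c("LL", "HH"), length.out = length(cB))
  g2 <- geno_matrix(A = cA, B = cB2)
  set.seed(5)
  y2 <- res_phen(setNames(rnorm(nrow(g2)), rownames(g2)))
  f2 <- fit_two_locus(y2, "A", "B", g2, min_n = 10)
  expect_true("d2" %in% f2$aliased)
  expect_error(fit_two_locus(y2, "A", "B", g2, min_n = 1e5), "minimum")
})

test_that("continuous predictors coincide with discrete ones on exact contrasts", {
  set.seed(11)
  cvals <- matrix(sample(c(-1, 0, 1), 400, replace = TRUE), 200, 2,
                  dimnames = list(sprintf("id%03d", 1:200), c("A", "B")))
  y <- res_phen(setNames(rnorm(200, sd = 10), rownames(cvals)))
  g <- discretize_contrasts(cvals)
  fd <- fit_two_locus(y, "A", "B", g)
  fc <- fit_two_locus(y, "A", "B", cvals, predictors = "continuous")
  expect_equal(fc$F_full_vs_marginal, fd$F_full_vs_marginal,
               tolerance = 1e-10)
  expect_equal(fc$coefficients, fd$coefficients, tolerance = 1e-10)
})

test_that("scan_2d selects planted interacting markers and breaks ties low", {
  set.seed(7)
  map <- default_marker_map(3)
  n <- 400
  g <- draw_calls(n, map$marker_id)
  # plant a noiseless aa interaction between Growth1.2 and Growth4.3
  y <- 10 * additive_code(g[, "Growth1.2"]) * additive_code(g[, "Growth4.3"])
  yr <- res_phen(setNames(y, rownames(g)))
  sel <- scan_2d(yr, g, map)
  expect_equal(nrow(sel), 9)
  expect_equal(sel$marker_id[sel$segment == "Growth1"], "Growth1.2")
  expect_equal(sel$marker_id[sel$segment == "Growth4"], "Growth4.3")

  # oracle: exhaustive enumeration reproduces the per-segment selection
  set.seed(8)
  small_map <- map[map$segment %in% c("Growth1", "Growth2"), ]
  gs <- draw_calls(300, small_map$marker_id)
  ys <- rnorm(300, sd = 3) +
    2 * additive_code(gs[, "Growth1.3"]) * additive_code(gs[, "Growth2.1"])
  ysr <- res_phen(setNames(ys, rownames(gs)))
  sel_s <- scan_2d(ysr, gs, small_map)
  score <- setNames(rep(-Inf, 6), small_map$marker_id)
  for (i in 1:5) for (j in (i + 1):6) {
    if (small_map$segment[i] == small_map$segment[j]) next
    d <- two_locus_design(gs[, i], gs[, j])
    f <- oracle_nested_f(ys, d$marginal, d$full)
    score[i] <- max(score[i], f)
    score[j] <- max(score[j], f)
  }
  for (seg in c("Growth1", "Growth2")) {
    k <- small_map$marker_id[small_map$segment == seg]
    expect_equal(sel_s$marker_id[sel_s$segment == seg],
                 k[which.max(score[k])])
  }

  # perfect tie via a duplicated marker column -> lower marker index wins
  gd <- gs
  gd[, "Growth1.2"] <- gd[, "Growth1.1"]
  yd <- 6 * additive_code(gd[, "Growth1.1"]) * additive_code(gd[, "Growth2.2"])
  seld <- scan_2d(res_phen(setNames(yd, rownames(gd))), gd, small_map)
  expect_equal(seld$marker_id[seld$segment == "Growth1"], "Growth1.1")
})

test_that("1D scan finds planted peaks and is shift invariant", {
  set.seed(21)
  markers <- paste0("m", 1:12)
  g <- draw_calls(500, markers)
  y <- 30 * additive_code(g[, "m7"])
  prof <- scan_1d(res_phen(setNames(y, rownames(g))), markers, g)
  expect_equal(nrow(prof), 12)
  expect_equal(prof$marker[which.max(prof$F)], "m7")

  y2 <- y + rnorm(500, sd = 25)
  p1 <- scan_1d(res_phen(setNames(y2, rownames(g))), markers, g)
  p2 <- scan_1d(res_phen(setNames(y2 + 1000, rownames(g))), markers, g)
  expect_equal(p1$F, p2$F, tolerance = 1e-10)

  gm <- g
  gm[, "m3"] <- "HL"
  pm <- scan_1d(res_phen(setNames(y2, rownames(gm))), markers, gm)
  expect_true(pm$monomorphic[pm$marker == "m3"])
  expect_equal(pm$F[pm$marker == "m3"], 0)

  expect_error(scan_1d(res_phen(setNames(y2, rownames(g))), character(0), g),
               "non-empty")
})

test_that("bootstrap averaging reduces to scan_1d under the identity resample", {
  set.seed(31)
  markers <- paste0("m", 1:8)
  g <- draw_calls(200, markers)
  y <- res_phen(setNames(20 * additive_code(g[, "m2"]) + rnorm(200, sd = 40),
                         rownames(g)))
  base <- scan_1d(y, markers, g)
  boot1 <- bootstrap_scan(y, markers, g, B = 1, indices_fun = function(n) 1:n)
  expect_equal(boot1$F, base$F, tolerance = 1e-12)
  expect_error(bootstrap_scan(y, markers, g[1:10, ], min_n = 30), "minimum")
})

test_that("bootstrap-averaged profiles peak at the true marker across seeds", {
  set.seed(41)
  markers <- paste0("m", 1:10)
  g <- draw_calls(300, markers)
  y <- res_phen(setNames(45 * additive_code(g[, "m5"]) + rnorm(300, sd = 110),
                         rownames(g)))
  hits <- 0
  for (s in 1:20) {
    prof <- bootstrap_scan(y, markers, g, B = 30, seed = s)
    if (prof$marker[which.max(prof$F)] == "m5") hits <- hits + 1
  }
  expect_gte(hits, 15)  # majority criterion

  # more replicates -> lower Monte-Carlo variance of the averaged profile
  stat_at <- function(B, seeds) {
    vapply(seeds, function(s) {
      bootstrap_scan(y, markers, g, B = B, seed = 1000 + s)$F[5]
    }, numeric(1))
  }
  v_small <- var(stat_at(5, 1:25))
  v_large <- var(stat_at(20, 1:25))
  expect_lt(v_large, v_small)
})

test_that("permutation thresholds honor quantile identities and invariances", {
  set.seed(51)
  markers <- paste0("m", 1:6)
  g <- draw_calls(150, markers)
  y <- res_phen(setNames(rnorm(150, sd = 50), rownames(g)))

  thr_min <- permutation_threshold(y, markers, g, N = 100, alpha = 1, seed = 1)
  expect_equal(thr_min$threshold, min(thr_min$maxima))
  expect_error(permutation_threshold(y, markers, g, N = 100, alpha = 0),
               "alpha")
  expect_error(permutation_threshold(y, markers, g, N = 50), "100")

  t1 <- permutation_threshold(y, markers, g, N = 200, seed = 7)
  t2 <- permutation_threshold(y, rev(markers), g, N = 200, seed = 7)
  expect_equal(t1$threshold, t2$threshold, tolerance = 1e-12)

  # dual route: permuting genotype rows (with the same RNG draws) must give
  # identical maxima, since the (phenotype, fixed-factor) pairing is kept
  yv <- y$residual[match(rownames(g), y$id)]
  set.seed(7); perms <- replicate(200, sample.int(150))
  maxima <- apply(perms, 2, function(p) {
    gp <- g[order(p), ]  # inverse permutation of the rows
    rownames(gp) <- rownames(g)
    max(scan_1d(y, markers, gp)$F)
  })
  set.seed(7)
  t3 <- permutation_threshold(y, markers, g, N = 200)
  expect_equal(t3$maxima, maxima, tolerance = 1e-9)
})
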