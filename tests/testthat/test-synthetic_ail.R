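test_that("default pedigree reproduces the study design", {
  ped <- build_pedigree(seed = 11)
  expect_equal(sum(is.na(ped$sire)), 59)
  expect_equal(sum(!is.na(ped$sire)), 1300)
  sizes <- table(ped$generation)
  expect_equal(as.integer(sizes[paste0("F", 1:8)]),
               c(100, 100, 300, 100, 100, 100, 100, 400))
  # parents precede offspring and come from the previous generation
  gen_of <- setNames(ped$generation, ped$id)
  off <- ped[!is.na(ped$sire), ]
  gen_num <- function(g) as.integer(sub("F", "", g))
  expect_true(all(gen_num(gen_of[off$sire]) == gen_num(off$generation) - 1L))
  expect_true(all(gen_num(gen_of[off$dam]) == gen_num(off$generation) - 1L))
  # sire male, dam female
  sex_of <- setNames(ped$sex, ped$id)
  expect_true(all(sex_of[off$sire] == "M"))
  expect_true(all(sex_of[off$dam] == "F"))
  # F1 crosses are strictly between lines
  line_of <- setNames(ped$line, ped$id)
  f1 <- ped[ped$generation == "F1", ]
  expect_true(all(line_of[f1$sire] != line_of[f1$dam]))
})

test_that("pedigree edge cases and determinism contract", {
  only_founders <- build_pedigree(
    ail_pedigree_spec(generation_sizes = numeric(0)), seed = 1)
  expect_equal(nrow(only_founders), 59)
  expect_true(all(only_founders$generation == "F0"))

  p1 <- build_pedigree(seed = 1)
  p2 <- build_pedigree(seed = 2)
  expect_identical(table(p1$generation), table(p2$generation))
  expect_false(identical(p1$sire, p2$sire))

  # a single F1 individual is one sex only -> F2 has no parents of the other
  spec <- ail_pedigree_spec(generation_sizes = c(F1 = 1, F2 = 10))
  expect_error(build_pedigree(spec, seed = 3), "generation F2")
  expect_error(ail_pedigree_spec(generation_sizes = c(F1 = 0)), "> 0")
})

test_that("gene dropping fixes founders, zeroes F1, and stays bounded", {
  ped <- build_pedigree(seed = 5)
  map <- default_marker_map(3)
  geno <- simulate_genotypes(ped, map, seed = 6, blur = 0.15)
  expect_true(all(geno >= -1 & geno <= 1))

  exact <- simulate_genotypes(ped, map, seed = 6)
  founders <- ped$id[ped$generation == "F0"]
  hws <- founders[ped$line[match(founders, ped$id)] == "H"]
  lws <- founders[ped$line[match(founders, ped$id)] == "L"]
  expect_true(all(exact[hws, ] == 1))
  expect_true(all(exact[lws, ] == -1))
  expect_true(all(exact[ped$generation == "F1", ] == 0))

  badmap <- map
  badmap$cm[2] <- NA
  expect_error(simulate_genotypes(ped, badmap), "genetic position")
})

test_that("offspring haplotypes are Mendelian", {
  spec <- ail_pedigree_spec(generation_sizes = c(F1 = 20, F2 = 40, F3 = 40))
  ped <- build_pedigree(spec, seed = 8)
  geno <- simulate_genotypes(ped, default_marker_map(4), seed = 9,
                             return_haplotypes = TRUE)
  h <- attr(geno, "haplotypes")
  off <- which(!is.na(ped$sire))
  si <- match(ped$sire[off], ped$id)
  di <- match(ped$dam[off], ped$id)
  pat_ok <- h$paternal[off, ] == h$paternal[si, ] |
    h$paternal[off, ] == h$maternal[si, ]
  mat_ok <- h$maternal[off, ] == h$paternal[di, ] |
    h$maternal[off, ] == h$maternal[di, ]
  expect_true(all(pat_ok))
  expect_true(all(mat_ok))
})

test_that("origin-switch frequency between adjacent markers follows Haldane", {
  # F1 sires carry one all-HWS and one all-LWS chromosome, so the paternal
  # haplotype of an F2 individual reveals the chromosome choice directly.
  n2 <- 4000
  ped <- data.frame(
    id = c("HM", "LF", "LM", "HF", "S", "D", sprintf("X%04d", seq_len(n2))),
    sire = c(NA, NA, NA, NA, "HM", "LM", rep("S", n2)),
    dam = c(NA, NA, NA, NA, "LF", "HF", rep("D", n2)),
    generation = c(rep("F0", 4), "F1", "F1", rep("F2", n2)),
    sex = c("M", "F", "M", "F", "M", "F", rep("M", n2)),
    line = c("H", "L", "L", "H", NA, NA, rep(NA, n2)),
    stringsAsFactors = FALSE
  )
  map <- default_marker_map(4)
  geno <- simulate_genotypes(ped, map, seed = 21, return_haplotypes = TRUE)
  pat <- attr(geno, "haplotypes")$paternal[ped$generation == "F2", ]
  for (seg in unique(map$segment)) {
    idx <- which(map$segment == seg)
    d <- diff(map$cm[idx])
    r_exp <- (1 - exp(-2 * d / 100)) / 2
    for (j in seq_along(d)) {
      r_obs <- mean(pat[, idx[j]] != pat[, idx[j + 1]])
      tol <- 4 * sqrt(r_exp[j] * (1 - r_exp[j]) / n2)
      expect_lt(abs(r_obs - r_exp[j]), max(tol, 0.01))
    }
  }
})

test_that("F8 mean contrast is drift-free in expectation", {
  # oracle: an intercross without selection keeps E[contrast] = 0
  reps <- 50
  means <- matrix(NA_real_, reps, 9)
  set.seed(31)
  for (r in seq_len(reps)) {
    ped <- build_pedigree()
    geno <- simulate_genotypes(ped, default_marker_map(1))
    means[r, ] <- colMeans(geno[ped$generation == "F8", ])
  }
  grand <- colMeans(means)
  se <- apply(means, 2, sd) / sqrt(reps)
  z <- grand / se
  # joint test across the 9 markers (3-sigma-equivalent, multiplicity aware)
  expect_lt(sum(z^2), qchisq(0.999, df = 9))
})

test_that("architecture presets reproduce the canonical plane geometry", {
  expect_error(make_architecture("nope"), "arg")
  expect_error(make_architecture("flat", loci = c("a", "b")), "3 loci")

  flat <- make_architecture("flat")
  expect_equal(length(flat$value_map), 27L)
  expect_true(all(flat$value_map == flat$value_map[1]))

  hub <- make_architecture("hub_only", hub_a = 30)
  vm <- hub$value_map
  # planes indexed by the hub genotype (first dimension)
  expect_equal(sd(vm["HH", , ]), 0)
  expect_equal(sd(vm["LL", , ]), 0)
  expect_equal(vm["HH", 1, 1] - vm["LL", 1, 1], 60)  # 2a

  for (preset in c("additive3", "pairwise_no_hub")) {
    vm <- make_architecture(preset)$value_map
    # hub planes are exact translates: same shape, equal variances
    expect_equal(vm["HH", , ] - vm["LL", , ],
                 matrix((vm["HH", 1, 1] - vm["LL", 1, 1]), 3, 3,
                        dimnames = dimnames(vm["HH", , ])))
    expect_equal(var(as.vector(vm["HH", , ])), var(as.vector(vm["LL", , ])))
  }

  cap <- make_architecture("capacitating")$value_map
  expect_equal(sd(cap["LL", , ]), 0)
  expect_equal(sd(cap["HL", , ]), 0)
  expect_gt(var(as.vector(cap["HH", , ])), 0)

  rad <- make_architecture("radial_network", hub_a = 25, radial_step = 85)
  vmr <- rad$value_map
  expect_equal(length(vmr), 243L)
  # released only in the hub-HH background, stepwise in the HH-count
  expect_equal(sd(vmr["LL", , , , ]), 0)
  expect_equal(vmr["HH", "HH", "HH", "HH", "HH"] - vmr["HH", "LL", "LL", "LL", "LL"],
               4 * 85)
})

test_that("phenotype simulation composes genetic and fixed effects", {
  sim <- simulate_ail("flat", noise_sd = 0, sex_effect = 0, seed = 77,
                      markers_per_segment = 1)
  expect_true(all(sim$phenotypes$weight56 == sim$phenotypes$weight56[1]))

  # single-locus additive architecture, a = 50 g, noiseless
  arch1 <- gp_architecture("Growth9.1", array(c(-50, 0, 50), 3L))
  sim1 <- simulate_ail(arch = arch1, noise_sd = 0, sex_effect = 0, seed = 78,
                       markers_per_segment = 1)
  calls <- discretize_contrasts(sim1$contrasts)[, "Growth9.1"]
  w <- sim1$phenotypes$weight56
  expect_equal(mean(w[calls == "HH"]) - mean(w[calls == "LL"]), 100)

  bad <- gp_architecture("NotAMarker", array(0, 3L))
  expect_error(
    simulate_phenotypes(sim1$contrasts, sim1$pedigree, bad),
    "absent from the matrix"
  )
})

test_that("F8 phenotypic variance matches the analytic component sum", {
  sim <- simulate_ail("radial_network", seed = 101, sex_effect = 0)
  f8 <- sim$phenotypes$generation == "F8"
  gval <- evaluate_architecture(sim$architecture,
                                discretize_contrasts(sim$contrasts))
  expected_var <- var(gval[f8]) + 127^2
  observed_var <- var(sim$phenotypes$weight56[f8])
  expect_lt(abs(observed_var - expected_var) / expected_var, 0.2)
})

test_that("simulation is reproducible under a fixed seed", {
  s1 <- simulate_ail("capacitating", seed = 13, markers_per_segment = 2)
  s2 <- simulate_ail("capacitating", seed = 13, markers_per_segment = 2)
  expect_identical(s1$contrasts, s2$contrasts)
  expect_identical(s1$phenotypes, s2$phenotypes)
})
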