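test_that("gamete simulation reproduces the map-function recombination fraction", {
  set.seed(21)
  n <- 20000
  r_theory <- map_to_recomb(0.1, "haldane")
  g <- simulate_gamete(n, c(1, 1), c(0, 0), rvec = r_theory)
  rf <- mean(g[, 1] != g[, 2])
  expect_equal(rf, r_theory, tolerance = 3 * sqrt(r_theory * (1 - r_theory) / n) / r_theory)
  # homozygous parent: gamete content fixed
  g2 <- simulate_gamete(50, c(1, 1, 1), c(1, 1, 1), rvec = c(0.2, 0.2))
  expect_true(all(g2 == 1))
  # zero distance never recombines
  g3 <- simulate_gamete(2000, c(1, 1), c(0, 0), rvec = 0)
  expect_true(all(g3[, 1] == g3[, 2]))
})

test_that("DH and RIL populations obey their recombination laws", {
  set.seed(22)
  n <- 2000
  r <- map_to_recomb(0.1, "haldane")
  dh <- simulate_pil(n, map2(), pil_type = "DH", fun = "haldane")
  expect_true(all(dh$markers %in% c(0L, 2L)))
  rf_dh <- mean(dh$markers[, 1] != dh$markers[, 2])
  expect_lt(abs(rf_dh - r), 3 * sqrt(r * (1 - r) / n))
  # allele frequency 1/2
  expect_lt(abs(mean(dh$markers[, 1] == 2L) - 0.5), 3 * sqrt(0.25 / n))
  ril <- simulate_pil(n, map2(), pil_type = "RIL", fun = "haldane")
  expect_true(all(ril$markers %in% c(0L, 2L)))
  R <- ril_recomb_adjust(r)
  rf_ril <- mean(ril$markers[, 1] != ril$markers[, 2])
  expect_lt(abs(rf_ril - R), 3 * sqrt(R * (1 - R) / n))
})

test_that("balanced IF2 sampling uses every line equally and mimics F2 frequencies", {
  des <- build_cross_design(200, 300, "balanced")
  expect_equal(unname(tabulate(as.vector(des$if2_pairs), 200)), rep(3L, 200))
  expect_true(all(des$if2_pairs[, 1] != des$if2_pairs[, 2]))
  expect_error(build_cross_design(200, 250, "balanced"), "divisible")
  expect_null(build_cross_design(10, 0)$if2_pairs)
  rnd <- build_cross_design(50, 500, "random")
  expect_true(all(rnd$if2_pairs[, 1] != rnd$if2_pairs[, 2]))

  set.seed(42)
  sim <- simulate_populations(map2(), qtl_model("c1", 5, 1, 0, -1, ve = 1),
                              2000, 0, 0, 2000, if2_sampling = "balanced")
  n <- 2000
  freq <- as.vector(table(factor(sim$populations$IF2$geno[, 1],
                                 levels = c(2, 1, 0)))) / n
  bands <- 3 * sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / n)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < bands))
})

test_that("backcross hybrids lack the other parent's homozygote", {
  set.seed(23)
  sim <- simulate_populations(map6(), model1(ve = 0.5), 200, 200, 200, 0)
  expect_true(all(sim$populations$IB1$geno != 0L))
  expect_true(all(sim$populations$IB2$geno != 2L))
})

test_that("genotypic values sum locus values and epistatic deviations", {
  m <- qtl_model(c("c1", "c1"), c(0, 10), v2 = c(1, 1), v1 = c(0.5, 0),
                 v0 = c(-1, -1), ve = 0)
  expect_equal(genotypic_value(rbind(c(1, 2)), m), 0.5 + 1)
  expect_equal(genotypic_value(rbind(c(2, 0)), m), 0)
  tab <- matrix(0, 3, 3)
  tab[1, 1] <- 0.5  # (2, 2) cell
  me <- qtl_model(c("c1", "c1"), c(0, 10), v2 = c(0, 0), v1 = c(0, 0),
                  v0 = c(0, 0), epistasis = list(list(a = 1, b = 2, table = tab)),
                  ve = 0)
  expect_equal(genotypic_value(rbind(c(2, 2)), me), 0.5)
  expect_equal(genotypic_value(rbind(c(2, 0)), me), 0)
  expect_error(qtl_model("c1", 0, 1, 0, -1,
                         epistasis = list(list(a = 1, b = 2, table = tab)),
                         ve = 1), "undeclared")
})

test_that("heritability converts to error variance on the F2 reference", {
  set.seed(24)
  ve <- error_variance_from_h2(model1(a = 1, d = 0, h2 = 0.5), map6())
  expect_equal(as.numeric(ve), 0.5, tolerance = 0.04)   # V_G(F2) = a^2/2
  expect_equal(attr(ve, "vg_f2"), 0.5, tolerance = 0.04)
  ve2 <- error_variance_from_h2(model1(a = 1, d = 1, h2 = 0.5), map6())
  expect_equal(as.numeric(ve2), 0.75, tolerance = 0.04) # a^2/2 + d^2/4
  expect_equal(as.numeric(error_variance_from_h2(model1(h2 = 1), map6())), 0)
  expect_error(error_variance_from_h2(model1(ve = 1), map6()), "nothing to convert")
  expect_error(qtl_model("chr1", 25, 1, 0, -1, h2 = 0), "\\(0, 1\\]")
})

test_that("pure-line and IF2 genetic variances follow single-locus theory", {
  set.seed(25)
  sim <- simulate_populations(map6(), model1(a = 1, d = 0.5, ve = 0),
                              2000, 0, 0, 2000, if2_sampling = "balanced")
  # PIL: Var over {a, -a} at 1:1 = a^2; IF2 (1:2:1): a^2/2 + d^2/4
  expect_equal(var(sim$populations$PIL$G), 1, tolerance = 0.1)
  expect_equal(var(sim$populations$IF2$G), 0.5 + 0.25 / 4, tolerance = 0.1)
})

test_that("phenotype noise has the requested variance and vanishes at Ve = 0", {
  set.seed(26)
  G <- rnorm(100)
  expect_equal(simulate_phenotypes(G, 0, reps = 2), cbind(G, G),
               ignore_attr = TRUE)
  y <- simulate_phenotypes(rep(0, 10000), 2.5)
  expect_equal(var(as.vector(y)), 2.5, tolerance = 0.05)
})

test_that("the same seed reproduces populations bit for bit", {
  one <- function() {
    set.seed(99)
    simulate_populations(map6(), model1(h2 = 0.5), 50, 50, 50, 100)
  }
  expect_identical(one(), one())
})

test_that("simulated runs round-trip through the QHP dialect", {
  set.seed(27)
  sim <- simulate_populations(map6(), model1(ve = 0.5), 40, 40, 40, 60,
                              if2_sampling = "balanced")
  f <- withr::local_tempfile(fileext = ".qhp")
  write_qhp_input(sim, f)
  inp <- read_qhp(f)
  expect_equal(unname(inp$geno[, ]), unname(sim$populations$PIL$geno[, ]))
  expect_equal(inp$if2_pairs, unname(sim$design$if2_pairs))
  for (p in names(inp$pheno)) {
    expect_equal(unname(inp$pheno[[p]][, 1]),
                 unname(rowMeans(sim$populations[[p]]$y)), tolerance = 1e-6,
                 info = p)
  }
  # QTL loci are not written as markers; one trait per file
  expect_equal(ncol(inp$geno), n_markers(sim$map))
  expect_equal(length(inp$traits), 1)
})
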