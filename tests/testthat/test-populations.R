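test_that("genotype tokens decode across number/letter/mixed coding", {
  expect_identical(parse_genotype_token(c("2", "A", "AA", "aa")), rep(2L, 4))
  expect_identical(parse_genotype_token(c("0", "B", "BB")), rep(0L, 3))
  expect_identical(parse_genotype_token(c("1", "H", "AB", "h")), rep(1L, 4))
  expect_identical(parse_genotype_token(c("-1", "X", "XX", "*", "**")),
                   rep(NA_integer_, 5))
  expect_error(parse_genotype_token("Q"), "unrecognized")
  expect_error(parse_genotype_token("Q", context = "marker m3, line 7"),
               "marker m3, line 7")
})

test_that("pure-line normalization converts heterozygous calls to missing", {
  g <- genotype_matrix(rbind(c(2, 1), c(0, 1), c(2, 0)), "PIL")
  ng <- normalize_pil(g)
  expect_identical(attr(ng, "n_het_replaced"), 2L)
  expect_true(all(is.na(ng[1:2, 2])))
  expect_identical(ng[3, ], c(2L, 0L))
  # no heterozygotes: identity
  g2 <- genotype_matrix(rbind(c(2, 0), c(0, 2)), "PIL")
  expect_identical(unname(normalize_pil(g2))[, ], unname(g2)[, ])
})

test_that("hybrid genotypes are deduced from pure-line genotypes", {
  pil <- normalize_pil(genotype_matrix(rbind(c(2, 0, NA), c(0, 2, 2)), "PIL"))
  ib1 <- derive_hybrid_genotypes(pil, target = "IB1")
  expect_identical(unname(ib1[1, ]), c(2L, 1L, NA))
  ib2 <- derive_hybrid_genotypes(pil, target = "IB2")
  expect_identical(unname(ib2[1, ]), c(1L, 0L, NA))
  des <- cross_design(2, rbind(c(1, 2)))
  if2 <- derive_hybrid_genotypes(pil, des, "IF2")
  expect_identical(unname(if2[1, ]), c(1L, 1L, NA))
  # symmetry in the pair
  des2 <- cross_design(2, rbind(c(2, 1)))
  expect_identical(unname(derive_hybrid_genotypes(pil, des2, "IF2")),
                   unname(if2))
})

test_that("derived IB1 frequencies conserve the pure-line frequencies", {
  set.seed(4)
  pil <- matrix(sample(c(2L, 0L), 300, replace = TRUE, prob = c(0.7, 0.3)),
                50, 6)
  pil <- normalize_pil(genotype_matrix(pil, "PIL"))
  ib1 <- derive_hybrid_genotypes(pil, target = "IB1")
  expect_identical(colSums(ib1 == 2L), colSums(pil == 2L))
  expect_identical(colSums(ib1 == 1L), colSums(pil == 0L))
  expect_true(all(ib1 != 0L))
})

test_that("marker summary tests 1:1 segregation and flags monomorphic markers", {
  g <- rbind(matrix(2L, 150, 3), matrix(0L, 50, 3))
  g[1:100, 2] <- 0L     # (50, 150) -> chi2 = 50
  g[, 3] <- 2L          # monomorphic
  g[1, 1] <- NA
  ms <- marker_summary(genotype_matrix(g, "PIL"))
  expect_equal(ms$n_missing, c(1, 0, 0))
  expect_equal(ms$chi_square[2], 50)
  expect_equal(ms$p_value[2], pchisq(50, 1, lower.tail = FALSE))
  expect_false(ms$usable[3])
  expect_true(all(ms$usable[1:2]))
  # perfect 1:1
  even <- marker_summary(genotype_matrix(cbind(rep(c(2L, 0L), 100)), "PIL"))
  expect_equal(even$chi_square, 0)
  expect_equal(even$p_value, 1)
})

test_that("imputation fills missing calls from flanking markers", {
  m <- tiny_map()
  pil <- genotype_matrix(rbind(c(2, NA, 2),    # flanked by 2s -> 2
                               c(2, NA, 0),    # closer to m1 (5 vs 7 cM) -> 2
                               c(0, NA, 0),
                               c(2, 0, 2)), "PIL")
  imp <- impute_missing(pil, m, "DH", "haldane")
  expect_identical(unname(imp[1, 2]), 2L)
  expect_identical(unname(imp[2, 2]), 2L)
  expect_identical(unname(imp[3, 2]), 0L)
  # non-missing cells never altered
  expect_identical(unname(imp[4, ]), c(2L, 0L, 2L))
  expect_false(anyNA(imp))
})

test_that("equidistant conflicting flanks impute to the first parent's class", {
  m <- linkage_map(rep("c1", 3), c("m1", "m2", "m3"), c(0, 5, 10))
  pil <- genotype_matrix(rbind(c(2, NA, 0), c(0, NA, 2)), "PIL")
  imp <- impute_missing(pil, m, "DH", "haldane")
  expect_identical(unname(imp[, 2]), c(2L, 2L))
})

test_that("an all-missing chromosome row falls back to the frequent class", {
  m <- tiny_map()
  pil <- genotype_matrix(rbind(matrix(c(2L, 2L, 0L), 4, 3, byrow = TRUE),
                               c(NA, NA, NA)), "PIL")
  imp <- impute_missing(pil, m, "DH", "haldane")
  expect_identical(unname(imp[5, ]), c(2L, 2L, 0L))
})

test_that("marker correlation matches the DH linkage expectation 1 - 2r", {
  set.seed(11)
  p <- simulate_pil(2000, map2(), pil_type = "DH", fun = "haldane")
  cc <- marker_correlation(p$markers)
  expect_equal(cc[2, 1], 1 - 2 * map_to_recomb(0.1, "haldane"),
               tolerance = 0.03 / 0.82)
  expect_equal(diag(cc), c(A = 1, B = 1))
  # identical and complementary columns
  x <- cbind(a = c(2, 0, 2, 0), b = c(2, 0, 2, 0), c = c(0, 2, 0, 2))
  cc2 <- marker_correlation(x)
  expect_equal(cc2[2, 1], 1)
  expect_equal(cc2[3, 1], -1)
  # zero-variance marker warns and records 0
  x2 <- cbind(a = c(2, 0, 2, 0), b = c(2, 2, 2, 2))
  expect_warning(cc3 <- marker_correlation(x2), "zero-variance")
  expect_equal(cc3[2, 1], 0)
})

test_that("cross designs validate sizes, self-pairs and balance", {
  expect_error(cross_design(4, rbind(c(1, 1))), "self-pairing")
  expect_error(cross_design(4, rbind(c(1, 5))), "out of range")
  expect_error(cross_design(4, rbind(c(1, 2), c(1, 3)), sampling = "balanced"),
               "equally often")
  d <- cross_design(4, rbind(c(1, 2), c(3, 4), c(1, 3), c(2, 4)),
                    sampling = "balanced")
  expect_s3_class(d, "cross_design")
})
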