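# Brute-force sums-of-squares oracle for the one-way decomposition.
ss_oracle <- function(m) {
  vals <- as.vector(t(m))
  entry <- rep(seq_len(nrow(m)), each = ncol(m))
  keep <- !is.na(vals)
  vals <- vals[keep]
  entry <- entry[keep]
  grand <- mean(vals)
  mi <- tapply(vals, entry, mean)
  ni <- tabulate(entry)
  ni <- ni[ni > 0]
  list(ss_g = sum(ni * (mi - grand)^2),
       ss_e = sum((vals - mi[as.character(entry)])^2),
       df_g = length(mi) - 1, df_e = length(vals) - length(mi))
}

test_that("one-way ANOVA matches the brute-force sums-of-squares oracle", {
  set.seed(31)
  m <- matrix(rnorm(60, sd = 2), 20, 3) + rnorm(20)
  m[3, 2] <- NA  # unbalanced
  r <- oneway_anova(m)
  o <- ss_oracle(m)
  expect_equal(r$table$SS[1:2], c(o$ss_g, o$ss_e))
  expect_equal(r$table$DF[1:2], c(o$df_g, o$df_e))
  expect_equal(r$Verror, o$ss_e / o$df_e)
  rbar <- 20 / sum(1 / rowSums(!is.na(m)))
  expect_equal(r$Vgeno, max(0, (o$ss_g / o$df_g - o$ss_e / o$df_e) / rbar))
  expect_equal(r$Vpheno, r$Vgeno + r$Verror / rbar)
  expect_equal(r$Hbroad, r$Vgeno / r$Vpheno)
})

test_that("textbook two-entry example gives the expected mean squares", {
  # entry means 0 and 2, within-entry deviations +/-1 -> MS_error = 2
  m <- rbind(c(-1, 1), c(1, 3))
  r <- oneway_anova(m)
  expect_equal(r$table$MS[2], 2)
  expect_equal(r$table$SS[1], 4)  # 2 * (1 - 0)^2 + 2 * (1 - ... ) textbook: n*(mi-m)^2
  # zero within-entry spread: Verror 0, Hbroad 1
  r2 <- oneway_anova(rbind(c(10, 10), c(20, 20)))
  expect_equal(r2$Verror, 0)
  expect_equal(r2$Hbroad, 1)
})

test_that("replication labels do not matter and heritability is affine-invariant", {
  set.seed(32)
  m <- matrix(rnorm(40), 10, 4) + 2 * rnorm(10)
  shuf <- t(apply(m, 1, sample))
  expect_equal(oneway_anova(m)$table, oneway_anova(shuf)$table)
  r1 <- oneway_anova(m)
  r2 <- oneway_anova(3.7 * m - 11)
  expect_equal(r1$Hbroad, r2$Hbroad)
  expect_equal(r2$Vgeno, 3.7^2 * r1$Vgeno)
})

test_that("single-replication data leaves components not estimable", {
  r <- oneway_anova(matrix(rnorm(10), 10, 1))
  expect_true(is.na(r$Vgeno) && is.na(r$Hbroad))
  expect_equal(r$DFerror, 0)
})

test_that("estimated genotypic values are replicate means with missing handling", {
  expect_equal(estimated_genotypic_values(rbind(c(1, 3), c(5, NA))), c(2, 5))
  expect_true(is.na(estimated_genotypic_values(rbind(c(1, 2), c(NA, NA)))[2]))
})

test_that("combined decomposition solves the moment equations exactly", {
  mk <- function(vg) list(Vgeno = vg, Verror = 1, DFerror = 100)
  cb <- combined_anova(list(PIL = mk(2), IF2 = mk(1.25)))
  expect_equal(cb$Vadd_F2, 1)
  expect_equal(cb$Vdom_F2, 0.25)
  expect_equal(cb$Verror_F2, 1)
  expect_equal(cb$Hnarrow_F2, 1 / (1 + 0.25 + 1))
  # third equation consistency: IB1 + IB2 = VA + 2 VD
  cb3 <- combined_anova(list(PIL = mk(2), IF2 = mk(1.25),
                             IB1 = mk(0.7), IB2 = mk(0.8)))
  expect_equal(cb3$Vadd_F2, 1, tolerance = 1e-8)
  expect_equal(cb3$Vdom_F2, 0.25, tolerance = 1e-8)
  # DF-weighted pooled error
  cb4 <- combined_anova(list(PIL = list(Vgeno = 2, Verror = 1, DFerror = 300),
                             IF2 = list(Vgeno = 1.25, Verror = 2, DFerror = 100)))
  expect_equal(cb4$Verror_F2, (300 * 1 + 100 * 2) / 400)
})

test_that("rank-deficient combined systems report composites, not fabrications", {
  mk <- function(vg) list(Vgeno = vg, Verror = 1, DFerror = 100)
  cb <- combined_anova(list(IB1 = mk(0.7), IB2 = mk(0.8)))
  expect_true(is.na(cb$Vadd_F2) && is.na(cb$Vdom_F2))
  expect_equal(cb$composite$value, 1.5)
  expect_equal(unname(cb$composite$coef), c(1, 2))
  # PIL + IB1 identifies VA only
  cb2 <- combined_anova(list(PIL = mk(2), IB1 = mk(0.7)))
  expect_equal(cb2$Vadd_F2, 1)
  expect_true(is.na(cb2$Vdom_F2))
  expect_error(combined_anova(list(PIL = mk(1))), "at least 2")
})

test_that("negative genetic variance estimates truncate at zero", {
  mk <- function(vg) list(Vgeno = vg, Verror = 1, DFerror = 50)
  cb <- combined_anova(list(PIL = mk(2), IF2 = mk(0.2)))  # implies VD < 0
  expect_gte(cb$Vdom_F2, 0)
  expect_gte(cb$Vadd_F2, 0)
})

test_that("the VHP dialect parses sizes, reps and missing tokens", {
  f <- withr::local_tempfile(fileext = ".vhp")
  writeLines(c("3 0 0 2  2  1 yield",
               "# PIL", "1.0 1.2", "0.9 NA", "2.0 2.2",
               "# IF2", "1.5 *", "-100 1.1"), f)
  ps <- read_vhp(f)
  expect_named(ps$data, c("PIL", "IF2"))
  expect_equal(ps$data$PIL$yield[2, ], c(0.9, NA))
  expect_equal(ps$data$IF2$yield[1, ], c(1.5, NA))
  expect_equal(ps$data$IF2$yield[2, ], c(NA, 1.1))
  # size rule: IB1 must match PIL
  writeLines(c("3 2 0 0 1 1 t", "1", "2", "3", "4", "5"), f)
  expect_error(read_vhp(f), "same size as PIL")
  # unknown missing token
  writeLines(c("2 0 0 0 1 1 t", "1.0", "oops"), f)
  expect_error(read_vhp(f), "not a valid")
})

test_that("run_vhp writes the components, genotypic-value and table outputs", {
  set.seed(33)
  sim <- simulate_populations(map6(), model1(a = 1, d = 0.5, h2 = 0.6),
                              80, 80, 80, 120, reps = 3)
  f <- withr::local_tempfile(fileext = ".vhp")
  write_vhp_input(sim, f)
  dir <- withr::local_tempdir()
  out <- run_vhp(f, out_prefix = file.path(dir, "x"))
  expect_true(all(file.exists(file.path(dir, c("x.adh", "x.egv", "x.tab")))))
  expect_named(out$anova, c("PIL", "IB1", "IB2", "IF2"))
  expect_false(is.null(out$combined))
  cb <- out$combined$simTrait
  expect_true(is.finite(cb$Vadd_F2) && is.finite(cb$Vdom_F2))
  expect_true(cb$Hnarrow_F2 >= 0 && cb$Hnarrow_F2 <= 1)
})
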