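# Small deterministic context helper: one chromosome, full data.
make_ctx <- function(pil, map, pil_type = "DH", fun = "haldane", step = 1,
                     design = cross_design(nrow(pil))) {
  immqtl:::build_qtl_context(map, pil, design, pil_type, fun, step = step)
}

test_that("QTL genotype priors match the exhaustive gamete enumeration", {
  m <- linkage_map(rep("c1", 2), c("L", "R"), c(0, 10))
  r <- map_to_recomb(0.05, "haldane")  # both flanks 5 cM from the QTL
  for (gl in c(2, 0)) for (gr in c(2, 0)) {
    pil <- genotype_matrix(rbind(c(gl, gr)), "PIL")
    pri <- qtl_genotype_priors(pil, m, "c1", 5, "PIL", pil_type = "DH",
                               fun = "haldane")
    expect_equal(unname(pri[1, "2"]), enum_prior(gl, gr, r, r),
                 tolerance = 1e-12, info = paste(gl, gr))
    expect_equal(sum(pri), 1)
  }
})

test_that("a position at an observed marker has a degenerate prior", {
  m <- tiny_map()
  pil <- genotype_matrix(rbind(c(2, 0, 2)), "PIL")
  pri <- qtl_genotype_priors(pil, m, "c1", 5, "PIL")
  expect_equal(unname(pri[1, ]), c(0, 0, 1))
  # missing at the marker: information comes from the flanks
  pil2 <- genotype_matrix(rbind(c(2, NA, 2)), "PIL")
  pri2 <- qtl_genotype_priors(pil2, m, "c1", 5, "PIL")
  expect_gt(pri2[1, "2"], 0.95)
  # no information at all marginalizes to line frequencies
  pil3 <- genotype_matrix(rbind(c(NA, NA, NA)), "PIL")
  pri3 <- qtl_genotype_priors(pil3, m, "c1", 5, "PIL")
  expect_equal(unname(pri3[1, ]), c(0.5, 0, 0.5))
  expect_error(qtl_genotype_priors(pil, m, "c1", 99, "PIL"), "outside")
})

test_that("hybrid priors factorize over parental gametes", {
  m <- tiny_map()
  pil <- genotype_matrix(rbind(c(2, NA, 0), c(0, 0, 0)), "PIL")
  p <- immqtl:::line_allele_prob(pil, m$pos, 6, "haldane", "DH")
  des <- cross_design(2, rbind(c(1, 2)))
  pri <- qtl_genotype_priors(pil, m, "c1", 6, "IF2", design = des,
                             fun = "haldane")
  p1 <- p[1]
  p2 <- p[2]
  expect_equal(unname(pri[1, ]),
               c(p1 * p2, p1 * (1 - p2) + p2 * (1 - p1), (1 - p1) * (1 - p2)))
  ib1 <- qtl_genotype_priors(pil, m, "c1", 6, "IB1", fun = "haldane")
  expect_equal(unname(ib1[, 3]), c(0, 0))   # IB1 has no P2 homozygote class
  ib2 <- qtl_genotype_priors(pil, m, "c1", 6, "IB2", fun = "haldane")
  expect_equal(unname(ib2[, 1]), c(0, 0))
})

test_that("EM at fully informative positions equals the least-squares LOD", {
  set.seed(41)
  sim <- simulate_populations(map6(), model1(a = 1, h2 = 0.4), 200)
  g <- sim$populations$PIL$geno
  y <- rowMeans(sim$populations$PIL$y)
  ctx <- make_ctx(g, map6(), step = 5)
  prof <- im_scan(ctx, list(PIL = y))
  rss0 <- sum((y - mean(y))^2)
  for (k in seq_len(6)) {
    x <- g[, k] - 1
    rss1 <- sum(resid(lm(y ~ x))^2)
    lod_ols <- length(y) / 2 * log10(rss0 / rss1)
    t <- which(ctx$scan$pos == map6()$pos[k])
    expect_equal(prof$lod[t], lod_ols, tolerance = 1e-6)
    expect_equal(prof$a[t], unname(coef(lm(y ~ x))[2]), tolerance = 1e-6)
  }
})

test_that("the observed-data log-likelihood never decreases across EM iterations", {
  set.seed(42)
  sim <- simulate_populations(map6(), model1(a = 1, h2 = 0.3), 120)
  g <- sim$populations$PIL$geno
  g[sample(length(g), 80)] <- NA  # missingness makes the priors soft
  ctx <- make_ctx(g, map6(), step = 1)
  grp <- immqtl:::build_group(ctx, list(PIL = rowMeans(sim$populations$PIL$y)))
  for (t in seq(3, nrow(ctx$scan), by = 9)) {
    pri <- immqtl:::group_prior(grp, ctx$P, t)
    fit <- immqtl:::fit_mixture(grp$y, grp, pri, trace = TRUE,
                                incl = c(TRUE, FALSE))
    expect_true(all(diff(fit$ll_trace) > -1e-7), info = paste("position", t))
  }
})

test_that("LOD localizes a strong QTL at its marker under vanishing noise", {
  set.seed(43)
  sim <- simulate_populations(map6(), qtl_model("chr1", 20, 1, 0, -1, ve = 1e-4),
                              150)
  ctx <- make_ctx(sim$populations$PIL$geno, map6(), step = 5)
  prof <- im_scan(ctx, list(PIL = rowMeans(sim$populations$PIL$y)))
  at_qtl <- prof$lod[prof$pos == 20]
  expect_gt(at_qtl, max(prof$lod[abs(prof$pos - 20) > 15]) + 10)
})

test_that("stepwise selection controls the null rate and finds real effects", {
  set.seed(44)
  # pure noise: with pin = 0.001 and 60 candidates, selections are rare
  n_sel <- vapply(1:10, function(i) {
    X <- matrix(sample(c(-1, 1), 200 * 60, replace = TRUE), 200, 60)
    colnames(X) <- paste0("m", 1:60)
    sw <- stepwise_select(rnorm(200), X, pin = 0.001)
    nrow(sw$selected)
  }, numeric(1))
  expect_lte(median(n_sel), 1)
  # one strong signal: selected (or an immediate neighbour) nearly always
  hits <- vapply(1:10, function(i) {
    sim <- simulate_populations(map6(), model1(a = 1, h2 = 0.5), 200)
    g <- immqtl:::build_qtl_context(map6(), sim$populations$PIL$geno,
                                    cross_design(200), "DH", "kosambi")
    grp <- immqtl:::build_group(g, list(PIL = rowMeans(sim$populations$PIL$y)))
    md <- immqtl:::marker_design(g, grp)
    sw <- stepwise_select(grp$y, md$X, forced = grp$X0, pin = 0.001)
    any(md$marker[match(sw$selected$variable, colnames(md$X))] %in% 3:4)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(stepwise_select(rnorm(10), matrix(rnorm(10)), pin = 0.01,
                               pout = 0.005), "pout")
})

test_that("partial-F entry tests agree with the lm/anova computation", {
  set.seed(45)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- 0.8 * X[, 2] + rnorm(n)
  # force pin high enough that exactly the strongest variable enters first
  sw <- stepwise_select(y, X, pin = 1e-12, pout = 1e-11)
  pv <- vapply(1:4, function(j) anova(lm(y ~ 1), lm(y ~ X[, j]))[["Pr(>F)"]][2],
               numeric(1))
  if (min(pv) <= 1e-12) {
    expect_equal(sw$selected$variable[1], paste0("v", which.min(pv)))
  } else {
    expect_equal(nrow(sw$selected), 0)
  }
})

test_that("with nothing selected ICIM reduces exactly to interval mapping", {
  set.seed(46)
  sim <- simulate_populations(map6(), model1(ve = 25), 80)  # drown the signal
  ctx <- make_ctx(sim$populations$PIL$geno, map6(), step = 5)
  y <- rowMeans(sim$populations$PIL$y)
  ic <- icim_scan(ctx, list(PIL = y), pin = 1e-9)
  expect_equal(nrow(ic$stepwise), 0)
  expect_equal(ic$profile, im_scan(ctx, list(PIL = y)))
})

test_that("QTL extraction follows the region, peak and one-LOD-interval rules", {
  map <- fixture_map(1, 7, 10)
  grid <- scan_positions(map, 5)$pos
  prof <- data.frame(chrom = "chr1", pos = grid,
                     lod = approx(map$pos, c(0, 1, 2, 8, 2, 1, 0),
                                  xout = grid)$y)
  prof$lod_add <- prof$lod
  prof$lod_dom <- NA
  prof[c("a", "d", "pve", "pve_add", "pve_dom")] <- 1
  q <- extract_qtl(prof, 3, map)
  expect_equal(nrow(q), 1)
  expect_equal(q$pos, 30)
  expect_equal(q$left_marker, "M1_4")
  expect_true(q$ci_low <= 30 && q$ci_high >= 30)
  # LOD >= 7 region spans 25..35 on the interpolated profile
  expect_true(all(prof$lod[prof$pos >= q$ci_low & prof$pos <= q$ci_high] >=
                    q$lod - 1))
  # everything below threshold: empty
  expect_equal(nrow(extract_qtl(prof, 99, map)), 0)
  # two regions split by a sub-threshold gap
  prof2 <- prof
  prof2$lod <- 0
  prof2$lod[prof2$pos %in% c(10, 50)] <- 5
  expect_equal(nrow(extract_qtl(prof2, 3, map)), 2)
  expect_error(extract_qtl(prof, 0, map), "positive")
})

test_that("dominance is estimable exactly in the designs that contain it", {
  set.seed(47)
  sim <- simulate_populations(map6(), model1(a = 1, d = 0.5, h2 = 0.5),
                              100, 100, 100, 150)
  ctx <- make_ctx(sim$populations$PIL$geno, map6(), step = 10,
                  design = sim$design)
  ph <- lapply(sim$populations, function(p) rowMeans(p$y))
  # single populations: composite effect only
  for (pop in c("PIL", "IB1", "IB2")) {
    prof <- im_scan(ctx, ph[pop])
    expect_true(all(is.na(prof$d)), info = pop)
    expect_true(all(is.na(prof$lod_dom)), info = pop)
  }
  # combined designs estimate both
  for (members in list(c("IB1", "IB2"), c("IF2", "PIL"),
                       c("IB1", "IB2", "IF2", "PIL"))) {
    prof <- im_scan(ctx, ph[members])
    expect_true(all(is.finite(prof$d)), info = paste(members, collapse = "+"))
  }
})

test_that("combined designs resolve to their group tags", {
  expect_equal(immqtl:::combined_group_for(c("IB1", "IB2")), "IBC")
  expect_equal(immqtl:::combined_group_for(c("PIL", "IF2")), "IFL")
  expect_equal(immqtl:::combined_group_for(c("IB1", "IB2", "PIL")), "IBL")
  expect_equal(immqtl:::combined_group_for(c("IB1", "IB2", "IF2")), "IBF")
  expect_equal(immqtl:::combined_group_for(c("PIL", "IB1", "IB2", "IF2")), "BFL")
  expect_null(immqtl:::combined_group_for(c("PIL", "IB1")))
  expect_null(immqtl:::combined_group_for("PIL"))
})

test_that("a combined fit over one population reduces to the single fit", {
  set.seed(48)
  sim <- simulate_populations(map6(), model1(a = 1, h2 = 0.4), 100)
  ctx <- make_ctx(sim$populations$PIL$geno, map6(), step = 10)
  y <- rowMeans(sim$populations$PIL$y)
  # build_group with a single member is the single-population analysis
  p1 <- im_scan(ctx, list(PIL = y))
  expect_true(all(p1$lod >= 0))
  expect_equal(p1, im_scan(ctx, list(PIL = y)))
})

test_that("Bayesian classification recovers genotypes with high accuracy", {
  set.seed(49)
  sim <- simulate_populations(map6(), qtl_model("chr1", 20, 1, 0, -1, ve = 0.01),
                              150)
  ctx <- make_ctx(sim$populations$PIL$geno, map6(), step = 5)
  y <- rowMeans(sim$populations$PIL$y)
  prof <- im_scan(ctx, list(PIL = y))
  q <- extract_qtl(prof, 3, ctx$map)
  q <- q[which.max(q$lod), ]
  cls <- bayes_genotype_classes(ctx, list(PIL = y), q)
  truth <- sim$populations$PIL$qtl[, 1]
  expect_gte(mean(cls$class == truth), 0.99)
  # degenerate prior at an observed marker: class equals the marker genotype
  qm <- q
  qm$pos <- 20
  cls2 <- bayes_genotype_classes(ctx, list(PIL = y), qm)
  expect_equal(cls2$class, unname(sim$populations$PIL$geno[, 3]))
})

test_that("descriptive statistics use standard moment definitions", {
  d <- descriptive_stats(list(PIL = list(t = c(1, 2, 3))))
  expect_equal(d$mean, 2)
  expect_equal(d$variance, 1)
  dc <- descriptive_stats(list(PIL = list(t = rep(5, 4))))
  expect_equal(dc$skewness, 0)
  expect_true(dc$degenerate)
  set.seed(50)
  dn <- descriptive_stats(list(PIL = list(t = rnorm(20000))))
  expect_lt(abs(dn$skewness), 3 * sqrt(6 / 20000))
  expect_lt(abs(dn$kurtosis), 3 * sqrt(24 / 20000))
})

test_that("the QHP dialect validates its configuration", {
  f <- withr::local_tempfile(fileext = ".qhp")
  # gPIL smaller than the PIL phenotyping size
  writeLines(c("1 2 1 1 1 1  3 0 0 0  1 t",
               "c1 2", "m1 0", "m2 10",
               "2 0", "0 2", "1 2 3"), f)
  expect_error(read_qhp(f), "exceeds")
  # unequal backcross sizes
  writeLines(c("1 4 1 1 1 1  4 3 0 0  1 t", "c1 2", "m1 0", "m2 10"), f)
  expect_error(read_qhp(f), "equal")
})

test_that("run_qhp analyzes populations independently plus one combined design", {
  set.seed(51)
  sim <- simulate_populations(map6(), model1(a = 1, d = 0.5, h2 = 0.6),
                              80, 80, 80, 120)
  f <- withr::local_tempfile(fileext = ".qhp")
  write_qhp_input(sim, f)
  res <- run_qhp(f, step = 5)
  expect_named(res$groups, c("pil", "ib1", "ib2", "if2", "bfl"))
  # BFL should see the QTL clearly at this heritability
  expect_gte(nrow(res$groups$bfl$simTrait$ICIM$qtl), 1)
  q <- res$groups$bfl$simTrait$ICIM$qtl
  expect_lte(min(abs(q$pos[q$chrom == "chr1"] - 25)), 10)
})
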