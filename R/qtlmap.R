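# Interval mapping (IM) and inclusive composite interval mapping (ICIM)
# by EM on normal mixtures, for single populations and the combined
# multi-population designs.
#
# Model at a scan position: y_i ~ sum_g pi_ig Normal(mu_pop(i) + a x_g +
# d z_g, sigma^2) with F2-metric codings x = (1, 0, -1), z = (0, 1, 0)
# for genotype classes (2, 1, 0); pi_ig are the marker-conditional priors;
# combined groups share (a, d) with population-specific intercepts and a
# pooled residual variance.

XCODE <- c(1, 0, -1)
ZCODE <- c(0, 1, 0)

# The five combined designs: exact present-set -> group tag.
COMBINED_GROUPS <- list(
  IBC = c("IB1", "IB2"),
  IFL = c("IF2", "PIL"),
  IBL = c("IB1", "IB2", "PIL"),
  IBF = c("IB1", "IB2", "IF2"),
  BFL = c("IB1", "IB2", "IF2", "PIL")
)

combined_group_for <- function(present) {
  for (tag in names(COMBINED_GROUPS)) {
    if (setequal(present, COMBINED_GROUPS[[tag]])) return(tag)
  }
  NULL
}

# ---- analysis context -----------------------------------------------------

# Precompute everything position-independent: scan grid, flanking-marker
# indices, line allele probabilities, derived/imputed genotype codings.
build_qtl_context <- function(map, pil_geno, design, pil_type, fun,
                              step = 1, drop_unusable = TRUE) {
  pil_geno <- normalize_pil(genotype_matrix(pil_geno, "PIL"))
  ms <- marker_summary(pil_geno, map)
  dropped <- character(0)
  if (drop_unusable && any(!ms$usable)) {
    dropped <- map$marker[!ms$usable]
    keep <- ms$usable
    chrom_ok <- tapply(keep, factor(map$chrom, unique(map$chrom)), sum) >= 2
    if (any(!chrom_ok)) {
      stop("chromosome(s) with fewer than 2 usable markers: ",
           paste(names(chrom_ok)[!chrom_ok], collapse = ", "))
    }
    map <- validate_linkage_map(as.data.frame(map)[keep, ])
    pil_geno <- pil_geno[, keep, drop = FALSE]
  }
  scan <- scan_positions(map, step)
  # flanking markers (global indices into `map`) of the interval holding
  # each scan position; a position at a marker uses the interval to its
  # right (the last marker uses the one to its left)
  fl <- matrix(NA_integer_, nrow(scan), 2)
  for (ch in unique(map$chrom)) {
    gi <- which(map$chrom == ch)
    mpos <- map$pos[gi]
    si <- which(scan$chrom == ch)
    kL <- findInterval(scan$pos[si] + 1e-9, mpos)
    kL <- pmin(kL, length(mpos) - 1L)
    fl[si, 1] <- gi[kL]
    fl[si, 2] <- gi[kL + 1L]
  }
  # line allele probabilities at every scan position
  P <- matrix(NA_real_, nrow(pil_geno), nrow(scan))
  for (ch in unique(map$chrom)) {
    gi <- which(map$chrom == ch)
    si <- which(scan$chrom == ch)
    P[, si] <- line_allele_prob(pil_geno[, gi, drop = FALSE], map$pos[gi],
                                scan$pos[si], fun, pil_type)
  }
  pil_imp <- impute_missing(pil_geno, map, pil_type, fun)
  geno <- list(PIL = pil_imp)
  if (!is.null(design)) {
    geno$IB1 <- derive_hybrid_genotypes(pil_imp, target = "IB1")
    geno$IB2 <- derive_hybrid_genotypes(pil_imp, target = "IB2")
    if (!is.null(design$if2_pairs)) {
      geno$IF2 <- derive_hybrid_genotypes(pil_imp, design, "IF2")
    }
  }
  list(map = map, fun = fun, pil_type = pil_type, design = design,
       pil_geno = pil_geno, pil_imp = pil_imp, geno = geno,
       scan = scan, flank = fl, P = P, dropped_markers = dropped)
}

# One analysis group: stacked phenotypes of one or more populations.
# `pheno` is a named list pop -> numeric vector (missing already replaced
# by the population mean); `n_pil` rows of the context refer to genotyped
# lines, of which the first length(pheno$PIL) are phenotyped.
build_group <- function(ctx, pheno) {
  pops <- names(pheno)
  y <- unlist(pheno, use.names = FALSE)
  kind <- rep(pops, lengths(pheno))
  popf <- factor(kind, levels = pops)
  par1 <- par2 <- integer(0)
  for (p in pops) {
    n <- length(pheno[[p]])
    if (p == "IF2") {
      pr <- ctx$design$if2_pairs
      par1 <- c(par1, pr[seq_len(n), 1])
      par2 <- c(par2, pr[seq_len(n), 2])
    } else {
      par1 <- c(par1, seq_len(n))
      par2 <- c(par2, rep(NA_integer_, n))
    }
  }
  n <- length(y)
  X0 <- matrix(0, n, nlevels(popf),
               dimnames = list(NULL, levels(popf)))
  X0[cbind(seq_len(n), as.integer(popf))] <- 1
  d_est <- "IF2" %in% pops || all(c("IB1", "IB2") %in% pops)
  Xe <- do.call(rbind, lapply(1:3, function(g) cbind(X0, x = XCODE[g], z = ZCODE[g])))
  list(y = y, kind = kind, popf = popf, par1 = par1, par2 = par2,
       pops = pops, n = n, X0 = X0, Xe = Xe, yrep = rep(y, 3),
       d_est = d_est, ll0 = null_loglik(y, popf))
}

group_prior <- function(g, P, t) {
  pri <- matrix(0, g$n, 3)
  for (p in g$pops) {
    rows <- which(g$kind == p)
    p1 <- P[g$par1[rows], t]
    if (p == "IF2") {
      pri[rows, ] <- population_priors("IF2", p1, P[g$par2[rows], t])
    } else {
      pri[rows, ] <- population_priors(p, p1)
    }
  }
  pri
}

null_loglik <- function(y, popf) {
  mu <- stats::ave(y, popf)
  s2 <- max(sum((y - mu)^2) / length(y), 1e-12)
  -length(y) / 2 * (log(2 * pi * s2) + 1)
}

# ---- EM fit at one position ----------------------------------------------

# incl: logical c(a, d).  Starts from the Haley-Knott regression on
# prior-expected codings, then iterates EM; returns the observed-data
# log-likelihood, effect estimates and posterior weights.
fit_mixture <- function(y, g, prior, incl = c(a = TRUE, d = TRUE),
                        maxit = 200, tol = 1e-6, trace = FALSE) {
  ll_trace <- if (trace) numeric(0) else NULL
  n <- g$n
  npop <- ncol(g$X0)
  cols <- c(seq_len(npop), if (incl[1]) npop + 1L, if (incl[2]) npop + 2L)
  Xe <- g$Xe[, cols, drop = FALSE]
  yrep <- g$yrep
  prv <- as.vector(prior)
  active <- prv > 0
  s2_floor <- max(stats::var(y), 1e-8) * 1e-10

  # init: weighted regression with prior weights (Haley-Knott)
  wv <- prv
  beta <- tryCatch(
    solve(crossprod(Xe[active, , drop = FALSE], Xe[active, , drop = FALSE] * wv[active]),
          crossprod(Xe[active, , drop = FALSE], (wv * yrep)[active])),
    error = function(e) NULL)
  if (is.null(beta)) beta <- matrix(0, length(cols), 1)
  s2 <- max(sum(wv * (yrep - Xe %*% beta)^2) / n, s2_floor)

  ll_old <- -Inf
  ll <- ll_old
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu_e <- as.vector(Xe %*% beta)
    dens <- prv * stats::dnorm(yrep, mu_e, sqrt(s2))
    dens <- matrix(dens, n, 3)
    lik <- rowSums(dens) + 1e-300
    ll <- sum(log(lik))
    if (trace) ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    w <- as.vector(dens / lik)
    A <- crossprod(Xe, Xe * w)
    b <- crossprod(Xe, w * yrep)
    beta_new <- tryCatch(solve(A, b), error = function(e) beta)
    beta <- beta_new
    s2 <- max(sum(w * (yrep - Xe %*% beta)^2) / n, s2_floor)
  }
  a_hat <- if (incl[1]) beta[npop + 1L] else NA_real_
  d_hat <- if (incl[2]) beta[npop + 1L + incl[1]] else NA_real_
  mu_e <- as.vector(Xe %*% beta)
  dens <- matrix(prv * stats::dnorm(yrep, mu_e, sqrt(s2)), n, 3)
  lik <- rowSums(dens) + 1e-300
  list(ll = sum(log(lik)), beta = as.vector(beta), a = a_hat, d = d_hat,
       s2 = s2, mu = as.vector(g$X0 %*% beta[seq_len(npop)]),
       post = dens / lik, converged = converged, ll_trace = ll_trace)
}

# ---- scan drivers ---------------------------------------------------------

# Within-population centered prior-expected codings, for PVE partitions.
coding_moments <- function(g, prior) {
  Ex <- as.vector(prior %*% XCODE)
  Ez <- as.vector(prior %*% ZCODE)
  Exc <- Ex - stats::ave(Ex, g$popf)
  Ezc <- Ez - stats::ave(Ez, g$popf)
  list(Exc = Exc, Ezc = Ezc)
}

pooled_pheno_var <- function(y, popf) {
  mu <- stats::ave(y, popf)
  sum((y - mu)^2) / (length(y) - nlevels(popf))
}

# Core scan over all context positions.  `adjust` (ICIM) carries the
# stepwise contributions; when present the phenotype and the null model
# are re-formed per position with the flanking markers' effects added
# back.  Returns a scan_profile data frame.
scan_profile <- function(ctx, g, adjust = NULL, submodels = TRUE) {
  npos <- nrow(ctx$scan)
  cols <- c("lod", "lod_add", "lod_dom", "a", "d", "pve", "pve_add", "pve_dom")
  out <- matrix(NA_real_, npos, length(cols), dimnames = list(NULL, cols))
  vp0 <- pooled_pheno_var(g$y, g$popf)
  for (t in seq_len(npos)) {
    pri <- group_prior(g, ctx$P, t)
    if (is.null(adjust)) {
      yt <- g$y
      ll0 <- g$ll0
      vp <- vp0
    } else {
      keep <- adjust$marker %in% ctx$flank[t, ]
      yt <- g$y - adjust$total +
        if (any(keep)) rowSums(adjust$contrib[, keep, drop = FALSE]) else 0
      ll0 <- null_loglik(yt, g$popf)
      vp <- pooled_pheno_var(yt, g$popf)
    }
    gt <- g
    gt$y <- yt
    gt$yrep <- rep(yt, 3)
    fit <- fit_mixture(yt, gt, pri, incl = c(TRUE, g$d_est))
    lod <- max(0, (fit$ll - ll0) / log(10))
    if (g$d_est && submodels) {
      f_a0 <- fit_mixture(yt, gt, pri, incl = c(FALSE, TRUE))
      f_d0 <- fit_mixture(yt, gt, pri, incl = c(TRUE, FALSE))
      lod_add <- max(0, (fit$ll - f_a0$ll) / log(10))
      lod_dom <- max(0, (fit$ll - f_d0$ll) / log(10))
    } else if (g$d_est) {
      lod_add <- lod_dom <- NA_real_
    } else {
      lod_add <- lod
      lod_dom <- NA_real_
    }
    cm <- coding_moments(g, pri)
    a <- fit$a
    d <- if (g$d_est) fit$d else NA_real_
    var_x <- stats::var(cm$Exc)
    var_z <- stats::var(cm$Ezc)
    eff <- a * cm$Exc + if (is.na(d)) 0 else d * cm$Ezc
    out[t, ] <- c(lod, lod_add, lod_dom, a, d,
                  100 * stats::var(eff) / vp,
                  100 * a^2 * var_x / vp,
                  if (is.na(d)) NA_real_ else 100 * d^2 * var_z / vp)
  }
  cbind(ctx$scan, as.data.frame(out))
}

#' Interval-mapping scan
#'
#' Scans every grid position with the EM normal-mixture model.  Single
#' populations with only two genotype classes (PIL, IB1 or IB2 alone) fit
#' one composite effect, reported in the \code{a} column with \code{d}
#' not estimable; groups containing IF2 or both backcross populations fit
#' additive and dominance effects with population-specific intercepts and
#' a pooled residual variance.
#'
#' @param ctx analysis context from the QHP pipeline (see [run_qhp()]).
#' @param pheno named list of per-population phenotype vectors.
#' @param submodels also fit the drop-one models for the additive and
#'   dominance LOD partitions (default TRUE).
#' @return a scan-profile data frame: chrom, pos, LOD scores, effect
#'   estimates and PVE partitions per position.
#' @export
im_scan <- function(ctx, pheno, submodels = TRUE) {
  g <- build_group(ctx, pheno)
  scan_profile(ctx, g, adjust = NULL, submodels = submodels)
}

#' Stepwise marker selection
#'
#' Classic forward-entry (partial-F p <= \code{pin}) / backward-removal
#' (p > \code{pout}) regression of the phenotype on marker additive and
#' dominance codings; population intercepts are forced covariates and are
#' never removed.  Used as the first step of inclusive composite interval
#' mapping.
#'
#' @param y response vector.
#' @param X candidate design matrix (columns named).
#' @param forced matrix of forced covariates (no intercept is added when
#'   given; otherwise an intercept is used).
#' @param pin,pout entry and removal probability thresholds,
#'   \code{pout >= pin}.
#' @return list with \code{selected} (data frame of variable name and
#'   coefficient) and the final \code{fit}.
#' @export
stepwise_select <- function(y, X, forced = NULL, pin = 0.001, pout = 2 * pin) {
  if (pout < pin) stop("pout must be >= pin")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- length(y)
  base <- if (is.null(forced)) matrix(1, n, 1) else as.matrix(forced)
  n_forced <- ncol(base)
  # constant candidates can never enter
  cands <- which(apply(X, 2, stats::var) > 0)
  selected <- integer(0)

  rss_of <- function(cols) {
    q <- qr(cbind(base, X[, cols, drop = FALSE]))
    sum(qr.resid(q, y)^2)
  }
  repeat {
    moved <- FALSE
    # forward: partial F of each remaining candidate given current model
    remaining <- setdiff(cands, selected)
    if (length(remaining)) {
      cur <- cbind(base, X[, selected, drop = FALSE])
      q <- qr(cur)
      p_cur <- q$rank
      y_r <- qr.resid(q, y)
      rss_cur <- sum(y_r^2)
      C_r <- qr.resid(q, X[, remaining, drop = FALSE])
      ss <- colSums(C_r^2)
      usable <- ss > 1e-8 * colSums(X[, remaining, drop = FALSE]^2)
      red <- ifelse(usable, colSums(C_r * y_r)^2 / ss, 0)
      df <- n - p_cur - 1
      Fv <- red / pmax(rss_cur - red, 1e-300) * df
      pv <- stats::pf(Fv, 1, df, lower.tail = FALSE)
      pv[!usable] <- 1  # collinear additions are skipped
      if (df > 0 && min(pv) <= pin) {
        selected <- c(selected, remaining[which.min(pv)])
        moved <- TRUE
      }
    }
    # backward: partial F of each selected variable in the current model
    if (length(selected) > 0) {
      rss_full <- rss_of(selected)
      p_full <- n_forced + length(selected)
      df <- n - p_full
      pv <- vapply(seq_along(selected), function(k) {
        rss_wo <- rss_of(selected[-k])
        Fv <- (rss_wo - rss_full) / (rss_full / df)
        stats::pf(Fv, 1, df, lower.tail = FALSE)
      }, numeric(1))
      if (max(pv) > pout) {
        selected <- selected[-which.max(pv)]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  co <- numeric(0)
  if (length(selected)) {
    q <- qr(cbind(base, X[, selected, drop = FALSE]))
    co <- qr.coef(q, y)[n_forced + seq_along(selected)]
  }
  list(selected = data.frame(variable = colnames(X)[selected],
                             coefficient = unname(co),
                             stringsAsFactors = FALSE),
       selected_index = selected)
}

# Candidate marker design for a group: additive coding x = code - 1 for
# every marker; dominance coding z = [code == 1] where heterozygotes occur.
marker_design <- function(ctx, g) {
  M <- nrow(ctx$map)
  codes <- do.call(rbind, lapply(g$pops, function(p) {
    gm <- ctx$geno[[p]]
    n <- sum(g$kind == p)
    if (p == "IF2") gm[seq_len(n), , drop = FALSE] else gm[seq_len(n), , drop = FALSE]
  }))
  X <- codes - 1
  colnames(X) <- paste0("add_", seq_len(M))
  marker_of <- seq_len(M)
  kind_of <- rep("additive", M)
  if (any(codes == 1L)) {
    Z <- (codes == 1L) * 1
    colnames(Z) <- paste0("dom_", seq_len(M))
    hz <- colSums(Z) > 0
    X <- cbind(X, Z[, hz, drop = FALSE])
    marker_of <- c(marker_of, which(hz))
    kind_of <- c(kind_of, rep("dominance", sum(hz)))
  }
  list(X = X, marker = marker_of, kind = kind_of)
}

#' Inclusive composite interval-mapping scan
#'
#' Two steps: [stepwise_select()] picks significant marker variables;
#' then the interval-mapping machinery runs on phenotypes adjusted by the
#' selected effects, with the two markers flanking the current scan
#' interval always added back (excluded from the adjustment) so the local
#' signal is not removed.  With nothing selected the scan reduces exactly
#' to [im_scan()].
#'
#' @inheritParams im_scan
#' @param pin,pout stepwise entry/removal thresholds.
#' @return list with \code{profile} (as [im_scan()]) and \code{stepwise}
#'   (selected variables with marker index, kind and coefficient).
#' @export
icim_scan <- function(ctx, pheno, pin = 0.001, pout = 2 * pin, submodels = TRUE) {
  g <- build_group(ctx, pheno)
  md <- marker_design(ctx, g)
  sw <- stepwise_select(g$y, md$X, forced = g$X0, pin = pin, pout = pout)
  sel <- sw$selected
  adjust <- NULL
  if (nrow(sel)) {
    ix <- match(sel$variable, colnames(md$X))
    contrib <- sweep(md$X[, ix, drop = FALSE], 2, sel$coefficient, `*`)
    adjust <- list(contrib = contrib, total = rowSums(contrib),
                   marker = md$marker[ix])
    sel$marker_index <- md$marker[ix]
    sel$marker <- ctx$map$marker[md$marker[ix]]
    sel$kind <- md$kind[ix]
  }
  prof <- scan_profile(ctx, g, adjust = adjust, submodels = submodels)
  list(profile = prof, stepwise = sel, adjust = adjust)
}

#' Permutation threshold for genome-wide LOD significance
#'
#' Phenotypes are permuted within each population (preserving population
#' means); the full genome scan is re-run on each permutation, and the
#' empirical \code{1 - alpha} quantile of the maximum LOD is the
#' threshold.
#'
#' @inheritParams icim_scan
#' @param method "IM" or "ICIM".
#' @param n_perm number of permutations (>= 100 recommended).
#' @param alpha genome-wide type-I error rate.
#' @return the LOD threshold, with the null maxima as attribute
#'   \code{"max_lods"}.
#' @export
permutation_threshold <- function(ctx, pheno, method = c("IM", "ICIM"),
                                  n_perm = 200, alpha = 0.05,
                                  pin = 0.001, pout = 2 * pin) {
  method <- match.arg(method)
  maxl <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- lapply(pheno, sample)
    prof <- if (method == "IM") {
      im_scan(ctx, perm, submodels = FALSE)
    } else {
      icim_scan(ctx, perm, pin = pin, pout = pout, submodels = FALSE)$profile
    }
    maxl[b] <- max(prof$lod)
  }
  thr <- stats::quantile(maxl, 1 - alpha, type = 1, names = FALSE)
  attr(thr, "max_lods") <- maxl
  thr
}

#' Extract QTL records from a scan profile
#'
#' A significant region is a maximal run of consecutive scan positions
#' with LOD >= threshold on one chromosome; each region yields one QTL at
#' its maximum-LOD position (ties broken leftmost).  The one-LOD support
#' interval is the widest interval around the peak where LOD >= peak - 1,
#' clipped at the chromosome ends; nearest flanking markers are recorded.
#'
#' @param profile a scan-profile data frame.
#' @param threshold LOD threshold (> 0).
#' @param map the \code{linkage_map} used for the scan.
#' @return data frame of QTL records (zero rows when nothing exceeds the
#'   threshold).
#' @export
extract_qtl <- function(profile, threshold, map) {
  if (threshold <= 0) stop("threshold must be positive")
  recs <- list()
  for (ch in unique(profile$chrom)) {
    pr <- profile[profile$chrom == ch, ]
    sig <- pr$lod >= threshold
    if (!any(sig)) next
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    mpos <- map$pos[map$chrom == ch]
    mnam <- map$marker[map$chrom == ch]
    for (k in which(r$values)) {
      seg <- starts[k]:ends[k]
      pk <- seg[which.max(pr$lod[seg])]
      peak_lod <- pr$lod[pk]
      # 1-LOD interval: extend from the peak while LOD >= peak - 1
      lo <- pk
      while (lo > 1 && pr$lod[lo - 1] >= peak_lod - 1) lo <- lo - 1
      hi <- pk
      while (hi < nrow(pr) && pr$lod[hi + 1] >= peak_lod - 1) hi <- hi + 1
      pos <- pr$pos[pk]
      iL <- findInterval(pos + 1e-9, mpos)
      iL <- max(1L, min(iL, length(mpos)))
      iR <- if (abs(mpos[iL] - pos) < 1e-9) iL else min(iL + 1L, length(mpos))
      recs[[length(recs) + 1]] <- data.frame(
        chrom = ch, pos = pos,
        left_marker = mnam[iL], right_marker = mnam[iR],
        lod = peak_lod, lod_add = pr$lod_add[pk], lod_dom = pr$lod_dom[pk],
        pve = pr$pve[pk], pve_add = pr$pve_add[pk], pve_dom = pr$pve_dom[pk],
        a = pr$a[pk], d = pr$d[pk],
        ci_low = pr$pos[lo], ci_high = pr$pos[hi],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) {
    return(data.frame(chrom = character(), pos = numeric(),
                      left_marker = character(), right_marker = character(),
                      lod = numeric(), lod_add = numeric(), lod_dom = numeric(),
                      pve = numeric(), pve_add = numeric(), pve_dom = numeric(),
                      a = numeric(), d = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Bayesian classification of QTL genotypes
#'
#' At a detected QTL, each individual's genotype class is the posterior
#' mode of prior (from flanking markers) times the normal likelihood of
#' its phenotype under the fitted class means; ties go to the class with
#' the higher prior.  The per-individual genotypic value is the fitted
#' mean of the assigned class.
#'
#' @param ctx analysis context.
#' @param pheno named list of per-population phenotype vectors.
#' @param qtl one row of an [extract_qtl()] result.
#' @param adjust optional ICIM adjustment (classification then uses the
#'   background-adjusted phenotypes, as in the scan).
#' @return data frame with population, individual index, posterior
#'   probabilities of codes 2/1/0, assigned class and genotypic value.
#' @export
bayes_genotype_classes <- function(ctx, pheno, qtl, adjust = NULL) {
  g <- build_group(ctx, pheno)
  t <- which(ctx$scan$chrom == qtl$chrom &
               abs(ctx$scan$pos - qtl$pos) < 1e-8)[1]
  if (is.na(t)) stop("QTL position is not on the scan grid")
  pri <- group_prior(g, ctx$P, t)
  yt <- g$y
  if (!is.null(adjust)) {
    keep <- adjust$marker %in% ctx$flank[t, ]
    yt <- g$y - adjust$total +
      if (any(keep)) rowSums(adjust$contrib[, keep, drop = FALSE]) else 0
    g$y <- yt
    g$yrep <- rep(yt, 3)
  }
  fit <- fit_mixture(yt, g, pri, incl = c(TRUE, g$d_est))
  post <- fit$post
  cls <- max.col(post, ties.method = "first")
  tie <- abs(post[cbind(seq_len(g$n), cls)] -
               apply(post, 1, max)) < 1e-12 &
    apply(post, 1, function(r) sum(abs(r - max(r)) < 1e-12)) > 1
  if (any(tie)) {
    cls[tie] <- apply(pri[tie, , drop = FALSE], 1, which.max)
  }
  a <- fit$a
  d <- if (g$d_est) fit$d else 0
  gval <- fit$mu + a * XCODE[cls] + ifelse(is.na(d), 0, d) * ZCODE[cls]
  data.frame(population = g$kind, index = unlist(lapply(g$pops, function(p)
               seq_len(sum(g$kind == p)))),
             p2 = post[, 1], p1 = post[, 2], p0 = post[, 3],
             class = c(2L, 1L, 0L)[cls], genotypic_value = gval,
             stringsAsFactors = FALSE)
}

#' Descriptive statistics of phenotypes
#'
#' Moment summaries per population and trait; skewness is
#' \eqn{m_3/m_2^{3/2}} and kurtosis the excess \eqn{m_4/m_2^2 - 3}
#' (both 0, flagged, for constant traits).  Missing values are excluded.
#'
#' @param ps a \code{phenotype_set}, or a named list of per-population
#'   numeric vectors/matrices.
#' @return data frame of summaries.
#' @export
descriptive_stats <- function(ps) {
  pops <- if (inherits(ps, "phenotype_set")) ps$data else ps
  rows <- list()
  for (pop in names(pops)) {
    el <- pops[[pop]]
    if (!is.list(el)) el <- list(trait = el)
    for (tr in names(el)) {
      x <- as.vector(el[[tr]])
      x <- x[!is.na(x)]
      n <- length(x)
      m <- mean(x)
      v <- stats::var(x)
      cm <- function(k) mean((x - m)^k)
      degenerate <- !is.finite(v) || v == 0
      rows[[length(rows) + 1]] <- data.frame(
        population = pop, trait = tr, n = n, mean = m,
        sd = sqrt(v), variance = v, min = min(x), max = max(x),
        skewness = if (degenerate) 0 else cm(3) / cm(2)^1.5,
        kurtosis = if (degenerate) 0 else cm(4) / cm(2)^2 - 3,
        degenerate = degenerate, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
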