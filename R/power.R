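# Repeated simulate -> map cycles: per-QTL detection power within a
# support interval, false positives and FDR, and run-averaged profiles.

#' Match detected QTL to the simulated truth
#'
#' Greedy nearest-first matching on the same chromosome: candidate
#' (detection, true QTL) pairs within the support interval are assigned in
#' order of increasing distance, each detection and each true QTL at most
#' once; unmatched detections are false positives.
#'
#' @param detected data frame of detections with columns \code{chrom},
#'   \code{pos} (an [extract_qtl()] result works).
#' @param truth data frame of true QTL positions (\code{chrom},
#'   \code{pos}).
#' @param si support interval in cM (> 0).
#' @return list with \code{tp} (data frame: detection row, truth row,
#'   distance) and \code{fp} (row indices of false-positive detections).
#' @export
match_detections <- function(detected, truth, si) {
  if (si <= 0) stop("support interval must be positive")
  nd <- nrow(detected)
  nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(tp = data.frame(detection = integer(), truth = integer(),
                                distance = numeric()),
                fp = seq_len(nd)))
  }
  cand <- expand.grid(detection = seq_len(nd), truth = seq_len(nt))
  cand <- cand[detected$chrom[cand$detection] == truth$chrom[cand$truth], ,
               drop = FALSE]
  cand$distance <- abs(detected$pos[cand$detection] - truth$pos[cand$truth])
  cand <- cand[cand$distance <= si, , drop = FALSE]
  cand <- cand[order(cand$distance), , drop = FALSE]
  used_d <- logical(nd)
  used_t <- logical(nt)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    d <- cand$detection[i]
    t <- cand$truth[i]
    if (!used_d[d] && !used_t[t]) {
      used_d[d] <- used_t[t] <- TRUE
      keep[i] <- TRUE
    }
  }
  tp <- cand[keep, , drop = FALSE]
  rownames(tp) <- NULL
  list(tp = tp, fp = which(!used_d))
}

#' Simulation-based QTL detection power study
#'
#' For each run: simulate the populations, map each group with each
#' method, extract QTL at the threshold, and match detections to the true
#' loci within the support interval.  Power of a QTL is the fraction of
#' runs in which it is matched; FDR pools counts over runs
#' (\eqn{\sum FP / (\sum TP + \sum FP)}).  Profiles are averaged per scan
#' position across runs.
#'
#' @param map \code{linkage_map}.
#' @param model \code{qtl_model} (truth).
#' @param n_pil,n_ib1,n_ib2,n_if2 population sizes per run.
#' @param pil_type "DH" or "RIL".
#' @param fun mapping function name.
#' @param if2_sampling "random" or "balanced".
#' @param methods subset of c("IM", "ICIM").
#' @param step scan step (cM).
#' @param threshold fixed LOD threshold (or \code{n_perm > 0} for per-run
#'   permutation thresholds).
#' @param n_perm,alpha permutation-threshold settings (0 = fixed).
#' @param si support interval in cM.
#' @param n_runs number of simulation runs.
#' @param seed random seed driving the whole study.
#' @param pin,pout ICIM stepwise thresholds.
#' @param keep_populations keep each run's simulated populations in the
#'   result (for writing QHP-format files).
#' @return a \code{power_study} list: per group x method a
#'   \code{power_table}, per-run detections, averaged profiles, stepwise
#'   selections, and the error variance used.
#' @export
run_power_study <- function(map, model, n_pil, n_ib1 = 0, n_ib2 = 0,
                            n_if2 = 0, pil_type = "DH", fun = "kosambi",
                            if2_sampling = "balanced",
                            methods = c("IM", "ICIM"), step = 1,
                            threshold = 3, n_perm = 0, alpha = 0.05,
                            si = 10, n_runs = 10, seed = 1,
                            pin = 0.001, pout = 2 * pin,
                            keep_populations = FALSE) {
  set.seed(seed)
  check_model_on_map(model, map)
  ve <- if (!is.null(model$ve)) model$ve else error_variance_from_h2(model, map, fun)
  ve <- as.numeric(ve)
  present <- c("PIL", if (n_ib1 > 0) "IB1", if (n_ib2 > 0) "IB2",
               if (n_if2 > 0) "IF2")
  tags <- tolower(present)
  cg <- combined_group_for(present)
  if (!is.null(cg)) tags <- c(tags, tolower(cg))
  truth <- model$loci[, c("chrom", "pos")]
  nq <- nrow(truth)

  acc <- list()
  for (tag in tags) for (m in methods) {
    acc[[paste(tag, m)]] <- list(tp_runs = matrix(FALSE, n_runs, nq),
                                 lod = matrix(NA_real_, n_runs, nq),
                                 a = matrix(NA_real_, n_runs, nq),
                                 d = matrix(NA_real_, n_runs, nq),
                                 fp = integer(n_runs),
                                 interval_hits = NULL,
                                 prof_sum = NULL, detections = list(),
                                 stepwise = list())
  }
  populations <- if (keep_populations) vector("list", n_runs) else NULL

  for (run in seq_len(n_runs)) {
    sim <- simulate_populations(map, model, n_pil, n_ib1, n_ib2, n_if2,
                                pil_type, fun, if2_sampling, reps = 1,
                                ve = ve)
    if (keep_populations) populations[[run]] <- sim
    ctx <- build_qtl_context(map, sim$populations$PIL$geno, sim$design,
                             pil_type, fun, step = step)
    pheno <- lapply(sim$populations[present], function(p) rowMeans(p$y))
    groups <- stats::setNames(as.list(present), tolower(present))
    if (!is.null(cg)) groups[[tolower(cg)]] <- present
    for (tag in names(groups)) {
      ph <- pheno[groups[[tag]]]
      for (m in methods) {
        key <- paste(tag, m)
        if (m == "IM") {
          prof <- im_scan(ctx, ph)
          sw <- NULL
        } else {
          ic <- icim_scan(ctx, ph, pin = pin, pout = pout)
          prof <- ic$profile
          sw <- ic$stepwise
        }
        thr <- if (n_perm > 0) {
          as.numeric(permutation_threshold(ctx, ph, m, n_perm, alpha,
                                           pin = pin, pout = pout))
        } else threshold
        det <- extract_qtl(prof, thr, ctx$map)
        mm <- match_detections(det, truth, si)
        a <- acc[[key]]
        if (nrow(mm$tp)) {
          a$tp_runs[run, mm$tp$truth] <- TRUE
          a$lod[run, mm$tp$truth] <- det$lod[mm$tp$detection]
          a$a[run, mm$tp$truth] <- det$a[mm$tp$detection]
          a$d[run, mm$tp$truth] <- det$d[mm$tp$detection]
        }
        a$fp[run] <- length(mm$fp)
        if (is.null(a$prof_sum)) {
          a$prof_sum <- prof
          a$prof_sum[, -(1:2)] <- 0
        }
        num <- as.matrix(prof[, -(1:2)])
        num[is.na(num)] <- 0
        a$prof_sum[, -(1:2)] <- a$prof_sum[, -(1:2)] + num
        if (nrow(det)) {
          det$run <- run
          det$true_positive <- seq_len(nrow(det)) %in% mm$tp$detection
          a$detections[[run]] <- det
          # marker interval containing each detection
          det_iv <- integer(nrow(det))
          for (i in seq_len(nrow(det))) {
            gi <- which(ctx$map$chrom == det$chrom[i])
            k <- findInterval(det$pos[i] + 1e-9, ctx$map$pos[gi])
            det_iv[i] <- gi[min(max(k, 1L), length(gi) - 1L)]
          }
          if (is.null(a$interval_hits)) {
            a$interval_hits <- integer(nrow(ctx$map))
          }
          for (iv in det_iv) a$interval_hits[iv] <- a$interval_hits[iv] + 1L
        }
        if (!is.null(sw)) a$stepwise[[run]] <- sw
        acc[[key]] <- a
      }
    }
  }

  tables <- list()
  for (key in names(acc)) {
    a <- acc[[key]]
    per_qtl <- data.frame(
      chrom = truth$chrom, pos = truth$pos,
      power = colMeans(a$tp_runs),
      mean_lod = colMeans(a$lod, na.rm = TRUE),
      mean_a = colMeans(a$a, na.rm = TRUE),
      mean_d = colMeans(a$d, na.rm = TRUE))
    tp_total <- sum(a$tp_runs)
    fp_total <- sum(a$fp)
    iv <- a$interval_hits
    per_interval <- if (!is.null(iv)) {
      keep <- which(iv > 0)
      data.frame(left_marker_index = keep, frequency = iv[keep] / n_runs)
    } else data.frame(left_marker_index = integer(), frequency = numeric())
    prof_mean <- a$prof_sum
    prof_mean[, -(1:2)] <- prof_mean[, -(1:2)] / n_runs
    tables[[key]] <- structure(
      list(per_qtl = per_qtl, per_interval = per_interval,
           fp_per_run = mean(a$fp),
           fdr = if (tp_total + fp_total > 0) fp_total / (tp_total + fp_total) else 0,
           n_runs = n_runs, si = si,
           mean_profile = prof_mean,
           detections = do.call(rbind, a$detections),
           stepwise = a$stepwise),
      class = "power_table")
  }
  structure(list(tables = tables, ve = ve, truth = truth, seed = seed,
                 methods = methods, tags = tags,
                 populations = populations,
                 params = list(n_pil = n_pil, n_ib1 = n_ib1, n_ib2 = n_ib2,
                               n_if2 = n_if2, pil_type = pil_type, fun = fun,
                               step = step, threshold = threshold,
                               n_perm = n_perm, alpha = alpha, si = si)),
            class = "power_study")
}

#' @export
print.power_table <- function(x, ...) {
  cat(sprintf("Power table (%d runs, SI = %g cM): FDR %.3f, %.2f FP/run\n",
              x$n_runs, x$si, x$fdr, x$fp_per_run))
  print(x$per_qtl, row.names = FALSE)
  invisible(x)
}
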