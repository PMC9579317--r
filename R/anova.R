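# Phenotypic variance analysis: per-population one-way ANOVA with
# replications, broad-sense heritability on an entry-mean basis, estimated
# genotypic values, and the combined across-population decomposition into
# additive and dominance variance on the F2 reference scale.

MISSING_PHENO_TOKENS <- c("NA", "na", "*", ".", "-100")

decode_pheno_token <- function(tok, file = "", what = "phenotypic value") {
  out <- suppressWarnings(as.numeric(tok))
  out[tok %in% MISSING_PHENO_TOKENS] <- NA_real_
  bad <- is.na(out) & !tok %in% MISSING_PHENO_TOKENS
  if (any(bad)) {
    stop(sprintf("%s'%s' is not a valid %s (missing values are NA, na, *, . or -100)",
                 if (nzchar(file)) paste0(file, ": ") else "", tok[bad][1], what),
         call. = FALSE)
  }
  out
}

#' Phenotype sets
#'
#' Container for replicated phenotypes of up to four populations.  Missing
#' values are coded NA (decoded from the tokens NA, na, *, . or -100 on
#' input).
#'
#' @param data named list (names among PIL, IB1, IB2, IF2); each element a
#'   list of entries x reps matrices, one per trait.
#' @param traits trait names.
#' @param if2_pairs optional IF2 parent-pair matrix carried along for QTL
#'   analysis.
#' @return a \code{phenotype_set}.
#' @export
phenotype_set <- function(data, traits, if2_pairs = NULL) {
  data <- data[!vapply(data, is.null, logical(1))]
  if (!length(data)) stop("no population has phenotypic data")
  if (!all(names(data) %in% c("PIL", "IB1", "IB2", "IF2"))) {
    stop("population names must be among PIL, IB1, IB2, IF2")
  }
  sizes <- vapply(data, function(p) nrow(p[[1]]), integer(1))
  if ("PIL" %in% names(data)) {
    for (bc in intersect(c("IB1", "IB2"), names(data))) {
      if (sizes[[bc]] != sizes[["PIL"]]) {
        stop(bc, " must have the same size as PIL (", sizes[["PIL"]],
             "), got ", sizes[[bc]])
      }
    }
  }
  structure(list(data = data, traits = traits, sizes = sizes,
                 if2_pairs = if2_pairs),
            class = "phenotype_set")
}

#' Read a phenotype (VHP) input file
#'
#' Five parts, '#' comments ignored:
#' \enumerate{
#'   \item general information: sizes of PIL, IB1, IB2, IF2 (0 for an
#'     absent population), number of replications, number of traits
#'     followed by the trait names;
#'   \item to 5. phenotypes of PIL, IB1, IB2, IF2: one row per entry with
#'     \code{reps} values for trait 1, then trait 2, etc.  Absent
#'     populations contribute nothing.
#' }
#'
#' @param file path to the input file.
#' @return a \code{phenotype_set}.
#' @export
read_vhp <- function(file) {
  tk <- token_reader(file)
  sizes <- tk$take_int(4, "population sizes (PIL, IB1, IB2, IF2)")
  reps <- tk$take_int(what = "number of replications")
  ntraits <- tk$take_int(what = "number of traits")
  traits <- tk$take(ntraits, "trait names")
  names(sizes) <- c("PIL", "IB1", "IB2", "IF2")
  if (sizes[["IB1"]] > 0 && sizes[["IB1"]] != sizes[["PIL"]]) {
    stop("IB1 must have the same size as PIL, got ", sizes[["IB1"]],
         " vs ", sizes[["PIL"]])
  }
  if (sizes[["IB2"]] > 0 && sizes[["IB2"]] != sizes[["PIL"]]) {
    stop("IB2 must have the same size as PIL, got ", sizes[["IB2"]],
         " vs ", sizes[["PIL"]])
  }
  data <- list()
  for (pop in names(sizes)) {
    n <- sizes[[pop]]
    if (n == 0) next
    vals <- decode_pheno_token(tk$take(n * ntraits * reps,
                                       paste0(pop, " phenotypes")), file)
    # row-major per entry: trait-major blocks of reps
    arr <- aperm(array(vals, dim = c(reps, ntraits, n)), c(3, 1, 2))
    data[[pop]] <- lapply(seq_len(ntraits), function(t) arr[, , t, drop = TRUE])
    data[[pop]] <- lapply(data[[pop]], function(m) matrix(m, nrow = n))
    names(data[[pop]]) <- traits
  }
  phenotype_set(data, traits)
}

#' One-way ANOVA with variance components and heritability
#'
#' Entries are the random genetic factor; replications within entries
#' estimate the error.  With mean replication number \eqn{\bar r} (the
#' harmonic mean over entries when replications are missing),
#' \eqn{V_{error} = MS_e}, \eqn{V_{geno} = \max(0, (MS_g - MS_e)/\bar r)},
#' \eqn{V_{pheno} = V_{geno} + V_{error}/\bar r} (entry-mean basis) and
#' \eqn{H^2 = V_{geno}/V_{pheno}}.  A plot-basis heritability
#' \eqn{V_{geno}/(V_{geno} + V_{error})} is also reported.
#'
#' @param values entries x reps numeric matrix (NA allowed).
#' @return list with \code{table} (Source/DF/SS/MS/F/p data frame),
#'   the components \code{Vgeno, Verror, Vpheno, Hbroad, Hplot, DFerror},
#'   the raw (untruncated) \code{Vgeno_raw}, \code{rbar}, and \code{egv}
#'   (entry means).
#' @export
oneway_anova <- function(values) {
  values <- as.matrix(values)
  n_i <- rowSums(!is.na(values))
  keep <- n_i > 0
  v <- values[keep, , drop = FALSE]
  n_i <- n_i[keep]
  k <- nrow(v)
  if (k < 2) stop("need at least 2 entries with data")
  m_i <- rowMeans(v, na.rm = TRUE)
  N <- sum(n_i)
  grand <- sum(v, na.rm = TRUE) / N
  ss_g <- sum(n_i * (m_i - grand)^2)
  df_g <- k - 1
  ss_e <- sum((v - m_i)^2, na.rm = TRUE)
  df_e <- N - k
  ms_g <- ss_g / df_g
  single_rep <- df_e == 0
  ms_e <- if (single_rep) NA_real_ else ss_e / df_e
  Fval <- ms_g / ms_e
  pval <- stats::pf(Fval, df_g, df_e, lower.tail = FALSE)
  rbar <- k / sum(1 / n_i)  # harmonic mean replication number
  vg_raw <- (ms_g - ms_e) / rbar
  vg <- max(0, vg_raw)
  vp <- vg + ms_e / rbar
  tab <- data.frame(
    Source = c("Genotype", "Error", "Total"),
    DF = c(df_g, df_e, df_g + df_e),
    SS = c(ss_g, ss_e, ss_g + ss_e),
    MS = c(ms_g, ms_e, NA),
    F = c(Fval, NA, NA),
    p = c(pval, NA, NA)
  )
  egv <- rowMeans(values, na.rm = TRUE)
  egv[!is.finite(egv)] <- NA_real_
  list(table = tab,
       Vgeno = if (single_rep) NA_real_ else vg,
       Vgeno_raw = vg_raw,
       Verror = ms_e,
       Vpheno = if (single_rep) NA_real_ else vp,
       Hbroad = if (single_rep) NA_real_ else if (vp > 0) vg / vp else 0,
       Hplot = if (single_rep) NA_real_ else if (vg + ms_e > 0) vg / (vg + ms_e) else 0,
       DFerror = df_e, rbar = rbar, egv = egv)
}

#' Estimated genotypic values
#'
#' Arithmetic mean over non-missing replications per entry; entries with
#' all replications missing stay NA.
#'
#' @param values entries x reps numeric matrix.
#' @return numeric vector of entry means.
#' @export
estimated_genotypic_values <- function(values) {
  egv <- rowMeans(as.matrix(values), na.rm = TRUE)
  egv[!is.finite(egv)] <- NA_real_
  egv
}

#' Combined across-population variance decomposition
#'
#' Under single-locus theory with linkage equilibrium and no epistasis the
#' genotypic variances of the populations have expectations
#' \deqn{E[V_g(PIL)] = 2 V_A, \quad E[V_g(IF2)] = V_A + V_D, \quad
#'       E[V_g(IB1) + V_g(IB2)] = V_A + 2 V_D,}
#' where \eqn{V_A, V_D} are the additive and dominance variances of the F2
#' reference population (the IB1 + IB2 sum cancels the \eqn{\sum a_i d_i}
#' cross term, so the two backcross populations enter only as a sum).  The
#' available equations are solved for \eqn{(V_A, V_D)} by non-negative
#' least squares.  When the system is rank deficient (e.g. only IB1 and
#' IB2 present) the identified composite is reported instead of separate
#' components.
#'
#' @param results named list of [oneway_anova()] results (names among PIL,
#'   IB1, IB2, IF2).
#' @return list with \code{Vadd_F2}, \code{Vdom_F2} (NA when not
#'   identified), \code{Verror_F2} (DF-weighted pooled error),
#'   \code{Hnarrow_F2}, \code{DFerror}, and when rank deficient a
#'   \code{composite} description.
#' @export
combined_anova <- function(results) {
  pops <- names(results)
  if (length(pops) < 2) stop("combined analysis needs at least 2 populations")
  rows <- list()
  if ("PIL" %in% pops) rows$PIL <- list(coef = c(2, 0), value = results$PIL$Vgeno)
  if ("IF2" %in% pops) rows$IF2 <- list(coef = c(1, 1), value = results$IF2$Vgeno)
  if (all(c("IB1", "IB2") %in% pops)) {
    rows$IBC <- list(coef = c(1, 2),
                     value = results$IB1$Vgeno + results$IB2$Vgeno)
  }
  rows <- Filter(function(r) is.finite(r$value), rows)
  dfs <- vapply(results, `[[`, numeric(1), "DFerror")
  ves <- vapply(results, `[[`, numeric(1), "Verror")
  ok <- is.finite(ves) & dfs > 0
  verr <- sum(dfs[ok] * ves[ok]) / sum(dfs[ok])
  dferr <- sum(dfs[ok])

  va <- vd <- NA_real_
  composite <- NULL
  if (length(rows)) {
    A <- do.call(rbind, lapply(rows, `[[`, "coef"))
    b <- vapply(rows, `[[`, numeric(1), "value")
    if (qr(A)$rank >= 2) {
      est <- nnls2(A, b)
      va <- est[1]
      vd <- est[2]
    } else {
      # single independent equation: report what it identifies
      cf <- unname(A[1, ])
      if (cf[2] == 0) {
        va <- unname(b[1]) / cf[1]
      } else {
        composite <- list(coef = cf, value = unname(b[1]),
                          label = sprintf("%g*Vadd + %g*Vdom", cf[1], cf[2]))
      }
    }
  }
  hn <- if (is.finite(va) && is.finite(vd) && is.finite(verr)) {
    va / (va + vd + verr)
  } else NA_real_
  list(Vadd_F2 = va, Vdom_F2 = vd, Verror_F2 = verr,
       Hnarrow_F2 = hn, DFerror = dferr, composite = composite)
}

# Non-negative least squares for the 2-parameter moment system: ordinary
# LS, then re-solve on the boundary if a component goes negative.
nnls2 <- function(A, b) {
  est <- as.vector(qr.solve(A, b))
  if (est[1] < 0 || est[2] < 0) {
    # candidate boundary solutions
    cand <- list(
      c(max(0, sum(A[, 1] * b) / sum(A[, 1]^2)), 0),
      c(0, max(0, sum(A[, 2] * b) / sum(A[, 2]^2)))
    )
    rss <- vapply(cand, function(x) sum((b - A %*% x)^2), numeric(1))
    est <- cand[[which.min(rss)]]
  }
  est
}

#' Run the phenotypic-variance analysis
#'
#' Per population and trait: one-way ANOVA, variance components,
#' broad-sense heritability and estimated genotypic values.  With more
#' than one population, the combined decomposition into additive and
#' dominance variance (F2 reference) and the narrow-sense heritability.
#' When \code{out_prefix} is given, writes the components file
#' (\code{.adh}), the genotypic values (\code{.egv}) and the ANOVA tables
#' (\code{.tab}).
#'
#' @param x a \code{phenotype_set} or path to a VHP input file.
#' @param out_prefix optional output path prefix.
#' @return list with \code{anova} (per population, per trait),
#'   \code{combined} (per trait, or NULL), and the input set.
#' @export
run_vhp <- function(x, out_prefix = NULL) {
  ps <- if (is.character(x)) read_vhp(x) else x
  res <- lapply(ps$data, function(pop) lapply(pop, oneway_anova))
  combined <- NULL
  if (length(ps$data) > 1) {
    combined <- lapply(ps$traits, function(tr) {
      combined_anova(lapply(res, `[[`, tr))
    })
    names(combined) <- ps$traits
  }
  out <- list(anova = res, combined = combined, phenotypes = ps)
  if (!is.null(out_prefix)) write_vhp_outputs(out, out_prefix)
  out
}

write_vhp_outputs <- function(out, prefix) {
  res <- out$anova
  ps <- out$phenotypes
  # .adh: components + heritabilities, two parts
  adh <- output_name(prefix, "common", "adh")
  part1 <- do.call(rbind, lapply(names(res), function(pop) {
    do.call(rbind, lapply(names(res[[pop]]), function(tr) {
      r <- res[[pop]][[tr]]
      data.frame(Population = pop, Trait = tr, Vgeno = r$Vgeno,
                 Verror = r$Verror, Vpheno = r$Vpheno, Hbroad = r$Hbroad,
                 Hplot = r$Hplot, DFerror = r$DFerror)
    }))
  }))
  write_lines("# Variance components and broad-sense heritability (entry-mean basis)", adh)
  write_tsv(part1, adh, append = TRUE, col.names = TRUE)
  if (!is.null(out$combined)) {
    write_lines(c("",
      "# Combined decomposition, F2 reference scale",
      "# assumptions: linkage equilibrium, no epistasis"), adh, append = TRUE)
    part2 <- do.call(rbind, lapply(names(out$combined), function(tr) {
      cb <- out$combined[[tr]]
      data.frame(Trait = tr, Vadd_F2 = cb$Vadd_F2, Vdom_F2 = cb$Vdom_F2,
                 Verror_F2 = cb$Verror_F2, Hnarrow_F2 = cb$Hnarrow_F2,
                 DFerror = cb$DFerror,
                 Composite = if (is.null(cb$composite)) "" else
                   sprintf("%s = %g", cb$composite$label, cb$composite$value))
    }))
    write_tsv(part2, adh, append = TRUE, col.names = TRUE)
  }
  # .egv: per-entry estimated genotypic values
  egv <- output_name(prefix, "common", "egv")
  first <- TRUE
  for (pop in names(res)) {
    df <- data.frame(Population = pop, Entry = seq_along(res[[pop]][[1]]$egv))
    for (tr in names(res[[pop]])) df[[tr]] <- res[[pop]][[tr]]$egv
    write_tsv(df, egv, append = !first, col.names = first)
    first <- FALSE
  }
  # .tab: one ANOVA table per trait per population
  tab <- output_name(prefix, "common", "tab")
  if (file.exists(tab)) file.remove(tab)
  for (pop in names(res)) {
    for (tr in names(res[[pop]])) {
      write_lines(sprintf("# ANOVA: population %s, trait %s", pop, tr),
                  tab, append = TRUE)
      write_tsv(res[[pop]][[tr]]$table, tab, append = TRUE, col.names = TRUE)
      write_lines("", tab, append = TRUE)
    }
  }
  invisible(prefix)
}
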