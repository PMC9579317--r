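# The QTL-mapping pipeline: input dialect, orchestration of independent
# and combined analyses, and the tab-separated output families.

#' Read a QTL-mapping (QHP) input file
#'
#' Eight parts, '#' comments ignored:
#' \enumerate{
#'   \item general information (11 parameters): pure-line type (1 = DH,
#'     2 = RIL); number of genotyped pure lines (gPIL); number of
#'     chromosomes; mapping function (1 = Kosambi, 2 = Haldane,
#'     3 = Morgan); marker space type (1 = positions, 2 = intervals);
#'     marker space unit (1 = cM, 2 = Morgan); phenotyping sizes of PIL,
#'     IB1, IB2, IF2 (0 = absent); number of traits followed by the trait
#'     names;
#'   \item marker numbers: \code{name count} per chromosome;
#'   \item linkage map: \code{marker value} per marker;
#'   \item marker types of PIL: gPIL rows of genotype tokens (one per
#'     marker, see [parse_genotype_token()]);
#'   \item to 7. phenotypes of PIL, IB1 and IB2: one row of trait values
#'     per entry, aligned with the first rows of the genotype matrix;
#'   \item phenotypes of IF2: per hybrid, the two parental line indices
#'     followed by the trait values.
#' }
#' Sizes of PIL, IB1 and IB2 must be equal when present, and gPIL must be
#' at least the PIL phenotyping size.
#'
#' @param file path to the input file.
#' @return a \code{qhp_input} list: map, genotypes, phenotypes, design and
#'   configuration.
#' @export
read_qhp <- function(file) {
  tk <- token_reader(file)
  pil_code <- tk$take_int(what = "pure-line type code")
  if (!pil_code %in% 1:2) stop("pure-line type must be 1 (DH) or 2 (RIL)")
  pil_type <- c("DH", "RIL")[pil_code]
  g_pil <- tk$take_int(what = "number of genotyped pure lines")
  n_chrom <- tk$take_int(what = "number of chromosomes")
  fun <- map_function_from_code(tk$take_int(what = "mapping function code"))
  space_type <- tk$take_int(what = "marker space type")
  space_unit <- tk$take_int(what = "marker space unit")
  sizes <- tk$take_int(4, "phenotyping sizes (PIL, IB1, IB2, IF2)")
  names(sizes) <- c("PIL", "IB1", "IB2", "IF2")
  ntraits <- tk$take_int(what = "number of traits")
  traits <- tk$take(ntraits, "trait names")
  present <- names(sizes)[sizes > 0]
  for (bc in intersect(c("IB1", "IB2"), present)) {
    if (sizes[[bc]] != sizes[["PIL"]]) {
      stop("sizes of PIL, IB1 and IB2 must be equal when present (",
           bc, " = ", sizes[[bc]], ", PIL = ", sizes[["PIL"]], ")")
    }
  }
  if (sizes[["PIL"]] > g_pil) {
    stop("PIL phenotyping size (", sizes[["PIL"]],
         ") exceeds the number of genotyped lines (", g_pil, ")")
  }
  if (sizes[["IB1"]] > g_pil || sizes[["IB2"]] > g_pil) {
    stop("backcross population size exceeds the number of genotyped lines")
  }
  chrom_names <- character(n_chrom)
  n_mark <- integer(n_chrom)
  for (i in seq_len(n_chrom)) {
    chrom_names[i] <- tk$take(what = "chromosome name")
    n_mark[i] <- tk$take_int(what = paste0("marker count of ", chrom_names[i]))
  }
  chrom <- marker <- character(0)
  pos <- numeric(0)
  for (i in seq_len(n_chrom)) {
    nm <- character(n_mark[i])
    pv <- numeric(n_mark[i])
    for (j in seq_len(n_mark[i])) {
      nm[j] <- tk$take(what = "marker name")
      pv[j] <- tk$take_num(what = "marker position")
    }
    if (space_unit == 2) pv <- pv * 100
    if (space_type == 2) pv <- cumsum(pv)
    chrom <- c(chrom, rep(chrom_names[i], n_mark[i]))
    marker <- c(marker, nm)
    pos <- c(pos, pv)
  }
  map <- linkage_map(chrom, marker, pos)
  M <- nrow(map)
  toks <- tk$take(g_pil * M, "PIL marker genotypes")
  geno <- matrix(parse_genotype_token(toks, context = "PIL genotype block"),
                 nrow = g_pil, ncol = M, byrow = TRUE)
  colnames(geno) <- map$marker
  pheno <- list()
  for (pop in c("PIL", "IB1", "IB2")) {
    n <- sizes[[pop]]
    if (n == 0) next
    vals <- decode_pheno_token(tk$take(n * ntraits, paste0(pop, " phenotypes")), file)
    pheno[[pop]] <- matrix(vals, nrow = n, ncol = ntraits, byrow = TRUE,
                           dimnames = list(NULL, traits))
  }
  if2_pairs <- NULL
  if (sizes[["IF2"]] > 0) {
    n <- sizes[["IF2"]]
    raw <- tk$take(n * (2 + ntraits), "IF2 parent indices and phenotypes")
    block <- matrix(raw, nrow = n, byrow = TRUE)
    if2_pairs <- matrix(as.integer(block[, 1:2]), ncol = 2)
    if (anyNA(if2_pairs) || any(if2_pairs < 1 | if2_pairs > g_pil)) {
      stop("IF2 parental line index out of range 1..", g_pil)
    }
    vals <- decode_pheno_token(as.vector(t(block[, -(1:2), drop = FALSE])), file)
    pheno$IF2 <- matrix(vals, nrow = n, ncol = ntraits, byrow = TRUE,
                        dimnames = list(NULL, traits))
  }
  structure(list(map = map, fun = fun, pil_type = pil_type, g_pil = g_pil,
                 geno = geno, pheno = pheno, if2_pairs = if2_pairs,
                 traits = traits, sizes = sizes),
            class = "qhp_input")
}

#' Run the full QTL-mapping pipeline
#'
#' Each population with phenotypes is analyzed independently; in addition,
#' exactly one combined analysis is run when the set of present
#' populations matches one of the five designs (IBC = IB1+IB2,
#' IFL = IF2+PIL, IBL = IB1+IB2+PIL, IBF = IB1+IB2+IF2,
#' BFL = all four).  Missing phenotypes are replaced by the population
#' mean before any analysis.  When \code{out_prefix} is given, the full
#' tab-separated output set is written (see [output_name()] for the
#' naming scheme).
#'
#' @param x a \code{qhp_input} or path to a QHP input file.
#' @param methods subset of c("IM", "ICIM").
#' @param step scan step in cM.
#' @param pin,pout stepwise entry/removal thresholds for ICIM.
#' @param threshold fixed LOD threshold used when \code{n_perm = 0}.
#' @param n_perm number of permutations for the empirical threshold
#'   (0 = use the fixed threshold).
#' @param alpha genome-wide type-I error for the permutation threshold.
#' @param out_prefix optional output path prefix.
#' @return a \code{qhp_result} list: the analysis context, per-group
#'   per-trait per-method profiles, QTL records, thresholds, stepwise
#'   selections and genotype classifications, plus the common summaries.
#' @export
run_qhp <- function(x, methods = c("IM", "ICIM"), step = 1,
                    pin = 0.001, pout = 2 * pin, threshold = 3,
                    n_perm = 0, alpha = 0.05, out_prefix = NULL) {
  inp <- if (is.character(x)) read_qhp(x) else x
  methods <- match.arg(methods, c("IM", "ICIM"), several.ok = TRUE)
  present <- names(inp$pheno)
  if (!length(present)) stop("no population has phenotypic data")
  design <- cross_design(inp$g_pil, inp$if2_pairs)
  ctx <- build_qtl_context(inp$map, inp$geno, design, inp$pil_type, inp$fun,
                           step = step)
  # population-mean replacement of missing phenotypes
  pheno <- lapply(inp$pheno, function(m) {
    apply(m, 2, function(v) {
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      v
    })
  })
  groups <- as.list(stats::setNames(as.list(present), tolower(present)))
  cg <- combined_group_for(present)
  if (!is.null(cg)) groups[[tolower(cg)]] <- present

  res <- list()
  for (tag in names(groups)) {
    members <- groups[[tag]]
    res[[tag]] <- list()
    for (tr in inp$traits) {
      ph <- lapply(stats::setNames(members, members), function(p) pheno[[p]][, tr])
      out_tr <- list()
      for (method in methods) {
        if (method == "IM") {
          prof <- im_scan(ctx, ph)
          sw <- NULL
          adj <- NULL
        } else {
          ic <- icim_scan(ctx, ph, pin = pin, pout = pout)
          prof <- ic$profile
          sw <- ic$stepwise
          adj <- ic$adjust
        }
        if (n_perm > 0) {
          thr <- permutation_threshold(ctx, ph, method, n_perm, alpha,
                                       pin = pin, pout = pout)
          thr_src <- sprintf("permutation (n=%d, alpha=%g)", n_perm, alpha)
        } else {
          thr <- threshold
          thr_src <- "fixed"
        }
        qtl <- extract_qtl(prof, as.numeric(thr), ctx$map)
        gtp <- NULL
        if (method == "ICIM" && nrow(qtl)) {
          gtp <- lapply(seq_len(nrow(qtl)), function(i) {
            bayes_genotype_classes(ctx, ph, qtl[i, ], adjust = adj)
          })
        }
        out_tr[[method]] <- list(profile = prof, qtl = qtl,
                                 threshold = as.numeric(thr),
                                 threshold_source = thr_src,
                                 max_lods = attr(thr, "max_lods"),
                                 stepwise = sw, gtp = gtp)
      }
      res[[tag]][[tr]] <- out_tr
    }
  }
  out <- structure(list(context = ctx, groups = res, input = inp,
                        marker_summary = marker_summary(ctx$pil_geno, ctx$map),
                        correlations = marker_correlation(ctx$pil_imp),
                        stats = descriptive_stats(lapply(inp$pheno, function(m)
                          as.list(as.data.frame(m)))),
                        params = list(methods = methods, step = step, pin = pin,
                                      pout = pout, threshold = threshold,
                                      n_perm = n_perm, alpha = alpha)),
                   class = "qhp_result")
  if (!is.null(out_prefix)) write_qhp_outputs(out, out_prefix)
  out
}

#' @export
print.qhp_result <- function(x, ...) {
  cat("QTL mapping result\n")
  cat("  groups:", paste(names(x$groups), collapse = ", "), "\n")
  for (tag in names(x$groups)) {
    for (tr in names(x$groups[[tag]])) {
      for (m in names(x$groups[[tag]][[tr]])) {
        r <- x$groups[[tag]][[tr]][[m]]
        cat(sprintf("  %s / %s / %s: %d QTL (threshold %.2f)\n",
                    tag, tr, m, nrow(r$qtl), r$threshold))
      }
    }
  }
  invisible(x)
}

# ---- output writers -------------------------------------------------------

profile_header <- c("Chromosome", "Position_cM", "LOD", "LOD_Add", "LOD_Dom",
                    "PVE_pct", "PVE_Add_pct", "PVE_Dom_pct",
                    "Additive_effect", "Dominant_effect")

format_profile <- function(prof) {
  stats::setNames(prof[, c("chrom", "pos", "lod", "lod_add", "lod_dom",
                           "pve", "pve_add", "pve_dom", "a", "d")],
                  profile_header)
}

format_qtl <- function(qtl) {
  stats::setNames(qtl[, c("chrom", "pos", "left_marker", "right_marker",
                          "lod", "lod_add", "lod_dom", "pve", "pve_add",
                          "pve_dom", "a", "d", "ci_low", "ci_high")],
                  c("Chromosome", "Position_cM", "LeftMarker", "RightMarker",
                    "LOD", "LOD_Add", "LOD_Dom", "PVE_pct", "PVE_Add_pct",
                    "PVE_Dom_pct", "Additive_effect", "Dominant_effect",
                    "CI_low_cM", "CI_high_cM"))
}

write_qhp_outputs <- function(res, prefix) {
  ctx <- res$context
  inp <- res$input
  ext_of <- c(IM = "im", ICIM = "ic")
  thr_rows <- list()
  for (tag in names(res$groups)) {
    for (method in res$params$methods) {
      qf <- output_name(prefix, tag, paste0("q", ext_of[method]))
      rf <- output_name(prefix, tag, paste0("r", ext_of[method]))
      for (f in c(qf, rf)) if (file.exists(f)) file.remove(f)
      for (tr in names(res$groups[[tag]])) {
        r <- res$groups[[tag]][[tr]][[method]]
        write_lines(sprintf("# trait %s", tr), rf, append = TRUE)
        write_tsv(format_profile(r$profile), rf, append = TRUE, col.names = TRUE)
        write_lines(sprintf("# trait %s", tr), qf, append = TRUE)
        write_tsv(format_qtl(r$qtl), qf, append = TRUE, col.names = TRUE)
        thr_rows[[length(thr_rows) + 1]] <- data.frame(
          Group = tag, Method = method, Trait = tr, Threshold = r$threshold,
          Source = r$threshold_source)
        if (!is.null(r$max_lods)) {
          tf <- output_name(prefix, tag, paste0("t", ext_of[method]))
          write_lines(sprintf("# trait %s: genome-wide max LOD per permutation", tr), tf)
          write_tsv(data.frame(Permutation = seq_along(r$max_lods),
                               MaxLOD = r$max_lods), tf, append = TRUE,
                    col.names = TRUE)
        }
      }
    }
    # ICIM extras: stepwise and genotype classification
    if ("ICIM" %in% res$params$methods) {
      sf <- output_name(prefix, tag, "stp")
      gf <- output_name(prefix, tag, "gtp")
      for (f in c(sf, gf)) if (file.exists(f)) file.remove(f)
      for (tr in names(res$groups[[tag]])) {
        r <- res$groups[[tag]][[tr]][["ICIM"]]
        write_lines(sprintf("# trait %s: selected marker variables", tr),
                    sf, append = TRUE)
        sel <- r$stepwise
        if (is.null(sel) || !nrow(sel)) {
          write_lines("# (none selected)", sf, append = TRUE)
        } else {
          write_tsv(data.frame(Marker = sel$marker, Kind = sel$kind,
                               Coefficient = sel$coefficient),
                    sf, append = TRUE, col.names = TRUE)
        }
        write_lines(sprintf("# trait %s: QTL genotype classification", tr),
                    gf, append = TRUE)
        if (is.null(r$gtp)) {
          write_lines("# (no QTL detected)", gf, append = TRUE)
        } else {
          for (i in seq_along(r$gtp)) {
            write_lines(sprintf("# QTL %d at %s %.1f cM", i,
                                r$qtl$chrom[i], r$qtl$pos[i]), gf, append = TRUE)
            write_tsv(r$gtp[[i]], gf, append = TRUE, col.names = TRUE)
          }
        }
      }
    }
  }
  # common outputs
  write_tsv(res$marker_summary, output_name(prefix, "common", "mtp"))
  mtpf <- output_name(prefix, "common", "mtp")
  write_lines("# imputed marker types (codes 2/0)", mtpf, append = TRUE)
  imp <- as.data.frame(ctx$pil_imp)
  write_tsv(imp, mtpf, append = TRUE, col.names = TRUE)
  # lower-triangular correlations
  cc <- res$correlations
  coef_lines <- vapply(seq_len(nrow(cc)), function(i) {
    paste(c(ctx$map$marker[i], formatC(cc[i, seq_len(i)], digits = 4,
                                       format = "f")), collapse = "\t")
  }, character(1))
  write_lines(coef_lines, output_name(prefix, "common", "coe"))
  write_tsv(res$stats, output_name(prefix, "common", "sta"))
  write_linkage_map_txt(ctx$map, file.path(dirname(prefix), "LinkageMap.txt"))
  # Phenotype.txt: stacked raw phenotypes
  phf <- file.path(dirname(prefix), "Phenotype.txt")
  first <- TRUE
  for (pop in names(inp$pheno)) {
    df <- cbind(data.frame(Population = pop,
                           Entry = seq_len(nrow(inp$pheno[[pop]]))),
                as.data.frame(inp$pheno[[pop]]))
    write_tsv(df, phf, append = !first, col.names = first)
    first <- FALSE
  }
  write_tsv(do.call(rbind, thr_rows),
            file.path(dirname(prefix), "Threshold.txt"))
  invisible(prefix)
}

#' Write a simulated run as a QHP input file
#'
#' Arranges a [simulate_populations()] result in the QHP input dialect so
#' it can be mapped directly by [run_qhp()].  QTL loci are not written
#' (they are not observed markers); replicated phenotypes are written as
#' entry means; one trait per file.
#'
#' @param sim a [simulate_populations()] result.
#' @param file output path.
#' @param trait trait name to write.
#' @return \code{file}, invisibly.
#' @export
write_qhp_input <- function(sim, file, trait = "simTrait") {
  map <- sim$map
  pops <- sim$populations
  n_pil <- nrow(pops$PIL$geno)
  sizes <- c(PIL = n_pil,
             IB1 = if (!is.null(pops$IB1)) nrow(pops$IB1$geno) else 0L,
             IB2 = if (!is.null(pops$IB2)) nrow(pops$IB2$geno) else 0L,
             IF2 = if (!is.null(pops$IF2)) nrow(pops$IF2$geno) else 0L)
  con <- file(file, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste(..., collapse = " "), con)
  wl("# general information")
  wl(paste(c(if (sim$pil_type == "DH") 1 else 2, n_pil,
             length(unique(map$chrom)),
             match(sim$fun, c("kosambi", "haldane", "morgan")),
             1, 1, sizes, 1, trait), collapse = " "))
  wl("# marker numbers")
  for (ch in unique(map$chrom)) wl(ch, sum(map$chrom == ch))
  wl("# linkage map")
  for (i in seq_len(nrow(map))) wl(map$marker[i], format(map$pos[i]))
  wl("# PIL marker types")
  gm <- pops$PIL$geno
  gm[is.na(gm)] <- -1L
  utils::write.table(gm, con, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (pop in c("PIL", "IB1", "IB2")) {
    wl(sprintf("# %s phenotypes", pop))
    if (sizes[[pop]] > 0) {
      writeLines(format(rowMeans(pops[[pop]]$y), trim = TRUE), con)
    }
  }
  wl("# IF2 phenotypes (parent i, parent j, value)")
  if (sizes[["IF2"]] > 0) {
    pr <- sim$design$if2_pairs
    writeLines(paste(pr[, 1], pr[, 2],
                     format(rowMeans(pops$IF2$y), trim = TRUE)), con)
  }
  invisible(file)
}
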