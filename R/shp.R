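# The simulation/power functionality: input dialect and pipeline driver.

#' Read a simulation (SHP) input file
#'
#' Five parts, '#' comments ignored:
#' \enumerate{
#'   \item general information (13 parameters): the first ten as in
#'     [read_qhp()] items 1-10 (pure-line type, gPIL, chromosomes, mapping
#'     function, space type, space unit, four phenotyping sizes), then the
#'     IF2 sampling indicator (1 = random, 2 = balanced so each pure line
#'     appears equally often), an indicator for the next value (1 =
#'     heritability, 2 = error variance), and that value (F2 is the
#'     reference population for the heritability conversion);
#'   \item marker numbers and 3. linkage map, as in [read_qhp()];
#'   \item QTL positions: per chromosome, a count followed by the
#'     positions in cM;
#'   \item genotypic values: per QTL a line \code{v2 v1 v0}; then the
#'     number of digenic epistatic pairs, and per pair the two QTL indices
#'     followed by the nine deviation-table values (rows = genotype of the
#'     first locus in code order 2/1/0).
#' }
#' Only one trait is simulated per input file.
#'
#' @param file path to the input file.
#' @return a \code{shp_input} list: map, model, sizes and configuration.
#' @export
read_shp <- function(file) {
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
  samp_code <- tk$take_int(what = "IF2 sampling code")
  if (!samp_code %in% 1:2) stop("IF2 sampling code must be 1 (random) or 2 (balanced)")
  noise_ind <- tk$take_int(what = "heritability/error-variance indicator")
  if (!noise_ind %in% 1:2) stop("indicator must be 1 (heritability) or 2 (error variance)")
  noise_val <- tk$take_num(what = "heritability or error variance")
  if (sizes[["PIL"]] > g_pil) {
    stop("PIL phenotyping size exceeds the number of simulated lines")
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
  q_chrom <- character(0)
  q_pos <- numeric(0)
  for (i in seq_len(n_chrom)) {
    nq <- tk$take_int(what = paste0("QTL count on ", chrom_names[i]))
    if (nq > 0) {
      q_pos <- c(q_pos, tk$take_num(nq, "QTL positions"))
      q_chrom <- c(q_chrom, rep(chrom_names[i], nq))
    }
  }
  nq <- length(q_pos)
  if (nq == 0) stop("the QTL model must declare at least one locus")
  vals <- matrix(tk$take_num(3 * nq, "QTL genotypic values"), nq, 3, byrow = TRUE)
  n_epi <- tk$take_int(what = "number of epistatic pairs")
  epistasis <- NULL
  if (n_epi > 0) {
    epistasis <- lapply(seq_len(n_epi), function(e) {
      ab <- tk$take_int(2, "epistatic pair indices")
      tab <- matrix(tk$take_num(9, "epistatic deviation table"), 3, 3, byrow = TRUE)
      list(a = ab[1], b = ab[2], table = tab)
    })
  }
  model <- qtl_model(q_chrom, q_pos, vals[, 1], vals[, 2], vals[, 3],
                     epistasis = epistasis,
                     h2 = if (noise_ind == 1) noise_val else NULL,
                     ve = if (noise_ind == 2) noise_val else NULL)
  check_model_on_map(model, map)
  structure(list(map = map, model = model, pil_type = pil_type,
                 g_pil = g_pil, sizes = sizes, fun = fun,
                 if2_sampling = c("random", "balanced")[samp_code]),
            class = "shp_input")
}

#' Run the simulation and power-analysis pipeline
#'
#' Simulates the configured populations \code{n_runs} times, maps each run
#' with the requested methods in every analysis group (independent
#' populations plus the matching combined design), and summarises per-QTL
#' detection power, false positives and run-averaged profiles.  When
#' \code{out_prefix} is given, writes per group and method the power
#' tables (\code{.pim}/\code{.pic}), the per-run detected QTL
#' (\code{.qim}/\code{.qic}), the averaged profiles
#' (\code{.rim}/\code{.ric}) and the per-run stepwise selections
#' (\code{.stp}), plus 'LinkageMap.txt' and 'Threshold.txt'; with
#' \code{emit_populations = TRUE} each run's populations are also written
#' as ready-to-map QHP input files.
#'
#' @param x a \code{shp_input} or path to an SHP input file.
#' @param methods subset of c("IM", "ICIM").
#' @param step scan step in cM.
#' @param threshold fixed LOD threshold (used when \code{n_perm = 0}).
#' @param n_perm,alpha per-run permutation-threshold settings.
#' @param si support interval in cM for truth matching.
#' @param n_runs number of simulation runs.
#' @param seed random seed.
#' @param pin,pout ICIM stepwise thresholds.
#' @param out_prefix optional output path prefix.
#' @param emit_populations write each run's populations as QHP files.
#' @return the [run_power_study()] result.
#' @export
run_shp <- function(x, methods = c("IM", "ICIM"), step = 1, threshold = 3,
                    n_perm = 0, alpha = 0.05, si = 10, n_runs = 10,
                    seed = 1, pin = 0.001, pout = 2 * pin,
                    out_prefix = NULL, emit_populations = FALSE) {
  inp <- if (is.character(x)) read_shp(x) else x
  st <- run_power_study(
    inp$map, inp$model,
    n_pil = inp$g_pil,
    n_ib1 = if (inp$sizes[["IB1"]] > 0) inp$g_pil else 0,
    n_ib2 = if (inp$sizes[["IB2"]] > 0) inp$g_pil else 0,
    n_if2 = inp$sizes[["IF2"]],
    pil_type = inp$pil_type, fun = inp$fun,
    if2_sampling = inp$if2_sampling,
    methods = methods, step = step, threshold = threshold,
    n_perm = n_perm, alpha = alpha, si = si, n_runs = n_runs, seed = seed,
    pin = pin, pout = pout, keep_populations = emit_populations)
  if (!is.null(out_prefix)) {
    write_shp_outputs(st, inp, out_prefix, emit_populations)
  }
  st
}

write_shp_outputs <- function(st, inp, prefix, emit_populations = FALSE) {
  ext_of <- c(IM = "im", ICIM = "ic")
  map <- inp$map
  for (tag in st$tags) {
    for (m in st$methods) {
      key <- paste(tag, m)
      tab <- st$tables[[key]]
      # power tables: per-QTL then per-interval
      pf <- output_name(prefix, tag, paste0("p", ext_of[m]))
      write_lines(sprintf("# detection power per predefined QTL (%d runs, SI = %g cM, FDR = %.4f, FP/run = %.3f)",
                          tab$n_runs, tab$si, tab$fdr, tab$fp_per_run), pf)
      write_tsv(tab$per_qtl, pf, append = TRUE, col.names = TRUE)
      write_lines("# detection frequency per marker interval (interval named by its left marker)",
                  pf, append = TRUE)
      iv <- tab$per_interval
      iv$left_marker <- map$marker[iv$left_marker_index]
      write_tsv(iv[, c("left_marker", "frequency")], pf, append = TRUE,
                col.names = TRUE)
      # per-run detections
      qf <- output_name(prefix, tag, paste0("q", ext_of[m]))
      if (is.null(tab$detections) || !nrow(tab$detections)) {
        write_lines("# no QTL detected in any run", qf)
      } else {
        det <- format_qtl(tab$detections)
        det$Run <- tab$detections$run
        det$TruePositive <- tab$detections$true_positive
        write_tsv(det, qf)
      }
      # averaged profile
      rf <- output_name(prefix, tag, paste0("r", ext_of[m]))
      write_lines(sprintf("# mean over %d runs", tab$n_runs), rf)
      write_tsv(format_profile(tab$mean_profile), rf, append = TRUE,
                col.names = TRUE)
      # stepwise per run (ICIM only)
      if (m == "ICIM") {
        sf <- output_name(prefix, tag, "stp")
        if (file.exists(sf)) file.remove(sf)
        for (run in seq_along(tab$stepwise)) {
          sel <- tab$stepwise[[run]]
          write_lines(sprintf("# run %d", run), sf, append = TRUE)
          if (is.null(sel) || !nrow(sel)) {
            write_lines("# (none selected)", sf, append = TRUE)
          } else {
            write_tsv(data.frame(Marker = sel$marker, Kind = sel$kind,
                                 Coefficient = sel$coefficient),
                      sf, append = TRUE, col.names = TRUE)
          }
        }
      }
    }
  }
  write_linkage_map_txt(map, file.path(dirname(prefix), "LinkageMap.txt"))
  write_tsv(data.frame(Threshold = st$params$threshold,
                       Source = if (st$params$n_perm > 0)
                         sprintf("permutation (n=%d, alpha=%g)",
                                 st$params$n_perm, st$params$alpha)
                       else "fixed"),
            file.path(dirname(prefix), "Threshold.txt"))
  if (emit_populations && !is.null(st$populations)) {
    for (run in seq_along(st$populations)) {
      write_qhp_input(st$populations[[run]],
                      sprintf("%s_run%d.qhp", prefix, run))
    }
  }
  invisible(prefix)
}
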