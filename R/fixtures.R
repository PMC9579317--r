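# Deterministic synthetic input generators.  These define the package's
# reference study conditions (used throughout the test suite): a
# seven-chromosome map with eleven markers at 10 cM spacing per
# chromosome, Kosambi mapping function, DH pure lines, population sizes
# 200/200/200/300 with balanced IF2 sampling, one trait controlled by
# five unlinked additive-dominant QTLs at overall heritability 0.6.

#' Reference linkage map and QTL model
#'
#' \code{fixture_map()} builds the default map (\code{n_chrom} chromosomes
#' of \code{n_markers} markers spaced \code{spacing} cM);
#' \code{fixture_model()} the default trait architecture: five unlinked
#' QTLs on chromosomes 1-5 with additive effects 1, 0.9, 0.8, 0.7, 0.6
#' and dominance effects 0.8, 0.7, 0.6, 0.5, 0.4, heritability 0.6 on
#' the F2 reference scale.
#'
#' @param n_chrom,n_markers,spacing map dimensions.
#' @return a \code{linkage_map} / \code{qtl_model}.
#' @export
fixture_map <- function(n_chrom = 7, n_markers = 11, spacing = 10) {
  chrom <- rep(paste0("chr", seq_len(n_chrom)), each = n_markers)
  pos <- rep(seq(0, by = spacing, length.out = n_markers), n_chrom)
  marker <- paste0("M", rep(seq_len(n_chrom), each = n_markers), "_",
                   rep(seq_len(n_markers), n_chrom))
  linkage_map(chrom, marker, pos)
}

#' @rdname fixture_map
#' @param h2 heritability of the generated trait.
#' @export
fixture_model <- function(h2 = 0.6) {
  a <- c(1, 0.9, 0.8, 0.7, 0.6)
  d <- c(0.8, 0.7, 0.6, 0.5, 0.4)
  qtl_model(chrom = paste0("chr", 1:5), pos = c(25, 45, 55, 35, 65),
            v2 = a, v1 = d, v0 = -a, h2 = h2)
}

#' Generate a synthetic input file
#'
#' Writes a deterministic, parseable input file for the requested
#' functionality under the reference study conditions (the same seed
#' always produces byte-identical files).  The map/phenotype/genotype
#' content of the vhp and qhp fixtures is produced by the simulation
#' engine.
#'
#' @param kind "mhp", "vhp", "qhp" or "shp".
#' @param file output path.
#' @param seed random seed.
#' @param n_pil,n_if2 population sizes (IB1/IB2 sizes equal
#'   \code{n_pil}); ignored for "mhp".
#' @param reps phenotype replications (vhp only).
#' @param map,model optional overrides of [fixture_map()] /
#'   [fixture_model()].
#' @return \code{file}, invisibly.
#' @export
generate_fixture <- function(kind = c("mhp", "vhp", "qhp", "shp"), file,
                             seed = 1, n_pil = 200, n_if2 = 300, reps = 3,
                             map = fixture_map(), model = fixture_model()) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
    mhp = write_mhp(map, file),
    shp = write_shp_input(map, model, n_pil, n_if2, file),
    qhp = {
      sim <- simulate_populations(map, model, n_pil, n_pil, n_pil, n_if2,
                                  pil_type = "DH", fun = "kosambi",
                                  if2_sampling = "balanced", reps = 1)
      write_qhp_input(sim, file)
    },
    vhp = {
      sim <- simulate_populations(map, model, n_pil, n_pil, n_pil, n_if2,
                                  pil_type = "DH", fun = "kosambi",
                                  if2_sampling = "balanced", reps = reps)
      write_vhp_input(sim, file)
    })
  invisible(file)
}

#' Write a linkage map in the MHP input dialect
#'
#' @param map a \code{linkage_map}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_mhp <- function(map, file) {
  con <- file(file, "w")
  on.exit(close(con))
  chs <- unique(map$chrom)
  writeLines("# general information: chromosomes, space type (1=positions), unit (1=cM)", con)
  writeLines(paste(length(chs), 1, 1), con)
  writeLines("# marker numbers", con)
  for (ch in chs) writeLines(paste(ch, sum(map$chrom == ch)), con)
  writeLines("# linkage map", con)
  for (i in seq_len(nrow(map))) {
    writeLines(paste(map$marker[i], format(map$pos[i])), con)
  }
  invisible(file)
}

#' Write a simulated run as a VHP input file
#'
#' @param sim a [simulate_populations()] result with replicated
#'   phenotypes.
#' @param file output path.
#' @param trait trait name.
#' @return \code{file}, invisibly.
#' @export
write_vhp_input <- function(sim, file, trait = "simTrait") {
  pops <- sim$populations
  sizes <- vapply(c("PIL", "IB1", "IB2", "IF2"), function(p)
    if (is.null(pops[[p]])) 0L else nrow(pops[[p]]$y), integer(1))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# sizes PIL IB1 IB2 IF2, replications, traits + names", con)
  writeLines(paste(c(sizes, sim$reps, 1, trait), collapse = " "), con)
  for (p in c("PIL", "IB1", "IB2", "IF2")) {
    writeLines(sprintf("# %s phenotypes", p), con)
    if (sizes[[p]] > 0) {
      utils::write.table(format(pops[[p]]$y, trim = TRUE), con, sep = " ",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(file)
}

#' Write an SHP input file for a map and QTL model
#'
#' @param map a \code{linkage_map}.
#' @param model a \code{qtl_model}.
#' @param n_pil,n_if2 population sizes (IB1/IB2 equal \code{n_pil}).
#' @param file output path.
#' @param pil_type "DH" or "RIL".
#' @param fun mapping function name.
#' @param if2_sampling "random" or "balanced".
#' @return \code{file}, invisibly.
#' @export
write_shp_input <- function(map, model, n_pil, n_if2, file,
                            pil_type = "DH", fun = "kosambi",
                            if2_sampling = "balanced") {
  con <- file(file, "w")
  on.exit(close(con))
  chs <- unique(map$chrom)
  writeLines("# 13 general parameters", con)
  writeLines(paste(
    if (pil_type == "DH") 1 else 2, n_pil, length(chs),
    match(fun, c("kosambi", "haldane", "morgan")), 1, 1,
    n_pil, n_pil, n_pil, n_if2,
    if (if2_sampling == "random") 1 else 2,
    if (!is.null(model$h2)) 1 else 2,
    if (!is.null(model$h2)) model$h2 else model$ve), con)
  writeLines("# marker numbers", con)
  for (ch in chs) writeLines(paste(ch, sum(map$chrom == ch)), con)
  writeLines("# linkage map", con)
  for (i in seq_len(nrow(map))) {
    writeLines(paste(map$marker[i], format(map$pos[i])), con)
  }
  writeLines("# QTL count and positions per chromosome", con)
  for (ch in chs) {
    qp <- model$loci$pos[model$loci$chrom == ch]
    writeLines(paste(c(length(qp), qp), collapse = " "), con)
  }
  writeLines("# genotypic values v2 v1 v0 per QTL (map order)", con)
  ord <- order(match(model$loci$chrom, chs), model$loci$pos)
  for (i in ord) {
    writeLines(paste(model$loci$v2[i], model$loci$v1[i], model$loci$v0[i]), con)
  }
  writeLines("# epistatic pairs", con)
  eps <- model$epistasis
  writeLines(as.character(length(eps)), con)
  for (ep in eps) {
    writeLines(paste(ep$a, ep$b), con)
    writeLines(apply(as.matrix(ep$table), 1, paste, collapse = " "), con)
  }
  invisible(file)
}
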