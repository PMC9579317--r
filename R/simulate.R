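# Meiosis-level simulation of pure-line populations (DH or RIL), the
# hybrid populations derived from them, genotypic values under
# additive/dominance/epistatic QTL models, and the heritability-to-error-
# variance conversion on the F2 reference scale.

#' QTL model for simulation
#'
#' @param chrom chromosome name of each locus.
#' @param pos position of each locus in cM.
#' @param v2,v1,v0 genotypic value of the three genotype classes at each
#'   locus (codes 2, 1, 0), in trait units.  The additive effect is
#'   a = (v2 - v0)/2 and the dominance effect d = v1 - (v2 + v0)/2.
#' @param epistasis optional list of digenic interactions, each a list
#'   with elements \code{a}, \code{b} (locus indices) and \code{table}, a
#'   3x3 deviation table in trait units with rows/columns indexed by the
#'   genotype of locus a/b in code order 2, 1, 0.
#' @param h2 broad-sense heritability on the F2 reference scale, in (0, 1];
#'   give either \code{h2} or \code{ve}.
#' @param ve error variance in squared trait units.
#' @return a \code{qtl_model} object.
#' @examples
#' m <- linkage_map(rep("chr1", 3), c("M1","M2","M3"), c(0, 10, 20))
#' q <- qtl_model("chr1", 5, v2 = 1, v1 = 0.5, v0 = -1, h2 = 0.5)
#' @export
qtl_model <- function(chrom, pos, v2, v1, v0, epistasis = NULL,
                      h2 = NULL, ve = NULL) {
  loci <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                     v2 = v2, v1 = v1, v0 = v0, stringsAsFactors = FALSE)
  loci$a <- (loci$v2 - loci$v0) / 2
  loci$d <- loci$v1 - (loci$v2 + loci$v0) / 2
  if (!is.null(epistasis)) {
    for (ep in epistasis) {
      if (!all(c("a", "b", "table") %in% names(ep))) {
        stop("each epistasis entry needs elements a, b and table")
      }
      if (any(c(ep$a, ep$b) < 1 | c(ep$a, ep$b) > nrow(loci))) {
        stop("epistatic pair references an undeclared locus")
      }
      if (!all(dim(as.matrix(ep$table)) == c(3, 3))) {
        stop("epistatic deviation table must be 3x3")
      }
    }
  }
  if (is.null(h2) == is.null(ve)) stop("give exactly one of h2 or ve")
  if (!is.null(h2) && (h2 <= 0 || h2 > 1)) stop("h2 must lie in (0, 1]")
  if (!is.null(ve) && ve < 0) stop("ve must be non-negative")
  structure(list(loci = loci, epistasis = epistasis, h2 = h2, ve = ve),
            class = "qtl_model")
}

check_model_on_map <- function(model, map) {
  for (i in seq_len(nrow(model$loci))) {
    ch <- model$loci$chrom[i]
    idx <- which(map$chrom == ch)
    if (!length(idx)) stop("QTL chromosome ", ch, " not on the map")
    rng <- range(map$pos[idx])
    if (model$loci$pos[i] < rng[1] - 1e-9 || model$loci$pos[i] > rng[2] + 1e-9) {
      stop("QTL at ", model$loci$pos[i], " cM lies outside chromosome ", ch)
    }
  }
  invisible(TRUE)
}

# Internal locus layout: markers and QTL merged per chromosome, sorted by
# position, so QTL genotypes are simulated jointly with markers.
locus_layout <- function(map, model = NULL) {
  chroms <- unique(map$chrom)
  lay <- lapply(chroms, function(ch) {
    mp <- map$pos[map$chrom == ch]
    qp <- if (!is.null(model)) model$loci$pos[model$loci$chrom == ch] else numeric(0)
    qi <- if (!is.null(model)) which(model$loci$chrom == ch) else integer(0)
    pos <- c(mp, qp)
    type <- c(rep("marker", length(mp)), rep("qtl", length(qp)))
    src <- c(which(map$chrom == ch), qi)   # index into map rows / model loci
    o <- order(pos, type)  # QTL after coincident marker (stable, r = 0)
    data.frame(chrom = ch, pos = pos[o], type = type[o], src = src[o],
               stringsAsFactors = FALSE)
  })
  names(lay) <- chroms
  lay
}

# Bernoulli-recombination meiosis: matrix of parental origins (0/1) for n
# gametes over loci of one chromosome with adjacent recombination
# fractions rvec (length = loci - 1).  No interference beyond the map
# function.
sim_origins <- function(n, rvec) {
  L <- length(rvec) + 1L
  o <- matrix(0L, n, L)
  o[, 1] <- sample(0:1, n, replace = TRUE)
  if (L > 1) {
    for (k in 2:L) {
      sw <- stats::rbinom(n, 1L, rvec[k - 1L])
      o[, k] <- (o[, k - 1L] + sw) %% 2L
    }
  }
  o
}

#' Simulate gametes from an F1 (or arbitrary) parent
#'
#' The first allele of each chromosome is drawn uniformly from the two
#' parental haplotypes; between adjacent loci the parental origin switches
#' with the recombination probability given by the mapping function.
#' Chromosomes recombine independently.
#'
#' @param n number of gametes.
#' @param hap1,hap2 parental haplotypes: n x L (or 1 x L) 0/1 matrices of
#'   "carries the first parent's allele" indicators for one chromosome.
#' @param rvec adjacent-locus recombination fractions (length L - 1).
#' @return n x L 0/1 matrix of gamete alleles.
#' @export
simulate_gamete <- function(n, hap1, hap2, rvec) {
  hap1 <- matrix(hap1, nrow = n, ncol = length(rvec) + 1L, byrow = is.vector(hap1))
  hap2 <- matrix(hap2, nrow = n, ncol = length(rvec) + 1L, byrow = is.vector(hap2))
  o <- sim_origins(n, rvec)
  hap1 * (1L - o) + hap2 * o
}

# Interval recombination fractions for one chromosome layout (per-meiosis,
# never RIL-adjusted: expansion emerges from the selfing process itself).
layout_rvec <- function(lay, fun) {
  if (nrow(lay) < 2) return(numeric(0))
  map_to_recomb(diff(lay$pos) / 100, fun)
}

#' Simulate a pure-line (DH or RIL) population
#'
#' DH lines double a single F1 gamete.  RILs are produced by ten selfing
#' generations from the F1 followed by forced fixation of the rare
#' residual heterozygous loci (each resolved to either allele with
#' probability 1/2), so every line is homozygous at every locus.
#'
#' @param n number of lines.
#' @param map \code{linkage_map}.
#' @param model optional \code{qtl_model}; its loci are simulated jointly
#'   with the markers.
#' @param pil_type "DH" or "RIL".
#' @param fun mapping function name.
#' @return list with \code{markers} (n x M genotype matrix, codes 2/0) and
#'   \code{qtl} (n x Q matrix, codes 2/0; NULL without a model).
#' @export
simulate_pil <- function(n, map, model = NULL, pil_type = c("DH", "RIL"),
                         fun = "kosambi") {
  pil_type <- match.arg(pil_type)
  lay <- locus_layout(map, model)
  allele <- lapply(lay, function(l) {
    rvec <- layout_rvec(l, fun)
    L <- nrow(l)
    if (pil_type == "DH") {
      # F1 haplotypes are all-A and all-B; a doubled gamete is its origin
      1L - sim_origins(n, rvec)
    } else {
      h1 <- matrix(1L, n, L)
      h2 <- matrix(0L, n, L)
      for (gen in 1:10) {
        g1 <- simulate_gamete(n, h1, h2, rvec)
        g2 <- simulate_gamete(n, h1, h2, rvec)
        h1 <- g1
        h2 <- g2
      }
      het <- h1 != h2
      if (any(het)) {
        pick <- matrix(stats::rbinom(n * L, 1L, 0.5), n, L)
        h1[het] <- ifelse(pick[het] == 1L, h1[het], h2[het])
      }
      h1
    }
  })
  split_layout(allele, lay, map, model)
}

# Assemble per-chromosome allele matrices (1 = first parent's allele) into
# marker and QTL genotype matrices in map / model order.
split_layout <- function(allele, lay, map, model, ploidy = 2L) {
  M <- nrow(map)
  n <- nrow(allele[[1]])
  markers <- matrix(NA_integer_, n, M)
  qtl <- if (!is.null(model)) matrix(NA_integer_, n, nrow(model$loci)) else NULL
  for (ch in names(lay)) {
    l <- lay[[ch]]
    g <- allele[[ch]] * ploidy   # homozygous lines: allele -> code 2/0
    mk <- l$type == "marker"
    markers[, l$src[mk]] <- g[, mk, drop = FALSE]
    if (!is.null(qtl) && any(!mk)) {
      qtl[, l$src[!mk]] <- g[, !mk, drop = FALSE]
    }
  }
  colnames(markers) <- map$marker
  attr(markers, "population") <- "PIL"
  list(markers = markers, qtl = qtl)
}

#' Build a crossing design for the IF2 population
#'
#' Random mode draws parent pairs uniformly (repeats allowed, self-pairs
#' excluded).  Balanced mode makes every pure line appear exactly
#' \code{2 n_if2 / n_pil} times over all pair slots, by pairing random
#' permutation blocks; this requires \code{2 n_if2} to be divisible by
#' \code{n_pil}.
#'
#' @param n_pil number of pure lines.
#' @param n_if2 number of IF2 hybrids (0 for none).
#' @param sampling "random" or "balanced".
#' @return a \code{cross_design}.
#' @export
build_cross_design <- function(n_pil, n_if2, sampling = c("random", "balanced")) {
  sampling <- match.arg(sampling)
  if (n_if2 == 0) return(cross_design(n_pil, NULL, sampling))
  if (sampling == "random") {
    i <- sample.int(n_pil, n_if2, replace = TRUE)
    j <- sample.int(n_pil, n_if2, replace = TRUE)
    while (any(i == j)) {
      k <- i == j
      j[k] <- sample.int(n_pil, sum(k), replace = TRUE)
    }
    pairs <- cbind(i, j)
  } else {
    slots <- 2L * n_if2
    if (slots %% n_pil != 0) {
      stop("balanced sampling requires 2*n_if2 divisible by n_pil")
    }
    reps <- slots %/% n_pil
    repeat {
      v <- as.vector(replicate(reps, sample.int(n_pil)))
      pairs <- matrix(v, ncol = 2, byrow = TRUE)
      if (!any(pairs[, 1] == pairs[, 2])) break
    }
  }
  cross_design(n_pil, pairs, sampling)
}

#' Genotypic value under a QTL model
#'
#' \eqn{G = \sum_{loci} v(code) + \sum_{pairs} table[code_a, code_b]}.
#' With values \code{(a, d, -a)} this is the usual
#' \eqn{\sum (a x + d z)} with \eqn{x \in \{1,0,-1\}},
#' \eqn{z \in \{0,1,0\}}.
#'
#' @param qtl_geno integer matrix (individuals x loci) of codes 2/1/0.
#' @param model a \code{qtl_model}.
#' @return numeric vector of genotypic values.
#' @export
genotypic_value <- function(qtl_geno, model) {
  qtl_geno <- as.matrix(qtl_geno)
  n <- nrow(qtl_geno)
  G <- numeric(n)
  vmat <- rbind(model$loci$v0, model$loci$v1, model$loci$v2)  # row = code + 1
  for (q in seq_len(ncol(qtl_geno))) {
    G <- G + vmat[qtl_geno[, q] + 1L, q]
  }
  for (ep in model$epistasis) {
    tab <- as.matrix(ep$table)  # rows/cols in code order 2, 1, 0
    ra <- 3L - qtl_geno[, ep$a]
    rb <- 3L - qtl_geno[, ep$b]
    G <- G + tab[cbind(ra, rb)]
  }
  G
}

#' Convert heritability to error variance on the F2 reference scale
#'
#' Simulates a reference F2 (two independent gametes from the F1 at the
#' model's QTL loci, with linkage) of \code{n_ref} individuals, computes
#' the genetic variance of the genotypic values, and returns
#' \eqn{V_e = V_G(F2) (1 - h^2) / h^2}.  Monte Carlo rather than a closed
#' form so that linkage between QTLs and epistasis are automatically
#' included.
#'
#' @param model a \code{qtl_model} with \code{h2} set.
#' @param map \code{linkage_map} (range checks).
#' @param fun mapping function name.
#' @param n_ref reference population size (default 20000).
#' @return error variance (squared trait units); the realized
#'   \eqn{V_G(F2)} is attached as attribute \code{"vg_f2"}.
#' @export
error_variance_from_h2 <- function(model, map, fun = "kosambi", n_ref = 20000) {
  if (is.null(model$h2)) stop("model specifies ve directly; nothing to convert")
  check_model_on_map(model, map)
  f2 <- simulate_f2_qtl(n_ref, map, model, fun)
  vg <- stats::var(genotypic_value(f2, model))
  if (model$h2 == 1) {
    ve <- 0
  } else {
    if (vg <= 0) stop("degenerate genetic variance in the F2 reference; cannot convert h2")
    ve <- vg * (1 - model$h2) / model$h2
  }
  attr(ve, "vg_f2") <- vg
  ve
}

# F2 reference: two independent F1 gametes at the QTL loci only.
simulate_f2_qtl <- function(n, map, model, fun) {
  qtl <- matrix(NA_integer_, n, nrow(model$loci))
  for (ch in unique(model$loci$chrom)) {
    qi <- which(model$loci$chrom == ch)
    pos <- model$loci$pos[qi]
    o <- order(pos)
    rvec <- map_to_recomb(diff(pos[o]) / 100, fun)
    g <- (1L - sim_origins(n, rvec)) + (1L - sim_origins(n, rvec))
    qtl[, qi[o]] <- g
  }
  qtl
}

#' Simulate replicated phenotypes
#'
#' \eqn{y = G + e}, with errors independent Normal(0, Ve) per observation.
#'
#' @param G numeric vector of genotypic values.
#' @param ve error variance.
#' @param reps number of replications (default 1).
#' @return numeric matrix (individuals x reps).
#' @export
simulate_phenotypes <- function(G, ve, reps = 1) {
  n <- length(G)
  matrix(G, n, reps) + matrix(stats::rnorm(n * reps, 0, sqrt(ve)), n, reps)
}

#' Simulate the full set of mapping populations
#'
#' Generates the pure lines with the QTL model's loci, derives the hybrid
#' populations (IB1/IB2 in line order, IF2 from a crossing design), and
#' attaches genotypic values and phenotypes.
#'
#' @param map \code{linkage_map}.
#' @param model \code{qtl_model}.
#' @param n_pil,n_ib1,n_ib2,n_if2 population sizes; IB1/IB2 must be 0 or
#'   equal to \code{n_pil}.
#' @param pil_type "DH" or "RIL".
#' @param fun mapping function name.
#' @param if2_sampling "random" or "balanced".
#' @param reps phenotype replications (default 1).
#' @param ve optional error variance; when NULL it is derived from the
#'   model's \code{h2} via [error_variance_from_h2()].
#' @return list with elements \code{pil} (markers + qtl), \code{design},
#'   per-population genotype/genetic-value/phenotype lists, and \code{ve}.
#' @export
simulate_populations <- function(map, model, n_pil, n_ib1 = 0, n_ib2 = 0,
                                 n_if2 = 0, pil_type = "DH", fun = "kosambi",
                                 if2_sampling = "balanced", reps = 1,
                                 ve = NULL) {
  if (!n_ib1 %in% c(0L, n_pil) || !n_ib2 %in% c(0L, n_pil)) {
    stop("IB1 and IB2 sizes must be 0 or equal to the pure-line population size")
  }
  check_model_on_map(model, map)
  if (is.null(ve)) {
    ve <- if (!is.null(model$ve)) model$ve else error_variance_from_h2(model, map, fun)
  }
  pil <- simulate_pil(n_pil, map, model, pil_type, fun)
  design <- build_cross_design(n_pil, n_if2, if2_sampling)

  pops <- list()
  G_pil <- genotypic_value(pil$qtl, model)
  pops$PIL <- list(geno = pil$markers, qtl = pil$qtl, G = G_pil,
                   y = simulate_phenotypes(G_pil, ve, reps))
  if (n_ib1 > 0) {
    qg <- derive_hybrid_genotypes(pil$qtl, target = "IB1")
    G <- genotypic_value(qg, model)
    pops$IB1 <- list(geno = derive_hybrid_genotypes(pil$markers, target = "IB1"),
                     qtl = qg, G = G, y = simulate_phenotypes(G, ve, reps))
  }
  if (n_ib2 > 0) {
    qg <- derive_hybrid_genotypes(pil$qtl, target = "IB2")
    G <- genotypic_value(qg, model)
    pops$IB2 <- list(geno = derive_hybrid_genotypes(pil$markers, target = "IB2"),
                     qtl = qg, G = G, y = simulate_phenotypes(G, ve, reps))
  }
  if (n_if2 > 0) {
    qg <- derive_hybrid_genotypes(pil$qtl, design, "IF2")
    G <- genotypic_value(qg, model)
    pops$IF2 <- list(geno = derive_hybrid_genotypes(pil$markers, design, "IF2"),
                     qtl = qg, G = G, y = simulate_phenotypes(G, ve, reps))
  }
  list(map = map, model = model, pil_type = pil_type, fun = fun,
       design = design, populations = pops, ve = as.numeric(ve), reps = reps)
}
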