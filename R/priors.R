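# Conditional QTL-genotype probabilities given flanking marker data.
#
# For a homozygous line the genotype at any chromosomal position is the
# doubled gamete allele, so conditional probabilities follow from the
# two-interval gamete classes: with nearest informative flanking markers at
# recombination fractions r1 (left -> position) and r2 (position -> right),
# and per-side transmission probabilities t1, t2 of the first parent's
# allele, the no-interference factorization gives
#   P(allele A | flanks) = t1 t2 / (t1 t2 + (1 - t1)(1 - t2)).
# Missing sides marginalize to t = 1/2 (lines segregate 1:1).  For RILs
# every pairwise fraction is Haldane-Waddington expanded.

# P(line carries the first parent's allele) for every line at every query
# position on ONE chromosome.  `geno` is the n x M matrix of that
# chromosome's marker codes (2/0/NA), `mpos` their cM positions, `qpos`
# the query positions.
line_allele_prob <- function(geno, mpos, qpos, fun = "kosambi", pil_type = "DH") {
  n <- nrow(geno)
  M <- ncol(geno)
  obs <- !is.na(geno)
  # nearest observed marker index at/left and at/right of each marker slot
  prev <- matrix(0L, n, M)
  nxt <- matrix(0L, n, M)
  prev[, 1] <- ifelse(obs[, 1], 1L, 0L)
  if (M > 1) for (k in 2:M) prev[, k] <- ifelse(obs[, k], k, prev[, k - 1])
  nxt[, M] <- ifelse(obs[, M], M, 0L)
  if (M > 1) for (k in (M - 1):1) nxt[, k] <- ifelse(obs[, k], k, nxt[, k + 1])

  P <- matrix(0.5, n, length(qpos))
  for (t in seq_along(qpos)) {
    pos <- qpos[t]
    kL <- findInterval(pos + 1e-9, mpos)
    at_marker <- kL >= 1 && abs(mpos[kL] - pos) < 1e-9
    kR <- if (at_marker) kL else kL + 1L
    L <- if (kL >= 1) prev[, kL] else rep(0L, n)
    R <- if (kR >= 1 && kR <= M) nxt[, kR] else rep(0L, n)

    t1 <- rep(0.5, n)
    hasL <- L > 0L
    if (any(hasL)) {
      gL <- geno[cbind(which(hasL), L[hasL])]
      r1 <- cm_to_recomb(pos - mpos[L[hasL]], fun, pil_type)
      t1[hasL] <- ifelse(gL == 2L, 1 - r1, r1)
    }
    t2 <- rep(0.5, n)
    hasR <- R > 0L
    if (any(hasR)) {
      gR <- geno[cbind(which(hasR), R[hasR])]
      r2 <- cm_to_recomb(mpos[R[hasR]] - pos, fun, pil_type)
      t2[hasR] <- ifelse(gR == 2L, 1 - r2, r2)
    }
    num <- t1 * t2
    P[, t] <- num / (num + (1 - t1) * (1 - t2))
  }
  P
}

# Class priors over genotype codes (2, 1, 0) for one population at one
# position, from the parental line allele probabilities p (and q for IF2).
population_priors <- function(kind, p, q = NULL) {
  switch(kind,
    PIL = cbind(p, 0, 1 - p),
    IB1 = cbind(p, 1 - p, 0),
    IB2 = cbind(0, p, 1 - p),
    IF2 = {
      if (is.null(q)) stop("IF2 priors need both parents' probabilities")
      cbind(p * q, p * (1 - q) + q * (1 - p), (1 - p) * (1 - q))
    },
    stop("unknown population kind: ", kind)
  )
}

#' QTL genotype priors at a scan position
#'
#' Probability of each QTL genotype class (codes 2, 1, 0) for every
#' individual of a population, conditional on the nearest non-missing
#' flanking markers of the underlying pure lines.  Pure lines have classes
#' \{2, 0\}; IB1 hybrids \{2, 1\}; IB2 hybrids \{1, 0\}; IF2 hybrids all
#' three, as the product over the two parental gametes.
#'
#' @param pil normalized pure-line genotype matrix (all markers).
#' @param map \code{linkage_map} matching the matrix columns.
#' @param chrom chromosome name of the scan position.
#' @param pos scan position in cM.
#' @param population "PIL", "IB1", "IB2" or "IF2".
#' @param design \code{cross_design} (needed for IF2).
#' @param pil_type "DH" or "RIL".
#' @param fun mapping function name.
#' @return numeric matrix (individuals x 3), columns for codes 2, 1, 0,
#'   rows summing to 1.
#' @export
qtl_genotype_priors <- function(pil, map, chrom, pos,
                                population = c("PIL", "IB1", "IB2", "IF2"),
                                design = NULL, pil_type = "DH", fun = "kosambi") {
  population <- match.arg(population)
  idx <- which(map$chrom == chrom)
  if (!length(idx)) stop("unknown chromosome: ", chrom)
  mpos <- map$pos[idx]
  if (pos < mpos[1] - 1e-9 || pos > mpos[length(mpos)] + 1e-9) {
    stop("position ", pos, " lies outside chromosome ", chrom)
  }
  p <- drop(line_allele_prob(pil[, idx, drop = FALSE], mpos, pos, fun, pil_type))
  pri <- if (population == "IF2") {
    i <- design$if2_pairs[, 1]
    j <- design$if2_pairs[, 2]
    population_priors("IF2", p[i], p[j])
  } else {
    population_priors(population, p)
  }
  colnames(pri) <- c("2", "1", "0")
  pri
}
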