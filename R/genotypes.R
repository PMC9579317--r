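# Genotype coding and marker diagnostics for the pure-line base population
# and the heterozygous populations deduced from it.
#
# Codes: 2 = homozygote for the first parent's allele (AA), 0 = homozygote
# for the second parent's allele (BB), 1 = heterozygote (AB), NA = missing.

GENO_CODES <- c(2L, 1L, 0L)

#' Parse marker genotype tokens
#'
#' Accepts number, letter or mixed coding: \{2, A, AA\} for the first
#' parent's homozygote, \{0, B, BB\} for the second parent's, \{1, H, AB\}
#' for heterozygotes and \{-1, X, XX, *, **\} for missing values.  Letters
#' are case-insensitive.
#'
#' @param token character vector of genotype tokens.
#' @param context optional label (marker/line identity) used in error
#'   messages.
#' @return integer vector of codes (2, 1, 0 or NA).
#' @export
parse_genotype_token <- function(token, context = NULL) {
  tok <- toupper(trimws(as.character(token)))
  out <- rep(NA_integer_, length(tok))
  out[tok %in% c("2", "A", "AA")] <- 2L
  out[tok %in% c("0", "B", "BB")] <- 0L
  out[tok %in% c("1", "H", "AB")] <- 1L
  missing_tok <- tok %in% c("-1", "X", "XX", "*", "**")
  bad <- !missing_tok & is.na(out)
  if (any(bad)) {
    where <- if (is.null(context)) "" else paste0(" at ", context[bad][1])
    stop("unrecognized genotype token '", token[bad][1], "'", where, call. = FALSE)
  }
  out
}

#' Genotype matrix constructor
#'
#' @param codes integer matrix (lines x markers) with entries in
#'   \{2, 1, 0, NA\}.
#' @param population one of "PIL", "IB1", "IB2", "IF2".
#' @return integer matrix with attributes \code{population}.
#' @export
genotype_matrix <- function(codes, population = c("PIL", "IB1", "IB2", "IF2")) {
  population <- match.arg(population)
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  ok <- is.na(codes) | codes %in% GENO_CODES
  if (!all(ok)) stop("genotype codes must be 2, 1, 0 or NA")
  attr(codes, "population") <- population
  codes
}

#' Normalize a pure-line genotype matrix
#'
#' Pure lines are homozygous by construction, so heterozygous calls are
#' genotyping artefacts and are converted to missing values.
#'
#' @param g genotype matrix of the pure-line population.
#' @return the matrix with every code 1 replaced by NA; the number of
#'   replacements is attached as attribute \code{"n_het_replaced"}.
#' @export
normalize_pil <- function(g) {
  n_het <- sum(g == 1L, na.rm = TRUE)
  g[which(g == 1L)] <- NA_integer_
  attr(g, "n_het_replaced") <- n_het
  attr(g, "population") <- "PIL"
  g
}

#' Crossing design linking pure lines to their hybrid populations
#'
#' IB1 and IB2 hybrids are the pure lines crossed to parent 1 and parent 2
#' respectively, in line order (so their sizes equal the pure-line
#' population size).  IF2 hybrids are crosses between pairs of distinct
#' pure lines.
#'
#' @param n_pil number of pure lines.
#' @param if2_pairs two-column integer matrix of (line i, line j) parent
#'   indices, or NULL for no IF2.
#' @param sampling how the pairs were drawn: "random" or "balanced" (each
#'   line appears equally often over all pair slots).
#' @return a \code{cross_design} list.
#' @export
cross_design <- function(n_pil, if2_pairs = NULL, sampling = c("random", "balanced")) {
  sampling <- match.arg(sampling)
  if (!is.null(if2_pairs)) {
    if2_pairs <- as.matrix(if2_pairs)
    if (ncol(if2_pairs) != 2) stop("if2_pairs must have two columns")
    if (any(if2_pairs < 1 | if2_pairs > n_pil)) stop("IF2 pair index out of range")
    if (any(if2_pairs[, 1] == if2_pairs[, 2])) {
      stop("IF2 pairs must cross two distinct lines (self-pairing is not a hybrid)")
    }
    if (sampling == "balanced") {
      cnt <- tabulate(as.vector(if2_pairs), nbins = n_pil)
      if (length(unique(cnt)) != 1) {
        stop("balanced design requires every line to appear equally often in IF2 pairs")
      }
    }
  }
  structure(list(n_pil = n_pil, if2_pairs = if2_pairs, sampling = sampling),
            class = "cross_design")
}

#' Deduce hybrid genotypes from pure-line genotypes
#'
#' Hybrid genotypes need not be assayed: an IB1 hybrid carries its
#' pure-line parent's allele plus the first parent's allele (so codes map
#' 2 -> 2, 0 -> 1), IB2 analogously with the second parent (0 -> 0,
#' 2 -> 1), and an IF2 hybrid combines the alleles of its two pure-line
#' parents ((2,2) -> 2, (0,0) -> 0, otherwise 1).  Missing parental calls
#' propagate to missing.
#'
#' @param pil normalized pure-line genotype matrix.
#' @param design a \code{cross_design} (needed for IF2).
#' @param target "IB1", "IB2" or "IF2".
#' @return genotype matrix of the hybrid population.
#' @export
derive_hybrid_genotypes <- function(pil, design = NULL, target = c("IB1", "IB2", "IF2")) {
  target <- match.arg(target)
  if (target == "IF2") {
    if (is.null(design) || is.null(design$if2_pairs)) {
      stop("IF2 derivation requires a cross design with if2_pairs")
    }
    gi <- pil[design$if2_pairs[, 1], , drop = FALSE]
    gj <- pil[design$if2_pairs[, 2], , drop = FALSE]
    # one allele from each homozygous parent: (2,2)->2, (0,0)->0, mixed->1
    out <- (gi + gj) %/% 2L
    rownames(out) <- NULL
  } else if (target == "IB1") {
    out <- pil
    out[pil == 0L] <- 1L            # BB x AA -> AB
  } else {
    out <- pil
    out[pil == 2L] <- 1L            # AA x BB -> AB
    out[pil == 0L] <- 0L
  }
  attr(out, "population") <- target
  attr(out, "n_het_replaced") <- NULL
  out
}

#' Per-marker summary and segregation-distortion test
#'
#' Counts the two homozygote classes, tests the observed (n2, n0) counts
#' against the 1:1 segregation expected in DH/RIL populations with a
#' 1-df Pearson chi-square, and flags markers unusable for mapping
#' (monomorphic in the observed lines).
#'
#' @param pil normalized pure-line genotype matrix.
#' @param map optional \code{linkage_map} supplying marker names/positions.
#' @return data frame with one row per marker: \code{n2, n0, n_missing,
#'   chi_square, p_value, usable}.
#' @export
marker_summary <- function(pil, map = NULL) {
  n2 <- colSums(pil == 2L, na.rm = TRUE)
  n0 <- colSums(pil == 0L, na.rm = TRUE)
  nmis <- colSums(is.na(pil))
  tot <- n2 + n0
  chi <- ifelse(tot > 0, (n2 - n0)^2 / tot, NA_real_)
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  out <- data.frame(
    marker = if (!is.null(map)) map$marker else colnames(pil) %||% paste0("M", seq_along(n2)),
    n2 = n2, n0 = n0, n_missing = nmis,
    chi_square = chi, p_value = p,
    usable = n2 > 0 & n0 > 0,
    stringsAsFactors = FALSE
  )
  if (!is.null(map)) {
    out$chrom <- map$chrom
    out$pos <- map$pos
    out <- out[, c("marker", "chrom", "pos", "n2", "n0", "n_missing",
                   "chi_square", "p_value", "usable")]
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Impute missing pure-line genotypes
#'
#' Each missing call is replaced by the most probable homozygote given the
#' nearest non-missing flanking markers on the same chromosome, using the
#' same conditional (map-function based) probabilities as the QTL
#' genotype-prior engine; ties and completely uninformative cells fall
#' back to the marker's more frequent class, with a final tie broken
#' towards code 2.  Non-missing cells are never altered.
#'
#' @param pil normalized pure-line genotype matrix.
#' @param map \code{linkage_map} matching the matrix columns.
#' @param pil_type "DH" or "RIL" (RIL recombination fractions are
#'   Haldane-Waddington expanded).
#' @param fun mapping function name.
#' @return the imputed genotype matrix (no NA left).
#' @export
impute_missing <- function(pil, map, pil_type = "DH", fun = "kosambi") {
  if (ncol(pil) != nrow(map)) stop("genotype columns must match map markers")
  out <- pil
  chroms <- unique(map$chrom)
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    sub <- pil[, idx, drop = FALSE]
    if (!anyNA(sub)) next
    p <- line_allele_prob(sub, map$pos[idx], map$pos[idx], fun, pil_type)
    freq2 <- colSums(sub == 2L, na.rm = TRUE)
    freq0 <- colSums(sub == 0L, na.rm = TRUE)
    miss <- which(is.na(sub), arr.ind = TRUE)
    pm <- p[miss]
    fill <- ifelse(pm > 0.5, 2L, ifelse(pm < 0.5, 0L, NA_integer_))
    # p == 0.5: no flanking information or exact tie -> frequency fallback
    tie <- is.na(fill)
    if (any(tie)) {
      f2 <- freq2[miss[tie, 2]]
      f0 <- freq0[miss[tie, 2]]
      fill[tie] <- ifelse(f2 >= f0, 2L, 0L)
    }
    sub[miss] <- fill
    out[, idx] <- sub
  }
  out
}

#' Pairwise marker correlations
#'
#' Pearson correlation between marker dosages (codes as numeric) over the
#' imputed pure-line matrix.  Zero-variance markers get correlation 0 with
#' a warning.
#'
#' @param pil imputed pure-line genotype matrix.
#' @return full symmetric correlation matrix (writers emit the lower
#'   triangle).
#' @export
marker_correlation <- function(pil) {
  x <- pil
  storage.mode(x) <- "double"
  sds <- apply(x, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(x))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance marker(s); correlations recorded as 0")
    cc[is.na(cc)] <- 0
  }
  diag(cc) <- 1
  cc
}
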