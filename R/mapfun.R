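#' Mapping functions
#'
#' Genetic map distance and recombination fraction are linked by a mapping
#' function.  Three classical choices are supported:
#' \describe{
#'   \item{kosambi}{\eqn{r = \tanh(2d)/2}; allows partial crossover
#'     interference.}
#'   \item{haldane}{\eqn{r = (1 - e^{-2d})/2}; no interference.}
#'   \item{morgan}{\eqn{r = \min(d, 0.5)}; complete additivity, capped at
#'     one half because r is a probability.}
#' }
#' Distances \code{d} are in Morgans.  Input files code the functions as
#' 1 = Kosambi, 2 = Haldane, 3 = Morgan.
#'
#' @param kind one of \code{"kosambi"}, \code{"haldane"}, \code{"morgan"}.
#' @return the validated function name (character scalar).
#' @seealso [map_to_recomb()], [recomb_to_map()]
#' @export
map_function <- function(kind = c("kosambi", "haldane", "morgan")) {
  match.arg(kind)
}

#' @rdname map_function
#' @param code integer code used in input files (1, 2 or 3).
#' @export
map_function_from_code <- function(code) {
  if (!code %in% 1:3) {
    stop("mapping function code must be 1 (Kosambi), 2 (Haldane) or 3 (Morgan), got ", code)
  }
  c("kosambi", "haldane", "morgan")[code]
}

#' Convert map distance to recombination fraction
#'
#' @param d map distance in Morgans (non-negative, vectorised).
#' @param fun mapping function name, see [map_function()].
#' @return recombination fraction in \[0, 0.5\].
#' @examples
#' map_to_recomb(0.10, "haldane")  # (1 - exp(-0.2))/2
#' map_to_recomb(0.10, "kosambi")  # tanh(0.2)/2
#' @export
map_to_recomb <- function(d, fun = "haldane") {
  fun <- map_function(fun)
  if (any(d < 0, na.rm = TRUE)) stop("map distance must be non-negative")
  switch(fun,
    haldane = (1 - exp(-2 * d)) / 2,
    kosambi = tanh(2 * d) / 2,
    morgan  = pmin(d, 0.5)
  )
}

#' Convert recombination fraction to map distance
#'
#' Analytic inverse of [map_to_recomb()].  For the Kosambi and Haldane
#' functions \code{r} must be strictly below 0.5 (the map distance diverges
#' at free recombination).
#'
#' @param r recombination fraction (vectorised).
#' @param fun mapping function name.
#' @return map distance in Morgans.
#' @export
recomb_to_map <- function(r, fun = "haldane") {
  fun <- map_function(fun)
  if (any(r < 0, na.rm = TRUE)) stop("recombination fraction must be non-negative")
  rmax <- if (fun == "morgan") 0.5 else 0.5 - .Machine$double.eps
  if (any(r > rmax, na.rm = TRUE)) {
    stop("recombination fraction must be < 0.5 for the ", fun, " function")
  }
  switch(fun,
    haldane = -log(1 - 2 * r) / 2,
    kosambi = atanh(2 * r) / 2,
    morgan  = r
  )
}

#' Map expansion in selfed recombinant inbred lines
#'
#' Repeated selfing gives recombinants additional opportunities to arise, so
#' the observed recombination fraction between line genotypes exceeds the
#' per-meiosis fraction.  For selfed RILs the classical
#' Haldane-Waddington result is \eqn{R = 2r / (1 + 2r)}.  Doubled-haploid
#' lines carry a single meiosis and need no adjustment.
#'
#' @param r per-meiosis recombination fraction in \[0, 0.5\] (vectorised).
#' @return line-level recombination fraction R in \[0, 0.5\].
#' @export
ril_recomb_adjust <- function(r) {
  if (any(r < 0 | r > 0.5, na.rm = TRUE)) {
    stop("recombination fraction must lie in [0, 0.5]")
  }
  2 * r / (1 + 2 * r)
}

# Recombination fraction between two map positions given in cM, at the line
# level: RIL fractions are Haldane-Waddington expanded, DH are per-meiosis.
cm_to_recomb <- function(d_cm, fun, pil_type = "DH") {
  r <- map_to_recomb(d_cm / 100, fun)
  if (pil_type == "RIL") r <- ril_recomb_adjust(r)
  r
}
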