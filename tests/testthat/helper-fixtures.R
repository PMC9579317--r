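# Shared small fixtures, built in code.

# two-marker chromosome at 10 cM: the workhorse for recombination laws
map2 <- function() linkage_map(rep("c1", 2), c("A", "B"), c(0, 10))

# one chromosome, 6 markers at 10 cM
map6 <- function() fixture_map(1, 6, 10)

# single fully additive QTL in the middle of map6
model1 <- function(a = 1, d = 0, h2 = NULL, ve = NULL) {
  qtl_model("chr1", 25, v2 = a, v1 = d, v0 = -a, h2 = h2, ve = ve)
}

# deterministic tiny PIL matrix (4 lines x 3 markers)
tiny_pil <- function() {
  genotype_matrix(rbind(c(2, 2, 0),
                        c(0, 0, 0),
                        c(2, NA, 2),
                        c(0, 2, 2)), "PIL")
}

tiny_map <- function() linkage_map(rep("c1", 3), c("m1", "m2", "m3"), c(0, 5, 12))

# brute-force two-interval gamete enumeration: P(Q = A | flank gL, gR)
# with recombination fractions r1, r2 -- the independent oracle for the
# prior engine
enum_prior <- function(gL, gR, r1, r2) {
  # enumerate gamete classes over (left, Q, right) alleles
  p <- 0
  tot <- 0
  for (qa in c(1, 0)) {
    for (la in c(1, 0)) {
      for (ra in c(1, 0)) {
        pr <- 0.5 *
          (if (la == qa) 1 - r1 else r1) *
          (if (qa == ra) 1 - r2 else r2)
        if (la == (gL == 2) && ra == (gR == 2)) {
          tot <- tot + pr
          if (qa == 1) p <- p + pr
        }
      }
    }
  }
  p / tot
}
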