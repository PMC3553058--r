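# Shared fixtures, all built in code.

# the four-codon / two-meaning translation table behind the leucine-threonine
# block of the merged genetic codes
lt_block_table <- function() {
  code_table(rep(c("CTT", "CTG", "CTA", "CTC"), each = 2),
             rep(c("L", "T"), times = 4), label = "LT_block")
}

# synthetic stand-in for a dense 16-species artificial chemistry with known
# capacity: four disjoint copies of the minimal code motif wired over
# distinct species (each motif contributes its sign-role and context-role
# code pair, 8 code pairs in total, verified against the brute-force oracle
# in test-acceptance.R).
synthetic_dense_fixture <- function() {
  rx <- list()
  for (b in 1:4) {
    s1 <- sprintf("s%da", b); s2 <- sprintf("s%db", b)
    c1 <- sprintf("c%da", b); c2 <- sprintf("c%db", b)
    m1 <- sprintf("m%da", b); m2 <- sprintf("m%db", b)
    rx <- c(rx, list(
      list(reactants = c(s1, c1), products = m1),
      list(reactants = c(s2, c1), products = m2),
      list(reactants = c(s1, c2), products = m2),
      list(reactants = c(s2, c2), products = m1)))
  }
  reaction_network(rx, name = "synthetic_dense")
}

# small CHEMKIN mechanism used by the parser tests
chemkin_fixture <- function() {
  paste(
    "! minimal synthetic mechanism",
    "ELEMENTS",
    "H O",
    "END",
    "SPECIES",
    "H2 O2 HO2 H OH O",
    "END",
    "REACTIONS",
    "H2+O2=HO2+H      1.0E13  0.0  0.0",
    "H+O2=>OH+O       2.0E14  0.0  16800.0",
    "H+O2(+M)=HO2(+M) 1.0E12  0.0  0.0",
    "LOW / 1.0E15 0.0 0.0 /",
    "H2/2.4/ O2/1.5/",
    "O+H2=OH+H        5.0E4   2.67 6290.0 ! comment",
    "END",
    sep = "\n")
}
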