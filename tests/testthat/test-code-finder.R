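grn2 <- build_grn(2)

test_that("realizes_mapping follows the context definition", {
  w <- realizes_mapping(grn2, S = c("TF1", "TF2"), M = c("P1", "P2"),
                        C = c("G11", "G22"))
  expect_identical(w$mapping, c(TF1 = "P1", TF2 = "P2"))

  # a context wiring one TF to both products is no mapping
  expect_null(realizes_mapping(grn2, c("TF1", "TF2"), c("P1", "P2"),
                               c("G11", "G12")))
  # a context that alone yields a meaning is no mapping
  expect_null(realizes_mapping(grn2, "TF1", "P1", c("TF2", "G21")))
  expect_error(realizes_mapping(grn2, c("TF1", "P1"), c("P1", "P2"), "G11"),
               "disjoint")
  expect_error(realizes_mapping(grn2, character(), "P1", "G11"), "non-empty")
})

test_that("is_code_pair finds crossed witnesses among candidate contexts", {
  motif <- build_code_motif()
  all_subsets <- unlist(lapply(0:6, function(k)
    combn(motif$species, k, simplify = FALSE)), recursive = FALSE)
  cp <- is_code_pair(motif, c("s1", "s2"), c("m1", "m2"), all_subsets)
  expect_s3_class(cp, "binary_code_pair")
  expect_identical(cp$context1, "c1")
  expect_identical(cp$context2, "c2")
  expect_identical(cp$f, c(s1 = "m1", s2 = "m2"))

  # symmetry: the canonical result ignores the order S and M are given in
  cp2 <- is_code_pair(motif, c("s2", "s1"), c("m2", "m1"), all_subsets)
  expect_identical(cp, cp2)

  # genes cannot be contingently remapped in the GRN
  grn_subsets <- unlist(lapply(0:3, function(k)
    combn(grn2$species, k, simplify = FALSE)), recursive = FALSE)
  expect_null(is_code_pair(grn2, c("G11", "G12"), c("P1", "P2"), grn_subsets))

  expect_error(is_code_pair(grn2, c("TF1", "P1"), c("P1", "P2"), list()),
               "disjoint")
  expect_error(is_code_pair(grn2, "TF1", c("P1", "P2"), list()), "exactly two")
})

test_that("find_codes_closure equals the exhaustive-context oracle", {
  set.seed(404)
  for (rep in 1:25) {
    net <- random_network(sample(5:8, 1), sample(5:24, 1), seed = 4300 + rep)
    expect_same_quads(find_codes_closure(net), oracle_codes(net))
  }
  # and on the structured fixtures
  for (net in list(build_code_motif(), grn2, build_phospho_cascade(TRUE),
                   build_translation_basic(all_mappings_table(2, 2)))) {
    expect_same_quads(find_codes_closure(net), oracle_codes(net))
  }
})

test_that("path-based results are a subset of closure results, equal at large k", {
  set.seed(405)
  for (rep in 1:10) {
    net <- random_network(7, sample(10:21, 1), seed = 4400 + rep)
    full <- report_quads(find_codes_closure(net))
    prev <- 0L
    for (k in c(1L, 3L, 30L)) {
      rp <- find_codes_paths(net, k = k)
      quads <- report_quads(rp)
      expect_true(nrow(merge(quads, full)) == nrow(quads))  # subset
      expect_gte(nrow(quads), prev)                         # monotone in k
      prev <- nrow(quads)
    }
    expect_identical(report_quads(find_codes_paths(net, k = 50L)), full)
  }
})

test_that("reports are deterministic", {
  net <- random_network(8, 18, seed = 4500)
  r1 <- find_codes_closure(net)
  r2 <- find_codes_closure(net)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  p1 <- find_codes_paths(net, k = 5)
  p2 <- find_codes_paths(net, k = 5)
  expect_identical(serialize(p1, NULL), serialize(p2, NULL))
})

test_that("semantic capacity counts deduplicated code pairs logarithmically", {
  r <- find_codes_closure(grn2)
  cap <- semantic_capacity(r)
  expect_identical(cap$n_cp, 1L)
  expect_identical(cap$L, 1)

  none <- find_codes_closure(reaction_network(species = c("A", "B")))
  expect_identical(semantic_capacity(none), list(n_cp = 0L, L = 0))
})

test_that("truncated closed-set enumeration is flagged in the report", {
  net <- random_network(8, 10, seed = 4600)
  r <- find_codes_closure(net, cap = 5L)
  expect_true(r$truncated)
  expect_identical(r$n_closed_sets, 5L)
})

test_that("merge_binary_codes links overlapping code pairs", {
  # four disjoint motifs (path finder: the 24-species closed-set lattice is
  # the product of the motif lattices and exceeds the default cap): each
  # motif contributes its sign-role and context-role pair, never linked
  # across roles (sign pairs disjoint) nor across motifs (species disjoint)
  r <- find_codes_paths(synthetic_dense_fixture(), k = 4)
  expect_identical(r$n_cp, 8L)
  merged <- merge_binary_codes(r)
  expect_length(merged, 8L)
  expect_true(all(vapply(merged, `[[`, integer(1), "n_bmc") == 1L))

  # the four-codon L/T block merges into one code of 4 signs x 2 meanings
  ltr <- find_codes_closure(build_translation_basic(lt_block_table()))
  m <- merge_binary_codes(ltr)
  expect_length(m, 1L)
  expect_identical(m[[1]]$signs, c("CTA", "CTC", "CTG", "CTT"))
  expect_identical(m[[1]]$meanings, c("L", "T"))
  expect_identical(m[[1]]$n_bmc, 6L)

  expect_identical(merge_binary_codes(find_codes_closure(
    reaction_network(species = c("A", "B")))), list())
})
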