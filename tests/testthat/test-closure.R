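test_that("closure fires reactions to the unique smallest closed superset", {
  net <- parse_reaction_list("A + B -> C")
  expect_identical(closure(net, "A"), "A")
  expect_identical(closure(net, c("A", "B")), c("A", "B", "C"))

  inflow <- parse_reaction_list("-> L\nL + X -> Y")
  expect_identical(closure(inflow, character()), "L")
  expect_identical(closure(inflow, "X"), c("L", "X", "Y"))

  expect_error(closure(net, "Z"), "unknown seed")
})

test_that("is_closed matches the definition", {
  net <- parse_reaction_list("A + B -> C")
  expect_false(is_closed(net, c("A", "B")))
  expect_true(is_closed(net, c("A", "C")))
  expect_true(is_closed(net, net$species))
  expect_true(is_closed(net, character()))
  # closures are closed, for arbitrary seeds
  for (seed in 1:10) {
    rnet <- random_network(8, 14, seed = seed)
    sub <- sample(rnet$species, 3)
    expect_true(is_closed(rnet, closure(rnet, sub)))
  }
})

test_that("closure is extensive, monotone and idempotent", {
  set.seed(401)
  for (rep in 1:20) {
    net <- random_network(sample(5:9, 1), sample(5:20, 1), seed = 4000 + rep)
    X <- sample(net$species, sample(0:3, 1))
    Y <- union(X, sample(net$species, sample(1:3, 1)))
    cX <- closure(net, X)
    cY <- closure(net, Y)
    expect_true(all(X %in% cX))                      # extensive
    expect_true(all(cX %in% cY))                     # monotone
    expect_identical(closure(net, cX), cX)           # idempotent
  }
})

test_that("closure(C u {s}) equals closure(closure(C) u {s})", {
  # the lemma that justifies searching contexts over closed sets only
  set.seed(402)
  for (rep in 1:20) {
    net <- random_network(7, 15, seed = 4100 + rep)
    C <- sample(net$species, sample(0:4, 1))
    s <- sample(net$species, 1)
    expect_identical(closure(net, c(C, s)),
                     closure(net, union(closure(net, C), s)))
  }
})

test_that("enumerate_closed_sets equals the brute-force subset filter", {
  net <- parse_reaction_list("A + B -> C")
  en <- enumerate_closed_sets(net)
  expect_identical(en$n_closed, 7L)
  expect_false(en$truncated)

  free <- reaction_network(species = c("u", "v", "w"))  # no reactions
  expect_identical(enumerate_closed_sets(free)$n_closed, 8L)

  for (seed in 1:8) {
    rnet <- random_network(sample(5:8, 1), sample(4:16, 1), seed = 500 + seed)
    en <- enumerate_closed_sets(rnet)
    oracle <- oracle_closed_sets(rnet)
    expect_false(en$truncated)
    expect_identical(en$n_closed, length(oracle))
    key <- function(sets) sort(vapply(sets, paste, character(1), collapse = ","))
    expect_identical(key(en$sets), key(oracle))
  }
})

test_that("each closed set appears exactly once, in lectic order, capped", {
  net <- random_network(7, 10, seed = 99)
  en <- enumerate_closed_sets(net)
  keys <- vapply(en$sets, paste, character(1), collapse = ",")
  expect_false(anyDuplicated(keys) > 0L)

  capped <- enumerate_closed_sets(net, cap = 3L)
  expect_identical(capped$n_closed, 3L)
  expect_true(capped$truncated)
  expect_identical(capped$sets, en$sets[1:3])
})

test_that("single-molecule closures cover every species", {
  grn <- build_grn(2)
  sm <- single_molecule_closures(grn)
  expect_identical(length(sm), length(grn$species))
  expect_identical(sm$TF1, "TF1")    # a lone transcription factor is inert

  loop <- parse_reaction_list("A -> B\nB -> A")
  expect_identical(single_molecule_closures(loop)$A, c("A", "B"))
})

test_that("the generic engine (> 30 species) agrees with the mask engine", {
  # a 36-species production chain: closed sets are exactly the suffixes
  chain <- parse_reaction_list(
    paste(sprintf("X%02d -> X%02d", 1:35, 2:36), collapse = "\n"))
  expect_identical(length(chain$species), 36L)
  expect_identical(closure(chain, "X34"), c("X34", "X35", "X36"))
  en <- enumerate_closed_sets(chain, cap = 100L)
  expect_identical(en$n_closed, 37L)   # 36 suffixes plus the empty set
  expect_false(en$truncated)

  # same small network through both engines
  net <- random_network(8, 12, seed = 77)
  idx <- molcode:::.net_index(net)
  masks <- molcode:::.enumerate_masks(idx, 100000L)
  gen <- molcode:::.enumerate_generic(idx, 100000L)
  mask_sets <- lapply(masks, function(m) molcode:::.mask_members(idx, m))
  expect_identical(mask_sets, lapply(gen, identity))
})
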