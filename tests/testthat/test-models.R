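test_that("code tables validate their alphabet", {
  expect_error(code_table("CTX", "L"), "invalid codon")
  expect_error(code_table("CTT", "Leu"), "invalid meaning")
  tb <- code_table(c("CTT", "CTT"), c("L", "T"))
  expect_identical(tb$entries$CTT, c("L", "T"))
})

test_that("the packaged genetic code tables are the classic seventeen", {
  tabs <- genetic_code_tables()
  expect_length(tabs, 17L)
  std <- tabs[[1]]
  expect_length(std$entries, 64L)
  expect_identical(std$entries$TGG, "W")
  expect_identical(std$entries$TAA, "Stop")
  # vertebrate mitochondrial reassignments present
  vert <- tabs[[2]]
  expect_identical(vert$entries$AGA, "Stop")
  expect_identical(vert$entries$TGA, "W")
})

test_that("basic translation networks wire codon + tRNA -> meaning", {
  net <- build_translation_basic(code_table("AAA", "K"))
  expect_identical(net$species, c("AAA", "K", "tRNA_AAA_K"))
  expect_length(net$reactions, 1L)
  r <- net$reactions[[1]]
  expect_identical(r$reactants, c("AAA", "tRNA_AAA_K"))
  expect_identical(r$products, c("AAA", "K", "tRNA_AAA_K"))

  # merging tables merges assignments without duplication
  two <- build_translation_basic(list(code_table("AAA", "K"),
                                      code_table(c("AAA", "AAG"), c("K", "K"))))
  expect_length(two$reactions, 2L)
})

test_that("the four-codon L/T block realizes six code pairs", {
  r <- find_codes_closure(build_translation_basic(lt_block_table()))
  expect_identical(r$n_cp, 6L)
  quads <- report_quads(r)
  expect_true(all(quads$m1 == "L" & quads$m2 == "T"))
  expect_identical(sort(unique(c(quads$s1, quads$s2))),
                   c("CTA", "CTC", "CTG", "CTT"))
})

test_that("closed-form code counts match enumeration on small models", {
  # basic all-mappings model: choose(nc,2) * choose(na,2)
  for (nc in 1:3) {
    for (na in 1:3) {
      want <- count_codes_basic(nc, na)
      net <- build_translation_basic(all_mappings_table(nc, na))
      got <- if (nc <= 2 && na <= 2) find_codes_closure(net)$n_cp
             else find_codes_paths(net, k = 4)$n_cp
      expect_identical(as.numeric(got), want,
                       label = sprintf("basic %dx%d", nc, na))
    }
  }
  expect_identical(count_codes_basic(1, 20), 0)
  expect_identical(count_codes_basic(64, 20), 383040)
  expect_error(count_codes_basic(-1, 2), "non-negative")

  # synthetase model: (choose(2 nc, 2) - nc) * choose(na, 2) counts the
  # codes of the codon / unloaded-tRNA sign system (with >= 3 amino acids
  # the full network realizes further codes, e.g. with loaded tRNAs as
  # signs, because reloading can produce amino acids outside a 2-element
  # codomain; see the methods vignette). Path-based finder here: the
  # closed-set counts of these networks explode beyond 2x2.
  for (nc in 1:3) {
    for (na in 1:3) {
      want <- count_codes_aars(nc, na)
      net <- build_translation_aars(nc, na)
      classic <- c(names(all_mappings_table(max(nc, 1), 1)$entries)[seq_len(nc)],
                   grep("^tRNA_[^.]+$", net$species, value = TRUE))
      quads <- report_quads(find_codes_paths(net, k = 3))
      got <- sum(quads$s1 %in% classic & quads$s2 %in% classic)
      expect_identical(as.numeric(got), want,
                       label = sprintf("aars %dx%d", nc, na))
      # no codon is ever paired with its own tRNA
      expect_false(any(quads$s1 %in% classic & quads$s2 %in% classic &
                       paste0("tRNA_", quads$s1) == quads$s2))
    }
  }
  # at the 2x2 anchor the full enumeration is exactly the closed form
  expect_identical(find_codes_paths(build_translation_aars(2, 2), k = 3)$n_cp, 4L)
  expect_identical(count_codes_aars(1, 5), 0)
  expect_identical(count_codes_aars(64, 20), 1532160)
})

test_that("synthetase networks have the stated size", {
  net <- build_translation_aars(2, 2, c("GGA", "AGT"), c("G", "S"))
  expect_length(net$species, 16L)
  expect_length(net$reactions, 8L)
  expect_true(all(c("tRNA_GGA", "tRNA_GGA.S", "aaRS_AGT.G", "pS") %in%
                  net$species))
  expect_error(build_translation_aars(2, 2, "GGA", c("G", "S")),
               "label vectors")
})

test_that("GRN models realize exactly the transcription-factor code", {
  net <- build_grn(2)
  expect_identical(net$species,
                   c("G11", "G12", "G21", "G22", "P1", "P2", "TF1", "TF2"))
  expect_length(net$reactions, 4L)

  r <- find_codes_closure(net)
  expect_identical(r$n_cp, 1L)
  cp <- r$code_pairs[[1]]
  expect_identical(c(cp$s1, cp$s2), c("TF1", "TF2"))
  expect_identical(c(cp$m1, cp$m2), c("P1", "P2"))
  expect_identical(sort(c(cp$context1, cp$context2)),
                   c("G11", "G12", "G21", "G22"))

  expect_identical(find_codes_closure(build_grn(1))$n_cp, 0L)

  # signs are always the transcription factors, also at n = 3
  r3 <- find_codes_closure(build_grn(3))
  expect_gt(r3$n_cp, 0L)
  quads <- report_quads(r3)
  expect_true(all(grepl("^TF", c(quads$s1, quads$s2))))
  expect_true(all(grepl("^P", c(quads$m1, quads$m2))))
})

test_that("phosphorylation cascades have no static code", {
  one <- build_phospho_cascade(two_step = FALSE)
  expect_identical(sort(one$species), c("K", "Kp", "X0"))
  expect_identical(find_codes_closure(one)$n_cp, 0L)

  two <- build_phospho_cascade(two_step = TRUE)
  expect_length(two$species, 7L)
  expect_length(two$reactions, 7L)
  expect_identical(find_codes_closure(two)$n_cp, 0L)
})

test_that("the minimal motif realizes its code pair (and its mirror)", {
  motif <- build_code_motif()
  expect_length(motif$species, 6L)
  expect_length(motif$reactions, 4L)
  r <- find_codes_closure(motif)
  quads <- report_quads(r)
  # the designed code: signs s1/s2 mapped to m1/m2 by contexts c1 vs c2
  expect_true(any(quads$s1 == "s1" & quads$s2 == "s2" &
                  quads$m1 == "m1" & quads$m2 == "m2"))
  # under set semantics the motif is symmetric in signs and contexts, so
  # the role-swapped pair {c1,c2} -> {m1,m2} is a code as well
  expect_identical(r$n_cp, 2L)
  expect_same_quads(r, oracle_codes(motif))
})
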