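# molcode

Measure the *semantic capacity* of a chemical reaction network: its ability
to implement **molecular codes** — sign→meaning mappings that are
*contingent*, i.e. fixed not by the signs and meanings themselves but by a
molecular context that could have been otherwise. The genetic code is the
paradigm: codons mean amino acids only because particular tRNAs are present,
and different adapters would realize a different mapping. `molcode` makes
this notion operational at the level of reaction networks and is aimed at
people studying biological information processing, artificial chemistries,
and origin-of-life questions ("which chemistries can carry codes at all?").

## The formalism in brief

For a network \(N = (M, R)\), the **closure** \(\mathrm{cl}(A)\) of a species
set \(A\) is the smallest closed superset of \(A\) — everything reachable by
repeatedly firing reactions whose reactants are present. A context \(C\)
realizes a mapping \(f : S \to M\) iff \(\mathrm{cl}(C) \cap M = \emptyset\)
and for each sign \(s\), \(\mathrm{cl}(C \cup \{s\}) \cap M = \{f(s)\}\).
A **binary molecular code** is a sign pair and meaning pair for which two
contexts realize the two crossed bijections

\[ C_1: s_1 \mapsto m_1,\; s_2 \mapsto m_2 \qquad
   C_2: s_1 \mapsto m_2,\; s_2 \mapsto m_1 . \]

The semantic capacity is the number \(n_{cp}\) of such code pairs, with
logarithmic form \(L = \log_2(n_{cp} + 1)\). Two detectors are provided: an
exact closure-based search over the network's closed sets, and a k-shortest-
path search that proposes contexts from the bipartite species–reaction graph
and verifies every candidate by closure.

## Worked example

The two-transcription-factor gene-regulation model: genes `Gij` fuse the
promoter recognized by `TFi` to the coding region of product `Pj`, and
expression is `TFi + Gij -> TFi + Gij + Pj`.

```r
library(molcode)
net <- build_grn(2)
find_codes_closure(net)
#> <code_report> grn_2 (closure): n_cp = 1, L = 1.000
#> <code pair> {TF1,TF2} -> {P1,P2} | C1={G11,G22} C2={G12,G21}
```

Exactly one code pair: the transcription factors are the signs, the products
the meanings, and the two complementary gene sets are the contexts — with
`{G11, G22}` present, `TF1` means `P1`; swap the promoters (`{G12, G21}`)
and the *same* signs mean the opposite products. That is contingency, and
the count says this network supports it in exactly one role assignment.

Merging the 17 classic NCBI genetic code tables into one translation network
(codon + tRNA → codon + tRNA + amino acid, one tRNA per observed assignment)
shows the genetic code itself is — weakly — contingent:

```r
net <- build_translation_basic(genetic_code_tables(), name = "merged_codes")
r <- find_codes_paths(net, k = 4)
r$n_cp
#> [1] 16
r$L
#> [1] 4.087463
```

Sixteen binary codes (e.g. the codons `CTT, CTG, CTA, CTC` crossed over
leucine/threonine — six pairs — reflecting the yeast mitochondrial
reassignment), against a theoretical maximum of
`count_codes_basic(64, 20)` = 383,040 if every codon could be read for every
amino acid: real cells use a tiny fraction of the available semantic
capacity.

Other entry points: `parse_reaction_list()` / `write_reaction_list()` for
plain-text networks and `parse_chemkin()` for mechanism files;
`enumerate_closed_sets()`; `build_translation_aars()` (translation with the
tRNA-loading step; unloaded tRNAs become signs, `count_codes_aars()` gives
the closed form); `random_network()`, `null_model_estimate()` and
`density_survey()` for the random-network null model (mean capacity is
unimodal in density, peaking near two reactions per species);
`randomize_network()` for robustness experiments; `response_curve()` and
`level_code_check()` for the concentration-level code of the two-step
phosphorylation cascade. A command-line front end is in
`inst/cli/molcode.R`. The methods vignette
(`vignettes/molecular-codes.Rmd`) documents the model, the algorithms and
all numerical conventions.

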