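---
title: "Detecting molecular codes in reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting molecular codes in reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molcode)
```

## The question

A code, in the semiotic sense, is a mapping from signs to meanings that is
*contingent*: the same signs could mean something else, and what they do mean
is fixed only by a context (the "codemaker"). The genetic code is the
canonical biological example -- codons mean amino acids only because a
particular set of tRNAs is present; with different adapters the same codons
would mean different amino acids. `molcode` implements a formal, purely
network-level criterion for this kind of contingency and uses it to measure
the *semantic capacity* of a chemistry: how many such contingent mappings a
reaction network can realize at all.

## The model

A reaction network is a pair $(M, R)$ of molecular species and reactions,
each reaction mapping a reactant species set to a product species set.
Everything here uses **set semantics**: stoichiometric coefficients are
parsed and kept (the kinetics module uses them) but ignored by the code
analysis, and species are never consumed -- what matters is reachability,
not mass balance.

A species set $C$ is **closed** iff every reaction whose reactants all lie
in $C$ has its products in $C$ too. Every set $A$ has a unique smallest
closed superset, its **closure**: fire all applicable reactions, add the
products, repeat to fixpoint. Inflow reactions (empty reactant side) fire
unconditionally, so their products belong to every closure; outflow
reactions never affect closure. `closure()`, `is_closed()` and
`enumerate_closed_sets()` implement this; enumeration uses the lectic
next-closure scheme, producing each closed set exactly once in a canonical
order, with a cap and an explicit truncation flag because sparse networks
can have exponentially many closed sets.

A context $C$ **realizes a mapping** from a domain $S$ to a codomain $M$
(disjoint from $S$) iff the context alone is mute,
$\mathrm{cl}(C) \cap M = \emptyset$, and for every sign $s \in S$ the
closure $\mathrm{cl}(C \cup \{s\})$ contains exactly one element of $M$,
the image $f(s)$. A **binary molecular code** (BMC) is a sign pair
$\{s_1, s_2\}$ and meaning pair $\{m_1, m_2\}$, pairwise disjoint, for
which two contexts exist realizing the two *crossed* bijections:
$C_1$ maps $s_1 \mapsto m_1, s_2 \mapsto m_2$ and $C_2$ maps
$s_1 \mapsto m_2, s_2 \mapsto m_1$. The pair of crossed mappings is a
**code pair**. The **semantic capacity** is the number $n_{cp}$ of
distinct code pairs; the logarithmic form is $L = \log_2(n_{cp} + 1)$, so
a network with no codes has $L = 0$.

Two counting conventions are deliberate:

* a code pair is counted once per (unordered sign pair, unordered meaning
  pair), however many context pairs witness it -- witnesses are reported,
  duplicates are not counted;
* direction matters: if $\{A,B\} \to \{C,D\}$ and $\{C,D\} \to \{A,B\}$
  both qualify they are counted separately.

## The two detection algorithms

**Closure-based** (`find_codes_closure()`). Candidate contexts may be
restricted to *closed* sets without losing any code, because
$\mathrm{cl}(C \cup \{s\}) = \mathrm{cl}(\mathrm{cl}(C) \cup \{s\})$ --
this lemma is property-tested. The finder enumerates all closed sets once,
precomputes $\mathrm{cl}(C \cup \{s\})$ for every closed set and species
(vectorized over bitmask representations for networks of at most 30
species), and then scans all sign/meaning pair combinations. It is exact,
but its cost scales with the number of closed sets, so it suits networks
whose closed-set lattice is moderate (dense networks, the models below).
If the closed-set cap is hit the report is flagged `truncated`.

**Path-based** (`find_codes_paths()`). Signs must reach meanings through
reactions, so candidate contexts can be harvested from paths in the
directed bipartite species-reaction graph. For every ordered species pair
up to `k` shortest loopless paths are collected (Yen's algorithm via
igraph, re-sorted by length then lexicographic node sequence); a path's
*context* is the union of the reactant sets along it minus the path's own
species. For a candidate code, contexts for the straight mapping are
unions of one $s_1 \to m_1$ and one $s_2 \to m_2$ path context (crossed
analogously), and every candidate is *verified with the closure operator*,
which is authoritative -- the path machinery only proposes. The result is
therefore always a subset of the closure-based result, equal once `k` is
large enough to exhaust the relevant paths; this subset/equality relation
is property-tested. Use it for networks with few paths but very many
closed sets (the merged genetic-code model, sparse large networks).

With small `k` the path finder is an approximation. In the density surveys
below the exact closure route is used by default precisely to avoid `k` as
a nuisance parameter.

## Model chemistries

`build_translation_basic()` builds the adapter-level translation model:
codons, meanings, and one tRNA per (codon, meaning) assignment, with
catalytic reading reactions
`codon + tRNA -> codon + tRNA + meaning`. Writing the reactions
catalytically is licensed because closure analysis is insensitive to
catalysis; the kinetics module is the only consumer of coefficients.
Merging several translation tables merges their assignment sets -- the
contingency visible across tables becomes alternative contexts of one
network. The 17 classic NCBI translation tables ship as plain-text package
data (`genetic_code_tables()`), with the stop signal modeled as an
ordinary meaning species `"Stop"`.

```{r}
lt <- code_table(rep(c("CTT", "CTG", "CTA", "CTC"), each = 2),
                 rep(c("L", "T"), times = 4))
find_codes_closure(build_translation_basic(lt))$n_cp
```

For the all-mappings model (every codon readable as every meaning) the
count has the closed form `count_codes_basic(n_c, n_aa)` $=
\binom{n_c}{2}\binom{n_{aa}}{2}$.

`build_translation_aars()` adds the tRNA loading step: free amino acids,
bound amino acids (the meanings), unloaded tRNAs (one per codon),
all loaded tRNAs and all synthetases, with loading reactions
`aa + tRNA + aaRS -> tRNA.aa + aaRS` and translation reactions
`codon + tRNA.aa -> codon + tRNA + bound_aa`. Here unloaded tRNAs are
signs alongside codons; the codon/own-tRNA pairs "belong together" (a
context that lets the tRNA be read must contain its codon, which then
collides with the mapping of that codon) and cannot be crossed, giving
`count_codes_aars(n_c, n_aa)` $= (\binom{2 n_c}{2} - n_c)
\binom{n_{aa}}{2}$.

A subtlety found during validation: this closed form counts the codes of
the codon/unloaded-tRNA sign system. For $n_{aa} \ge 3$ the full network
realizes *additional* codes under the formal definition -- for example
loaded tRNAs can act as signs, because translation releases the unloaded
tRNA, reloading can route it to an amino acid *outside* the two-element
codomain, and the singleton condition only inspects the codomain. With
two amino acids every bound amino acid is in the codomain, so at the
2-codon/2-amino-acid anchor the full enumeration and the closed form
coincide at 4 code pairs. The tests check exactly that: full enumeration
at the anchor, the codon/tRNA-sign subsystem against the formula up to
$3 \times 3$.

`build_grn(n)` models transcription-factor gene regulation: each gene
$G_{ij}$ fuses the promoter of $TF_i$ to the coding region of $P_j$, with
expression `TF_i + G_ij -> TF_i + G_ij + P_j`. The network realizes its
code in exactly one role assignment -- transcription factors as signs,
products as meanings, genes as contexts -- which the exhaustive oracle
confirms for small $n$:

```{r}
find_codes_closure(build_grn(2))
```

`build_code_motif()` is the smallest coding chemistry: signs $s_1, s_2$,
meanings $m_1, m_2$ and two context species wired crosswise. Note that
under set semantics this motif is perfectly symmetric in the sign and
context roles, so it realizes **two** code pairs -- the designed
$\{s_1,s_2\} \to \{m_1,m_2\}$ and its role-swapped mirror
$\{c_1,c_2\} \to \{m_1,m_2\}$. This symmetry is a real property of the
definition, verified by the brute-force oracle; breaking it requires
additional network structure (as in the gene-regulation model, where a
gene can only ever produce one specific product).

`build_phospho_cascade()` builds the one-step kinase motif (a molecular
mapping, never a code) and the two-step cascade (seven species, seven
reactions) whose code only exists at the level of concentrations -- see
below.

## The random-network null model

`random_network()` inserts `n_reactions` distinct bimolecular rules (two
distinct reactants, unordered; one product, possibly equal to a reactant)
into an empty network. Rules are drawn uniformly *without replacement*
over the $\binom{n}{2} n$ possible rules, which is distributionally the
same as rejecting duplicate redraws and exactly reproducible from the
seed. These conventions (no `A + A -> B`, product may coincide with a
reactant, duplicates forbidden) are fixed here because the source
description of the null model does not pin them down, and they shift the
null-model statistics; absolute closed-set or path means from other
implementations are therefore treated as plausibility checks, not targets.

`null_model_estimate()` reports means and standard errors of closed-set
counts, k-limited path counts and capacity over seeded replicates.
`density_survey()` runs the full factorial over sizes and densities
(reactions per species) and records where the mean capacity peaks. The
characteristic findings -- capacity is unimodal in density, and the
optimal reaction count grows like roughly twice the species count -- are
asserted in the acceptance tests as tolerance-band properties (peak
interior to the density grid, through-origin slope of $r^*$ on $n$ within
$[1.5, 2.5]$), never as exact values, and with replicate counts scaled to
the rarity of codes at each size (small networks produce codes rarely, so
they get more replicates). `randomize_network()` rewires uniformly chosen
rules while preserving each rule's reactant/product arity, which is the
robustness experiment: increasing randomization drives a structured
coding chemistry toward the (code-free) random ensemble.

## Concentration-level codes in the cascade

The two-step cascade realizes no code at the species level; its
contingency lives in concentrations. `kinetic_model()` and
`simulate_mass_action()` provide deliberately minimal mass-action
kinetics: a fixed-step fourth-order Runge-Kutta integrator (the systems
are tiny and non-stiff at the default unit rates; no implicit solver is
warranted), rate constants defaulting to 1, phosphatase steps first-order
(phosphatases and the phosphate pool are assumed buffered and are not
modeled), and a steady-state criterion of relative change below $10^{-8}$
between 90% and 100% of the time span, with non-convergence flagged
rather than raised.

`response_curve()` runs the cascade with either the A branch (active
unphosphorylated) or the B branch (active phosphorylated) present and
scans the steady-state $T_p/T$ ratio over initial $X_0$. Under the A
context the ratio decreases in $X_0$ (at unit rates the steady state is
exactly $1/(1+X_0)$, which the integrator is tested against); under the B
context it increases (exactly $X_0/(1+X_0)$). Note the two curves meet
nowhere at $X_0 = 0$ -- they start at opposite ends (1 versus 0) and
cross in between; this is what makes the high/low discretization work.
`level_code_check()` applies a user-chosen threshold (the choice is
genuinely arbitrary within the curves' range; 0.5 is a natural midpoint
at unit rates) and reports whether the two contexts realize crossed
high/low mappings -- the dynamic analogue of a code pair. Only the signs
of the trends and the crossing are asserted anywhere; exact curve shapes
depend on rate constants that the source does not specify.

## What the synthetic fixtures do and do not establish

All test inputs are built in code: the model chemistries above, seeded
random networks, and a synthetic 24-species "dense coding chemistry"
(four disjoint code motifs) standing in for an artificial chemistry whose
published network file is not available. A green randomization-trend test
on that stand-in establishes that the trend measurement behaves as
designed on a network of known capacity -- it does not reproduce any
published capacity value for the original artificial chemistry. Likewise
the null-model and survey tests establish properties of *this* package's
stated random-network conventions, not numerical agreement with surveys
run under unknown conventions.

## Numerical and design choices

* Species ids are case-sensitive tokens; writers sort species and
  reactions in C-locale order so output is byte-stable; reaction ids are
  auto-assigned `r0001, ...` where absent.
* Networks with at most 30 species use integer bitmask set
  representations throughout the hot paths; larger networks fall back to
  a generic engine (same results, property-tested against the mask
  engine).
* Path tie-breaks: length first, then lexicographic node sequence. At the
  `k` boundary among equal-length paths the selection follows igraph's
  deterministic internal order; for `k` large enough to exhaust ties this
  is immaterial, which is what all consumers rely on.
* Mechanism files in CHEMKIN format are imported structurally only
  (`SPECIES`/`REACTIONS` blocks; third bodies and rate data stripped).
  Reversible reactions are split into both directions by default; no
  thermodynamic direction selection is attempted, because no defensible
  procedure is specified for it.
* `is_code_pair()` checks candidate contexts in the order given and
  returns the first witnesses; the finders return the lectically first
  witness contexts, so reports are byte-reproducible.

## Limitations

* Codes of arity greater than two are not searched directly; larger codes
  arise only by merging binary codes (`merge_binary_codes()`), which
  links code pairs sharing a meaning pair with overlapping signs (or vice
  versa).
* Partially contingent mappings are out of scope.
* The closure finder's cost grows with the closed-set count and the path
  finder's completeness grows with `k`; for chemistries rich in both
  closed sets and paths, exact analysis is genuinely expensive.
* The analysis presumes the network models *all* possible reactions among
  its species; databases of observed reactions generally do not satisfy
  this, and the measure is only meaningful relative to that completeness
  assumption.
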