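# The 21-symbol meaning alphabet of translation models: the 20 proteinogenic
# amino acids (one-letter) plus the translation stop signal.
.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V", "Stop")

#' Construct a codon translation table
#'
#' A code table assigns meanings (amino acids or `"Stop"`) to codons.
#' `codons` and `meanings` are parallel vectors of assignments; a codon may
#' appear several times with different meanings (the table then records the
#' set).
#'
#' @param codons character vector of length-3 strings over `T`, `C`, `A`, `G`.
#' @param meanings character vector over the 20 one-letter amino-acid codes
#'   plus `"Stop"`.
#' @param label table label.
#' @return A `code_table`: list with `entries` (named list codon -> meaning
#'   set) and `label`.
#' @export
code_table <- function(codons, meanings, label = "code") {
  codons <- as.character(codons)
  meanings <- as.character(meanings)
  stopifnot(length(codons) == length(meanings), length(codons) > 0L)
  bad <- !grepl("^[TCAG]{3}$", codons)
  if (any(bad)) stop("invalid codon(s): ", paste(unique(codons[bad]), collapse = ", "),
                     call. = FALSE)
  bad <- !(meanings %in% .AA_ALPHABET)
  if (any(bad)) stop("invalid meaning symbol(s): ",
                     paste(unique(meanings[bad]), collapse = ", "), call. = FALSE)
  entries <- lapply(split(meanings, codons), function(x) .csort(x))
  entries <- entries[order(names(entries), method = "radix")]
  structure(list(entries = entries, label = as.character(label)),
            class = "code_table")
}

#' @export
print.code_table <- function(x, ...) {
  cat(sprintf("<code_table> %s: %d codons, %d assignments\n", x$label,
              length(x$entries), sum(lengths(x$entries))))
  invisible(x)
}

#' The 17 NCBI genetic code tables
#'
#' The classic list of known genetic codes (nuclear, mitochondrial and
#' plastid variants; NCBI translation tables 1-6, 9-16 and 21-23), shipped
#' as package data so the merged translation network can be built offline.
#' Stop codons are recorded with the ordinary meaning symbol `"Stop"`.
#'
#' @param path optional path to a TSV with columns `table_id`, `table_name`,
#'   `codon`, `meaning`; defaults to the packaged copy.
#' @return A named list of [code_table()] objects, one per translation table.
#' @export
genetic_code_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ncbi_genetic_codes_17.tsv",
                        package = "molcode", mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("table_id", "table_name", "codon", "meaning") %in% names(df)))
  out <- lapply(split(df, df$table_id), function(d) {
    code_table(d$codon, d$meaning,
               label = sprintf("table_%s_%s", d$table_id[1], d$table_name[1]))
  })
  out[order(as.integer(names(out)))]
}

#' All-mappings code table
#'
#' The table in which each of the first `n_codons` codons can be read for
#' each of the first `n_meanings` meanings -- the maximal-contingency
#' translation chemistry whose code-pair count is given in closed form by
#' [count_codes_basic()].
#'
#' @param n_codons,n_meanings positive counts (at most 64 and 21).
#' @return A [code_table()].
#' @export
all_mappings_table <- function(n_codons, n_meanings) {
  stopifnot(n_codons >= 1L, n_codons <= 64L, n_meanings >= 1L, n_meanings <= 21L)
  b <- c("T", "C", "A", "G")
  codons64 <- as.vector(t(outer(as.vector(t(outer(b, b, paste0))), b, paste0)))
  cods <- codons64[seq_len(n_codons)]
  aas <- .AA_ALPHABET[seq_len(n_meanings)]
  grid <- expand.grid(codon = cods, aa = aas, stringsAsFactors = FALSE)
  code_table(grid$codon, grid$aa, label = sprintf("all_%dx%d", n_codons, n_meanings))
}

#' Basic translation network from code tables
#'
#' Builds the adapter-level model of gene translation: species are the
#' codons, the meanings, and one tRNA species per distinct
#' (codon, meaning) assignment found across all tables; every assignment
#' contributes the catalytic reading reaction
#' `codon + tRNA_codon_meaning -> codon + tRNA_codon_meaning + meaning`.
#' Merging several tables merges their assignment sets, so contingent
#' alternatives present in different tables become alternative contexts of
#' one network.
#'
#' @param tables a [code_table()] or list of them.
#' @param name network name.
#' @return A [reaction_network()].
#' @examples
#' net <- build_translation_basic(code_table("AAA", "K"))
#' net$species   # AAA, K, tRNA_AAA_K
#' @export
build_translation_basic <- function(tables, name = "translation_basic") {
  if (inherits(tables, "code_table")) tables <- list(tables)
  stopifnot(length(tables) > 0L,
            all(vapply(tables, inherits, logical(1), "code_table")))
  assign_codon <- character(0)
  assign_meaning <- character(0)
  for (tb in tables) {
    for (cod in names(tb$entries)) {
      assign_codon <- c(assign_codon, rep(cod, length(tb$entries[[cod]])))
      assign_meaning <- c(assign_meaning, tb$entries[[cod]])
    }
  }
  key <- paste(assign_codon, assign_meaning)
  keep <- !duplicated(key)
  assign_codon <- assign_codon[keep]
  assign_meaning <- assign_meaning[keep]
  trna <- sprintf("tRNA_%s_%s", assign_codon, assign_meaning)
  rx <- Map(function(cod, aa, tr) {
    list(reactants = c(cod, tr), products = c(cod, tr, aa))
  }, assign_codon, assign_meaning, trna)
  reaction_network(unname(rx), name = name)
}

#' Closed-form code count of the basic all-mappings translation model
#'
#' In the basic translation model in which every codon can be read for
#' every meaning, each unordered codon pair forms a code pair with each
#' unordered meaning pair, so the number of binary molecular codes is
#' `choose(n_codons, 2) * choose(n_aa, 2)`.
#'
#' @param n_codons,n_aa non-negative counts.
#' @return The code-pair count (numeric).
#' @examples
#' count_codes_basic(64, 20)   # 383040
#' @export
count_codes_basic <- function(n_codons, n_aa) {
  if (n_codons < 0 || n_aa < 0) stop("counts must be non-negative", call. = FALSE)
  choose(n_codons, 2) * choose(n_aa, 2)
}

#' Translation network with aminoacyl-tRNA synthetases
#'
#' The refined model of gene translation that makes the tRNA loading step
#' explicit. Species: `n_codons` codons, `n_aa` free amino acids, `n_aa`
#' peptide-bound amino acids (the meanings), one unloaded tRNA per codon,
#' all `n_codons * n_aa` loaded tRNAs, and all `n_codons * n_aa`
#' synthetases. Reactions: loading
#' `aa_j + tRNA_i + aaRS_ij -> tRNA_i.aa_j + aaRS_ij` and translation
#' `codon_i + tRNA_i.aa_j -> codon_i + tRNA_i + bound_aa_j`. In this model
#' both codons and unloaded tRNAs can act as signs; the closed-form
#' code-pair count is [count_codes_aars()].
#'
#' @param n_codons,n_aa positive counts.
#' @param codon_labels,aa_labels optional label vectors of those lengths;
#'   defaults to the leading codons over `T`,`C`,`A`,`G` and the one-letter
#'   amino-acid alphabet.
#' @param name network name.
#' @return A [reaction_network()]. Bound amino acids are named `p<aa>`,
#'   unloaded tRNAs `tRNA_<codon>`, loaded tRNAs `tRNA_<codon>.<aa>`,
#'   synthetases `aaRS_<codon>.<aa>`.
#' @examples
#' net <- build_translation_aars(2, 2, c("GGA", "AGT"), c("G", "S"))
#' length(net$species)     # 16
#' length(net$reactions)   # 8
#' @export
build_translation_aars <- function(n_codons, n_aa,
                                   codon_labels = NULL, aa_labels = NULL,
                                   name = "translation_aars") {
  stopifnot(n_codons >= 1L, n_aa >= 1L)
  if (is.null(codon_labels)) {
    codon_labels <- names(all_mappings_table(n_codons, 1)$entries)
  }
  if (is.null(aa_labels)) {
    stopifnot(n_aa <= 21L)
    aa_labels <- .AA_ALPHABET[seq_len(n_aa)]
  }
  if (length(codon_labels) != n_codons || length(aa_labels) != n_aa) {
    stop("label vectors must match n_codons / n_aa", call. = FALSE)
  }
  rx <- list()
  for (i in seq_len(n_codons)) {
    tr <- sprintf("tRNA_%s", codon_labels[i])
    for (j in seq_len(n_aa)) {
      lt <- sprintf("tRNA_%s.%s", codon_labels[i], aa_labels[j])
      rs <- sprintf("aaRS_%s.%s", codon_labels[i], aa_labels[j])
      rx[[length(rx) + 1L]] <- list(reactants = c(aa_labels[j], tr, rs),
                                    products = c(lt, rs))
      rx[[length(rx) + 1L]] <- list(reactants = c(codon_labels[i], lt),
                                    products = c(codon_labels[i], tr,
                                                 paste0("p", aa_labels[j])))
    }
  }
  reaction_network(rx, name = name)
}

#' Closed-form code count of the synthetase translation model
#'
#' With the loading step modeled, the signs are the `n_codons` codons plus
#' the `n_codons` unloaded tRNAs (`n_S = 2 * n_codons`), the meanings the
#' `n_aa` bound amino acids. Every sign pair combines with every meaning
#' pair except the `n_codons` codon/own-tRNA pairs, which belong together
#' and cannot be crossed:
#' `(choose(n_S, 2) - n_codons) * choose(n_aa, 2)`.
#'
#' @inheritParams count_codes_basic
#' @return The code-pair count (numeric).
#' @examples
#' count_codes_aars(2, 2)     # 4
#' count_codes_aars(64, 20)   # 1532160
#' @export
count_codes_aars <- function(n_codons, n_aa) {
  if (n_codons < 0 || n_aa < 0) stop("counts must be non-negative", call. = FALSE)
  (choose(2 * n_codons, 2) - n_codons) * choose(n_aa, 2)
}

#' Gene regulatory network model
#'
#' Transcription-factor controlled expression as a reaction network:
#' `n` transcription factors `TF_i`, `n` products `P_j`, and all `n^2`
#' genes `G_ij` (promoter specific to `TF_i` fused to the coding region of
#' `P_j`), with the catalytic expression reactions
#' `TF_i + G_ij -> TF_i + G_ij + P_j`. The genes form the molecular
#' context: exchanging a promoter region remaps transcription factors to
#' products, which is exactly a molecular code with the TFs as signs.
#'
#' @param n number of transcription factors / products (>= 1).
#' @return A [reaction_network()]. Genes are named `G<ij>` for `n <= 9`,
#'   `G<i>_<j>` otherwise.
#' @examples
#' find_codes_closure(build_grn(2))$n_cp   # 1
#' @export
build_grn <- function(n) {
  stopifnot(n >= 1L)
  gname <- if (n <= 9L) function(i, j) sprintf("G%d%d", i, j)
           else function(i, j) sprintf("G%d_%d", i, j)
  rx <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      tf <- sprintf("TF%d", i)
      gg <- gname(i, j)
      pp <- sprintf("P%d", j)
      rx[[length(rx) + 1L]] <- list(reactants = c(tf, gg),
                                    products = c(tf, gg, pp))
    }
  }
  reaction_network(rx, name = sprintf("grn_%d", n))
}

#' Phosphorylation cascade networks
#'
#' `two_step = FALSE`: the one-step motif -- a kinase `X0` phosphorylates a
#' target kinase (`X0 + K -> X0 + Kp`, `Kp -> K`). It realizes a molecular
#' mapping but no molecular code. `two_step = TRUE`: two branch kinases sit
#' between `X0` and the target `T`; branch `A` is active unphosphorylated
#' (`A + T -> A + Tp`) while branch `B` is active phosphorylated
#' (`Bp + T -> Bp + Tp`), with `X0` phosphorylating both branches and
#' first-order dephosphorylations. Statically this network still realizes
#' no code; with concentrations (see [response_curve()]) the choice of
#' branch acts as a context that inverts the mapping from `X0` level to
#' `Tp/T` level.
#'
#' @param two_step logical.
#' @return A [reaction_network()].
#' @export
build_phospho_cascade <- function(two_step = TRUE) {
  if (!two_step) {
    return(reaction_network(list(
      list(reactants = c("X0", "K"), products = c("X0", "Kp")),
      list(reactants = "Kp", products = "K")
    ), name = "cascade_one_step"))
  }
  reaction_network(list(
    list(reactants = c("X0", "A"), products = c("X0", "Ap")),
    list(reactants = "Ap", products = "A"),
    list(reactants = c("A", "T"), products = c("A", "Tp")),
    list(reactants = c("X0", "B"), products = c("X0", "Bp")),
    list(reactants = "Bp", products = "B"),
    list(reactants = c("Bp", "T"), products = c("Bp", "Tp")),
    list(reactants = "Tp", products = "T")
  ), name = "cascade_two_step")
}

#' Minimal binary code motif
#'
#' The smallest chemistry realizing one code pair: two signs `s1`, `s2`,
#' two meanings `m1`, `m2` and two context molecules `c1`, `c2` wired so
#' that `c1` realizes the straight mapping and `c2` the crossed one:
#' `s1 + c1 -> m1`, `s2 + c1 -> m2`, `s1 + c2 -> m2`, `s2 + c2 -> m1`.
#'
#' @return A [reaction_network()] with 6 species and 4 reactions.
#' @export
build_code_motif <- function() {
  reaction_network(list(
    list(reactants = c("s1", "c1"), products = "m1"),
    list(reactants = c("s2", "c1"), products = "m2"),
    list(reactants = c("s1", "c2"), products = "m2"),
    list(reactants = c("s2", "c2"), products = "m1")
  ), name = "code_motif")
}
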