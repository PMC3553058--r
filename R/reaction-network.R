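# C-locale sort so writer output is byte-stable across locales
.csort <- function(x) sort(unique(x), method = "radix")

.reaction_signature <- function(reactants, products) {
  paste(paste(.csort(reactants), collapse = "+"), "->",
        paste(.csort(products), collapse = "+"))
}

.validate_token <- function(x, what) {
  bad <- !nzchar(x) | grepl("[[:space:]+>#:]|->", x)
  if (any(bad)) {
    stop(sprintf("invalid %s id(s): %s", what,
                 paste(sQuote(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

.make_reaction <- function(id, reactants, products,
                           r_coef = NULL, p_coef = NULL) {
  reactants <- as.character(reactants)
  products <- as.character(products)
  if (length(reactants) == 0L && length(products) == 0L) {
    stop("reaction with empty reactant and product sets", call. = FALSE)
  }
  if (is.null(r_coef)) r_coef <- rep(1L, length(reactants))
  if (is.null(p_coef)) p_coef <- rep(1L, length(products))
  names(r_coef) <- reactants
  names(p_coef) <- products
  o1 <- order(reactants, method = "radix")
  o2 <- order(products, method = "radix")
  list(id = as.character(id),
       reactants = reactants[o1], products = products[o2],
       r_coef = as.integer(r_coef[o1]), p_coef = as.integer(p_coef[o2]))
}

#' Construct a reaction network
#'
#' A reaction network is the universe the code analysis works in: a set of
#' molecular species together with a set of reactions, each mapping a
#' reactant species set to a product species set. Stoichiometric
#' coefficients are retained for the kinetics module but play no role in
#' the closure operator, which uses set semantics only.
#'
#' Reactions with an empty reactant set are inflow reactions and fire
#' unconditionally (used e.g. to model a light influx); reactions with an
#' empty product set are outflows and never affect closures. Reactions
#' with identical (reactant set, product set) signatures are collapsed.
#'
#' @param reactions a list, each element a list with character vectors
#'   `reactants` and `products` (either may be empty, not both), and
#'   optionally `id` and integer coefficient vectors `r_coef`, `p_coef`
#'   parallel to the species vectors.
#' @param species optional character vector of additional (possibly
#'   unreacting) species; the species set is the union of these and all
#'   species mentioned by reactions.
#' @param name network label.
#' @return An object of class `reaction_network` with sorted `species`,
#'   normalized `reactions` (ids `r0001`, ... assigned where missing) and
#'   `name`.
#' @examples
#' net <- reaction_network(list(list(reactants = c("A", "B"), products = "C")))
#' net$species
#' @export
reaction_network <- function(reactions = list(), species = character(),
                             name = "network") {
  stopifnot(is.list(reactions), is.character(species))
  rx <- vector("list", length(reactions))
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    rx[[i]] <- .make_reaction(if (is.null(r$id)) NA_character_ else r$id,
                              r$reactants, r$products, r$r_coef, r$p_coef)
  }
  sigs <- vapply(rx, function(r) .reaction_signature(r$reactants, r$products),
                 character(1))
  rx <- rx[!duplicated(sigs)]
  sigs <- sigs[!duplicated(sigs)]
  o <- order(sigs, method = "radix")
  rx <- rx[o]
  auto <- sprintf("r%04d", seq_along(rx))
  for (i in seq_along(rx)) {
    if (is.na(rx[[i]]$id)) rx[[i]]$id <- auto[i]
  }
  ids <- vapply(rx, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  all_sp <- .csort(c(species,
                     unlist(lapply(rx, function(r) c(r$reactants, r$products)),
                            use.names = FALSE)))
  .validate_token(all_sp, "species")
  structure(list(species = all_sp, reactions = rx, name = as.character(name)),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %s: %d species, %d reactions\n",
              x$name, length(x$species), length(x$reactions)))
  invisible(x)
}

#' @export
format.reaction_network <- function(x, ...) {
  sprintf("%s (%d species, %d reactions)", x$name,
          length(x$species), length(x$reactions))
}

.check_species <- function(network, ids, arg = "species") {
  ids <- as.character(ids)
  unknown <- setdiff(ids, network$species)
  if (length(unknown)) {
    stop(sprintf("unknown %s in network '%s': %s", arg, network$name,
                 paste(sQuote(unknown), collapse = ", ")), call. = FALSE)
  }
  ids
}

.format_side <- function(sp, coef) {
  if (length(sp) == 0L) return("")
  term <- ifelse(coef > 1L, paste(coef, sp), sp)
  paste(term, collapse = " + ")
}

# ---- reaction-list text format (".rxn") -------------------------------------

.parse_side <- function(txt, lineno) {
  txt <- trimws(txt)
  if (!nzchar(txt)) return(list(species = character(), coef = integer()))
  if (grepl("^\\+|\\+$", txt)) {
    stop(sprintf("line %d: dangling '+'", lineno), call. = FALSE)
  }
  terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  if (any(!nzchar(terms))) {
    stop(sprintf("line %d: empty '+' term", lineno), call. = FALSE)
  }
  sp <- character(length(terms))
  coef <- integer(length(terms))
  for (i in seq_along(terms)) {
    m <- regmatches(terms[i], regexec("^([0-9]+)[[:space:]]+(.+)$", terms[i]))[[1]]
    if (length(m) == 3L) {
      coef[i] <- as.integer(m[2])
      sp[i] <- m[3]
    } else {
      coef[i] <- 1L
      sp[i] <- terms[i]
    }
    if (grepl("[[:space:]]", sp[i])) {
      stop(sprintf("line %d: species token contains whitespace: '%s'",
                   lineno, sp[i]), call. = FALSE)
    }
  }
  # repeated species on a side accumulate their coefficients
  agg <- tapply(coef, sp, sum)
  list(species = names(agg), coef = as.integer(agg))
}

#' Parse a plain-text reaction list
#'
#' Reads the simple line-oriented reaction format: one reaction per line,
#' `"[label :] LHS -> RHS"`, where each side is a `+`-separated list of
#' species terms with optional integer coefficients (e.g. `"2 H + O -> H2O"`).
#' Lines starting with `#` are comments; `# species: A B C` declares species
#' that appear in no reaction. An empty left-hand side denotes an inflow
#' reaction, an empty right-hand side an outflow.
#'
#' @param text a character scalar (possibly multi-line), a character vector
#'   of lines, or a file path to read.
#' @param name network name; defaults to a name found in a `# network:`
#'   header comment, else `"network"`.
#' @return A normalized [reaction_network()].
#' @seealso [write_reaction_list()] for the byte-stable inverse.
#' @examples
#' parse_reaction_list("A + B -> C")
#' parse_reaction_list("-> hv")   # inflow
#' @export
parse_reaction_list <- function(text, name = NULL) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  declared <- character()
  rx <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#+", "", ln))
      if (grepl("^network:", body)) {
        if (is.null(name)) name <- trimws(sub("^network:", "", body))
      } else if (grepl("^species:", body)) {
        declared <- c(declared,
                      strsplit(trimws(sub("^species:", "", body)),
                               "[[:space:],]+")[[1]])
      }
      next
    }
    if (!grepl("->", ln, fixed = TRUE)) {
      stop(sprintf("line %d: no '->' found in '%s'", i, ln), call. = FALSE)
    }
    label <- NA_character_
    head <- sub("->.*$", "", ln)
    if (grepl(":", head, fixed = TRUE)) {
      label <- trimws(sub(":.*$", "", ln))
      ln <- trimws(sub("^[^:]*:", "", ln))
      if (!nzchar(label)) stop(sprintf("line %d: empty label", i), call. = FALSE)
    }
    parts <- strsplit(ln, "->", fixed = TRUE)[[1]]
    if (length(parts) > 2L) {
      stop(sprintf("line %d: more than one '->'", i), call. = FALSE)
    }
    lhs <- .parse_side(parts[1], i)
    rhs <- .parse_side(if (length(parts) == 2L) parts[2] else "", i)
    if (length(lhs$species) == 0L && length(rhs$species) == 0L) {
      stop(sprintf("line %d: reaction with both sides empty", i), call. = FALSE)
    }
    rx[[length(rx) + 1L]] <- list(id = label,
                                  reactants = lhs$species, r_coef = lhs$coef,
                                  products = rhs$species, p_coef = rhs$coef)
  }
  reaction_network(rx, species = declared,
                   name = if (is.null(name)) "network" else name)
}

#' Write a reaction network as a plain-text reaction list
#'
#' The output is canonical: species and reactions are sorted in C-locale
#' order, so writing the same network always yields byte-identical text and
#' `parse_reaction_list(write_reaction_list(net))` is the identity on
#' normalized networks.
#'
#' @param network a [reaction_network()].
#' @param file optional path; when given the text is also written there.
#' @return The reaction-list text, invisibly when `file` is given.
#' @export
write_reaction_list <- function(network, file = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  header <- c(sprintf("# network: %s", network$name),
              sprintf("# species: %s", paste(network$species, collapse = " ")))
  body <- vapply(network$reactions, function(r) {
    sprintf("%s: %s -> %s", r$id,
            .format_side(r$reactants, r$r_coef),
            .format_side(r$products, r$p_coef))
  }, character(1))
  txt <- paste0(paste(c(header, body), collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(sub("\n$", "", txt), file)
    return(invisible(txt))
  }
  txt
}

# ---- CHEMKIN-II mechanism files ---------------------------------------------

.chemkin_block <- function(lines, keyword) {
  up <- toupper(trimws(lines))
  start <- which(up == keyword | startsWith(up, paste0(keyword, " ")))
  if (!length(start)) return(NULL)
  start <- start[1]
  ends <- which(up == "END" & seq_along(up) > start)
  if (!length(ends)) stop(sprintf("CHEMKIN %s block has no END", keyword),
                          call. = FALSE)
  block <- lines[(start):(ends[1] - 1L)]
  block[1] <- sub(sprintf("^\\s*%s", keyword), "", block[1], ignore.case = TRUE)
  block
}

.chemkin_side <- function(txt, lineno) {
  txt <- gsub("\\(\\+\\s*[Mm]\\)", "", txt)      # pressure dependence (+M)
  terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  terms <- terms[nzchar(terms)]
  terms <- terms[toupper(terms) != "M"]          # third body
  sp <- character(0)
  coef <- integer(0)
  for (t in terms) {
    m <- regmatches(t, regexec("^([0-9]+)(.*)$", t))[[1]]
    if (length(m) == 3L && nzchar(m[3])) {
      sp <- c(sp, m[3]); coef <- c(coef, as.integer(m[2]))
    } else {
      sp <- c(sp, t); coef <- c(coef, 1L)
    }
  }
  if (length(sp)) {
    agg <- tapply(coef, sp, sum)
    list(species = names(agg), coef = as.integer(agg))
  } else list(species = character(), coef = integer())
}

#' Parse a CHEMKIN-II mechanism into a reaction network
#'
#' Only the `SPECIES` and `REACTIONS` blocks are read. Arrhenius and
#' thermodynamic numbers, third bodies (`+M`) and pressure-dependence
#' markers (`(+M)`) are stripped. Reversible reactions (`=` or `<=>`) are
#' split into both directions under `reversible_mode = "split_both"`
#' (the default -- no thermodynamic direction selection is attempted) or
#' kept forward-only; `=>` reactions are always one directed reaction.
#'
#' @param text character scalar/vector of mechanism text or a file path.
#' @param reversible_mode `"split_both"` or `"forward_only"`.
#' @param name network name.
#' @return A [reaction_network()].
#' @export
parse_chemkin <- function(text, reversible_mode = c("split_both", "forward_only"),
                          name = "chemkin") {
  reversible_mode <- match.arg(reversible_mode)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("!.*$", "", lines)                # CHEMKIN comments
  spec_block <- .chemkin_block(lines, "SPECIES")
  rxn_block <- .chemkin_block(lines, "REACTIONS")
  if (is.null(rxn_block)) stop("missing REACTIONS block", call. = FALSE)
  species <- if (is.null(spec_block)) character() else
    unlist(strsplit(trimws(spec_block), "[[:space:]]+"), use.names = FALSE)
  species <- species[nzchar(species)]
  aux <- c("LOW", "TROE", "SRI", "REV", "PLOG", "DUPLICATE", "DUP", "FORD", "RORD")
  rx <- list()
  for (i in seq_along(rxn_block)) {
    ln <- trimws(rxn_block[i])
    if (!nzchar(ln)) next
    first <- toupper(strsplit(ln, "[[:space:]/]+")[[1]][1])
    if (first %in% aux || grepl("^[A-Za-z0-9*()]+/", ln)) next  # aux/efficiency line
    if (!grepl("=", ln, fixed = TRUE)) next
    eqn <- strsplit(ln, "[[:space:]]+")[[1]][1]
    reversible <- TRUE
    if (grepl("<=>", eqn, fixed = TRUE)) {
      sides <- strsplit(eqn, "<=>", fixed = TRUE)[[1]]
    } else if (grepl("=>", eqn, fixed = TRUE)) {
      sides <- strsplit(eqn, "=>", fixed = TRUE)[[1]]
      reversible <- FALSE
    } else {
      sides <- strsplit(eqn, "=", fixed = TRUE)[[1]]
    }
    if (length(sides) != 2L) {
      stop(sprintf("REACTIONS line %d: cannot parse '%s'", i, eqn), call. = FALSE)
    }
    lhs <- .chemkin_side(sides[1], i)
    rhs <- .chemkin_side(sides[2], i)
    if (length(species)) {
      unknown <- setdiff(c(lhs$species, rhs$species), species)
      if (length(unknown)) {
        stop(sprintf("REACTIONS line %d: species not declared in SPECIES block: %s",
                     i, paste(unknown, collapse = ", ")), call. = FALSE)
      }
    }
    rx[[length(rx) + 1L]] <- list(reactants = lhs$species, r_coef = lhs$coef,
                                  products = rhs$species, p_coef = rhs$coef)
    if (reversible && reversible_mode == "split_both") {
      rx[[length(rx) + 1L]] <- list(reactants = rhs$species, r_coef = rhs$coef,
                                    products = lhs$species, p_coef = lhs$coef)
    }
  }
  reaction_network(rx, species = species, name = name)
}
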