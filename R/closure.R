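# Internal index over a network: integer species ids, reaction index sets and
# (for networks with <= 30 species) bitmask encodings used by the hot loops.
.net_index <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  sp <- network$species
  n <- length(sp)
  spmap <- seq_len(n)
  names(spmap) <- sp
  r_idx <- lapply(network$reactions, function(r) unname(spmap[r$reactants]))
  p_idx <- lapply(network$reactions, function(r) unname(spmap[r$products]))
  idx <- list(n = n, species = sp, spmap = spmap,
              r_idx = r_idx, p_idx = p_idx,
              use_mask = n <= 30L)
  if (idx$use_mask) {
    bits <- bitwShiftL(1L, 0:(max(n, 1L) - 1L))
    idx$bits <- bits
    idx$rmask <- vapply(r_idx, function(i) {
      m <- 0L
      for (b in i) m <- bitwOr(m, bits[b])
      m
    }, integer(1))
    idx$pmask <- vapply(p_idx, function(i) {
      m <- 0L
      for (b in i) m <- bitwOr(m, bits[b])
      m
    }, integer(1))
  }
  idx
}

.mask_of <- function(idx, members) {
  m <- 0L
  for (b in members) m <- bitwOr(m, idx$bits[b])
  m
}

.mask_members <- function(idx, mask) {
  which(bitwAnd(mask, idx$bits[seq_len(idx$n)]) != 0L)
}

# closure of a single bitmask
.closure_mask <- function(mask, idx) {
  rmask <- idx$rmask
  pmask <- idx$pmask
  repeat {
    fire <- bitwAnd(mask, rmask) == rmask
    new <- mask
    if (any(fire)) new <- Reduce(bitwOr, pmask[fire], mask)
    if (new == mask) return(mask)
    mask <- new
  }
}

# element-wise closure of a whole vector of bitmasks (vectorized fixpoint)
.closure_masks <- function(masks, idx) {
  rmask <- idx$rmask
  pmask <- idx$pmask
  repeat {
    new <- masks
    for (j in seq_along(rmask)) {
      f <- bitwAnd(new, rmask[j]) == rmask[j]
      if (any(f)) new[f] <- bitwOr(new[f], pmask[j])
    }
    if (identical(new, masks)) return(masks)
    masks <- new
  }
}

# closure over integer index sets, no size limit
.closure_generic <- function(members, idx) {
  inset <- logical(idx$n)
  inset[members] <- TRUE
  nr <- length(idx$r_idx)
  done <- logical(nr)
  repeat {
    changed <- FALSE
    for (j in seq_len(nr)) {
      if (done[j]) next
      if (all(inset[idx$r_idx[[j]]])) {
        done[j] <- TRUE
        pj <- idx$p_idx[[j]]
        if (!all(inset[pj])) {
          inset[pj] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) return(which(inset))
  }
}

.closure_members <- function(members, idx) {
  if (idx$use_mask) .mask_members(idx, .closure_mask(.mask_of(idx, members), idx))
  else .closure_generic(members, idx)
}

#' Closure of a species set
#'
#' The closure of a seed set `A` is the unique smallest closed superset of
#' `A`: all reactions whose reactants are fully present are fired (inflow
#' reactions fire unconditionally) and their products added, until a
#' fixpoint is reached. Intuitively it is everything reachable from `A` by
#' arbitrary reaction paths among the present species. Stoichiometric
#' coefficients are ignored (set semantics).
#'
#' @param network a [reaction_network()].
#' @param seed character vector of species ids (may be empty).
#' @return Character vector of species, sorted.
#' @examples
#' net <- parse_reaction_list("A + B -> C")
#' closure(net, "A")          # {A}: B missing, nothing fires
#' closure(net, c("A", "B"))  # {A,B,C}
#' @export
closure <- function(network, seed = character()) {
  idx <- .net_index(network)
  seed <- .check_species(network, seed, "seed species")
  idx$species[.closure_members(unname(idx$spmap[seed]), idx)]
}

#' Test whether a species set is closed
#'
#' A set `C` is closed iff every reaction whose reactants all lie in `C`
#' has all its products in `C` as well (inflow products must always be
#' present; outflow reactions never violate closedness).
#'
#' @inheritParams closure
#' @param candidate character vector of species ids.
#' @return `TRUE` or `FALSE`.
#' @export
is_closed <- function(network, candidate = character()) {
  idx <- .net_index(network)
  candidate <- .check_species(network, candidate, "candidate species")
  inset <- logical(idx$n)
  inset[idx$spmap[candidate]] <- TRUE
  for (j in seq_along(idx$r_idx)) {
    if (all(inset[idx$r_idx[[j]]]) && !all(inset[idx$p_idx[[j]]])) return(FALSE)
  }
  TRUE
}

# ---- lectic ("next-closure") enumeration ------------------------------------

# mask variant; returns integer vector of closed-set masks, attr truncated
.enumerate_masks <- function(idx, cap) {
  out <- integer(0)
  grow <- function(v, x) c(v, x)   # amortized append below instead
  buf <- integer(1024L)
  cnt <- 0L
  truncated <- FALSE
  A <- .closure_mask(0L, idx)
  n <- idx$n
  bits <- idx$bits
  repeat {
    cnt <- cnt + 1L
    if (cnt > length(buf)) buf <- c(buf, integer(length(buf)))
    buf[cnt] <- A
    if (cnt >= cap) {
      # is there anything beyond the cap?
      truncated <- !is.null(.next_closed_mask(A, idx))
      break
    }
    nxt <- .next_closed_mask(A, idx)
    if (is.null(nxt)) break
    A <- nxt
  }
  structure(buf[seq_len(cnt)], truncated = truncated)
}

.next_closed_mask <- function(A, idx) {
  n <- idx$n
  bits <- idx$bits
  for (i in n:1) {
    if (bitwAnd(A, bits[i]) != 0L) next
    below <- bits[i] - 1L
    B <- .closure_mask(bitwOr(bitwAnd(A, below), bits[i]), idx)
    if (bitwAnd(bitwAnd(B, below), bitwNot(A)) == 0L) return(B)
  }
  NULL
}

# generic variant for networks with > 30 species; sets as logical vectors
.enumerate_generic <- function(idx, cap) {
  n <- idx$n
  cl <- function(members) .closure_generic(members, idx)
  nxt <- function(A) {          # A: sorted integer vector
    inA <- logical(n)
    inA[A] <- TRUE
    for (i in n:1) {
      if (inA[i]) next
      B <- cl(c(A[A < i], i))
      if (!any(B < i & !inA[B])) return(B)
    }
    NULL
  }
  out <- vector("list", 1024L)
  cnt <- 0L
  truncated <- FALSE
  A <- cl(integer(0))
  repeat {
    cnt <- cnt + 1L
    if (cnt > length(out)) out <- c(out, vector("list", length(out)))
    out[[cnt]] <- A
    if (cnt >= cap) {
      truncated <- !is.null(nxt(A))
      break
    }
    nn <- nxt(A)
    if (is.null(nn)) break
    A <- nn
  }
  structure(out[seq_len(cnt)], truncated = truncated)
}

#' Enumerate all closed species sets
#'
#' Produces every closed set of the network exactly once, in lectic
#' (next-closure) order over the sorted species alphabet. The number of
#' closed sets can grow exponentially with network sparseness, so
#' enumeration stops at `cap` sets and flags truncation instead of failing.
#'
#' @inheritParams closure
#' @param cap maximum number of closed sets to produce (>= 1).
#' @return A list with elements `sets` (list of character vectors),
#'   `n_closed` (number produced) and `truncated` (`TRUE` if the cap was
#'   hit before exhaustion), of class `closed_sets`.
#' @examples
#' enumerate_closed_sets(parse_reaction_list("A + B -> C"))$n_closed  # 7
#' @export
enumerate_closed_sets <- function(network, cap = 100000L) {
  stopifnot(cap >= 1L)
  idx <- .net_index(network)
  if (idx$use_mask) {
    masks <- .enumerate_masks(idx, cap)
    sets <- lapply(masks, function(m) idx$species[.mask_members(idx, m)])
    truncated <- attr(masks, "truncated")
  } else {
    mem <- .enumerate_generic(idx, cap)
    sets <- lapply(mem, function(m) idx$species[m])
    truncated <- attr(mem, "truncated")
  }
  structure(list(sets = sets, n_closed = length(sets), truncated = truncated),
            class = "closed_sets")
}

#' @export
print.closed_sets <- function(x, ...) {
  cat(sprintf("<closed_sets> %d closed sets%s\n", x$n_closed,
              if (x$truncated) " (truncated at cap)" else ""))
  invisible(x)
}

#' Closures generated by single species
#'
#' For each species `s` of the network, the closed set generated by `s`
#' alone, i.e. `closure(network, s)`. These single-molecule closures are
#' the domain/codomain building blocks of the closure-based code finder.
#'
#' @inheritParams closure
#' @return A named list mapping each species id to a character vector.
#' @export
single_molecule_closures <- function(network) {
  idx <- .net_index(network)
  out <- lapply(seq_len(idx$n),
                function(i) idx$species[.closure_members(i, idx)])
  names(out) <- idx$species
  out
}
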