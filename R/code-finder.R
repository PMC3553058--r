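# A binary molecular code pair: signs {s1,s2}, meanings {m1,m2}, and two
# witness contexts. context1 realizes f = {s1 -> m1, s2 -> m2}; context2
# realizes the crossed mapping {s1 -> m2, s2 -> m1}. Conditions:
#   (i)   closure(C1 u {s1}) n M = {m1},  closure(C1 u {s2}) n M = {m2}
#   (ii)  closure(C2 u {s1}) n M = {m2},  closure(C2 u {s2}) n M = {m1}
#   (iii) closure(C1) n M = closure(C2) n M = {}   (a context alone is mute)
#   (iv)  s1 != s2, m1 != m2, {s1,s2} n {m1,m2} = {}
.new_code_pair <- function(s1, s2, m1, m2, context1, context2) {
  structure(list(s1 = s1, s2 = s2, m1 = m1, m2 = m2,
                 context1 = context1, context2 = context2,
                 f = stats::setNames(c(m1, m2), c(s1, s2))),
            class = "binary_code_pair")
}

#' @export
print.binary_code_pair <- function(x, ...) {
  cat(sprintf("<code pair> {%s,%s} -> {%s,%s} | C1={%s} C2={%s}\n",
              x$s1, x$s2, x$m1, x$m2,
              paste(x$context1, collapse = ","),
              paste(x$context2, collapse = ",")))
  invisible(x)
}

.new_code_report <- function(code_pairs, method, k = NULL, truncated = FALSE,
                             n_closed_sets = NULL, n_paths = NULL,
                             network_name = "network") {
  n_cp <- length(code_pairs)
  structure(list(code_pairs = code_pairs, n_cp = n_cp, L = log2(n_cp + 1),
                 method = method, k = k, truncated = truncated,
                 n_closed_sets = n_closed_sets, n_paths = n_paths,
                 network = network_name),
            class = "code_report")
}

#' @export
print.code_report <- function(x, ...) {
  cat(sprintf("<code_report> %s (%s%s): n_cp = %d, L = %.3f%s\n",
              x$network, x$method,
              if (!is.null(x$k)) sprintf(", k = %d", x$k) else "",
              x$n_cp, x$L,
              if (isTRUE(x$truncated)) " [closed-set cap hit]" else ""))
  if (x$n_cp > 0) for (cp in x$code_pairs) print(cp)
  invisible(x)
}

#' Semantic capacity of a code report
#'
#' The semantic capacity of a network is the number of distinct code pairs
#' `n_cp` it can realize (each unordered sign pair / unordered meaning pair
#' combination counted once, however many witness contexts exist), and the
#' logarithmic semantic capacity `L = log2(n_cp + 1)`, which is zero iff
#' the network realizes no code.
#'
#' @param report a `code_report` from [find_codes_closure()] or
#'   [find_codes_paths()].
#' @return A list with elements `n_cp` and `L`.
#' @export
semantic_capacity <- function(report) {
  stopifnot(inherits(report, "code_report"))
  list(n_cp = report$n_cp, L = report$L)
}

# ---- molecular mappings -----------------------------------------------------

#' Test whether a context realizes a molecular mapping
#'
#' A context `C` realizes a mapping from domain `S` to codomain `M` iff
#' the context alone produces no codomain species
#' (`closure(C)` is disjoint from `M`) and for every `s` in `S` the
#' closure of `C` plus `s` contains exactly one codomain species, the image
#' `f(s)`.
#'
#' @inheritParams closure
#' @param S,M non-empty, disjoint character vectors (domain and codomain).
#' @param C character vector, the candidate context.
#' @return A witness list with fields `domain`, `codomain`, `context` and
#'   `mapping` (named character vector `s -> f(s)`), or `NULL` if `C` does
#'   not realize a mapping.
#' @export
realizes_mapping <- function(network, S, M, C = character()) {
  S <- .check_species(network, S, "domain species")
  M <- .check_species(network, M, "codomain species")
  C <- .check_species(network, C, "context species")
  if (length(S) == 0L || length(M) == 0L) {
    stop("domain and codomain must be non-empty", call. = FALSE)
  }
  if (length(intersect(S, M))) {
    stop("domain and codomain must be disjoint", call. = FALSE)
  }
  if (length(intersect(closure(network, C), M))) return(NULL)
  img <- character(length(S))
  for (i in seq_along(S)) {
    hit <- intersect(closure(network, c(C, S[i])), M)
    if (length(hit) != 1L) return(NULL)
    img[i] <- hit
  }
  list(domain = S, codomain = M, context = .csort(C),
       mapping = stats::setNames(img, S))
}

#' Test a sign pair / meaning pair for the binary code property
#'
#' Checks whether among `candidate_contexts` there are two contexts that
#' realize the two crossed bijections between the sign pair `S` and the
#' meaning pair `M` (the operational form of contingency). Contexts are
#' tried in the order given; the first witnesses found are returned.
#'
#' @inheritParams realizes_mapping
#' @param S,M character vectors of exactly two distinct species each,
#'   disjoint from one another.
#' @param candidate_contexts list of character vectors to try as contexts.
#' @return A `binary_code_pair` or `NULL`.
#' @export
is_code_pair <- function(network, S, M, candidate_contexts) {
  S <- .csort(.check_species(network, S, "sign species"))
  M <- .csort(.check_species(network, M, "meaning species"))
  if (length(S) != 2L || length(M) != 2L) {
    stop("S and M must each contain exactly two distinct species", call. = FALSE)
  }
  if (length(intersect(S, M))) {
    stop("signs and meanings must be disjoint", call. = FALSE)
  }
  straight <- NULL   # realizes s1 -> m1, s2 -> m2
  crossed <- NULL    # realizes s1 -> m2, s2 -> m1
  for (C in candidate_contexts) {
    w <- realizes_mapping(network, S, M, C)
    if (is.null(w)) next
    if (w$mapping[[1]] == M[1] && w$mapping[[2]] == M[2] && is.null(straight)) {
      straight <- w
    } else if (w$mapping[[1]] == M[2] && w$mapping[[2]] == M[1] && is.null(crossed)) {
      crossed <- w
    }
    if (!is.null(straight) && !is.null(crossed)) {
      return(.new_code_pair(S[1], S[2], M[1], M[2],
                            straight$context, crossed$context))
    }
  }
  NULL
}

# ---- closure-based finder ---------------------------------------------------

# Fast path for networks with <= 30 species: all closed sets as bitmasks,
# vectorized evaluation of closure(C u {s}) for every context at once.
.find_codes_closure_mask <- function(network, idx, cap) {
  cs <- .enumerate_masks(idx, cap)
  truncated <- attr(cs, "truncated")
  n <- idx$n
  ncs <- length(cs)
  cl1 <- vapply(seq_len(n), function(i) .closure_mask(idx$bits[i], idx),
                integer(1))
  # A[c, s] = closure(C_c u closure({s})) -- the candidate-context lemma
  # closure(C u {s}) = closure(closure(C) u closure({s})) makes closed C enough.
  A <- matrix(0L, nrow = ncs, ncol = n)
  for (s in seq_len(n)) {
    A[, s] <- .closure_masks(bitwOr(cs, cl1[s]), idx)
  }
  pairs <- list()
  for (mi in seq_len(n - 1L)) {
    bi <- idx$bits[mi]
    for (mj in seq.int(mi + 1L, n)) {
      bj <- idx$bits[mj]
      Mm <- bitwOr(bi, bj)
      V <- which(bitwAnd(cs, Mm) == 0L)     # contexts mute about M (closed => closure(C)=C)
      if (!length(V)) next
      AV <- A[V, , drop = FALSE]
      h1 <- matrix(bitwAnd(AV, bi) != 0L, nrow = nrow(AV))  # bitwAnd drops dim
      h2 <- matrix(bitwAnd(AV, bj) != 0L, nrow = nrow(AV))
      v1 <- h1 & !h2                        # closure hits exactly m_i
      v2 <- h2 & !h1                        # closure hits exactly m_j
      c1 <- colSums(v1) > 0L
      c2 <- colSums(v2) > 0L
      cand <- which((c1 | c2) & !(seq_len(n) %in% c(mi, mj)))
      if (length(cand) < 2L) next
      for (ai in seq_len(length(cand) - 1L)) {
        a <- cand[ai]
        for (bi2 in seq.int(ai + 1L, length(cand))) {
          b <- cand[bi2]
          if (!((c1[a] && c2[b]) && (c2[a] && c1[b]))) next
          st <- v1[, a] & v2[, b]
          if (!any(st)) next
          cr <- v2[, a] & v1[, b]
          if (!any(cr)) next
          C1 <- idx$species[.mask_members(idx, cs[V[which.max(st)]])]
          C2 <- idx$species[.mask_members(idx, cs[V[which.max(cr)]])]
          pairs[[length(pairs) + 1L]] <-
            .new_code_pair(idx$species[a], idx$species[b],
                           idx$species[mi], idx$species[mj], C1, C2)
        }
      }
    }
  }
  list(pairs = pairs, truncated = truncated, n_closed = ncs)
}

# Generic fallback for networks with > 30 species. Correct but slow; the
# path-based finder is the practical choice for large networks.
.find_codes_closure_generic <- function(network, idx, cap) {
  en <- .enumerate_generic(idx, cap)
  truncated <- attr(en, "truncated")
  n <- idx$n
  ncs <- length(en)
  cl1 <- lapply(seq_len(n), function(i) .closure_generic(i, idx))
  inC <- matrix(FALSE, nrow = ncs, ncol = n)
  for (ci in seq_len(ncs)) inC[ci, en[[ci]]] <- TRUE
  # A[[c]][[s]]: logical membership of closure(C u {s}), computed lazily
  Aenv <- new.env(parent = emptyenv())
  getA <- function(ci, s) {
    key <- paste0(ci, ".", s)
    v <- Aenv[[key]]
    if (is.null(v)) {
      v <- logical(n)
      v[.closure_generic(unique(c(en[[ci]], cl1[[s]])), idx)] <- TRUE
      Aenv[[key]] <- v
    }
    v
  }
  pairs <- list()
  for (mi in seq_len(n - 1L)) {
    for (mj in seq.int(mi + 1L, n)) {
      V <- which(!inC[, mi] & !inC[, mj])
      if (!length(V)) next
      v <- matrix(0L, nrow = length(V), ncol = n)
      for (vi in seq_along(V)) {
        for (s in seq_len(n)) {
          if (s == mi || s == mj) next
          a <- getA(V[vi], s)
          if (a[mi] && !a[mj]) v[vi, s] <- 1L
          else if (a[mj] && !a[mi]) v[vi, s] <- 2L
        }
      }
      for (a in seq_len(n - 1L)) {
        for (b in seq.int(a + 1L, n)) {
          if (a %in% c(mi, mj) || b %in% c(mi, mj)) next
          st <- v[, a] == 1L & v[, b] == 2L
          cr <- v[, a] == 2L & v[, b] == 1L
          if (any(st) && any(cr)) {
            pairs[[length(pairs) + 1L]] <-
              .new_code_pair(idx$species[a], idx$species[b],
                             idx$species[mi], idx$species[mj],
                             idx$species[en[[V[which.max(st)]]]],
                             idx$species[en[[V[which.max(cr)]]]])
          }
        }
      }
    }
  }
  list(pairs = pairs, truncated = truncated, n_closed = ncs)
}

#' Find all binary molecular codes via closed sets
#'
#' Enumerates the network's closed sets once and searches all sign pair /
#' meaning pair combinations for two closed contexts realizing the crossed
#' mappings. Restricting candidate contexts to closed sets loses nothing
#' because `closure(C u {s}) = closure(closure(C) u {s})`. Best suited to
#' networks whose closed-set count is moderate; use [find_codes_paths()]
#' for dense or very large networks.
#'
#' @inheritParams closure
#' @param cap cap on the closed-set enumeration; if hit, the report is
#'   flagged `truncated` and may undercount codes.
#' @return A `code_report`: `code_pairs` (deduplicated, one entry per
#'   unordered sign pair x unordered meaning pair, with the lectically
#'   first witness contexts), `n_cp`, `L = log2(n_cp + 1)`, `method`,
#'   `truncated`, `n_closed_sets`.
#' @examples
#' find_codes_closure(build_code_motif())$n_cp   # 1
#' @export
find_codes_closure <- function(network, cap = 100000L) {
  idx <- .net_index(network)
  res <- if (idx$use_mask) .find_codes_closure_mask(network, idx, cap)
         else .find_codes_closure_generic(network, idx, cap)
  .new_code_report(res$pairs, method = "closure", truncated = res$truncated,
                   n_closed_sets = res$n_closed, network_name = network$name)
}

# ---- path-based finder ------------------------------------------------------

#' Find binary molecular codes via k-shortest paths
#'
#' Collects up to `k` shortest loopless paths between every ordered pair of
#' species and combines path contexts (reactant sets along a path minus the
#' path's own species) into candidate code contexts: for a sign pair
#' `(s1,s2)` and meaning pair `(m1,m2)`, contexts for the straight mapping
#' are unions of a `s1 -> m1` and a `s2 -> m2` path context, and
#' analogously for the crossed mapping. Every candidate is verified with
#' the closure operator (the closure check is authoritative), so the result
#' is always a subset of [find_codes_closure()]'s and equals it for
#' sufficiently large `k`.
#'
#' @inheritParams closure
#' @param k number of shortest paths kept per ordered species pair.
#' @return A `code_report` with `method = "paths"`, the `k` used and
#'   `n_paths`, the total number of (k-limited) paths found.
#' @examples
#' find_codes_paths(build_code_motif(), k = 4)$n_cp   # 1
#' @export
find_codes_paths <- function(network, k = 20L) {
  stopifnot(k >= 1L)
  k <- as.integer(k)
  idx <- .net_index(network)
  n <- idx$n
  if (n < 4L || length(network$reactions) == 0L) {
    return(.new_code_report(list(), method = "paths", k = k, n_paths = 0L,
                            network_name = network$name))
  }
  g <- .sr_graph(network)
  spv <- paste0("s:", idx$species)
  d <- suppressWarnings(igraph::distances(g, v = spv, to = spv, mode = "out"))
  reach <- is.finite(d)
  diag(reach) <- FALSE

  # closure memoisation keyed by member set
  cl_env <- new.env(parent = emptyenv())
  cl_of <- function(members) {
    key <- paste0("k", paste(members, collapse = ","))
    v <- cl_env[[key]]
    if (is.null(v)) {
      v <- .closure_members(members, idx)
      cl_env[[key]] <- v
    }
    v
  }

  # per ordered pair: list of legs, each leg = list(ctx, cl_ctx, cl_src)
  legs <- vector("list", n * n)
  n_paths <- 0L
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (!reach[s, t]) next
      pl <- .k_paths_raw(g, idx$species[s], idx$species[t], k)
      n_paths <- n_paths + length(pl)
      legs[[(s - 1L) * n + t]] <- lapply(pl, function(p) {
        ctx <- sort(unname(idx$spmap[path_context(network, p)]))
        list(ctx = ctx, cl_ctx = cl_of(ctx), cl_src = cl_of(sort(unique(c(ctx, s)))))
      })
    }
  }

  # try to realize sa -> ma, sb -> mb from leg contexts; M = {ma, mb}
  find_ctx <- function(sa, sb, ma, mb) {
    M <- c(ma, mb)
    la <- legs[[(sa - 1L) * n + ma]]
    lb <- legs[[(sb - 1L) * n + mb]]
    if (is.null(la) || is.null(lb)) return(NULL)
    ok_leg <- function(lg, src_m) {
      !any(lg$cl_ctx %in% M) && identical(intersect(lg$cl_src, M), src_m)
    }
    la <- Filter(function(lg) ok_leg(lg, ma), la)
    lb <- Filter(function(lg) ok_leg(lg, mb), lb)
    for (pa in la) {
      for (pb in lb) {
        C <- sort(unique(c(pa$ctx, pb$ctx)))
        if (any(cl_of(C) %in% M)) next
        ca <- cl_of(sort(unique(c(C, sa))))
        if (!identical(intersect(ca, M), ma)) next
        cb <- cl_of(sort(unique(c(C, sb))))
        if (!identical(intersect(cb, M), mb)) next
        return(C)
      }
    }
    NULL
  }

  pairs <- list()
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      common <- unname(which(reach[a, ] & reach[b, ]))  # unname: identical() below
      common <- common[!(common %in% c(a, b))]
      if (length(common) < 2L) next
      for (ii in seq_len(length(common) - 1L)) {
        for (jj in seq.int(ii + 1L, length(common))) {
          mi <- common[ii]
          mj <- common[jj]
          C1 <- find_ctx(a, b, mi, mj)
          if (is.null(C1)) next
          C2 <- find_ctx(a, b, mj, mi)
          if (is.null(C2)) next
          pairs[[length(pairs) + 1L]] <-
            .new_code_pair(idx$species[a], idx$species[b],
                           idx$species[mi], idx$species[mj],
                           idx$species[C1], idx$species[C2])
        }
      }
    }
  }
  .new_code_report(pairs, method = "paths", k = k, n_paths = n_paths,
                   network_name = network$name)
}

# ---- merging binary codes ---------------------------------------------------

#' Merge binary codes into larger molecular codes
#'
#' Binary codes are merged when they plausibly express one larger code:
#' two code pairs are linked if they share their meaning pair and their
#' sign pairs overlap, or share their sign pair and their meaning pairs
#' overlap. Connected components of this graph are reported with the union
#' of their signs and meanings.
#'
#' @param report a `code_report`.
#' @return A list of merged codes, each a list with `signs`, `meanings`,
#'   `members` (indices into `report$code_pairs`) and `n_bmc`.
#' @export
merge_binary_codes <- function(report) {
  stopifnot(inherits(report, "code_report"))
  cps <- report$code_pairs
  m <- length(cps)
  if (m == 0L) return(list())
  S <- lapply(cps, function(cp) c(cp$s1, cp$s2))
  M <- lapply(cps, function(cp) c(cp$m1, cp$m2))
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      link <- (setequal(M[[i]], M[[j]]) && length(intersect(S[[i]], S[[j]])) > 0L) ||
              (setequal(S[[i]], S[[j]]) && length(intersect(M[[i]], M[[j]])) > 0L)
      if (link) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  lapply(unique(roots), function(r) {
    members <- which(roots == r)
    list(signs = .csort(unlist(S[members])),
         meanings = .csort(unlist(M[members])),
         members = members, n_bmc = length(members))
  })
}
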