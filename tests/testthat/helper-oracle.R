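# Independent brute-force oracles. These deliberately share no code with the
# package internals: closures are computed by naive repeated scanning over
# subsets enumerated as raw bitmasks, and code pairs by checking ALL context
# subsets, not just closed sets.

# closure of every subset of a network with <= 12 species, as a logical
# matrix: row (mask + 1) gives the membership vector of closure(subset(mask)).
oracle_all_closures <- function(net) {
  sp <- net$species
  n <- length(sp)
  stopifnot(n <= 12L)
  rl <- lapply(net$reactions, function(r) match(r$reactants, sp))
  pl <- lapply(net$reactions, function(r) match(r$products, sp))
  cl <- function(v) {
    repeat {
      v2 <- v
      for (j in seq_along(rl)) {
        if (all(v2[rl[[j]]])) v2[pl[[j]]] <- TRUE
      }
      if (identical(v2, v)) return(v)
      v <- v2
    }
  }
  nmask <- bitwShiftL(1L, n)
  out <- matrix(FALSE, nrow = nmask, ncol = n)
  for (mask in 0:(nmask - 1L)) {
    v <- logical(n)
    for (i in seq_len(n)) if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0L) v[i] <- TRUE
    out[mask + 1L, ] <- cl(v)
  }
  out
}

# all closed sets by direct definition: subsets equal to their own closure
oracle_closed_sets <- function(net) {
  CL <- oracle_all_closures(net)
  n <- length(net$species)
  nmask <- nrow(CL)
  keep <- vapply(0:(nmask - 1L), function(mask) {
    v <- logical(n)
    for (i in seq_len(n)) if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0L) v[i] <- TRUE
    identical(v, CL[mask + 1L, ])
  }, logical(1))
  lapply(which(keep) - 1L, function(mask) {
    net$species[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
  })
}

# exhaustive binary-code search over ALL context subsets C1, C2 of the
# species set; returns a sorted data.frame of quadruples (s1, s2, m1, m2)
oracle_codes <- function(net) {
  sp <- net$species
  n <- length(sp)
  CL <- oracle_all_closures(net)
  nmask <- nrow(CL)
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  masks <- 0:(nmask - 1L)
  rows <- list()
  for (m1 in seq_len(n - 1L)) {
    for (m2 in seq.int(m1 + 1L, n)) {
      ok <- !CL[, m1] & !CL[, m2]             # context alone yields no meaning
      if (!any(ok)) next
      okm <- masks[ok]
      # val[c, s]: 1 if closure(C u {s}) picks exactly m1, 2 if exactly m2
      for (s1 in seq_len(n - 1L)) {
        if (s1 == m1 || s1 == m2) next
        a1 <- CL[bitwOr(okm, bit[s1]) + 1L, m1]
        a2 <- CL[bitwOr(okm, bit[s1]) + 1L, m2]
        v1 <- ifelse(a1 & !a2, 1L, ifelse(a2 & !a1, 2L, 0L))
        if (!any(v1 > 0L)) next
        for (s2 in seq.int(s1 + 1L, n)) {
          if (s2 == m1 || s2 == m2) next
          b1 <- CL[bitwOr(okm, bit[s2]) + 1L, m1]
          b2 <- CL[bitwOr(okm, bit[s2]) + 1L, m2]
          v2 <- ifelse(b1 & !b2, 1L, ifelse(b2 & !b1, 2L, 0L))
          if (any(v1 == 1L & v2 == 2L) && any(v1 == 2L & v2 == 1L)) {
            rows[[length(rows) + 1L]] <- data.frame(
              s1 = sp[s1], s2 = sp[s2], m1 = sp[m1], m2 = sp[m2],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(s1 = character(), s2 = character(),
                      m1 = character(), m2 = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$s1, out$s2, out$m1, out$m2, method = "radix"), , drop = FALSE]
}

# quadruple table of a code_report, in the oracle's sort order
report_quads <- function(report) {
  if (report$n_cp == 0L) {
    return(data.frame(s1 = character(), s2 = character(),
                      m1 = character(), m2 = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(report$code_pairs, function(cp) {
    data.frame(s1 = cp$s1, s2 = cp$s2, m1 = cp$m1, m2 = cp$m2,
               stringsAsFactors = FALSE)
  }))
  out[order(out$s1, out$s2, out$m1, out$m2, method = "radix"), , drop = FALSE]
}

expect_same_quads <- function(report, oracle_df) {
  got <- report_quads(report)
  rownames(got) <- NULL
  rownames(oracle_df) <- NULL
  expect_identical(got, oracle_df)
}

# exhaustive enumeration of simple paths in the bipartite species-reaction
# digraph, by depth-first search (independent of igraph)
oracle_all_paths <- function(net, from, to) {
  sp <- net$species
  rids <- vapply(net$reactions, `[[`, character(1), "id")
  out <- list()
  walk <- function(cur_species, nodes, used_sp, used_rx) {
    for (j in seq_along(rids)) {
      r <- net$reactions[[j]]
      if (used_rx[j]) next
      if (!(cur_species %in% r$reactants)) next
      for (p in r$products) {
        pi <- match(p, sp)
        if (used_sp[pi]) next
        nn <- c(nodes, rids[j], p)
        if (p == to) {
          out[[length(out) + 1L]] <<- nn
        } else {
          u1 <- used_sp; u1[pi] <- TRUE
          u2 <- used_rx; u2[j] <- TRUE
          walk(p, nn, u1, u2)
        }
      }
    }
  }
  used <- logical(length(sp))
  used[match(from, sp)] <- TRUE
  used[match(to, sp)] <- FALSE
  walk(from, from, used, logical(length(rids)))
  # sort by (length, lexicographic node sequence) like the package
  len <- vapply(out, length, integer(1))
  key <- vapply(out, paste, character(1), collapse = "\x01")
  out[order(len, key, method = "radix")]
}
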