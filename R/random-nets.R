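# Run fn with a private, seeded RNG stream, restoring the caller's state.
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

.random_species_names <- function(n) sprintf("S%02d", seq_len(n))

#' Random bimolecular reaction network
#'
#' The null model: `n_reactions` distinct rules inserted into an empty
#' network over `n_species` species. Each rule is bimolecular with two
#' distinct reactants (unordered, uniform) and one product (uniform over
#' all species, possibly equal to a reactant). Rules are drawn uniformly
#' without replacement from the `choose(n,2) * n` possible rules, which is
#' equivalent to rejecting and redrawing duplicates. Fully reproducible
#' from `seed`.
#'
#' @param n_species number of species (>= 2).
#' @param n_reactions number of rules, at most `choose(n_species, 2) * n_species`.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return A [reaction_network()].
#' @examples
#' net <- random_network(10, 38, seed = 1)
#' length(net$reactions)  # 38
#' @export
random_network <- function(n_species, n_reactions, seed = NULL) {
  stopifnot(n_species >= 2L, n_reactions >= 0L)
  n <- as.integer(n_species)
  npairs <- choose(n, 2)
  nmax <- npairs * n
  if (n_reactions > nmax) {
    stop(sprintf("n_reactions = %d exceeds the %d possible distinct bimolecular rules",
                 n_reactions, nmax), call. = FALSE)
  }
  sp <- .random_species_names(n)
  pairs <- t(utils::combn(n, 2))
  .with_seed(seed, function() {
    rule <- sample.int(nmax, n_reactions, replace = FALSE)
    pair_id <- (rule - 1L) %/% n + 1L
    prod_id <- (rule - 1L) %% n + 1L
    rx <- lapply(seq_len(n_reactions), function(i) {
      list(reactants = sp[pairs[pair_id[i], ]], products = sp[prod_id[i]])
    })
    reaction_network(rx, species = sp,
                     name = sprintf("random_%d_%d", n, n_reactions))
  })
}

# Per-network structural statistics used by the survey operations.
.net_stats <- function(net, k, cap, method, count_paths = TRUE) {
  idx <- .net_index(net)
  if (idx$use_mask) {
    masks <- .enumerate_masks(idx, cap)
    n_closed <- length(masks)
  } else {
    en <- .enumerate_generic(idx, cap)
    n_closed <- length(en)
  }
  rep <- if (method == "closure") find_codes_closure(net, cap = cap)
         else find_codes_paths(net, k = k)
  n_paths <- rep$n_paths
  if (is.null(n_paths) && !count_paths) n_paths <- NA_real_
  if (is.null(n_paths)) {
    # closure-based finder does not count paths; count them k-limited
    g <- .sr_graph(net)
    spv <- paste0("s:", net$species)
    d <- suppressWarnings(igraph::distances(g, v = spv, to = spv, mode = "out"))
    reach <- is.finite(d)
    diag(reach) <- FALSE
    n_paths <- 0L
    for (s in seq_len(idx$n)) for (t in seq_len(idx$n)) if (reach[s, t]) {
      n_paths <- n_paths + length(.k_paths_raw(g, net$species[s], net$species[t], k))
    }
  }
  c(n_closed = n_closed, n_paths = n_paths, n_cp = rep$n_cp, L = rep$L)
}

.sem <- function(x) {
  if (length(x) <= 1L) return(0)
  stats::sd(x) / sqrt(length(x))
}

#' Null-model estimate at a fixed size and density
#'
#' Generates `replicates` random bimolecular networks with the given size
#' and density, computes the number of closed sets (capped), the number of
#' k-limited paths, and the semantic capacity of each, and reports means
#' with standard errors. Used to judge whether the (lack of) codes in a
#' real chemistry is what chance alone would produce.
#'
#' @inheritParams random_network
#' @param replicates number of random networks (>= 1).
#' @param k path limit per ordered species pair.
#' @param seed seed of the whole experiment.
#' @param method `"closure"` (exact; for small networks) or `"paths"`.
#' @param cap closed-set enumeration cap.
#' @param count_paths set `FALSE` to skip the (relatively costly) k-limited
#'   path count when `method = "closure"`; the path columns are then `NA`.
#' @return One-row `data.frame` with means and SEMs of the closed-set,
#'   path and code-pair counts and of the logarithmic capacity.
#' @export
null_model_estimate <- function(n_species, n_reactions, replicates = 100L,
                                k = 20L, seed = 1L,
                                method = c("paths", "closure"),
                                cap = 100000L, count_paths = TRUE) {
  method <- match.arg(method)
  stopifnot(replicates >= 1L)
  stats_mat <- .with_seed(seed, function() {
    vapply(seq_len(replicates), function(i) {
      net <- random_network(n_species, n_reactions, seed = NULL)
      .net_stats(net, k = k, cap = cap, method = method,
                 count_paths = count_paths)
    }, numeric(4))
  })
  data.frame(n_species = n_species, n_reactions = n_reactions,
             replicates = replicates, k = k, method = method,
             mean_closed = mean(stats_mat["n_closed", ]),
             sem_closed = .sem(stats_mat["n_closed", ]),
             mean_paths = mean(stats_mat["n_paths", ]),
             sem_paths = .sem(stats_mat["n_paths", ]),
             mean_cp = mean(stats_mat["n_cp", ]),
             sem_cp = .sem(stats_mat["n_cp", ]),
             mean_L = mean(stats_mat["L", ]),
             sem_L = .sem(stats_mat["L", ]))
}

#' Semantic-capacity survey over network sizes and densities
#'
#' Full-factorial Monte-Carlo survey: for every network size in
#' `n_species` and every density (reactions per species) in `densities`,
#' random networks are generated and their mean semantic capacity, path
#' and closed-set counts estimated. The mean capacity is unimodal in
#' density; the survey also records, per size, the reaction count
#' `r_star` at which the mean capacity peaks. Across sizes `r_star` grows
#' roughly linearly with slope about two reactions per species.
#'
#' @param n_species integer vector of network sizes.
#' @param densities numeric vector of reactions-per-species values; the
#'   reaction count is `round(density * n)`.
#' @inheritParams null_model_estimate
#' @return A `data.frame` (class `survey_result`) with one row per
#'   (size, density) cell, plus attributes `optimum` (a `data.frame` of
#'   `n`, `r_star`) and `slope` (through-origin regression of `r_star`
#'   on `n`).
#' @export
density_survey <- function(n_species, densities, replicates = 100L, k = 20L,
                           seed = 1L, method = c("paths", "closure"),
                           cap = 100000L, count_paths = TRUE) {
  method <- match.arg(method)
  stopifnot(length(n_species) > 0L, length(densities) > 0L)
  rows <- list()
  for (ni in seq_along(n_species)) {
    n <- n_species[ni]
    for (di in seq_along(densities)) {
      r <- as.integer(round(densities[di] * n))
      cell_seed <- (seed * 997L + ni * 131L + di) %% .Machine$integer.max
      row <- null_model_estimate(n, r, replicates = replicates, k = k,
                                 seed = cell_seed, method = method, cap = cap,
                                 count_paths = count_paths)
      row$density <- densities[di]
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  opt <- do.call(rbind, lapply(unique(out$n_species), function(n) {
    sub <- out[out$n_species == n, ]
    data.frame(n = n, r_star = sub$n_reactions[which.max(sub$mean_cp)])
  }))
  slope <- if (nrow(opt) >= 1L) sum(opt$r_star * opt$n) / sum(opt$n^2) else NA_real_
  structure(out, class = c("survey_result", "data.frame"),
            optimum = opt, slope = slope)
}

#' Rewire random reactions of a network
#'
#' Robustness randomization: `n_replacements` times, a uniformly chosen
#' reaction rule has its species resampled uniformly while keeping the
#' numbers of reactants and products (the arity profile) fixed. With more
#' replacements the network drifts toward the random-network null model
#' and its semantic capacity decays on average. `n_replacements` may
#' exceed the rule count, in which case rules are rewired repeatedly.
#'
#' @inheritParams closure
#' @param n_replacements non-negative number of rewiring steps; 0 returns
#'   the network unchanged.
#' @param seed integer seed or `NULL`.
#' @return A [reaction_network()] over the same species set.
#' @export
randomize_network <- function(network, n_replacements, seed = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  if (n_replacements < 0) stop("n_replacements must be >= 0", call. = FALSE)
  if (n_replacements == 0L) return(network)
  sp <- network$species
  n <- length(sp)
  rx <- lapply(network$reactions, function(r)
    list(reactants = r$reactants, products = r$products))
  .with_seed(seed, function() {
    sig <- vapply(rx, function(r) .reaction_signature(r$reactants, r$products),
                  character(1))
    for (step in seq_len(n_replacements)) {
      j <- sample.int(length(rx), 1L)
      nr <- length(rx[[j]]$reactants)
      np <- length(rx[[j]]$products)
      for (attempt in seq_len(10000L)) {
        cand <- list(reactants = if (nr) sample(sp, nr) else character(),
                     products = if (np) sample(sp, np) else character())
        s <- .reaction_signature(cand$reactants, cand$products)
        if (!(s %in% sig[-j])) {
          rx[[j]] <- cand
          sig[j] <- s
          break
        }
      }
    }
    reaction_network(rx, species = sp,
                     name = paste0(network$name, "_randomized"))
  })
}
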