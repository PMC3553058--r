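# Mass-action kinetics for small networks; fixed-step RK4 (the cascade
# models are tiny and non-stiff at unit rates, so no implicit solver is
# needed).

#' Construct a mass-action kinetic model
#'
#' Attaches rate constants and initial concentrations to a reaction
#' network. Rates default to 1 for every reaction; unspecified initial
#' concentrations default to 0. Stoichiometric coefficients are honored
#' here (unlike in the closure analysis): the rate of a reaction is
#' `k * prod(conc[reactants]^coef)` and the net species change per firing
#' is product minus reactant coefficients, so catalytic species are
#' correctly left untouched.
#'
#' @inheritParams closure
#' @param rates single number recycled to all reactions, or a named vector
#'   by reaction id.
#' @param initial named non-negative vector of starting concentrations.
#' @param t_end simulation end time.
#' @return A `kinetic_model`.
#' @export
kinetic_model <- function(network, rates = 1, initial = c(), t_end = 500) {
  stopifnot(inherits(network, "reaction_network"), t_end > 0)
  rids <- vapply(network$reactions, `[[`, character(1), "id")
  if (length(rates) == 1L && is.null(names(rates))) {
    rates <- stats::setNames(rep(as.numeric(rates), length(rids)), rids)
  } else {
    missing <- setdiff(rids, names(rates))
    if (length(missing)) stop("no rate for reaction(s): ",
                              paste(missing, collapse = ", "), call. = FALSE)
    rates <- rates[rids]
  }
  if (any(rates <= 0)) stop("rates must be positive", call. = FALSE)
  x0 <- stats::setNames(rep(0, length(network$species)), network$species)
  if (length(initial)) {
    .check_species(network, names(initial), "initial species")
    if (any(initial < 0)) stop("initial concentrations must be non-negative",
                               call. = FALSE)
    x0[names(initial)] <- as.numeric(initial)
  }
  structure(list(network = network, rates = rates, initial = x0,
                 t_end = as.numeric(t_end)),
            class = "kinetic_model")
}

# stoichiometry matrices: per-reaction reactant orders and net changes
.kin_matrices <- function(model) {
  net <- model$network
  sp <- net$species
  nr <- length(net$reactions)
  Vr <- matrix(0, nrow = length(sp), ncol = nr, dimnames = list(sp, NULL))
  Sn <- Vr
  for (j in seq_len(nr)) {
    r <- net$reactions[[j]]
    Vr[r$reactants, j] <- r$r_coef
    Sn[r$reactants, j] <- Sn[r$reactants, j] - r$r_coef
    Sn[r$products, j] <- Sn[r$products, j] + r$p_coef
  }
  list(Vr = Vr, Sn = Sn, k = unname(model$rates))
}

#' Simulate mass-action dynamics
#'
#' Integrates the model with a fixed-step fourth-order Runge-Kutta scheme
#' and checks for a steady state: the relative concentration change over
#' the final 10 percent of the time span must fall below `ss_tol`
#' (default 1e-8). Non-convergence is flagged, not raised.
#'
#' @param model a [kinetic_model()].
#' @param n_steps number of RK4 steps.
#' @param ss_tol steady-state relative-change tolerance.
#' @return A list with `times`, `conc` (time x species matrix), `final`
#'   (named concentrations at `t_end`) and `converged`.
#' @export
simulate_mass_action <- function(model, n_steps = 5000L, ss_tol = 1e-8) {
  stopifnot(inherits(model, "kinetic_model"), n_steps >= 10L)
  mats <- .kin_matrices(model)
  Vr <- mats$Vr
  Sn <- mats$Sn
  kk <- mats$k
  deriv <- function(x) {
    x <- pmax(x, 0)
    # reaction rate: k_j * prod_i x_i^Vr[i,j]
    lograte <- crossprod(Vr, log(pmax(x, 1e-300)))
    rate <- kk * as.vector(exp(lograte))
    # a rate is exactly zero if any required reactant is absent
    zero <- vapply(seq_along(rate), function(j) {
      any(x[Vr[, j] > 0] == 0)
    }, logical(1))
    rate[zero] <- 0
    as.vector(Sn %*% rate)
  }
  dt <- model$t_end / n_steps
  keep <- unique(c(seq(1L, n_steps + 1L, length.out = min(n_steps + 1L, 501L))))
  keep <- as.integer(round(keep))
  x <- model$initial
  traj <- matrix(NA_real_, nrow = length(keep), ncol = length(x),
                 dimnames = list(NULL, names(x)))
  times <- numeric(length(keep))
  ki <- 1L
  x_mark <- NULL   # state at 90% of t_end, for the steady-state check
  mark_step <- as.integer(floor(0.9 * n_steps))
  for (step in 0:n_steps) {
    if (ki <= length(keep) && step + 1L == keep[ki]) {
      traj[ki, ] <- x
      times[ki] <- step * dt
      ki <- ki + 1L
    }
    if (step == mark_step) x_mark <- x
    if (step == n_steps) break
    k1 <- deriv(x)
    k2 <- deriv(x + dt / 2 * k1)
    k3 <- deriv(x + dt / 2 * k2)
    k4 <- deriv(x + dt * k3)
    x <- pmax(x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
  }
  rel <- max(abs(x - x_mark) / pmax(abs(x), 1e-12))
  list(times = times, conc = traj, final = x,
       converged = is.finite(rel) && rel < ss_tol)
}

#' Steady-state response of the two-step cascade under a branch context
#'
#' Runs the two-step phosphorylation cascade with either the A branch
#' (`context = "A"`: active when unphosphorylated) or the B branch
#' (`context = "B"`: active when phosphorylated) present, over a grid of
#' initial kinase concentrations `X0`, and records the steady-state
#' `Tp/T` ratio. Under the A context the ratio falls with `X0`; under the
#' B context it rises -- the two contexts realize opposite mappings from
#' `X0` level to target phosphorylation level.
#'
#' @param context `"A"` or `"B"`.
#' @param x0_grid non-negative grid of initial `X0` concentrations.
#' @param branch_total,target_total initial branch kinase and target
#'   concentrations (the unphosphorylated forms start with the total).
#' @param rates,t_end,n_steps passed to the kinetic model / integrator.
#' @return A `response_curve`: data.frame columns `x0` and `ratio`, with
#'   attributes `context_label` and `trend` (+1 increasing, -1 decreasing,
#'   0 otherwise).
#' @export
response_curve <- function(context = c("A", "B"),
                           x0_grid = seq(0, 5, by = 0.25),
                           branch_total = 1, target_total = 1,
                           rates = 1, t_end = 500, n_steps = 5000L) {
  context <- match.arg(context)
  stopifnot(all(x0_grid >= 0), branch_total > 0, target_total > 0)
  net <- build_phospho_cascade(two_step = TRUE)
  branch_species <- if (context == "A") "A" else "B"
  ratio <- vapply(x0_grid, function(x0) {
    init <- stats::setNames(c(x0, branch_total, target_total),
                            c("X0", branch_species, "T"))
    model <- kinetic_model(net, rates = rates, initial = init, t_end = t_end)
    res <- simulate_mass_action(model, n_steps = n_steps)
    unname(res$final["Tp"] / max(res$final["T"], 1e-12))
  }, numeric(1))
  d <- diff(ratio)
  trend <- if (length(d) && all(d < 0)) -1L else if (length(d) && all(d > 0)) 1L else 0L
  structure(data.frame(x0 = x0_grid, ratio = ratio),
            class = c("response_curve", "data.frame"),
            context_label = context, trend = trend)
}

#' Check for a concentration-level code
#'
#' Discretizes the two response curves with a shared high/low threshold on
#' the `Tp/T` ratio and tests whether the two contexts realize crossed
#' level mappings: the high-`X0` end maps to a low target level under one
#' context and to a high level under the other (and conversely at the
#' low-`X0` end). This is the dynamic analogue of a binary code pair.
#'
#' @param curve1,curve2 `response_curve` objects on the same `x0` grid.
#' @param threshold positive ratio threshold separating high from low.
#' @return `TRUE` iff the discretized mappings are crossed.
#' @export
level_code_check <- function(curve1, curve2, threshold) {
  stopifnot(inherits(curve1, "response_curve"),
            inherits(curve2, "response_curve"), threshold > 0)
  if (!isTRUE(all.equal(curve1$x0, curve2$x0))) {
    stop("response curves must share the x0 grid", call. = FALSE)
  }
  lab <- function(curve) {
    i_lo <- which.min(curve$x0)
    i_hi <- which.max(curve$x0)
    c(lo = curve$ratio[i_lo] > threshold, hi = curve$ratio[i_hi] > threshold)
  }
  l1 <- lab(curve1)
  l2 <- lab(curve2)
  # each context must map the two input levels to distinct output levels,
  # and the two contexts must disagree at both input levels
  (l1["lo"] != l1["hi"]) && (l2["lo"] != l2["hi"]) &&
    (l1["lo"] != l2["lo"]) && (l1["hi"] != l2["hi"])
}
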