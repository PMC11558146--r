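#' Mass-action ODE system of a reaction network
#'
#' Builds the derivative function (and analytic Jacobian) of the mass-action
#' ODE system of a network: the derivative of each species is the sum over
#' reactions of its stoichiometric coefficient times the rate constant times
#' the product of reactant concentrations. Fluxes are evaluated on the raw
#' state (no clamping): tiny negative integrator excursions then produce
#' restoring fluxes and stay within the absolute tolerance, and the smooth
#' right-hand side lets the stiff solver take large steps. Because fluxes
#' enter through the stoichiometric matrix, conservation laws hold exactly
#' for any flux vector.
#'
#' @param x a validated `crn`.
#' @return list with `func(t, y, parms)` and `jac(t, y, parms)` in
#'   [deSolve::lsoda()] form, `y0` (named initial state, nM) and `species`.
#' @export
crn_odes <- function(x) {
  v <- validate_crn(x)
  if (!v$ok) stop("invalid CRN: ", paste(v$findings, collapse = "; "),
                  call. = FALSE)
  ns <- nrow(x$species)
  nr <- nrow(x$reactions)
  S <- stoich_matrix(x)
  idx <- stats::setNames(seq_len(ns), x$species$name)
  r1 <- unname(idx[x$reactions$r1])
  r2 <- unname(idx[x$reactions$r2])      # NA for unimolecular
  k <- x$reactions$rate
  bi <- !is.na(r2)
  uni <- which(!bi)
  bi_same <- which(bi & r1 == r2)        # A + A -> ... (dv/dA = 2kA)
  bi_diff <- which(bi & r1 != r2)
  bi_idx <- which(bi)
  y0 <- stats::setNames(x$species$initial, x$species$name)

  func <- function(t, y, parms) {
    v <- numeric(nr)
    if (length(uni)) v[uni] <- k[uni] * y[r1[uni]]
    if (length(bi_idx)) v[bi_idx] <- k[bi_idx] * y[r1[bi_idx]] *
        y[r2[bi_idx]]
    list(as.vector(S %*% v))
  }

  jac <- function(t, y, parms) {
    Dv <- matrix(0, nr, ns)
    if (length(uni)) Dv[cbind(uni, r1[uni])] <- k[uni]
    if (length(bi_diff)) {
      Dv[cbind(bi_diff, r1[bi_diff])] <- k[bi_diff] * y[r2[bi_diff]]
      Dv[cbind(bi_diff, r2[bi_diff])] <- k[bi_diff] * y[r1[bi_diff]]
    }
    if (length(bi_same)) {
      Dv[cbind(bi_same, r1[bi_same])] <- 2 * k[bi_same] * y[r1[bi_same]]
    }
    S %*% Dv
  }

  list(func = func, jac = jac, y0 = y0, species = x$species$name)
}

#' Deterministic simulation of a reaction network
#'
#' Integrates the mass-action ODE system with a stiff solver (BDF via
#' [deSolve::vode()] by default, with the analytic Jacobian — the toehold
#' rate constants span nine orders of magnitude, so stiffness is the norm)
#' on a fixed evaluation grid
#' and returns the full trajectory. The simulation is deterministic; `nsim`
#' and `seed` are accepted for compatibility with the [stats::simulate()]
#' generic but ignored. Endpoint concentrations are reported at exactly
#' `t_end` regardless of whether the network has reached steady state.
#'
#' @param object a validated `crn`.
#' @param nsim,seed ignored (deterministic system).
#' @param t_end simulation horizon in seconds (default 30000, the standard
#'   diagnosis horizon; the loser-take-all fixtures use 10000).
#' @param n_points number of grid points including 0 and `t_end`.
#' @param rtol,atol relative / absolute (nM) integration tolerances.
#' @param method a [deSolve::ode()] method name.
#' @param ... further arguments to [deSolve::ode()].
#' @return an object of class `crn_sim`: list with `times`, `conc`
#'   (time-by-species matrix, nM), `final` (named endpoint state),
#'   `diagnostics` and `crn`.
#' @export
simulate.crn <- function(object, nsim = 1, seed = NULL, t_end = 30000,
                         n_points = 600, rtol = 1e-8, atol = 1e-12,
                         method = "vode", ...) {
  stopifnot(t_end > 0, n_points >= 2)
  sys <- crn_odes(object)
  times <- seq(0, t_end, length.out = n_points)
  out <- deSolve::ode(y = sys$y0, times = times, func = sys$func,
                      parms = NULL, jacfunc = sys$jac, jactype = "fullusr",
                      method = method, rtol = rtol, atol = atol, ...)
  diagn <- attributes(out)[c("istate", "rstate")]
  if (attr(out, "istate")[1L] < 0) {
    stop("integration failed: istate = ", attr(out, "istate")[1L],
         call. = FALSE)
  }
  conc <- unclass(out)[, -1L, drop = FALSE]
  structure(list(
    times = times,
    conc = conc,
    species = sys$species,
    final = stats::setNames(conc[nrow(conc), ], sys$species),
    diagnostics = c(diagn, list(rtol = rtol, atol = atol, method = method)),
    crn = object
  ), class = "crn_sim")
}

#' @export
print.crn_sim <- function(x, ...) {
  cat(sprintf("CRN trajectory: %d species, %d time points, t_end = %g s\n",
              ncol(x$conc), length(x$times), max(x$times)))
  rep_sp <- grep("^FLUOR\\[", x$species, value = TRUE)
  if (length(rep_sp)) {
    cat("  reporter endpoints (nM):\n")
    print(round(x$final[rep_sp], 3))
  }
  invisible(x)
}

#' @export
plot.crn_sim <- function(x, species = NULL, ...) {
  if (is.null(species)) {
    species <- grep("^(FLUOR|D|S)\\[", x$species, value = TRUE)
    if (!length(species)) species <- utils::head(x$species, 8L)
  }
  sel <- x$conc[, species, drop = FALSE]
  graphics::matplot(x$times, sel, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "concentration (nM)", ...)
  graphics::legend("topleft", legend = species, lty = 1,
                   col = seq_along(species), cex = 0.7, bty = "n")
  invisible(x)
}

#' Detect steady state in a simulated trajectory
#'
#' Scans the trajectory for the earliest time from which the largest
#' absolute concentration slope among the monitored species stays below
#' `tol` through the end of the run, over at least a trailing window.
#'
#' @param result a `crn_sim`.
#' @param window trailing window length in seconds (default 5% of the
#'   horizon).
#' @param tol slope threshold in nM/s.
#' @param species species names to monitor; defaults to the fluorescent
#'   reporters when present, otherwise all species.
#' @return list with `steady` (criterion holds over the trailing window) and
#'   `time` (earliest steady time, NA when never reached).
#' @export
detect_steady_state <- function(result, window = NULL, tol = 1e-6,
                                species = NULL) {
  stopifnot(inherits(result, "crn_sim"))
  t <- result$times
  if (is.null(window)) window <- 0.05 * max(t)
  if (is.null(species)) {
    species <- grep("^FLUOR\\[", result$species, value = TRUE)
    if (!length(species)) species <- result$species
  }
  conc <- result$conc[, species, drop = FALSE]
  dt <- diff(t)
  slope <- abs(apply(conc, 2L, diff)) / dt
  max_slope <- if (is.null(dim(slope))) abs(slope) else
    apply(slope, 1L, max)                       # per interval
  quiet <- max_slope < tol
  ## earliest interval index from which all later intervals are quiet
  first_quiet <- if (any(!quiet)) max(which(!quiet)) + 1L else 1L
  if (first_quiet > length(quiet)) {
    return(list(steady = FALSE, time = NA_real_))
  }
  steady_time <- t[first_quiet]
  ## steady only if the quiet tail covers at least the trailing window
  steady <- (max(t) - steady_time) >= window ||
    (first_quiet == 1L)                          # constant from the start
  list(steady = steady,
       time = if (first_quiet == 1L) 0 else steady_time)
}

#' Write a trajectory as CSV
#'
#' One `time` column plus one column per species, concentrations in nM.
#'
#' @param result a `crn_sim`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(result, path) {
  stopifnot(inherits(result, "crn_sim"))
  df <- data.frame(time = result$times, result$conc, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
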