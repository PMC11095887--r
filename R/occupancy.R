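#' State-occupation probabilities from per-edge hazard increments
#'
#' Product-integral (Aalen-Johansen type) state-occupation computation on a
#' uniform time grid, generalized to the two-phase clock-reset design:
#' phase-I transitions run on the calendar clock; on entry into a phase-II
#' state the clock resets, the phase-II sub-chain is evaluated on the reset
#' clock, and the two are chained by total probability over the phase-I
#' entry-time distribution. Within a grid step, increments are treated as
#' constant competing hazards (stay probability `exp(-sum)`, movers split
#' proportionally), which is exact for piecewise-constant hazards.
#'
#' @param graph a [build_state_graph()] object.
#' @param increments named list over `graph$edges$id` of `T x n` matrices of
#'   expected hazard increments per grid step (rows = steps between
#'   consecutive grid points, columns = subjects). Phase-II edges are indexed
#'   on the reset clock.
#' @param grid uniform, increasing time grid of length `T + 1` (months).
#' @param patient_id optional subject identifiers.
#' @return object of class `risk_trajectories`: list with `time`, `states`,
#'   and `prob`, an array `(T+1) x n_states x n` of occupation probabilities
#'   (each time slice sums to 1 per subject).
#' @export
occupancy_from_hazards <- function(graph, increments, grid,
                                   patient_id = NULL) {
  steps <- diff(grid)
  if (any(abs(steps - steps[1L]) > 1e-9))
    stop("grid must be uniform for phase chaining")
  Tn <- length(grid) - 1L
  eids <- graph$edges$id
  miss <- setdiff(eids, names(increments))
  if (length(miss)) stop("missing hazard increments for: ",
                         paste(miss, collapse = ", "))
  n <- ncol(increments[[eids[1L]]])
  states <- graph$states
  p1 <- states[graph$phase[states] == 1L]
  p2 <- states[graph$phase[states] == 2L]

  # discrete AJ over `sub_states`; edges to states outside the set are
  # recorded as external-entry increments dQ
  aj <- function(sub_states, init_mass, external) {
    P <- matrix(0, length(sub_states), n,
                dimnames = list(sub_states, NULL))
    P[init_mass$state, ] <- init_mass$mass
    occ <- array(0, c(Tn + 1L, length(sub_states), n))
    occ[1L, , ] <- P
    dQ <- lapply(external, function(s) matrix(0, Tn, n))
    names(dQ) <- external
    ed <- graph$edges[graph$edges$from %in% sub_states, , drop = FALSE]
    for (t in seq_len(Tn)) {
      newP <- P
      for (s in unique(ed$from)) {
        es <- ed[ed$from == s, , drop = FALSE]
        inc <- lapply(es$id, function(e) increments[[e]][t, ])
        tot <- Reduce(`+`, inc)
        stay <- exp(-tot)
        flow <- P[s, ] * (1 - stay)
        newP[s, ] <- newP[s, ] - flow
        safe_tot <- ifelse(tot > 0, tot, 1)
        for (j in seq_len(nrow(es))) {
          part <- flow * inc[[j]] / safe_tot
          tgt <- es$to[j]
          if (tgt %in% sub_states) newP[tgt, ] <- newP[tgt, ] + part
          else dQ[[tgt]][t, ] <- dQ[[tgt]][t, ] + part
        }
      }
      P <- newP
      occ[t + 1L, , ] <- P
    }
    list(occ = occ, dQ = dQ)
  }

  prob <- array(0, c(Tn + 1L, length(states), n),
                dimnames = list(NULL, states, patient_id))
  if (length(p1)) {
    entered <- unique(graph$edges$to[graph$edges$from %in% p1 &
                                       graph$edges$to %in% p2])
    ph1 <- aj(p1, list(state = graph$initial, mass = rep(1, n)), entered)
    prob[, p1, ] <- ph1$occ
  } else {
    entered <- graph$initial
    ph1 <- list(dQ = stats::setNames(
      list({m <- matrix(0, Tn, n); m}), entered))
    # initial state already in phase II: all mass enters at time 0
  }

  if (length(p2)) {
    for (s in names(ph1$dQ)) {
      dQ <- ph1$dQ[[s]]
      if (all(dQ == 0) && !(length(p1) == 0 && s == graph$initial)) next
      sub <- aj(p2, list(state = s, mass = rep(1, n)), character(0))
      L <- sub$occ  # (T+1) x p2 x n occupancy since entry
      if (length(p1) == 0L && s == graph$initial) {
        prob[, p2, ] <- L
      } else {
        # chain: P(s', t) += sum_u dQ[u] * L(s', t - u); entries land
        # mid-step on average, so evaluate L at the midpoint (average of
        # adjacent grid values) for O(step^2) accuracy
        for (t in seq_len(Tn)) {
          u <- seq_len(t)
          i1 <- t - u + 1L
          i2 <- pmin(i1 + 1L, Tn + 1L)
          for (sp in seq_along(p2)) {
            Ls <- L[, sp, , drop = FALSE]
            dim(Ls) <- c(Tn + 1L, n)
            Lmid <- 0.5 * (Ls[i1, , drop = FALSE] + Ls[i2, , drop = FALSE])
            contrib <- dQ[u, , drop = FALSE] * Lmid
            prob[t + 1L, p2[sp], ] <- prob[t + 1L, p2[sp], ] +
              colSums(contrib)
          }
        }
      }
    }
  }
  structure(list(time = grid, states = states, prob = prob,
                 patient_id = patient_id),
            class = "risk_trajectories")
}

#' @export
print.risk_trajectories <- function(x, ...) {
  cat("risk_trajectories:", dim(x$prob)[3L], "subjects,",
      length(x$states), "states, grid", x$time[1L], "..",
      x$time[length(x$time)], "months\n")
  invisible(x)
}

#' Occupation probabilities at a time point
#' @param traj a `risk_trajectories`.
#' @param at time (months) on the grid.
#' @return matrix n x states.
#' @export
occupancy_at <- function(traj, at) {
  idx <- which(abs(traj$time - at) < 1e-9)
  if (!length(idx)) {
    if (at > max(traj$time))
      stop("time ", at, " beyond trajectory grid (extrapolation not allowed)")
    idx <- max(which(traj$time <= at))
  }
  t(traj$prob[idx, , ])
}

#' Progression-free survival from a trajectory
#'
#' PFS at the horizon is the probability of being alive and in remission:
#' the summed occupation probability of the remission states (default the
#' on-induction and post-induction remission states S0 and S3).
#'
#' @param traj `risk_trajectories`.
#' @param horizon months (default 60 = 5 years).
#' @param remission_states states counted as progression-free.
#' @return named numeric vector of PFS probabilities per subject.
#' @export
predict_pfs <- function(traj, horizon = 60, remission_states = c("S0", "S3")) {
  bad <- setdiff(remission_states, traj$states)
  if (length(bad)) stop("unknown remission state(s): ",
                        paste(bad, collapse = ", "))
  occ <- occupancy_at(traj, horizon)
  out <- rowSums(occ[, remission_states, drop = FALSE])
  stats::setNames(out, traj$patient_id)
}
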