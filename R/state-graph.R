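#' Build the two-phase multi-state structure
#'
#' The default graph has six states across two phases. Phase I (induction,
#' clock = months from diagnosis): `S0` on induction, `S1` progression during
#' induction, `S2` lost to follow-up / non-disease death in phase I. Phase II
#' (post-induction, clock reset at the end of induction): `S3` remission after
#' induction, `S4` post-induction progression, `S5` death. Default transitions:
#' S0->S1, S0->S2, S0->S3, S1->S5, S3->S4, S3->S5, S4->S5. `S2` is treated as
#' absorbing. Hazards for a transition run on the clock of the phase of its
#' source state (semi-Markov reset at S3 entry).
#'
#' @param config optional list with `states` (character), `edges`
#'   (data.frame from,to), `phase` (named integer 1/2 per state),
#'   `initial` (default first state).
#' @return object of class `state_graph`.
#' @export
build_state_graph <- function(config = NULL) {
  if (is.null(config)) {
    config <- list(
      states = c("S0", "S1", "S2", "S3", "S4", "S5"),
      edges = data.frame(
        from = c("S0", "S0", "S0", "S1", "S3", "S3", "S4"),
        to   = c("S1", "S2", "S3", "S5", "S4", "S5", "S5"),
        stringsAsFactors = FALSE),
      phase = c(S0 = 1L, S1 = 1L, S2 = 1L, S3 = 2L, S4 = 2L, S5 = 2L),
      initial = "S0")
  }
  states <- config$states
  edges <- config$edges
  if (!all(c(edges$from, edges$to) %in% states))
    stop("edge references unknown state: ",
         paste(setdiff(c(edges$from, edges$to), states), collapse = ", "))
  initial <- config$initial %||% states[1L]
  phase <- config$phase
  if (is.null(phase)) phase <- stats::setNames(rep(1L, length(states)), states)
  # reachability from the initial state
  reach <- initial
  repeat {
    nxt <- unique(c(reach, edges$to[edges$from %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  unreachable <- setdiff(states, reach)
  if (length(unreachable))
    stop("unreachable state(s): ", paste(unreachable, collapse = ", "))
  absorbing <- setdiff(states, unique(edges$from))
  edges$id <- paste(edges$from, edges$to, sep = "->")
  structure(list(states = states, edges = edges, phase = phase,
                 initial = initial, absorbing = absorbing),
            class = "state_graph")
}

#' @export
print.state_graph <- function(x, ...) {
  cat("state_graph:", length(x$states), "states,", nrow(x$edges),
      "transitions\n  phase I:",
      paste(x$states[x$phase[x$states] == 1L], collapse = " "),
      "\n  phase II:",
      paste(x$states[x$phase[x$states] == 2L], collapse = " "),
      "\n  edges:", paste(x$edges$id, collapse = ", "), "\n")
  invisible(x)
}

#' Validate observed multi-state trajectories
#'
#' Histories are long tables (patient_id, state, entry_time) in months from
#' diagnosis; every patient starts in the initial state at time 0, entry times
#' are nondecreasing, consecutive states follow graph edges, and at most one
#' absorbing state is entered.
#'
#' @param histories data.frame (patient_id, state, entry_time).
#' @param graph a `state_graph`.
#' @return invisibly `TRUE`; stops with the first violation found.
#' @export
validate_histories <- function(histories, graph = build_state_graph()) {
  sp <- split(histories[c("state", "entry_time")], histories$patient_id)
  edge_ids <- graph$edges$id
  for (pid in names(sp)) {
    h <- sp[[pid]]
    h <- h[order(h$entry_time), , drop = FALSE]
    if (h$state[1L] != graph$initial || h$entry_time[1L] != 0)
      stop("patient ", pid, ": history must start in ", graph$initial,
           " at time 0")
    if (is.unsorted(h$entry_time))
      stop("patient ", pid, ": entry times decrease")
    if (nrow(h) > 1L) {
      steps <- paste(h$state[-nrow(h)], h$state[-1L], sep = "->")
      bad <- setdiff(steps, edge_ids)
      if (length(bad))
        stop("patient ", pid, ": transition not in graph: ", bad[1L])
    }
    n_abs <- sum(h$state %in% graph$absorbing)
    if (n_abs > 1L)
      stop("patient ", pid, ": multiple absorbing states entered")
  }
  invisible(TRUE)
}

#' Per-transition counting-process data
#'
#' Converts histories into per-edge (start, stop, status) risk intervals on
#' each edge's phase clock: phase-I edges run on months from diagnosis,
#' phase-II edges on months from entry into the first phase-II state
#' (remission), implementing the clock reset at the end of induction.
#'
#' @param histories long history table.
#' @param followup named vector (by patient_id) of censoring times in months
#'   from diagnosis.
#' @param graph a `state_graph`.
#' @return named list over edge ids of data.frames
#'   (patient_id, start, stop, status).
#' @export
transition_data <- function(histories, followup, graph = build_state_graph()) {
  h <- histories[order(histories$patient_id, histories$entry_time), , drop = FALSE]
  n <- nrow(h)
  pid <- as.character(h$patient_id)
  cens <- followup[pid]
  if (any(is.na(cens)))
    stop("no follow-up time for patient(s): ",
         paste(utils::head(unique(pid[is.na(cens)]), 5), collapse = ", "))
  is_last <- c(pid[-1L] != pid[-n], TRUE)
  exit <- c(h$entry_time[-1L], NA_real_)
  exit[is_last] <- unname(cens[is_last])
  nxt <- c(h$state[-1L], NA_character_)
  nxt[is_last] <- NA_character_
  # phase-II clock anchor: first entry into a phase-II state, per patient
  in_p2 <- graph$phase[h$state] == 2L
  anchor_t <- ifelse(in_p2, h$entry_time, NA_real_)
  anchor <- stats::ave(anchor_t, pid, FUN = function(x)
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  entry <- h$entry_time
  entry[in_p2] <- entry[in_p2] - anchor[in_p2]
  exit[in_p2] <- exit[in_p2] - anchor[in_p2]
  exit <- pmax(exit, entry + 1e-6)  # guard zero-length sojourns
  out <- lapply(seq_len(nrow(graph$edges)), function(j) {
    sel <- h$state == graph$edges$from[j]
    data.frame(patient_id = pid[sel],
               start = entry[sel], stop = exit[sel],
               status = as.integer(!is.na(nxt[sel]) &
                                     nxt[sel] == graph$edges$to[j]),
               stringsAsFactors = FALSE)
  })
  names(out) <- graph$edges$id
  out
}
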