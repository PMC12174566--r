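# ---------------------------------------------------------------------------
# The physiological update cycle. One simulation cycle (tau-1 -> tau)
# executes, in order:
#   1. generation/restriction among the five viscera  (synchronous)
#   2. exterior-to-interior influence, viscera -> bowels
#   3. interior-to-exterior feedback, bowels -> viscera
#   4. acupoint stimulation of the mapped organs
#   5. qi/blood/fluid generation
#   6. substance transport (uniform delivery to every organ)
#   7. substance absorption, then clamping to the state bounds
# Intermediate stages are conventionally written tau', tau'', tau~, tau^.
# ---------------------------------------------------------------------------

#' Five-Elements stage: generation and restriction among the viscera
#'
#' Updates each element-bearing viscus X synchronously from the previous
#' cycle's values: `f_X' = g * f_gen(X) - r * f_res(X) + s * f_X`, where
#' `gen(X)` is the viscus whose element generates X's and `res(X)` the one
#' whose element restricts it. Bowels and the pericardium are unchanged.
#'
#' @param states Named numeric vector over the twelve organs (cycle start).
#' @param params An [amt_params()] set.
#' @return Updated state vector (stage tau').
#' @export
step_viscera <- function(states, params = amt_params()) {
  vs <- viscera_elements()
  upd <- params$g * states[generation_partner(vs)] -
    params$r * states[restriction_partner(vs)] +
    params$s * states[vs]
  states[vs] <- upd
  states
}

#' Pair stages: viscera to bowels and back
#'
#' `step_viscera_to_bowels()` updates each bowel from its paired viscus's
#' stage-tau' value and its own previous value:
#' `f_B' = c * f_V' + s * f_B(prev)`. `step_bowels_to_viscera()` then feeds
#' back `f_V'' = c * f_B' + s * f_V'`. Both run over all six
#' exterior-interior pairs (including pericardium-triple energizer).
#'
#' @param states State vector at stage tau' (viscera updated).
#' @param prev State vector at the previous cycle (for the bowels' own
#'   lagged term).
#' @param params An [amt_params()] set.
#' @return Updated state vector.
#' @export
step_viscera_to_bowels <- function(states, prev, params = amt_params()) {
  o <- amt_organs()
  vs <- o$organ[o$klass == "viscus"]
  bs <- paired_organ(vs)
  states[bs] <- params$c * states[vs] + params$s * prev[bs]
  states
}

#' @rdname step_viscera_to_bowels
#' @export
step_bowels_to_viscera <- function(states, params = amt_params()) {
  o <- amt_organs()
  vs <- o$organ[o$klass == "viscus"]
  bs <- paired_organ(vs)
  states[vs] <- params$c * states[bs] + params$s * states[vs]
  states
}

#' Stimulation stage
#'
#' Applies the protocol's per-organ summed stimulation potential (see
#' [protocol_potentials()]): with the default `"deviation"` response each
#' organ V changes by `w * sum(fp) * |f_V - h|`; with `"additive"` by
#' `w * sum(fp)`.
#'
#' @param states State vector at stage tau~ (after the organ stages).
#' @param protocol An [amt_protocol()].
#' @param params An [amt_params()] set.
#' @return Updated state vector (stage tau^).
#' @export
apply_stimulation <- function(states, protocol, params = amt_params()) {
  pot <- protocol_potentials(protocol, params)
  gain <- switch(params$response,
    deviation = abs(states - params$h),
    additive = rep(1, length(states)))
  states + params$w * pot * gain
}

#' Substance generation
#'
#' Production of qi, blood and body fluid. Each substance i is produced at
#' `fi = fi_normal * B * G` where
#' `B = max(0, n*h - |sum_{j in O} f_j - n*h|) / (n*h)` measures systemic
#' balance over the organ set O and
#' `G = max(0, h - |f_me(i) - h|) / h` the health of the substance's
#' generator organ. Production is maximal (`fi_normal`) exactly when the
#' organ set and the generator sit at the healthy target.
#'
#' @param states State vector at stage tau^.
#' @param params An [amt_params()] set.
#' @return Named numeric vector `c(qi=, blood=, fluid=)`.
#' @export
substance_generation <- function(states, params = amt_params()) {
  n <- length(params$organ_set)
  h <- params$h
  bal <- max(0, n * h - abs(sum(states[params$organ_set]) - n * h)) / (n * h)
  vapply(c(qi = "qi", blood = "blood", fluid = "fluid"), function(i) {
    gen <- max(0, h - abs(states[[params$me[[i]]]] - h)) / h
    params$fi_normal[[i]] * bal * gen
  }, 0)
}

#' Substance transport
#'
#' Delivery of each substance pool to the organs. Transport is uniform:
#' every organ receives `fi / v * B * U`, with `B` the balance factor of
#' [substance_generation()] and `U = max(0, h - |f_ue(i) - h|) / h` the
#' health of the substance's transporter organ.
#'
#' @param fi Substance pools from [substance_generation()].
#' @param states State vector at stage tau^.
#' @param params An [amt_params()] set.
#' @return Named numeric vector of per-organ delivered amounts per
#'   substance (`qi`, `blood`, `fluid`).
#' @export
substance_transport <- function(fi, states, params = amt_params()) {
  n <- length(params$organ_set)
  h <- params$h
  bal <- max(0, n * h - abs(sum(states[params$organ_set]) - n * h)) / (n * h)
  vapply(c(qi = "qi", blood = "blood", fluid = "fluid"), function(i) {
    tr <- max(0, h - abs(states[[params$ue[[i]]]] - h)) / h
    fi[[i]] / params$v * bal * tr
  }, 0)
}

#' Substance absorption
#'
#' Closes the cycle: `f_V <- f_V * m + fq * q + fb * b + fl * l`, then
#' clamps every organ to the state bounds.
#'
#' @param states State vector at stage tau^.
#' @param deliveries Per-organ delivered amounts from
#'   [substance_transport()].
#' @param params An [amt_params()] set.
#' @return State vector at cycle end (tau), clamped.
#' @export
substance_absorption <- function(states, deliveries, params = amt_params()) {
  out <- states * params$m + deliveries[["qi"]] * params$q +
    deliveries[["blood"]] * params$b + deliveries[["fluid"]] * params$l
  pmin(pmax(out, params$state_bounds[1]), params$state_bounds[2])
}

amt_cycle_direct <- function(states, protocol, params) {
  prev <- states
  st <- step_viscera(states, params)
  st <- step_viscera_to_bowels(st, prev, params)
  st <- step_bowels_to_viscera(st, params)
  st <- apply_stimulation(st, protocol, params)
  fi <- substance_generation(st, params)
  del <- substance_transport(fi, st, params)
  st <- substance_absorption(st, del, params)
  list(states = st, fi = fi, deliveries = del)
}

#' Simulate a treatment course
#'
#' Runs `steps` cycles of the physiological update from `initial` under
#' `protocol`. `mode = "direct"` evaluates the stage equations in sequence;
#' `mode = "cpn"` builds the colored Petri net via [build_amt_net()],
#' augments it with the TGTC schedule, and executes it cycle by cycle with
#' the seeded random firing policy. Both modes produce identical
#' trajectories (to floating-point noise from expression evaluation order).
#'
#' @param initial Named organ-state vector (see [amt_state()]).
#' @param protocol An [amt_protocol()] (or a named level vector).
#' @param steps Number of cycles `T >= 0`.
#' @param params An [amt_params()] set.
#' @param mode `"direct"` or `"cpn"`.
#' @param seed Integer seed (used by the `"cpn"` firing policy).
#' @return An `amt_trajectory`: data frame with columns `tau` (0..T), one
#'   column per organ, and the substance pools `qi`, `blood`, `fluid`.
#' @examples
#' traj <- amt_simulate(meniere_initial_state(),
#'                      meniere_reference_protocol(), steps = 10)
#' traj[traj$tau <= 3, c("tau", "liver", "spleen", "kidney")]
#' @export
amt_simulate <- function(initial, protocol = amt_protocol(integer()),
                         steps = 50L, params = amt_params(),
                         mode = c("direct", "cpn"), seed = 1L) {
  mode <- match.arg(mode)
  if (!inherits(protocol, "amt_protocol")) protocol <- amt_protocol(protocol)
  if (!inherits(params, "amt_params")) stop("params must be amt_params()")
  stopifnot(steps >= 0, steps == round(steps))
  stopifnot(is.numeric(initial), all(organ_names() %in% names(initial)))
  initial <- initial[organ_names()]

  rows <- matrix(NA_real_, steps + 1L, 15L,
                 dimnames = list(NULL, c(organ_names(),
                                         "qi", "blood", "fluid")))
  rows[1L, ] <- c(initial, params$fi_normal[c("qi", "blood", "fluid")])

  if (mode == "direct") {
    st <- initial
    for (tau in seq_len(steps)) {
      cyc <- amt_cycle_direct(st, protocol, params)
      st <- cyc$states
      rows[tau + 1L, ] <- c(st, cyc$fi)
    }
  } else {
    built <- build_amt_net(protocol, params, initial = initial)
    marking <- built$marking
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(seed)
    for (tau in seq_len(steps)) {
      marking <- tgtc_seed(built$net, marking, built$control)
      trace <- cpn_run(built$net, marking, max_steps = 1000L,
                       policy = "random", record_markings = FALSE)
      marking <- trace$final
      rows[tau + 1L, ] <- vapply(
        c(paste0("p_", organ_names()), "p_qi", "p_blood", "p_fluid"),
        function(p) marking[[p]][[1L]], 0)
    }
  }
  traj <- data.frame(tau = 0:steps, rows, check.names = FALSE)
  attr(traj, "protocol") <- protocol
  attr(traj, "params") <- params
  attr(traj, "mode") <- mode
  class(traj) <- c("amt_trajectory", "data.frame")
  traj
}

#' @export
print.amt_trajectory <- function(x, ...) {
  cat("<amt_trajectory> ", nrow(x) - 1L, " cycles, mode=",
      attr(x, "mode") %||% "?", "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4L), digits = 4)
  if (nrow(x) > 4L) cat("  ... (", nrow(x) - 4L, " more rows)\n", sep = "")
  invisible(x)
}

#' Organ columns of a trajectory
#' @param traj An `amt_trajectory` (or compatible data frame).
#' @return Numeric matrix, rows tau = 0..T, columns the twelve organs.
#' @export
trajectory_states <- function(traj) {
  as.matrix(as.data.frame(traj)[, organ_names(), drop = FALSE])
}
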