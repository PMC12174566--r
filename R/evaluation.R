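# ---------------------------------------------------------------------------
# Multicriteria treatment assessment: PTR (in-range time ratio), fRMSD
# (binary windowed-RMSD indicator), PET (reference-envelope similarity),
# combined into the weighted Eval score. The initial condition (tau = 0)
# is excluded from the PTR/PET denominators: a protocol is not penalized
# for the presenting pathology.
# ---------------------------------------------------------------------------

#' Evaluation weights
#'
#' @param ptr,rmsd,pet Weights of the three components; must sum to 1.
#'   Defaults 0.4, 0.4, 0.2.
#' @return An `eval_weights` list.
#' @export
eval_weights <- function(ptr = 0.4, rmsd = 0.4, pet = 0.2) {
  w <- list(ptr = ptr, rmsd = rmsd, pet = pet)
  if (abs(ptr + rmsd + pet - 1) > 1e-12)
    stop("evaluation weights must sum to 1")
  structure(w, class = "eval_weights")
}

#' In-range time ratio (PTR)
#'
#' Mean over the monitored organs of the fraction of cycles tau = 1..T the
#' organ's state spends inside the healthy range.
#'
#' @param traj An `amt_trajectory` (or data frame with organ columns).
#' @param monitored Organ names to average over (default: all twelve).
#' @param healthy_range Two-element numeric range (default `[2.5, 3.5]`).
#' @return A value in `[0, 1]`.
#' @export
ptr <- function(traj, monitored = organ_names(),
                healthy_range = c(2.5, 3.5)) {
  if (!length(monitored)) stop("monitored organ set is empty")
  st <- trajectory_states(traj)[, monitored, drop = FALSE]
  if (nrow(st) < 2L) stop("trajectory has no post-initial cycles")
  st <- st[-1L, , drop = FALSE]
  inr <- st >= healthy_range[1] & st <= healthy_range[2]
  mean(colMeans(inr))
}

#' Windowed-RMSD health indicator (fRMSD)
#'
#' For each organ, the root-mean-square deviation from the healthy target
#' is computed over every sliding window of `window` cycles (tau = 1..T)
#' and minimized over windows; the indicator is 1 iff the worst organ's
#' minimum windowed RMSD is at or below `threshold`, meaning every organ
#' attains a sustained near-healthy episode.
#'
#' @param traj An `amt_trajectory`.
#' @param threshold RMSD threshold (default 0.5).
#' @param window Window length in cycles (default 10; must not exceed T).
#' @param target Healthy target level (default 3).
#' @param monitored Organ names (default: all twelve).
#' @return Integer 0 or 1.
#' @export
frmsd <- function(traj, threshold = 0.5, window = 10L, target = 3,
                  monitored = organ_names()) {
  st <- trajectory_states(traj)[, monitored, drop = FALSE]
  st <- st[-1L, , drop = FALSE]
  n <- nrow(st)
  if (window > n) stop("window exceeds trajectory length")
  sq <- (st - target)^2
  worst <- 0
  for (x in seq_len(ncol(sq))) {
    cs <- c(0, cumsum(sq[, x]))
    win <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
    worst <- max(worst, sqrt(min(win)))
  }
  as.integer(worst <= threshold)
}

#' Reference envelope
#'
#' Pointwise minimum and maximum over one or more reference trajectories,
#' per organ and cycle, stored with an acceptance margin.
#'
#' @param refs A single `amt_trajectory` or a list of them (equal lengths).
#' @param margin Margin delta added on both sides when testing membership
#'   (default 0.25).
#' @return An `amt_envelope` with matrices `min`, `max` (rows tau = 0..T)
#'   and the margin.
#' @export
build_envelope <- function(refs, margin = 0.25) {
  if (is.data.frame(refs)) refs <- list(refs)
  stopifnot(length(refs) >= 1L, margin >= 0)
  mats <- lapply(refs, trajectory_states)
  nr <- unique(vapply(mats, nrow, 0L))
  if (length(nr) != 1L) stop("reference trajectories differ in length")
  lo <- Reduce(pmin, mats)
  hi <- Reduce(pmax, mats)
  structure(list(min = lo, max = hi, margin = margin, n_refs = length(refs)),
            class = "amt_envelope")
}

#' Envelope similarity (PET)
#'
#' Fraction of (organ, cycle) points of the test trajectory lying inside
#' the reference envelope widened by its margin, over cycles tau = 1..T.
#'
#' @param traj An `amt_trajectory`.
#' @param envelope An [build_envelope()] result of matching length.
#' @return A value in `[0, 1]`.
#' @export
pet <- function(traj, envelope) {
  stopifnot(inherits(envelope, "amt_envelope"))
  st <- trajectory_states(traj)
  if (nrow(st) != nrow(envelope$min))
    stop("trajectory and envelope lengths differ")
  organs <- colnames(envelope$min)
  st <- st[-1L, organs, drop = FALSE]
  lo <- envelope$min[-1L, , drop = FALSE] - envelope$margin
  hi <- envelope$max[-1L, , drop = FALSE] + envelope$margin
  mean(st >= lo & st <= hi)
}

#' Combined evaluation score
#'
#' The weighted composite
#' `Eval = w_ptr * PTR + w_rmsd * fRMSD + w_pet * PET`; monotone in each
#' component and confined to `[0, 1]` for components in range. Values are
#' reported unrounded; round only for display (conventionally 3 decimals).
#'
#' @param ptr,frmsd,pet Component values (`ptr`, `pet` in `[0, 1]`,
#'   `frmsd` 0 or 1).
#' @param weights An [eval_weights()] triple.
#' @return Numeric score.
#' @export
eval_score <- function(ptr, frmsd, pet, weights = eval_weights()) {
  if (!inherits(weights, "eval_weights")) weights <- do.call(eval_weights, weights)
  stopifnot(ptr >= 0, ptr <= 1, pet >= 0, pet <= 1, frmsd %in% c(0, 1))
  weights$ptr * ptr + weights$rmsd * frmsd + weights$pet * pet
}

#' Evaluate a simulated protocol against a reference envelope
#'
#' @param traj The test `amt_trajectory`.
#' @param envelope Reference [build_envelope()].
#' @param weights [eval_weights()].
#' @param healthy_range,threshold,window,target,monitored Component
#'   settings (see [ptr()], [frmsd()]).
#' @return An `amt_eval`: list with `PTR`, `fRMSD`, `PET`, `Eval` and a
#'   per-organ in-range diagnostic.
#' @export
evaluate_trajectory <- function(traj, envelope, weights = eval_weights(),
                                healthy_range = c(2.5, 3.5),
                                threshold = 0.5, window = 10L, target = 3,
                                monitored = organ_names()) {
  p <- ptr(traj, monitored, healthy_range)
  f <- frmsd(traj, threshold, window, target, monitored)
  e <- pet(traj, envelope)
  st <- trajectory_states(traj)[-1L, monitored, drop = FALSE]
  per_organ <- colMeans(st >= healthy_range[1] & st <= healthy_range[2])
  structure(list(PTR = p, fRMSD = f, PET = e,
                 Eval = eval_score(p, f, e, weights),
                 per_organ_ptr = per_organ),
            class = "amt_eval")
}

#' @export
print.amt_eval <- function(x, ...) {
  cat(sprintf("<amt_eval> PTR=%.3f fRMSD=%d PET=%.3f Eval=%.3f\n",
              x$PTR, x$fRMSD, x$PET, x$Eval))
  invisible(x)
}
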