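# ---------------------------------------------------------------------------
# Randomized protocol exploration: three acupoint-selection strategies and
# batch simulate-evaluate-rank screening.
#
#   R  completely random over the full registry, excluding the acupoints
#      of the known reference treatment
#   M  meridian-based: points on the meridians of the affected organs
#   C  correspondence-based: points on the meridians of the affected
#      organs' exterior-interior paired bowels
# ---------------------------------------------------------------------------

#' Clinical condition specification
#'
#' @param excess,deficient Disjoint sets of organ names describing the
#'   pattern.
#' @param reference The known reference [amt_protocol()] (its acupoints
#'   are excluded from the R strategy's pool).
#' @return A `condition_spec`.
#' @export
condition_spec <- function(excess = character(), deficient = character(),
                           reference = amt_protocol(integer())) {
  stopifnot(all(c(excess, deficient) %in% organ_names()))
  if (length(intersect(excess, deficient)))
    stop("an organ cannot be both excess and deficient")
  if (!inherits(reference, "amt_protocol")) reference <- amt_protocol(reference)
  structure(list(excess = excess, deficient = deficient,
                 reference = reference),
            class = "condition_spec")
}

#' Protocol generation settings
#'
#' @param strategy `"R"`, `"M"` or `"C"`.
#' @param n_points Range of protocol sizes sampled uniformly (default
#'   5 to 7).
#' @param levels Allowed stimulation levels (default: nonzero integers in
#'   `[-5, 5]`, sampled uniformly).
#' @return A `generation_config`.
#' @export
generation_config <- function(strategy = c("R", "M", "C"),
                              n_points = 5:7,
                              levels = c(-5:-1, 1:5)) {
  strategy <- match.arg(strategy)
  stopifnot(length(n_points) >= 1L, all(n_points >= 1L),
            all(levels != 0), all(abs(levels) <= 5),
            all(levels == round(levels)))
  structure(list(strategy = strategy, n_points = as.integer(n_points),
                 levels = as.integer(levels)),
            class = "generation_config")
}

strategy_pool <- function(cond, strategy) {
  affected <- c(cond$excess, cond$deficient)
  if (strategy == "R") {
    setdiff(all_acupoints(), names(cond$reference))
  } else {
    organs <- if (strategy == "M") affected else paired_bowel(affected)
    mer <- meridians_of_organs(organs)
    pts <- all_acupoints()
    pts[sub("[0-9]+$", "", pts) %in% mer]
  }
}

#' Generate a randomized protocol
#'
#' Samples a protocol under the configured strategy: point count uniform
#' over `cfg$n_points`, acupoints sampled without replacement from the
#' strategy's pool, levels sampled uniformly from `cfg$levels`.
#'
#' @param cond A [condition_spec()].
#' @param cfg A [generation_config()].
#' @param seed Optional integer seed; the same seed reproduces the same
#'   protocol. `NULL` draws from the current RNG stream.
#' @return An [amt_protocol()].
#' @export
generate_protocol <- function(cond, cfg = generation_config(), seed = NULL) {
  stopifnot(inherits(cond, "condition_spec"),
            inherits(cfg, "generation_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  pool <- strategy_pool(cond, cfg$strategy)
  n <- if (length(cfg$n_points) == 1L) cfg$n_points
       else sample(cfg$n_points, 1L)
  if (length(pool) < n)
    stop("candidate pool (", length(pool), ") smaller than protocol size ", n)
  pts <- sample(pool, n)
  lv <- sample(cfg$levels, n, replace = TRUE)
  amt_protocol(stats::setNames(lv, pts))
}

#' Batch screen protocols
#'
#' Simulates each protocol from a shared initial state, evaluates each
#' trajectory against the reference envelope, and returns the ranking by
#' Eval (descending; ties keep input order). A failing protocol is
#' reported with `NA` scores and a warning rather than aborting the batch.
#'
#' @param protocols Named list of [amt_protocol()] objects.
#' @param initial Shared initial organ-state vector.
#' @param envelope Reference [build_envelope()].
#' @param steps,params,mode,seed Simulation settings (see
#'   [amt_simulate()]).
#' @param weights [eval_weights()].
#' @param ... Further component settings passed to
#'   [evaluate_trajectory()].
#' @return Data frame with columns `group`, `n_points`, `PTR`, `fRMSD`,
#'   `PET`, `Eval`, ordered by `Eval` descending; the trajectories are
#'   attached as attribute `"trajectories"`.
#' @export
batch_screen <- function(protocols, initial, envelope, steps = 50L,
                         params = amt_params(), weights = eval_weights(),
                         mode = "direct", seed = 1L, ...) {
  stopifnot(is.list(protocols))
  groups <- if (!length(protocols)) character() else
    names(protocols) %||% paste0("P", seq_along(protocols))
  rows <- vector("list", length(protocols))
  trajs <- vector("list", length(protocols))
  names(trajs) <- groups
  for (i in seq_along(protocols)) {
    res <- tryCatch({
      traj <- amt_simulate(initial, protocols[[i]], steps = steps,
                           params = params, mode = mode, seed = seed)
      ev <- evaluate_trajectory(traj, envelope, weights, ...)
      trajs[[i]] <- traj
      data.frame(group = groups[i], n_points = length(protocols[[i]]),
                 PTR = ev$PTR, fRMSD = ev$fRMSD, PET = ev$PET,
                 Eval = ev$Eval, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("protocol ", groups[i], " failed: ", conditionMessage(e),
              call. = FALSE)
      data.frame(group = groups[i], n_points = length(protocols[[i]]),
                 PTR = NA_real_, fRMSD = NA_integer_, PET = NA_real_,
                 Eval = NA_real_, stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  if (!length(rows)) {
    out <- data.frame(group = character(), n_points = integer(),
                      PTR = numeric(), fRMSD = integer(), PET = numeric(),
                      Eval = numeric(), stringsAsFactors = FALSE)
    attr(out, "trajectories") <- trajs
    return(out)
  }
  out <- do.call(rbind, rows)
  if (nrow(out)) {
    out <- out[order(-xtfrm(out$Eval)), , drop = FALSE]  # stable, NA last
    rownames(out) <- NULL
  }
  attr(out, "trajectories") <- trajs
  out
}
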