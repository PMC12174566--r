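# ---------------------------------------------------------------------------
# Colored Petri net core: places, transitions, arcs, markings, firing.
#
# Tokens are R scalars typed by their place's color set:
#   REAL    -> finite numeric
#   INT     -> whole-valued numeric
#   STRING  -> character
#   UNIT    -> the value TRUE (the anonymous "black" token)
#   PRODUCT -> an unnamed list of scalars
# A marking maps each place id to a list of token values (a multiset).
#
# Nets precompute a per-transition index (input/output arcs, variable
# sources, constant requirements) so the enabling test on a gated
# transition whose control place is empty costs almost nothing; the
# engine's hot loop relies on that.
# ---------------------------------------------------------------------------

.cpn_colorsets <- c("REAL", "INT", "STRING", "UNIT", "PRODUCT")

#' Unit token
#'
#' The anonymous token carried by `UNIT`-colored places (control places and
#' plain weighted arcs).
#' @return The unit token value.
#' @export
unit_token <- function() TRUE

token_ok <- function(value, colorset) {
  switch(colorset,
    REAL    = is.numeric(value) && length(value) == 1L && is.finite(value),
    INT     = is.numeric(value) && length(value) == 1L && is.finite(value) &&
              value == round(value),
    STRING  = is.character(value) && length(value) == 1L && !is.na(value),
    UNIT    = isTRUE(value),
    PRODUCT = is.list(value),
    FALSE)
}

#' Construct a place
#'
#' @param id Unique place identifier.
#' @param colorset One of `"REAL"`, `"INT"`, `"STRING"`, `"UNIT"`,
#'   `"PRODUCT"`.
#' @param label Free-text label (defaults to the id).
#' @return A `cpn_place` object.
#' @export
cpn_place <- function(id, colorset = "UNIT", label = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  colorset <- match.arg(colorset, .cpn_colorsets)
  structure(list(id = id, colorset = colorset, label = label),
            class = "cpn_place")
}

#' Construct a transition
#'
#' @param id Unique transition identifier.
#' @param guard `NULL` (always true), a guard string in the arc-expression
#'   mini-language (see [parse_cpn_expr()]), or a quoted expression.
#' @return A `cpn_transition` object.
#' @export
cpn_transition <- function(id, guard = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.character(guard)) guard <- parse_cpn_expr(guard, guard = TRUE)
  if (!is.null(guard) && !is.language(guard) && !is.logical(guard))
    stop("guard must be NULL, a string, or a quoted expression")
  structure(list(id = id, guard = guard), class = "cpn_transition")
}

#' Construct an arc
#'
#' Normal arcs carry tokens; their expression is either an integer weight
#' `n` (n unit tokens) or a character vector of mini-language expressions,
#' one per token. A bare variable name (`"x"`) binds/emits a single token.
#' Inhibitor arcs run place-to-transition only and enable their transition
#' only while the source place is empty; their expression is ignored.
#'
#' @param src,dst Place and transition ids (one of each, either direction).
#' @param expr Integer weight or character vector of expressions.
#' @param kind `"normal"` or `"inhibitor"`.
#' @return A `cpn_arc` object.
#' @export
cpn_arc <- function(src, dst, expr = 1L, kind = c("normal", "inhibitor")) {
  kind <- match.arg(kind)
  stopifnot(is.character(src), length(src) == 1L,
            is.character(dst), length(dst) == 1L)
  if (is.numeric(expr)) {
    stopifnot(length(expr) == 1L, expr >= 0, expr == round(expr))
    exprs <- rep(list(unit_token()), expr)
  } else if (is.character(expr)) {
    exprs <- lapply(expr, parse_cpn_expr)
  } else {
    stop("arc expr must be an integer weight or character expressions")
  }
  vars <- unique(unlist(lapply(exprs, all.vars)))
  structure(list(src = src, dst = dst, kind = kind, expr_spec = expr,
                 exprs = exprs, vars = vars %||% character()),
            class = "cpn_arc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a colored Petri net
#'
#' Validates the bipartite structure: arcs connect a place to a transition
#' or vice versa, all endpoints exist, ids are unique, inhibitor arcs run
#' place-to-transition, and every guard only references variables bound by
#' that transition's input arcs.
#'
#' @param places List of [cpn_place()] objects.
#' @param transitions List of [cpn_transition()] objects.
#' @param arcs List of [cpn_arc()] objects.
#' @param meta Optional metadata (module grouping labels, for reporting).
#' @return A `cpn_net` object.
#' @export
cpn_net <- function(places, transitions, arcs, meta = list()) {
  stopifnot(is.list(places), is.list(transitions), is.list(arcs))
  pids <- vapply(places, function(p) p$id, "")
  tids <- vapply(transitions, function(t) t$id, "")
  if (anyDuplicated(pids)) stop("duplicate place ids")
  if (anyDuplicated(tids)) stop("duplicate transition ids")
  if (any(pids %in% tids)) stop("place and transition ids must be disjoint")
  names(places) <- pids
  names(transitions) <- tids

  for (a in arcs) {
    sp <- a$src %in% pids; st <- a$src %in% tids
    dp <- a$dst %in% pids; dt <- a$dst %in% tids
    if (!((sp && dt) || (st && dp)))
      stop("arc ", a$src, " -> ", a$dst,
           " must connect a place and a transition")
    if (a$kind == "inhibitor" && !(sp && dt))
      stop("inhibitor arcs must run place -> transition")
  }

  # per-transition index for the enabling/firing hot path
  tinfo <- stats::setNames(lapply(tids, function(tid) {
    list(in_arcs = list(), out_arcs = list(), inh = character(),
         vars = character(), var_places = list(), guard = NULL)
  }), tids)
  p_dep <- stats::setNames(rep(list(character()), length(pids)), pids)

  for (i in seq_along(arcs)) {
    a <- arcs[[i]]
    if (a$src %in% pids) {
      ti <- tinfo[[a$dst]]
      if (a$kind == "inhibitor") {
        ti$inh <- c(ti$inh, a$src)
      } else {
        const <- length(a$vars) == 0L
        ti$in_arcs[[length(ti$in_arcs) + 1L]] <- list(
          src = a$src, exprs = a$exprs, n = length(a$exprs),
          const_vals = if (const) lapply(a$exprs, function(e)
            if (is.language(e)) eval_cpn_expr(e, list()) else e),
          arc_index = i)
        ti$vars <- unique(c(ti$vars, a$vars))
        for (e in a$exprs) {
          if (is.symbol(e)) {
            v <- as.character(e)
            ti$var_places[[v]] <- unique(c(ti$var_places[[v]], a$src))
          }
        }
      }
      tinfo[[a$dst]] <- ti
      p_dep[[a$src]] <- unique(c(p_dep[[a$src]], a$dst))
    } else {
      ti <- tinfo[[a$src]]
      const <- length(a$vars) == 0L
      ti$out_arcs[[length(ti$out_arcs) + 1L]] <- list(
        dst = a$dst, exprs = a$exprs,
        colorset = places[[a$dst]]$colorset,
        const_vals = if (const) lapply(a$exprs, function(e)
          if (is.language(e)) eval_cpn_expr(e, list()) else e),
        arc_index = i)
      tinfo[[a$src]] <- ti
    }
  }

  for (tid in tids) {
    g <- transitions[[tid]]$guard
    if (is.language(g)) {
      extra <- setdiff(all.vars(g), tinfo[[tid]]$vars)
      if (length(extra))
        stop("guard of ", tid, " references unbound variables: ",
             paste(extra, collapse = ", "))
    }
    tinfo[[tid]]$guard <- if (is.language(g)) g else NULL
  }

  structure(list(places = places, transitions = transitions, arcs = arcs,
                 tinfo = tinfo, p_dep = p_dep, meta = meta),
            class = "cpn_net")
}

#' @export
print.cpn_net <- function(x, ...) {
  cat("<cpn_net> ", length(x$places), " places, ",
      length(x$transitions), " transitions, ",
      length(x$arcs), " arcs\n", sep = "")
  invisible(x)
}

#' Construct a marking
#'
#' @param net A [cpn_net()].
#' @param tokens Named list: place id -> vector or list of token values.
#'   Unlisted places start empty.
#' @return A `cpn_marking`: named list of token lists, one entry per place.
#' @export
cpn_marking <- function(net, tokens = list()) {
  stopifnot(inherits(net, "cpn_net"))
  pids <- names(net$places)
  unknown <- setdiff(names(tokens), pids)
  if (length(unknown)) stop("unknown places in marking: ",
                            paste(unknown, collapse = ", "))
  m <- stats::setNames(rep(list(list()), length(pids)), pids)
  for (pid in names(tokens)) {
    vals <- tokens[[pid]]
    if (!is.list(vals)) vals <- as.list(vals)
    cs <- net$places[[pid]]$colorset
    for (v in vals) {
      if (!token_ok(v, cs))
        stop("token ", deparse1(v), " violates color set ", cs,
             " of place ", pid)
    }
    m[[pid]] <- vals
  }
  structure(m, class = "cpn_marking")
}

#' @export
print.cpn_marking <- function(x, ...) {
  nonempty <- x[vapply(x, length, 0L) > 0L]
  if (!length(nonempty)) {
    cat("<cpn_marking> (empty)\n")
    return(invisible(x))
  }
  cat("<cpn_marking>\n")
  for (pid in names(nonempty)) {
    cat("  ", pid, ": ",
        paste(vapply(nonempty[[pid]], deparse1, ""), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# -- multiset helpers (identical()-based; no string keys) -------------------

token_match <- function(have, v) {
  for (j in seq_along(have)) if (identical(have[[j]], v)) return(j)
  0L
}

# remove `need` (list) from `have` (list); NULL if not contained
multiset_remove <- function(have, need) {
  for (v in need) {
    j <- token_match(have, v)
    if (j == 0L) return(NULL)
    have <- have[-j]
  }
  have
}

unique_tokens <- function(vals) {
  if (length(vals) < 2L) return(vals)
  keep <- logical(length(vals))
  out <- list()
  for (j in seq_along(vals)) {
    if (token_match(out, vals[[j]]) == 0L) out[[length(out) + 1L]] <- vals[[j]]
  }
  out
}

# stable deterministic ordering: numerics by value, everything else by
# deparsed key (only reached for STRING/PRODUCT tokens)
sort_tokens <- function(vals) {
  if (length(vals) < 2L) return(vals)
  if (all(vapply(vals, function(v) is.numeric(v) || is.logical(v), TRUE))) {
    vals[order(unlist(vals))]
  } else {
    vals[order(vapply(vals, deparse1, ""))]
  }
}

# -- enabling and firing ----------------------------------------------------

# required tokens per input place under `binding`; NULL if the guard fails
transition_requirements <- function(net, tid, binding) {
  ti <- net$tinfo[[tid]]
  if (!is.null(ti$guard)) {
    ok <- tryCatch(isTRUE(eval_cpn_expr(ti$guard, binding)),
                   error = function(e) FALSE)
    if (!ok) return(NULL)
  }
  req <- list()
  for (a in ti$in_arcs) {
    vals <- if (!is.null(a$const_vals)) a$const_vals
            else lapply(a$exprs, function(e)
              if (is.language(e)) eval_cpn_expr(e, binding) else e)
    req[[a$src]] <- c(req[[a$src]], vals)
  }
  req
}

requirements_met <- function(marking, req) {
  for (pid in names(req)) {
    if (is.null(multiset_remove(marking[[pid]], req[[pid]]))) return(FALSE)
  }
  TRUE
}

# cheap necessary condition: every input place holds at least as many
# tokens as the arc demands, every inhibitor place is empty
quick_reject <- function(ti, marking) {
  for (p in ti$inh) if (length(marking[[p]]) > 0L) return(TRUE)
  for (a in ti$in_arcs) {
    if (length(marking[[a$src]]) < a$n) return(TRUE)
  }
  FALSE
}

#' Enabled bindings of a transition
#'
#' Returns every variable binding under which the transition may fire:
#' each normal input arc's token demand is covered by its place, every
#' inhibitor input place is empty, and the guard evaluates to true. A
#' transition without variables yields at most one (empty) binding.
#'
#' Candidate values for a variable come from the places whose input arcs
#' carry it as a bare symbol (falling back to all input places), sorted
#' deterministically, so repeated calls enumerate bindings in a fixed
#' order.
#'
#' @param net A [cpn_net()].
#' @param marking A [cpn_marking()].
#' @param t Transition id.
#' @param max_bindings Enumeration budget; exceeding it is an error.
#' @return List of bindings (named lists, possibly empty lists).
#' @export
enabled <- function(net, marking, t, max_bindings = 10000L) {
  stopifnot(inherits(net, "cpn_net"))
  ti <- net$tinfo[[t]]
  if (is.null(ti)) stop("unknown transition: ", t)
  if (quick_reject(ti, marking)) return(list())
  vars <- ti$vars
  if (!length(vars)) {
    req <- transition_requirements(net, t, list())
    if (is.null(req) || !requirements_met(marking, req)) return(list())
    return(list(stats::setNames(list(), character())))
  }
  doms <- vector("list", length(vars))
  names(doms) <- vars
  all_tokens <- NULL
  for (v in vars) {
    srcs <- ti$var_places[[v]]
    if (is.null(srcs)) {
      if (is.null(all_tokens)) {
        all_tokens <- unique_tokens(
          do.call(c, lapply(ti$in_arcs, function(a) marking[[a$src]])))
      }
      dom <- all_tokens
    } else {
      dom <- unique_tokens(do.call(c, lapply(srcs, function(p) marking[[p]])))
    }
    if (!length(dom)) return(list())
    doms[[v]] <- sort_tokens(dom)
  }
  if (prod(vapply(doms, length, 0L)) > max_bindings)
    stop("binding enumeration budget exceeded for transition ", t)
  out <- list()
  binding <- stats::setNames(vector("list", length(vars)), vars)
  recurse <- function(k) {
    if (k > length(vars)) {
      req <- transition_requirements(net, t, binding)
      if (!is.null(req) && requirements_met(marking, req)) {
        out[[length(out) + 1L]] <<- binding
      }
      return(invisible())
    }
    for (val in doms[[k]]) {
      binding[[k]] <<- val
      recurse(k + 1L)
    }
  }
  recurse(1L)
  out
}

produce_outputs <- function(net, m, tid, binding) {
  for (a in net$tinfo[[tid]]$out_arcs) {
    vals <- if (!is.null(a$const_vals)) a$const_vals
            else lapply(a$exprs, function(e)
              if (is.language(e)) eval_cpn_expr(e, binding) else e)
    for (v in vals) {
      if (!token_ok(v, a$colorset))
        stop("transition ", tid, " would place token ", deparse1(v),
             " violating color set ", a$colorset, " of ", a$dst)
    }
    m[[a$dst]] <- c(m[[a$dst]], vals)
  }
  m
}

fire_unchecked <- function(net, marking, tid, binding, req) {
  m <- unclass(marking)
  for (pid in names(req)) m[[pid]] <- multiset_remove(m[[pid]], req[[pid]])
  m <- produce_outputs(net, m, tid, binding)
  structure(m, class = "cpn_marking")
}

#' Fire a transition
#'
#' Consumes the tokens demanded by the input arcs under `binding` and adds
#' the tokens produced by the output arc expressions. The input marking is
#' left untouched; a new marking is returned. Firing a transition that is
#' not enabled under the given binding is an error.
#'
#' @inheritParams enabled
#' @param binding A named list of variable values (empty list for
#'   variable-free transitions).
#' @return A new `cpn_marking`.
#' @export
fire <- function(net, marking, t, binding = list()) {
  stopifnot(inherits(net, "cpn_net"), inherits(marking, "cpn_marking"))
  ti <- net$tinfo[[t]]
  if (is.null(ti)) stop("unknown transition: ", t)
  for (p in ti$inh) {
    if (length(marking[[p]]) > 0L) stop("transition ", t, " is inhibited")
  }
  req <- transition_requirements(net, t, binding)
  if (is.null(req)) stop("transition ", t, " is not enabled: guard fails")
  if (!requirements_met(marking, req))
    stop("transition ", t, " is not enabled: insufficient tokens")
  fire_unchecked(net, marking, t, binding, req)
}

# all enabled (transition, binding) pairs, in deterministic order; with a
# cache, only transitions in `dirty` are recomputed
enabled_pairs <- function(net, marking, cache = NULL, dirty = NULL) {
  tids <- names(net$transitions)
  if (is.null(cache)) {
    cache <- lapply(tids, function(tid) enabled(net, marking, tid))
    names(cache) <- tids
  } else if (length(dirty)) {
    for (tid in dirty) cache[[tid]] <- enabled(net, marking, tid)
  }
  pairs <- list()
  for (tid in tids) {
    bs <- cache[[tid]]
    for (b in bs) pairs[[length(pairs) + 1L]] <- list(transition = tid,
                                                      binding = b)
  }
  list(pairs = pairs, cache = cache)
}

#' Execute a net
#'
#' Repeatedly selects an enabled (transition, binding) pair and fires it,
#' until no transition is enabled or `max_steps` firings have occurred.
#' Policy `"random"` picks uniformly among enabled pairs using the seeded
#' RNG; `"priority"` picks the first enabled pair in `priority` order (then
#' net order). The same seed and policy always reproduce the same trace.
#'
#' @inheritParams enabled
#' @param m0 Initial marking.
#' @param max_steps Maximum number of firings (>= 0).
#' @param seed Integer seed for the `"random"` policy, or `NULL` to draw
#'   from the current RNG stream.
#' @param policy `"random"` or `"priority"`.
#' @param priority Character vector of transition ids tried first under the
#'   `"priority"` policy.
#' @param record_markings Keep the marking after every firing in the trace.
#' @return A `cpn_trace`: list with `steps` (each: step, transition,
#'   binding, marking), `final` marking, and the run settings.
#' @export
cpn_run <- function(net, m0, max_steps = 10000L, seed = NULL,
                    policy = c("random", "priority"), priority = NULL,
                    record_markings = TRUE) {
  policy <- match.arg(policy)
  stopifnot(max_steps >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  tids <- names(net$transitions)
  rank <- if (is.null(priority)) seq_along(tids) else {
    r <- match(tids, priority)
    ifelse(is.na(r), length(priority) + seq_along(tids), r)
  }
  names(rank) <- tids
  marking <- m0
  steps <- list()
  cache <- NULL
  dirty <- NULL
  step <- 0L
  while (step < max_steps) {
    ep <- enabled_pairs(net, marking, cache, dirty)
    cache <- ep$cache
    pairs <- ep$pairs
    if (!length(pairs)) break
    sel <- if (policy == "random") {
      if (length(pairs) == 1L) 1L else sample.int(length(pairs), 1L)
    } else {
      which.min(vapply(pairs, function(p) rank[[p$transition]], 0))
    }
    tid <- pairs[[sel]]$transition
    b <- pairs[[sel]]$binding
    req <- transition_requirements(net, tid, b)
    marking <- fire_unchecked(net, marking, tid, b, req)
    step <- step + 1L
    steps[[step]] <- list(step = step, transition = tid, binding = b,
                          marking = if (record_markings) marking else NULL)
    ti <- net$tinfo[[tid]]
    touched <- unique(c(vapply(ti$in_arcs, `[[`, "", "src"),
                        vapply(ti$out_arcs, `[[`, "", "dst")))
    dirty <- unique(unlist(net$p_dep[touched], use.names = FALSE))
  }
  structure(list(steps = steps, initial = m0, final = marking,
                 seed = seed, policy = policy),
            class = "cpn_trace")
}

#' Transition sequence of a trace
#' @param trace A `cpn_trace`.
#' @return Character vector of fired transition ids, in order.
#' @export
trace_transitions <- function(trace) {
  stopifnot(inherits(trace, "cpn_trace"))
  vapply(trace$steps, function(s) s$transition, "")
}

#' @export
print.cpn_trace <- function(x, ...) {
  cat("<cpn_trace> ", length(x$steps), " firings (policy=", x$policy, ")\n",
      sep = "")
  if (length(x$steps)) {
    cat(" ", paste(trace_transitions(x), collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Write a firing trace as a line-per-firing text log
#'
#' @param trace A `cpn_trace`.
#' @param path Output file (or `""` for stdout).
#' @export
write_trace_log <- function(trace, path = "") {
  lines <- vapply(trace$steps, function(s) {
    b <- if (length(s$binding)) {
      paste(names(s$binding), vapply(s$binding, deparse1, ""),
            sep = "=", collapse = ",")
    } else "-"
    sprintf("%d\t%s\t%s", s$step, s$transition, b)
  }, "")
  writeLines(c("step\ttransition\tbinding", lines), con = path)
  invisible(path)
}

#' Exhaustive firing sequences (brute-force oracle)
#'
#' Depth-first exploration of every enabled choice from `m0`, recording the
#' transition sequence of each maximal run (dead marking) and of each run
#' cut off at `depth`. Intended as a test oracle on small nets; the search
#' is aborted with an error when the node budget is exceeded.
#'
#' @inheritParams cpn_run
#' @param depth Maximum sequence length explored.
#' @param max_nodes Exploration budget (number of visited prefixes).
#' @return List of unique character vectors of transition ids.
#' @export
reachable_sequences <- function(net, m0, depth = 20L, max_nodes = 50000L) {
  stopifnot(inherits(net, "cpn_net"), depth >= 0)
  seqs <- new.env(parent = emptyenv())
  nodes <- 0L
  recurse <- function(marking, prefix) {
    nodes <<- nodes + 1L
    if (nodes > max_nodes)
      stop("reachable_sequences: exploration budget exceeded (",
           max_nodes, " nodes)")
    pairs <- enabled_pairs(net, marking)$pairs
    if (!length(pairs) || length(prefix) >= depth) {
      key <- paste(prefix, collapse = "\r")
      assign(key, prefix, envir = seqs)
      return(invisible())
    }
    for (p in pairs) {
      req <- transition_requirements(net, p$transition, p$binding)
      recurse(fire_unchecked(net, marking, p$transition, p$binding, req),
              c(prefix, p$transition))
    }
  }
  recurse(m0, character())
  out <- mget(ls(seqs, sorted = TRUE), envir = seqs)
  names(out) <- NULL
  out
}
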