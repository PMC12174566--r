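# Independent oracles and small net builders used across the suite.

# Brute-force binding enumerator: every variable ranges over the union of
# ALL tokens in ALL input places; containment is checked with a count-based
# multiset representation. Kept deliberately independent of the engine's
# domain pruning and identical()-based multisets.
brute_force_enabled <- function(net, marking, tid) {
  arcs <- Filter(function(a) a$dst == tid && a$kind == "normal", net$arcs)
  inh <- Filter(function(a) a$dst == tid && a$kind == "inhibitor", net$arcs)
  for (a in inh) if (length(marking[[a$src]]) > 0L) return(list())
  vars <- sort(unique(unlist(lapply(arcs, `[[`, "vars"))))
  key <- function(v) paste(deparse(v), collapse = " ")
  counts <- function(vals) {
    k <- vapply(vals, key, "")
    as.list(table(k))
  }
  covered <- function(need, have) {
    all(vapply(names(need), function(k)
      !is.null(have[[k]]) && have[[k]] >= need[[k]], TRUE))
  }
  guard <- net$transitions[[tid]]$guard
  check <- function(binding) {
    if (is.language(guard)) {
      ok <- tryCatch(isTRUE(eval(guard, binding, baseenv())),
                     error = function(e) FALSE)
      if (!ok) return(FALSE)
    }
    for (pid in unique(vapply(arcs, `[[`, "", "src"))) {
      need <- unlist(lapply(Filter(function(a) a$src == pid, arcs),
                            function(a) lapply(a$exprs, function(e)
                              if (is.language(e)) eval(e, binding, baseenv())
                              else e)), recursive = FALSE)
      if (!covered(counts(need), counts(marking[[pid]]))) return(FALSE)
    }
    TRUE
  }
  pool <- unlist(lapply(arcs, function(a) marking[[a$src]]),
                 recursive = FALSE)
  pool <- pool[!duplicated(vapply(pool, key, ""))]
  if (!length(vars)) {
    return(if (check(list())) list(stats::setNames(list(), character()))
           else list())
  }
  if (!length(pool)) return(list())
  grid <- expand.grid(rep(list(seq_along(pool)), length(vars)))
  out <- list()
  for (r in seq_len(nrow(grid))) {
    b <- stats::setNames(lapply(seq_along(vars),
                                function(j) pool[[grid[r, j]]]), vars)
    if (check(b)) out[[length(out) + 1L]] <- b
  }
  out
}

# canonical string form of a binding list, for set comparison
binding_keys <- function(bindings) {
  sort(vapply(bindings, function(b) {
    if (!length(b)) return("<empty>")
    b <- b[order(names(b))]
    paste(names(b), vapply(b, function(v) paste(deparse(v), collapse = ""),
                           ""), sep = "=", collapse = ";")
  }, ""))
}

# all interleavings of two sequences, preserving internal order
interleavings <- function(a, b) {
  if (!length(a)) return(list(b))
  if (!length(b)) return(list(a))
  c(lapply(interleavings(a[-1], b), function(s) c(a[1], s)),
    lapply(interleavings(a, b[-1]), function(s) c(b[1], s)))
}

# all linear extensions of a partial order given as a (before, after) pair
# matrix over `elems`
linear_extensions <- function(elems, pairs) {
  recurse <- function(remaining, acc) {
    if (!length(remaining)) return(list(acc))
    ready <- Filter(function(x) {
      preds <- pairs[pairs[, 2] == x, 1]
      !any(preds %in% remaining)
    }, remaining)
    out <- list()
    for (x in ready) {
      out <- c(out, recurse(setdiff(remaining, x), c(acc, x)))
    }
    out
  }
  recurse(elems, character())
}

seq_key <- function(s) paste(s, collapse = ">")

# a net of bare transitions (no data places); behavior comes entirely from
# an added TGTC layer
bare_net <- function(tids) {
  cpn_net(places = list(),
          transitions = lapply(tids, cpn_transition),
          arcs = list())
}

# random series-parallel schedule over the given transition ids
random_schedule <- function(tids) {
  build <- function(ids) {
    if (length(ids) == 1L) return(sched_step(ids))
    k <- sample(seq_len(length(ids) - 1L), 1L)
    left <- build(ids[seq_len(k)])
    right <- build(ids[-seq_len(k)])
    if (stats::runif(1) < 0.5) sched_seq(left, right)
    else sched_par(left, right)
  }
  build(sample(tids))
}

# the two-3-chain + 4-suffix schedule used throughout (the concurrency
# worked example): two concurrent chains t1>t2>t3 and t6>t7>t8, then the
# fixed tail t5>t4>t10>t9
two_chain_schedule <- function() {
  sched_seq(
    sched_par(sched_seq("t1", "t2", "t3"), sched_seq("t6", "t7", "t8")),
    sched_seq("t5", "t4", "t10", "t9"))
}
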