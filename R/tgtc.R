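# ---------------------------------------------------------------------------
# Token-guided transition control (TGTC).
#
# A series-parallel schedule over a net's transitions is compiled into an
# auxiliary control layer: one UNIT control place per scheduled transition,
# control arcs chaining sequential steps, token splits opening concurrent
# branches, and shared join places (consumed with arc weight = branch
# count) closing them. The augmented net fires the scheduled transitions in
# exactly the linear extensions of the schedule's partial order, while the
# data layer is untouched.
# ---------------------------------------------------------------------------

#' Schedule constructors
#'
#' A schedule is a series-parallel tree whose leaves name transitions:
#' `sched_step(id)` a single transition, `sched_seq(...)` children run in
#' order, `sched_par(...)` children run concurrently. Bare character
#' strings are promoted to steps, so `sched_seq("t1", "t2")` works.
#'
#' @param id Transition id (for `sched_step`).
#' @param ... Child nodes (schedules or transition id strings).
#' @return A `tgtc_schedule` node.
#' @export
sched_step <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(kind = "step", id = id), class = "tgtc_schedule")
}

#' @rdname sched_step
#' @export
sched_seq <- function(...) {
  children <- lapply(list(...), as_schedule)
  if (!length(children)) stop("empty seq node")
  structure(list(kind = "seq", children = children), class = "tgtc_schedule")
}

#' @rdname sched_step
#' @export
sched_par <- function(...) {
  children <- lapply(list(...), as_schedule)
  if (!length(children)) stop("empty par node")
  structure(list(kind = "par", children = children), class = "tgtc_schedule")
}

as_schedule <- function(x) {
  if (inherits(x, "tgtc_schedule")) return(x)
  if (is.character(x) && length(x) == 1L) return(sched_step(x))
  stop("not a schedule node: ", deparse1(x))
}

#' Transitions named by a schedule
#' @param schedule A `tgtc_schedule`.
#' @return Character vector, in tree order.
#' @export
schedule_transitions <- function(schedule) {
  s <- as_schedule(schedule)
  switch(s$kind,
    step = s$id,
    unlist(lapply(s$children, schedule_transitions)))
}

validate_schedule <- function(schedule) {
  ids <- schedule_transitions(schedule)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("transition scheduled more than once: ",
         paste(unique(dup), collapse = ", "))
  ids
}

#' Read / write a schedule as structured text
#'
#' Schedules serialize as nested JSON objects, e.g.
#' `{"seq":[{"par":[{"seq":["t1","t2"]},"t3"]},"t4"]}`.
#'
#' @param x For writing: a schedule. For reading: a file path or JSON
#'   string.
#' @param path Output file, or `NULL` to return the JSON string.
#' @return `read_schedule()` a `tgtc_schedule`; `write_schedule()` the path
#'   or JSON string, invisibly.
#' @export
read_schedule <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  from_obj <- function(o) {
    if (is.character(o)) return(sched_step(o))
    if (is.list(o) && length(o) == 1L && names(o) %in% c("seq", "par")) {
      children <- lapply(o[[1L]], from_obj)
      node <- if (names(o) == "seq") do.call(sched_seq, children)
              else do.call(sched_par, children)
      return(node)
    }
    stop("malformed schedule document")
  }
  s <- from_obj(obj)
  validate_schedule(s)
  s
}

#' @rdname read_schedule
#' @export
write_schedule <- function(x, path = NULL) {
  to_obj <- function(s) {
    switch(s$kind,
      step = s$id,
      seq = list(seq = lapply(s$children, to_obj)),
      par = list(par = lapply(s$children, to_obj)))
  }
  json <- jsonlite::toJSON(to_obj(as_schedule(x)), auto_unbox = TRUE)
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(as.character(json), path)
  invisible(path)
}

#' Partial order induced by a schedule
#'
#' @param schedule A `tgtc_schedule`.
#' @return Two-column character matrix of (before, after) precedence pairs
#'   (transitive closure over sequential composition).
#' @export
schedule_order <- function(schedule) {
  pairs <- matrix(character(), 0L, 2L)
  recurse <- function(s) {
    if (s$kind == "step") return(s$id)
    elems <- lapply(s$children, recurse)
    if (s$kind == "seq") {
      for (i in seq_along(elems)) {
        for (j in seq_along(elems)) {
          if (i < j) {
            pairs <<- rbind(pairs, as.matrix(expand.grid(
              elems[[i]], elems[[j]], stringsAsFactors = FALSE)))
          }
        }
      }
    }
    unlist(elems)
  }
  recurse(as_schedule(schedule))
  dimnames(pairs) <- list(NULL, c("before", "after"))
  pairs
}

#' Augment a net with TGTC control structure
#'
#' Adds to `net`: a start place holding the cycle's control token, a start
#' transition that consumes it, one UNIT control place and input control
#' arc per scheduled transition, token-split arcs opening parallel blocks,
#' and shared join places (consumed with weight = branch count) closing
#' them. When a parallel block directly follows another parallel block a
#' synthetic control transition is inserted to collect the joined token and
#' re-split it. Data places and arcs are untouched, and removing the
#' control layer with [tgtc_strip()] restores the original net exactly.
#'
#' @param net A [cpn_net()].
#' @param schedule A `tgtc_schedule` over transitions of `net`.
#' @param start_transition Id of the added start transition.
#' @return List with `net` (augmented) and `control` (a
#'   `tgtc_augmentation`: control place map, start place, join places,
#'   added transition ids and arc count).
#' @export
tgtc_augment <- function(net, schedule, start_transition = "t_start") {
  stopifnot(inherits(net, "cpn_net"))
  schedule <- as_schedule(schedule)
  ids <- validate_schedule(schedule)
  missing <- setdiff(ids, names(net$transitions))
  if (length(missing))
    stop("scheduled transitions missing from net: ",
         paste(missing, collapse = ", "))
  if (start_transition %in% names(net$transitions))
    stop("start transition id already in net: ", start_transition)

  new_places <- list()
  new_trans <- list()
  new_arcs <- list()
  control_places <- character()
  join_places <- character()
  n_join <- 0L

  add_place <- function(id) {
    new_places[[length(new_places) + 1L]] <<- cpn_place(id, "UNIT")
    id
  }
  add_arc <- function(src, dst, weight = 1L) {
    new_arcs[[length(new_arcs) + 1L]] <<- cpn_arc(src, dst, weight)
  }

  # compile(node, feeders): wire `node` so it starts after every feeder
  # transition has fired; returns the node's terminal transition ids
  compile <- function(node, feeders) {
    if (node$kind == "step") {
      cp <- add_place(paste0("cp_", node$id))
      control_places[[node$id]] <<- cp
      for (f in feeders) add_arc(f, cp)
      # a step fed by k parallel terminals consumes all k tokens from the
      # shared place: that place is the join
      add_arc(cp, node$id, length(feeders))
      if (length(feeders) > 1L) join_places <<- c(join_places, cp)
      return(node$id)
    }
    if (node$kind == "seq") {
      for (child in node$children) feeders <- compile(child, feeders)
      return(feeders)
    }
    # par: needs a single splitting feeder
    if (length(feeders) > 1L) {
      n_join <<- n_join + 1L
      jp <- add_place(paste0("jp_", n_join))
      tj <- paste0("tj_", n_join)
      new_trans[[length(new_trans) + 1L]] <<- cpn_transition(tj)
      join_places <<- c(join_places, jp)
      for (f in feeders) add_arc(f, jp)
      add_arc(jp, tj, length(feeders))
      feeders <- tj
    }
    unlist(lapply(node$children, compile, feeders = feeders))
  }

  start_place <- add_place(paste0("s_", start_transition))
  new_trans[[length(new_trans) + 1L]] <- cpn_transition(start_transition)
  add_arc(start_place, start_transition)
  compile(schedule, start_transition)

  aug <- cpn_net(c(net$places, new_places),
                 c(net$transitions, new_trans),
                 c(net$arcs, new_arcs),
                 meta = net$meta)
  control <- structure(list(
    control_places = control_places,
    start_place = start_place,
    start_transition = start_transition,
    join_places = join_places,
    added_places = vapply(new_places, `[[`, "", "id"),
    added_transitions = vapply(new_trans, `[[`, "", "id"),
    n_control_arcs = length(new_arcs),
    schedule = schedule), class = "tgtc_augmentation")
  list(net = aug, control = control)
}

#' Remove a TGTC control layer
#'
#' @param net An augmented net.
#' @param control The `tgtc_augmentation` returned by [tgtc_augment()].
#' @return The original net (identical structure to the pre-augmentation
#'   net).
#' @export
tgtc_strip <- function(net, control) {
  stopifnot(inherits(net, "cpn_net"), inherits(control, "tgtc_augmentation"))
  drop_p <- control$added_places
  drop_t <- control$added_transitions
  # every control arc touches an added place or transition, so endpoint
  # filtering removes exactly the control layer
  keep_arc <- vapply(net$arcs, function(a) {
    !(a$src %in% c(drop_p, drop_t)) && !(a$dst %in% c(drop_p, drop_t))
  }, TRUE)
  cpn_net(net$places[setdiff(names(net$places), drop_p)],
          net$transitions[setdiff(names(net$transitions), drop_t)],
          net$arcs[keep_arc],
          meta = net$meta)
}

#' Initial control marking
#'
#' Adds the cycle's control token to the start place, leaving all data
#' tokens as given.
#'
#' @param net The augmented net.
#' @param marking Data marking (a [cpn_marking()] on the augmented net).
#' @param control The `tgtc_augmentation`.
#' @return A new marking with one unit token in the start place.
#' @export
tgtc_seed <- function(net, marking, control) {
  m <- unclass(marking)
  m[[control$start_place]] <- list(unit_token())
  structure(m, class = "cpn_marking")
}

#' Check a trace against a schedule
#'
#' True iff the trace's restriction to scheduled transitions respects the
#' schedule's partial order: no scheduled transition fires twice, and none
#' fires before all of its predecessors have fired. Prefixes of complete
#' runs (including the empty trace) pass.
#'
#' @param trace A `cpn_trace` or a character vector of transition ids.
#' @param schedule A `tgtc_schedule`.
#' @return Logical scalar.
#' @export
verify_order <- function(trace, schedule) {
  fired <- if (inherits(trace, "cpn_trace")) trace_transitions(trace)
           else as.character(trace)
  ids <- schedule_transitions(schedule)
  fired <- fired[fired %in% ids]
  if (anyDuplicated(fired)) return(FALSE)
  ord <- schedule_order(schedule)
  pos <- match(ids, fired)  # NA if not fired
  names(pos) <- ids
  for (i in seq_len(nrow(ord))) {
    a <- pos[[ord[i, "before"]]]
    b <- pos[[ord[i, "after"]]]
    if (!is.na(b) && (is.na(a) || a > b)) return(FALSE)
  }
  TRUE
}
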