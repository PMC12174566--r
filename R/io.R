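# ---------------------------------------------------------------------------
# Structured-text I/O: net serialization, run configurations, trajectory
# CSVs, evaluation reports, fixture materialization.
# CSV dialect: comma-separated, '.' decimal, 6 significant digits for
# states, LF line endings.
# ---------------------------------------------------------------------------

#' Read / write a net as structured text
#'
#' Nets serialize as JSON:
#' `{"places": [{"id","colorset","label"}], "transitions": [{"id","guard"}],`
#' `"arcs": [{"src","dst","kind","expr"}], "marking": {place: [tokens]}}`.
#' Arc expressions are integer weights or mini-language strings (see
#' [parse_cpn_expr()]); guards are mini-language strings.
#'
#' @param net A [cpn_net()].
#' @param path File path.
#' @param marking Optional [cpn_marking()] stored alongside the structure.
#' @return `read_cpn_net()`: list with `net` and `marking` (`NULL` if
#'   absent); `write_cpn_net()`: the path, invisibly.
#' @export
write_cpn_net <- function(net, path, marking = NULL) {
  stopifnot(inherits(net, "cpn_net"))
  doc <- list(
    places = lapply(net$places, function(p)
      list(id = p$id, colorset = p$colorset, label = p$label)),
    transitions = lapply(net$transitions, function(t) {
      out <- list(id = t$id)
      if (is.language(t$guard)) out$guard <- deparse1(t$guard)
      out
    }),
    arcs = lapply(net$arcs, function(a) {
      expr <- if (is.numeric(a$expr_spec)) as.integer(a$expr_spec)
              else as.list(a$expr_spec)
      list(src = a$src, dst = a$dst, kind = a$kind, expr = expr)
    }))
  doc$places <- unname(doc$places)
  doc$transitions <- unname(doc$transitions)
  doc$arcs <- unname(doc$arcs)
  if (!is.null(marking)) {
    doc$marking <- lapply(unclass(marking), function(vals) vals)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cpn_net
#' @export
read_cpn_net <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  places <- lapply(doc$places, function(p)
    cpn_place(p$id, p$colorset %||% "UNIT", p$label %||% p$id))
  transitions <- lapply(doc$transitions, function(t)
    cpn_transition(t$id, t$guard))
  arcs <- lapply(doc$arcs, function(a) {
    expr <- a$expr
    expr <- if (is.numeric(expr)) expr else unlist(expr)
    cpn_arc(a$src, a$dst, expr, a$kind %||% "normal")
  })
  net <- cpn_net(places, transitions, arcs)
  marking <- NULL
  if (!is.null(doc$marking)) {
    marking <- cpn_marking(net, doc$marking)
  }
  list(net = net, marking = marking)
}

.config_keys <- c("initial", "acupoints", "steps", "params", "seed", "mode",
                  "eval")
.eval_keys <- c("weights", "threshold", "window", "margin", "monitored")

#' Read and validate a run configuration
#'
#' A run configuration is a JSON document:
#' `{"initial": {"liver": 5, ...}, "acupoints": {"GB20": -3, ...},`
#' `"steps": 50, "params": {...}, "seed": 1, "mode": "direct",`
#' `"eval": {"weights": {"ptr":0.4,"rmsd":0.4,"pet":0.2}, "threshold":0.5,`
#' `"window":10, "margin":0.25}}`. Unknown keys are rejected; omitted
#' keys take package defaults.
#'
#' @param path File path (or JSON string).
#' @return An `amt_run_config`: validated list with `initial`, `protocol`,
#'   `steps`, `params`, `seed`, `mode`, `eval`.
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(doc), .config_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  params <- do.call(amt_params, as.list(doc$params %||% list()))
  initial <- amt_state(unlist(doc$initial %||% list()), params = params)
  protocol <- amt_protocol(unlist(doc$acupoints %||% list()))
  steps <- doc$steps %||% 50L
  stopifnot(is.numeric(steps), steps >= 0, steps == round(steps))
  mode <- match.arg(doc$mode %||% "direct", c("direct", "cpn"))
  seed <- as.integer(doc$seed %||% 1L)
  ev <- as.list(doc$eval %||% list())
  unknown <- setdiff(names(ev), .eval_keys)
  if (length(unknown))
    stop("unknown eval keys: ", paste(unknown, collapse = ", "))
  ev$weights <- if (is.null(ev$weights)) eval_weights()
                else do.call(eval_weights, as.list(ev$weights))
  ev$threshold <- ev$threshold %||% 0.5
  ev$window <- as.integer(ev$window %||% 10L)
  ev$margin <- ev$margin %||% 0.25
  ev$monitored <- ev$monitored %||% organ_names()
  structure(list(initial = initial, protocol = protocol,
                 steps = as.integer(steps), params = params, seed = seed,
                 mode = mode, eval = ev),
            class = "amt_run_config")
}

#' Write / read a trajectory CSV
#'
#' Columns: `tau`, the twelve organs, `qi`, `blood`, `fluid`; states at 6
#' significant digits.
#'
#' @param traj An `amt_trajectory`.
#' @param path File path.
#' @return `read_trajectory()` an `amt_trajectory`;
#'   `write_trajectory()` the path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, TRUE) & names(df) != "tau"
  df[num] <- lapply(df[num], function(x) signif(x, 6L))
  con <- file(path, open = "wb")  # LF line endings on every platform
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tau", organ_names())
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("trajectory file lacks columns: ", paste(missing, collapse = ", "))
  class(df) <- c("amt_trajectory", "data.frame")
  df
}

#' Write an evaluation report
#'
#' @param report Data frame with columns `group`, `PTR`, `fRMSD`, `PET`,
#'   `Eval` (as from [batch_screen()]).
#' @param path Output path; `.json` writes a JSON array, anything else a
#'   CSV with scores rounded half-to-even to 3 decimals for display.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  } else {
    df <- report
    for (cl in c("PTR", "PET", "Eval")) {
      if (cl %in% names(df)) df[[cl]] <- round(df[[cl]], 3L)
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  }
  invisible(path)
}

#' Materialize the shipped fixtures
#'
#' Writes into `dir`: the meridian registry tables, the sixteen protocol
#' files, the Meniere's case initial state, a ready-to-run reference
#' configuration, and two synthetic evaluation trajectories with known
#' component scores (constant healthy and constant excess; `synthetic` in
#' the filename marks them as constructed, not simulated).
#'
#' @param dir Output directory (created if needed).
#' @param steps Length of the synthetic trajectories.
#' @return Character vector of written paths, invisibly.
#' @export
make_fixtures <- function(dir, steps = 50L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  put <- function(p) { paths <<- c(paths, p); p }

  for (f in c("meridians.csv", "ex_series.csv", "protocols.json")) {
    file.copy(system.file("extdata", f, package = "amtsim"),
              put(file.path(dir, f)), overwrite = TRUE)
  }
  jsonlite::write_json(as.list(meniere_initial_state()),
                       put(file.path(dir, "meniere_initial.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  config <- list(
    initial = list(liver = 5, spleen = 1, kidney = 1),
    acupoints = as.list(unclass(meniere_reference_protocol())),
    steps = 50L, seed = 1L, mode = "direct")
  jsonlite::write_json(config, put(file.path(dir, "meniere_reference.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (grp in names(fixture_protocols())) {
    pr <- fixture_protocols()[[grp]]
    jsonlite::write_json(as.list(unclass(pr)),
                         put(file.path(dir, paste0("protocol_", grp, ".json"))),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  flat <- function(level) {
    st <- matrix(level, steps + 1L, 12L,
                 dimnames = list(NULL, organ_names()))
    df <- data.frame(tau = 0:steps, st,
                     qi = rep(3, steps + 1L), blood = rep(3, steps + 1L),
                     fluid = rep(3, steps + 1L), check.names = FALSE)
    class(df) <- c("amt_trajectory", "data.frame")
    df
  }
  write_trajectory(flat(3), put(file.path(dir, "synthetic_healthy.csv")))
  write_trajectory(flat(5), put(file.path(dir, "synthetic_excess.csv")))
  invisible(paths)
}
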