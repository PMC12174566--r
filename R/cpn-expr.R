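#' Arc-expression mini-language
#'
#' Arc expressions and transition guards are written in a small, safe
#' arithmetic language: numeric constants, variable names, the operators
#' `+ - * /`, parentheses, and the functions `abs`, `min`, `max`. Guards may
#' additionally use comparisons (`< > <= >= == !=`), logical connectives
#' (`& | !`) and the constants `TRUE`/`FALSE`. Expressions are parsed with
#' the R parser and the resulting syntax tree is validated against this
#' whitelist, so no other function can be called from a net file.
#'
#' @param text A single character string.
#' @param guard Logical; allow the comparison/logical extensions.
#' @return A quoted R expression (language object or atomic constant).
#' @examples
#' parse_cpn_expr("0.1 * x + 0.9 * y")
#' parse_cpn_expr("x > 3", guard = TRUE)
#' @export
parse_cpn_expr <- function(text, guard = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  parsed <- tryCatch(str2lang(text), error = function(e) {
    stop("invalid expression: ", text, call. = FALSE)
  })
  validate_cpn_expr(parsed, guard = guard)
  parsed
}

.cpn_expr_calls <- c("+", "-", "*", "/", "(", "abs", "min", "max")
.cpn_guard_calls <- c(.cpn_expr_calls, "<", ">", "<=", ">=", "==", "!=",
                      "&", "|", "!")

validate_cpn_expr <- function(e, guard = FALSE) {
  allowed <- if (guard) .cpn_guard_calls else .cpn_expr_calls
  recurse <- function(x) {
    if (is.numeric(x) || is.symbol(x)) return(invisible(TRUE))
    if (is.logical(x) && guard) return(invisible(TRUE))
    if (is.call(x)) {
      fn <- x[[1L]]
      if (!is.symbol(fn) || !(as.character(fn) %in% allowed)) {
        stop("disallowed call in expression: ", deparse1(x), call. = FALSE)
      }
      for (i in seq_along(x)[-1L]) recurse(x[[i]])
      return(invisible(TRUE))
    }
    stop("disallowed element in expression: ", deparse1(x), call. = FALSE)
  }
  recurse(e)
  invisible(e)
}

#' Variables referenced by an arc expression or guard
#'
#' @param expr A quoted expression as returned by [parse_cpn_expr()], or a
#'   character string.
#' @return Character vector of variable names (possibly empty).
#' @export
cpn_expr_vars <- function(expr) {
  if (is.character(expr)) expr <- str2lang(expr)
  all.vars(expr)
}

# Evaluate a whitelisted expression under a binding (named list).
eval_cpn_expr <- function(expr, binding) {
  eval(expr, envir = binding, enclos = .cpn_eval_env)
}

.cpn_eval_env <- local({
  env <- new.env(parent = emptyenv())
  for (fn in c("+", "-", "*", "/", "(", "abs", "min", "max",
               "<", ">", "<=", ">=", "==", "!=", "&", "|", "!")) {
    assign(fn, get(fn, envir = baseenv()), envir = env)
  }
  env
})
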