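# ---------------------------------------------------------------------------
# Model parameters and stimulation protocols.
# ---------------------------------------------------------------------------

#' Model parameters
#'
#' Returns the physiological parameter set with the published defaults:
#' `g = 0.15` (generation), `r = 0.05` (restriction), `s = 0.9` (organ
#' self-persistence), `c = 0.1` (viscus-bowel coupling), `e = 0.25`
#' (stimulation efficiency), `w = 0.01` (stimulation weight), `h = 3`
#' (healthy target level), `v = 10` (transport divisor), `m = 0.999`
#' (retention), `q`, `b`, `l` (`0.004`, `0.004`, `0.002`: absorption of
#' qi, blood and fluid). At these defaults `g - r + s = 1` and `c + s = 1`,
#' so the all-healthy state (every organ at `h`) is an exact fixed point of
#' the organ stages, and `fi_normal = 3` makes the substance loop
#' reconstitute it exactly.
#'
#' Reconstruction choices that the main text leaves open are configurable:
#'
#' * `stimulus`: `"linear"` (default) maps a stimulation level to the
#'   potential `fp = mu * e * v`; `"saturating"` uses the saturating
#'   quotient `fp = mu * e * v / (v + e * v)` (i.e. `mu * e / (1 + e)`);
#'   or supply `function(mu, params)`.
#' * `response`: how an organ converts the summed potential of its treated
#'   acupoints into a state change. `"deviation"` (default) scales by the
#'   organ's current distance from the healthy target,
#'   `delta = w * sum(fp) * |f - h|`, so treatment acts on disordered
#'   organs and vanishes as balance is restored; `"additive"` applies
#'   `delta = w * sum(fp)` unconditionally.
#' * `vessel_routing`: where stimulation of organ-less points (conception/
#'   governor vessel and EX points) is routed: `"viscera"` (default;
#'   split equally, weight 1/5, over the five element-bearing viscera),
#'   `"none"`, or a named numeric vector of organ weights.
#' * `organ_set`: organs summed in the substance generation/transport
#'   balance factor (default: all twelve).
#' * `me`, `ue`: generator and transporter organ per substance (defaults:
#'   the spleen generates all three; qi moves via the lung, blood via the
#'   heart, fluid via the kidney).
#' * `fi_normal`: baseline production per substance (default 3 each).
#'
#' @param ... Named overrides of any field above.
#' @return An `amt_params` list.
#' @export
amt_params <- function(...) {
  p <- list(
    g = 0.15, r = 0.05, s = 0.9, c = 0.1, e = 0.25, w = 0.01,
    h = 3, v = 10, m = 0.999, q = 0.004, b = 0.004, l = 0.002,
    fi_normal = c(qi = 3, blood = 3, fluid = 3),
    organ_set = organ_names(),
    me = c(qi = "spleen", blood = "spleen", fluid = "spleen"),
    ue = c(qi = "lung", blood = "heart", fluid = "kidney"),
    stimulus = "linear",
    response = "deviation",
    vessel_routing = "viscera",
    state_bounds = c(0.5, 5.5),
    healthy_range = c(2.5, 3.5))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown parameters: ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  substances <- c("qi", "blood", "fluid")
  stopifnot(all(substances %in% names(p$fi_normal)),
            all(substances %in% names(p$me)),
            all(substances %in% names(p$ue)),
            all(p$organ_set %in% organ_names()),
            length(p$state_bounds) == 2L, p$state_bounds[1] < p$state_bounds[2],
            length(p$healthy_range) == 2L)
  if (is.character(p$stimulus))
    p$stimulus <- match.arg(p$stimulus, c("linear", "saturating"))
  else stopifnot(is.function(p$stimulus))
  p$response <- match.arg(p$response, c("deviation", "additive"))
  if (is.character(p$vessel_routing)) {
    p$vessel_routing <- match.arg(p$vessel_routing, c("viscera", "none"))
  } else {
    stopifnot(is.numeric(p$vessel_routing),
              all(names(p$vessel_routing) %in% organ_names()))
  }
  structure(p, class = "amt_params")
}

#' Stimulation potential of a level
#'
#' Maps an integer stimulation level `mu` in `[-5, 5]` (negative =
#' purgation, positive = tonification, 0 = untreated) to the stimulus
#' potential `fp`. The default `"linear"` form is `fp = mu * e * v`; the
#' `"saturating"` alternative is `fp = mu * e * v / (v + e * v)`. Both are
#' odd in `mu` and zero at `mu = 0`.
#'
#' @param mu Integer vector of levels in `[-5, 5]`.
#' @param params An [amt_params()] set.
#' @return Numeric vector of potentials.
#' @export
stimulus <- function(mu, params = amt_params()) {
  stopifnot(all(mu >= -5 & mu <= 5), all(mu == round(mu)))
  f <- params$stimulus
  if (is.function(f)) return(f(mu, params))
  switch(f,
    linear = mu * params$e * params$v,
    saturating = mu * params$e * params$v / (params$v + params$e * params$v))
}

#' Stimulation protocol
#'
#' A map from acupoint codes to integer stimulation levels in `[-5, 5]`
#' (sign: purgation/tonification; 0 means untreated and is not stored).
#'
#' @param levels Named integer vector (names: acupoint codes in any
#'   accepted spelling).
#' @return An `amt_protocol`: named integer vector with canonical codes.
#' @export
amt_protocol <- function(levels) {
  if (!length(levels)) {
    return(structure(stats::setNames(integer(), character()),
                     class = "amt_protocol"))
  }
  stopifnot(is.numeric(levels), !is.null(names(levels)),
            all(nzchar(names(levels))))
  if (any(levels != round(levels)) || any(abs(levels) > 5))
    stop("stimulation levels must be integers in [-5, 5]")
  codes <- parse_acupoint(names(levels))$code
  if (anyDuplicated(codes))
    stop("duplicate acupoints in protocol: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  lv <- as.integer(levels)
  keep <- lv != 0L
  structure(stats::setNames(lv[keep], codes[keep]), class = "amt_protocol")
}

#' @export
print.amt_protocol <- function(x, ...) {
  if (!length(x)) {
    cat("<amt_protocol> (no treated acupoints)\n")
  } else {
    cat("<amt_protocol> ",
        paste(names(x), unclass(x), sep = ": ", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Per-organ summed stimulation potential of a protocol
#'
#' Resolves each treated acupoint to its affiliated organ (contributions on
#' one organ sum), routing organ-less vessel/extra points per
#' `params$vessel_routing`.
#'
#' @param protocol An [amt_protocol()].
#' @param params An [amt_params()] set.
#' @return Named numeric vector over the twelve organs: `sum of fp`.
#' @export
protocol_potentials <- function(protocol, params = amt_params()) {
  out <- stats::setNames(numeric(12L), organ_names())
  if (!length(protocol)) return(out)
  organ <- organ_of_acupoint(names(protocol))
  fp <- stimulus(unclass(protocol), params)
  for (i in seq_along(fp)) {
    if (!is.na(organ[i])) {
      out[organ[i]] <- out[organ[i]] + fp[i]
    } else if (identical(params$vessel_routing, "viscera")) {
      vs <- viscera_elements()
      out[vs] <- out[vs] + fp[i] / length(vs)
    } else if (is.numeric(params$vessel_routing)) {
      rt <- params$vessel_routing
      out[names(rt)] <- out[names(rt)] + fp[i] * rt
    }  # "none": dropped
  }
  out
}

#' Initial organ-state vector
#'
#' @param ... Named organ levels overriding the healthy baseline `h`.
#' @param params An [amt_params()] set (supplies the baseline and bounds).
#' @return Named numeric vector over the twelve organs.
#' @export
amt_state <- function(..., params = amt_params()) {
  st <- stats::setNames(rep(params$h, 12L), organ_names())
  dots <- unlist(list(...))
  if (length(dots)) {
    unknown <- setdiff(names(dots), organ_names())
    if (length(unknown))
      stop("unknown organs: ", paste(unknown, collapse = ", "))
    st[names(dots)] <- dots
  }
  bad <- st < params$state_bounds[1] | st > params$state_bounds[2]
  if (any(bad))
    stop("organ states outside bounds [",
         params$state_bounds[1], ", ", params$state_bounds[2], "]: ",
         paste(names(st)[bad], collapse = ", "))
  st
}
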