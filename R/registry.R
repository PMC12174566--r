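# ---------------------------------------------------------------------------
# Static domain knowledge: the twelve internal organs, the Five-Elements
# generation/restriction cycles among the five viscera, exterior-interior
# viscus-bowel pairs, the fourteen organ/vessel meridians plus the extra
# (EX) points, and WHO acupoint notation.
# ---------------------------------------------------------------------------

.registry_env <- new.env(parent = emptyenv())

#' The twelve internal organs
#'
#' Five viscera carry a Five-Elements attribution (liver=wood, heart=fire,
#' spleen=earth, lung=metal, kidney=water); the pericardium and the six
#' bowels carry none.
#'
#' @return Data frame with columns `organ`, `klass` (`"viscus"`/`"bowel"`),
#'   `element`.
#' @export
amt_organs <- function() {
  data.frame(
    organ = c("liver", "heart", "spleen", "lung", "kidney", "pericardium",
              "gallbladder", "small_intestine", "stomach",
              "large_intestine", "bladder", "triple_energizer"),
    klass = c(rep("viscus", 6L), rep("bowel", 6L)),
    element = c("wood", "fire", "earth", "metal", "water", rep("none", 7L)),
    stringsAsFactors = FALSE)
}

organ_names <- function() amt_organs()$organ

viscera_elements <- function() {
  o <- amt_organs()
  o$organ[o$element != "none"]
}

#' Meridian registry
#'
#' Loads the packaged meridian table (WHO code, affiliated organ, point
#' count) and the extra-point (EX) sub-series, validating the totals: the
#' fourteen organ/vessel meridians carry 361 standard points and the EX
#' series 48 extra points.
#'
#' @return List with data frames `meridians` and `ex_series`.
#' @export
amt_registry <- function() {
  if (!is.null(.registry_env$registry)) return(.registry_env$registry)
  mer <- utils::read.csv(system.file("extdata", "meridians.csv",
                                     package = "amtsim"),
                         stringsAsFactors = FALSE, colClasses = "character")
  mer$n_points <- as.integer(mer$n_points)
  mer$organ[mer$organ == ""] <- NA_character_
  ex <- utils::read.csv(system.file("extdata", "ex_series.csv",
                                    package = "amtsim"),
                        stringsAsFactors = FALSE)
  ex$n_points <- as.integer(ex$n_points)
  if (sum(mer$n_points) != 361L)
    stop("registry corrupt: standard acupoints must total 361")
  if (sum(ex$n_points) != 48L)
    stop("registry corrupt: extra acupoints must total 48")
  bad <- setdiff(stats::na.omit(mer$organ), organ_names())
  if (length(bad)) stop("registry corrupt: unknown organs ",
                        paste(bad, collapse = ", "))
  reg <- list(meridians = mer, ex_series = ex)
  .registry_env$registry <- reg
  reg
}

#' Parse WHO acupoint codes
#'
#' Accepts forms like `"GB20"`, `"gb-20"`, `"EX-HN4"` or `"EXHN4"`
#' (case-insensitive, optional hyphens/spaces) and validates the index
#' against the meridian's point count (per sub-series for EX points).
#'
#' @param x Character vector of codes.
#' @return Data frame with columns `meridian`, `series` (`NA` except for
#'   EX points), `index`, and the canonical `code`.
#' @export
parse_acupoint <- function(x) {
  stopifnot(is.character(x))
  reg <- amt_registry()
  clean <- toupper(gsub("[-_ ]", "", x))
  out <- data.frame(meridian = character(length(x)),
                    series = NA_character_, index = NA_integer_,
                    code = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(clean)) {
    s <- clean[i]
    if (grepl("^EX", s)) {
      m <- regmatches(s, regexec("^EX([A-Z]+)([0-9]+)$", s))[[1L]]
      if (length(m) != 3L)
        stop("malformed acupoint code: ", x[i])
      ser <- m[2L]; idx <- as.integer(m[3L])
      row <- match(ser, reg$ex_series$series)
      if (is.na(row)) stop("unknown EX sub-series in code: ", x[i])
      if (idx < 1L || idx > reg$ex_series$n_points[row])
        stop("acupoint index out of range: ", x[i], " (EX-", ser,
             " has ", reg$ex_series$n_points[row], " points)")
      out$meridian[i] <- "EX"; out$series[i] <- ser; out$index[i] <- idx
      out$code[i] <- paste0("EX", ser, idx)
    } else {
      m <- regmatches(s, regexec("^([A-Z]+)([0-9]+)$", s))[[1L]]
      if (length(m) != 3L)
        stop("malformed acupoint code: ", x[i])
      mer <- m[2L]; idx <- as.integer(m[3L])
      row <- match(mer, reg$meridians$code)
      if (is.na(row)) stop("unknown meridian code in: ", x[i])
      if (idx < 1L || idx > reg$meridians$n_points[row])
        stop("acupoint index out of range: ", x[i], " (", mer,
             " has ", reg$meridians$n_points[row], " points)")
      out$meridian[i] <- mer; out$index[i] <- idx
      out$code[i] <- paste0(mer, idx)
    }
  }
  out
}

#' Canonical text form of parsed acupoints
#' @param a Data frame as returned by [parse_acupoint()].
#' @return Character vector of canonical codes (e.g. `"GB20"`, `"EXHN4"`).
#' @export
format_acupoint <- function(a) {
  stopifnot(is.data.frame(a), all(c("meridian", "index") %in% names(a)))
  ifelse(a$meridian == "EX",
         paste0("EX", a$series, a$index),
         paste0(a$meridian, a$index))
}

#' All recognized acupoint codes
#' @return Character vector of the 361 standard + 48 extra point codes.
#' @export
all_acupoints <- function() {
  reg <- amt_registry()
  std <- unlist(lapply(seq_len(nrow(reg$meridians)), function(i) {
    paste0(reg$meridians$code[i], seq_len(reg$meridians$n_points[i]))
  }))
  ex <- unlist(lapply(seq_len(nrow(reg$ex_series)), function(i) {
    paste0("EX", reg$ex_series$series[i],
           seq_len(reg$ex_series$n_points[i]))
  }))
  c(std, ex)
}

check_viscus <- function(v, allow_pericardium = FALSE) {
  ok <- viscera_elements()
  if (allow_pericardium) ok <- c(ok, "pericardium")
  bad <- setdiff(v, ok)
  if (length(bad))
    stop("not an element-bearing viscus: ", paste(bad, collapse = ", "))
  invisible(v)
}

#' Five-Elements partners of a viscus
#'
#' The generation cycle runs wood -> fire -> earth -> metal -> water ->
#' wood; the restriction cycle wood -| earth, earth -| water, water -| fire,
#' fire -| metal, metal -| wood. `generation_partner(v)` returns the viscus
#' whose element generates `v`'s element; `restriction_partner(v)` the one
#' whose element restricts it. Both error on organs outside the five
#' element-bearing viscera.
#'
#' @param v Character vector of viscus names.
#' @return Character vector of viscus names.
#' @export
generation_partner <- function(v) {
  check_viscus(v)
  unname(c(liver = "kidney", heart = "liver", spleen = "heart",
           lung = "spleen", kidney = "lung")[v])
}

#' @rdname generation_partner
#' @export
restriction_partner <- function(v) {
  check_viscus(v)
  unname(c(liver = "lung", heart = "kidney", spleen = "liver",
           lung = "heart", kidney = "spleen")[v])
}

#' Exterior-interior paired organ
#'
#' Viscus to bowel (and back): liver-gallbladder, heart-small intestine,
#' spleen-stomach, lung-large intestine, kidney-bladder,
#' pericardium-triple energizer. The relation is an involution on the
#' twelve organs.
#'
#' @param v Character vector of organ names.
#' @return Character vector of the paired organs.
#' @export
paired_organ <- function(v) {
  fwd <- c(liver = "gallbladder", heart = "small_intestine",
           spleen = "stomach", lung = "large_intestine",
           kidney = "bladder", pericardium = "triple_energizer")
  map <- c(fwd, stats::setNames(names(fwd), unname(fwd)))
  bad <- setdiff(v, names(map))
  if (length(bad)) stop("unknown organ: ", paste(bad, collapse = ", "))
  unname(map[v])
}

#' @rdname paired_organ
#' @export
paired_bowel <- function(v) {
  o <- amt_organs()
  bad <- v[!(v %in% o$organ[o$klass == "viscus"])]
  if (length(bad))
    stop("paired_bowel() expects a viscus, got: ",
         paste(bad, collapse = ", "))
  paired_organ(v)
}

#' Organ affiliated with an acupoint
#'
#' @param x Character vector of acupoint codes (or a data frame from
#'   [parse_acupoint()]).
#' @return Character vector of organ names; `NA` for conception/governor
#'   vessel and EX points, which have no affiliated organ.
#' @export
organ_of_acupoint <- function(x) {
  a <- if (is.data.frame(x)) x else parse_acupoint(x)
  reg <- amt_registry()
  unname(stats::setNames(reg$meridians$organ, reg$meridians$code)[a$meridian])
}

#' Meridians affiliated with organs
#' @param organs Character vector of organ names.
#' @return Character vector of WHO meridian codes.
#' @export
meridians_of_organs <- function(organs) {
  reg <- amt_registry()
  bad <- setdiff(organs, stats::na.omit(reg$meridians$organ))
  if (length(bad)) stop("no meridian for organ: ", paste(bad, collapse = ", "))
  reg$meridians$code[match(organs, reg$meridians$organ)]
}
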