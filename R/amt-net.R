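# ---------------------------------------------------------------------------
# Colored-Petri-net realization of the physiological cycle. Organ states,
# substance pools, deliveries and treated acupoints live in REAL/INT data
# places; the stage equations are embedded as arc expressions; the stage
# order is enforced by a TGTC schedule:
#
#   seq( t_snapshot,
#        par( one chain per viscus-bowel pair:
#             seq(t_gen_<v>, t_vb_<v>, t_bv_<v>)   [no t_gen for pericardium] ),
#        t_stim, t_generate, t_transport, t_absorb )
#
# The snapshot transition copies each viscus's generator/restrictor values
# into pair-local places before the parallel block, so the five-viscera
# stage reads the previous cycle's values even though the six pair chains
# run concurrently.
# ---------------------------------------------------------------------------

# shortest decimal literal that round-trips to exactly x
num_lit <- function(x) {
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g")
    if (as.numeric(s) == x) return(s)
  }
  sprintf("%.17g", x)
}

#' Build the treatment net
#'
#' Constructs the colored Petri net embedding the stage equations as arc
#' expressions, the series-parallel stage schedule, and the TGTC-augmented
#' net with its initial data marking: one REAL place per organ state, per
#' substance pool and per delivery channel, and one INT place per treated
#' acupoint holding its stimulation level.
#'
#' @param protocol An [amt_protocol()].
#' @param params An [amt_params()] set.
#' @param initial Named organ-state vector (see [amt_state()]).
#' @return List with `net` (TGTC-augmented), `base_net` (data layer only),
#'   `schedule`, `control` (the augmentation record), `marking` (data
#'   tokens; seed the control token per cycle with [tgtc_seed()]), and
#'   `acupoint_places`.
#' @export
build_amt_net <- function(protocol = amt_protocol(integer()),
                          params = amt_params(),
                          initial = NULL) {
  if (!inherits(protocol, "amt_protocol")) protocol <- amt_protocol(protocol)
  if (is.null(initial)) initial <- amt_state(params = params)
  initial <- initial[organ_names()]
  o <- amt_organs()
  vs_all <- o$organ[o$klass == "viscus"]
  vs5 <- viscera_elements()
  subs <- c("qi", "blood", "fluid")

  places <- c(
    lapply(organ_names(), function(x) cpn_place(paste0("p_", x), "REAL",
                                                label = x)),
    lapply(subs, function(i) cpn_place(paste0("p_", i), "REAL",
                                       label = paste(i, "pool"))),
    lapply(subs, function(i) cpn_place(paste0("p_del_", i), "REAL",
                                       label = paste(i, "delivery"))),
    unlist(lapply(vs5, function(x) list(
      cpn_place(paste0("p_snap_", x, "_gen"), "REAL"),
      cpn_place(paste0("p_snap_", x, "_res"), "REAL"))), recursive = FALSE),
    lapply(names(protocol), function(a) cpn_place(paste0("p_acu_", a), "INT",
                                                  label = a)))

  transitions <- list()
  arcs <- list()
  add_t <- function(id) transitions[[length(transitions) + 1L]] <<-
    cpn_transition(id)
  add_a <- function(src, dst, expr) arcs[[length(arcs) + 1L]] <<-
    cpn_arc(src, dst, expr)

  g <- num_lit(params$g); r <- num_lit(params$r); s <- num_lit(params$s)
  cc <- num_lit(params$c); h <- num_lit(params$h); v <- num_lit(params$v)

  # snapshot: copy each viscus's generator/restrictor values to pair-local
  # places; organ places keep their (previous-cycle) values
  add_t("t_snapshot")
  for (x in vs5) add_a(paste0("p_", x), "t_snapshot", paste0("f_", x))
  for (x in vs5) {
    add_a("t_snapshot", paste0("p_", x), paste0("f_", x))
    add_a("t_snapshot", paste0("p_snap_", x, "_gen"),
          paste0("f_", generation_partner(x)))
    add_a("t_snapshot", paste0("p_snap_", x, "_res"),
          paste0("f_", restriction_partner(x)))
  }

  # pair chains
  for (x in vs5) {
    tid <- paste0("t_gen_", x)
    add_t(tid)
    add_a(paste0("p_", x), tid, "fv")
    add_a(paste0("p_snap_", x, "_gen"), tid, "gv")
    add_a(paste0("p_snap_", x, "_res"), tid, "rv")
    add_a(tid, paste0("p_", x),
          sprintf("%s * gv - %s * rv + %s * fv", g, r, s))
  }
  for (x in vs_all) {
    bw <- paired_organ(x)
    tid <- paste0("t_vb_", x)
    add_t(tid)
    add_a(paste0("p_", x), tid, "fv")
    add_a(paste0("p_", bw), tid, "fb")
    add_a(tid, paste0("p_", x), "fv")
    add_a(tid, paste0("p_", bw), sprintf("%s * fv + %s * fb", cc, s))
    tid <- paste0("t_bv_", x)
    add_t(tid)
    add_a(paste0("p_", x), tid, "fv")
    add_a(paste0("p_", bw), tid, "fb")
    add_a(tid, paste0("p_", x), sprintf("%s * fb + %s * fv", cc, s))
    add_a(tid, paste0("p_", bw), "fb")
  }

  # stimulation: every organ place and every acupoint place is read; the
  # per-organ expression adds w * (summed potential terms) * response gain
  add_t("t_stim")
  for (x in organ_names()) add_a(paste0("p_", x), "t_stim", paste0("f_", x))
  for (a in names(protocol)) add_a(paste0("p_acu_", a), "t_stim",
                                   paste0("mu_", a))
  pot_terms <- stats::setNames(rep(list(character()), 12L), organ_names())
  if (length(protocol)) {
    organ_map <- organ_of_acupoint(names(protocol))
    fp <- stimulus(unclass(protocol), params)
    for (i in seq_along(protocol)) {
      a <- names(protocol)[i]
      coef <- fp[i] / unclass(protocol)[i]  # potentials are linear in mu
      targets <- if (!is.na(organ_map[i])) {
        stats::setNames(1, organ_map[i])
      } else if (identical(params$vessel_routing, "viscera")) {
        stats::setNames(rep(1 / length(vs5), length(vs5)), vs5)
      } else if (is.numeric(params$vessel_routing)) {
        params$vessel_routing
      } else NULL  # "none"
      for (x in names(targets)) {
        pot_terms[[x]] <- c(pot_terms[[x]],
          sprintf("%s * mu_%s", num_lit(coef * targets[[x]]), a))
      }
    }
  }
  w <- num_lit(params$w)
  for (x in organ_names()) {
    fx <- paste0("f_", x)
    expr <- if (!length(pot_terms[[x]])) fx else {
      pot <- paste(pot_terms[[x]], collapse = " + ")
      gain <- switch(params$response,
        deviation = sprintf("abs(%s - %s)", fx, h),
        additive = "1")
      sprintf("%s + %s * (%s) * %s", fx, w, pot, gain)
    }
    add_a("t_stim", paste0("p_", x), expr)
  }
  for (a in names(protocol)) add_a("t_stim", paste0("p_acu_", a),
                                   paste0("mu_", a))

  sum_expr <- paste(paste0("f_", params$organ_set), collapse = " + ")
  nh <- num_lit(length(params$organ_set) * params$h)
  bal <- sprintf("(max(0, %s - abs((%s) - %s)) / %s)", nh, sum_expr, nh, nh)
  organ_health <- function(x)
    sprintf("(max(0, %s - abs(f_%s - %s)) / %s)", h, x, h, h)

  # substance generation: consume old pools, read organs, emit new pools
  add_t("t_generate")
  for (x in organ_names()) add_a(paste0("p_", x), "t_generate",
                                 paste0("f_", x))
  for (x in organ_names()) add_a("t_generate", paste0("p_", x),
                                 paste0("f_", x))
  for (i in subs) {
    add_a(paste0("p_", i), "t_generate", paste0("po_", i))
    add_a("t_generate", paste0("p_", i),
          sprintf("%s * %s * %s", num_lit(params$fi_normal[[i]]), bal,
                  organ_health(params$me[[i]])))
  }

  # transport: read pools and organs, emit uniform deliveries
  add_t("t_transport")
  for (x in organ_names()) add_a(paste0("p_", x), "t_transport",
                                 paste0("f_", x))
  for (x in organ_names()) add_a("t_transport", paste0("p_", x),
                                 paste0("f_", x))
  for (i in subs) {
    add_a(paste0("p_", i), "t_transport", paste0("fi_", i))
    add_a("t_transport", paste0("p_", i), paste0("fi_", i))
    add_a("t_transport", paste0("p_del_", i),
          sprintf("fi_%s / %s * %s * %s", i, v, bal,
                  organ_health(params$ue[[i]])))
  }

  # absorption + clamp
  add_t("t_absorb")
  for (x in organ_names()) add_a(paste0("p_", x), "t_absorb",
                                 paste0("f_", x))
  for (i in subs) add_a(paste0("p_del_", i), "t_absorb", paste0("d_", i))
  lb <- num_lit(params$state_bounds[1]); ub <- num_lit(params$state_bounds[2])
  for (x in organ_names()) {
    add_a("t_absorb", paste0("p_", x),
          sprintf("min(%s, max(%s, f_%s * %s + d_qi * %s + d_blood * %s + d_fluid * %s))",
                  ub, lb, x, num_lit(params$m), num_lit(params$q),
                  num_lit(params$b), num_lit(params$l)))
  }

  base_net <- cpn_net(places, transitions, arcs,
                      meta = list(module = "amt"))

  chains <- lapply(vs_all, function(x) {
    steps <- c(if (x %in% vs5) paste0("t_gen_", x),
               paste0("t_vb_", x), paste0("t_bv_", x))
    do.call(sched_seq, as.list(steps))
  })
  schedule <- sched_seq("t_snapshot", do.call(sched_par, chains),
                        "t_stim", "t_generate", "t_transport", "t_absorb")

  aug <- tgtc_augment(base_net, schedule)
  tokens <- c(
    stats::setNames(as.list(initial), paste0("p_", organ_names())),
    stats::setNames(as.list(params$fi_normal[subs]), paste0("p_", subs)),
    if (length(protocol))
      stats::setNames(lapply(unclass(protocol), as.numeric),
                      paste0("p_acu_", names(protocol))))
  marking <- cpn_marking(aug$net, tokens)

  list(net = aug$net, base_net = base_net, schedule = schedule,
       control = aug$control, marking = marking,
       acupoint_places = if (length(protocol))
         paste0("p_acu_", names(protocol)) else character())
}
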