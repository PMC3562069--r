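# Defaults for the ROS-cFLIP regulation model. Units: hours; cFLIP on the
# same copies/cell scale as the apoptosis network (baseline 1000), ROS
# species on an arbitrary intracellular-level scale. Timescales are
# calibrated so superoxide peaks well before 1 h and hydrogen peroxide
# accumulates over hours, giving the early-rise / late-fall cFLIP
# phenomenology.
ros_cflip_defaults <- function() {
  list(
    initial = c(LY30 = 0, SoxCap = 100, Sox = 0, H2O2 = 0,
                cFLIP_mRNA = 20, cFLIP = 1000, cFLIP_Deg = 0),
    parameters = c(
      k_sox_prod  = 0.05, # LY30-catalysed superoxide production (/uM/h per unit capacity)
      k_sox_conv  = 4,    # superoxide -> H2O2 conversion (dismutation, /h)
      k_h2o2_deg  = 0.5,  # H2O2 clearance (/h)
      k_mrna_prod = 20,   # cFLIP transcription (units/h), H2O2-inhibited
      K_h2o2      = 15,   # H2O2 level halving cFLIP transcription
      k_mrna_deg  = 1,    # cFLIP mRNA decay (/h)
      k_transl    = 75,   # translation (cFLIP copies per mRNA unit per h)
      k_cflip_deg = 1.5,  # cFLIP degradation (/h), superoxide-inhibited
      K_sox       = 20))  # superoxide level halving cFLIP degradation
}

#' Build the ROS-driven cFLIP regulation network
#'
#' A compact model of how an ROS-producing drug can regulate cFLIP
#' non-monotonically: LY30 drives superoxide production from a finite
#' generating capacity (\code{SoxCap}), superoxide is dismutated into
#' hydrogen peroxide, and H2O2 is cleared by antioxidant systems.
#' Superoxide acts fast and pro-cFLIP (it inhibits cFLIP degradation);
#' H2O2 acts slowly and anti-cFLIP (it inhibits cFLIP production at the
#' transcript level). cFLIP is translated from an mRNA pool and degraded
#' into an explicit \code{cFLIP_Deg} pool so degradation flux is
#' accountable. With no LY30 the network rests exactly at its positive
#' baseline (mRNA 20, cFLIP 1000).
#'
#' The two inhibition terms are saturating multipliers \code{1/(1 + X/K)}
#' on the affected rates -- the only non-elementary rate laws in the
#' package. The finite \code{SoxCap} pool makes the superoxide burst
#' transient, which is what lets a late H2O2-dominated phase emerge; it is
#' also why the model composes with a non-depleting LY30 input when coupled
#' to the apoptosis network. Dismutation is encoded 1:1 (every superoxide
#' unit removed by conversion appears as H2O2); the physiological 2:1
#' stoichiometry would only rescale the H2O2 axis and K_h2o2.
#'
#' @param overrides Optional named numeric parameter overrides.
#' @return A \code{reaction_network}.
#' @export
build_ros_cflip_network <- function(overrides = NULL) {
  d <- ros_cflip_defaults()
  sp <- lapply(names(d$initial), function(s) species(s, d$initial[[s]]))
  rx <- list(
    reaction("sox_production", "SoxCap", "Sox", modifiers = "LY30",
             rate_param = "k_sox_prod"),
    reaction("sox_to_h2o2", "Sox", "H2O2", rate_param = "k_sox_conv"),
    reaction("h2o2_degradation", "H2O2", rate_param = "k_h2o2_deg",
             kind = "first_order_degradation"),
    reaction("cflip_transcription", products = "cFLIP_mRNA",
             rate_param = "k_mrna_prod", kind = "zeroth_order_synthesis",
             inhibitors = data.frame(species = "H2O2", K_param = "K_h2o2")),
    reaction("cflip_mrna_decay", "cFLIP_mRNA", rate_param = "k_mrna_deg",
             kind = "first_order_degradation"),
    reaction("cflip_translation", products = "cFLIP",
             modifiers = "cFLIP_mRNA", rate_param = "k_transl"),
    reaction("cflip_degradation", "cFLIP", "cFLIP_Deg",
             rate_param = "k_cflip_deg",
             inhibitors = data.frame(species = "Sox", K_param = "K_sox")))
  net <- reaction_network(sp, rx, d$parameters)
  if (!is.null(overrides)) net <- set_parameters(net, overrides)
  net
}

#' Add a ROS-scavenger intervention
#'
#' Adds a first-order removal reaction for exactly one ROS species: Tiron
#' removes superoxide (default pre-incubation from -1 h), catalase removes
#' hydrogen peroxide (default pre-treatment, active from the start).
#' Interventions are recorded on the network; the simulator activates them
#' at \code{start_time}.
#'
#' @param network A ROS-cFLIP network (or a coupled network carrying its
#'   species).
#' @param kind \code{"tiron_superoxide"} or \code{"catalase_h2o2"}.
#' @param removal_rate First-order removal constant (/h); large values
#'   approximate complete scavenging.
#' @param start_time Hours (<= 0 means active from the simulation start).
#' @return The network with the removal reaction added.
#' @export
apply_scavenger <- function(network, kind = c("tiron_superoxide",
                                              "catalase_h2o2"),
                            removal_rate = 50,
                            start_time = if (kind == "tiron_superoxide") -1 else 0) {
  kind <- match.arg(kind)
  stopifnot(removal_rate >= 0)
  target <- switch(kind, tiron_superoxide = "Sox", catalase_h2o2 = "H2O2")
  rxname <- switch(kind, tiron_superoxide = "tiron_sox_removal",
                   catalase_h2o2 = "catalase_h2o2_removal")
  if (rxname %in% names(network$reactions)) {
    stop("scavenger '", kind, "' already applied")
  }
  parname <- paste0("k_", rxname)
  net <- add_reactions(
    network,
    list(reaction(rxname, target, rate_param = parname,
                  kind = "first_order_degradation")),
    parameters = stats::setNames(removal_rate, parname))
  scav <- attr(net, "scavengers") %||% list()
  scav[[kind]] <- list(kind = kind, param = parname, rate = removal_rate,
                       start_time = start_time)
  attr(net, "scavengers") <- scav
  net
}

#' Simulate the ROS-cFLIP model under an LY30 step input
#'
#' Integrates from the LY30-free steady state with LY30 set to the dose at
#' \code{ly30_time}. Scavenger interventions recorded on the network are
#' activated at their start times (the grid is extended backwards if a
#' scavenger pre-incubation starts before the first grid point).
#'
#' @param network A network from \code{\link{build_ros_cflip_network}},
#'   possibly with scavengers applied.
#' @param ly30_uM LY30 dose (uM input level); default 25.
#' @param times Output grid, hours; default 0-8 h at 0.01 h.
#' @param ly30_time Time of the LY30 step (default 0).
#' @return A \code{trajectory}.
#' @export
simulate_ros_cflip <- function(network, ly30_uM = 25,
                               times = seq(0, 8, 0.01), ly30_time = 0) {
  if (ly30_uM < 0) stop("dose must be non-negative")
  ev <- event(ly30_time, "LY30", ly30_uM)
  scav <- attr(network, "scavengers") %||% list()
  for (s in scav) {
    if (s$start_time > times[1]) {
      # inactive until its start: zero the rate, re-enable by event
      network <- set_parameters(network,
                                stats::setNames(0, s$param))
      ev <- rbind(ev, event(s$start_time, s$param, s$rate))
    } else if (s$start_time < times[1]) {
      step <- min(diff(times))
      times <- c(seq(s$start_time, times[1] - step, step), times)
    }
  }
  integrate_network(network, events = ev, times = times)
}

#' cFLIP fold-change relative to the pre-treatment baseline
#'
#' @param trajectory A \code{trajectory} containing the cFLIP species.
#' @param times Times (hours) at which to report fold-change; default the
#'   full trajectory grid.
#' @param species_name Name of the cFLIP species (\code{"flip"} in coupled
#'   apoptosis networks).
#' @param baseline_time Time defining the baseline (default 0, the moment
#'   of treatment).
#' @return Data frame with columns \code{time} and \code{fold_change};
#'   fold-change at the baseline time is exactly 1.
#' @export
cflip_fold_change <- function(trajectory, times = NULL,
                              species_name = "cFLIP", baseline_time = 0) {
  tr_t <- trajectory[, "time"]
  vals <- trace_of(trajectory, species_name)
  base <- stats::approx(tr_t, vals, xout = baseline_time, rule = 2)$y
  if (base <= 0) stop("baseline cFLIP is zero; fold-change undefined")
  if (is.null(times)) times <- tr_t
  fc <- stats::approx(tr_t, vals, xout = times, rule = 2)$y / base
  # the baseline point is 1 by definition; guard against interpolation fuzz
  fc[times == baseline_time] <- 1
  data.frame(time = times, fold_change = fc)
}

#' Couple the ROS-cFLIP submodel into the combination apoptosis model
#'
#' Replaces the constant-rate LY30-catalysed cFLIP degradation of the
#' LY30 extension with the dynamic ROS-driven cFLIP submodel: the
#' \code{flip_degradation_ly30} reaction is removed, the ROS-cFLIP species
#' and reactions are merged in with its \code{cFLIP} identified with the
#' apoptosis species \code{flip}, and \code{LY30} shared by name. The
#' coupled model therefore shows the early cFLIP rise (and hence delayed
#' caspase-8 activation) that the constant-decay model cannot produce.
#'
#' @param combined An LY30-extended apoptosis network.
#' @param ros_network A \code{\link{build_ros_cflip_network}} network
#'   (without scavengers).
#' @return The coupled \code{reaction_network}.
#' @export
couple_to_apoptosis <- function(combined, ros_network) {
  stopifnot(inherits(combined, "reaction_network"),
            inherits(ros_network, "reaction_network"))
  if (!"flip_degradation_ly30" %in% names(combined$reactions)) {
    stop("expected an LY30-extended network with constant-rate cFLIP decay")
  }
  shared_map <- c(cFLIP = "flip", LY30 = "LY30")
  rename <- function(x) ifelse(x %in% names(shared_map), shared_map[x], x)
  new_sp_names <- rename(ros_network$species$name)
  collide <- intersect(setdiff(new_sp_names, unname(shared_map)),
                       combined$species$name)
  if (length(collide)) {
    stop("species name collision on non-shared species: ",
         paste(collide, collapse = ", "))
  }
  pcollide <- intersect(names(ros_network$parameters),
                        names(combined$parameters))
  if (length(pcollide)) {
    stop("parameter name collision: ", paste(pcollide, collapse = ", "))
  }
  net <- combined
  net$reactions[["flip_degradation_ly30"]] <- NULL
  keep <- !new_sp_names %in% combined$species$name
  add_sp <- ros_network$species[keep, , drop = FALSE]
  add_sp$name <- new_sp_names[keep]
  rx <- lapply(unname(ros_network$reactions), function(r) {
    r$reactants <- unname(rename(r$reactants))
    r$products <- unname(rename(r$products))
    r$modifiers <- unname(rename(r$modifiers))
    if (!is.null(r$inhibitors)) {
      r$inhibitors$species <- unname(rename(r$inhibitors$species))
    }
    r
  })
  add_reactions(net, rx, parameters = ros_network$parameters,
                species_list = add_sp)
}
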