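# LY30 effect parameters (calibration defaults; hours / molecules-per-cell
# units, LY30 measured on its uM input scale).
ly30_defaults <- function() {
  c(k_prime        = 0.08,  # LY30-catalysed receptor priming (/uM/h)
    prime_factor   = 150,   # fold speed-up of DISC formation at primed receptors
    k_flip_deg     = 0.12,  # LY30-catalysed cFLIP degradation (/uM/h)
    k_ros_prod     = 40,    # LY30-driven ROS production (units/uM/h)
    k_ros_decay    = 1,     # ROS first-order clearance (/h)
    k_ros_mito     = 1e-6,  # ROS-catalysed Bax activation (mito permeability)
    k_ros_parp     = 0,     # ROS-driven direct death channel (flagged cells)
    k_ly30_decay   = 0)     # LY30 non-depleting by default
}

#' Extend the TRAIL network with the LY30 mechanism
#'
#' Adds the three modelled effects of LY303511: (a) receptor priming, an
#' LY30-catalysed conversion of the TRAIL receptor into a primed form whose
#' DISC-formation rate constant is \code{prime_factor} times faster; (b)
#' LY30-catalysed first-order degradation of cFLIP (a lumped stand-in for
#' transcriptional repression, ubiquitylation, and similar routes); (c)
#' LY30-driven ROS production with ROS-catalysed mitochondrial
#' permeabilisation (via Bax activation) and a direct, mitochondria-
#' independent PARP-cleavage channel whose rate constant
#' (\code{k_ros_parp}) is zero by default and is switched on per cell in a
#' small flagged subpopulation by the population simulator.
#'
#' LY30 itself is a non-depleting input species (no clearance) unless
#' \code{k_ly30_decay > 0}.
#'
#' @param network A TRAIL network from \code{\link{build_trail_network}}.
#' @param overrides Optional named numeric overrides of the LY30
#'   parameters.
#' @return The extended network.
#' @export
build_ly30_extension <- function(network, overrides = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  if ("LY30" %in% network$species$name) {
    stop("network already carries the LY30 extension")
  }
  pars <- ly30_defaults()
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(pars))
    if (length(unknown)) stop("unknown LY30 parameters: ",
                              paste(unknown, collapse = ", "))
    pars[names(overrides)] <- overrides
  }
  # primed DISC formation rate = k_bind * prime_factor, kept as its own
  # parameter so events/calibration can address it, but derived here
  pars <- c(pars, k_bind_primed =
              unname(network$parameters[["k_bind"]] * pars[["prime_factor"]]))
  sp <- list(species("LY30", 0, compartment = "extracellular"),
             species("Rp", 0),
             species("ROS", 0))
  rx <- list(
    reaction("receptor_priming", "R", "Rp", modifiers = "LY30",
             rate_param = "k_prime"),
    reaction("disc_formation_primed", c("TRAIL", "Rp"), "DISC",
             rate_param = "k_bind_primed"),
    reaction("flip_degradation_ly30", "flip", modifiers = "LY30",
             rate_param = "k_flip_deg"),
    reaction("ros_production", products = "ROS", modifiers = "LY30",
             rate_param = "k_ros_prod"),
    reaction("ros_decay", "ROS", rate_param = "k_ros_decay",
             kind = "first_order_degradation"),
    reaction("ros_mito_permeabilisation", "Bax", "BaxA", modifiers = "ROS",
             rate_param = "k_ros_mito"),
    reaction("ros_direct_parp", "PARP", "cPARP", modifiers = "ROS",
             rate_param = "k_ros_parp"))
  if (pars[["k_ly30_decay"]] > 0) {
    rx[[length(rx) + 1L]] <- reaction("ly30_decay", "LY30",
                                      rate_param = "k_ly30_decay",
                                      kind = "first_order_degradation")
  }
  add_reactions(network, rx, parameters = pars, species_list = sp)
}

#' Treatment schedule for a model variant
#'
#' Encodes the study protocol: in the combination arm LY30 is applied at
#' 0 h and TRAIL 1 h later (pre-incubation); single agents are applied at
#' 0 h. Doses default to 25 uM LY30 and 20 ng/ml TRAIL.
#'
#' @param variant_tag One of \code{"trail_only"}, \code{"ly30_only"},
#'   \code{"combination"}, \code{"untreated"}.
#' @param trail_ngml,ly30_uM Doses; must be non-negative.
#' @param ly30_time,trail_time Application times in hours (combination
#'   only; TRAIL must not precede LY30).
#' @return A \code{treatment_schedule}: list with the doses and an
#'   \code{events} data frame.
#' @export
make_schedule <- function(variant_tag = c("combination", "trail_only",
                                          "ly30_only", "untreated"),
                          trail_ngml = 20, ly30_uM = 25,
                          ly30_time = 0, trail_time = 1) {
  variant_tag <- match.arg(variant_tag)
  if (trail_ngml < 0 || ly30_uM < 0) stop("doses must be non-negative")
  amounts <- dose_to_amounts(trail_ngml, ly30_uM)
  ev <- switch(variant_tag,
    untreated = data.frame(time = numeric(), target = character(),
                           value = numeric()),
    trail_only = event(0, "TRAIL", amounts[["TRAIL"]]),
    ly30_only = event(0, "LY30", amounts[["LY30"]]),
    combination = {
      if (trail_time < ly30_time) {
        stop("combination treatment requires LY30 before (or with) TRAIL")
      }
      rbind(event(ly30_time, "LY30", amounts[["LY30"]]),
            event(trail_time, "TRAIL", amounts[["TRAIL"]]))
    })
  structure(list(variant_tag = variant_tag, trail_ngml = trail_ngml,
                 ly30_uM = ly30_uM, ly30_time = ly30_time,
                 trail_time = trail_time, events = ev),
            class = "treatment_schedule")
}

#' Bundle a network with its treatment schedule
#'
#' @param variant_tag Treatment arm tag (see \code{\link{make_schedule}}).
#' @param network The network to simulate. Arms involving LY30 require the
#'   LY30 extension; by default the appropriate network is built.
#' @param schedule A \code{treatment_schedule}; defaults to the study
#'   protocol for the given tag.
#' @return A \code{model_variant} object.
#' @export
model_variant <- function(variant_tag = c("combination", "trail_only",
                                          "ly30_only", "untreated"),
                          network = NULL, schedule = NULL) {
  variant_tag <- match.arg(variant_tag)
  if (is.null(network)) {
    network <- build_trail_network()
    if (variant_tag %in% c("ly30_only", "combination")) {
      network <- build_ly30_extension(network)
    }
  }
  if (is.null(schedule)) schedule <- make_schedule(variant_tag)
  if (schedule$variant_tag != variant_tag) {
    stop("schedule tag does not match variant tag")
  }
  needs_ly30 <- variant_tag %in% c("ly30_only", "combination")
  if (needs_ly30 && !"LY30" %in% network$species$name) {
    stop("variant '", variant_tag, "' needs the LY30-extended network")
  }
  structure(list(variant_tag = variant_tag, network = network,
                 schedule = schedule),
            class = "model_variant")
}

#' @export
print.model_variant <- function(x, ...) {
  cat("<model_variant> ", x$variant_tag, ": ", nrow(x$network$species),
      " species; events at ",
      if (nrow(x$schedule$events)) paste(x$schedule$events$time, collapse = ", ")
      else "none", " h\n", sep = "")
  invisible(x)
}
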