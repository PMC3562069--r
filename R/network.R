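#' Define a chemical species
#'
#' A species is a named, non-negative pool of molecules belonging to a
#' compartment. Amounts are copy numbers (molecules/cell) throughout the
#' package; time is in hours.
#'
#' @param name Species identifier (unique within a network).
#' @param initial Initial amount, molecules/cell; must be >= 0.
#' @param compartment Compartment label, e.g. "cytosol", "mitochondria",
#'   "extracellular". Purely annotational: the model is well-mixed.
#' @param observable Logical flag marking species reported by default in
#'   trajectory summaries.
#' @return A one-row data frame describing the species.
#' @export
species <- function(name, initial = 0, compartment = "cytosol",
                    observable = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(initial) || length(initial) != 1L || is.na(initial) ||
      initial < 0) {
    stop("initial amount of '", name, "' must be a single non-negative number")
  }
  data.frame(name = name, initial = as.numeric(initial),
             compartment = compartment, observable = observable,
             stringsAsFactors = FALSE)
}

#' Define a reaction
#'
#' Reactions follow mass-action kinetics: the flux is
#' \code{rate_constant * prod(reactant amounts) * prod(modifier amounts)},
#' optionally damped by saturating inhibition factors
#' \code{1 / (1 + [I]/K)}. Modifiers (catalysts) enter the flux but carry
#' zero net stoichiometry. Repeated reactant names denote stoichiometry > 1
#' (e.g. \code{c("Bax2", "Bax2")} gives a flux proportional to Bax2 squared).
#'
#' @param name Reaction identifier (unique within a network).
#' @param reactants Character vector of consumed species (possibly empty,
#'   with repeats for stoichiometry).
#' @param products Character vector of produced species.
#' @param modifiers Character vector of catalytic species (not consumed).
#' @param rate_param Name of the rate-constant entry in the network
#'   parameter table. Units must match the reaction order
#'   (e.g. /h for first order, /molecule/h for second order).
#' @param kind One of \code{"mass_action"}, \code{"zeroth_order_synthesis"}
#'   (no reactants or modifiers; flux = rate constant, molecules/h) or
#'   \code{"first_order_degradation"} (exactly one reactant, no products).
#' @param inhibitors Optional data frame with columns \code{species} and
#'   \code{K_param}: each row multiplies the flux by
#'   \code{1/(1 + [species]/K)}. This is the only non-elementary rate law in
#'   the package; it is used solely for the ROS-mediated regulation of cFLIP
#'   turnover, where a strictly elementary encoding would require explicit
#'   sequestration species.
#' @return A \code{reaction} object (list).
#' @export
reaction <- function(name, reactants = character(), products = character(),
                     modifiers = character(), rate_param, kind = "mass_action",
                     inhibitors = NULL) {
  kind <- match.arg(kind, c("mass_action", "zeroth_order_synthesis",
                            "first_order_degradation"))
  stopifnot(is.character(name), length(name) == 1L,
            is.character(reactants), is.character(products),
            is.character(modifiers),
            is.character(rate_param), length(rate_param) == 1L)
  if (kind == "zeroth_order_synthesis" &&
      (length(reactants) > 0L || length(modifiers) > 0L)) {
    stop("zeroth-order synthesis '", name, "' cannot have reactants or modifiers")
  }
  if (kind == "first_order_degradation" &&
      (length(reactants) != 1L || length(products) > 0L)) {
    stop("first-order degradation '", name,
         "' must have exactly one reactant and no products")
  }
  if (kind == "mass_action" && length(reactants) + length(modifiers) == 0L) {
    stop("mass-action reaction '", name,
         "' needs at least one reactant or modifier")
  }
  if (!is.null(inhibitors)) {
    stopifnot(is.data.frame(inhibitors),
              all(c("species", "K_param") %in% names(inhibitors)))
  }
  structure(list(name = name, reactants = reactants, products = products,
                 modifiers = modifiers, rate_param = rate_param, kind = kind,
                 inhibitors = inhibitors),
            class = "reaction")
}

#' Assemble a reaction network
#'
#' @param species_list List of \code{\link{species}} rows (or a data frame).
#' @param reactions List of \code{\link{reaction}} objects.
#' @param parameters Named numeric vector of rate constants and inhibition
#'   constants; every \code{rate_param}/\code{K_param} referenced by a
#'   reaction must be present and non-negative.
#' @return A \code{reaction_network} object.
#' @export
reaction_network <- function(species_list, reactions, parameters) {
  spec <- if (is.data.frame(species_list)) species_list else
    do.call(rbind, species_list)
  if (anyDuplicated(spec$name)) {
    stop("duplicate species names: ",
         paste(unique(spec$name[duplicated(spec$name)]), collapse = ", "))
  }
  if (any(spec$initial < 0)) stop("negative initial amounts are not allowed")
  stopifnot(is.list(reactions), is.numeric(parameters),
            !is.null(names(parameters)))
  rnames <- vapply(reactions, function(r) r$name, character(1))
  if (anyDuplicated(rnames)) {
    stop("duplicate reaction names: ",
         paste(unique(rnames[duplicated(rnames)]), collapse = ", "))
  }
  names(reactions) <- rnames
  net <- structure(list(species = spec, reactions = reactions,
                        parameters = parameters),
                   class = "reaction_network")
  validate_network(net)
  net
}

#' Validate a reaction network
#'
#' Checks the structural invariants: all referenced species exist, all rate
#' parameters are defined and non-negative, and reaction kinds obey their
#' constraints.
#'
#' @param network A \code{reaction_network}.
#' @return The network, invisibly; errors on violation.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  known <- network$species$name
  for (r in network$reactions) {
    refs <- c(r$reactants, r$products, r$modifiers,
              if (!is.null(r$inhibitors)) r$inhibitors$species)
    bad <- setdiff(refs, known)
    if (length(bad)) {
      stop("reaction '", r$name, "' references unknown species: ",
           paste(bad, collapse = ", "))
    }
    pars <- c(r$rate_param, if (!is.null(r$inhibitors)) r$inhibitors$K_param)
    miss <- setdiff(pars, names(network$parameters))
    if (length(miss)) {
      stop("reaction '", r$name, "' references undefined parameters: ",
           paste(miss, collapse = ", "))
    }
  }
  if (any(network$parameters < 0)) {
    stop("negative parameters: ",
         paste(names(network$parameters)[network$parameters < 0],
               collapse = ", "))
  }
  invisible(network)
}

#' Update network parameters
#'
#' @param network A \code{reaction_network}.
#' @param values Named numeric vector; names must already exist in the
#'   parameter table.
#' @return The updated network.
#' @export
set_parameters <- function(network, values) {
  stopifnot(inherits(network, "reaction_network"), is.numeric(values))
  unknown <- setdiff(names(values), names(network$parameters))
  if (length(unknown)) {
    stop("unknown parameters: ", paste(unknown, collapse = ", "))
  }
  network$parameters[names(values)] <- values
  validate_network(network)
}

#' Update initial amounts
#'
#' @param network A \code{reaction_network}.
#' @param values Named numeric vector of initial amounts (molecules/cell).
#' @return The updated network.
#' @export
set_initial <- function(network, values) {
  stopifnot(inherits(network, "reaction_network"), is.numeric(values))
  idx <- match(names(values), network$species$name)
  if (anyNA(idx)) {
    stop("unknown species: ", paste(names(values)[is.na(idx)], collapse = ", "))
  }
  if (any(values < 0)) stop("initial amounts must be non-negative")
  network$species$initial[idx] <- as.numeric(values)
  network
}

#' Add reactions (and any new parameters) to a network
#'
#' @param network A \code{reaction_network}.
#' @param reactions List of \code{\link{reaction}} objects to append.
#' @param parameters Named numeric vector of new parameter values (optional).
#' @param species_list Optional list of new \code{\link{species}} rows.
#' @return The extended, validated network.
#' @export
add_reactions <- function(network, reactions, parameters = NULL,
                          species_list = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  if (!is.null(species_list)) {
    newsp <- if (is.data.frame(species_list)) species_list else
      do.call(rbind, species_list)
    network$species <- rbind(network$species, newsp)
    if (anyDuplicated(network$species$name)) stop("duplicate species names")
  }
  if (!is.null(parameters)) {
    clash <- intersect(names(parameters), names(network$parameters))
    if (length(clash)) {
      stop("parameters already defined: ", paste(clash, collapse = ", "))
    }
    network$parameters <- c(network$parameters, parameters)
  }
  rnames <- vapply(reactions, function(r) r$name, character(1))
  if (any(rnames %in% names(network$reactions))) {
    stop("reactions already defined: ",
         paste(intersect(rnames, names(network$reactions)), collapse = ", "))
  }
  names(reactions) <- rnames
  network$reactions <- c(network$reactions, reactions)
  validate_network(network)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", nrow(x$species), " species, ",
      length(x$reactions), " reactions, ", length(x$parameters),
      " parameters\n", sep = "")
  invisible(x)
}

#' Initial state vector of a network
#'
#' @param network A \code{reaction_network}.
#' @return Named numeric vector of initial amounts.
#' @export
initial_state <- function(network) {
  stats::setNames(network$species$initial, network$species$name)
}
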