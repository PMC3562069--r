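#' Add balanced synthesis/degradation turnover for a set of species
#'
#' For each species in \code{species_subset}, adds a first-order degradation
#' reaction with rate constant \code{deg_rates[species]} and a zeroth-order
#' synthesis reaction whose rate equals
#' \code{degradation constant x initial amount}, so that in the absence of
#' any stimulus the species rests exactly at its initial amount. Species
#' with initial amount zero (e.g. active caspase forms) receive degradation
#' only. In the apoptosis model turnover is applied to the caspases only.
#'
#' @param network A \code{reaction_network}.
#' @param species_subset Character vector of species names.
#' @param deg_rates Named numeric vector of first-order degradation
#'   constants (/h), one per species in the subset; all must be > 0.
#' @return The extended network.
#' @export
set_turnover <- function(network, species_subset, deg_rates) {
  stopifnot(inherits(network, "reaction_network"),
            is.character(species_subset), is.numeric(deg_rates))
  miss <- setdiff(species_subset, names(deg_rates))
  if (length(miss)) {
    stop("no degradation rate given for: ", paste(miss, collapse = ", "))
  }
  if (any(deg_rates[species_subset] <= 0)) {
    stop("degradation constants must be positive (zero turnover cannot be ",
         "balanced by synthesis)")
  }
  targets <- stats::setNames(network$species$initial, network$species$name)
  rx <- list(); pars <- numeric()
  for (s in species_subset) {
    if (!s %in% names(targets)) stop("unknown species '", s, "'")
    kd_name <- paste0("k_deg_", s)
    pars[kd_name] <- deg_rates[[s]]
    rx[[length(rx) + 1L]] <- reaction(
      name = paste0("deg_", s), reactants = s, rate_param = kd_name,
      kind = "first_order_degradation")
    if (targets[[s]] > 0) {
      ks_name <- paste0("k_syn_", s)
      pars[ks_name] <- deg_rates[[s]] * targets[[s]]
      rx[[length(rx) + 1L]] <- reaction(
        name = paste0("syn_", s), products = s, rate_param = ks_name,
        kind = "zeroth_order_synthesis")
    }
  }
  add_reactions(network, rx, parameters = pars)
}
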