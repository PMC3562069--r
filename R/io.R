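#' Write a network to a YAML config file
#'
#' One record per reaction with explicit reactant/product/modifier lists; no
#' rate-law strings, so nothing but mass-action (plus declared saturating
#' inhibitors) can be expressed. The round trip
#' \code{import_network(export_network(net))} reproduces species, reactions
#' and parameters exactly.
#'
#' @param network A \code{reaction_network}.
#' @param path Output file path (.yaml).
#' @return \code{path}, invisibly.
#' @export
export_network <- function(network, path) {
  validate_network(network)
  doc <- list(
    species = lapply(seq_len(nrow(network$species)), function(i) {
      s <- network$species[i, ]
      list(name = s$name, initial = s$initial, compartment = s$compartment,
           observable = s$observable)
    }),
    reactions = lapply(unname(network$reactions), function(r) {
      rec <- list(name = r$name, kind = r$kind,
                  reactants = as.list(r$reactants),
                  products = as.list(r$products),
                  modifiers = as.list(r$modifiers),
                  rate_param = r$rate_param)
      if (!is.null(r$inhibitors)) {
        rec$inhibitors <- lapply(seq_len(nrow(r$inhibitors)), function(q) {
          list(species = r$inhibitors$species[q],
               K_param = r$inhibitors$K_param[q])
        })
      }
      rec
    }),
    parameters = as.list(network$parameters))
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' Read a network from a YAML/JSON config file
#'
#' @param path Path to a file written by \code{\link{export_network}} (YAML)
#'   or an equivalent JSON document.
#' @return A validated \code{reaction_network}.
#' @export
import_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (field in c("species", "reactions", "parameters")) {
    if (is.null(doc[[field]])) {
      stop("malformed network config '", path, "': missing '", field, "' block")
    }
  }
  sp <- do.call(rbind, lapply(doc$species, function(s) {
    if (is.null(s$name) || is.null(s$initial)) {
      stop("malformed species record in '", path,
           "': need at least name and initial")
    }
    species(s$name, s$initial,
            compartment = s$compartment %||% "cytosol",
            observable = s$observable %||% TRUE)
  }))
  kinds <- c("mass_action", "zeroth_order_synthesis", "first_order_degradation")
  rx <- lapply(doc$reactions, function(r) {
    if (is.null(r$name) || is.null(r$kind) || is.null(r$rate_param)) {
      stop("malformed reaction record in '", path, "'")
    }
    if (!r$kind %in% kinds) {
      stop("unknown reaction kind '", r$kind, "' in reaction '", r$name, "'")
    }
    inhib <- NULL
    if (!is.null(r$inhibitors)) {
      inhib <- data.frame(
        species = vapply(r$inhibitors, function(e) e$species, character(1)),
        K_param = vapply(r$inhibitors, function(e) e$K_param, character(1)),
        stringsAsFactors = FALSE)
    }
    reaction(r$name,
             reactants = as.character(unlist(r$reactants)),
             products = as.character(unlist(r$products)),
             modifiers = as.character(unlist(r$modifiers)),
             rate_param = r$rate_param, kind = r$kind, inhibitors = inhib)
  })
  pars <- unlist(doc$parameters)
  reaction_network(sp, rx, pars)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a network as an SBML Level 3 document
#'
#' Writes an SBML L3v2 model: compartments from the species compartment
#' tags, species with initial amounts, global parameters, and reactions
#' with reactant/product/modifier references and mass-action kinetic laws
#' in MathML. Saturating inhibition factors are emitted as part of the
#' kinetic-law MathML (a divide node).
#'
#' @param network A \code{reaction_network}.
#' @param path Output file path (.xml).
#' @param model_id SBML model id.
#' @return \code{path}, invisibly.
#' @export
export_sbml <- function(network, path, model_id = "reaction_network") {
  validate_network(network)
  comps <- unique(network$species$compartment)
  ml_times <- function(factors) {
    if (length(factors) == 1L) return(factors)
    paste0("<apply><times/>", paste0(factors, collapse = ""), "</apply>")
  }
  ci <- function(x) paste0("<ci> ", x, " </ci>")
  rx_xml <- vapply(unname(network$reactions), function(r) {
    spref <- function(tag, who) {
      if (!length(who)) return("")
      tab <- table(who)
      paste0("<listOf", tag, "s>",
             paste0("<", substr(tag, 1, 1), tolower(substr(tag, 2, nchar(tag))),
                    " species=\"", names(tab), "\"",
                    if (tag != "Modifier") paste0(" stoichiometry=\"",
                                                  as.integer(tab),
                                                  "\" constant=\"true\""),
                    "/>", collapse = ""),
             "</listOf", tag, "s>")
    }
    factors <- c(ci(r$rate_param), vapply(c(r$reactants, r$modifiers), ci,
                                          character(1)))
    math <- ml_times(factors)
    if (!is.null(r$inhibitors)) {
      for (q in seq_len(nrow(r$inhibitors))) {
        denom <- paste0("<apply><plus/><cn> 1 </cn><apply><divide/>",
                        ci(r$inhibitors$species[q]),
                        ci(r$inhibitors$K_param[q]), "</apply></apply>")
        math <- paste0("<apply><divide/>", math, denom, "</apply>")
      }
    }
    paste0("<reaction id=\"", r$name, "\" reversible=\"false\">",
           spref("Reactant", r$reactants),
           spref("Product", r$products),
           spref("Modifier", r$modifiers),
           "<kineticLaw><math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
           math, "</math></kineticLaw></reaction>")
  }, character(1))
  doc <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version2/core\" ",
    "level=\"3\" version=\"2\"><model id=\"", model_id,
    "\" substanceUnits=\"item\" timeUnits=\"hour\">",
    "<listOfCompartments>",
    paste0("<compartment id=\"", comps,
           "\" spatialDimensions=\"3\" size=\"1\" constant=\"true\"/>",
           collapse = ""),
    "</listOfCompartments><listOfSpecies>",
    paste0("<species id=\"", network$species$name, "\" compartment=\"",
           network$species$compartment, "\" initialAmount=\"",
           network$species$initial,
           "\" hasOnlySubstanceUnits=\"true\" boundaryCondition=\"false\"",
           " constant=\"false\"/>", collapse = ""),
    "</listOfSpecies><listOfParameters>",
    paste0("<parameter id=\"", names(network$parameters), "\" value=\"",
           network$parameters, "\" constant=\"true\"/>", collapse = ""),
    "</listOfParameters><listOfReactions>",
    paste0(rx_xml, collapse = ""),
    "</listOfReactions></model></sbml>")
  # parse/serialize through xml2 so the output is well-formed, indented XML
  xml2::write_xml(xml2::read_xml(doc), path)
  invisible(path)
}

#' Write a trajectory as tidy CSV
#'
#' @param trajectory A \code{trajectory}.
#' @param path Output CSV path; columns time, species, amount.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
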