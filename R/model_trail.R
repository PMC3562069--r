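# Default rate constants and initial amounts for the TRAIL-induced
# apoptosis network. Units: molecules/cell and hours. Initial amounts
# follow the Albeck HeLa convention; cFLIP is raised 10-fold above the
# cycloheximide-era value because protein synthesis is not blocked here.
# Rate constants are calibration defaults chosen so that, at the study
# doses (20 ng/ml TRAIL, 25 uM LY30), each single agent kills only a small
# fraction of a 40%-CV population within 24 h while the combination kills
# synergistically.
trail_defaults <- function() {
  list(
    initial = c(
      TRAIL = 0, R = 200, DISC = 0, DISC_flip = 0,
      flip = 1000,
      ARC = 1000, C8_ARC = 0,
      pC8 = 20000, C8 = 0,
      pC3 = 10000, C3 = 0,
      pC9 = 100000, C9 = 0,
      Bid = 40000, tBid = 0,
      Bax = 100000, BaxA = 0, Bax2 = 0, Pore = 0,
      Bcl2 = 20000, BaxA_Bcl2 = 0,
      CytCm = 500000, CytC = 0,
      Smacm = 100000, Smac = 0,
      XIAP = 100000, C3_XIAP = 0, Smac_XIAP = 0,
      Apaf = 100000, Apop = 0,
      PARP = 1000000, cPARP = 0),
    compartment = c(
      TRAIL = "extracellular",
      Bax = "mitochondria", BaxA = "mitochondria", Bax2 = "mitochondria",
      Pore = "mitochondria", Bcl2 = "mitochondria",
      BaxA_Bcl2 = "mitochondria", CytCm = "mitochondria",
      Smacm = "mitochondria"),
    parameters = c(
      k_bind       = 8e-6,   # TRAIL + receptor -> DISC
      kon_flip     = 1e-2,   # cFLIP binding to DISC (inhibitory)
      koff_flip    = 0.1,
      k_c8_act     = 1.5e-3, # DISC-catalysed pC8 -> C8
      kon_arc      = 1e-2,   # ARC sequestration of active C8
      koff_arc     = 0.036,
      k_bid        = 1e-4,   # C8-catalysed Bid -> tBid
      k_c3_by_c8   = 3e-4,   # C8-catalysed pC3 -> C3
      k_bax_act    = 1e-4,   # tBid-catalysed Bax activation
      kon_bcl2     = 1e-2,
      koff_bcl2    = 3.6,
      k_bax_dim    = 1e-3,   # BaxA dimerisation
      k_pore       = 1e-3,   # dimer pairing -> mitochondrial pore
      k_cytc_rel   = 3e-3,   # pore-catalysed cytochrome-c release
      k_smac_rel   = 3e-3,   # pore-catalysed Smac release
      k_apaf_act   = 1e-6,   # cytochrome-c-catalysed apoptosome formation
      k_c9_act     = 5e-6,   # apoptosome-catalysed pC9 -> C9
      k_c3_by_c9   = 1e-5,   # C9-catalysed pC3 -> C3
      k_c9_by_c3   = 1e-5,   # feedback: C3-catalysed pC9 -> C9
      k_c8_by_c3   = 3e-5,   # feedback: C3-catalysed pC8 -> C8 (no C6)
      kon_xiap     = 1e-2,   # XIAP sequestration of C3
      koff_xiap    = 0.36,
      kon_smac     = 1e-2,   # Smac neutralisation of XIAP
      koff_smac    = 0.36,
      k_parp       = 3e-4),  # C3-catalysed PARP cleavage
    caspase_turnover = c(pC8 = 0.1, C8 = 0.7, pC3 = 0.1, C3 = 0.5,
                         pC9 = 0.1, C9 = 0.5),
    trail_molecules_per_ngml = 60,  # 20 ng/ml ~ 1200 ligand copies/cell
    ly30_level_per_uM = 1)
}

#' Build the TRAIL-induced apoptosis network
#'
#' Constructs the death-receptor apoptosis model used throughout the
#' package: an Albeck-style HeLa extrinsic-apoptosis network condensed to
#' catalytic mass-action steps, with four modifications: (a) feedback from
#' active caspase-3 to caspase-9 activation, (b) direct caspase-3 to
#' caspase-8 feedback with caspase-6 removed from the network entirely,
#' (c) a 10-fold higher cFLIP level (the low published value reflected
#' cycloheximide co-treatment, absent here), and (d) ARC in place of BAR as
#' the caspase-8 inhibitor. Caspases (and only caspases) carry balanced
#' synthesis/degradation turnover so that the unstimulated network rests at
#' its initial state.
#'
#' TRAIL starts at zero; treatment is applied through timed events (see
#' \code{\link{make_schedule}}).
#'
#' @param overrides Optional named numeric vector of rate-constant
#'   overrides applied after construction.
#' @return A \code{reaction_network}.
#' @export
build_trail_network <- function(overrides = NULL) {
  d <- trail_defaults()
  comp <- function(s) if (s %in% names(d$compartment)) d$compartment[[s]] else "cytosol"
  sp <- lapply(names(d$initial), function(s) {
    species(s, d$initial[[s]], compartment = comp(s))
  })
  rx <- list(
    reaction("disc_formation", c("TRAIL", "R"), "DISC", rate_param = "k_bind"),
    reaction("flip_disc_bind", c("flip", "DISC"), "DISC_flip",
             rate_param = "kon_flip"),
    reaction("flip_disc_unbind", "DISC_flip", c("flip", "DISC"),
             rate_param = "koff_flip"),
    reaction("c8_activation", "pC8", "C8", modifiers = "DISC",
             rate_param = "k_c8_act"),
    reaction("arc_c8_bind", c("ARC", "C8"), "C8_ARC", rate_param = "kon_arc"),
    reaction("arc_c8_unbind", "C8_ARC", c("ARC", "C8"),
             rate_param = "koff_arc"),
    reaction("bid_cleavage", "Bid", "tBid", modifiers = "C8",
             rate_param = "k_bid"),
    reaction("c3_activation_by_c8", "pC3", "C3", modifiers = "C8",
             rate_param = "k_c3_by_c8"),
    reaction("bax_activation", "Bax", "BaxA", modifiers = "tBid",
             rate_param = "k_bax_act"),
    reaction("bcl2_bax_bind", c("Bcl2", "BaxA"), "BaxA_Bcl2",
             rate_param = "kon_bcl2"),
    reaction("bcl2_bax_unbind", "BaxA_Bcl2", c("Bcl2", "BaxA"),
             rate_param = "koff_bcl2"),
    reaction("bax_dimerisation", c("BaxA", "BaxA"), "Bax2",
             rate_param = "k_bax_dim"),
    reaction("pore_formation", c("Bax2", "Bax2"), "Pore",
             rate_param = "k_pore"),
    reaction("cytc_release", "CytCm", "CytC", modifiers = "Pore",
             rate_param = "k_cytc_rel"),
    reaction("smac_release", "Smacm", "Smac", modifiers = "Pore",
             rate_param = "k_smac_rel"),
    reaction("apoptosome_formation", "Apaf", "Apop", modifiers = "CytC",
             rate_param = "k_apaf_act"),
    reaction("c9_activation", "pC9", "C9", modifiers = "Apop",
             rate_param = "k_c9_act"),
    reaction("c3_activation_by_c9", "pC3", "C3", modifiers = "C9",
             rate_param = "k_c3_by_c9"),
    reaction("c9_feedback_by_c3", "pC9", "C9", modifiers = "C3",
             rate_param = "k_c9_by_c3"),
    reaction("c8_feedback_by_c3", "pC8", "C8", modifiers = "C3",
             rate_param = "k_c8_by_c3"),
    reaction("xiap_c3_bind", c("XIAP", "C3"), "C3_XIAP",
             rate_param = "kon_xiap"),
    reaction("xiap_c3_unbind", "C3_XIAP", c("XIAP", "C3"),
             rate_param = "koff_xiap"),
    reaction("smac_xiap_bind", c("Smac", "XIAP"), "Smac_XIAP",
             rate_param = "kon_smac"),
    reaction("smac_xiap_unbind", "Smac_XIAP", c("Smac", "XIAP"),
             rate_param = "koff_smac"),
    reaction("parp_cleavage", "PARP", "cPARP", modifiers = "C3",
             rate_param = "k_parp"))
  net <- reaction_network(sp, rx, d$parameters)
  net <- set_turnover(net, names(d$caspase_turnover), d$caspase_turnover)
  if (!is.null(overrides)) net <- set_parameters(net, overrides)
  net
}

#' Dose-unit conversions
#'
#' The study doses are stated in assay units (ng/ml TRAIL, uM LY30); the
#' model works in per-cell copy numbers / input levels. The conversion
#' constants are configurable model choices.
#'
#' @param trail_ngml TRAIL dose in ng/ml.
#' @param ly30_uM LY30 dose in micromolar.
#' @param constants List from \code{trail_defaults()} (or compatible).
#' @return Named numeric vector with \code{TRAIL} (molecules/cell) and
#'   \code{LY30} (model input level).
#' @export
dose_to_amounts <- function(trail_ngml = 20, ly30_uM = 25,
                            constants = trail_defaults()) {
  if (trail_ngml < 0 || ly30_uM < 0) stop("doses must be non-negative")
  c(TRAIL = trail_ngml * constants$trail_molecules_per_ngml,
    LY30 = ly30_uM * constants$ly30_level_per_uM)
}
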