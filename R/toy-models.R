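#' Toy HEK-like core metabolic network
#'
#' A ~50-reaction carbon-balanced core network used throughout the
#' package: full glycolysis with all glycolysis/gluconeogenesis-shared
#' steps, the gluconeogenic enzymes PEPCK and FBPase, triosephosphate
#' isomerase, pyruvate links to alanine and serine, a lumped TCA cycle
#' and oxidative phosphorylation, extracellular carbonic anhydrase
#' (CO2 + H2O <-> H+ + HCO3-), sodium/potassium-utilising transport
#' reactions, exchanges for glucose, lactate, ammonium, O2, CO2, H+,
#' HCO3-, H2O and four amino acids, and a biomass assembly with a
#' growth-demand objective. The base model deliberately lacks Na+/K+
#' exchange reactions, so every ion-utilising reaction is flux-blocked
#' until [add_ion_exchanges()] is applied — mirroring how genome-scale
#' HEK293 reconstructions have historically omitted these exchanges.
#'
#' The network is a self-consistent teaching/testing fixture; it is not
#' a reduction of any published genome-scale model and makes no
#' quantitative claim about one.
#'
#' @param glucose_uptake maximal glucose uptake, mmol/(g CDW h)
#'   (uptake bounds are negative lower bounds on the exchange).
#' @return a validated `metabolic_model`.
#' @export
toy_cell_model <- function(glucose_uptake = 1.5) {
  met <- function(id, comp, carbon) list(id = id, compartment = comp,
                                         carbon = carbon)
  mets <- do.call(rbind, lapply(list(
    met("glc_e", "e", 6), met("lac_e", "e", 3), met("nh4_e", "e", 0),
    met("o2_e", "e", 0), met("co2_e", "e", 1), met("h_e", "e", 0),
    met("hco3_e", "e", 1), met("h2o_e", "e", 0), met("ala_e", "e", 3),
    met("ser_e", "e", 3), met("gln_e", "e", 5), met("glu_e", "e", 5),
    met("na_e", "e", 0), met("k_e", "e", 0), met("pi_e", "e", 0),
    met("glc_c", "c", 6), met("g6p_c", "c", 6), met("f6p_c", "c", 6),
    met("fdp_c", "c", 6), met("dhap_c", "c", 3), met("g3p_c", "c", 3),
    met("pep_c", "c", 3), met("pyr_c", "c", 3), met("lac_c", "c", 3),
    met("accoa_c", "c", 2), met("oaa_c", "c", 4), met("akg_c", "c", 5),
    met("ala_c", "c", 3), met("ser_c", "c", 3), met("gln_c", "c", 5),
    met("glu_c", "c", 5), met("nh4_c", "c", 0), met("co2_c", "c", 1),
    met("o2_c", "c", 0), met("h_c", "c", 0), met("h2o_c", "c", 0),
    met("na_c", "c", 0), met("k_c", "c", 0),
    met("atp_c", "c", 0), met("adp_c", "c", 0), met("pi_c", "c", 0),
    met("nad_c", "c", 0), met("nadh_c", "c", 0), met("coa_c", "c", 0),
    met("biomass_c", "c", 0)),
    function(m) data.frame(m, stringsAsFactors = FALSE)))

  rxn <- function(id, stoich, lb = 0, ub = 1000)
    list(id = id, stoich = stoich, lb = lb, ub = ub)
  rev <- function(id, stoich) rxn(id, stoich, lb = -1000, ub = 1000)
  ex <- function(id, met, lb = -1000, ub = 1000)
    rxn(id, stats::setNames(-1, met), lb = lb, ub = ub)

  reactions <- list(
    ## exchanges (positive flux = secretion, negative = uptake)
    ex("EX_glc",  "glc_e", lb = -glucose_uptake),
    ex("EX_lac",  "lac_e"),
    ex("EX_nh4",  "nh4_e"),
    ex("EX_o2",   "o2_e"),
    ex("EX_co2",  "co2_e"),
    ex("EX_h",    "h_e"),
    ex("EX_hco3", "hco3_e"),
    ex("EX_h2o",  "h2o_e"),
    ex("EX_ala",  "ala_e"),
    ex("EX_ser",  "ser_e"),
    ex("EX_gln",  "gln_e"),
    ex("EX_glu",  "glu_e"),
    ex("EX_pi",   "pi_e"),
    ## transport
    rev("GLUT",  c(glc_e = -1, glc_c = 1)),
    rxn("SGLT",  c(glc_e = -1, na_e = -1, glc_c = 1, na_c = 1)),
    rev("O2t",   c(o2_e = -1, o2_c = 1)),
    rev("CO2t",  c(co2_c = -1, co2_e = 1)),
    rev("H2Ot",  c(h2o_c = -1, h2o_e = 1)),
    rev("NH4t",  c(nh4_c = -1, nh4_e = 1)),
    rev("MCT",   c(lac_c = -1, h_c = -1, lac_e = 1, h_e = 1)),
    rev("NHE",   c(h_c = -1, h_e = 1)),
    rev("ALAt",  c(ala_e = -1, ala_c = 1)),
    rev("SERt",  c(ser_e = -1, ser_c = 1)),
    rev("GLNt",  c(gln_e = -1, gln_c = 1)),
    rev("GLUt",  c(glu_e = -1, glu_c = 1)),
    rev("PIt",   c(pi_e = -1, pi_c = 1)),
    ## sodium/potassium handling (no exchanges in the base model)
    rxn("NAL",   c(na_e = -1, na_c = 1)),
    rxn("KUP",   c(k_e = -1, k_c = 1)),
    rxn("NAK",   c(na_c = -3, k_e = -2, atp_c = -1, h2o_c = -1,
                   na_e = 3, k_c = 2, adp_c = 1, pi_c = 1)),
    ## glycolysis / gluconeogenesis
    rxn("HK",    c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1, h_c = 1)),
    rev("PGI",   c(g6p_c = -1, f6p_c = 1)),
    rxn("PFK",   c(f6p_c = -1, atp_c = -1, fdp_c = 1, adp_c = 1, h_c = 1)),
    rxn("FBP",   c(fdp_c = -1, h2o_c = -1, f6p_c = 1, pi_c = 1)),
    rev("ALD",   c(fdp_c = -1, dhap_c = 1, g3p_c = 1)),
    rev("TPI",   c(dhap_c = -1, g3p_c = 1)),
    rev("GAPDE", c(g3p_c = -1, pi_c = -1, nad_c = -1, adp_c = -1,
                   pep_c = 1, nadh_c = 1, atp_c = 1, h2o_c = 1)),
    rxn("PYK",   c(pep_c = -1, adp_c = -1, h_c = -1, pyr_c = 1, atp_c = 1)),
    rxn("PEPCK", c(oaa_c = -1, atp_c = -1, pep_c = 1, adp_c = 1, co2_c = 1)),
    rxn("PC",    c(pyr_c = -1, co2_c = -1, atp_c = -1, h2o_c = -1,
                   oaa_c = 1, adp_c = 1, pi_c = 1, h_c = 1)),
    rev("LDH",   c(pyr_c = -1, nadh_c = -1, h_c = -1, lac_c = 1, nad_c = 1)),
    ## TCA, amino-acid catabolism, respiration
    rxn("PDH",   c(pyr_c = -1, coa_c = -1, nad_c = -1,
                   accoa_c = 1, co2_c = 1, nadh_c = 1)),
    rxn("TCA",   c(accoa_c = -1, nad_c = -3, adp_c = -1, pi_c = -1,
                   h2o_c = -2, co2_c = 2, nadh_c = 3, atp_c = 1, coa_c = 1)),
    rxn("GLS",   c(gln_c = -1, h2o_c = -1, glu_c = 1, nh4_c = 1)),
    rev("GDH",   c(glu_c = -1, nad_c = -1, h2o_c = -1,
                   akg_c = 1, nadh_c = 1, nh4_c = 1, h_c = 1)),
    rxn("AKGD",  c(akg_c = -1, nad_c = -1, adp_c = -1, pi_c = -1,
                   oaa_c = 1, co2_c = 1, nadh_c = 1, atp_c = 1)),
    rev("ALT",   c(pyr_c = -1, glu_c = -1, ala_c = 1, akg_c = 1)),
    rxn("SERD",  c(ser_c = -1, pyr_c = 1, nh4_c = 1)),
    rxn("OXPHOS", c(nadh_c = -1, o2_c = -0.5, adp_c = -2.5, pi_c = -2.5,
                    nad_c = 1, atp_c = 2.5, h2o_c = 1)),
    rxn("ATPM",  c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1)),
    ## extracellular carbonic anhydrase
    rev("CA",    c(co2_e = -1, h2o_e = -1, h_e = 1, hco3_e = 1)),
    ## biomass assembly: plain route and an ion-requiring route
    rxn("BIOMASS", c(g6p_c = -0.3, ala_c = -0.4, ser_c = -0.3, gln_c = -0.2,
                     atp_c = -30, h2o_c = -30,
                     biomass_c = 1, adp_c = 30, pi_c = 30, h_c = 30)),
    rxn("BIOMASS_k", c(g6p_c = -0.3, ala_c = -0.4, ser_c = -0.3,
                       gln_c = -0.2, na_c = -0.05, k_c = -0.05,
                       atp_c = -30, h2o_c = -30,
                       biomass_c = 1, adp_c = 30, pi_c = 30, h_c = 30)),
    rxn("DM_biomass", c(biomass_c = -1))
  )

  metabolic_model(
    id = "toy_hek_core",
    metabolites = mets,
    reactions = reactions,
    objective = "DM_biomass",
    annotations = list(
      shared_glycolysis = c("PGI", "ALD", "GAPDE"),
      tpi = "TPI",
      pepck = "PEPCK",
      fbpase = "FBP",
      amino_acid_exchanges = c("EX_ala", "EX_ser", "EX_gln", "EX_glu"),
      amino_acid_exchanges_tight = character(0),
      proton_exchange = "EX_h",
      bicarbonate_exchange = "EX_hco3",
      carbonic_anhydrase = "CA",
      ion_metabolites = c(na = "na_e", k = "k_e"),
      ion_reactions = c("SGLT", "NAL", "KUP", "NAK", "BIOMASS_k"),
      carbon_exempt = c("BIOMASS", "BIOMASS_k", "DM_biomass")
    ))
}

#' Bundled small test networks
#'
#' Named list of metabolic models with at most eight reactions each,
#' small enough for the flux optimum to be recomputed by exhaustive
#' vertex enumeration of the flux polytope. Used to certify the LP layer.
#'
#' @return named list of `metabolic_model` objects.
#' @export
toy_lp_models <- function() {
  rxn <- function(id, stoich, lb = 0, ub = 1000)
    list(id = id, stoich = stoich, lb = lb, ub = ub)
  mets <- function(ids) data.frame(id = ids, compartment = "x",
                                   carbon = NA_real_,
                                   stringsAsFactors = FALSE)
  chain <- metabolic_model(
    "lp_chain", mets(c("A", "B")),
    list(rxn("EX_A", c(A = -1), lb = -1, ub = 0),
         rxn("AB", c(A = -1, B = 1), ub = 10),
         rxn("EX_B", c(B = -1), ub = 10)),
    objective = "EX_B")
  branch <- metabolic_model(
    "lp_branch", mets(c("S", "P1", "P2", "X")),
    list(rxn("EX_S", c(S = -1), lb = -2, ub = 0),
         rxn("S1", c(S = -1, P1 = 1), ub = 0.7),
         rxn("S2", c(S = -1, P2 = 1), ub = 0.8),
         rxn("P1X", c(P1 = -1, X = 1)),
         rxn("P2X", c(P2 = -1, X = 1)),
         rxn("EX_X", c(X = -1), ub = 10)),
    objective = "EX_X")
  diamond <- metabolic_model(
    "lp_diamond", mets(c("A", "B", "C", "D")),
    list(rxn("EX_A", c(A = -1), lb = -1.2, ub = 0),
         rxn("AB", c(A = -1, B = 1), lb = -5, ub = 5),
         rxn("AC", c(A = -1, C = 1), ub = 0.9),
         rxn("BD", c(B = -1, D = 1), ub = 0.5),
         rxn("CD", c(C = -1, D = 1), ub = 5),
         rxn("BC", c(B = -1, C = 1), lb = -5, ub = 5),
         rxn("EX_D", c(D = -1), ub = 10)),
    objective = "EX_D")
  coupled <- metabolic_model(
    "lp_coupled", mets(c("A", "B", "E")),
    list(rxn("EX_A", c(A = -1), lb = -1, ub = 0),
         rxn("SRC_E", c(E = 1), ub = 0.6),
         rxn("AB", c(A = -1, E = -0.5, B = 1), ub = 10),
         rxn("EX_B", c(B = -1), ub = 10),
         rxn("WASTE_E", c(E = -1), ub = 10)),
    objective = "EX_B")
  closed <- metabolic_model(
    "lp_closed", mets(c("A", "B")),
    list(rxn("AB", c(A = -1, B = 1), lb = -3, ub = 3),
         rxn("BA", c(B = -1, A = 1), lb = 0, ub = 3),
         rxn("EX_B", c(B = -1), lb = 0, ub = 10)),
    objective = "EX_B")
  list(chain = chain, branch = branch, diamond = diamond,
       coupled = coupled, closed = closed)
}
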