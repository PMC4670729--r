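# Metabolic model readers/writers: COBRA-style JSON and SBML Level 3 FBC.

#' Read a constraint-based metabolic model
#'
#' Reads a COBRA-style model JSON (\code{metabolites}/\code{reactions} lists
#' with per-reaction stoichiometry and bounds) or an SBML Level 3 file with
#' the FBC package (bounds referenced as flux-bound parameters). The
#' designated exchange/maintenance reactions must exist in the model.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"json"} or
#'   \code{"sbml"}.
#' @param glucose,product,oxygen,maintenance designated reaction ids; the
#'   defaults are the usual identifiers of genome-scale E. coli
#'   reconstructions.
#' @param gam,biomass optional designated reactions (\code{NA} to omit).
#' @return A \linkS4class{MetabolicModel}; the metabolite/reaction counts are
#'   reported with \code{message()}.
#' @export
readMetabolicModel <- function(path, format = c("auto", "json", "sbml"),
                               glucose = "EX_glc__D_e", product = "EX_glyc_e",
                               oxygen = "EX_o2_e", maintenance = "ATPM",
                               gam = NA_character_, biomass = NA_character_) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
              else "json"
  raw <- if (format == "json") parseModelJSON(path) else parseModelSBML(path)
  ids <- c(glucose, product, oxygen, maintenance)
  miss <- setdiff(ids, raw$reactions)
  if (length(miss))
    gsStop("gs_config_error",
           "designated reaction(s) not found in '%s': %s",
           basename(path), paste(miss, collapse = ", "))
  m <- MetabolicModel(raw$metabolites, raw$reactions, raw$S, raw$lb, raw$ub,
                      glucose = glucose, product = product, oxygen = oxygen,
                      maintenance = maintenance, gam = gam, biomass = biomass)
  message(sprintf("model '%s': %d metabolites, %d reactions",
                  basename(path), length(raw$metabolites),
                  length(raw$reactions)))
  m
}

parseModelJSON <- function(path) {
  doc <- tryCatch(fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    gsStop("gs_parse_error", "malformed model JSON '%s': %s",
                           path, conditionMessage(e)))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    gsStop("gs_parse_error",
           "'%s' lacks 'metabolites'/'reactions' lists", path)
  mets <- vapply(doc$metabolites, function(m) m$id, character(1))
  rxns <- vapply(doc$reactions, function(r) r$id, character(1))
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  lb <- numeric(length(rxns)); ub <- numeric(length(rxns))
  for (j in seq_along(doc$reactions)) {
    r <- doc$reactions[[j]]
    st <- r$metabolites
    bad <- setdiff(names(st), mets)
    if (length(bad))
      gsStop("gs_parse_error",
             "reaction '%s' references unknown metabolite(s): %s",
             r$id, paste(bad, collapse = ", "))
    S[names(st), j] <- unlist(st)
    lb[j] <- if (is.null(r$lower_bound)) -1000 else r$lower_bound
    ub[j] <- if (is.null(r$upper_bound)) 1000 else r$upper_bound
  }
  list(metabolites = mets, reactions = rxns, S = S, lb = lb, ub = ub)
}

parseModelSBML <- function(path) {
  doc <- tryCatch(read_xml(path),
                  error = function(e)
                    gsStop("gs_parse_error", "cannot parse SBML '%s': %s",
                           path, conditionMessage(e)))
  # work namespace-free: SBML files use a default namespace plus fbc
  sp <- xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (!length(sp))
    gsStop("gs_parse_error", "'%s' contains no species", path)
  spec_id <- xml_attr(sp, "id")
  boundary <- xml_attr(sp, "boundaryCondition")
  mets <- spec_id[is.na(boundary) | boundary != "true"]
  pars <- xml_find_all(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- setNames(as.numeric(xml_attr(pars, "value")), xml_attr(pars, "id"))
  rx <- xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rx))
    gsStop("gs_parse_error", "'%s' contains no reactions", path)
  rxns <- xml_attr(rx, "id")
  S <- matrix(0, length(mets), length(rx), dimnames = list(mets, rxns))
  lb <- numeric(length(rx)); ub <- numeric(length(rx))
  for (j in seq_along(rx)) {
    r <- rx[[j]]
    addRefs <- function(xpath, sgn) {
      refs <- xml_find_all(r, xpath)
      for (ref in refs) {
        sid <- xml_attr(ref, "species")
        coef <- as.numeric(xml_attr(ref, "stoichiometry"))
        if (is.na(coef)) coef <- 1
        if (sid %in% mets) S[sid, j] <<- S[sid, j] + sgn * coef
      }
    }
    addRefs(".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']", -1)
    addRefs(".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']", +1)
    lbp <- xml_attr(r, "lowerFluxBound")
    ubp <- xml_attr(r, "upperFluxBound")
    rev <- xml_attr(r, "reversible")
    lb[j] <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]]
             else if (identical(rev, "false")) 0 else -1000
    ub[j] <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else 1000
  }
  list(metabolites = mets, reactions = rxns, S = S, lb = lb, ub = ub)
}

#' Write a model as COBRA-style JSON
#'
#' Round-trips through \code{\link{readMetabolicModel}} with identical
#' stoichiometry and bounds.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeModelJSON <- function(model, path) {
  rx <- lapply(seq_along(model@reactions), function(j) {
    nz <- which(model@S[, j] != 0)
    list(id = model@reactions[j],
         metabolites = as.list(setNames(model@S[nz, j],
                                        model@metabolites[nz])),
         lower_bound = model@lb[j], upper_bound = model@ub[j])
  })
  doc <- list(
    metabolites = lapply(model@metabolites, function(m) list(id = m)),
    reactions = rx,
    annotation = list(
      exchanges = model@exchanges, maintenance = model@maintenance
    )
  )
  write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
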