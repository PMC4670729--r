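# Flux balance analysis: model IO, reference constraints, LP optimization.

#' Construct a MetabolicModel
#'
#' @param metabolites,reactions identifier vectors.
#' @param S stoichiometric matrix (metabolites x reactions).
#' @param lb,ub flux bounds (mmol/gDW/h).
#' @param glucose,product,oxygen designated exchange reaction ids.
#' @param maintenance id of the non-growth-associated maintenance (NGAM)
#'   reaction.
#' @param gam id of a growth-associated maintenance reaction (\code{NA} if
#'   folded into the biomass stoichiometry).
#' @param biomass id of the biomass reaction (\code{NA} if absent).
#' @return A validated \linkS4class{MetabolicModel}.
#' @export
MetabolicModel <- function(metabolites, reactions, S, lb, ub,
                           glucose, product, oxygen, maintenance,
                           gam = NA_character_, biomass = NA_character_) {
  dimnames(S) <- list(metabolites, reactions)
  obj <- new("MetabolicModel", metabolites = metabolites,
             reactions = reactions, S = S, lb = lb, ub = ub,
             exchanges = list(glucose = glucose, product = product,
                              oxygen = oxygen),
             maintenance = maintenance, gam = gam, biomass = biomass)
  validObject(obj)
  obj
}

setMethod("show", "MetabolicModel", function(object) {
  cat(sprintf("MetabolicModel: %d metabolites x %d reactions\n",
              length(object@metabolites), length(object@reactions)))
  cat(sprintf("  exchanges: glucose=%s, product=%s, oxygen=%s; NGAM=%s\n",
              object@exchanges$glucose, object@exchanges$product,
              object@exchanges$oxygen, object@maintenance))
  invisible(NULL)
})

#' Toy glucose-to-glycerol network
#'
#' A 7-metabolite, 9-reaction core network capturing the stoichiometry of
#' the engineered pathway: glucose is split into two triose units, each
#' either drained to glycerol (the heterologous GPD1-GPP2 branch), oxidized
#' to regenerate ATP, or invested in biomass. With unconstrained
#' maintenance the whole carbon flux can go to glycerol (2 mol per mol
#' glucose, mass yield 2 x 92.09 / 180.16 = 1.0224 g/g); fixing the NGAM
#' flux at 6.75 forces 0.5 triose into oxidation.
#'
#' @return A \linkS4class{MetabolicModel}.
#' @examples
#' toyGlycerolModel()
#' @export
toyGlycerolModel <- function() {
  mets <- c("GLC", "TRI", "GLY", "ATP", "ADP", "O2", "BIO")
  rxns <- c("EX_glc", "GLK", "G2G", "OXI", "BIOS", "EX_bio", "NGAM",
            "EX_o2", "EX_gly")
  S <- matrix(0, 7, 9, dimnames = list(mets, rxns))
  S["GLC", "EX_glc"] <- -1
  S["GLC", "GLK"] <- -1; S["TRI", "GLK"] <- 2
  S["TRI", "G2G"] <- -1; S["GLY", "G2G"] <- 1
  S["TRI", "OXI"] <- -1; S["O2", "OXI"] <- -3
  S["ADP", "OXI"] <- -13.5; S["ATP", "OXI"] <- 13.5
  S["TRI", "BIOS"] <- -1.5; S["ATP", "BIOS"] <- -10
  S["ADP", "BIOS"] <- 10; S["BIO", "BIOS"] <- 1
  S["BIO", "EX_bio"] <- -1
  S["ATP", "NGAM"] <- -1; S["ADP", "NGAM"] <- 1
  S["O2", "EX_o2"] <- -1
  S["GLY", "EX_gly"] <- -1
  MetabolicModel(mets, rxns, S,
                 lb = c(-10, 0, 0, 0, 0, 0, 0, -1000, 0),
                 ub = c(0, 1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000),
                 glucose = "EX_glc", product = "EX_gly", oxygen = "EX_o2",
                 maintenance = "NGAM", biomass = "BIOS")
}

#' Apply the reference yield-computation constraints
#'
#' The constraint set used for the theoretical-maximum yield computation:
#' glucose exchange fixed at -1 mmol/gDW/h, the non-growth-associated
#' maintenance flux fixed at its default 6.75 mmol/gDW/h, the
#' growth-associated maintenance flux set to 0 (when the model carries it as
#' a separate reaction), and the oxygen exchange left unconstrained.
#' Applying the function twice is idempotent.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param glucose_uptake fixed glucose exchange flux (negative = uptake).
#' @param ngam fixed maintenance flux.
#' @param fix_biomass also fix the biomass reaction to 0 (the reference
#'   computation leaves it free; growth is suppressed by the maintenance
#'   constraint alone).
#' @return The constrained \linkS4class{MetabolicModel}.
#' @export
applyYieldConstraints <- function(model, glucose_uptake = -1, ngam = 6.75,
                                  fix_biomass = FALSE) {
  ix <- function(id) match(id, model@reactions)
  g <- ix(model@exchanges$glucose)
  model@lb[g] <- glucose_uptake; model@ub[g] <- glucose_uptake
  m <- ix(model@maintenance)
  model@lb[m] <- ngam; model@ub[m] <- ngam
  o <- ix(model@exchanges$oxygen)
  model@lb[o] <- -1e6; model@ub[o] <- 1e6
  if (!is.na(model@gam)) {
    gm <- ix(model@gam)
    model@lb[gm] <- 0; model@ub[gm] <- 0
  }
  if (fix_biomass && !is.na(model@biomass)) {
    b <- ix(model@biomass)
    model@lb[b] <- 0; model@ub[b] <- 0
  }
  validObject(model)
  model
}

# Dense Big-M simplex for  max obj'v  s.t.  Aeq v = beq, lb <= v <= ub.
# Written for the small networks handled here; Dantzig pricing with a
# degenerate-pivot guard. Returns list(status, v, objective).
solveLP <- function(obj, Aeq, beq, lb, ub, maxiter = 20000, tol = 1e-9,
                    box = 1e8) {
  n <- length(obj)
  # infinite bounds are boxed; an optimum on the artificial box means the
  # original problem is unbounded
  boxed_lo <- !is.finite(lb); boxed_hi <- !is.finite(ub)
  lb[boxed_lo] <- -box; ub[boxed_hi] <- box
  rhs_eq <- beq - as.numeric(Aeq %*% lb)
  ubx <- ub - lb
  finite_ub <- which(is.finite(ubx) & ubx > tol)
  # variables fixed by equal bounds are shifted out entirely
  nub <- length(finite_ub)
  m1 <- nrow(Aeq)
  Aeq2 <- Aeq
  for (i in seq_len(m1)) if (rhs_eq[i] < 0) {
    Aeq2[i, ] <- -Aeq2[i, ]; rhs_eq[i] <- -rhs_eq[i]
  }
  m <- m1 + nub
  A <- matrix(0, m, n + nub + m1)
  b <- numeric(m)
  A[seq_len(m1), seq_len(n)] <- Aeq2
  A[cbind(seq_len(m1), n + nub + seq_len(m1))] <- 1
  b[seq_len(m1)] <- rhs_eq
  for (k in seq_len(nub)) {
    A[m1 + k, finite_ub[k]] <- 1
    A[m1 + k, n + k] <- 1
    b[m1 + k] <- ubx[finite_ub[k]]
  }
  bigM <- 1e7 * max(1, max(abs(obj)))
  cvec <- c(obj, rep(0, nub), rep(-bigM, m1))
  basis <- integer(m)
  basis[seq_len(m1)] <- n + nub + seq_len(m1)
  if (nub > 0) basis[m1 + seq_len(nub)] <- n + seq_len(nub)
  Tb <- cbind(A, b)
  nc <- ncol(A)
  for (it in seq_len(maxiter)) {
    red <- cvec - as.numeric(crossprod(cvec[basis], Tb[, seq_len(nc), drop = FALSE]))
    red[abs(red) < tol] <- 0
    enter <- which(red > tol)
    if (!length(enter)) break
    j <- enter[which.max(red[enter])]
    col <- Tb[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratio <- Tb[pos, nc + 1] / col[pos]
    i <- pos[which.min(ratio)]
    Tb[i, ] <- Tb[i, ] / Tb[i, j]
    nz <- which(abs(Tb[, j]) > 0)
    for (r in setdiff(nz, i)) Tb[r, ] <- Tb[r, ] - Tb[r, j] * Tb[i, ]
    basis[i] <- j
  }
  x <- numeric(nc)
  x[basis] <- Tb[, nc + 1]
  art <- basis > n + nub
  if (any(art) && any(x[basis[art]] > 1e-6))
    return(list(status = "infeasible",
                residual = max(x[basis[art]])))
  v <- x[seq_len(n)] + lb
  if (any(boxed_lo & v < -0.99 * box) || any(boxed_hi & v > 0.99 * box))
    return(list(status = "unbounded"))
  list(status = "optimal", v = v, objective = sum(obj * v))
}

#' Maximize the mass yield of a product by flux balance analysis
#'
#' Linear-programming maximization of the product exchange flux subject to
#' the steady-state constraint \code{S v = 0} and the flux bounds, followed
#' by conversion to a mass yield using the molecular weights of glycerol
#' (92.09 g/mol) and glucose (180.16 g/mol) by default.
#'
#' @param model a constrained \linkS4class{MetabolicModel} (see
#'   \code{\link{applyYieldConstraints}}).
#' @param product reaction id to maximize; defaults to the designated
#'   product exchange.
#' @param mw_product,mw_substrate molecular weights (g/mol).
#' @return An \linkS4class{FBAResult}.
#' @examples
#' m <- applyYieldConstraints(toyGlycerolModel())
#' maximizeProductYield(m)
#' @export
maximizeProductYield <- function(model, product = NULL,
                                 mw_product = 92.09, mw_substrate = 180.16) {
  if (is.null(product)) product <- model@exchanges$product
  j <- match(product, model@reactions)
  if (is.na(j))
    gsStop("gs_config_error", "product reaction '%s' not in model", product)
  obj <- numeric(length(model@reactions)); obj[j] <- 1
  sol <- solveLP(obj, model@S, numeric(length(model@metabolites)),
                 model@lb, model@ub)
  if (sol$status == "infeasible") {
    fixed <- model@reactions[model@lb == model@ub]
    gsStop("gs_infeasible",
           "no steady-state flux distribution satisfies the constraints (fixed fluxes: %s)",
           paste(fixed, collapse = ", "))
  }
  if (sol$status == "unbounded")
    gsStop("gs_unbounded", "objective '%s' is unbounded under the given bounds",
           product)
  g <- match(model@exchanges$glucose, model@reactions)
  uptake <- abs(sol$v[g])
  my <- if (uptake > 0)
    sol$v[j] * mw_product / (uptake * mw_substrate) else NA_real_
  new("FBAResult", objective_flux = sol$objective,
      fluxes = setNames(sol$v, model@reactions),
      mass_yield = my, status = "optimal")
}

setMethod("show", "FBAResult", function(object) {
  cat(sprintf("FBAResult (%s): objective flux %.5g mmol/gDW/h, mass yield %.4g g/g\n",
              object@status, object@objective_flux, object@mass_yield))
  invisible(NULL)
})
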