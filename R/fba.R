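# Linear programming backend ------------------------------------------------
#
# FBA solves: max c'v  s.t.  S v = 0,  lb <= v <= ub.
# The solver is pluggable; the default backend fixes zero-span variables,
# shifts the rest to x = v - lb >= 0 and hands the problem to the
# package's two-phase simplex (see lp.R for why it is not an external
# routine).

#' Solve a bounded linear program
#'
#' Maximizes `obj' v` subject to `S v = 0` and `lb <= v <= ub`. This is the
#' pluggable solver seam: any function with this signature returning a list
#' with `status` (`"optimal"`/`"infeasible"`), `objective_value` and `fluxes`
#' can replace it via the `solver` argument of [fba()].
#'
#' @param S Stoichiometric matrix (metabolites x reactions).
#' @param obj Objective coefficient vector over reactions.
#' @param lb,ub Flux bounds (finite).
#' @param tol Solver tolerance.
#' @return List with `status`, `objective_value`, `fluxes`.
#' @export
solve_lp_default <- function(S, obj, lb, ub, tol = 1e-9) {
  n <- length(obj)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  span <- ub - lb
  free <- span > 0
  v <- lb  # fixed variables sit at their (equal) bounds
  if (!any(free)) {
    feasible <- all(abs(S %*% v) <= max(tol, 1e-9) * max(1, max(abs(v))))
    if (!feasible) {
      return(list(status = "infeasible", objective_value = NA_real_,
                  fluxes = NULL))
    }
    return(list(status = "optimal", objective_value = sum(obj * v),
                fluxes = v))
  }
  # shift to x = v - lb >= 0 over the free variables only:
  #   S_f x = -S lb ;  x <= ub - lb
  b3 <- as.numeric(-S %*% lb)
  A3 <- S[, free, drop = FALSE]
  res <- .lp_bounded(A3, b3, obj[free], span[free], tol = tol)
  if (res$status != "optimal") {
    return(list(status = "infeasible", objective_value = NA_real_,
                fluxes = NULL))
  }
  v[free] <- res$x + lb[free]
  list(status = "optimal",
       objective_value = sum(obj * v),
       fluxes = v)
}

# Build the LP data for a model and objective (reaction id or a
# biomass_composition, which is mounted as a temporary reaction).
.gem_lp <- function(model, objective = NULL) {
  objective <- objective %||% model$objective
  if (is.null(objective)) stop("no objective given or set", call. = FALSE)
  S <- stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  rxn_ids <- names(model$reactions)
  if (inherits(objective, "biomass_composition") || is.numeric(objective)) {
    comp <- biomass_composition(objective)
    if (!length(comp)) stop("empty biomass composition", call. = FALSE)
    miss <- setdiff(names(comp), rownames(S))
    if (length(miss)) {
      stop("objective composition references metabolite(s) not in model: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    col <- stats::setNames(numeric(nrow(S)), rownames(S))
    col[names(comp)] <- as.numeric(comp)
    S <- cbind(S, .objective_ = col)
    lb <- c(lb, 0); ub <- c(ub, 1000)
    rxn_ids <- c(rxn_ids, ".objective_")
    obj_idx <- length(rxn_ids)
  } else {
    obj_idx <- match(objective, rxn_ids)
    if (is.na(obj_idx)) {
      stop("objective reaction '", objective, "' not in model",
           call. = FALSE)
    }
  }
  cvec <- numeric(length(rxn_ids))
  cvec[obj_idx] <- 1
  list(S = S, obj = cvec, lb = unname(lb), ub = unname(ub),
       rxn_ids = rxn_ids)
}

.lp_run <- function(lp, solver, tol) {
  res <- solver(lp$S, lp$obj, lp$lb, lp$ub, tol = tol)
  if (res$status != "optimal") {
    return(structure(list(status = "infeasible",
                          objective_value = NA_real_, fluxes = NULL),
                     class = "flux_result"))
  }
  structure(list(status = "optimal",
                 objective_value = res$objective_value,
                 fluxes = stats::setNames(res$fluxes, lp$rxn_ids)),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat("<flux_result>", x$status)
  if (x$status == "optimal") cat(", objective =", x$objective_value)
  cat("\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the objective flux subject to steady state (`S v = 0`) and the
#' model's flux bounds. The objective is either a reaction id or a
#' [biomass_composition()], which is mounted as a temporary irreversible
#' reaction for the solve.
#'
#' @param model A [gem()].
#' @param objective Reaction id or [biomass_composition()]; defaults to the
#'   model's objective.
#' @param solver LP backend (see [solve_lp_default()]).
#' @param tol Solver tolerance.
#' @return A `flux_result`: `status` (`"optimal"`/`"infeasible"`),
#'   `objective_value`, and the flux vector when optimal.
#' @examples
#' m <- make_toy_model(toy_spec(seed = 1))
#' fba(m)
#' @export
fba <- function(model, objective = NULL, solver = solve_lp_default,
                tol = 1e-9) {
  lp <- .gem_lp(model, objective)
  .lp_run(lp, solver, tol)
}

#' Growth threshold for binarizing knockout phenotypes
#'
#' Wherever a growth/no-growth call is made, growth below this absolute
#' threshold counts as no growth.
#' @export
GROWTH_ZERO_TOL <- 1e-6

#' Single-gene-deletion screen
#'
#' Deletes each gene in turn: every reaction whose gene-protein-reaction
#' rule evaluates to false with that gene absent gets its bounds closed to
#' `(0, 0)`, and FBA is re-run. Genes mentioned by no rule return exactly
#' the wild-type growth. Infeasible knockouts are recorded as zero growth.
#'
#' @param model A [gem()].
#' @param objective Objective passed to [fba()].
#' @param genes Genes to screen (default: all model genes).
#' @param solver,tol LP backend and tolerance.
#' @return Named numeric vector of post-knockout objective values.
#' @export
single_gene_deletion <- function(model, objective = NULL, genes = NULL,
                                 solver = solve_lp_default, tol = 1e-9) {
  genes <- genes %||% model$genes
  lp <- .gem_lp(model, objective)
  wt <- .lp_run(lp, solver, tol)
  wt_growth <- if (wt$status == "optimal") wt$objective_value else 0
  # genes -> reactions whose rule mentions them, rules parsed once
  rules <- lapply(model$reactions, function(r) .gpr_parse(r$gpr))
  mention <- lapply(model$reactions, function(r) gpr_genes(r$gpr))
  out <- stats::setNames(numeric(length(genes)), genes)
  for (g in genes) {
    hit <- which(vapply(mention, function(m) g %in% m, logical(1)))
    if (!length(hit)) {
      out[[g]] <- wt_growth
      next
    }
    off <- hit[!vapply(rules[hit], function(e) eval(e, list(.ko = g)),
                       logical(1))]
    if (!length(off)) {
      out[[g]] <- wt_growth
      next
    }
    lpg <- lp
    lpg$lb[off] <- 0
    lpg$ub[off] <- 0
    res <- .lp_run(lpg, solver, tol)
    out[[g]] <- if (res$status == "optimal") res$objective_value else 0
  }
  out
}

#' Install a biomass composition as the model objective
#'
#' Adds a reaction carrying the composition's stoichiometry (or replaces
#' the reaction named by `reaction_id` if it already exists) and makes it
#' the objective. The input model is not modified.
#'
#' @param model A [gem()].
#' @param composition A non-empty [biomass_composition()] whose ids all
#'   resolve in the model.
#' @param reaction_id Id for the biomass reaction.
#' @return A new [gem()].
#' @export
set_biomass <- function(model, composition, reaction_id = "BIOMASS_bofkit") {
  composition <- biomass_composition(composition)
  if (!length(composition)) {
    stop("empty biomass composition", call. = FALSE)
  }
  miss <- setdiff(names(composition), model$metabolites$id)
  if (length(miss)) {
    stop("composition references metabolite(s) not in model: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  rxn <- list(id = reaction_id,
              metabolites = stats::setNames(as.numeric(composition),
                                            names(composition)),
              lower_bound = 0, upper_bound = 1000, gpr = "")
  model$reactions[[reaction_id]] <- rxn
  model$objective <- reaction_id
  model
}

#' Read back the objective of a model as a composition
#'
#' @param model A [gem()] with a reaction objective.
#' @return The objective reaction's stoichiometry as a
#'   [biomass_composition()].
#' @export
get_biomass <- function(model) {
  if (is.null(model$objective)) stop("model has no objective", call. = FALSE)
  biomass_composition(model$reactions[[model$objective]]$metabolites)
}
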