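# Synthetic fixtures with planted ground truth. Every generator is
# deterministic under its seed, and each planted truth is recoverable by
# the pipeline stage it exercises — that is the module's reason to exist.

#' Specification for a toy linear-pathway model
#'
#' Describes a small metabolic network made of parallel linear pathways:
#' each pathway takes an exchange metabolite through `pathway_length`
#' gene-associated conversions to a terminal product. This is the
#' simplest network on which adding a terminal metabolite to the
#' objective makes its whole pathway computationally essential.
#'
#' @param n_pathways Number of parallel linear pathways (>= 1).
#' @param pathway_length Reactions per pathway (>= 1).
#' @param n_isozymes Genes per reaction, joined by `or` (redundancy; 1
#'   means every reaction is a single-gene step).
#' @param uptake_bound Uptake bound on each exchange (mmol/gDW/hr).
#' @param planted_bof Optional [biomass_composition()]; defaults to unit
#'   consumption of pathway 1's terminal metabolite.
#' @param seed Integer seed fixing the metabolite formulas.
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(n_pathways = 2, pathway_length = 3, n_isozymes = 1,
                     uptake_bound = 10, planted_bof = NULL, seed = 1L) {
  stopifnot(n_pathways >= 1, pathway_length >= 1, n_isozymes >= 1)
  structure(list(n_pathways = n_pathways, pathway_length = pathway_length,
                 n_isozymes = n_isozymes, uptake_bound = uptake_bound,
                 planted_bof = planted_bof, seed = as.integer(seed)),
            class = "toy_spec")
}

#' Build a toy linear-pathway model
#'
#' Pathway `p` is `s<p>_e -> m<p>1_c -> ... -> m<p>L_c`, each conversion
#' carrying its own gene (`g001`, `g002`, ... numbered across the model;
#' with `n_isozymes > 1`, each reaction's rule is an `or` over that many
#' genes). Exchange reactions (no gene) admit each source metabolite up
#' to the uptake bound. All metabolites get simple CHO formulas drawn
#' under the seed, so formula weights are exactly reproducible. The
#' planted biomass composition is installed as the objective reaction
#' `BIOMASS_planted`.
#'
#' @param spec A [toy_spec()].
#' @return A [gem()] with attribute `planted_bof`.
#' @export
make_toy_model <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  set.seed(spec$seed)
  P <- spec$n_pathways; L <- spec$pathway_length
  met_ids <- character(); comp <- character()
  for (p in seq_len(P)) {
    met_ids <- c(met_ids, sprintf("s%d_e", p),
                 sprintf("m%d%d_c", p, seq_len(L)))
    comp <- c(comp, "e", rep("c", L))
  }
  formulas <- sprintf("C%dH%dO%d",
                      sample(2:12, length(met_ids), replace = TRUE),
                      sample(4:24, length(met_ids), replace = TRUE),
                      sample(1:6, length(met_ids), replace = TRUE))
  mets <- data.frame(id = met_ids, formula = formulas,
                     formula_weight = formula_weight(formulas),
                     compartment = comp, stringsAsFactors = FALSE)
  rxns <- list()
  gene_n <- 0L
  for (p in seq_len(P)) {
    ex_id <- sprintf("EX_s%d_e", p)
    rxns[[ex_id]] <- list(
      id = ex_id,
      metabolites = stats::setNames(-1, sprintf("s%d_e", p)),
      lower_bound = -spec$uptake_bound, upper_bound = 1000, gpr = "")
    chain <- c(sprintf("s%d_e", p), sprintf("m%d%d_c", p, seq_len(L)))
    for (k in seq_len(L)) {
      rid <- sprintf("R%d_%d", p, k)
      genes <- sprintf("g%03d", gene_n + seq_len(spec$n_isozymes))
      gene_n <- gene_n + spec$n_isozymes
      rxns[[rid]] <- list(
        id = rid,
        metabolites = stats::setNames(c(-1, 1), chain[c(k, k + 1)]),
        lower_bound = 0, upper_bound = 1000,
        gpr = paste(genes, collapse = " or "))
    }
  }
  planted <- spec$planted_bof %||%
    biomass_composition(stats::setNames(-1, sprintf("m1%d_c", L)))
  model <- gem(mets, rxns)
  model <- set_biomass(model, planted, reaction_id = "BIOMASS_planted")
  attr(model, "planted_bof") <- planted
  model
}

#' Build a toy energy model for maintenance-cost fixtures
#'
#' A minimal network with explicit ATP bookkeeping: glucose uptake and
#' transport, a catabolic reaction yielding `atp_per_substrate` ATP per
#' substrate, an ATP hydrolysis (maintenance) reaction `ATPM`, a proton
#' sink, and a biomass reaction costing `atp_per_biomass` ATP per unit
#' growth. Under fixed uptake `u` and growth `mu`, the maximum ATPM flux
#' is exactly `atp_per_substrate * u - atp_per_biomass * mu`, which makes
#' planted maintenance costs analytically invertible.
#'
#' @param atp_per_substrate ATP yield per substrate (mol/mol).
#' @param atp_per_biomass ATP cost per unit of biomass flux.
#' @return A [gem()] with objective `BIOMASS` and reaction `ATPM`.
#' @export
make_energy_model <- function(atp_per_substrate = 10,
                              atp_per_biomass = 20) {
  ids <- c("glc_e", "glc_c", "atp_c", "adp_c", "pi_c", "h2o_c", "h_c")
  formulas <- c("C6H12O6", "C6H12O6", "C10H12N5O13P3", "C10H12N5O10P2",
                "HO4P", "H2O", "H")
  mets <- data.frame(id = ids, formula = formulas,
                     formula_weight = formula_weight(formulas),
                     compartment = sub("^.*_", "", ids),
                     stringsAsFactors = FALSE)
  a <- atp_per_substrate; g <- atp_per_biomass
  rxns <- list(
    list(id = "EX_glc_e", metabolites = c(glc_e = -1),
         lower_bound = -1000, upper_bound = 0, gpr = ""),
    list(id = "GLCt", metabolites = c(glc_e = -1, glc_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = ""),
    list(id = "CAT",
         metabolites = c(glc_c = -1, adp_c = -a, pi_c = -a,
                         atp_c = a, h2o_c = a),
         lower_bound = 0, upper_bound = 1000, gpr = ""),
    list(id = "ATPM",
         metabolites = c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1,
                         h_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = ""),
    list(id = "DM_h_c", metabolites = c(h_c = -1),
         lower_bound = 0, upper_bound = 1000, gpr = ""),
    list(id = "BIOMASS",
         metabolites = c(atp_c = -g, h2o_c = -g, adp_c = g, pi_c = g,
                         h_c = g),
         lower_bound = 0, upper_bound = 1000, gpr = "")
  )
  gem(mets, rxns, objective = "BIOMASS")
}

#' A bare metabolite catalogue for Step 1 oracles
#'
#' Builds a reaction-free model holding the requested metabolites with
#' either explicit formula weights or formulas. Step 1 calculators only
#' read weights from the model, so this is the smallest fixture they
#' accept.
#'
#' @param ids Metabolite ids.
#' @param weights Optional numeric vector of formula weights (g/mol).
#' @param formulas Optional character vector of formulas (used when
#'   `weights` is `NULL`).
#' @return A [gem()] with no reactions.
#' @export
make_monomer_model <- function(ids, weights = NULL, formulas = NULL) {
  if (is.null(weights)) {
    stopifnot(!is.null(formulas))
    weights <- .resolve_weights(formulas)
  } else {
    formulas <- formulas %||% rep(NA_character_, length(ids))
  }
  mets <- data.frame(id = ids, formula = formulas,
                     formula_weight = weights,
                     compartment = compartment_of(ids),
                     stringsAsFactors = FALSE)
  gem(mets, list())
}

#' Random sequences with abundances
#'
#' @param n_genes Number of sequences (>= 1).
#' @param lengths Sequence length(s), recycled.
#' @param alphabet Character vector of letters (e.g. `c("A","C","G","T")`).
#' @param seed Integer seed.
#' @return List: `sequences` (named character) and `abundances` (named
#'   positive numeric), identifiers `seq1`, `seq2`, ...
#' @export
make_sequences_and_abundances <- function(n_genes, lengths = 100,
                                          alphabet = c("A", "C", "G", "T"),
                                          seed = 1L) {
  stopifnot(n_genes >= 1)
  set.seed(seed)
  lengths <- rep_len(lengths, n_genes)
  ids <- paste0("seq", seq_len(n_genes))
  seqs <- vapply(lengths, function(l) {
    paste(sample(alphabet, l, replace = TRUE), collapse = "")
  }, character(1))
  ab <- stats::runif(n_genes, 0.1, 10)
  list(sequences = stats::setNames(seqs, ids),
       abundances = stats::setNames(ab, ids))
}

#' Simulated gene essentiality under a planted biomass function
#'
#' Runs the single-gene-deletion screen with `bof` as objective,
#' binarizes growth, and optionally flips each call independently with
#' probability `noise` (symmetric label noise).
#'
#' @param model A [gem()].
#' @param bof A [biomass_composition()] resolving in the model.
#' @param noise Label-flip probability in [0, 1).
#' @param seed Seed for the noise draws.
#' @param solver,tol LP backend and tolerance.
#' @return Named logical vector (`TRUE` = essential).
#' @export
make_essentiality <- function(model, bof, noise = 0, seed = 1L,
                              solver = solve_lp_default, tol = 1e-9) {
  growth <- single_gene_deletion(model, bof, solver = solver, tol = tol)
  calls <- predict_essential(growth)
  if (noise > 0) {
    set.seed(seed)
    flip <- stats::runif(length(calls)) < noise
    calls[flip] <- !calls[flip]
  }
  calls
}

#' Growth data consistent with planted maintenance costs
#'
#' The inverse problem of [maintenance_costs()]: for each growth rate it
#' finds the substrate uptake at which the maximal ATP-hydrolysis flux
#' equals `gam * mu + ngam`. The response of max ATPM flux to the uptake
#' bound is piecewise linear; two feasible probes identify the active
#' segment and the exact uptake is obtained by interpolation and
#' verified by a re-solve.
#'
#' @param model A [gem()] (e.g. [make_energy_model()]).
#' @param gam,ngam Planted maintenance costs (mmol ATP/gDW and
#'   mmol ATP/gDW/hr).
#' @param growth_rates Growth rates (1/hr, > 0, at least two distinct).
#' @param exchange_id Substrate exchange reaction (uptake is negative
#'   flux).
#' @param atp_reaction_id ATP hydrolysis reaction.
#' @param biomass_reaction_id Reaction fixed to the growth rate.
#' @param solver,tol LP backend and tolerance.
#' @return Data frame with columns `condition`, `growth_rate`, and the
#'   exchange flux column — the input format of [maintenance_costs()].
#' @export
make_growth_data <- function(model, gam, ngam, growth_rates,
                             exchange_id = "EX_glc_e",
                             atp_reaction_id = "ATPM",
                             biomass_reaction_id = model$objective,
                             solver = solve_lp_default, tol = 1e-9) {
  stopifnot(length(growth_rates) >= 2, all(growth_rates > 0))
  lp <- .gem_lp(model, atp_reaction_id)
  j_ex <- match(exchange_id, lp$rxn_ids)
  j_bm <- match(biomass_reaction_id, lp$rxn_ids)
  if (is.na(j_ex) || is.na(j_bm)) {
    stop("exchange or biomass reaction not in model", call. = FALSE)
  }
  max_atpm <- function(u, mu) {
    lpc <- lp
    lpc$lb[j_ex] <- -u; lpc$ub[j_ex] <- -u
    lpc$lb[j_bm] <- mu; lpc$ub[j_bm] <- mu
    res <- .lp_run(lpc, solver, tol)
    if (res$status != "optimal") NA_real_ else res$objective_value
  }
  uptake <- vapply(growth_rates, function(mu) {
    target <- gam * mu + ngam
    # find two feasible probe uptakes bracketing a linear segment
    u1 <- mu; a1 <- max_atpm(u1, mu)
    tries <- 0
    while (is.na(a1) && tries < 60) {
      u1 <- u1 * 2; a1 <- max_atpm(u1, mu); tries <- tries + 1
    }
    if (is.na(a1)) stop("no feasible uptake for growth rate ", mu,
                        call. = FALSE)
    u2 <- u1 * 2; a2 <- max_atpm(u2, mu)
    if (is.na(a2) || a2 == a1) {
      stop("ATP flux does not respond to uptake at growth rate ", mu,
           call. = FALSE)
    }
    u <- u1 + (target - a1) * (u2 - u1) / (a2 - a1)
    a <- max_atpm(u, mu)
    if (is.na(a) || abs(a - target) > 1e-6) {
      stop("cannot realize maintenance target at growth rate ", mu,
           call. = FALSE)
    }
    u
  }, numeric(1))
  out <- data.frame(condition = paste0("cond", seq_along(growth_rates)),
                    growth_rate = growth_rates)
  out[[exchange_id]] <- -uptake
  out
}
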