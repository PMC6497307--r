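# Step 1: macromolecule stoichiometric coefficients and maintenance costs.
#
# The shared closed form: given molar monomer frequencies f_i and the
# macromolecular weight fraction wf of a category,
#     c_i = -1000 * wf * f_i / sum_j f_j * MW_j      [mmol/gDW]
# where MW_j is the model's formula weight of monomer j (g/mol). The
# denominator is the frequency-weighted mean monomer weight, so
# sum_i |c_i| * MW_i / 1000 == wf exactly: the category's mass is conserved.

#' Default monomer-to-metabolite maps
#'
#' BiGG-style cytosolic identifiers for the deoxynucleotide, ribonucleotide
#' and amino-acid building blocks, keyed by sequence letter. Pass your own
#' map to the coefficient calculators when the model uses another
#' namespace.
#'
#' @format Named character vectors.
#' @export
DNA_MONOMERS <- c(A = "datp_c", C = "dctp_c", G = "dgtp_c", T = "dttp_c")

#' @rdname DNA_MONOMERS
#' @export
RNA_MONOMERS <- c(A = "atp_c", C = "ctp_c", G = "gtp_c", U = "utp_c")

#' @rdname DNA_MONOMERS
#' @export
PROTEIN_MONOMERS <- c(
  A = "ala__L_c", R = "arg__L_c", N = "asn__L_c", D = "asp__L_c",
  C = "cys__L_c", Q = "gln__L_c", E = "glu__L_c", G = "gly_c",
  H = "his__L_c", I = "ile__L_c", L = "leu__L_c", K = "lys__L_c",
  M = "met__L_c", F = "phe__L_c", P = "pro__L_c", S = "ser__L_c",
  T = "thr__L_c", W = "trp__L_c", Y = "tyr__L_c", V = "val__L_c")

#' Macromolecular weight fractions
#'
#' Collects the dry-mass fractions of the macromolecule categories and the
#' soluble pool. Each must lie in [0, 1]. Flux balance analysis predicts
#' growth on a 1 gDW/hr basis, so a full biomass function should have
#' fractions summing to 1; `validate_weight_fractions()` reports whether
#' the provided fractions sum to at most 1 (they need not, e.g. when only
#' some categories are being rebuilt).
#'
#' @param dna,rna,protein,lipid,soluble_pool Fractions in [0, 1].
#' @return A `weight_fractions` list.
#' @export
weight_fractions <- function(dna = 0, rna = 0, protein = 0, lipid = 0,
                             soluble_pool = 0) {
  wf <- list(dna = dna, rna = rna, protein = protein, lipid = lipid,
             soluble_pool = soluble_pool)
  for (nm in names(wf)) {
    v <- wf[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("weight fraction '", nm, "' must be a single value in [0, 1]",
           call. = FALSE)
    }
  }
  structure(wf, class = "weight_fractions")
}

#' @rdname weight_fractions
#' @param wf A `weight_fractions` object.
#' @export
validate_weight_fractions <- function(wf) {
  total <- sum(unlist(wf))
  ok <- total <= 1 + 1e-12
  if (!ok) {
    warning("weight fractions sum to ", signif(total, 6),
            " > 1; growth predictions will not be on a 1 gDW basis",
            call. = FALSE)
  }
  invisible(list(total = total, ok = ok))
}

# Coerce sequences to a named character vector (accepts Biostrings sets).
as_sequence_set <- function(x) {
  if (inherits(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x) || is.null(names(x)) || !length(x)) {
    stop("sequences must be a non-empty named character vector or ",
         "XStringSet", call. = FALSE)
  }
  if (any(!nzchar(x))) stop("empty sequence present", call. = FALSE)
  toupper(x)
}

# Core conversion: molar frequencies (named by metabolite id, need not be
# normalized) + weight fraction -> consumed-species coefficients.
.freqs_to_coefficients <- function(freqs, wf, model, r_mass = NA_real_) {
  if (wf <= 0 || wf > 1) {
    stop("weight fraction must be in (0, 1]", call. = FALSE)
  }
  freqs <- freqs[freqs > 0]
  if (!length(freqs)) stop("no monomers observed", call. = FALSE)
  freqs <- freqs / sum(freqs)
  mw <- metabolite_weights(model, names(freqs), r_mass = r_mass)
  denom <- sum(freqs * mw)  # mean monomer weight, g/mol
  biomass_composition(-1000 * wf * freqs / denom)
}

#' DNA nucleotide coefficients from a genome sequence
#'
#' Counts the four deoxynucleotides over the genome — by default over both
#' strands (sequence plus reverse complement), since the chromosome is
#' double-stranded — and converts the molar frequencies into biomass
#' coefficients using the DNA weight fraction and the model's nucleotide
#' formula weights.
#'
#' @param genome Named character vector or `DNAStringSet` of genome
#'   sequences (chromosomes/contigs).
#' @param dna_wf DNA dry-weight fraction in (0, 1].
#' @param model A [gem()] providing formula weights.
#' @param monomer_map Letter-to-metabolite map (default [DNA_MONOMERS]).
#' @param both_strands Count the reverse complement too (default `TRUE`).
#' @param max_invalid_frac Tolerated fraction of non-ACGT characters.
#' @return A [biomass_composition()] over the four dNTPs (consumed).
#' @export
dna_coefficients <- function(genome, dna_wf, model,
                             monomer_map = DNA_MONOMERS,
                             both_strands = TRUE,
                             max_invalid_frac = 0.01) {
  seqs <- as_sequence_set(genome)
  chars <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  valid <- chars %in% names(monomer_map)
  if (mean(!valid) > max_invalid_frac) {
    stop(sprintf("%.1f%% of genome characters outside %s (tolerance %.1f%%)",
                 100 * mean(!valid),
                 paste(names(monomer_map), collapse = ""),
                 100 * max_invalid_frac), call. = FALSE)
  }
  counts <- table(factor(chars[valid], levels = names(monomer_map)))
  counts <- stats::setNames(as.numeric(counts), names(monomer_map))
  if (both_strands) {
    # reverse complement swaps A<->T and C<->G, so add the mirrored counts
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    counts <- counts + counts[comp[names(counts)]]
  }
  freqs <- stats::setNames(counts, monomer_map[names(counts)])
  .freqs_to_coefficients(freqs, dna_wf, model)
}

#' Abundance-weighted monomer coefficients (RNA / protein)
#'
#' Computes whole-cell monomer frequencies by weighting each sequence's
#' monomer counts by the relative abundance of that transcript or protein:
#' `f_i = sum_g a_g n_gi / sum_g a_g L_g`, then converts to biomass
#' coefficients with the category weight fraction. Abundances must be on a
#' linear scale (not log-transformed); scaling all abundances by a
#' constant leaves the coefficients unchanged. When expression data is
#' unavailable, equal abundances (e.g. all 1) reduce this to the
#' length-weighted mean composition.
#'
#' @param seqs Named character vector or `XStringSet` (transcripts or
#'   proteins).
#' @param abundances Named numeric vector of linear-scale relative
#'   abundances (>= 0, at least one positive).
#' @param wf Category dry-weight fraction in (0, 1].
#' @param model A [gem()].
#' @param monomer_map Letter-to-metabolite map ([RNA_MONOMERS] or
#'   [PROTEIN_MONOMERS]).
#' @return A [biomass_composition()] over the mapped monomers (consumed).
#' @export
weighted_monomer_coefficients <- function(seqs, abundances, wf, model,
                                          monomer_map) {
  seqs <- as_sequence_set(seqs)
  abundances <- unlist(abundances)
  if (any(abundances < 0) || !any(abundances > 0)) {
    stop("abundances must be >= 0 with at least one positive value",
         call. = FALSE)
  }
  shared <- intersect(names(seqs), names(abundances))
  if (!length(shared)) {
    stop("no identifier overlap between sequences and abundances",
         call. = FALSE)
  }
  dropped <- length(abundances) - length(shared)
  if (dropped > 0) {
    warning(dropped, " abundance identifier(s) have no sequence and were ",
            "dropped", call. = FALSE)
  }
  counts <- stats::setNames(numeric(length(monomer_map)),
                            names(monomer_map))
  for (g in shared) {
    a <- abundances[[g]]
    if (a == 0) next
    tab <- table(factor(strsplit(seqs[[g]], "")[[1]],
                        levels = names(monomer_map)))
    counts <- counts + a * as.numeric(tab)
  }
  freqs <- stats::setNames(counts, monomer_map[names(counts)])
  .freqs_to_coefficients(freqs, wf, model)
}

#' Lipid coefficients from a lipidomic dataset
#'
#' Maps lipid common names to model identifiers, normalizes the measured
#' abundances to molar fractions, resolves molecular weights from the
#' model formulas — substituting `default_r_mass` for each `"R"`
#' pseudo-element (acyl chain of unknown length) — and converts to biomass
#' coefficients with the lipid weight fraction.
#'
#' @param name_to_id Named character vector: lipid common name -> model
#'   metabolite id.
#' @param abundances Named numeric vector: lipid common name -> relative
#'   abundance. Every name must be present in `name_to_id`.
#' @param lipid_wf Lipid dry-weight fraction in (0, 1].
#' @param model A [gem()].
#' @param default_r_mass Mass (g/mol) used for each `"R"` pseudo-element;
#'   the shipped default of 100 g/mol is logged whenever it is used.
#' @param mass_fractions Interpret abundances as mass fractions instead of
#'   molar fractions (they are divided by molecular weight first).
#' @return A [biomass_composition()] over the mapped lipids (consumed).
#' @export
lipid_coefficients <- function(name_to_id, abundances, lipid_wf, model,
                               default_r_mass = 100,
                               mass_fractions = FALSE) {
  abundances <- unlist(abundances)
  miss <- setdiff(names(abundances), names(name_to_id))
  if (length(miss)) {
    stop("lipid name(s) without a model identifier mapping: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ids <- unname(name_to_id[names(abundances)])
  freqs <- tapply(abundances, ids, sum)  # same id from several names adds
  freqs <- stats::setNames(as.numeric(freqs), names(freqs))
  idx <- match(names(freqs), model$metabolites$id)
  if (anyNA(idx)) {
    stop("mapped lipid id(s) not in model: ",
         paste(names(freqs)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  f_idx <- model$metabolites$formula[idx]
  has_r <- !is.na(f_idx) & grepl("R(?![a-z])", f_idx, perl = TRUE)
  if (any(has_r)) {
    message("using R-chain mass of ", default_r_mass, " g/mol for: ",
            paste(names(freqs)[has_r], collapse = ", "))
  }
  if (mass_fractions) {
    mw <- metabolite_weights(model, names(freqs), r_mass = default_r_mass)
    freqs <- freqs / mw
  }
  .freqs_to_coefficients(freqs, lipid_wf, model, r_mass = default_r_mass)
}

#' Growth- and non-growth-associated maintenance from growth data
#'
#' For each measured condition the exchange fluxes are fixed to their
#' measured values and the growth (biomass) flux to the measured growth
#' rate; the flux through the ATP hydrolysis reaction is then maximized.
#' The maximal ATP turnover is regressed on growth rate by ordinary least
#' squares: the slope is the growth-associated maintenance (GAM, mmol
#' ATP/gDW) and the intercept the non-growth-associated maintenance (NGAM,
#' mmol ATP/gDW/hr).
#'
#' @param model A [gem()] whose objective is the biomass reaction used to
#'   fix growth (override with `biomass_reaction_id`).
#' @param data Data frame with columns `condition`, `growth_rate`, and one
#'   column per exchange reaction id carrying the measured flux
#'   (mmol/gDW/hr, uptake negative).
#' @param atp_reaction_id Id of the ATP hydrolysis (maintenance) reaction.
#' @param biomass_reaction_id Reaction fixed to the growth rate.
#' @param solver,tol LP backend and tolerance.
#' @return List with `gam`, `ngam`, `r_squared`, and the per-condition
#'   `atp_flux` table.
#' @export
maintenance_costs <- function(model, data, atp_reaction_id,
                              biomass_reaction_id = model$objective,
                              solver = solve_lp_default, tol = 1e-9) {
  stopifnot(is.data.frame(data),
            all(c("condition", "growth_rate") %in% names(data)))
  if (nrow(data) < 2) {
    stop("at least two conditions are required", call. = FALSE)
  }
  if (length(unique(data$growth_rate)) < 2) {
    stop("all growth rates identical: regression is singular",
         call. = FALSE)
  }
  if (!atp_reaction_id %in% names(model$reactions)) {
    stop("ATP hydrolysis reaction '", atp_reaction_id, "' not in model",
         call. = FALSE)
  }
  ex_cols <- setdiff(names(data), c("condition", "growth_rate"))
  bad <- setdiff(ex_cols, names(model$reactions))
  if (length(bad)) {
    stop("exchange column(s) not in model: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lp <- .gem_lp(model, atp_reaction_id)
  atp <- numeric(nrow(data))
  for (i in seq_len(nrow(data))) {
    lpc <- lp
    for (ex in ex_cols) {
      j <- match(ex, lp$rxn_ids)
      v <- data[[ex]][i]
      lpc$lb[j] <- v; lpc$ub[j] <- v
    }
    j <- match(biomass_reaction_id, lp$rxn_ids)
    lpc$lb[j] <- data$growth_rate[i]; lpc$ub[j] <- data$growth_rate[i]
    res <- .lp_run(lpc, solver, tol)
    if (res$status != "optimal") {
      stop("condition '", data$condition[i],
           "' is infeasible under the measured fluxes", call. = FALSE)
    }
    atp[i] <- res$objective_value
  }
  fit <- stats::lm(atp ~ data$growth_rate)
  gam <- unname(stats::coef(fit)[2])
  ngam <- unname(stats::coef(fit)[1])
  if (ngam < 0) {
    warning("negative NGAM estimate (", signif(ngam, 4),
            "); check measured rates", call. = FALSE)
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are fine
  list(gam = gam, ngam = ngam, r_squared = r2,
       atp_flux = data.frame(condition = data$condition,
                             growth_rate = data$growth_rate,
                             atp_flux = atp))
}

#' Default metabolite ids for the ATP maintenance quartet
#' @keywords internal
GAM_METABOLITES <- list(consumed = c("atp_c", "h2o_c"),
                        produced = c("adp_c", "pi_c", "h_c"))

#' Assemble the Step 1 biomass composition
#'
#' Merges the macromolecule category compositions and adds the
#' growth-associated maintenance as ATP + H2O consumption balanced by
#' ADP + Pi + H production, scaled by the GAM. The NGAM is not part of the
#' biomass reaction (it is enforced as a separate flux bound on the ATP
#' hydrolysis reaction) and is returned alongside for that purpose.
#'
#' @param dna,rna,protein,lipid Category [biomass_composition()]s (any may
#'   be `NULL`).
#' @param maintenance Result of [maintenance_costs()], or `NULL` to skip
#'   the GAM terms.
#' @param gam_metabolites Ids for the ATP hydrolysis quartet.
#' @return A merged [biomass_composition()].
#' @export
assemble_step1 <- function(dna = NULL, rna = NULL, protein = NULL,
                           lipid = NULL, maintenance = NULL,
                           gam_metabolites = GAM_METABOLITES) {
  parts <- Filter(Negate(is.null), list(dna, rna, protein, lipid))
  gam_part <- NULL
  if (!is.null(maintenance)) {
    gam <- maintenance$gam
    gam_part <- biomass_composition(c(
      stats::setNames(rep(-gam, length(gam_metabolites$consumed)),
                      gam_metabolites$consumed),
      stats::setNames(rep(gam, length(gam_metabolites$produced)),
                      gam_metabolites$produced)))
  }
  do.call(merge_compositions, c(parts, list(gam_part)[!is.null(gam_part)]))
}
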