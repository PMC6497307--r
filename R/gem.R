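#' Construct a genome-scale metabolic model
#'
#' A `gem` is the in-memory representation of a constraint-based model:
#' metabolites (with chemical formula and molecular weight), reactions
#' (stoichiometry, flux bounds, gene-protein-reaction rules), genes, and a
#' designated objective reaction. All services in the package (FBA, gene
#' deletions, metabolite graphs, biomass swapping) operate on this class.
#'
#' @param metabolites `data.frame` with columns `id`, `formula`,
#'   `formula_weight` (g/mol, may be `NA` while unresolved), `compartment`.
#' @param reactions Named list of reactions; each a list with fields `id`,
#'   `metabolites` (named numeric, signed stoichiometry), `lower_bound`,
#'   `upper_bound` (mmol/gDW/hr), `gpr` (boolean rule string over gene ids,
#'   possibly `""`).
#' @param genes Character vector of gene identifiers.
#' @param objective Reaction id to maximize in [fba()] by default.
#' @return An object of class `gem`.
#' @seealso [read_gem()], [fba()], [single_gene_deletion()]
#' @export
gem <- function(metabolites, reactions, genes = character(), objective = NULL) {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "formula", "formula_weight", "compartment") %in%
                  names(metabolites)))
  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]),
               collapse = ", "), call. = FALSE)
  }
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(names(reactions))) {
    stop("duplicate reaction ids", call. = FALSE)
  }
  for (r in reactions) {
    if (!length(r$metabolites)) {
      stop("reaction '", r$id, "' has empty stoichiometry", call. = FALSE)
    }
    missing <- setdiff(names(r$metabolites), metabolites$id)
    if (length(missing)) {
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (r$lower_bound > r$upper_bound) {
      stop("reaction '", r$id, "' has lower_bound > upper_bound",
           call. = FALSE)
    }
  }
  gpr_genes <- unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr))))
  genes <- union(genes, gpr_genes)
  if (!is.null(objective) && !objective %in% names(reactions)) {
    stop("objective reaction '", objective, "' not in model", call. = FALSE)
  }
  structure(
    list(metabolites = metabolites, reactions = reactions,
         genes = genes, objective = objective),
    class = "gem")
}

#' @export
print.gem <- function(x, ...) {
  cat("<gem>", length(x$reactions), "reactions,", nrow(x$metabolites),
      "metabolites,", length(x$genes), "genes\n")
  if (!is.null(x$objective)) cat("  objective:", x$objective, "\n")
  nw <- sum(is.na(x$metabolites$formula_weight))
  if (nw) cat(" ", nw, "metabolite(s) with unresolved formula weight\n")
  invisible(x)
}

#' Metabolite ids of a model
#' @param model A [gem()].
#' @return Character vector.
#' @export
metabolite_ids <- function(model) model$metabolites$id

#' Reaction ids of a model
#' @param model A [gem()].
#' @return Character vector.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' Formula weights for a set of metabolites
#'
#' @param model A [gem()].
#' @param ids Metabolite ids; all must exist in the model.
#' @param r_mass Mass for the `"R"` pseudo-element, used to resolve weights
#'   that the model stores as formulas containing `"R"`.
#' @param require_resolved Error (rather than return `NA`) on weights that
#'   remain unresolved.
#' @return Named numeric vector, g/mol.
#' @export
metabolite_weights <- function(model, ids, r_mass = NA_real_,
                               require_resolved = TRUE) {
  idx <- match(ids, model$metabolites$id)
  if (anyNA(idx)) {
    stop("metabolite id(s) not in model: ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  w <- model$metabolites$formula_weight[idx]
  if (!is.na(r_mass)) {
    unres <- is.na(w)
    if (any(unres)) {
      w[unres] <- formula_weight(model$metabolites$formula[idx[unres]],
                                 r_mass = r_mass)
    }
  }
  if (require_resolved && anyNA(w)) {
    stop("unresolved formula weight for: ",
         paste(ids[is.na(w)], collapse = ", "), call. = FALSE)
  }
  stats::setNames(w, ids)
}

#' Compartment tag from a namespaced metabolite id
#'
#' BiGG-style identifiers carry the compartment as a trailing underscore
#' token (`"atp_c"` is cytosolic atp). Strips or extracts that token.
#'
#' @param id Character vector of metabolite ids.
#' @return For `compartment_of`, the trailing token (or `""` when absent);
#'   for `strip_compartment`, the id without it.
#' @export
compartment_of <- function(id) {
  ifelse(grepl("_[A-Za-z0-9]+$", id), sub("^.*_", "", id), "")
}

#' @rdname compartment_of
#' @export
strip_compartment <- function(id) sub("_[A-Za-z0-9]+$", "", id)

#' Stoichiometric matrix of a model
#'
#' @param model A [gem()].
#' @return Dense numeric matrix, metabolites (rows) by reactions (columns),
#'   with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- names(model$reactions)
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$reactions[[j]]$metabolites
    S[names(st), j] <- st
  }
  S
}

# ---- gene-protein-reaction rules ------------------------------------------

# Tokenize a GPR rule string into parens, and/or operators and gene ids.
.gpr_tokens <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(character())
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Gene identifiers referenced by a GPR rule
#' @param rule GPR rule string, e.g. `"(b0001 and b0002) or b0003"`.
#' @return Character vector of gene ids (empty for an empty rule).
#' @export
gpr_genes <- function(rule) {
  toks <- .gpr_tokens(rule)
  setdiff(toks, c("(", ")", "and", "or", "AND", "OR", "And", "Or"))
}

# Parse a GPR rule once into an R expression over `.ko`, the character
# vector of knocked-out genes. Genes absent from the rule's vocabulary are
# simply never knocked, so they evaluate as present.
.gpr_parse <- function(rule) {
  toks <- .gpr_tokens(rule)
  if (!length(toks)) return(NULL)
  out <- vapply(toks, function(t) {
    switch(tolower(t),
           "(" = "(", ")" = ")", "and" = "&", "or" = "|",
           sprintf("(!(\"%s\" %%in%% .ko))", t))
  }, character(1))
  str2lang(paste(out, collapse = " "))
}

#' Evaluate a GPR rule under a gene knockout
#'
#' Missing gene identifiers (genes not mentioned by the rule) evaluate as
#' present, matching knockout semantics: only the named deletions can turn
#' a rule off. An empty rule is always active.
#'
#' @param rule GPR rule string.
#' @param knocked Character vector of deleted gene ids.
#' @return `TRUE` if the reaction remains active.
#' @export
gpr_eval <- function(rule, knocked = character()) {
  expr <- .gpr_parse(rule)
  if (is.null(expr)) return(TRUE)
  eval(expr, list(.ko = knocked))
}
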