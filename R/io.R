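#' Read a constraint-based model
#'
#' Loads a genome-scale model from either the JSON dialect used by the BiGG
#' model repository or SBML Level 3 with the FBC v2 package. Identifiers
#' are taken verbatim after stripping the conventional SBML `M_`/`R_`/`G_`
#' prefixes; the compartment tag is the final `"_x"` token of the
#' metabolite id. Formula weights are computed from the stored chemical
#' formulas with standard atomic masses; formulas containing the `"R"`
#' pseudo-element (generic acyl chains) are kept but their weight is left
#' unresolved until a caller supplies an `"R"` mass — this is flagged, not
#' fatal.
#'
#' @param path Path to the model file.
#' @param format `"json"` or `"sbml-fbc"`; inferred from the file extension
#'   when `NULL`.
#' @return A [gem()].
#' @export
read_gem <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- format %||%
    if (grepl("\\.json$", path, TRUE)) "json" else "sbml-fbc"
  model <- switch(format,
                  "json" = .read_gem_json(path),
                  "sbml-fbc" = .read_gem_sbml(path),
                  stop("unknown model format: ", format, call. = FALSE))
  n_unres <- sum(is.na(model$metabolites$formula_weight))
  if (n_unres) {
    message(n_unres, " metabolite(s) have unresolved formula weights ",
            "(missing formula or 'R' pseudo-element)")
  }
  model
}

.resolve_weights <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f) || grepl("R(?![a-z])", f, perl = TRUE)) {
      return(NA_real_)
    }
    tryCatch(formula_weight(f), error = function(e) NA_real_)
  }, numeric(1), USE.NAMES = FALSE)
}

.read_gem_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("model JSON parse failure: ",
                                         conditionMessage(e), call. = FALSE))
  for (field in c("metabolites", "reactions")) {
    if (is.null(x[[field]])) {
      stop("model JSON missing '", field, "' array", call. = FALSE)
    }
  }
  met_id <- vapply(x$metabolites, `[[`, character(1), "id")
  met_formula <- vapply(x$metabolites, function(m) {
    f <- m$formula
    if (is.null(f) || is.na(f)) NA_character_ else as.character(f)
  }, character(1))
  met_comp <- vapply(x$metabolites, function(m) {
    m$compartment %||% compartment_of(m$id)
  }, character(1))
  mets <- data.frame(id = met_id, formula = met_formula,
                     formula_weight = .resolve_weights(met_formula),
                     compartment = met_comp, stringsAsFactors = FALSE)
  objective <- NULL
  rxns <- lapply(x$reactions, function(r) {
    st <- unlist(r$metabolites)
    if (!is.null(r$objective_coefficient) &&
        isTRUE(r$objective_coefficient != 0)) {
      objective <<- r$id
    }
    list(id = r$id, metabolites = st,
         lower_bound = as.numeric(r$lower_bound %||% -1000),
         upper_bound = as.numeric(r$upper_bound %||% 1000),
         gpr = as.character(r$gene_reaction_rule %||% ""))
  })
  genes <- vapply(x$genes %||% list(), `[[`, character(1), "id")
  gem(mets, rxns, genes = genes, objective = objective)
}

#' Write a model as BiGG-style JSON
#'
#' @param model A [gem()].
#' @param path Output path.
#' @param id Model id stored in the file.
#' @return `path`, invisibly.
#' @export
write_gem_json <- function(model, path, id = "model") {
  out <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      list(id = m$id,
           formula = if (is.na(m$formula)) NULL else m$formula,
           compartment = m$compartment)
    }),
    reactions = lapply(model$reactions, function(r) {
      list(id = r$id, metabolites = as.list(r$metabolites),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gene_reaction_rule = r$gpr,
           objective_coefficient =
             if (!is.null(model$objective) && r$id == model$objective) 1
             else 0)
    }),
    genes = lapply(model$genes, function(g) list(id = g)),
    id = id, version = "1"
  )
  names(out$reactions) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# ---- SBML L3 + FBC v2 ------------------------------------------------------

.SBML_NS <- c(
  sbml = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2"
)

.strip_sid <- function(id, prefix) sub(paste0("^", prefix, "_"), "", id)

# Recursively convert an fbc:geneProductAssociation node to a rule string.
.gpa_to_rule <- function(node, labels) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gp <- xml2::xml_attr(node, "geneProduct")
    return(labels[[gp]] %||% .strip_sid(gp, "G"))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, .gpa_to_rule, character(1), labels = labels)
  op <- switch(nm, "and" = " and ", "or" = " or ",
               stop("unexpected element in gene association: ", nm,
                    call. = FALSE))
  paste0("(", paste(parts, collapse = op), ")")
}

.read_gem_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  ns <- .SBML_NS
  sp <- xml2::xml_find_all(doc, "//sbml:listOfSpecies/sbml:species", ns)
  if (!length(sp)) stop("SBML file declares no species", call. = FALSE)
  met_id <- .strip_sid(xml2::xml_attr(sp, "id"), "M")
  met_formula <- xml2::xml_attr(sp, "chemicalFormula")
  met_comp <- xml2::xml_attr(sp, "compartment")
  mets <- data.frame(id = met_id, formula = met_formula,
                     formula_weight = .resolve_weights(met_formula),
                     compartment = met_comp, stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(doc, "//sbml:listOfParameters/sbml:parameter",
                             ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  gps <- xml2::xml_find_all(doc, "//fbc:listOfGeneProducts/fbc:geneProduct",
                            ns)
  gp_id <- xml2::xml_attr(gps, "id")
  gp_label <- xml2::xml_attr(gps, "label")
  labels <- stats::setNames(as.list(ifelse(is.na(gp_label),
                                           .strip_sid(gp_id, "G"), gp_label)),
                            gp_id)

  rx <- xml2::xml_find_all(doc, "//sbml:listOfReactions/sbml:reaction", ns)
  rxns <- lapply(rx, function(r) {
    rid <- .strip_sid(xml2::xml_attr(r, "id"), "R")
    refs <- function(side, sgn) {
      nodes <- xml2::xml_find_all(
        r, paste0("./sbml:", side, "/sbml:speciesReference"), ns)
      if (!length(nodes)) return(numeric())
      stats::setNames(
        sgn * as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
        .strip_sid(xml2::xml_attr(nodes, "species"), "M"))
    }
    st_neg <- refs("listOfReactants", -1)
    st_pos <- refs("listOfProducts", 1)
    st <- c(st_neg, st_pos)
    lb_ref <- xml2::xml_attr(r, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(r, "upperFluxBound")
    gpa <- xml2::xml_find_first(r, "./fbc:geneProductAssociation/*", ns)
    rule <- if (inherits(gpa, "xml_missing")) "" else
      .gpa_to_rule(gpa, labels)
    list(id = rid, metabolites = st,
         lower_bound = unname(parval[lb_ref]) %|na|% -1000,
         upper_bound = unname(parval[ub_ref]) %|na|% 1000,
         gpr = rule)
  })

  fo <- xml2::xml_find_first(
    doc, "//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  objective <- if (inherits(fo, "xml_missing")) NULL else
    .strip_sid(xml2::xml_attr(fo, "reaction"), "R")

  genes <- unname(unlist(labels))
  gem(mets, rxns, genes = genes, objective = objective)
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

# Convert a rule string to nested fbc association elements (list form for
# xml2). Returns NULL for empty rules.
.rule_to_gpa <- function(rule) {
  toks <- .gpr_tokens(rule)
  if (!length(toks)) return(NULL)
  # shunting-yard-free recursive descent: or -> and -> atom
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_atom <- function() {
    t <- take()
    if (t == "(") {
      node <- parse_or()
      stopifnot(take() == ")")
      node
    } else list(kind = "ref", gene = t)
  }
  parse_and <- function() {
    parts <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); parts <- c(parts, list(parse_atom()))
    }
    if (length(parts) == 1) parts[[1]] else list(kind = "and", parts = parts)
  }
  parse_or <- function() {
    parts <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); parts <- c(parts, list(parse_and()))
    }
    if (length(parts) == 1) parts[[1]] else list(kind = "or", parts = parts)
  }
  parse_or()
}

.gpa_xml <- function(node, parent) {
  if (node$kind == "ref") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", node$gene))
  } else {
    el <- xml2::xml_add_child(parent, paste0("fbc:", node$kind))
    for (p in node$parts) .gpa_xml(p, el)
  }
}

#' Write a model as SBML Level 3 with FBC v2
#'
#' @param model A [gem()].
#' @param path Output path.
#' @param id Model id stored in the file.
#' @return `path`, invisibly.
#' @export
write_gem_sbml <- function(model, path, id = "model") {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = .SBML_NS[["sbml"]], "xmlns:fbc" = .SBML_NS[["fbc"]],
    level = "3", version = "1", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = id, "fbc:strict" = "true")

  comps <- unique(model$metabolites$compartment)
  lc <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  }

  ls <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(
      ls, "species", id = paste0("M_", m$id), compartment = m$compartment,
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (!is.na(m$formula)) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    }
  }

  bounds <- unique(unlist(lapply(model$reactions, function(r)
    c(r$lower_bound, r$upper_bound))))
  bid <- function(v) paste0("par_", gsub("[^0-9A-Za-z]", "_",
                                         format(v, scientific = FALSE)))
  lp <- xml2::xml_add_child(mnode, "listOfParameters")
  for (v in bounds) {
    xml2::xml_add_child(lp, "parameter", id = bid(v),
                        value = format(v, scientific = FALSE),
                        constant = "true")
  }

  lr <- xml2::xml_add_child(mnode, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(
      lr, "reaction", id = paste0("R_", r$id),
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = bid(r$lower_bound),
      "fbc:upperFluxBound" = bid(r$upper_bound))
    gpa <- .rule_to_gpa(r$gpr)
    if (!is.null(gpa)) {
      el <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      .gpa_xml(gpa, el)
    }
    reac <- r$metabolites[r$metabolites < 0]
    prod <- r$metabolites[r$metabolites > 0]
    if (length(reac)) {
      el <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in seq_along(reac)) {
        xml2::xml_add_child(el, "speciesReference",
                            species = paste0("M_", names(reac)[i]),
                            stoichiometry = format(-reac[[i]],
                                                   scientific = FALSE),
                            constant = "true")
      }
    }
    if (length(prod)) {
      el <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in seq_along(prod)) {
        xml2::xml_add_child(el, "speciesReference",
                            species = paste0("M_", names(prod)[i]),
                            stoichiometry = format(prod[[i]],
                                                   scientific = FALSE),
                            constant = "true")
      }
    }
  }

  if (!is.null(model$objective)) {
    lo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", model$objective),
                        "fbc:coefficient" = "1")
  }

  if (length(model$genes)) {
    lg <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in model$genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", g), "fbc:label" = g)
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}
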