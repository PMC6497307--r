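# Step 2: coenzymes by network degree, inorganic ions by list matching,
# and even-mass soluble-pool coefficients.

#' Metabolite degree table
#'
#' The degree of a metabolite is the number of reactions it participates
#' in. (An alternative reading — the number of neighboring metabolites in
#' the co-occurrence graph — is available via `definition =
#' "neighbors"`; the two are not equivalent and are deliberately not
#' reconciled.) Metabolites already placed in the biomass function by
#' Step 1 are typically passed as `exclude` so they do not enter the
#' coenzyme analysis.
#'
#' @param model A [gem()].
#' @param exclude Metabolite ids to leave out.
#' @param definition `"reactions"` (default) or `"neighbors"`.
#' @return Named integer vector of degrees.
#' @export
degree_table <- function(model, exclude = character(),
                         definition = c("reactions", "neighbors")) {
  definition <- match.arg(definition)
  keep <- setdiff(model$metabolites$id, exclude)
  if (definition == "reactions") {
    deg <- stats::setNames(integer(length(keep)), keep)
    for (r in model$reactions) {
      hit <- intersect(names(r$metabolites), keep)
      deg[hit] <- deg[hit] + 1L
    }
    deg
  } else {
    g <- metabolite_graph(model, excluded = exclude)
    d <- igraph::degree(g)
    stats::setNames(as.integer(d[keep]), keep)
  }
}

# Population (not sample) standard deviation.
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Degree threshold and coenzyme selection
#'
#' Currency metabolites (ATP, NAD, ...) take part in a disproportionate
#' number of reactions. The selection threshold is the mean degree plus
#' one population standard deviation; metabolites strictly above it are
#' reported as coenzymes, sorted by degree descending.
#'
#' @param degrees Named numeric vector from [degree_table()] (>= 2
#'   entries).
#' @return Character vector of metabolite ids (possibly empty when the
#'   degree distribution is flat).
#' @export
select_coenzymes <- function(degrees) {
  if (length(degrees) < 2) {
    stop("need at least two degree entries", call. = FALSE)
  }
  thr <- degree_threshold(degrees)
  hits <- degrees[degrees > thr]
  names(sort(hits, decreasing = TRUE))
}

#' @rdname select_coenzymes
#' @export
degree_threshold <- function(degrees) {
  mean(degrees) + .pop_sd(degrees)
}

#' The packaged universal inorganic ion list
#'
#' Reads the compartment-free ion identifiers shipped with the package
#' (derived from the inventory of ions recurring across published biomass
#' functions), or a user-supplied replacement file with one identifier per
#' line (`#` comments allowed).
#'
#' @param path Optional path to a replacement list.
#' @return Character vector of ion identifiers.
#' @export
universal_ions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "universal_ions.txt",
                                package = "bofkit", mustWork = TRUE)
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  unique(x[nzchar(x)])
}

#' Match universal ions against a model
#'
#' A model metabolite matches a list entry when its compartment-stripped
#' identifier equals the entry. One match is returned per ion; when the
#' same ion exists in several compartments the cytosolic species is
#' preferred, then the lexicographically first.
#'
#' @param model A [gem()].
#' @param ions Character vector of compartment-free ion identifiers
#'   (default: the packaged list).
#' @param preferred_compartment Compartment tag to prefer on duplicates.
#' @return Character vector of matched metabolite ids.
#' @export
select_ions <- function(model, ions = universal_ions(),
                        preferred_compartment = "c") {
  base <- strip_compartment(model$metabolites$id)
  out <- character()
  for (ion in unique(ions)) {
    hits <- model$metabolites$id[base == ion]
    if (!length(hits)) next
    pref <- hits[compartment_of(hits) == preferred_compartment]
    out <- c(out, if (length(pref)) sort(pref)[1] else sort(hits)[1])
  }
  out
}

#' Soluble-pool stoichiometric coefficients
#'
#' Splits the soluble-pool weight fraction evenly by mass across the
#' selected metabolites: each receives `soluble_wf / N` grams per gDW,
#' hence `c_i = -1000 * (soluble_wf / N) / MW_i` mmol/gDW. The summed mass
#' `sum |c_i| MW_i / 1000` equals `soluble_wf` exactly.
#'
#' @param ids Non-empty character vector of metabolite ids (coenzymes and
#'   ions).
#' @param soluble_wf Soluble-pool dry-weight fraction in (0, 1]; defaults
#'   to 0.05 (5% of the cell).
#' @param model A [gem()].
#' @return A [biomass_composition()] (consumed species).
#' @export
pool_coefficients <- function(ids, soluble_wf = 0.05, model) {
  if (!length(ids)) stop("empty metabolite list", call. = FALSE)
  if (soluble_wf <= 0 || soluble_wf > 1) {
    stop("soluble_wf must be in (0, 1]", call. = FALSE)
  }
  ids <- unique(ids)
  mw <- metabolite_weights(model, ids)
  per_met_mass <- soluble_wf / length(ids)   # g/gDW each
  biomass_composition(-1000 * per_met_mass / mw)
}

#' Run Step 2 end to end
#'
#' Degree analysis (excluding the Step 1 metabolites), coenzyme selection,
#' ion matching, and soluble-pool coefficient assignment.
#'
#' @param model A [gem()].
#' @param step1 The Step 1 [biomass_composition()] (its metabolites are
#'   excluded from the degree analysis); may be `NULL`.
#' @param soluble_wf Soluble-pool weight fraction.
#' @param ions Ion identifier list.
#' @return List with `coenzymes`, `ions`, `composition` (the soluble-pool
#'   part only) and `threshold`.
#' @export
step2_pool <- function(model, step1 = NULL, soluble_wf = 0.05,
                       ions = universal_ions()) {
  exclude <- if (is.null(step1)) character() else names(step1)
  deg <- degree_table(model, exclude = exclude)
  coen <- select_coenzymes(deg)
  ion_ids <- select_ions(model, ions)
  picked <- union(coen, ion_ids)
  comp <- if (length(picked)) {
    pool_coefficients(picked, soluble_wf, model)
  } else {
    biomass_composition()
  }
  list(coenzymes = coen, ions = ion_ids, composition = comp,
       threshold = degree_threshold(deg))
}
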