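# Evaluation metrics for comparing biomass objective functions:
# metabolite overlap, Levenshtein distance, predicted growth rate, and
# gene-essentiality MCC.

#' Metabolite overlap between two compositions
#'
#' Set intersection and differences on metabolite ids; coefficient
#' magnitudes are ignored — the comparison is between lists of
#' metabolites.
#'
#' @param a,b [biomass_composition()] objects (or anything with names).
#' @return List: `shared`, `only_a`, `only_b` (character vectors).
#' @export
bof_overlap <- function(a, b) {
  ia <- names(a); ib <- names(b)
  list(shared = intersect(ia, ib),
       only_a = setdiff(ia, ib),
       only_b = setdiff(ib, ia))
}

#' Levenshtein distance between metabolite lists
#'
#' Edit distance over id-token sequences: the number of additions,
#' removals or substitutions needed to turn one list into the other, each
#' metabolite id counting as one token. Both lists are sorted
#' lexicographically first (default) so the distance reflects set
#' composition rather than serialization order; pass `sort = FALSE` to
#' compare the lists as given.
#'
#' @param a,b Character vectors of metabolite ids (or compositions, whose
#'   names are used).
#' @param sort Sort both lists before comparing (default `TRUE`).
#' @return Non-negative integer; at least `abs(length(a) - length(b))`.
#' @export
levenshtein <- function(a, b, sort = TRUE) {
  if (!is.character(a)) a <- names(a) %||% character()
  if (!is.character(b)) b <- names(b) %||% character()
  if (sort) { a <- sort(a); b <- sort(b) }
  n <- length(a); m <- length(b)
  if (!n) return(m)
  if (!m) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      cost <- if (a[i] == b[j]) 0L else 1L
      cur[j + 1] <- min(prev[j + 1] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  prev[m + 1]
}

#' Gene-essentiality MCC of a biomass composition
#'
#' Installs the composition as the model objective, runs a
#' single-gene-deletion screen over the genes shared with the dataset,
#' binarizes growth (below [GROWTH_ZERO_TOL] means no growth), and scores
#' the Matthews correlation coefficient against the experimental calls.
#'
#' @param model A [gem()].
#' @param bof A [biomass_composition()] resolving in the model.
#' @param essentiality Named calls accepted by [as_essentiality()].
#' @param solver,tol LP backend and tolerance.
#' @return MCC in [-1, 1].
#' @export
essentiality_mcc <- function(model, bof, essentiality,
                             solver = solve_lp_default, tol = 1e-9) {
  ess <- as_essentiality(essentiality)
  m2 <- set_biomass(model, bof)
  shared <- intersect(m2$genes, names(ess))
  if (!length(shared)) {
    stop("no genes shared between model and essentiality dataset",
         call. = FALSE)
  }
  growth <- single_gene_deletion(m2, genes = shared, solver = solver,
                                 tol = tol)
  mcc(predict_essential(growth), ess[shared])
}

#' Predicted growth rate under a biomass composition
#'
#' Installs the composition as the objective, optionally applies medium
#' bounds (lower bounds on exchange reactions), and runs FBA. An
#' infeasible problem is reported as zero growth with the status attached.
#'
#' @param model A [gem()].
#' @param bof A [biomass_composition()].
#' @param medium_bounds Optional named numeric vector: exchange reaction
#'   id -> lower bound (mmol/gDW/hr, uptake negative).
#' @param solver,tol LP backend and tolerance.
#' @return Growth rate in 1/hr with attribute `status`.
#' @export
growth_rate <- function(model, bof, medium_bounds = NULL,
                        solver = solve_lp_default, tol = 1e-9) {
  m2 <- set_biomass(model, bof)
  if (!is.null(medium_bounds)) {
    bad <- setdiff(names(medium_bounds), names(m2$reactions))
    if (length(bad)) {
      stop("medium bound(s) for unknown reaction(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (ex in names(medium_bounds)) {
      m2$reactions[[ex]]$lower_bound <- medium_bounds[[ex]]
    }
  }
  res <- fba(m2, solver = solver, tol = tol)
  mu <- if (res$status == "optimal") res$objective_value else 0
  structure(mu, status = res$status)
}

#' Read medium bounds
#'
#' Two-column delimited text: exchange reaction id, lower bound.
#'
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_medium <- function(path) {
  df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                        col.names = c("id", "lb"))
  if (is.na(suppressWarnings(as.numeric(df$lb[1])))) df <- df[-1, ]
  stats::setNames(as.numeric(df$lb), df$id)
}

#' Side-by-side comparison of biomass compositions
#'
#' Computes, for each candidate composition against a reference: shared
#' and specific metabolite counts, Levenshtein distance, predicted growth
#' rate, and (when essentiality data is given) the gene-essentiality MCC.
#'
#' @param model A [gem()].
#' @param reference The reference [biomass_composition()].
#' @param candidates Named list of compositions to compare.
#' @param essentiality Optional named calls for the MCC column.
#' @param medium_bounds Optional medium for the growth column.
#' @param solver,tol LP backend and tolerance.
#' @return Data frame, one row per candidate.
#' @export
compare_bofs <- function(model, reference, candidates,
                         essentiality = NULL, medium_bounds = NULL,
                         solver = solve_lp_default, tol = 1e-9) {
  stopifnot(is.list(candidates), !is.null(names(candidates)))
  rows <- lapply(names(candidates), function(nm) {
    cand <- candidates[[nm]]
    ov <- bof_overlap(cand, reference)
    data.frame(
      method = nm,
      shared = length(ov$shared),
      specific = length(ov$only_a),
      levenshtein = levenshtein(cand, reference),
      growth_rate = as.numeric(growth_rate(model, cand, medium_bounds,
                                           solver = solver, tol = tol)),
      mcc = if (is.null(essentiality)) NA_real_ else
        essentiality_mcc(model, cand, essentiality, solver = solver,
                         tol = tol))
  })
  do.call(rbind, rows)
}
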