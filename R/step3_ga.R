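# Step 3 (search): feature selection of candidate metabolites and a
# genetic algorithm over binary metabolite-inclusion vectors whose fitness
# is the Matthews correlation coefficient of gene-essentiality prediction,
# with a size penalty as secondary objective.

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` over two binary
#' vectors. When any factor of the denominator is zero (a degenerate
#' confusion matrix: one class absent from predictions or observations)
#' the score is 0 by convention — equivalent to a random prediction.
#'
#' @param predicted,observed Logical (or 0/1) vectors of equal length.
#' @return Value in [-1, 1].
#' @export
mcc <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed lengths differ", call. = FALSE)
  }
  if (!length(predicted)) stop("empty vectors", call. = FALSE)
  p <- as.logical(predicted); o <- as.logical(observed)
  tp <- sum(p & o); tn <- sum(!p & !o)
  fp <- sum(p & !o); fn <- sum(!p & o)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
}

#' Coerce gene essentiality calls
#'
#' Accepts named logical vectors, 0/1, or `"E"`/`"NE"` character calls and
#' returns a named logical vector (`TRUE` = essential). Warns when only
#' one class is present.
#'
#' @param x Named vector of calls.
#' @return Named logical vector.
#' @export
as_essentiality <- function(x) {
  if (is.null(names(x)) || !length(x)) {
    stop("essentiality calls must be a non-empty named vector",
         call. = FALSE)
  }
  v <- if (is.character(x)) {
    up <- toupper(trimws(x))
    if (!all(up %in% c("E", "NE", "1", "0"))) {
      stop("essentiality calls must be E/NE or 1/0", call. = FALSE)
    }
    up %in% c("E", "1")
  } else as.logical(as.numeric(x))
  v <- stats::setNames(v, names(x))
  if (length(unique(v)) < 2) {
    warning("only one essentiality class present", call. = FALSE)
  }
  v
}

#' Read an essentiality table
#'
#' Two-column delimited text: gene id, call in `{E, NE}` (or `{1, 0}`);
#' header optional.
#'
#' @param path File path.
#' @return Named logical vector (`TRUE` = essential).
#' @export
read_essentiality <- function(path) {
  df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                        col.names = c("gene", "call"))
  if (!toupper(trimws(df$call[1])) %in% c("E", "NE", "1", "0")) {
    df <- df[-1, ]
  }
  as_essentiality(stats::setNames(df$call, df$gene))
}

#' Binarize knockout growth into essentiality predictions
#'
#' @param growth Named numeric vector of post-knockout growth.
#' @param mode `"absolute"`: essential iff growth < [GROWTH_ZERO_TOL];
#'   `"relative"`: essential iff growth < 5% of `wild_type`.
#' @param wild_type Wild-type growth, required in relative mode.
#' @return Named logical vector (`TRUE` = predicted essential).
#' @export
predict_essential <- function(growth, mode = c("absolute", "relative"),
                              wild_type = NULL) {
  mode <- match.arg(mode)
  if (mode == "absolute") growth < GROWTH_ZERO_TOL
  else {
    stopifnot(!is.null(wild_type))
    growth < 0.05 * wild_type
  }
}

# ---- feature selection ----------------------------------------------------

#' Filter candidates for individual producibility
#'
#' A metabolite can only belong to the biomass function if the network can
#' actually produce it: for each candidate a unit-consumption objective on
#' that metabolite alone is optimized and the candidate is kept when the
#' LP is optimal with objective flux above `1e-6`.
#'
#' @param model A [gem()].
#' @param candidates Metabolite ids (must resolve in the model).
#' @param solver,tol LP backend and tolerance.
#' @return The surviving candidate ids.
#' @export
producibility_filter <- function(model, candidates,
                                 solver = solve_lp_default, tol = 1e-9) {
  miss <- setdiff(candidates, model$metabolites$id)
  if (length(miss)) {
    stop("candidate(s) not in model: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    comp <- biomass_composition(stats::setNames(-1, candidates[i]))
    res <- fba(model, comp, solver = solver, tol = tol)
    keep[i] <- res$status == "optimal" &&
      res$objective_value > GROWTH_ZERO_TOL
  }
  candidates[keep]
}

#' Per-metabolite essentiality screen
#'
#' Evaluates each candidate on its own: the candidate becomes a
#' unit-consumption objective, a single-gene-deletion screen is run,
#' growth is binarized, and the MCC against the experimental essentiality
#' calls (restricted to genes present in both model and dataset) is
#' recorded. Candidates with MCC strictly above the screen distribution's
#' mean plus one population standard deviation form the metabolites
#' subset handed to the genetic algorithm.
#'
#' @param model A [gem()].
#' @param candidates Producible metabolite ids.
#' @param essentiality Named calls accepted by [as_essentiality()].
#' @param threshold Selection threshold; `NULL` (default) uses
#'   mean + 1 population SD of the screen scores.
#' @param solver,tol LP backend and tolerance.
#' @return List: `scores` (named MCC vector), `threshold`, `selected`
#'   (ids above threshold), `n_shared_genes`.
#' @export
metabolite_mcc_screen <- function(model, candidates, essentiality,
                                  threshold = NULL,
                                  solver = solve_lp_default, tol = 1e-9) {
  ess <- as_essentiality(essentiality)
  shared <- intersect(model$genes, names(ess))
  if (!length(shared)) {
    stop("no genes shared between model and essentiality dataset",
         call. = FALSE)
  }
  dropped <- length(ess) - length(shared)
  if (dropped > 0) {
    message(dropped, " dataset gene(s) absent from the model were dropped")
  }
  obs <- ess[shared]
  scores <- stats::setNames(numeric(length(candidates)), candidates)
  for (m in candidates) {
    comp <- biomass_composition(stats::setNames(-1, m))
    growth <- single_gene_deletion(model, comp, genes = shared,
                                   solver = solver, tol = tol)
    scores[[m]] <- mcc(predict_essential(growth), obs)
  }
  thr <- threshold %||% (mean(scores) + .pop_sd(scores))
  list(scores = scores, threshold = thr,
       selected = names(scores)[scores > thr],
       n_shared_genes = length(shared))
}

# ---- GA machinery ---------------------------------------------------------

#' Genetic algorithm configuration
#'
#' Defaults: population of 100 individuals initialized with 60 to 100
#' metabolites each (clamped to the subset size), one-point crossover with
#' probability 0.8, per-individual mutation with probability 0.2 flipping
#' each bit with probability `1/|subset|`, tournament selection of size 3,
#' fitness weights `w_mcc = 1.0` and `w_size = -0.25`, and a hall of fame
#' of capacity 1000. The default comparator is lexicographic — MCC
#' dominates and the (weighted) size only breaks ties, which stabilizes
#' individual size without ever sacrificing MCC; a scalar weighted-sum
#' comparator is available via `comparator = "weighted_sum"`.
#'
#' @param population_size,generations GA dimensions.
#' @param crossover_prob,mutation_prob Per-pair / per-individual operator
#'   probabilities in [0, 1].
#' @param flip_prob Per-bit flip probability; `NULL` means `1/|subset|`.
#' @param w_mcc,w_size Fitness weights.
#' @param init_size Inclusive range the initial individual sizes are drawn
#'   from.
#' @param hof_capacity Hall-of-fame capacity.
#' @param tournament_size Tournament size for selection.
#' @param comparator `"lexicographic"` or `"weighted_sum"`.
#' @param seed Integer seed; all GA randomness derives from it.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 100, generations = 50,
                      crossover_prob = 0.8, mutation_prob = 0.2,
                      flip_prob = NULL, w_mcc = 1.0, w_size = -0.25,
                      init_size = c(60, 100), hof_capacity = 1000,
                      tournament_size = 3,
                      comparator = c("lexicographic", "weighted_sum"),
                      seed = 42L) {
  stopifnot(population_size >= 1, generations >= 0,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            length(init_size) == 2, init_size[1] <= init_size[2])
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob, flip_prob = flip_prob,
                 w_mcc = w_mcc, w_size = w_size,
                 init_size = as.integer(init_size),
                 hof_capacity = as.integer(hof_capacity),
                 tournament_size = as.integer(tournament_size),
                 comparator = match.arg(comparator),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Scalar keys used to rank fitness (higher = better). Lexicographic
# ranking compares key1 then key2; weighted-sum collapses to key1.
.fitness_keys <- function(fit, config) {
  if (config$comparator == "weighted_sum") {
    cbind(config$w_mcc * fit[, "mcc"] + config$w_size * fit[, "size"], 0)
  } else {
    cbind(config$w_mcc * fit[, "mcc"], config$w_size * fit[, "size"])
  }
}

# TRUE when fitness row a beats fitness row b.
.fitness_better <- function(a, b, config) {
  ka <- .fitness_keys(rbind(a), config); kb <- .fitness_keys(rbind(b), config)
  ka[1] > kb[1] || (ka[1] == kb[1] && ka[2] > kb[2])
}

#' Evaluate a binary biomass individual
#'
#' Builds the candidate objective — the (possibly empty) base composition
#' plus unit consumption (-1 mmol/gDW) of each selected metabolite — runs
#' a single-gene-deletion screen restricted to genes shared with the
#' essentiality dataset, binarizes growth, and scores the MCC. The
#' consumption magnitude is irrelevant to the essentiality topology: any
#' nonzero demand forces the producing pathways. An all-zero individual
#' receives the worst fitness `(-1, 0)` rather than raising, so the GA can
#' tolerate it.
#'
#' @param model A [gem()].
#' @param bits Integer/logical inclusion vector over `subset`.
#' @param subset Character vector of candidate metabolite ids.
#' @param essentiality Named calls accepted by [as_essentiality()].
#' @param base_composition Optional [biomass_composition()] always present
#'   in the objective (e.g. the Step 1+2 output).
#' @param solver,tol LP backend and tolerance.
#' @return Named numeric vector `c(mcc = , size = )`.
#' @export
evaluate_individual <- function(model, bits, subset, essentiality,
                                base_composition = NULL,
                                solver = solve_lp_default, tol = 1e-9) {
  stopifnot(length(bits) == length(subset))
  bits <- as.integer(as.logical(bits))
  size <- sum(bits)
  if (size == 0 && is.null(base_composition)) {
    return(c(mcc = -1, size = 0))
  }
  ess <- as_essentiality(essentiality)
  shared <- intersect(model$genes, names(ess))
  if (!length(shared)) {
    stop("no genes shared between model and essentiality dataset",
         call. = FALSE)
  }
  picked <- subset[bits == 1]
  part <- if (length(picked)) {
    biomass_composition(stats::setNames(rep(-1, length(picked)), picked))
  } else NULL
  obj <- merge_compositions(base_composition %||% biomass_composition(),
                            part %||% biomass_composition())
  growth <- single_gene_deletion(model, obj, genes = shared,
                                 solver = solver, tol = tol)
  c(mcc = mcc(predict_essential(growth), ess[shared]), size = size)
}

#' Generate seeded initial populations
#'
#' Each individual draws its size uniformly from `config$init_size`
#' (clamped to the subset length) and selects that many distinct
#' metabolites uniformly at random. Population `p` is seeded with
#' `config$seed + p`, so runs are reproducible and each population is an
#' independent draw — multiple evolutions from different initial
#' populations are recommended because a single evolution's outcome
#' depends on its start.
#'
#' @param subset Non-empty character vector of candidate metabolites.
#' @param n_populations Number of populations (>= 1).
#' @param config A [ga_config()].
#' @return List of populations; each a list of integer bit vectors.
#' @export
initialize_populations <- function(subset, n_populations = 1,
                                   config = ga_config()) {
  L <- length(subset)
  if (!L) stop("empty metabolite subset", call. = FALSE)
  stopifnot(n_populations >= 1)
  lo <- max(1L, min(config$init_size[1], L))
  hi <- max(1L, min(config$init_size[2], L))
  lapply(seq_len(n_populations), function(p) {
    set.seed(config$seed + p)
    lapply(seq_len(config$population_size), function(i) {
      k <- if (lo == hi) lo else sample(lo:hi, 1)
      b <- integer(L)
      b[sample.int(L, k)] <- 1L
      b
    })
  })
}

# ---- hall of fame ---------------------------------------------------------

#' Hall of fame
#'
#' Bounded archive of the best distinct individuals seen during an
#' evolution, ordered best-first by the fitness comparator.
#'
#' @param capacity Maximum number of stored individuals (default 1000).
#' @return An empty `hall_of_fame`.
#' @export
hall_of_fame <- function(capacity = 1000) {
  structure(list(capacity = as.integer(capacity), bits = list(),
                 fitness = matrix(numeric(), ncol = 2,
                                  dimnames = list(NULL, c("mcc", "size")))),
            class = "hall_of_fame")
}

#' @export
print.hall_of_fame <- function(x, ...) {
  cat("<hall_of_fame>", length(x$bits), "of", x$capacity, "members")
  if (length(x$bits)) {
    cat(sprintf("; best mcc = %.4f (size %d)",
                x$fitness[1, "mcc"], as.integer(x$fitness[1, "size"])))
  }
  cat("\n")
  invisible(x)
}

#' Update a hall of fame with a population
#'
#' @param hof A [hall_of_fame()].
#' @param population List of bit vectors.
#' @param fitness Matrix with columns `mcc`, `size`, one row per
#'   individual.
#' @param config A [ga_config()] (supplies the comparator).
#' @return The updated `hall_of_fame`.
#' @export
hof_update <- function(hof, population, fitness, config = ga_config()) {
  keys_old <- vapply(hof$bits, paste, character(1), collapse = "")
  keys_new <- vapply(population, paste, character(1), collapse = "")
  keep <- !duplicated(keys_new) & !(keys_new %in% keys_old)
  bits <- c(hof$bits, population[keep])
  fit <- rbind(hof$fitness, fitness[keep, , drop = FALSE])
  keys <- .fitness_keys(fit, config)
  ord <- order(keys[, 1], keys[, 2], decreasing = TRUE)
  ord <- ord[seq_len(min(length(ord), hof$capacity))]
  hof$bits <- bits[ord]
  hof$fitness <- fit[ord, , drop = FALSE]
  hof
}

# ---- evolution ------------------------------------------------------------

#' Run one evolution
#'
#' Applies the genetic operators generation by generation: tournament
#' selection into a new population, one-point crossover on adjacent pairs
#' with probability `crossover_prob`, per-individual mutation with
#' probability `mutation_prob` flipping each bit with `flip_prob`,
#' re-evaluation of changed individuals, and hall-of-fame / logbook
#' updates. Fitness evaluations are memoized on the bit pattern
#' (evaluation is a pure function of the bits), so converged populations
#' cost little. With `generations = 0` the initial population is evaluated
#' and archived but no operators are applied.
#'
#' @param model A [gem()].
#' @param population List of bit vectors (from
#'   [initialize_populations()]).
#' @param subset Candidate metabolite ids the bits index.
#' @param essentiality Named calls accepted by [as_essentiality()].
#' @param config A [ga_config()].
#' @param base_composition Optional composition always in the objective.
#' @param solver,tol LP backend and tolerance.
#' @return List: `hof` (a [hall_of_fame()]) and `logbook` (data frame with
#'   per-generation mean/max/min population MCC and mean size).
#' @export
evolve <- function(model, population, subset, essentiality,
                   config = ga_config(), base_composition = NULL,
                   solver = solve_lp_default, tol = 1e-9) {
  stopifnot(length(population) >= 1)
  L <- length(subset)
  flip <- config$flip_prob %||% (1 / L)
  cache <- new.env(parent = emptyenv())
  eval_one <- function(b) {
    key <- paste(b, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    f <- evaluate_individual(model, b, subset, essentiality,
                             base_composition = base_composition,
                             solver = solver, tol = tol)
    cache[[key]] <- f
    f
  }
  eval_pop <- function(pop) {
    t(vapply(pop, eval_one, c(mcc = 0, size = 0)))
  }
  set.seed(config$seed)
  fitness <- eval_pop(population)
  hof <- hall_of_fame(config$hof_capacity)
  hof <- hof_update(hof, population, fitness, config)
  log_rows <- vector("list", config$generations)

  n <- length(population)
  for (gen in seq_len(config$generations)) {
    # tournament selection
    keys <- .fitness_keys(fitness, config)
    sel <- vapply(seq_len(n), function(i) {
      cand <- sample.int(n, config$tournament_size, replace = TRUE)
      best <- cand[1]
      for (cc in cand[-1]) {
        if (keys[cc, 1] > keys[best, 1] ||
            (keys[cc, 1] == keys[best, 1] && keys[cc, 2] > keys[best, 2])) {
          best <- cc
        }
      }
      best
    }, integer(1))
    offspring <- population[sel]
    # one-point crossover on adjacent pairs
    if (n >= 2 && L >= 2) {
      for (i in seq(1, n - 1, by = 2)) {
        if (stats::runif(1) < config$crossover_prob) {
          cut <- sample.int(L - 1, 1)
          a <- offspring[[i]]; b <- offspring[[i + 1]]
          offspring[[i]] <- c(a[1:cut], b[(cut + 1):L])
          offspring[[i + 1]] <- c(b[1:cut], a[(cut + 1):L])
        }
      }
    }
    # per-bit mutation
    for (i in seq_len(n)) {
      if (stats::runif(1) < config$mutation_prob) {
        mask <- stats::runif(L) < flip
        offspring[[i]][mask] <- 1L - offspring[[i]][mask]
      }
    }
    population <- offspring
    fitness <- eval_pop(population)
    hof <- hof_update(hof, population, fitness, config)
    log_rows[[gen]] <- data.frame(
      generation = gen,
      mcc_mean = mean(fitness[, "mcc"]),
      mcc_max = max(fitness[, "mcc"]),
      mcc_min = min(fitness[, "mcc"]),
      size_mean = mean(fitness[, "size"]),
      hof_best_mcc = hof$fitness[1, "mcc"],
      hof_best_size = hof$fitness[1, "size"])
  }
  logbook <- if (config$generations) do.call(rbind, log_rows) else
    data.frame(generation = integer(), mcc_mean = numeric(),
               mcc_max = numeric(), mcc_min = numeric(),
               size_mean = numeric(), hof_best_mcc = numeric(),
               hof_best_size = numeric())
  list(hof = hof, logbook = logbook)
}

#' Run several evolutions from independent initial populations
#'
#' Convenience wrapper: generates `n_evolutions` seeded initial
#' populations and evolves each (evolution `i` uses seed
#' `config$seed + i`), returning the halls of fame and logbooks.
#'
#' @inheritParams evolve
#' @param n_evolutions Number of independent evolutions.
#' @param evolution_index Optional single index to run just one evolution
#'   (sharding for external schedulers); results from shards merged by
#'   concatenating the returned `hofs` equal a serial run.
#' @return List with `hofs` (list of [hall_of_fame()]) and `logbooks`.
#' @export
run_evolutions <- function(model, subset, essentiality, n_evolutions = 1,
                           config = ga_config(), base_composition = NULL,
                           evolution_index = NULL,
                           solver = solve_lp_default, tol = 1e-9) {
  pops <- initialize_populations(subset, n_evolutions, config)
  idx <- evolution_index %||% seq_len(n_evolutions)
  res <- lapply(idx, function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    evolve(model, pops[[i]], subset, essentiality, cfg,
           base_composition = base_composition, solver = solver, tol = tol)
  })
  list(hofs = lapply(res, `[[`, "hof"),
       logbooks = lapply(res, `[[`, "logbook"))
}
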