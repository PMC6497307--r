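# Shared fixture builders. Everything is generated in code; no data files.

# A 2-reaction linear chain: EX_a (uptake <= 10) -> a -> b, demand on b.
# The LP optimum is the uptake bound: growth = 10.
chain_model <- function(uptake = 10) {
  mets <- data.frame(id = c("a_e", "b_c"),
                     formula = c("C2H4O2", "C2H4O2"),
                     formula_weight = formula_weight(c("C2H4O2", "C2H4O2")),
                     compartment = c("e", "c"),
                     stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "EX_a_e", metabolites = c(a_e = -1),
         lower_bound = -uptake, upper_bound = 1000, gpr = ""),
    list(id = "CONV", metabolites = c(a_e = -1, b_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = "gA"),
    list(id = "DM_b_c", metabolites = c(b_c = -1),
         lower_bound = 0, upper_bound = 1000, gpr = "")
  )
  gem(mets, rxns, objective = "DM_b_c")
}

# A branched toy with a hand-computable optimum: one substrate (uptake 10)
# feeding two routes to the product, one with yield 1 (capacity 4) and one
# with yield 0.5 (uncapped). Optimum = 4 * 1 + 6 * 0.5 = 7.
branched_model <- function() {
  ids <- c("s_e", "p_c")
  mets <- data.frame(id = ids, formula = c("C6H12O6", "C3H6O3"),
                     formula_weight = formula_weight(c("C6H12O6", "C3H6O3")),
                     compartment = c("e", "c"), stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "EX_s_e", metabolites = c(s_e = -1),
         lower_bound = -10, upper_bound = 1000, gpr = ""),
    list(id = "HIGH", metabolites = c(s_e = -1, p_c = 1),
         lower_bound = 0, upper_bound = 4, gpr = "gH"),
    list(id = "LOW", metabolites = c(s_e = -1, p_c = 0.5),
         lower_bound = 0, upper_bound = 1000, gpr = "gL"),
    list(id = "DM_p_c", metabolites = c(p_c = -1),
         lower_bound = 0, upper_bound = 1000, gpr = "")
  )
  gem(mets, rxns, objective = "DM_p_c")
}

# Independent brute-force knockout oracle: evaluates GPR rules itself
# (recursive descent on the rule string is avoided by reusing only base R
# parsing of tokens) and re-solves FBA with the hit reactions closed.
brute_force_deletion <- function(model, objective = NULL) {
  genes <- model$genes
  out <- stats::setNames(numeric(length(genes)), genes)
  for (g in genes) {
    m2 <- model
    for (rid in names(m2$reactions)) {
      rule <- m2$reactions[[rid]]$gpr
      if (!nzchar(rule)) next
      # evaluate the boolean rule with gene g absent, all others present
      expr <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", rule,
                                          ignore.case = TRUE),
                   ignore.case = TRUE)
      for (gg in unique(unlist(regmatches(
        rule, gregexpr("[A-Za-z0-9_.]+", rule))))) {
        if (tolower(gg) %in% c("and", "or")) next
        expr <- gsub(paste0("\\b", gg, "\\b"),
                     if (gg == g) "FALSE" else "TRUE", expr)
      }
      if (!eval(parse(text = expr))) {
        m2$reactions[[rid]]$lower_bound <- 0
        m2$reactions[[rid]]$upper_bound <- 0
      }
    }
    res <- fba(m2, objective)
    out[[g]] <- if (res$status == "optimal") res$objective_value else 0
  }
  out
}

# Breadth-first-search distance oracle on a unit-weight adjacency built by
# an independent double loop over reactions.
bfs_distance_oracle <- function(model, ids, excluded = character()) {
  keep <- setdiff(model$metabolites$id, excluded)
  adj <- stats::setNames(vector("list", length(keep)), keep)
  for (r in model$reactions) {
    mets <- intersect(names(r$metabolites), keep)
    for (x in mets) adj[[x]] <- union(adj[[x]], setdiff(mets, x))
  }
  d <- matrix(Inf, length(ids), length(ids), dimnames = list(ids, ids))
  for (src in ids) {
    dist <- stats::setNames(rep(Inf, length(keep)), keep)
    dist[src] <- 0
    queue <- src
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          queue <- c(queue, v)
        }
      }
    }
    d[src, ] <- dist[ids]
  }
  d
}

# Toy setup for GA experiments: `n` parallel 2-step pathways, candidates =
# all cytosolic metabolites, essentiality planted from a 2-terminal BOF.
ga_toy <- function(n_pathways = 4, seed = 7) {
  model <- make_toy_model(toy_spec(n_pathways = n_pathways,
                                   pathway_length = 2, seed = seed))
  planted <- biomass_composition(c(m12_c = -1, m32_c = -1))
  ess <- make_essentiality(model, planted)
  subset <- grep("_c$", metabolite_ids(model), value = TRUE)
  list(model = model, planted = planted, essentiality = ess,
       subset = subset)
}

# Exhaustive enumeration of all bit patterns over a candidate subset;
# returns the best achievable fitness under the lexicographic comparator.
enumerate_best <- function(model, subset, essentiality,
                           base_composition = NULL) {
  L <- length(subset)
  best <- c(mcc = -Inf, size = Inf)
  for (k in 0:(2^L - 1)) {
    bits <- as.integer(intToBits(k)[1:L])
    f <- evaluate_individual(model, bits, subset, essentiality,
                             base_composition = base_composition)
    if (f[["mcc"]] > best[["mcc"]] ||
        (f[["mcc"]] == best[["mcc"]] && f[["size"]] < best[["size"]])) {
      best <- f
    }
  }
  best
}
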