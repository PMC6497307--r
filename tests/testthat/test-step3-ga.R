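# MCC, feature selection, individual evaluation and the genetic algorithm.

test_that("mcc handles agreement, disagreement and the derived confusion
           table", {
  expect_equal(mcc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(mcc(c(1, 0, 1), c(0, 1, 0)), -1)
  # TP=2 FP=1 FN=1 TN=4: (2*4 - 1*1)/sqrt(3*3*5*5) = 7/15
  p <- c(1, 1, 1, 0, 0, 0, 0, 0)
  o <- c(1, 1, 0, 1, 0, 0, 0, 0)
  expect_equal(mcc(p, o), 7 / 15)
  expect_error(mcc(c(1, 0), c(1)), "lengths")
})

test_that("mcc equals the Pearson correlation of the binary vectors and is
           0 on degenerate tables", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    p <- sample(0:1, n, replace = TRUE)
    o <- sample(0:1, n, replace = TRUE)
    r <- suppressWarnings(stats::cor(p, o))
    expect_equal(mcc(p, o), if (is.na(r)) 0 else r, tolerance = 1e-12)
  }
  expect_equal(mcc(c(0, 0, 0), c(1, 0, 1)), 0)  # no positive predictions
})

test_that("mcc is symmetric under simultaneous class relabeling", {
  set.seed(8)
  for (i in 1:20) {
    p <- sample(0:1, 12, replace = TRUE)
    o <- sample(0:1, 12, replace = TRUE)
    expect_equal(mcc(p, o), mcc(1 - p, 1 - o), tolerance = 1e-12)
  }
})

test_that("essentiality coercion accepts E/NE, 0/1 and logical input", {
  expect_equal(as_essentiality(c(a = "E", b = "NE")),
               c(a = TRUE, b = FALSE))
  expect_equal(as_essentiality(c(a = 1, b = 0)), c(a = TRUE, b = FALSE))
  expect_warning(as_essentiality(c(a = "E", b = "E")), "one")
  expect_error(as_essentiality(c(a = "yes")), "E/NE")
})

test_that("producibility filtering removes orphans and keeps reachable
           pathway intermediates", {
  m <- make_toy_model(toy_spec(n_pathways = 2, pathway_length = 3, seed = 3))
  # orphan: declared but produced by nothing
  m$metabolites <- rbind(m$metabolites,
                         data.frame(id = "orphan_c", formula = "C2H4O2",
                                    formula_weight = formula_weight("C2H4O2"),
                                    compartment = "c"))
  cands <- c(grep("^m", metabolite_ids(m), value = TRUE), "orphan_c")
  kept <- producibility_filter(m, cands)
  expect_false("orphan_c" %in% kept)
  expect_setequal(kept, grep("^m", metabolite_ids(m), value = TRUE))
  expect_error(producibility_filter(m, "ghost_c"), "not in model")
})

test_that("the per-metabolite screen equals a brute-force knockout oracle
           and thresholds at mean + 1 SD", {
  toy <- ga_toy()
  scr <- metabolite_mcc_screen(toy$model, toy$subset, toy$essentiality)
  # oracle: per candidate, independent deletion simulation + cor-as-mcc
  shared <- intersect(toy$model$genes, names(toy$essentiality))
  for (cand in toy$subset) {
    growth <- brute_force_deletion(
      toy$model, biomass_composition(stats::setNames(-1, cand)))[shared]
    pred <- growth < GROWTH_ZERO_TOL
    r <- suppressWarnings(stats::cor(as.numeric(pred),
                                     as.numeric(toy$essentiality[shared])))
    expect_equal(unname(scr$scores[cand]), if (is.na(r)) 0 else r,
                 tolerance = 1e-9)
  }
  expect_equal(scr$threshold,
               mean(scr$scores) + sqrt(mean((scr$scores -
                                               mean(scr$scores))^2)))
  expect_setequal(scr$selected,
                  names(scr$scores)[scr$scores > scr$threshold])
})

test_that("individual evaluation is pure, penalizes the empty individual and
           matches a scripted end-to-end oracle", {
  toy <- ga_toy()
  L <- length(toy$subset)
  bits <- integer(L); bits[match(c("m12_c", "m32_c"), toy$subset)] <- 1L
  f1 <- evaluate_individual(toy$model, bits, toy$subset, toy$essentiality)
  f2 <- evaluate_individual(toy$model, bits, toy$subset, toy$essentiality)
  expect_identical(f1, f2)
  expect_equal(unname(f1["mcc"]), 1)  # planted composition: perfect recall
  expect_equal(unname(f1["size"]), 2)
  # scripted oracle on a different individual
  bits2 <- integer(L); bits2[match("m11_c", toy$subset)] <- 1L
  obj <- biomass_composition(c(m11_c = -1))
  shared <- intersect(toy$model$genes, names(toy$essentiality))
  growth <- brute_force_deletion(toy$model, obj)[shared]
  expected <- mcc(growth < GROWTH_ZERO_TOL, toy$essentiality[shared])
  f3 <- evaluate_individual(toy$model, bits2, toy$subset, toy$essentiality)
  expect_equal(unname(f3["mcc"]), expected, tolerance = 1e-9)
  # all-zero individual: worst fitness, no exception
  expect_equal(evaluate_individual(toy$model, integer(L), toy$subset,
                                   toy$essentiality),
               c(mcc = -1, size = 0))
})

test_that("selecting a terminal metabolite makes its pathway genes
           essential in the evaluation", {
  m <- make_toy_model(toy_spec(n_pathways = 2, pathway_length = 3, seed = 1))
  ess <- make_essentiality(m, biomass_composition(c(m13_c = -1)))
  expect_true(all(ess[paste0("g00", 1:3)]))
  expect_false(any(ess[paste0("g00", 4:6)]))
})

test_that("initial populations respect the clamped size range, are seeded
           and cover the subset", {
  subset <- paste0("m", 1:30)
  cfg <- ga_config(population_size = 40, init_size = c(5, 12), seed = 99)
  pops <- initialize_populations(subset, 3, cfg)
  expect_length(pops, 3)
  sizes <- unlist(lapply(pops, vapply, sum, numeric(1)))
  expect_true(all(sizes >= 5 & sizes <= 12))
  # clamping: range wider than the subset
  cfg2 <- ga_config(population_size = 10, init_size = c(60, 100), seed = 1)
  pops2 <- initialize_populations(paste0("x", 1:8), 1, cfg2)
  expect_true(all(vapply(pops2[[1]], sum, numeric(1)) == 8))
  # reproducibility
  expect_identical(initialize_populations(subset, 2, cfg),
                   initialize_populations(subset, 2, cfg))
  # coverage: every metabolite appears somewhere in a modest population
  coverage <- Reduce(`+`, pops[[1]])
  expect_true(all(coverage >= 1))
  expect_error(initialize_populations(character(), 1, cfg), "empty")
})

test_that("zero-generation evolution returns the best of the initial
           population and an empty logbook", {
  toy <- ga_toy()
  cfg <- ga_config(population_size = 12, generations = 0,
                   init_size = c(1, 4), seed = 5)
  pop <- initialize_populations(toy$subset, 1, cfg)[[1]]
  res <- evolve(toy$model, pop, toy$subset, toy$essentiality, cfg)
  expect_equal(nrow(res$logbook), 0)
  fits <- t(vapply(pop, function(b)
    evaluate_individual(toy$model, b, toy$subset, toy$essentiality),
    c(mcc = 0, size = 0)))
  best_mcc <- max(fits[, "mcc"])
  best_size <- min(fits[fits[, "mcc"] == best_mcc, "size"])
  expect_equal(unname(res$hof$fitness[1, "mcc"]), best_mcc)
  expect_equal(unname(res$hof$fitness[1, "size"]), best_size)
})

test_that("the hall of fame is bounded, deduplicated and ordered by the
           comparator", {
  cfg <- ga_config(hof_capacity = 3)
  h <- hall_of_fame(3)
  pop <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, 0L), c(0L, 0L))
  fit <- rbind(c(0.5, 1), c(0.5, 1), c(0.9, 2), c(0.5, 1), c(0.1, 0))
  colnames(fit) <- c("mcc", "size")
  h <- hof_update(h, pop, fit, cfg)
  expect_lte(length(h$bits), 3)
  expect_equal(unname(h$fitness[1, "mcc"]), 0.9)
  # duplicate bits stored once
  keys <- vapply(h$bits, paste, character(1), collapse = "")
  expect_equal(anyDuplicated(keys), 0L)
  # ties on mcc broken by smaller size
  fit2 <- rbind(c(0.9, 5), c(0.9, 1))
  colnames(fit2) <- c("mcc", "size")
  h2 <- hof_update(hall_of_fame(5), list(c(1L, 1L, 1L), c(1L, 0L, 0L)),
                   fit2, cfg)
  expect_equal(unname(h2$fitness[1, "size"]), 1)
})

test_that("evolution with the same seed is bit-reproducible", {
  toy <- ga_toy()
  cfg <- ga_config(population_size = 10, generations = 5,
                   init_size = c(1, 4), seed = 17)
  pop <- initialize_populations(toy$subset, 1, cfg)[[1]]
  r1 <- evolve(toy$model, pop, toy$subset, toy$essentiality, cfg)
  r2 <- evolve(toy$model, pop, toy$subset, toy$essentiality, cfg)
  expect_identical(r1$hof$bits, r2$hof$bits)
  expect_identical(r1$logbook, r2$logbook)
})

test_that("sharded evolutions merge to the serial multi-evolution result", {
  toy <- ga_toy()
  cfg <- ga_config(population_size = 8, generations = 3,
                   init_size = c(1, 4), seed = 23)
  serial <- run_evolutions(toy$model, toy$subset, toy$essentiality,
                           n_evolutions = 3, config = cfg)
  shards <- lapply(1:3, function(i)
    run_evolutions(toy$model, toy$subset, toy$essentiality,
                   n_evolutions = 3, config = cfg, evolution_index = i))
  for (i in 1:3) {
    expect_identical(shards[[i]]$hofs[[1]]$bits, serial$hofs[[i]]$bits)
  }
})

test_that("without a size penalty individual sizes drift upward; with the
           default penalty they stay near the optimum", {
  toy <- ga_toy()
  base <- ga_config(population_size = 16, generations = 12,
                    init_size = c(1, 3), seed = 3)
  no_pen <- base; no_pen$w_size <- 0
  pop <- initialize_populations(toy$subset, 1, base)[[1]]
  r_pen <- evolve(toy$model, pop, toy$subset, toy$essentiality, base)
  r_no <- evolve(toy$model, pop, toy$subset, toy$essentiality, no_pen)
  # same top MCC, but the penalized run keeps the archive lean
  expect_gte(mean(r_no$logbook$size_mean),
             mean(r_pen$logbook$size_mean))
  expect_lte(r_pen$hof$fitness[1, "size"], r_no$hof$fitness[1, "size"])
})
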