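# Pooling halls of fame, frequency selection, network-distance clustering
# and the automated final selection.

# hand-made hall with explicit members
hand_hof <- function(bits, mcc, size, capacity = 100) {
  h <- hall_of_fame(capacity)
  fit <- cbind(mcc = mcc, size = size)
  hof_update(h, bits, fit, ga_config())
}

test_that("significant-metabolite frequencies match a manual tally", {
  subset <- c("A", "B", "C", "D")
  # ten distinct individuals (the hall stores unique bit patterns)
  bits <- list(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L), c(1L, 0L, 0L, 0L),
               c(0L, 1L, 0L, 0L), c(1L, 1L, 1L, 0L),
               c(0L, 0L, 0L, 1L), c(1L, 0L, 0L, 1L), c(0L, 1L, 1L, 0L),
               c(0L, 0L, 1L, 0L), c(1L, 1L, 1L, 1L))
  h <- hand_hof(bits, mcc = seq(1, 0.1, by = -0.1), size = rep(1, 10))
  # top 50% by fitness = first five individuals (mcc 1.0 .. 0.6)
  freqs <- select_significant(list(h), subset, best_fraction = 0.5)
  all_f <- attr(freqs, "all_frequencies")
  expect_equal(unname(all_f[c("A", "B", "C", "D")]),
               c(4 / 5, 3 / 5, 2 / 5, 0))
  # mean over support = (0.8 + 0.6 + 0.4)/3 = 0.6; strictly above: A only
  expect_equal(names(freqs), "A")
})

test_that("a uniform pool returns every member metabolite at frequency 1", {
  subset <- c("A", "B", "C")
  bits <- rep(list(c(1L, 1L, 0L)), 6)
  h <- hand_hof(bits, mcc = rep(0.9, 6), size = rep(2, 6))
  freqs <- select_significant(list(h), subset, best_fraction = 0.5)
  expect_setequal(names(freqs), c("A", "B"))
  expect_true(all(freqs == 1))
})

test_that("frequencies are invariant to hall ordering and support grows
           with best_fraction", {
  subset <- c("A", "B", "C")
  set.seed(12)
  bits <- replicate(12, as.integer(stats::runif(3) < 0.5),
                    simplify = FALSE)
  bits <- Filter(function(b) sum(b) > 0, bits)
  # fitness is a pure function of the bits, as in a real evaluation
  mccs <- vapply(bits, function(b) sum(b * c(0.11, 0.29, 0.43)),
                 numeric(1))
  h1 <- hand_hof(bits, mccs, vapply(bits, sum, numeric(1)))
  perm <- sample(length(bits))
  h2 <- hand_hof(bits[perm], mccs[perm],
                 vapply(bits[perm], sum, numeric(1)))
  f1 <- select_significant(list(h1), subset, best_fraction = 0.4)
  f2 <- select_significant(list(h2), subset, best_fraction = 0.4)
  expect_equal(attr(f1, "all_frequencies"), attr(f2, "all_frequencies"))
  # growing the kept fraction never shrinks the support
  s1 <- names(which(attr(f1, "all_frequencies") > 0))
  f3 <- select_significant(list(h1), subset, best_fraction = 0.9)
  s3 <- names(which(attr(f3, "all_frequencies") > 0))
  expect_true(all(s1 %in% s3))
})

test_that("network distances follow chains, use the unreachable sentinel
           and match the BFS oracle", {
  m <- make_toy_model(toy_spec(n_pathways = 2, pathway_length = 3, seed = 2))
  ids <- c("m11_c", "m12_c", "m13_c", "m21_c")
  d <- distance_matrix(m, ids, remove_hubs = FALSE)
  expect_equal(d["m11_c", "m13_c"], 2)
  oracle <- bfs_distance_oracle(m, ids)
  # pathways are connected through the shared biomass reaction? no:
  # pathway 2 only reaches pathway 1 via exchange metabolites if shared.
  sentinel <- max(oracle[is.finite(oracle)]) + 1
  oracle[is.infinite(oracle)] <- sentinel
  expect_equal(d, oracle)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("hub removal honors the Step 2 degree threshold", {
  m <- make_energy_model()
  # atp/adp/pi/h2o/h are the busiest species; measuring between glc_e and
  # glc_c must not route through removed hubs when they are above the
  # threshold
  deg <- degree_table(m)
  thr <- degree_threshold(deg)
  hubs <- names(deg)[deg > thr]
  d_raw <- distance_matrix(m, c("glc_e", "glc_c"), remove_hubs = FALSE)
  d_cut <- distance_matrix(m, c("glc_e", "glc_c"), remove_hubs = TRUE)
  expect_equal(d_raw["glc_e", "glc_c"], 1)
  expect_equal(d_cut["glc_e", "glc_c"], 1)  # direct edge survives
  expect_true(all(!hubs %in% c("glc_e", "glc_c")))
})

test_that("DBSCAN on a planted two-cluster matrix recovers the clusters at
           the stated radius", {
  ids <- c("a1", "a2", "a3", "b1", "b2")
  d <- matrix(20, 5, 5, dimnames = list(ids, ids))
  d[1:3, 1:3] <- 1; d[4:5, 4:5] <- 1
  diag(d) <- 0
  lab <- dbscan_precomputed(d, eps = 3, min_samples = 1)
  expect_equal(length(unique(lab)), 2)
  expect_true(all(lab[c("a1", "a2", "a3")] == lab[["a1"]]))
  expect_true(all(lab[c("b1", "b2")] == lab[["b1"]]))
  expect_false(lab[["a1"]] == lab[["b1"]])
  expect_true(all(lab > 0))  # no noise
  # saturating radius merges everything
  lab2 <- dbscan_precomputed(d, eps = 30, min_samples = 1)
  expect_equal(unname(lab2), rep(1L, 5))
  expect_error(dbscan_precomputed(d, eps = 0), "eps")
})

test_that("DBSCAN labels are invariant under point reordering up to label
           permutation, and min_samples > 1 creates noise", {
  set.seed(4)
  n <- 12
  ids <- paste0("m", 1:n)
  base <- matrix(sample(c(1, 2, 15, 18), n * n, replace = TRUE), n, n)
  d <- pmax(base, t(base)); diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  lab <- dbscan_precomputed(d, eps = 3, min_samples = 1)
  perm <- sample(n)
  lab_p <- dbscan_precomputed(d[perm, perm], eps = 3, min_samples = 1)
  # same partition: co-membership matrices agree
  same <- outer(lab, lab, "==")
  same_p <- outer(lab_p[ids], lab_p[ids], "==")
  expect_equal(unname(same), unname(same_p))
  # an isolated point becomes noise once min_samples exceeds its
  # neighborhood
  iso <- matrix(50, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  iso[1:3, 1:3] <- 1; diag(iso) <- 0
  lab3 <- dbscan_precomputed(iso, eps = 3, min_samples = 2)
  expect_equal(unname(lab3[4]), 0L)
  expect_true(all(lab3[1:3] > 0))
})

test_that("clusters are ranked by summed member frequency and the report is
           internally consistent", {
  ids <- c("a1", "a2", "b1", "b2", "b3")
  d <- matrix(20, 5, 5, dimnames = list(ids, ids))
  d[1:2, 1:2] <- 1; d[3:5, 3:5] <- 1; diag(d) <- 0
  freqs <- c(a1 = 0.9, a2 = 0.8, b1 = 0.5, b2 = 0.4, b3 = 0.3)
  rep <- cluster_end_goals(d, freqs, eps = 3, min_samples = 1)
  expect_equal(nrow(rep$clusters), 2)
  # cluster frequencies: {a} = 1.7, {b} = 1.2
  expect_equal(rep$clusters$frequency, c(1.7, 1.2))
  expect_equal(rep$clusters$n_members, c(2, 3))
  expect_equal(sort(unname(rep$labels)), sort(c(1L, 1L, 2L, 2L, 2L)))
  expect_error(cluster_end_goals(d, freqs[1:3], eps = 3), "frequency")
})

test_that("final selection emits the highest-frequency member per cluster,
           ties broken lexicographically", {
  ids <- c("a1", "a2", "b1", "b2")
  d <- matrix(20, 4, 4, dimnames = list(ids, ids))
  d[1:2, 1:2] <- 1; d[3:4, 3:4] <- 1; diag(d) <- 0
  freqs <- c(a1 = 0.9, a2 = 0.2, b1 = 0.6, b2 = 0.6)
  rep <- cluster_end_goals(d, freqs, eps = 3)
  # cluster frequencies: {b} = 1.2 outranks {a} = 1.1; within {b} the tie
  # at 0.6 breaks lexicographically
  expect_equal(final_selection(rep), c("b1", "a1"))
  # singleton cluster yields its only member
  d1 <- matrix(0, 1, 1, dimnames = list("solo", "solo"))
  rep1 <- cluster_end_goals(d1, c(solo = 1), eps = 3)
  expect_equal(final_selection(rep1), "solo")
})

test_that("the eps sweep matches direct clustering and cluster counts fall
           beyond the saturation point", {
  set.seed(9)
  n <- 10
  ids <- paste0("p", 1:n)
  base <- matrix(sample(1:12, n * n, replace = TRUE), n, n)
  d <- pmax(base, t(base)); diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  sweep <- eps_guidance(d, min_samples = 1, eps_grid = 1:12)
  for (k in seq_len(nrow(sweep))) {
    lab <- dbscan_precomputed(d, sweep$eps[k], 1)
    expect_equal(sweep$n_clusters[k], length(unique(lab[lab > 0])))
  }
  # counts are non-increasing from the first eps where everything clusters
  sat <- which(sweep$n_noise == 0)[1]
  expect_true(all(diff(sweep$n_clusters[sat:nrow(sweep)]) <= 0))
  # min_samples <= 1 and > 1 trace different curves
  sweep2 <- eps_guidance(d, min_samples = 3, eps_grid = 1:12)
  expect_false(identical(sweep$n_clusters, sweep2$n_clusters))
})

test_that("step3 coefficients are unit consumption by default or an even
           mass split of the residual fraction", {
  expect_equal(unclass(step3_coefficients(c("x_c", "y_c"))),
               c(x_c = -1, y_c = -1))
  m <- make_monomer_model(c("x_c", "y_c"), c(100, 400))
  comp <- step3_coefficients(c("x_c", "y_c"), m, residual_wf = 0.1)
  expect_equal(composition_mass(comp, m), 0.1, tolerance = 1e-12)
})
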