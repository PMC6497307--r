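# Macromolecule coefficient calculators and maintenance costs.

mono_model <- function(ids, weights) make_monomer_model(ids, weights)

test_that("equal frequencies and equal masses give the uniform closed-form
           coefficient", {
  m <- mono_model(unname(DNA_MONOMERS), rep(500, 4))
  genome <- c(chr = paste(rep("ACGT", 25), collapse = ""))
  comp <- dna_coefficients(genome, 0.05, m)
  # wf/MW * 1000 / 4 species = 0.025 mmol/gDW each, consumed
  expect_equal(unname(unclass(comp)[unname(DNA_MONOMERS)]),
               rep(-0.025, 4), tolerance = 1e-12)
})

test_that("forward-strand counts reproduce the spreadsheet oracle", {
  m <- mono_model(c("datp_c", "dgtp_c"), c(400, 600))
  comp <- dna_coefficients(c(g = "AAAG"), 0.05, m,
                           monomer_map = c(A = "datp_c", G = "dgtp_c"),
                           both_strands = FALSE)
  # f_A = 3/4, f_G = 1/4; mean MW = .75*400 + .25*600 = 450
  # c_A = 1000 * .05 * .75 / 450 ; c_G = 1000 * .05 * .25 / 450
  expect_equal(unname(unclass(comp)["datp_c"]), -0.0833333333,
               tolerance = 1e-7)
  expect_equal(unname(unclass(comp)["dgtp_c"]), -0.0277777778,
               tolerance = 1e-7)
})

test_that("both-strand counting pairs A with T and C with G", {
  m <- mono_model(unname(DNA_MONOMERS), c(400, 450, 500, 550))
  comp <- dna_coefficients(c(g = "AAAA"), 0.02, m)  # + reverse complement
  # both strands of AAAA hold 4 A and 4 T, nothing else
  expect_setequal(names(comp), c("datp_c", "dttp_c"))
  expect_equal(unclass(comp)[["datp_c"]] == unclass(comp)[["dttp_c"]], TRUE)
})

test_that("dna coefficients depend only on counts, not sequence order", {
  m <- mono_model(unname(DNA_MONOMERS), c(420, 480, 510, 530))
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
             collapse = "")
  shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(unclass(dna_coefficients(c(a = s), 0.031, m)),
               unclass(dna_coefficients(c(a = shuffled), 0.031, m)))
})

test_that("excess invalid characters are an input error, few are tolerated", {
  m <- mono_model(unname(DNA_MONOMERS), rep(500, 4))
  expect_error(dna_coefficients(c(g = "ACGTNNNNNN"), 0.05, m), "tolerance")
  expect_silent(dna_coefficients(c(g = paste0(strrep("ACGT", 100), "N")),
                                 0.05, m))
})

test_that("abundance weighting reproduces the hand-weighted oracle and its
           invariances", {
  m <- mono_model(c("atp_c", "ctp_c"), c(500, 480))
  seqs <- c(t1 = "AAAA", t2 = "CCCC")
  comp <- weighted_monomer_coefficients(seqs, c(t1 = 2, t2 = 1), 0.1, m,
                                        monomer_map = c(A = "atp_c",
                                                        C = "ctp_c"))
  # f_A = 2*4 / (2*4 + 1*4) = 2/3 ; mean MW = (2*500 + 480)/3
  f_a <- 2 / 3
  denom <- f_a * 500 + (1 - f_a) * 480
  expect_equal(unname(unclass(comp)["atp_c"]), -1000 * 0.1 * f_a / denom,
               tolerance = 1e-12)
  # uniform rescaling of abundances changes nothing
  comp_k <- weighted_monomer_coefficients(seqs, c(t1 = 20, t2 = 10), 0.1, m,
                                          monomer_map = c(A = "atp_c",
                                                          C = "ctp_c"))
  expect_equal(unclass(comp_k), unclass(comp), tolerance = 1e-12)
  # single sequence reduces to its own unweighted composition
  single <- weighted_monomer_coefficients(c(t1 = "AACC"), c(t1 = 5), 0.1, m,
                                          monomer_map = c(A = "atp_c",
                                                          C = "ctp_c"))
  even <- weighted_monomer_coefficients(c(t1 = "AACC"), c(t1 = 1), 0.1, m,
                                        monomer_map = c(A = "atp_c",
                                                        C = "ctp_c"))
  expect_equal(unclass(single), unclass(even), tolerance = 1e-12)
})

test_that("sequence/abundance identifier mismatches warn or error
           appropriately", {
  m <- mono_model(c("atp_c", "ctp_c"), c(500, 480))
  map <- c(A = "atp_c", C = "ctp_c")
  expect_warning(
    weighted_monomer_coefficients(c(t1 = "AC"), c(t1 = 1, tX = 2), 0.1, m,
                                  monomer_map = map),
    "dropped")
  expect_error(
    weighted_monomer_coefficients(c(t1 = "AC"), c(zz = 1), 0.1, m,
                                  monomer_map = map),
    "overlap")
})

test_that("lipid coefficients follow the closed formula, including the
           default R-chain mass", {
  m <- mono_model(c("lipidA_c", "lipidB_c"), c(800, NA))
  m$metabolites$formula <- c(NA, "C5H9RO2")
  # single lipid: c = 1000 * 0.02 / 800
  comp1 <- lipid_coefficients(c(LA = "lipidA_c"), c(LA = 3), 0.02, m)
  expect_equal(unname(unclass(comp1)), -0.025, tolerance = 1e-12)
  # two lipids 1:1 with MW 700 and 900: each c = 1000*0.02*0.5/800
  m2 <- mono_model(c("l1_c", "l2_c"), c(700, 900))
  comp2 <- lipid_coefficients(c(a = "l1_c", b = "l2_c"),
                              c(a = 1, b = 1), 0.02, m2)
  expect_equal(unname(unclass(comp2)[c("l1_c", "l2_c")]),
               c(-0.0125, -0.0125), tolerance = 1e-12)
  # R-containing formula resolves with the shipped default and says so
  expect_message(
    lipid_coefficients(c(LB = "lipidB_c"), c(LB = 1), 0.02, m,
                       default_r_mass = 100),
    "R-chain")
  expect_error(lipid_coefficients(c(LB = "lipidB_c"), c(LX = 1), 0.02, m),
               "mapping")
})

test_that("every category conserves its weight fraction mass", {
  for (seed in 1:5) {
    set.seed(seed)
    ids <- c(unname(DNA_MONOMERS), "l1_c", "l2_c")
    m <- mono_model(ids, c(runif(4, 300, 600), runif(2, 600, 900)))
    wf <- runif(1, 0.01, 0.6)
    genome <- c(g = paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                          collapse = ""))
    dna <- dna_coefficients(genome, wf, m)
    expect_equal(composition_mass(dna, m), wf, tolerance = 1e-9)
    lip <- lipid_coefficients(c(x = "l1_c", y = "l2_c"),
                              c(x = runif(1), y = runif(1)), wf, m)
    expect_equal(composition_mass(lip, m), wf, tolerance = 1e-9)
  }
})

test_that("two conditions give the exact two-point maintenance line", {
  em <- make_energy_model()
  gd <- make_growth_data(em, gam = 50, ngam = 5, growth_rates = c(0.5, 1))
  res <- maintenance_costs(em, gd, "ATPM")
  expect_equal(res$gam, 50, tolerance = 1e-6)
  expect_equal(res$ngam, 5, tolerance = 1e-6)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  # the planted line passes through (0.5, 30) and (1.0, 55)
  expect_equal(res$atp_flux$atp_flux, c(30, 55), tolerance = 1e-6)
})

test_that("planted maintenance costs are recovered exactly from noiseless
           conditions, independent of condition order", {
  em <- make_energy_model()
  gd <- make_growth_data(em, gam = 40, ngam = 3,
                         growth_rates = c(0.2, 0.4, 0.6, 0.8, 1.0))
  res <- maintenance_costs(em, gd, "ATPM")
  expect_equal(res$gam, 40, tolerance = 1e-6)
  expect_equal(res$ngam, 3, tolerance = 1e-6)
  shuffled <- gd[c(3, 1, 5, 2, 4), ]
  res2 <- maintenance_costs(em, shuffled, "ATPM")
  expect_equal(res2$gam, res$gam, tolerance = 1e-9)
  expect_equal(res2$ngam, res$ngam, tolerance = 1e-9)
})

test_that("degenerate maintenance inputs are rejected with clear errors", {
  em <- make_energy_model()
  gd <- make_growth_data(em, gam = 40, ngam = 3, growth_rates = c(0.5, 1))
  expect_error(maintenance_costs(em, gd[1, ], "ATPM"), "two conditions")
  gd2 <- gd; gd2$growth_rate <- c(0.5, 0.5)
  expect_error(maintenance_costs(em, gd2, "ATPM"), "singular|identical")
  gd3 <- gd; gd3$EX_glc_e <- c(-0.01, -0.01)
  expect_error(maintenance_costs(em, gd3, "ATPM"), "infeasible")
})

test_that("assemble_step1 merges categories, adds GAM terms and keeps the
           mass audit per category", {
  ids <- c(unname(DNA_MONOMERS), "atp_c", "ctp_c", "gtp_c", "utp_c",
           "h2o_c", "adp_c", "pi_c", "h_c")
  m <- mono_model(ids, c(rep(490, 4), rep(510, 4), 18, 430, 98, 1))
  genome <- c(g = strrep("ACGT", 30))
  dna <- dna_coefficients(genome, 0.05, m)
  rna <- weighted_monomer_coefficients(
    c(t1 = "ACGU"), c(t1 = 1), 0.2, m,
    monomer_map = RNA_MONOMERS)
  maint <- list(gam = 12.5)
  full <- assemble_step1(dna = dna, rna = rna, maintenance = maint)
  expect_true(all(c("datp_c", "utp_c", "h2o_c", "adp_c") %in% names(full)))
  # GAM terms: consumed atp/h2o each -gam on top of monomer demand
  expect_equal(unname(full["h2o_c"]), -12.5)
  expect_equal(unname(full["adp_c"]), 12.5)
  expect_equal(unname(full["atp_c"] - rna["atp_c"]), -12.5)
  # category mass audit survives the merge
  expect_equal(composition_mass(dna, m), 0.05, tolerance = 1e-9)
  expect_equal(composition_mass(rna, m), 0.2, tolerance = 1e-9)
  # conflicting signs on a shared id abort
  a <- biomass_composition(c(x_c = -1))
  b <- biomass_composition(c(x_c = 2))
  expect_error(merge_compositions(a, b), "conflicting")
})

test_that("weight fraction validation accepts partial sets and flags
           over-unity totals", {
  wf <- weight_fractions(dna = 0.031, rna = 0.205, protein = 0.55,
                         lipid = 0.091, soluble_pool = 0.05)
  expect_true(validate_weight_fractions(wf)$ok)
  expect_warning(
    validate_weight_fractions(weight_fractions(dna = 0.6, protein = 0.6)),
    "sum")
  expect_error(weight_fractions(dna = 1.2), "\\[0, 1\\]")
})
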