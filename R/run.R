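# Workflow wiring: a validated run configuration, per-step drivers that
# write their outputs plus a manifest, and a YAML front end used by the
# thin command-line wrapper shipped in inst/scripts/bofkit.

#' Read a run configuration
#'
#' A single YAML file with per-step sections (`model`, `step1`, `step2`,
#' `step3`, `evaluate`, `output_dir`, `seed`). Values given as function
#' arguments to [run_step()] override the file.
#'
#' @param path YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

.require_fields <- function(config, fields, where) {
  miss <- fields[!vapply(fields, function(f) !is.null(config[[f]]),
                         logical(1))]
  if (length(miss)) {
    stop("config section '", where, "' is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

.write_manifest <- function(dir, step, inputs, params, seed, outputs) {
  manifest <- list(
    tool = "bofkit", version = as.character(utils::packageVersion("bofkit")),
    step = step, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, inputs = inputs, parameters = params, outputs = outputs)
  jsonlite::write_json(manifest, file.path(dir, paste0(step, ".manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

#' Run one workflow step
#'
#' Drives the exported functions for one step of the workflow and writes
#' its outputs (plus a JSON manifest recording inputs, parameters and
#' seed) into `config$output_dir`. Steps: `step1-dna`, `step1-rna`,
#' `step1-protein`, `step1-lipid`, `step1-maintenance`, `step2`,
#' `step3-init`, `step3-evolve`, `step3-cluster`, `evaluate`. The steps
#' can be run sequentially or independently; `step3-evolve` accepts an
#' `evolution_index` so shards can be distributed by an external
#' scheduler and merged afterwards.
#'
#' @param step Step name (see above).
#' @param config Named list (see [read_run_config()]); must contain
#'   `model` (path) and `output_dir`, plus the section for the requested
#'   step.
#' @return Invisibly, a list of output paths.
#' @export
run_step <- function(step = c("step1-dna", "step1-rna", "step1-protein",
                              "step1-lipid", "step1-maintenance", "step2",
                              "step3-init", "step3-evolve", "step3-cluster",
                              "evaluate"),
                     config) {
  step <- match.arg(step)
  .require_fields(config, c("model", "output_dir"), "top level")
  if (!file.exists(config$model)) {
    stop("model file does not exist: ", config$model, call. = FALSE)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  model <- read_gem(config$model)
  out <- config$output_dir
  seed <- config$seed %||% 42L
  outputs <- list()

  comp_out <- function(comp, name) {
    p <- file.path(out, paste0(name, ".csv"))
    write_composition(comp, p)
    p
  }

  if (step == "step1-dna") {
    s <- config$step1
    .require_fields(s, c("genome_fasta", "dna_wf"), "step1")
    genome <- read_sequences(s$genome_fasta, "dna")
    comp <- dna_coefficients(genome, s$dna_wf, model,
                             both_strands = s$both_strands %||% TRUE)
    outputs$composition <- comp_out(comp, "step1_dna")
  } else if (step %in% c("step1-rna", "step1-protein")) {
    s <- config$step1
    kind <- sub("step1-", "", step)
    fa <- s[[paste0(kind, "_fasta")]]
    ab <- s[[paste0(kind, "_abundance")]]
    wfv <- s[[paste0(kind, "_wf")]]
    if (is.null(fa) || is.null(ab) || is.null(wfv)) {
      stop("config section 'step1' needs ", kind, "_fasta, ", kind,
           "_abundance and ", kind, "_wf", call. = FALSE)
    }
    seqs <- read_sequences(fa, if (kind == "rna") "rna" else "protein")
    comp <- weighted_monomer_coefficients(
      seqs, read_abundance(ab), wfv, model,
      monomer_map = if (kind == "rna") RNA_MONOMERS else PROTEIN_MONOMERS)
    outputs$composition <- comp_out(comp, paste0("step1_", kind))
  } else if (step == "step1-lipid") {
    s <- config$step1
    .require_fields(s, c("lipid_mapping", "lipid_abundance", "lipid_wf"),
                    "step1")
    comp <- lipid_coefficients(
      read_lipid_mapping(s$lipid_mapping),
      read_abundance(s$lipid_abundance), s$lipid_wf, model,
      default_r_mass = s$default_r_mass %||% 100)
    outputs$composition <- comp_out(comp, "step1_lipid")
  } else if (step == "step1-maintenance") {
    s <- config$step1
    .require_fields(s, c("growth_data", "atp_reaction"), "step1")
    res <- maintenance_costs(model, read_maintenance(s$growth_data),
                             s$atp_reaction)
    p <- file.path(out, "step1_maintenance.json")
    jsonlite::write_json(res[c("gam", "ngam", "r_squared")], p,
                         auto_unbox = TRUE, digits = NA)
    outputs$maintenance <- p
  } else if (step == "step2") {
    s <- config$step2 %||% list()
    step1 <- if (!is.null(s$step1_composition)) {
      read_composition(s$step1_composition)
    } else NULL
    res <- step2_pool(model, step1,
                      soluble_wf = s$soluble_wf %||% 0.05,
                      ions = if (!is.null(s$ion_list))
                        universal_ions(s$ion_list) else universal_ions())
    merged <- merge_compositions(step1 %||% biomass_composition(),
                                 res$composition)
    outputs$composition <- comp_out(merged, "step2_bof")
    p <- file.path(out, "step2_report.json")
    jsonlite::write_json(list(coenzymes = res$coenzymes, ions = res$ions,
                              degree_threshold = res$threshold),
                         p, auto_unbox = TRUE, digits = NA)
    outputs$report <- p
  } else if (step == "step3-init") {
    s <- config$step3
    .require_fields(s, c("essentiality"), "step3")
    ess <- read_essentiality(s$essentiality)
    exclude <- if (!is.null(s$step2_composition)) {
      names(read_composition(s$step2_composition))
    } else character()
    cand <- setdiff(model$metabolites$id, exclude)
    cand <- producibility_filter(model, cand)
    screen <- metabolite_mcc_screen(model, cand, ess)
    p <- file.path(out, "step3_subset.json")
    jsonlite::write_json(list(subset = screen$selected,
                              scores = as.list(screen$scores),
                              threshold = screen$threshold),
                         p, auto_unbox = TRUE, digits = NA)
    outputs$subset <- p
  } else if (step == "step3-evolve") {
    s <- config$step3
    .require_fields(s, c("essentiality", "subset"), "step3")
    ess <- read_essentiality(s$essentiality)
    subset <- unlist(jsonlite::read_json(s$subset,
                                         simplifyVector = TRUE)$subset)
    cfg <- ga_config(
      population_size = s$population_size %||% 100,
      generations = s$generations %||% 50,
      seed = seed)
    base <- if (!is.null(s$step2_composition)) {
      read_composition(s$step2_composition)
    } else NULL
    res <- run_evolutions(model, subset, ess,
                          n_evolutions = s$n_evolutions %||% 1,
                          config = cfg, base_composition = base,
                          evolution_index = s$evolution_index)
    p <- file.path(out, paste0("step3_hof",
                               if (!is.null(s$evolution_index))
                                 paste0("_", s$evolution_index) else "",
                               ".json"))
    write_hofs(res$hofs, subset, p)
    outputs$hof <- p
  } else if (step == "step3-cluster") {
    s <- config$step3
    .require_fields(s, c("hof_files"), "step3")
    loaded <- lapply(unlist(s$hof_files), read_hofs)
    subset <- attr(loaded[[1]], "subset")
    hofs <- do.call(c, loaded)
    freqs <- select_significant(hofs, subset,
                                best_fraction = s$best_fraction %||% 0.2)
    d <- distance_matrix(model, names(freqs))
    rep <- cluster_end_goals(d, freqs, eps = s$eps %||% 8,
                             min_samples = s$min_samples %||% 1)
    sel <- final_selection(rep)
    p1 <- file.path(out, "step3_clusters.csv")
    utils::write.csv(data.frame(metabolite = rep$metabolites,
                                cluster = rep$labels,
                                frequency = rep$frequencies),
                     p1, row.names = FALSE)
    p2 <- file.path(out, "step3_distance_matrix.csv")
    utils::write.csv(as.data.frame(rep$distance_matrix), p2)
    p3 <- file.path(out, "step3_selection.csv")
    write_composition(step3_coefficients(sel), p3)
    outputs <- c(outputs, list(clusters = p1, distances = p2,
                               selection = p3))
  } else if (step == "evaluate") {
    s <- config$evaluate
    .require_fields(s, c("reference", "candidates"), "evaluate")
    ref <- read_composition(s$reference)
    cands <- lapply(unlist(s$candidates), read_composition)
    names(cands) <- names(s$candidates) %||%
      basename(unlist(s$candidates))
    ess <- if (!is.null(s$essentiality)) read_essentiality(s$essentiality)
    med <- if (!is.null(s$medium)) read_medium(s$medium)
    cmp <- compare_bofs(model, ref, cands, essentiality = ess,
                        medium_bounds = med)
    p <- file.path(out, "evaluation.csv")
    utils::write.csv(cmp, p, row.names = FALSE)
    outputs$evaluation <- p
  }

  .write_manifest(out, step,
                  inputs = list(model = config$model),
                  params = config[[sub("-.*$", "", step)]] %||% list(),
                  seed = seed, outputs = outputs)
  invisible(outputs)
}

#' Serialize halls of fame
#'
#' JSON form: the metabolite subset plus each hall's members as bitstrings
#' with their `(mcc, size)` fitness.
#'
#' @param hofs List of [hall_of_fame()] objects.
#' @param subset Candidate metabolite ids the bits index.
#' @param path Output path.
#' @return `path` (write) / list of halls with attribute `subset` (read).
#' @export
write_hofs <- function(hofs, subset, path) {
  body <- list(
    subset = subset,
    hofs = lapply(hofs, function(h) {
      list(capacity = h$capacity,
           bits = vapply(h$bits, paste, character(1), collapse = ""),
           mcc = as.numeric(h$fitness[, "mcc"]),
           size = as.numeric(h$fitness[, "size"]))
    }))
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hofs
#' @export
read_hofs <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  hofs <- lapply(x$hofs, function(hh) {
    h <- hall_of_fame(hh$capacity)
    h$bits <- lapply(strsplit(unlist(hh$bits), ""), as.integer)
    h$fitness <- cbind(mcc = as.numeric(unlist(hh$mcc)),
                       size = as.numeric(unlist(hh$size)))
    h
  })
  attr(hofs, "subset") <- unlist(x$subset)
  hofs
}
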