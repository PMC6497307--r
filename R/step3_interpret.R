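# Step 3 (interpretation): pool the halls of fame of multiple evolutions,
# select significant metabolites by frequency of apparition, cluster them
# by shortest-path network distance into metabolic end goals, and emit an
# automated final metabolite selection.

#' Significant metabolites from pooled halls of fame
#'
#' Pools the members of every hall of fame, keeps the `best_fraction`
#' (default 20%) best individuals by the fitness comparator, computes each
#' metabolite's frequency of apparition among the kept individuals, and
#' returns the metabolites whose frequency is strictly above the mean
#' frequency (mean taken over the metabolites that appear at all).
#'
#' @param hofs List of [hall_of_fame()] objects from [run_evolutions()].
#' @param subset Candidate metabolite ids the bits index.
#' @param best_fraction Fraction of pooled individuals to keep, in (0, 1].
#' @param config A [ga_config()] (supplies the comparator).
#' @return Named numeric vector of frequencies (the selected metabolites),
#'   plus attributes `all_frequencies` and `n_kept`.
#' @export
select_significant <- function(hofs, subset, best_fraction = 0.2,
                               config = ga_config()) {
  if (inherits(hofs, "hall_of_fame")) hofs <- list(hofs)
  bits <- do.call(c, lapply(hofs, `[[`, "bits"))
  fit <- do.call(rbind, lapply(hofs, `[[`, "fitness"))
  if (!length(bits)) stop("no pooled individuals", call. = FALSE)
  stopifnot(best_fraction > 0, best_fraction <= 1)
  keys <- .fitness_keys(fit, config)
  ord <- order(keys[, 1], keys[, 2], decreasing = TRUE)
  n_keep <- max(1L, ceiling(best_fraction * length(bits)))
  kept <- bits[ord[seq_len(n_keep)]]
  counts <- Reduce(`+`, kept)
  freq <- stats::setNames(counts / n_keep, subset)
  support <- freq[freq > 0]
  # strictly above the mean; when the distribution is flat (every observed
  # metabolite equally frequent) nothing is distinguishable and the whole
  # support is returned
  sel <- if (.pop_sd(support) == 0) support else
    support[support > mean(support)]
  sel <- sel[order(-sel, names(sel))]
  attr(sel, "all_frequencies") <- freq
  attr(sel, "n_kept") <- n_keep
  sel
}

#' Network distance matrix between metabolites
#'
#' Builds the metabolite co-occurrence graph with highly connected
#' metabolites removed — those above the Step 2 degree threshold (mean +
#' one population SD) computed on the full model — and measures
#' shortest-path lengths (one reaction = one distance unit) between the
#' requested metabolites, which are never themselves removed. Removing
#' hubs can disconnect metabolites from the rest of the network; such
#' unreachable pairs are assigned the maximum finite distance observed
#' plus one, keeping them strictly farther than any connected pair.
#'
#' @param model A [gem()].
#' @param metabolites Ids to measure between.
#' @param remove_hubs Remove metabolites above the degree threshold
#'   (default `TRUE`).
#' @return Symmetric numeric matrix with zero diagonal (units: reactions).
#' @export
distance_matrix <- function(model, metabolites, remove_hubs = TRUE) {
  miss <- setdiff(metabolites, model$metabolites$id)
  if (length(miss)) {
    stop("metabolite(s) not in model: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  excluded <- character()
  if (remove_hubs) {
    deg <- degree_table(model)
    thr <- degree_threshold(deg)
    excluded <- setdiff(names(deg)[deg > thr], metabolites)
  }
  g <- metabolite_graph(model, excluded = excluded)
  d <- graph_distances(g, metabolites)
  if (any(is.infinite(d))) {
    # sentinel: strictly farther than any reachable pair; when no pair is
    # reachable at all, fall back to one more than the graph order (an
    # upper bound on any shortest path)
    sentinel <- if (any(is.finite(d) & d > 0)) {
      max(d[is.finite(d)]) + 1
    } else {
      igraph::vcount(g) + 1
    }
    d[is.infinite(d)] <- sentinel
  }
  d
}

#' DBSCAN over a precomputed distance matrix
#'
#' Density-based clustering: a point is a core point when its
#' eps-neighborhood (itself included) holds at least `min_samples` points;
#' clusters are grown from core points through density-reachability;
#' non-core points within eps of a cluster join it as border points;
#' everything else is noise. With `min_samples <= 1` every point is core
#' and clusters are exactly the connected components of the eps-graph.
#'
#' @param dist Square symmetric distance matrix with dimnames.
#' @param eps Neighborhood radius (> 0).
#' @param min_samples Minimum neighborhood size for a core point.
#' @return Integer vector of cluster labels (named by point), `0` = noise.
#' @export
dbscan_precomputed <- function(dist, eps, min_samples = 1) {
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  n <- nrow(dist)
  stopifnot(ncol(dist) == n)
  nb <- lapply(seq_len(n), function(i) which(dist[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- setdiff(nb[[i]], i)
    while (length(frontier)) {
      j <- frontier[1]
      frontier <- frontier[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) frontier <- union(frontier, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  stats::setNames(labels, rownames(dist))
}

#' Cluster significant metabolites into metabolic end goals
#'
#' Runs DBSCAN on the precomputed network-distance matrix and ranks the
#' clusters by cluster frequency — the sum of the member metabolites'
#' frequencies of apparition. Neighboring metabolites in the network are
#' interpreted as alternative representatives of one metabolic end goal.
#'
#' @param dist Distance matrix from [distance_matrix()].
#' @param freqs Named frequencies from [select_significant()] covering the
#'   matrix's metabolites.
#' @param eps DBSCAN radius in reaction units (default 8).
#' @param min_samples DBSCAN core threshold (default 1: every point
#'   clusters, no noise).
#' @return A `cluster_report`: `metabolites`, `distance_matrix`, `labels`
#'   (0 = noise), `clusters` (data frame ranked by frequency), `noise`,
#'   `eps`, `min_samples`.
#' @export
cluster_end_goals <- function(dist, freqs, eps = 8, min_samples = 1) {
  ids <- rownames(dist)
  miss <- setdiff(ids, names(freqs))
  if (length(miss)) {
    stop("no frequency for metabolite(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  labels <- dbscan_precomputed(dist, eps, min_samples)
  freqs <- freqs[ids]
  cl_ids <- sort(unique(labels[labels > 0]))
  clusters <- do.call(rbind, lapply(cl_ids, function(k) {
    members <- ids[labels == k]
    data.frame(cluster = k,
               frequency = sum(freqs[members]),
               n_members = length(members),
               members = paste(members, collapse = ";"))
  }))
  if (!is.null(clusters)) {
    clusters <- clusters[order(-clusters$frequency, clusters$cluster), ]
    rownames(clusters) <- NULL
  } else {
    clusters <- data.frame(cluster = integer(), frequency = numeric(),
                           n_members = integer(), members = character())
  }
  structure(list(metabolites = ids, distance_matrix = dist,
                 labels = labels, frequencies = freqs, clusters = clusters,
                 noise = ids[labels == 0], eps = eps,
                 min_samples = min_samples),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("<cluster_report>", nrow(x$clusters), "cluster(s),",
      length(x$noise), "noise point(s); eps =", x$eps,
      ", min_samples =", x$min_samples, "\n")
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Automated final metabolite selection
#'
#' One representative per metabolic end goal: the member with the highest
#' frequency of apparition (ties broken lexicographically by id), with
#' clusters ordered by cluster frequency.
#'
#' @param report A `cluster_report` from [cluster_end_goals()] with at
#'   least one cluster.
#' @return Character vector of metabolite ids.
#' @export
final_selection <- function(report) {
  if (!nrow(report$clusters)) {
    stop("no clusters in report", call. = FALSE)
  }
  vapply(seq_len(nrow(report$clusters)), function(i) {
    members <- strsplit(report$clusters$members[i], ";")[[1]]
    f <- report$frequencies[members]
    members <- members[order(-f, members)]
    members[1]
  }, character(1))
}

#' Cluster-count sweep to guide the choice of eps
#'
#' Re-clusters a fixed distance matrix over a grid of eps values and
#' reports the resulting cluster (and noise) counts. A practical eps
#' yields a number of clusters around half the number of metabolites;
#' cluster counts generally fall as eps grows and neighborhoods merge.
#'
#' @param dist Distance matrix.
#' @param min_samples DBSCAN core threshold.
#' @param eps_grid Numeric grid (default 1 to the matrix maximum).
#' @return Data frame: `eps`, `n_clusters`, `n_noise`.
#' @export
eps_guidance <- function(dist, min_samples = 1, eps_grid = NULL) {
  eps_grid <- eps_grid %||% seq(1, max(1, ceiling(max(dist))), by = 1)
  do.call(rbind, lapply(eps_grid, function(e) {
    lab <- dbscan_precomputed(dist, e, min_samples)
    data.frame(eps = e, n_clusters = length(unique(lab[lab > 0])),
               n_noise = sum(lab == 0))
  }))
}

#' Biomass coefficients for the final Step 3 selection
#'
#' Converts the selected metabolite ids to consumed-species coefficients:
#' unit consumption (-1 mmol/gDW each) by default, or — when
#' `residual_wf` is given — the residual dry-mass fraction
#' `1 - sum(other fractions)` split evenly by mass, as in the soluble
#' pool.
#'
#' @param ids Selected metabolite ids.
#' @param model A [gem()] (needed for the mass-split mode).
#' @param residual_wf Optional residual weight fraction in (0, 1].
#' @return A [biomass_composition()].
#' @export
step3_coefficients <- function(ids, model = NULL, residual_wf = NULL) {
  if (!length(ids)) stop("empty selection", call. = FALSE)
  if (is.null(residual_wf)) {
    biomass_composition(stats::setNames(rep(-1, length(ids)), ids))
  } else {
    stopifnot(!is.null(model))
    pool_coefficients(ids, residual_wf, model)
  }
}
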