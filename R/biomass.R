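#' Biomass composition
#'
#' The central artifact of the package: a map from metabolite identifier to
#' stoichiometric coefficient in mmol/gDW. Consumed species carry negative
#' coefficients, produced species positive ones, following the sign
#' convention of the biomass pseudo-reaction. Zero coefficients are not
#' allowed (a zero entry is an absent entry).
#'
#' @param coefficients Named numeric vector (names are metabolite ids).
#' @return Object of class `biomass_composition` (a named numeric vector).
#' @export
biomass_composition <- function(coefficients = numeric()) {
  coefficients <- unlist(coefficients)
  if (length(coefficients)) {
    if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
      stop("coefficients must be named by metabolite id", call. = FALSE)
    }
    if (anyDuplicated(names(coefficients))) {
      stop("duplicate metabolite ids in composition", call. = FALSE)
    }
    if (any(coefficients == 0)) {
      stop("zero-valued coefficients are not allowed", call. = FALSE)
    }
  }
  structure(coefficients, class = "biomass_composition")
}

#' @export
print.biomass_composition <- function(x, ...) {
  cat("<biomass_composition>", length(x), "metabolites",
      sprintf("(%d consumed, %d produced)\n", sum(x < 0), sum(x > 0)))
  if (length(x)) {
    df <- data.frame(metabolite = names(x), coefficient = as.numeric(x))
    print(utils::head(df[order(df$coefficient), ], 10), row.names = FALSE)
    if (length(x) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' Merge biomass compositions
#'
#' Takes the union of several compositions. A metabolite occurring in more
#' than one input must carry coefficients of the same sign; the merged
#' coefficient is their sum (consumption demands add). Opposite signs for
#' the same species indicate a bookkeeping error and abort.
#'
#' @param ... `biomass_composition` objects (or named numeric vectors).
#' @return A merged [biomass_composition()].
#' @export
merge_compositions <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, length, integer(1)) > 0]
  if (!length(parts)) return(biomass_composition())
  all_ids <- unique(unlist(lapply(parts, names)))
  out <- stats::setNames(numeric(length(all_ids)), all_ids)
  sign_seen <- stats::setNames(numeric(length(all_ids)), all_ids)
  for (p in parts) {
    s <- sign(unclass(p))
    conflict <- names(p)[sign_seen[names(p)] * s < 0]
    if (length(conflict)) {
      stop("conflicting coefficient signs on merge for: ",
           paste(conflict, collapse = ", "), call. = FALSE)
    }
    sign_seen[names(p)] <- s
    out[names(p)] <- out[names(p)] + unclass(p)
  }
  biomass_composition(out[out != 0])
}

#' Mass accounted for by a composition
#'
#' Audits the dry-weight bookkeeping: `sum(|c_i| * MW_i) / 1000` over the
#' composition's metabolites, in g/gDW. For a composition produced from a
#' macromolecular weight fraction this equals that fraction exactly.
#'
#' @param composition A [biomass_composition()].
#' @param model A [gem()] supplying formula weights.
#' @param r_mass Optional `"R"` pseudo-element mass for lipid species.
#' @return Mass fraction in g/gDW.
#' @export
composition_mass <- function(composition, model, r_mass = NA_real_) {
  if (!length(composition)) return(0)
  w <- metabolite_weights(model, names(composition), r_mass = r_mass)
  sum(abs(unclass(composition)) * w) / 1000
}

#' Read / write a biomass composition
#'
#' Two on-disk forms are supported: two-column delimited text
#' (`metabolite_id, coefficient`, comma- or tab-separated, header optional)
#' and a JSON object mapping id to coefficient.
#'
#' @param path File path.
#' @param composition A [biomass_composition()].
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   `NULL`.
#' @return `read_composition` returns a [biomass_composition()];
#'   `write_composition` returns `path` invisibly.
#' @export
read_composition <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path, TRUE)) "json" else "csv"
  if (format == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(biomass_composition(unlist(x)))
  }
  df <- utils::read.table(path, header = FALSE, sep = "", fill = TRUE,
                          stringsAsFactors = FALSE,
                          col.names = c("id", "coef"))
  # auto-detect delimiter and an optional header row
  if (ncol(df) == 1 || all(is.na(df$coef))) {
    df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("id", "coef"))
  }
  if (is.na(suppressWarnings(as.numeric(df$coef[1])))) df <- df[-1, ]
  biomass_composition(stats::setNames(as.numeric(df$coef), df$id))
}

#' @rdname read_composition
#' @export
write_composition <- function(composition, path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path, TRUE)) "json" else "csv"
  if (format == "json") {
    jsonlite::write_json(as.list(unclass(composition)), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(
      data.frame(metabolite_id = names(composition),
                 coefficient = as.numeric(composition)),
      path, sep = ",", row.names = FALSE, col.names = TRUE, quote = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
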