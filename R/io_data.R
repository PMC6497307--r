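# Readers for the delimited-text data formats the workflow consumes.

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @param type `"dna"`, `"rna"` or `"protein"` (selects the Biostrings
#'   reader and alphabet validation).
#' @return Named character vector of sequences (first whitespace token of
#'   each header is the identifier).
#' @export
read_sequences <- function(path, type = c("dna", "rna", "protein")) {
  type <- match.arg(type)
  x <- switch(type,
              dna = Biostrings::readDNAStringSet(path),
              rna = Biostrings::readRNAStringSet(path),
              protein = Biostrings::readAAStringSet(path))
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Read a two-column abundance table
#'
#' Delimited text (comma or tab, header optional): identifier, relative
#' abundance on a linear scale.
#'
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_abundance <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          stringsAsFactors = FALSE,
                          col.names = c("id", "abundance"))
  if (is.na(suppressWarnings(as.numeric(df$abundance[1])))) df <- df[-1, ]
  stats::setNames(as.numeric(df$abundance), df$id)
}

#' Read a maintenance (growth) data table
#'
#' CSV with header: `condition`, `growth_rate`, then one column per
#' exchange reaction id carrying the measured flux.
#'
#' @param path File path.
#' @return Data frame in the format [maintenance_costs()] expects.
#' @export
read_maintenance <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        check.names = FALSE)
  stopifnot(all(c("condition", "growth_rate") %in% names(df)))
  df
}

#' Read a lipid name-to-identifier mapping
#'
#' Two-column delimited text: lipid common name, model metabolite id.
#'
#' @param path File path.
#' @return Named character vector (names are lipid common names).
#' @export
read_lipid_mapping <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          stringsAsFactors = FALSE,
                          col.names = c("name", "id"))
  if (tolower(df$name[1]) %in% c("name", "lipid", "lipid_name")) {
    df <- df[-1, ]
  }
  stats::setNames(df$id, df$name)
}
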