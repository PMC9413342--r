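#' Read a feature-by-sample table into an omic_matrix
#'
#' Reads a delimited text table whose first column holds feature IDs and
#' whose header row holds sample IDs. The delimiter is auto-detected between
#' tab and comma (tab wins when both occur in the header line, matching the
#' usual TSV-with-commas-in-names case).
#'
#' @param path path to a TSV or CSV file.
#' @param kind `"gene"` or `"metabolite"`.
#' @param phenotype_map named character vector (or two-column data frame:
#'   sample, phenotype) mapping every sample in the file to its level.
#' @param reference reference phenotype level, see [omic_matrix()].
#' @return a validated [omic_matrix].
#' @seealso [read_phenotype_map()] to load the map from a file.
#' @export
read_feature_matrix <- function(path, kind, phenotype_map, reference = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  ids <- as.character(tab[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature IDs in ", path, ": ", paste(dup, collapse = ", "))
  samp <- colnames(tab)[-1L]
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s))
    stop("duplicate sample IDs in header of ", path, ": ",
         paste(dup_s, collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric values in ", path)
  rownames(vals) <- ids

  if (is.data.frame(phenotype_map))
    phenotype_map <- stats::setNames(as.character(phenotype_map[[2L]]),
                                     as.character(phenotype_map[[1L]]))
  unknown <- setdiff(samp, names(phenotype_map))
  if (length(unknown))
    stop("samples absent from phenotype map: ", paste(unknown, collapse = ", "))
  omic_matrix(vals, kind = kind, phenotype = phenotype_map[samp],
              reference = reference)
}

#' Read a two-column sample-to-phenotype map
#'
#' @param path TSV/CSV file with columns sample ID and phenotype level
#'   (header optional; detected by whether the second field of the first
#'   line repeats later as a level).
#' @return named character vector, sample -> level.
#' @export
read_phenotype_map <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = FALSE, sep = sep,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("phenotype map needs two columns")
  # drop a header line if its second field never recurs as a level
  if (nrow(tab) > 1L && !tab[1L, 2L] %in% tab[-1L, 2L])
    tab <- tab[-1L, , drop = FALSE]
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Write an omic_matrix (or any matrix) as TSV
#'
#' First column `feature_id`, then one column per sample.
#'
#' @param x matrix with dimnames.
#' @param path output path.
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data frame as TSV
#'
#' Plain `write.table` wrapper used for all tabular artifacts (differential
#' tables, topology tables, pair lists, enrichment results).
#'
#' @param df a data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read annotation sets in GMT format
#'
#' Standard gene-matrix-transposed format: one set per line, tab-separated
#' fields `name`, `description`, then member feature IDs.
#'
#' @param path GMT file.
#' @return named list of character vectors (the `description` field is kept
#'   as an attribute `description`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT lines with fewer than 3 fields: ", paste(bad, collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Write annotation sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}
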