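#' Read and write the package's tabular formats
#'
#' Plain-TSV readers/writers for the expression matrix (genes as rows,
#' header = sample ids), the sample table, regulon tables, STRING-style
#' edge lists, tissue TPM matrices and ground-truth JSON. All writers are
#' deterministic (input order preserved) so repeated runs produce
#' byte-identical files.
#'
#' @param expr,samples,regulons,edges,tpm,truth objects to serialize.
#' @param path file path.
#' @name netrewire-io
NULL

.write_tsv <- function(df, path, row_names = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = row_names, col.names = TRUE)
}

#' @rdname netrewire-io
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname netrewire-io
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df))
    stop("expression TSV must have a 'gene_id' column")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' @rdname netrewire-io
#' @export
write_samples_tsv <- function(samples, path) .write_tsv(samples, path)

#' @rdname netrewire-io
#' @export
read_samples_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample TSV missing columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname netrewire-io
#' @export
write_regulons_tsv <- function(regulons, path) .write_tsv(regulons, path)

#' @rdname netrewire-io
#' @export
write_string_tsv <- function(edges, path) .write_tsv(edges, path)

#' @rdname netrewire-io
#' @export
write_tpm_tsv <- function(tpm, path) {
  df <- data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname netrewire-io
#' @export
read_tpm_tsv <- function(path) read_expression_tsv(path)

#' Write a gene-set collection in GMT format
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional character vector of set descriptions
#'   (defaults to the set names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines of `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Lines with fewer than three fields are rejected with a warning;
#' duplicate genes within a set are dropped.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("read_gmt: empty file '", path, "'")
    return(structure(list(), descriptions = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 3L
  if (any(!ok))
    warning("read_gmt: rejected ", sum(!ok),
            " line(s) with fewer than 3 fields")
  fields <- fields[ok]
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  structure(sets,
            descriptions = vapply(fields, `[`, character(1), 2L))
}

#' @rdname netrewire-io
#' @export
write_ground_truth_json <- function(truth, path) {
  # named atomic vectors become JSON objects (names would otherwise drop)
  as_obj <- function(x) {
    if (is.list(x)) lapply(x, as_obj)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(as_obj(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}
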