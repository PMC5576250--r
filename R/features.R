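#' Feature-construction configuration
#'
#' Controls how raw evidence records are aggregated into the per-gene design
#' matrix: which data types become columns, the minimum score retained for
#' animal-model evidence (low-confidence associations below it are dropped
#' before averaging), whether indirect (ontology-propagated) associations are
#' removed, and which data types are excluded outright. `known_drug` is
#' excluded because it is essentially the outcome being predicted;
#' `literature` because it is reserved for external validation.
#'
#' @param used_data_types Ordered character vector of feature columns.
#' @param animal_model_min_score Minimum retained animal_model score, in [0,1].
#' @param drop_indirect Drop indirect associations before aggregation?
#' @param excluded_data_types Data types removed from the matrix.
#' @param animal_model_filter `"record"` applies the threshold to individual
#'   records before averaging (default); `"aggregate"` applies it to the
#'   per-gene mean afterwards, for sensitivity analysis.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(used_data_types = DEFAULT_FEATURE_TYPES,
                           animal_model_min_score = 0.4,
                           drop_indirect = TRUE,
                           excluded_data_types = c("known_drug", "literature"),
                           animal_model_filter = c("record", "aggregate")) {
  animal_model_filter <- match.arg(animal_model_filter)
  if (length(intersect(used_data_types, excluded_data_types)))
    stopf("used_data_types and excluded_data_types overlap")
  if (!is_prob(animal_model_min_score) || length(animal_model_min_score) != 1)
    stopf("animal_model_min_score must be a single value in [0,1]")
  structure(list(
    used_data_types = used_data_types,
    animal_model_min_score = animal_model_min_score,
    drop_indirect = isTRUE(drop_indirect),
    excluded_data_types = excluded_data_types,
    animal_model_filter = animal_model_filter
  ), class = "feature_config")
}

#' Read gene-disease evidence records
#'
#' Reads evidence from JSON-lines (one object per line with keys `gene`,
#' `disease`, `datatype`, `score`, `is_direct`) or TSV with the same columns.
#' Malformed lines, unknown data types and scores outside [0,1] are rejected
#' record by record and reported in a warning with line numbers / counts;
#' valid records are kept.
#'
#' @param path Input file path.
#' @param format `"jsonl"` or `"tsv"`.
#' @return Data frame of valid evidence records, with attribute `n_rejected`.
#' @export
read_evidence <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("evidence file not found: %s", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "disease", "datatype", "score", "is_direct")
    if (!all(need %in% names(df)))
      stopf("TSV evidence must have columns: %s", paste(need, collapse = ", "))
    df <- df[need]
    df$is_direct <- as.logical(df$is_direct)
    bad_lines <- integer()
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      warnf("empty evidence file: %s", path)
      out <- data.frame(gene = character(), disease = character(),
                        datatype = character(), score = numeric(),
                        is_direct = logical(), stringsAsFactors = FALSE)
      attr(out, "n_rejected") <- 0L
      return(out)
    }
    parsed <- lapply(lines, function(l)
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL))
    ok <- !vapply(parsed, is.null, logical(1)) &
      vapply(parsed, function(p)
        all(c("gene", "disease", "datatype", "score", "is_direct") %in% names(p)),
        logical(1))
    bad_lines <- which(!ok)
    df <- data.frame(
      gene = vapply(parsed[ok], function(p) as.character(p$gene), character(1)),
      disease = vapply(parsed[ok], function(p) as.character(p$disease), character(1)),
      datatype = vapply(parsed[ok], function(p) as.character(p$datatype), character(1)),
      score = vapply(parsed[ok], function(p) as.numeric(p$score), numeric(1)),
      is_direct = vapply(parsed[ok], function(p) isTRUE(p$is_direct), logical(1)),
      stringsAsFactors = FALSE
    )
  }
  bad_type <- !(df$datatype %in% OT_DATA_TYPES)
  bad_score <- !is.finite(df$score) | df$score < 0 | df$score > 1
  keep <- !bad_type & !bad_score
  n_rejected <- sum(!keep) + length(bad_lines)
  if (n_rejected > 0)
    warnf(paste0(
      "rejected %d evidence record(s): %d malformed line(s)%s, ",
      "%d unknown data type(s), %d score(s) outside [0,1]"),
      n_rejected, length(bad_lines),
      if (length(bad_lines)) sprintf(" (lines %s)",
        paste(utils::head(bad_lines, 10), collapse = ",")) else "",
      sum(bad_type), sum(bad_score & !bad_type))
  if (nrow(df) == 0) warnf("no valid evidence records in %s", path)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Build the per-gene feature matrix from evidence records
#'
#' Applies the filtering rules (indirect removal, excluded data types, the
#' animal-model confidence threshold) and then collapses each gene's evidence
#' to a single pan-disease score per data type: the mean score across the
#' diseases that retain at least one record. Gene/data-type combinations with
#' no retained evidence are encoded as 0, so the matrix has exactly one row
#' per gene and one column per used data type.
#'
#' @param records Evidence data frame as returned by [read_evidence()].
#' @param config A [feature_config()].
#' @param universe Optional character vector of gene ids; genes with no
#'   retained evidence get all-zero rows so the matrix spans the full universe.
#' @return Numeric matrix, rows = genes (rownames), columns = data types.
#' @export
build_feature_matrix <- function(records, config = feature_config(),
                                 universe = NULL) {
  stopifnot(inherits(config, "feature_config"))
  df <- records
  if (nrow(df)) {
    if (config$drop_indirect) df <- df[df$is_direct, , drop = FALSE]
    df <- df[!(df$datatype %in% config$excluded_data_types), , drop = FALSE]
    df <- df[df$datatype %in% config$used_data_types, , drop = FALSE]
    if (config$animal_model_filter == "record") {
      drop <- df$datatype == "animal_model" &
        df$score < config$animal_model_min_score
      df <- df[!drop, , drop = FALSE]
    }
  }
  genes <- sort(unique(c(df$gene, universe)))
  mat <- matrix(0, nrow = length(genes), ncol = length(config$used_data_types),
                dimnames = list(genes, config$used_data_types))
  if (nrow(df)) {
    ## mean over (gene, datatype) groups; each record is one associated disease
    means <- tapply(df$score,
                    list(factor(df$gene, levels = genes),
                         factor(df$datatype, levels = config$used_data_types)),
                    mean)
    means[is.na(means)] <- 0
    mat[] <- means[genes, config$used_data_types]
  }
  if (config$animal_model_filter == "aggregate" &&
      "animal_model" %in% colnames(mat)) {
    am <- mat[, "animal_model"]
    mat[am < config$animal_model_min_score, "animal_model"] <- 0
  }
  mat
}

#' Write / read a feature matrix as TSV
#'
#' TSV with a header row and the gene id in the first column; the round trip
#' `read_feature_matrix(write_feature_matrix(m, f))` reproduces `m` exactly.
#'
#' @param matrix Numeric matrix with gene rownames.
#' @param path File path.
#' @return `path` invisibly (write) / the matrix (read).
#' @export
write_feature_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(matrix)), collapse = "\t"), con)
  if (nrow(matrix)) {
    chr <- base::matrix(formatC(matrix, format = "g", digits = 17),
                        nrow = nrow(matrix))
    writeLines(apply(cbind(rownames(matrix), chr), 1, paste, collapse = "\t"),
               con)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene
  m
}
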