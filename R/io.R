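# Readers and writers for the pipeline's external formats: TSV expression
# matrix + sample metadata, GMT target sets, ranking TSV, results TSV.

new_drug_corpus <- function(values, samples) {
  structure(list(values = values, samples = samples), class = "drug_corpus")
}

#' @export
print.drug_corpus <- function(x, ...) {
  cat("<drug_corpus> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  batches: ", length(unique(x$samples$batch_id)),
      "; vehicles: ", sum(x$samples$is_vehicle),
      "; compounds: ",
      length(unique(x$samples$compound_id[!x$samples$is_vehicle])),
      "\n", sep = "")
  invisible(x)
}

validate_corpus <- function(values, samples) {
  if (anyDuplicated(rownames(values)) > 0) {
    stop("duplicate gene identifiers in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values)) > 0) {
    stop("duplicate sample identifiers in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id) > 0) {
    stop("duplicate sample identifiers in metadata", call. = FALSE)
  }
  missing <- setdiff(colnames(values), samples$sample_id)
  if (length(missing) > 0) {
    stop("matrix samples absent from metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(samples$sample_id, colnames(values))
  if (length(extra) > 0) {
    warning("dropping ", length(extra),
            " metadata rows without matrix columns: ",
            paste(head(extra, 5), collapse = ", "), call. = FALSE)
    samples <- samples[samples$sample_id %in% colnames(values), , drop = FALSE]
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  bad <- !samples$is_vehicle & (is.na(samples$compound_id) |
                                  samples$compound_id == "")
  if (any(bad)) {
    stop("non-vehicle samples without compound_id: ",
         paste(head(samples$sample_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  no_vehicle <- setdiff(samples$batch_id,
                        samples$batch_id[samples$is_vehicle])
  if (length(no_vehicle) > 0) {
    stop("batch without vehicle-control samples: ",
         paste(no_vehicle, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("expression matrix contains non-finite values", call. = FALSE)
  }
  new_drug_corpus(values, tibble::as_tibble(samples))
}

#' Read an expression matrix and its sample metadata
#'
#' The matrix is a TSV with gene rows and sample columns: the first column
#' holds gene identifiers and the header row holds sample identifiers.
#' Metadata is a TSV with columns `sample_id`, `compound_id`, `batch_id`,
#' `is_vehicle`.  Values are taken as log-scale intensities (so that fold
#' change against vehicle is a difference); pass `linear = TRUE` to log2 a
#' linear-scale matrix on load.
#'
#' Validation is strict: duplicate identifiers, matrix samples missing from
#' the metadata, non-numeric or missing cells, non-vehicle samples without a
#' compound, and batches without a vehicle control are all errors.  Metadata
#' rows without a matrix column are dropped with a warning.
#'
#' @param matrix_path Path to the expression TSV.
#' @param metadata_path Path to the sample-metadata TSV.
#' @param linear If `TRUE`, values are log2-transformed on load.
#' @return A `drug_corpus`: list with `values` (numeric matrix, genes x
#'   samples) and `samples` (tibble of per-sample metadata, in matrix column
#'   order).
#' @export
read_expression <- function(matrix_path, metadata_path, linear = FALSE) {
  raw <- read.delim(matrix_path, check.names = FALSE,
                    colClasses = "character", sep = "\t")
  if (ncol(raw) < 2) stop("malformed expression TSV: ", matrix_path,
                          call. = FALSE)
  gene_ids <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  values <- suppressWarnings(apply(cells, 2, as.numeric))
  if (!is.matrix(values)) values <- matrix(values, nrow = length(gene_ids))
  dimnames(values) <- list(gene_ids, colnames(cells))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing cell at gene '", gene_ids[idx[1]],
         "', sample '", colnames(values)[idx[2]], "'", call. = FALSE)
  }
  if (linear) {
    if (any(values <= 0)) stop("linear values must be positive to log2",
                               call. = FALSE)
    values <- log2(values)
  }
  meta <- read.delim(metadata_path, check.names = FALSE,
                     colClasses = "character", sep = "\t")
  need <- c("sample_id", "compound_id", "batch_id", "is_vehicle")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  meta$is_vehicle <- parse_flag(meta$is_vehicle)
  meta$compound_id[is.na(meta$compound_id)] <- ""
  validate_corpus(values, meta[, need])
}

parse_flag <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0", "no", "")] <- FALSE
  if (anyNA(out)) stop("is_vehicle values must be TRUE/FALSE (or 1/0)",
                       call. = FALSE)
  out
}

#' Write an expression corpus back to TSV
#'
#' Inverse of [read_expression()]: values with 6 significant digits, metadata
#' written exactly.
#'
#' @param corpus A `drug_corpus`.
#' @param matrix_path,metadata_path Output paths.
#' @return Invisibly, the corpus.
#' @export
write_expression <- function(corpus, matrix_path, metadata_path) {
  stopifnot(inherits(corpus, "drug_corpus"))
  v <- corpus$values
  header <- paste(c("gene_id", colnames(v)), collapse = "\t")
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], sprintf("%.6g", v[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), matrix_path)
  s <- corpus$samples
  meta_rows <- paste(s$sample_id, s$compound_id, s$batch_id,
                     ifelse(s$is_vehicle, "TRUE", "FALSE"), sep = "\t")
  writeLines(c("sample_id\tcompound_id\tbatch_id\tis_vehicle", meta_rows),
             metadata_path)
  invisible(corpus)
}

#' Read drug-target compound sets from a GMT file
#'
#' One set per line: `target_id <TAB> description <TAB> member ...`.  The
#' description field encodes the association source: `"predicted"` marks a
#' computationally predicted off-target set, anything else (conventionally
#' `"referenced"`) a curated association.  Duplicate members within a line
#' are deduplicated with a warning; a duplicated `target_id` across lines is
#' an error.
#'
#' @param path Path to the GMT file.
#' @return A tibble `target_id`, `source`, `members` (list-column of
#'   character vectors), `set_size`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids) > 0) {
    stop("duplicate target_id in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  src <- ifelse(vapply(fields, `[[`, character(1), 2) == "predicted",
                "predicted", "referenced")
  members <- lapply(fields, function(f) f[-(1:2)])
  dup <- vapply(members, anyDuplicated, integer(1)) > 0
  if (any(dup)) {
    warning("deduplicated members in target sets: ",
            paste(ids[dup], collapse = ", "), call. = FALSE)
    members <- lapply(members, unique)
  }
  tibble::tibble(
    target_id = ids,
    source = src,
    members = members,
    set_size = lengths(members)
  )
}

#' Write drug-target compound sets to GMT
#'
#' @param target_sets A tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return Invisibly, `target_sets`.
#' @export
write_gmt <- function(target_sets, path) {
  lines <- vapply(seq_len(nrow(target_sets)), function(i) {
    paste(c(target_sets$target_id[i], target_sets$source[i],
            target_sets$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(target_sets)
}

#' Write a compound ranking to TSV
#'
#' Columns `position`, `compound_id`, `query_rank`, `normalized_score`; this
#' file is the enrichment stage's input.
#'
#' @param ranking A `compound_ranking` tibble (see [rank_compounds()]).
#' @param path Output path.
#' @return Invisibly, the ranking.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "compound_ranking"))
  rows <- paste(ranking$position, ranking$compound_id, ranking$query_rank,
                sprintf("%.6g", ranking$normalized_score), sep = "\t")
  writeLines(c("position\tcompound_id\tquery_rank\tnormalized_score", rows),
             path)
  invisible(ranking)
}

#' Read a compound ranking written by [write_ranking()]
#'
#' @param path Path to the ranking TSV.
#' @return A `compound_ranking` tibble.
#' @export
read_ranking <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          position = readr::col_integer(),
                          compound_id = readr::col_character(),
                          query_rank = readr::col_integer(),
                          normalized_score = readr::col_double()
                        ))
  if (any(tb$position != seq_len(nrow(tb)))) {
    stop("ranking positions must be 1..N in order", call. = FALSE)
  }
  structure(tb, class = c("compound_ranking", class(tibble::tibble())))
}

#' Write enrichment results to TSV
#'
#' Columns `target_id`, `source`, `set_size`, `es`, `p_value`, `fdr`,
#' `direction`; rows sorted by ascending FDR, then p-value, then target id;
#' floats rendered with 6 significant digits.  Re-running on identical
#' inputs and seed produces a byte-identical file.
#'
#' @param results An `enrichment_result` tibble (see [enrich_all()]).
#' @param path Output path.
#' @return Invisibly, the (sorted) results.
#' @export
write_results <- function(results, path) {
  need <- c("target_id", "source", "set_size", "es", "p_value", "fdr",
            "direction")
  stopifnot(all(need %in% names(results)))
  results <- results[str_order(results$fdr, results$p_value,
                               results$target_id), , drop = FALSE]
  rows <- paste(results$target_id, results$source, results$set_size,
                sprintf("%.6g", results$es), sprintf("%.6g", results$p_value),
                sprintf("%.6g", results$fdr), results$direction, sep = "\t")
  writeLines(c(paste(need, collapse = "\t"), rows), path)
  invisible(results)
}

#' Read enrichment results written by [write_results()]
#'
#' @param path Path to the results TSV.
#' @return A tibble.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    target_id = readr::col_character(),
                    source = readr::col_character(),
                    set_size = readr::col_integer(),
                    es = readr::col_double(),
                    p_value = readr::col_double(),
                    fdr = readr::col_double(),
                    direction = readr::col_character()
                  ))
}
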