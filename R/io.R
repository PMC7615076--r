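#' Read a DDA intensity table
#'
#' Reads the tab-separated export produced by search-engine protein-group
#' or peptide tables: columns \code{id}, \code{n_peptides}, \code{score},
#' \code{contaminant}, \code{reverse} (and \code{protein} for the peptide
#' dialect), followed by one intensity column per sample. Column order is
#' irrelevant. Zeros and blanks are mapped to missing, following the
#' label-free-quantification convention that a zero intensity records a
#' non-detection, not a measurement.
#'
#' @param path file path.
#' @param format_dialect \code{"protein_groups"} or \code{"peptides"}
#'   (the latter requires a \code{protein} mapping column).
#' @param lectin,cohort optional metadata attached to the table.
#' @return a data.frame with attributes \code{lectin}, \code{cohort},
#'   \code{scale} (\code{"linear"}) and \code{samples}.
#' @export
read_dda_table <- function(path, format_dialect = c("peptides",
                                                    "protein_groups"),
                           lectin = NA_character_, cohort = NA_character_) {
  format_dialect <- match.arg(format_dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("id", "n_peptides", "score", "contaminant", "reverse")
  if (format_dialect == "peptides") required <- c(required[1], "protein",
                                                  required[-1])
  for (col in required)
    if (!col %in% names(x))
      stop("required column missing: '", col, "'")
  if (anyDuplicated(x$id))
    stop("duplicate feature id(s): ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  samples <- setdiff(names(x), required)
  x$n_peptides <- parse_num(x$n_peptides, "n_peptides")
  x$score <- parse_num(x$score, "score")
  x$contaminant <- parse_bool(x$contaminant, "contaminant")
  x$reverse <- parse_bool(x$reverse, "reverse")
  for (s in samples) {
    v <- parse_num(x[[s]], s, allow_blank = TRUE)
    if (any(v < 0, na.rm = TRUE))
      stop("negative intensity in column '", s, "'")
    v[!is.na(v) & v == 0] <- NA_real_
    x[[s]] <- v
  }
  x <- x[c(required, samples)]
  attr(x, "lectin") <- lectin
  attr(x, "cohort") <- cohort
  attr(x, "scale") <- "linear"
  attr(x, "samples") <- samples
  x
}

parse_num <- function(v, col, allow_blank = FALSE) {
  blank <- is.na(v) | trimws(v) == "" | v == "NA"
  out <- suppressWarnings(as.numeric(v))
  bad <- is.na(out) & !blank
  if (any(bad))
    stop("malformed numeric value(s) in column '", col, "': ",
         paste(utils::head(unique(v[bad]), 3), collapse = ", "))
  if (any(blank) && !allow_blank)
    stop("missing value(s) not allowed in column '", col, "'")
  out
}

parse_bool <- function(v, col) {
  map <- stats::setNames(
    c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    c("TRUE", "FALSE", "true", "false", "1", "0", "+", "-", ""))
  if (!all(v %in% names(map)))
    stop("malformed logical value(s) in column '", col, "'")
  unname(map[v])
}

#' Write a DDA intensity table
#'
#' Inverse of \code{\link{read_dda_table}}; missing intensities are
#' written as empty cells.
#'
#' @param table a DDA table.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_dda_table <- function(table, path) {
  out <- table
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read an MRM transition report
#'
#' Long-format comma-separated export with columns \code{protein},
#' \code{peptide}, \code{transition}, \code{sample}, \code{area}.
#'
#' @param path file path.
#' @param lectin optional lectin label.
#' @param standards optional list(ovalbumin=, sis=) naming the
#'   internal-standard peptides.
#' @return a transition table data.frame.
#' @export
read_transition_report <- function(path, lectin = NA_character_,
                                   standards = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  required <- c("protein", "peptide", "transition", "sample", "area")
  for (col in required)
    if (!col %in% names(x)) stop("required column missing: '", col, "'")
  x <- x[required]
  x$area <- parse_num(x$area, "area")
  if (any(x$area < 0, na.rm = TRUE)) stop("negative transition area")
  key <- paste(x$peptide, x$transition, x$sample, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (peptide, transition, sample) row(s)")
  attr(x, "lectin") <- lectin
  if (!is.null(standards)) attr(x, "standards") <- standards
  x
}

#' @rdname read_transition_report
#' @param table a transition table.
#' @export
write_transition_report <- function(table, path) {
  utils::write.csv(table[c("protein", "peptide", "transition", "sample",
                           "area")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write sample annotation
#'
#' CSV with columns \code{sample_id}, \code{group} (case / benign /
#' healthy), \code{cohort}, \code{batch} and optionally \code{age}.
#'
#' @param path file path.
#' @return a sample annotation data.frame.
#' @export
read_sample_metadata <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "cohort", "batch")
  for (col in required)
    if (!col %in% names(x)) stop("required column missing: '", col, "'")
  if (anyDuplicated(x$sample_id)) stop("duplicate sample_id")
  if (!all(x$group %in% c("case", "benign", "healthy")))
    stop("group must be one of case, benign, healthy")
  x
}

#' @rdname read_sample_metadata
#' @param metadata a sample annotation data.frame.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a result bundle
#'
#' Writes tab-separated tables for every stage result handed in, plus a
#' machine-readable run manifest (configuration and seed), so that a rerun
#' with identical inputs reproduces identical files. File names are fixed;
#' empty results yield header-only files.
#'
#' @param results named list; recognised elements are written as TSV
#'   (data.frames) or JSON (lists), all others are skipped with a warning.
#' @param out_dir output directory, created if absent.
#' @param config the \code{\link{analysis_config}} recorded in the
#'   manifest.
#' @return invisible character vector of files written.
#' @export
write_results <- function(results, out_dir, config = NULL) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  written <- character()
  for (nm in names(results)) {
    obj <- results[[nm]]
    if (is.data.frame(obj)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      utils::write.table(obj, f, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "")
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
    }
    written <- c(written, f)
  }
  manifest <- list(
    package = "glycomark",
    version = as.character(utils::packageVersion("glycomark")),
    config = if (!is.null(config)) unclass(config) else NULL)
  f <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(written, f))
}
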