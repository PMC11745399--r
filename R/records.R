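#' Read a raw screening export
#'
#' Reads a delimited export of deduplicated search results (one row per
#' bibliographic record) and maps its columns onto the canonical raw-record
#' fields: `title`, `abstract`, `screening1`, and optionally `screening2`,
#' `language` and `source_key`. Missing cells become empty strings; missing
#' screening labels become `"unknown"`. Row order is preserved.
#'
#' @param path Path to a CSV or TSV file with a header row. The delimiter is
#'   taken from the file extension (`.tsv`/`.tab` means tab, anything else
#'   comma) unless `delim` is given.
#' @param column_map Named character vector mapping canonical field names to
#'   column names in the file, e.g.
#'   `c(title = "Title", abstract = "Abstract", screening1 = "screening1")`.
#'   `title`, `abstract` and `screening1` are required; `screening2`,
#'   `language` and `source_key` are optional.
#' @param delim Field delimiter override.
#' @return A data frame of raw record rows with columns `title`, `abstract`,
#'   `screening1`, `screening2`, `language`, `source_key`. Screening labels
#'   are kept as normalized strings (`"included"`, `"excluded"`, `"unknown"`);
#'   see [preprocess_records()] for label enforcement.
#' @seealso [preprocess_records()]
#' @export
read_screening_table <- function(path,
                                 column_map = c(title = "title",
                                                abstract = "abstract",
                                                screening1 = "screening1"),
                                 delim = NULL) {
  if (!file.exists(path)) {
    sf_stop("screenflow_io_error", "cannot read screening table: '%s' does not exist", path)
  }
  if (is.null(delim)) {
    ext <- tolower(tools::file_ext(path))
    delim <- if (ext %in% c("tsv", "tab")) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character())

  required <- c("title", "abstract", "screening1")
  missing_req <- setdiff(required, names(column_map))
  if (length(missing_req) > 0) {
    sf_stop("screenflow_config_error",
            "column_map must map the field(s): %s", paste(missing_req, collapse = ", "))
  }
  absent <- column_map[!column_map %in% names(tab)]
  if (length(absent) > 0) {
    sf_stop("screenflow_config_error",
            "mapped column(s) not found in '%s': %s",
            path, paste(sprintf("%s (for field '%s')", absent, names(absent)), collapse = ", "))
  }

  get_col <- function(field, default = "") {
    if (field %in% names(column_map)) tab[[column_map[[field]]]] else rep(default, nrow(tab))
  }
  out <- data.frame(
    title      = get_col("title"),
    abstract   = get_col("abstract"),
    screening1 = normalize_screen_label(get_col("screening1")),
    screening2 = normalize_screen_label(get_col("screening2")),
    language   = get_col("language"),
    source_key = get_col("source_key"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# Normalize a human screening label to "included"/"excluded"/"unknown".
# Accepted spellings (case-insensitive): 1/0, true/false, included/excluded.
normalize_screen_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("1", "true", "included", "include")] <- "included"
  out[x %in% c("0", "false", "excluded", "exclude")] <- "excluded"
  out
}

#' Assemble a clean review dataset from raw rows
#'
#' Applies the first-stage preprocessing used before automated screening:
#' rows with an empty abstract are removed, exact duplicates (case-folded,
#' whitespace-normalized equality of title and abstract, first occurrence
#' kept) are removed, and records failing the language filter are removed.
#' Surviving records get a `record_text` field joining title and abstract —
#' the unit of text an automated judge reads — and a deterministic unique
#' `record_id` assigned from row order.
#'
#' @param rows Data frame of raw rows as returned by [read_screening_table()].
#' @param original_total Number of records originally identified by the
#'   review's search, before any preprocessing. This is the workload
#'   denominator used by [workload_reduction()]; it must be at least
#'   `nrow(rows)`.
#' @param review_name Label for the dataset.
#' @param record_format `"labeled"` (default) renders `record_text` as
#'   `"Title: <title> Abstract: <abstract>"`; `"plain"` joins the two fields
#'   with a single space.
#' @param language_filter `"column"` (default) keeps rows whose `language`
#'   tag is empty or English (`en`, `eng`, `english`, case-insensitive);
#'   `"none"` keeps everything. Alternatively a function taking the rows data
#'   frame and returning a logical keep-vector.
#' @return A `review_dataset`: a list with `review_name`, `records` (data
#'   frame with `record_id`, `title`, `abstract`, `record_text`,
#'   `human_screen1`, `human_screen2`), `original_total`,
#'   `preprocessed_total`, and a `dropped` count breakdown.
#' @details A row whose `screening1` label is `"unknown"` is a labelling
#'   error in the export and aborts preprocessing (condition class
#'   `screenflow_label_error`): silent guessing of the human ground truth
#'   would corrupt every downstream comparison. `screening2` may be unknown
#'   (it is optional) and becomes `NA`.
#' @export
preprocess_records <- function(rows, original_total = nrow(rows),
                               review_name = "review",
                               record_format = c("labeled", "plain"),
                               language_filter = c("column", "none")) {
  record_format <- match.arg(record_format)
  if (original_total < nrow(rows)) {
    sf_stop("screenflow_config_error",
            "original_total (%d) is smaller than the number of rows (%d)",
            original_total, nrow(rows))
  }

  rows$screening1 <- normalize_screen_label(rows$screening1)
  rows$screening2 <- normalize_screen_label(rows$screening2)
  bad <- which(rows$screening1 == "unknown")
  if (length(bad) > 0) {
    sf_stop("screenflow_label_error",
            "unrecognized screening1 label in row(s): %s (accepted: 1/0, true/false, included/excluded)",
            paste(utils::head(bad, 10), collapse = ", "))
  }

  keep_lang <- if (is.function(language_filter)) {
    language_filter(rows)
  } else if (match.arg(language_filter) == "column") {
    lang <- tolower(trimws(rows$language))
    lang == "" | lang %in% c("en", "eng", "english")
  } else {
    rep(TRUE, nrow(rows))
  }

  abstract_ok <- trimws(rows$abstract) != ""
  dup_key <- paste(normalize_text(rows$title), normalize_text(rows$abstract), sep = "\r")
  first_seen <- !duplicated(dup_key)

  keep <- keep_lang & abstract_ok & first_seen
  dropped <- c(
    empty_abstract = sum(!abstract_ok),
    duplicate      = sum(abstract_ok & !first_seen),
    language       = sum(abstract_ok & first_seen & !keep_lang)
  )

  rec <- rows[keep, , drop = FALSE]
  if (nrow(rec) == 0) {
    sf_stop("screenflow_empty_dataset", "no records survive preprocessing")
  }

  record_text <- if (record_format == "labeled") {
    paste0("Title: ", rec$title, " Abstract: ", rec$abstract)
  } else {
    paste(rec$title, rec$abstract)
  }

  records <- data.frame(
    record_id     = sprintf("rec-%05d", seq_len(nrow(rec))),
    title         = rec$title,
    abstract      = rec$abstract,
    record_text   = record_text,
    human_screen1 = rec$screening1 == "included",
    human_screen2 = ifelse(rec$screening2 == "unknown", NA, rec$screening2 == "included"),
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL

  structure(
    list(review_name = review_name,
         records = records,
         original_total = as.integer(original_total),
         preprocessed_total = nrow(records),
         dropped = dropped),
    class = "review_dataset"
  )
}

#' @export
print.review_dataset <- function(x, ...) {
  cat(sprintf("<review_dataset> %s\n", x$review_name))
  cat(sprintf("  records: %d preprocessed of %d original\n",
              x$preprocessed_total, x$original_total))
  cat(sprintf("  passed screening 1 (human): %d\n", sum(x$records$human_screen1)))
  cat(sprintf("  dropped: %s\n",
              paste(sprintf("%s=%d", names(x$dropped), x$dropped), collapse = ", ")))
  invisible(x)
}

#' Write a preprocessed dataset with a summary sidecar
#'
#' Writes the records as CSV plus a JSON sidecar with the preprocessing
#' counts (original total, preprocessed total, per-reason drop counts, and
#' the number of records passing human screening 1).
#'
#' @param dataset A `review_dataset`.
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.counts.json`.
#' @return `path`, invisibly.
#' @export
write_review_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "review_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE)
  counts <- list(
    review_name = dataset$review_name,
    original_total = dataset$original_total,
    preprocessed_total = dataset$preprocessed_total,
    passed_screening1 = sum(dataset$records$human_screen1),
    dropped = as.list(dataset$dropped)
  )
  jsonlite::write_json(counts, paste0(path, ".counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read back a dataset written by [write_review_dataset()]
#'
#' @param path CSV path written by [write_review_dataset()].
#' @return A `review_dataset`.
#' @export
read_review_dataset <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(record_id = "character", title = "character",
                                            abstract = "character", record_text = "character"))
  records$human_screen1 <- as.logical(records$human_screen1)
  records$human_screen2 <- as.logical(records$human_screen2)
  sidecar <- paste0(path, ".counts.json")
  counts <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  structure(
    list(review_name = counts$review_name %||% "review",
         records = records,
         original_total = as.integer(counts$original_total %||% nrow(records)),
         preprocessed_total = nrow(records),
         dropped = unlist(counts$dropped %||% list())),
    class = "review_dataset"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
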