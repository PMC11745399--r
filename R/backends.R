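#' Signal a rate-limit failure from a judging backend
#'
#' Backends raise this condition (class `screenflow_rate_limit`) when the
#' upstream service throttles the request; [screen_record()] retries such
#' failures with exponential backoff. Any other failure is signalled with
#' [backend_error()] and is not retried.
#'
#' @param message Failure message.
#' @export
rate_limit_error <- function(message = "rate limited") {
  stop(structure(class = c("screenflow_rate_limit", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}

#' @rdname rate_limit_error
#' @export
backend_error <- function(message = "backend failure") {
  stop(structure(class = c("screenflow_backend_error", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}

# Identify which dataset record a prompt is about. Prefers an embedded
# record-id token (synthetic corpora carry one); falls back to locating the
# record_text verbatim inside the prompt.
match_prompt_record <- function(prompt, dataset) {
  hits <- regmatches(prompt, gregexpr("rec-[0-9]{5}", prompt))[[1]]
  hits <- intersect(hits, dataset$records$record_id)
  if (length(hits) >= 1) return(hits[1])
  for (i in seq_len(nrow(dataset$records))) {
    if (grepl(dataset$records$record_text[i], prompt, fixed = TRUE)) {
      return(dataset$records$record_id[i])
    }
  }
  NA_character_
}

#' Deterministic mock judging backend
#'
#' Builds a backend for offline runs and tests: it looks up which record a
#' prompt is about and answers with a canned JSON verdict object. Verdicts
#' come from a logical matrix (rows = record ids, columns = criterion
#' keys), typically produced by [simulate_verdicts()]; with `verdicts =
#' NULL` every criterion is answered `true`. The backend is stateful only
#' where failure injection requires it, and fully deterministic otherwise.
#'
#' Failure injection mirrors the failure taxonomy of live services:
#' `fail_ids` records raise a permanent backend error, `garble_ids` return
#' text with no recoverable JSON (a parse failure downstream), and
#' `rate_limit_times` makes the first `n` calls for a record raise a
#' rate-limit error before succeeding.
#'
#' @param dataset A `review_dataset`; used to resolve prompts to records.
#' @param verdicts Logical matrix with rownames = record ids and colnames =
#'   criterion keys, or `NULL` for all-true answers.
#' @param criteria A [criteria_set()]; required when `verdicts` is `NULL`.
#' @param prose_prefix If `TRUE`, responses are prefaced with extraneous
#'   prose ("Here is the output in the requested format: ..."), exercising
#'   the parser's JSON-recovery path.
#' @param string_booleans If `TRUE`, Boolean values are rendered as the
#'   strings `"True"`/`"False"` instead of JSON Booleans.
#' @param fail_ids Record ids for which the backend raises
#'   [backend_error()].
#' @param garble_ids Record ids for which the backend returns unparseable
#'   text.
#' @param rate_limit_times Named integer vector: number of initial calls
#'   per record id that raise [rate_limit_error()] before succeeding.
#' @return A backend function: prompt text in, response text out.
#' @export
mock_backend <- function(dataset, verdicts = NULL, criteria = NULL,
                         prose_prefix = FALSE, string_booleans = FALSE,
                         fail_ids = character(), garble_ids = character(),
                         rate_limit_times = integer()) {
  stopifnot(inherits(dataset, "review_dataset"))
  if (is.null(verdicts)) {
    if (is.null(criteria)) {
      sf_stop("screenflow_config_error", "mock_backend needs verdicts or criteria")
    }
    verdicts <- matrix(TRUE, nrow = nrow(dataset$records), ncol = nrow(criteria),
                       dimnames = list(dataset$records$record_id, criteria$key))
  }
  calls_seen <- new.env(parent = emptyenv())

  function(prompt) {
    id <- match_prompt_record(prompt, dataset)
    if (is.na(id)) backend_error("mock backend could not identify the record in the prompt")
    if (id %in% names(rate_limit_times)) {
      seen <- get0(id, envir = calls_seen, ifnotfound = 0L)
      assign(id, seen + 1L, envir = calls_seen)
      if (seen < rate_limit_times[[id]]) rate_limit_error(sprintf("throttled for %s", id))
    }
    if (id %in% fail_ids) backend_error(sprintf("permanent failure for %s", id))
    if (id %in% garble_ids) return("I could not format this as requested.")

    row <- verdicts[id, , drop = TRUE]
    render_value <- function(v) {
      if (string_booleans) sprintf('"%s"', if (v) "True" else "False")
      else if (v) "true" else "false"
    }
    entries <- vapply(names(row), function(k) {
      sprintf('"%s": {"value": %s, "justification": "simulated verdict for %s"}',
              k, render_value(row[[k]]), k)
    }, character(1))
    body <- sprintf("{%s}", paste(entries, collapse = ", "))
    if (prose_prefix) paste0("Here is the output in the requested format: ", body)
    else body
  }
}
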