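#' Judge sampling configuration
#'
#' Generation settings handed to a live judging backend. Defaults are the
#' reproducibility-oriented settings used throughout this package: greedy
#' decoding (temperature 0), top-p 0.95, fixed seed 28, a 25,000-token
#' context window so differently sized models see the same input, and no
#' cap on response length so JSON outputs are never truncated mid-object.
#'
#' @param temperature Sampling temperature, `>= 0`.
#' @param top_p Nucleus-sampling mass, in `(0, 1]`.
#' @param seed Integer seed forwarded to backends that accept one.
#' @param context_window Context window in tokens.
#' @param response_length_limit Maximum response length in tokens
#'   (`Inf` = unlimited).
#' @return A `judge_config` list.
#' @export
judge_config <- function(temperature = 0.0, top_p = 0.95, seed = 28L,
                         context_window = 25000L, response_length_limit = Inf) {
  if (temperature < 0) sf_stop("screenflow_config_error", "temperature must be >= 0")
  if (!(top_p > 0 && top_p <= 1)) sf_stop("screenflow_config_error", "top_p must be in (0, 1]")
  structure(list(temperature = temperature, top_p = top_p, seed = as.integer(seed),
                 context_window = as.integer(context_window),
                 response_length_limit = response_length_limit),
            class = "judge_config")
}

#' Retry policy for transient backend failures
#'
#' Rate-limit errors are retried with exponential backoff: the delay before
#' re-attempting after attempt `a` is `base^a` seconds (2, 4, 8, 16 s for
#' the default base 2 and the up-to-5-attempts default). Any other failure
#' class is non-retriable.
#'
#' @param max_attempts Maximum attempts per record (default 5).
#' @param base Backoff base (default 2).
#' @param retriable Failure classes that trigger a retry.
#' @return A `retry_policy` with a `delay(attempt)` function.
#' @export
retry_policy <- function(max_attempts = 5L, base = 2, retriable = "rate_limit") {
  max_attempts <- as.integer(max_attempts)
  stopifnot(max_attempts >= 1L, base > 1)
  structure(list(max_attempts = max_attempts,
                 delay = function(attempt) base^attempt,
                 retriable = retriable),
            class = "retry_policy")
}

#' Build the screening prompt for one record
#'
#' Renders the prompt a judging backend receives: the record text (title
#' plus abstract) exactly once, every criterion's key and instruction in
#' display order, and an explicit directive to answer with only a JSON
#' object keyed by criterion, each entry carrying a Boolean `value` and a
#' brief `justification`.
#'
#' @param record_text The record (title and abstract) under evaluation.
#' @param criteria A [criteria_set()].
#' @param template Optional template string with `{{record}}` and
#'   `{{criteria}}` placeholders; the default template satisfies the
#'   contract above.
#' @return The prompt string.
#' @export
build_prompt <- function(record_text, criteria, template = NULL) {
  if (!inherits(criteria, "criteria_set") || nrow(criteria) == 0) {
    sf_stop("screenflow_config_error", "build_prompt needs a non-empty criteria_set")
  }
  stopifnot(is_string(record_text))
  if (is.null(template)) {
    template <- paste0(
      "You are screening scientific articles for a systematic review.\n",
      "Analyze the provided scientific article and determine, for each criterion ",
      "below, whether the article meets it.\n\n",
      "Article:\n{{record}}\n\n",
      "Criteria:\n{{criteria}}\n\n",
      "Respond with only a JSON object and no other text. The object must contain ",
      "exactly one key per criterion, using the criterion keys listed above. Each ",
      "value must be an object with a field \"value\" holding a JSON boolean ",
      "(true or false) and a field \"justification\" holding a brief justification."
    )
  }
  crit_block <- paste(sprintf("- %s: %s", criteria$key, criteria$instruction),
                      collapse = "\n")
  out <- sub("{{record}}", record_text, template, fixed = TRUE)
  sub("{{criteria}}", crit_block, out, fixed = TRUE)
}

# Locate the first balanced, parseable JSON object inside free text.
# Scans candidate '{' positions left to right; for each, walks to the
# matching close brace (string- and escape-aware) and tries to parse.
extract_json_object <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  starts <- which(chars == "{")
  for (s in starts) {
    depth <- 0L
    in_str <- FALSE
    esc <- FALSE
    for (i in s:n) {
      ch <- chars[i]
      if (esc) { esc <- FALSE; next }
      if (in_str) {
        if (ch == "\\") esc <- TRUE else if (ch == "\"") in_str <- FALSE
        next
      }
      if (ch == "\"") in_str <- TRUE
      else if (ch == "{") depth <- depth + 1L
      else if (ch == "}") {
        depth <- depth - 1L
        if (depth == 0L) {
          candidate <- substr(text, s, i)
          parsed <- tryCatch(jsonlite::fromJSON(candidate, simplifyVector = FALSE),
                             error = function(e) NULL)
          if (is.list(parsed)) return(parsed)
          break
        }
      }
    }
  }
  NULL
}

# Coerce the many spellings judges use for a Boolean to TRUE/FALSE/NA.
coerce_bool <- function(x) {
  if (is.logical(x) && length(x) == 1L && !is.na(x)) return(x)
  if (is.numeric(x) && length(x) == 1L && x %in% c(0, 1)) return(x == 1)
  if (is.character(x) && length(x) == 1L) {
    v <- tolower(trimws(x))
    if (v == "true") return(TRUE)
    if (v == "false") return(FALSE)
  }
  NA
}

#' Parse a judge response into per-criterion verdicts
#'
#' Extracts the first JSON object found in `raw_response` — tolerating
#' extraneous prose before or after it, the classic failure mode of judges
#' that preface their output with text like "Here is the output in the
#' requested format" — and normalizes it into one verdict per criterion.
#' String Booleans (`"true"`, `"True"`) are converted to logical; entries
#' may be full `{value, justification}` objects or bare Booleans. Criteria
#' absent from the response (or with an uninterpretable value) are filled
#' with the conservative default `value = FALSE`, pushing the record toward
#' exclusion and thus into the residual human workload rather than a silent
#' inclusion.
#'
#' The parser is total: for any input it either returns one verdict per
#' criterion or throws a parse error (condition class
#' `screenflow_parse_error`) when no JSON object can be recovered — never a
#' partial map.
#'
#' @param raw_response Raw response text from a backend.
#' @param criteria A [criteria_set()].
#' @return Named list (one element per criterion key, in criteria order) of
#'   verdicts, each a list with logical `value` and character
#'   `justification`.
#' @export
parse_verdicts <- function(raw_response, criteria) {
  stopifnot(inherits(criteria, "criteria_set"))
  if (!is_string(raw_response)) {
    sf_stop("screenflow_parse_error", "judge response is not a character string")
  }
  obj <- extract_json_object(raw_response)
  if (is.null(obj)) {
    sf_stop("screenflow_parse_error", "no recoverable JSON object in judge response")
  }
  obj_keys <- names(obj) %||% character()
  out <- vector("list", nrow(criteria))
  names(out) <- criteria$key
  for (k in criteria$key) {
    hit <- which(tolower(obj_keys) == tolower(k))
    if (length(hit) == 0) {
      out[[k]] <- list(value = FALSE, justification = "missing - defaulted")
      next
    }
    entry <- obj[[hit[1]]]
    if (is.list(entry)) {
      value <- coerce_bool(entry$value)
      justification <- entry$justification
    } else {
      value <- coerce_bool(entry)
      justification <- NULL
    }
    if (is.na(value)) {
      value <- FALSE
      justification <- justification %||% "uninterpretable value - defaulted"
    }
    if (!is_string(justification <- as.character(justification %||% "no justification given")[1])) {
      justification <- "no justification given"
    }
    out[[k]] <- list(value = value, justification = justification)
  }
  out
}

new_verdict_set <- function(record_id, verdicts = list(), status = "ok",
                            attempts = 1L, failure_class = NA_character_) {
  structure(list(record_id = record_id, verdicts = verdicts, status = status,
                 attempts = as.integer(attempts), failure_class = failure_class),
            class = "verdict_set")
}

#' @export
print.verdict_set <- function(x, ...) {
  cat(sprintf("<verdict_set> %s status=%s attempts=%d%s\n", x$record_id, x$status,
              x$attempts,
              if (!is.na(x$failure_class)) paste0(" failure=", x$failure_class) else ""))
  if (x$status == "ok") {
    for (k in names(x$verdicts)) {
      cat(sprintf("  %-28s %s\n", k, x$verdicts[[k]]$value))
    }
  }
  invisible(x)
}

#' Screen one record against all criteria
#'
#' Builds the prompt, calls the judging backend, and parses the response
#' into a verdict set. Rate-limit failures (condition class
#' `screenflow_rate_limit`) are retried with exponential backoff under the
#' given [retry_policy()]; any other backend failure, and unparseable
#' responses, fail immediately with the corresponding failure class. The
#' sleep function is injectable so backoff schedules are testable without
#' real delays.
#'
#' @param record_id Record identifier (carried into the verdict set).
#' @param source Either an `embedded_index` (the record text is fetched by
#'   id, guaranteeing exact retrieval) or the record text itself.
#' @param criteria A [criteria_set()].
#' @param backend Judging function: prompt text in, response text out.
#'   Backends signal transient failures with [rate_limit_error()] and
#'   permanent ones with [backend_error()].
#' @param retry A [retry_policy()].
#' @param sleep_fn Function called with the delay in seconds before each
#'   retry (default [Sys.sleep()]).
#' @param template Optional prompt template for [build_prompt()].
#' @return A `verdict_set`: `record_id`, `verdicts` (one per criterion when
#'   `status == "ok"`), `status` (`"ok"`/`"failed"`), `attempts`, and
#'   `failure_class` (`"rate_limit"`, `"parse"`, or `"other"` when failed).
#' @export
screen_record <- function(record_id, source, criteria, backend,
                          retry = retry_policy(), sleep_fn = Sys.sleep,
                          template = NULL) {
  record_text <- if (inherits(source, "embedded_index")) {
    fetch_by_id(source, record_id)
  } else {
    stopifnot(is_string(source))
    source
  }
  prompt <- build_prompt(record_text, criteria, template)

  for (attempt in seq_len(retry$max_attempts)) {
    response <- tryCatch(
      backend(prompt),
      screenflow_rate_limit = function(e) e,
      screenflow_backend_error = function(e) e,
      error = function(e) {
        structure(class = c("screenflow_backend_error", "condition"),
                  list(message = conditionMessage(e)))
      }
    )
    if (inherits(response, "screenflow_rate_limit")) {
      if (attempt < retry$max_attempts && "rate_limit" %in% retry$retriable) {
        sleep_fn(retry$delay(attempt))
        next
      }
      return(new_verdict_set(record_id, status = "failed", attempts = attempt,
                             failure_class = "rate_limit"))
    }
    if (inherits(response, "screenflow_backend_error")) {
      return(new_verdict_set(record_id, status = "failed", attempts = attempt,
                             failure_class = "other"))
    }
    verdicts <- tryCatch(parse_verdicts(response, criteria),
                         screenflow_parse_error = function(e) e)
    if (inherits(verdicts, "screenflow_parse_error")) {
      return(new_verdict_set(record_id, status = "failed", attempts = attempt,
                             failure_class = "parse"))
    }
    return(new_verdict_set(record_id, verdicts = verdicts, status = "ok",
                           attempts = attempt))
  }
}

#' Screen a whole corpus with checkpointing
#'
#' Runs [screen_record()] over every record of a dataset, in batches, and
#' maintains two mutually exclusive sets: successfully judged records and
#' records whose processing failed ("missing" records, which become
#' residual human workload). After every batch the full state is persisted
#' atomically to the checkpoint directory, so an interrupted run can be
#' resumed without re-judging records that already succeeded; previously
#' failed records are re-attempted on resume. Disjointness of the two sets
#' is validated at every checkpoint.
#'
#' Records are processed sequentially; `concurrency_limit` states the
#' maximum number of in-flight judgments the configuration permits and is
#' validated, so the run configuration is portable to asynchronous
#' backends.
#'
#' @param dataset A `review_dataset`.
#' @param criteria A [criteria_set()].
#' @param backend Judging function (see [screen_record()]).
#' @param checkpoint_dir Directory for checkpoint state, or `NULL` to
#'   disable checkpointing.
#' @param batch_size Records per batch between checkpoints (default 20).
#' @param concurrency_limit Maximum simultaneous judgments permitted
#'   (default 5; must be `>= 1`).
#' @param retry A [retry_policy()].
#' @param sleep_fn Sleep function forwarded to [screen_record()].
#' @param template Optional prompt template.
#' @return A `screen_result`: list with `succeeded` and `missing`, each a
#'   named list of `verdict_set`s keyed by record id, disjoint and jointly
#'   covering all records.
#' @export
screen_corpus <- function(dataset, criteria, backend, checkpoint_dir = NULL,
                          batch_size = 20L, concurrency_limit = 5L,
                          retry = retry_policy(), sleep_fn = Sys.sleep,
                          template = NULL) {
  stopifnot(inherits(dataset, "review_dataset"))
  if (as.integer(concurrency_limit) < 1L) {
    sf_stop("screenflow_config_error", "concurrency_limit must be >= 1")
  }
  batch_size <- max(1L, as.integer(batch_size))

  succeeded <- list()
  missing <- list()
  if (!is.null(checkpoint_dir)) {
    state <- read_checkpoint(checkpoint_dir)
    succeeded <- state$succeeded
    missing <- list()  # failed records are re-attempted on resume
  }

  ids <- dataset$records$record_id
  todo <- setdiff(ids, names(succeeded))
  texts <- stats::setNames(dataset$records$record_text, ids)

  if (length(todo) > 0) {
    batch_starts <- seq(1L, length(todo), by = batch_size)
    for (s in batch_starts) {
      batch <- todo[s:min(s + batch_size - 1L, length(todo))]
      for (id in batch) {
        vs <- screen_record(id, texts[[id]], criteria, backend,
                            retry = retry, sleep_fn = sleep_fn, template = template)
        if (vs$status == "ok") succeeded[[id]] <- vs else missing[[id]] <- vs
      }
      overlap <- intersect(names(succeeded), names(missing))
      if (length(overlap) > 0) {
        sf_stop("screenflow_state_error",
                "succeeded and missing sets overlap: %s", paste(overlap, collapse = ", "))
      }
      if (!is.null(checkpoint_dir)) {
        write_checkpoint(checkpoint_dir, succeeded, missing)
      }
    }
  }

  structure(list(succeeded = succeeded, missing = missing),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> succeeded=%d missing=%d\n",
              length(x$succeeded), length(x$missing)))
  invisible(x)
}

verdict_set_to_json <- function(vs, set) {
  jsonlite::toJSON(
    list(record_id = vs$record_id, set = set, status = vs$status,
         attempts = vs$attempts,
         failure_class = if (is.na(vs$failure_class)) NULL else vs$failure_class,
         verdicts = vs$verdicts),
    auto_unbox = TRUE, null = "null")
}

json_to_verdict_set <- function(line) {
  x <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  verdicts <- lapply(x$verdicts, function(v) {
    list(value = isTRUE(v$value), justification = as.character(v$justification))
  })
  list(set = x$set,
       vs = new_verdict_set(x$record_id, verdicts = verdicts, status = x$status,
                            attempts = x$attempts,
                            failure_class = x$failure_class %||% NA_character_))
}

write_checkpoint <- function(dir, succeeded, missing) {
  lines <- c(
    vapply(succeeded, verdict_set_to_json, character(1), set = "succeeded"),
    vapply(missing, verdict_set_to_json, character(1), set = "missing")
  )
  atomic_write(file.path(dir, "checkpoint.jsonl"), function(tmp) {
    writeLines(lines, tmp)
  })
}

read_checkpoint <- function(dir) {
  path <- file.path(dir, "checkpoint.jsonl")
  if (!file.exists(path)) return(list(succeeded = list(), missing = list()))
  lines <- readLines(path, warn = FALSE)
  succeeded <- list()
  missing <- list()
  for (ln in lines) {
    if (trimws(ln) == "") next
    parsed <- tryCatch(json_to_verdict_set(ln), error = function(e) NULL)
    if (is.null(parsed) || is.null(parsed$vs$record_id)) {
      sf_stop("screenflow_checkpoint_error",
              "corrupt checkpoint at '%s'; refusing to resume", path)
    }
    if (identical(parsed$set, "succeeded")) {
      succeeded[[parsed$vs$record_id]] <- parsed$vs
    } else {
      missing[[parsed$vs$record_id]] <- parsed$vs
    }
  }
  if (length(intersect(names(succeeded), names(missing))) > 0) {
    sf_stop("screenflow_checkpoint_error",
            "corrupt checkpoint at '%s': succeeded and missing overlap", path)
  }
  list(succeeded = succeeded, missing = missing)
}

#' Persist verdict sets as JSON lines
#'
#' One `verdict_set` per line, interchangeable between [screen_corpus()]
#' output and [simulate_verdicts()] output.
#'
#' @param result A `screen_result` (or a named list of `verdict_set`s).
#' @param path Output `.jsonl` path.
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(result, path) {
  if (inherits(result, "screen_result")) {
    lines <- c(vapply(result$succeeded, verdict_set_to_json, character(1), set = "succeeded"),
               vapply(result$missing, verdict_set_to_json, character(1), set = "missing"))
  } else {
    lines <- vapply(result, function(vs) {
      verdict_set_to_json(vs, if (vs$status == "ok") "succeeded" else "missing")
    }, character(1))
  }
  atomic_write(path, function(tmp) writeLines(lines, tmp))
}

#' Read verdict sets written by [write_verdicts()]
#'
#' @param path `.jsonl` path.
#' @return A `screen_result` with `succeeded` and `missing`.
#' @export
read_verdicts <- function(path) {
  if (!file.exists(path)) {
    sf_stop("screenflow_io_error", "verdicts file '%s' does not exist", path)
  }
  lines <- readLines(path, warn = FALSE)
  succeeded <- list()
  missing <- list()
  for (ln in lines) {
    if (trimws(ln) == "") next
    parsed <- json_to_verdict_set(ln)
    if (identical(parsed$set, "succeeded")) succeeded[[parsed$vs$record_id]] <- parsed$vs
    else missing[[parsed$vs$record_id]] <- parsed$vs
  }
  structure(list(succeeded = succeeded, missing = missing), class = "screen_result")
}
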