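#' Define a set of screening criteria
#'
#' A criteria set names the Boolean inclusion/exclusion criteria a judge
#' evaluates for every record. Each criterion has a short unique `key` and an
#' `instruction`: free text telling the judge when to answer true and when
#' false for that criterion.
#'
#' @param keys Character vector of unique, non-empty criterion keys.
#' @param instructions Character vector of non-empty instruction texts, same
#'   length as `keys`.
#' @return A `criteria_set`: a data frame with columns `key` and
#'   `instruction`, in display order.
#' @examples
#' criteria_set(c("population", "outcome"),
#'              c("Return true if the study population is adults with low back pain.",
#'                "Return true if a full economic evaluation is reported."))
#' @export
criteria_set <- function(keys, instructions) {
  keys <- as.character(keys)
  instructions <- as.character(instructions)
  if (length(keys) == 0) {
    sf_stop("screenflow_config_error", "a criteria set needs at least one criterion")
  }
  if (length(keys) != length(instructions)) {
    sf_stop("screenflow_config_error", "keys and instructions differ in length")
  }
  if (anyDuplicated(keys) || any(trimws(keys) == "")) {
    sf_stop("screenflow_config_error", "criterion keys must be unique and non-empty")
  }
  if (any(trimws(instructions) == "")) {
    sf_stop("screenflow_config_error", "criterion instructions must be non-empty")
  }
  structure(data.frame(key = keys, instruction = instructions,
                       stringsAsFactors = FALSE),
            class = c("criteria_set", "data.frame"))
}

#' Read a criteria configuration file
#'
#' Criteria configs are YAML or JSON: a top-level `criteria` list whose
#' entries have `key` and `instruction` fields (display order is file
#' order). The package ships the screening-1 criteria of three published
#' systematic reviews as examples under
#' `system.file("extdata", "criteria", package = "screenflow")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` criteria config.
#' @return A [criteria_set()].
#' @export
read_criteria <- function(path) {
  if (!file.exists(path)) {
    sf_stop("screenflow_io_error", "criteria config '%s' does not exist", path)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path) else yaml::read_yaml(path)
  entries <- raw$criteria %||% raw
  if (length(entries) == 0) {
    sf_stop("screenflow_config_error", "criteria config '%s' defines no criteria", path)
  }
  criteria_set(
    keys = vapply(entries, function(e) e$key %||% "", character(1)),
    instructions = vapply(entries, function(e) e$instruction %||% "", character(1))
  )
}

#' @export
print.criteria_set <- function(x, ...) {
  cat(sprintf("<criteria_set> %d criteria\n", nrow(x)))
  for (i in seq_len(nrow(x))) {
    instr <- x$instruction[i]
    if (nchar(instr) > 70) instr <- paste0(substr(instr, 1, 67), "...")
    cat(sprintf("  %-28s %s\n", x$key[i], instr))
  }
  invisible(x)
}
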