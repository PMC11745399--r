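#' @keywords internal
"_PACKAGE"

# Condition helpers: every user-facing failure carries a screenflow_* class so
# callers (and the CLI) can branch on the failure kind rather than on message text.
sf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "screenflow_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Round half away from zero
#'
#' Integer rounding used for workload-reduction percentages. Unlike base
#' [round()], which rounds half to even, halves move away from zero, the
#' convention under which all printed whole-percent workload figures in this
#' package are reproducible.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @examples
#' round_half_away(c(0.5, 1.5, 2.5, -0.5))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Write `lines` (or a writer function) to `path` atomically: temp file in the
# same directory, then rename. Guards checkpoint files against partial writes.
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    # rename across filesystems can fail; fall back to copy+remove
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# Case-folded, whitespace-normalized form of a string; the duplicate key.
normalize_text <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_seed_local <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}
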