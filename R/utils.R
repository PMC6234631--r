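# Internal condition helpers. Every user-facing failure is signalled with a
# classed condition so callers (and the CLI) can react without parsing text.

xs_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "xs_error", "error")))
}

xs_format_error     <- function(msg, ...) xs_abort(msg, "xs_format_error", ...)
xs_validation_error <- function(msg, ...) xs_abort(msg, "xs_validation_error", ...)
xs_schema_error     <- function(msg, ...) xs_abort(msg, "xs_schema_error", ...)
xs_load_error       <- function(msg, ...) xs_abort(msg, "xs_load_error", ...)
xs_unknown_code_error <- function(msg, ...) xs_abort(msg, "xs_unknown_code_error", ...)
xs_unmapped_label_error <- function(msg, ...) xs_abort(msg, "xs_unmapped_label_error", ...)
xs_execution_error  <- function(msg, ...) xs_abort(msg, "xs_execution_error", ...)
xs_spec_error       <- function(msg, ...) xs_abort(msg, "xs_spec_error", ...)

# Rounding used for displayed percentages: half-up (half away from zero),
# not banker's rounding, so 56.75 -> 56.8.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Strict CSV read: everything as character, empty string preserved (missing
# handling is the loader's job, not the parser's).
read_csv_chr <- function(path) {
  if (!file.exists(path)) {
    xs_format_error(sprintf("file not found: %s", path), path = path)
  }
  read.csv(path, colClasses = "character", check.names = FALSE,
           na.strings = character(0), stringsAsFactors = FALSE)
}

require_columns <- function(df, cols, what, path = NULL) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    xs_format_error(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      columns = missing, path = path)
  }
  invisible(df)
}

is_token <- function(x) is.character(x) & !is.na(x) & nzchar(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
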