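#' @importFrom rlang .data %||%
NULL

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Canonical lowercase for two-level sex coding; anything else is an error
# because the creatinine-clearance threshold cannot be resolved.
normalize_sex <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out[out %in% c("m")] <- "male"
  out[out %in% c("f")] <- "female"
  bad <- !is.na(out) & !out %in% c("male", "female")
  if (any(bad)) {
    stop("sex must be coded male/female; offending value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

parse_logical_flag <- function(x, field) {
  out <- tolower(trimws(as.character(x)))
  map <- c("true" = TRUE, "false" = FALSE, "t" = TRUE, "f" = FALSE,
           "1" = TRUE, "0" = FALSE, "yes" = TRUE, "no" = FALSE)
  res <- unname(map[out])
  bad <- is.na(res) & !is.na(out)
  if (any(bad)) {
    stop(sprintf("column %s has non-boolean value(s): %s", field,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  res
}
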