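# Internal helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Case-insensitive column lookup against an alias vector; returns the actual
# column name or NA. Header names are normalized by trimming, lowercasing and
# collapsing internal whitespace.
match_column <- function(nms, aliases) {
  norm <- function(x) gsub("\\s+", " ", trimws(tolower(x)))
  hit <- match(norm(aliases), norm(nms))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) NA_character_ else nms[hit[1]]
}

# Parse a character vector as numeric, collecting row-level failures instead
# of failing: non-missing cells that do not parse become NA and are reported.
parse_numeric_cells <- function(x, column) {
  suppressWarnings(val <- as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(val))
  errors <- if (length(bad) > 0) {
    tibble::tibble(row = bad, column = column, value = x[bad])
  } else {
    tibble::tibble(row = integer(), column = character(), value = character())
  }
  list(values = val, errors = errors)
}

is_scorable_sequence <- function(x) {
  !is.na(x) & nzchar(x) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}
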