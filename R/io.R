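#' Read and validate a cave inventory table
#'
#' Expects a comma-separated UTF-8 file with header
#' `cave_id,name,x,y,length_m,season`. Coordinates are planar meters;
#' `season` is one of `dry`, `wet`, `unknown`.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with columns `cave_id` (character), `name`
#'   (character), `x`, `y`, `length_m` (numeric), `season` (character), in
#'   file row order.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("cave_id,name,x,y,length_m,season",
#'              "C1,Eden,100,200,350,dry"), tf)
#' read_caves(tf)
#' @seealso [read_occurrences()], [read_impacts()], [write_caves()]
#' @export
read_caves <- function(path) {
  df <- .kp_read_csv(path, c("cave_id", "name", "x", "y", "length_m", "season"))
  df$cave_id <- as.character(df$cave_id)
  df$name <- as.character(df$name)
  for (col in c("x", "y", "length_m")) {
    df[[col]] <- .kp_parse_numeric(df[[col]], col)
  }
  dup <- unique(df$cave_id[duplicated(df$cave_id)])
  if (length(dup)) {
    stop("duplicate cave_id: ", paste(dup, collapse = ", "))
  }
  if (any(df$length_m <= 0)) {
    bad <- which(df$length_m <= 0)[1]
    stop(sprintf("length_m must be > 0 (row %d: %g)", bad, df$length_m[bad]))
  }
  df$season <- tolower(as.character(df$season))
  bad <- which(!df$season %in% .kp_seasons)
  if (length(bad)) {
    stop(sprintf("invalid season '%s' in row %d; allowed: %s",
                 df$season[bad[1]], bad[1], paste(.kp_seasons, collapse = ", ")))
  }
  rownames(df) <- NULL
  df
}

#' Read and validate a species occurrence table
#'
#' Expects header `cave_id,species_id,troglobiont`. The troglobiont flag
#' accepts `true`/`false`/`1`/`0` case-insensitively and must be constant per
#' species across all rows.
#'
#' @param path Path to a CSV file.
#' @param dedupe If `TRUE`, exact duplicate `(cave_id, species_id)` rows are
#'   collapsed; if `FALSE` (default) they raise an error.
#' @return A data.frame with columns `cave_id`, `species_id` (character) and
#'   `troglobiont` (logical).
#' @export
read_occurrences <- function(path, dedupe = FALSE) {
  df <- .kp_read_csv(path, c("cave_id", "species_id", "troglobiont"))
  df$cave_id <- as.character(df$cave_id)
  df$species_id <- as.character(df$species_id)
  df$troglobiont <- .kp_parse_logical(df$troglobiont, "troglobiont")
  key <- paste(df$cave_id, df$species_id, sep = "\r")
  if (anyDuplicated(key)) {
    if (dedupe) {
      df <- df[!duplicated(key), , drop = FALSE]
    } else {
      d <- df[duplicated(key), , drop = FALSE][1, ]
      stop(sprintf("duplicate occurrence (cave_id=%s, species_id=%s)",
                   d$cave_id, d$species_id))
    }
  }
  flags <- tapply(df$troglobiont, df$species_id, function(z) length(unique(z)))
  bad <- names(flags)[flags > 1]
  if (length(bad)) {
    stop("inconsistent troglobiont flag for species: ",
         paste(bad, collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Read and validate an anthropogenic impact site table
#'
#' Expects header `impact_type,x,y` with `impact_type` drawn from the closed
#' set: pasture, agriculture_forestry, mining, urbanization, paved_road.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with columns `impact_type` (character), `x`, `y`
#'   (numeric meters).
#' @export
read_impacts <- function(path) {
  df <- .kp_read_csv(path, c("impact_type", "x", "y"))
  df$impact_type <- as.character(df$impact_type)
  bad <- which(!df$impact_type %in% .kp_impact_types)
  if (length(bad)) {
    stop(sprintf("unknown impact_type '%s' in row %d; allowed values: %s",
                 df$impact_type[bad[1]], bad[1],
                 paste(.kp_impact_types, collapse = ", ")))
  }
  df$x <- .kp_parse_numeric(df$x, "x")
  df$y <- .kp_parse_numeric(df$y, "y")
  rownames(df) <- NULL
  df
}

#' Write pipeline tables as CSV
#'
#' Plain comma-separated UTF-8 with a header row and "." decimal mark, the
#' same dialect the readers expect, so that write-then-read round-trips.
#'
#' @param x Data frame to write (`caves`, `occurrences`, or `impacts`
#'   layout, or any derived table such as attributes or scores).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @rdname write_tables
#' @export
write_caves <- function(x, path) .kp_write_csv(x, path)

#' @rdname write_tables
#' @export
write_occurrences <- function(x, path) {
  x$troglobiont <- tolower(as.character(x$troglobiont))
  .kp_write_csv(x, path)
}

#' @rdname write_tables
#' @export
write_impacts <- function(x, path) .kp_write_csv(x, path)

.kp_read_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")))
  }
  df[required]
}

.kp_write_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

.kp_parse_numeric <- function(v, col) {
  out <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(out) | !is.finite(out))
  if (length(bad)) {
    stop(sprintf("non-numeric or non-finite value '%s' in column %s, row %d",
                 v[bad[1]], col, bad[1]))
  }
  out
}

.kp_parse_logical <- function(v, col) {
  z <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(z))
  out[z %in% c("true", "1")] <- TRUE
  out[z %in% c("false", "0")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad)) {
    stop(sprintf("cannot parse '%s' as boolean in column %s, row %d (use true/false/1/0)",
                 v[bad[1]], col, bad[1]))
  }
  out
}
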