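#' Phenotype table construction
#'
#' A phenotype table holds plot-level records of a multi-environment progeny
#' trial: one row per (progeny, location, block) plot, with one numeric column
#' per trait. Blocks are interpreted as nested within their location. Missing
#' trait values are allowed and stored as `NA`.
#'
#' @param df data frame with columns `progeny`, `location`, `block`, optionally
#'   `population`, plus one numeric column per trait.
#' @param traits character vector naming the trait columns.
#' @return an object of class `phenotype_table` (a data frame with a `traits`
#'   attribute).
#' @export
phenotype_table <- function(df, traits) {
  stopifnot(is.data.frame(df))
  if (length(traits) < 1L) stop("at least one trait column is required", call. = FALSE)
  need <- c("progeny", "location", "block")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(traits, names(df))
  if (length(miss)) {
    stop("trait column(s) not found: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df$progeny <- as.character(df$progeny)
  df$location <- as.character(df$location)
  df$block <- as.character(df$block)
  if (!"population" %in% names(df)) df$population <- NA_character_
  for (tr in traits) {
    if (!is.numeric(df[[tr]])) {
      suppressWarnings(conv <- as.numeric(as.character(df[[tr]])))
      bad <- which(!is.na(df[[tr]]) & df[[tr]] != "" & is.na(conv))
      if (length(bad)) {
        stop(sprintf("non-numeric value in trait column '%s' at row %d ('%s')",
                     tr, bad[1], as.character(df[[tr]][bad[1]])), call. = FALSE)
      }
      df[[tr]] <- conv
    }
  }
  df <- df[, c("progeny", "population", "location", "block", traits)]
  structure(df, traits = traits, class = c("phenotype_table", "data.frame"))
}

#' Traits stored in a phenotype table
#' @param table a `phenotype_table`.
#' @return character vector of trait column names.
#' @export
trait_names <- function(table) attr(table, "traits")

#' Read a plot-level phenotype table from delimited text
#'
#' The file dialect is delimited text (comma or tab, auto-detected from the
#' header line), UTF-8, mandatory header row, `.` decimal separator, and
#' `"NA"` or empty cells for missing values. Column names are mapped to the
#' required roles through `schema`, so arbitrary supplementary layouts can be
#' read without renaming files.
#'
#' @param path path to a delimited text file.
#' @param schema named list mapping roles to column names:
#'   `progeny`, `location`, `block`, optionally `population`, and `traits`
#'   (a character vector of trait columns, optionally named to rename them).
#'   Defaults to [default_schema()].
#' @return a [phenotype_table()] with rows in file order.
#' @export
read_phenotypes <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, na.strings = c("NA", ""),
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character", comment.char = "",
                   fileEncoding = "UTF-8")
  roles <- c("progeny", "location", "block")
  for (role in roles) {
    col <- schema[[role]]
    if (is.null(col)) stop("schema must name a column for role '", role, "'", call. = FALSE)
    if (!col %in% names(df)) {
      stop(sprintf("declared column '%s' (role %s) not present in %s", col, role, path),
           call. = FALSE)
    }
  }
  traits_in <- schema$traits
  if (is.null(traits_in) || !length(traits_in)) {
    stop("schema$traits must list at least one trait column", call. = FALSE)
  }
  miss <- setdiff(unname(traits_in), names(df))
  if (length(miss)) {
    stop("declared trait column(s) not present: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    progeny = df[[schema$progeny]],
    location = df[[schema$location]],
    block = df[[schema$block]],
    stringsAsFactors = FALSE
  )
  if (!is.null(schema$population) && schema$population %in% names(df)) {
    out$population <- df[[schema$population]]
  }
  new_names <- if (is.null(names(traits_in))) unname(traits_in) else {
    ifelse(names(traits_in) == "", unname(traits_in), names(traits_in))
  }
  for (k in seq_along(traits_in)) {
    raw <- df[[unname(traits_in)[k]]]
    suppressWarnings(conv <- as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(conv))
    if (length(bad)) {
      stop(sprintf("non-numeric trait value in column '%s', file row %d ('%s')",
                   unname(traits_in)[k], bad[1], raw[bad[1]]), call. = FALSE)
    }
    out[[new_names[k]]] <- conv
  }
  phenotype_table(out, traits = new_names)
}

#' Default column schema for [read_phenotypes()]
#'
#' @param traits character vector of trait column names (default the soybean
#'   trial traits `DM`, `SW`, `SY`).
#' @return a schema list.
#' @export
default_schema <- function(traits = c("DM", "SW", "SY")) {
  list(progeny = "progeny", population = "population",
       location = "location", block = "block", traits = traits)
}

#' Write a phenotype table as delimited text
#'
#' Round-trips losslessly with [read_phenotypes()]: missing values are written
#' as `NA`, numbers at full precision.
#'
#' @param table a `phenotype_table`.
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(table, path, sep = "\t") {
  df <- as.data.frame(table)
  for (tr in trait_names(table)) df[[tr]] <- format(df[[tr]], digits = 15, trim = TRUE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE, na = "NA",
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a phenotype table
#'
#' Checks the design structure of the trial: duplicate plots are an error;
#' the report counts progeny, locations, blocks per location, and missing
#' trait cells, and flags whether the trial is balanced (every progeny
#' observed exactly once in every location-block combination).
#'
#' @param table a `phenotype_table`.
#' @return an object of class `validation_report`: a list with `n_progeny`,
#'   `n_locations`, `n_blocks_per_location`, `n_missing_cells`,
#'   `balance_flag`, and `messages`.
#' @export
validate_table <- function(table) {
  stopifnot(inherits(table, "phenotype_table"))
  if (nrow(table) == 0L) stop("phenotype table is empty", call. = FALSE)
  key <- paste(table$progeny, table$location, table$block, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    stop("duplicate (progeny, location, block) plot(s): ",
         paste(head(gsub("\r", "/", dup), 5L), collapse = ", "), call. = FALSE)
  }
  traits <- trait_names(table)
  progeny <- sort(unique(table$progeny))
  locations <- sort(unique(table$location))
  blocks_per_loc <- vapply(locations, function(l) {
    length(unique(table$block[table$location == l]))
  }, integer(1))
  n_missing <- sum(vapply(traits, function(tr) sum(is.na(table[[tr]])), integer(1)))
  cells <- table(table$progeny, paste(table$location, table$block, sep = "\r"))
  balanced <- all(cells == 1L) &&
    ncol(cells) == sum(blocks_per_loc) && nrow(cells) == length(progeny)
  messages <- character(0)
  if (!balanced) messages <- c(messages, "trial is not balanced: some progeny are missing from some location-block cells")
  if (n_missing > 0) messages <- c(messages, sprintf("%d missing trait cell(s)", n_missing))
  structure(list(
    n_progeny = length(progeny),
    n_locations = length(locations),
    n_blocks_per_location = blocks_per_loc,
    n_missing_cells = n_missing,
    balance_flag = balanced,
    messages = messages
  ), class = "validation_report")
}

#' @method print validation_report
#' @export
print.validation_report <- function(x, ...) {
  cat("Trial validation report\n")
  cat(sprintf("  progeny: %d, locations: %d, blocks/location: %s\n",
              x$n_progeny, x$n_locations,
              paste(x$n_blocks_per_location, collapse = ", ")))
  cat(sprintf("  missing cells: %d, balanced: %s\n", x$n_missing_cells, x$balance_flag))
  for (m in x$messages) cat("  note:", m, "\n")
  invisible(x)
}
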