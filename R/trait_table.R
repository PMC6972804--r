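#' Construct a validated plantation trait table
#'
#' A trait table holds one row per tree: its design cell in the plantation
#' (block, population, family) plus measured trait values. Validation
#' enforces the design invariants of a half-sib provenance trial: tree ids
#' are unique, every family belongs to exactly one population, block labels
#' come from a finite set, and trait values are finite or missing.
#'
#' @param data data.frame with columns `tree_id`, `block`, `population`,
#'   `family`, plus one numeric column per trait.
#' @param traits character vector of trait column names. Defaults to every
#'   column not part of the design.
#' @return A `trait_table`: a data.frame with attribute `traits`.
#' @export
trait_table <- function(data, traits = NULL) {
  design_cols <- c("tree_id", "block", "population", "family")
  missing_cols <- setdiff(design_cols, names(data))
  if (length(missing_cols) > 0L) {
    stop("trait table schema error: missing design column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(traits)) traits <- setdiff(names(data), design_cols)
  missing_tr <- setdiff(traits, names(data))
  if (length(missing_tr) > 0L) {
    stop("trait column(s) absent: ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$tree_id <- as.character(data$tree_id)
  data$block <- factor(data$block)
  data$population <- factor(as.character(data$population))
  data$family <- factor(as.character(data$family))
  dup <- data$tree_id[duplicated(data$tree_id)]
  if (length(dup) > 0L) {
    stop("duplicate tree id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  fam_pop <- unique(data.frame(family = data$family,
                               population = data$population))
  bad_fam <- fam_pop$family[duplicated(fam_pop$family)]
  if (length(bad_fam) > 0L) {
    stop("family mapped to more than one population: ",
         paste(unique(as.character(bad_fam)), collapse = ", "),
         call. = FALSE)
  }
  for (tr in traits) {
    v <- data[[tr]]
    if (!is.numeric(v)) {
      suppressWarnings(v <- as.numeric(as.character(v)))
      n_bad <- sum(is.na(v) & !is.na(data[[tr]]))
      if (n_bad > 0L) {
        message(n_bad, " unparseable value(s) in trait '", tr,
                "' retained as missing")
      }
      data[[tr]] <- v
    }
    if (any(is.infinite(data[[tr]]))) {
      stop("non-finite trait value(s) in '", tr, "'", call. = FALSE)
    }
  }
  structure(data, traits = traits,
            class = c("trait_table", "data.frame"))
}

#' Read a plantation trait table from CSV
#'
#' The CSV schema is explicit: `schema` maps the file's column names onto the
#' canonical design columns and trait names, so deposited and synthetic files
#' can share one reader. No header guessing is performed.
#'
#' @param path CSV file with a header row.
#' @param schema named list with entries `tree_id`, `block`, `population`,
#'   `family` (column names in the file) and `traits`, a named character
#'   vector `c(<trait name> = <file column>, ...)`. `NULL` uses canonical
#'   names directly.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path, schema = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(schema)) {
    return(trait_table(raw))
  }
  design_cols <- c("tree_id", "block", "population", "family")
  for (col in design_cols) {
    src <- schema[[col]]
    if (is.null(src) || !src %in% names(raw)) {
      stop("trait table schema error: no column '", src %||% col,
           "' for design field '", col, "'", call. = FALSE)
    }
  }
  traits <- schema$traits
  missing_tr <- setdiff(unname(traits), names(raw))
  if (length(missing_tr) > 0L) {
    stop("trait table schema error: trait column(s) absent: ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    tree_id = raw[[schema$tree_id]],
    block = raw[[schema$block]],
    population = raw[[schema$population]],
    family = raw[[schema$family]],
    stringsAsFactors = FALSE
  )
  for (tr in names(traits)) out[[tr]] <- raw[[traits[[tr]]]]
  trait_table(out, traits = names(traits))
}

#' Write a trait table to CSV
#'
#' Values round-trip through [read_trait_table()] exactly (full double
#' precision is written).
#'
#' @param table a [trait_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  stopifnot(inherits(table, "trait_table"))
  df <- as.data.frame(table)
  df$block <- as.character(df$block)
  df$population <- as.character(df$population)
  df$family <- as.character(df$family)
  old <- options(digits = 17)
  on.exit(options(old))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.trait_table <- function(x, ...) {
  traits <- attr(x, "traits")
  cat("Plantation trait table: ", nrow(x), " trees, ",
      nlevels(x$population), " populations, ",
      nlevels(x$family), " families, ",
      nlevels(x$block), " blocks\n", sep = "")
  cat("Traits: ", paste(traits, collapse = ", "), "\n", sep = "")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
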