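#' Canonical trait names
#'
#' The six functional traits measured on each worker ant, in the fixed order
#' used throughout the package: Weber's length (body size), head width, eye
#' width, mandible length, scape length, and hindleg length, all in mm.
#' Readers reorder input columns to this order so that ordination loadings
#' are always reported against it.
#'
#' @return character vector of length 6.
#' @export
trait_names <- function() {
  c("webers_length", "head_width", "eye_width",
    "mandible_length", "scape_length", "hindleg_length")
}

#' Construct and validate a trait table
#'
#' A trait table holds one row per individual: an identifier, a population
#' label (e.g. the park the ant was collected in), and the six traits of
#' [trait_names()].  Validation enforces that every trait value is present,
#' finite and strictly positive, that population labels are non-empty, that
#' identifiers are unique, and that at least two populations are present.
#'
#' @param x data.frame with a population column and the six trait columns
#'   (canonical names, or mapped through `schema`).
#' @param schema optional named character vector mapping canonical column
#'   names (`"population"`, `"individual_id"`, and [trait_names()]) to the
#'   actual column names in `x`.  Unmapped canonical names are looked up
#'   directly.
#' @return `x` reordered to canonical columns, with class `trait_table`.
#' @export
as_trait_table <- function(x, schema = NULL) {
  x <- as.data.frame(x)
  canonical <- c("individual_id", "population", trait_names())
  lookup <- stats::setNames(canonical, canonical)
  if (!is.null(schema)) {
    schema <- unlist(schema)
    bad <- setdiff(names(schema), canonical)
    if (length(bad) > 0L) {
      stop(sprintf("schema maps unknown field(s): %s", paste(bad, collapse = ", ")))
    }
    lookup[names(schema)] <- schema
  }

  required <- setdiff(canonical, "individual_id")
  missing <- required[!(lookup[required] %in% names(x))]
  if (length(missing) > 0L) {
    stop(sprintf("schema error: column(s) not found in input: %s",
                 paste(sprintf("%s (mapped to '%s')", missing, lookup[missing]),
                       collapse = ", ")))
  }

  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
    individual_id = if (lookup[["individual_id"]] %in% names(x)) {
      as.character(x[[lookup[["individual_id"]]]])
    } else {
      sprintf("row_%d", seq_len(nrow(x)))
    },
    population = as.character(x[[lookup[["population"]]]])
  )
  for (tr in trait_names()) {
    v <- x[[lookup[[tr]]]]
    if (is.character(v) || is.factor(v)) {
      suppressWarnings(v <- as.numeric(as.character(v)))
    }
    out[[tr]] <- as.numeric(v)
  }

  problems <- character(0)
  for (i in seq_len(nrow(out))) {
    vals <- unlist(out[i, trait_names()])
    if (any(!is.finite(vals))) {
      problems <- c(problems, sprintf(
        "row %d: missing or non-numeric trait value (%s)", i,
        paste(trait_names()[!is.finite(vals)], collapse = ", ")))
    } else if (any(vals <= 0)) {
      problems <- c(problems, sprintf(
        "row %d: non-positive trait value (%s)", i,
        paste(trait_names()[vals <= 0], collapse = ", ")))
    }
    if (is.na(out$population[i]) || !nzchar(out$population[i])) {
      problems <- c(problems, sprintf("row %d: empty population label", i))
    }
  }
  if (length(problems) > 0L) {
    stop(paste(c("trait table validation failed:", problems), collapse = "\n  "))
  }
  if (anyDuplicated(out$individual_id)) {
    dup <- unique(out$individual_id[duplicated(out$individual_id)])
    stop(sprintf("duplicate individual_id: %s", paste(utils::head(dup, 5L), collapse = ", ")))
  }
  if (length(unique(out$population)) < 2L) {
    stop("structural error: a trait table needs at least 2 populations")
  }
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Read a per-individual trait table from delimited text
#'
#' Reads a comma- or tab-separated file (auto-detected from the header line)
#' with one header row and one row per individual, validates it (see
#' [as_trait_table()]) and reorders columns to the canonical trait order.
#' Row order is preserved.
#'
#' @param path path to the file.
#' @param schema optional column-name mapping, as in [as_trait_table()].
#' @param sep field separator; `NULL` (default) auto-detects `","` vs `"\t"`.
#' @return a `trait_table`.
#' @examples
#' tab <- generate_traits(default_design())
#' f <- tempfile(fileext = ".csv")
#' write_trait_table(tab, f)
#' tab2 <- read_trait_table(f)
#' nrow(tab2)  # 163
#' @export
read_trait_table <- function(path, schema = NULL, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0L) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  as_trait_table(raw, schema = schema)
}

#' Write a trait table as CSV
#'
#' Canonical column order; values at full double precision so a write/read
#' round trip reproduces the table.
#'
#' @param x a `trait_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(x, path) {
  stopifnot(inherits(x, "trait_table"))
  df <- as.data.frame(x)
  for (tr in trait_names()) df[[tr]] <- format(df[[tr]], digits = 17, trim = TRUE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Per-population sample sizes
#'
#' @param x a `trait_table`.
#' @return named integer vector of counts, sorted by population label.
#' @export
population_counts <- function(x) {
  stopifnot(inherits(x, "trait_table"))
  tab <- table(x$population)
  stats::setNames(as.integer(tab), names(tab))
}

#' Which populations have enough individuals for a d-dimensional hull?
#'
#' A population needs at least `d + 1` individuals to span a `d`-dimensional
#' convex hull; smaller populations are flagged unusable for hull
#' construction (they still contribute to ordination and pooled statistics).
#'
#' @param x a `trait_table`.
#' @param d hull dimensionality (default 4, the retained ordination axes).
#' @return named logical vector, one entry per population.
#' @export
hull_usable <- function(x, d = 4L) {
  counts <- population_counts(x)
  counts >= d + 1L
}

#' @export
print.trait_table <- function(x, ...) {
  counts <- population_counts(x)
  cat(sprintf("Trait table: %d individuals, %d populations, %d traits\n",
              nrow(x), length(counts), length(trait_names())))
  cat("  counts: ", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  NextMethod()
}
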