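#' Construct a validated trait table
#'
#' A trait table holds replicated phenotype measurements keyed by
#' genotype, trait, treatment level and replicate. It is the input of
#' every downstream stage: resistance coefficients are formed per
#' (genotype, trait, stress level) from the replicate means, against the
#' control level (`treatment == 0`) of the same genotype and trait.
#'
#' @param records data frame with columns `genotype`, `trait`,
#'   `treatment` (numeric dose, 0 = control), `replicate` (positive
#'   integer) and `value` (numeric measurement in trait units).
#' @param nonnegative_traits character vector of trait labels whose
#'   values must be >= 0 (colony areas, biomass, concentrations).
#' @return A `trait_table`, a data frame with the five canonical columns
#'   in canonical order. Row order of `records` is preserved.
#' @examples
#' tt <- trait_table(data.frame(
#'   genotype = "G1", trait = "area",
#'   treatment = c(0, 0, 2, 2), replicate = c(1, 2, 1, 2),
#'   value = c(4.1, 3.9, 2.1, 1.9)))
#' @export
trait_table <- function(records, nonnegative_traits = character()) {
  required <- c("genotype", "trait", "treatment", "replicate", "value")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("trait table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- as.data.frame(records)[required]
  tab$genotype <- as.character(tab$genotype)
  tab$trait <- as.character(tab$trait)
  tab$treatment <- as.numeric(tab$treatment)
  tab$replicate <- as.integer(tab$replicate)
  tab$value <- as.numeric(tab$value)

  if (nrow(tab) == 0) stop("trait table has no rows", call. = FALSE)
  if (any(!is.finite(tab$value))) {
    stop("non-finite trait values at row(s): ",
         paste(which(!is.finite(tab$value)), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(tab$treatment)) || any(tab$treatment < 0)) {
    stop("treatment levels must be numeric and >= 0 (0 = control)",
         call. = FALSE)
  }
  if (any(is.na(tab$replicate)) || any(tab$replicate < 1)) {
    stop("replicate ids must be positive integers", call. = FALSE)
  }

  key <- paste(tab$genotype, tab$trait, tab$treatment, tab$replicate,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- tab[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf(
      "duplicate measurement key: genotype=%s trait=%s treatment=%g replicate=%d",
      d$genotype, d$trait, d$treatment, d$replicate), call. = FALSE)
  }

  # every (genotype, trait) pair needs its control level
  pairs <- unique(tab[c("genotype", "trait")])
  has_ctrl <- paste(tab$genotype[tab$treatment == 0],
                    tab$trait[tab$treatment == 0], sep = "\r")
  want <- paste(pairs$genotype, pairs$trait, sep = "\r")
  miss <- pairs[!(want %in% has_ctrl), , drop = FALSE]
  if (nrow(miss) > 0) {
    stop(sprintf(
      "missing control level (treatment = 0) for genotype=%s trait=%s",
      miss$genotype[1], miss$trait[1]), call. = FALSE)
  }

  if (length(nonnegative_traits) > 0) {
    bad <- tab$trait %in% nonnegative_traits & tab$value < 0
    if (any(bad)) {
      stop(sprintf("negative value for non-negative trait '%s' (genotype %s)",
                   tab$trait[bad][1], tab$genotype[bad][1]), call. = FALSE)
    }
  }

  rownames(tab) <- NULL
  class(tab) <- c("trait_table", "data.frame")
  tab
}

#' Read a trait table from CSV
#'
#' Reads long-format CSV (canonical) or wide-format CSV with one column
#' per treatment level, controlled by a dialect configuration. The
#' dialect maps file headers to the canonical columns and flags
#' non-negative traits.
#'
#' @param path path to a CSV file (UTF-8, comma separated, header row).
#' @param dialect list (or path to a YAML/JSON file) with optional
#'   entries:
#'   \describe{
#'     \item{columns}{named list mapping canonical names (`genotype`,
#'       `trait`, `treatment`, `replicate`, `value`) to the file's
#'       header names.}
#'     \item{format}{`"long"` (default) or `"wide"`.}
#'     \item{treatment_columns}{for wide format: named list mapping each
#'       value column header to its numeric treatment level, e.g.
#'       `list(ctrl = 0, cd2 = 2)`.}
#'     \item{nonnegative_traits}{character vector of trait labels that
#'       must be >= 0.}
#'   }
#' @return A validated [trait_table()].
#' @export
read_trait_table <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(dialect) && length(dialect) == 1) {
    dialect <- read_config(dialect)
  }
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) stop("malformed CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))

  fmt <- dialect$format %||% "long"
  cols <- dialect$columns %||% list()
  col_of <- function(canonical) {
    nm <- cols[[canonical]] %||% canonical
    if (!nm %in% names(raw)) {
      stop(sprintf("column '%s' (for '%s') not found in %s",
                   nm, canonical, path), call. = FALSE)
    }
    nm
  }

  if (identical(fmt, "wide")) {
    tc <- dialect$treatment_columns
    if (is.null(tc) || is.null(names(tc))) {
      stop("wide format requires dialect$treatment_columns (column -> level)",
           call. = FALSE)
    }
    gcol <- col_of("genotype"); tcol <- col_of("trait")
    rcol <- col_of("replicate")
    long <- do.call(rbind, lapply(names(tc), function(vc) {
      if (!vc %in% names(raw)) {
        stop("wide value column not found: ", vc, call. = FALSE)
      }
      data.frame(genotype = raw[[gcol]], trait = raw[[tcol]],
                 treatment = as.numeric(tc[[vc]]),
                 replicate = raw[[rcol]], value = raw[[vc]],
                 stringsAsFactors = FALSE)
    }))
    records <- long
  } else {
    records <- data.frame(
      genotype  = raw[[col_of("genotype")]],
      trait     = raw[[col_of("trait")]],
      treatment = raw[[col_of("treatment")]],
      replicate = raw[[col_of("replicate")]],
      value     = raw[[col_of("value")]],
      stringsAsFactors = FALSE)
  }
  trait_table(records,
              nonnegative_traits = dialect$nonnegative_traits %||% character())
}

#' Write a stage result to CSV
#'
#' All stage outputs are written as plain CSV with a stable column order
#' and numeric columns formatted to 6 decimal places, so that re-reading
#' reproduces the values exactly at that precision. Matrices gain a
#' leading `genotype` column from their row names; an empty result
#' writes a header-only file.
#'
#' @param x a data frame, matrix, [trait_table()], evaluation result,
#'   tolerance classing, or association result.
#' @param path output file path; the directory must exist and be
#'   writable.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir,
                             call. = FALSE)
  df <- as_result_frame(x)
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.6f", out[[j]])
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

# normalize any stage output to a plain data frame for CSV output
as_result_frame <- function(x) {
  if (inherits(x, "tolerance_classing")) {
    return(data.frame(genotype = x$genotypes,
                      class = x$label,
                      class_name = x$class_names[x$label],
                      d = x$d, stringsAsFactors = FALSE))
  }
  if (inherits(x, "cd_association")) {
    return(data.frame(statistic = c("r", "t", "df", "p_two_tailed", "n"),
                      value = c(x$r, x$t_stat, x$df, x$p_two_tailed, x$n)))
  }
  if (is.matrix(x)) {
    df <- as.data.frame(x)
    if (!is.null(rownames(x))) {
      df <- cbind(genotype = rownames(x), df)
      rownames(df) <- NULL
    }
    return(df)
  }
  as.data.frame(x)
}

#' Read a YAML or JSON configuration file
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return the parsed configuration as a list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("Trait table: %d records, %d genotype(s), %d trait(s), %d treatment level(s)\n",
              nrow(x), length(unique(x$genotype)), length(unique(x$trait)),
              length(unique(x$treatment))))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
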