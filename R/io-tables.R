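## TSV table schemas shared by the pipeline. Missing values are encoded
## as "." on disk and NA in memory -- semantically distinct from 0/FALSE.

.table_schemas <- list(
  evidence = list(
    required = c("contig_id", "virsorter_category", "virfinder_score",
                 "cat_viral", "phaster_prophage"),
    optional = c("contig_length"),
    types = c(contig_id = "character", virsorter_category = "integer",
              virfinder_score = "numeric", cat_viral = "logical",
              phaster_prophage = "logical", contig_length = "integer")),
  samples = list(
    required = c("sample_id", "depth_m", "zone", "metagenome_size_bp"),
    optional = character(),
    types = c(sample_id = "character", depth_m = "numeric",
              zone = "character", metagenome_size_bp = "numeric")),
  genes = list(
    required = c("contig_id", "gene_index", "start", "end", "strand",
                 "category"),
    optional = c("amg_name"),
    types = c(contig_id = "character", gene_index = "integer",
              start = "integer", end = "integer", strand = "character",
              category = "character", amg_name = "character")),
  boundary = list(
    required = c("contig_id"),
    optional = c("attL_coord", "attR_coord", "termini_predicted",
                 "phaster_start", "phaster_end"),
    types = c(contig_id = "character", attL_coord = "integer",
              attR_coord = "integer", termini_predicted = "logical",
              phaster_start = "integer", phaster_end = "integer")),
  pcs = list(
    required = c("population_id", "pc_id"),
    optional = character(),
    types = c(population_id = "character", pc_id = "character"))
)

.convert_column <- function(x, type, col) {
  x[x == "."] <- NA_character_
  out <- switch(type,
    character = x,
    integer = suppressWarnings(as.integer(x)),
    numeric = suppressWarnings(as.numeric(x)),
    logical = {
      lo <- tolower(x)
      v <- rep(NA, length(x))
      v[lo %in% c("true", "t", "1")] <- TRUE
      v[lo %in% c("false", "f", "0")] <- FALSE
      attr(v, "unparsed") <- !is.na(x) & !lo %in%
        c("true", "t", "1", "false", "f", "0")
      v
    })
  bad <- if (type == "logical") attr(out, "unparsed") else is.na(out) & !is.na(x)
  if (any(bad))
    .stopf("column '%s', row %d: cannot parse value '%s' as %s",
           col, which(bad)[1], x[which(bad)[1]], type)
  attr(out, "unparsed") <- NULL
  out
}

#' Read a typed pipeline table
#'
#' Reads one of the pipeline's TSV tables and validates it against the
#' named schema. `"."` encodes a missing value (returned as `NA`), which
#' is distinct from a score of 0 or `FALSE`. Unknown columns are kept as
#' character but otherwise ignored.
#'
#' @param path Path to a TSV file with a header row.
#' @param schema One of `"evidence"`, `"samples"`, `"genes"`,
#'   `"boundary"`, `"pcs"`.
#' @return A typed `data.frame`.
#' @seealso [writePipelineTable()], [readAbundanceTable()]
#' @export
readPipelineTable <- function(path,
                              schema = c("evidence", "samples", "genes",
                                         "boundary", "pcs")) {
  schema <- match.arg(schema)
  sc <- .table_schemas[[schema]]
  if (!file.exists(path)) .stopf("table not found: %s", path)
  raw <- read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL, stringsAsFactors = FALSE)
  miss <- setdiff(sc$required, names(raw))
  if (length(miss))
    .stopf("%s table is missing required column(s): %s", schema,
           paste(miss, collapse = ", "))
  for (col in intersect(names(raw), names(sc$types)))
    raw[[col]] <- .convert_column(raw[[col]], sc$types[[col]], col)
  if (schema == "samples") {
    .check_zone(raw$zone)
    if (any(raw$metagenome_size_bp <= 0, na.rm = TRUE))
      .stopf("metagenome_size_bp must be > 0")
  }
  raw
}

#' Write a pipeline table
#'
#' Writes a TSV with `NA` encoded as `"."`, so
#' `readPipelineTable(writePipelineTable(x))` is an identity on the
#' schema columns.
#'
#' @param x A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePipelineTable <- function(x, path) {
  write.table(x, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  invisible(path)
}

#' Read / write an abundance matrix TSV
#'
#' The on-disk layout is a TSV with a `population_id` column followed by
#' one numeric column per sample; `readAbundanceTable(writeAbundanceTable(m))`
#' is an identity.
#'
#' @param path Path to the TSV.
#' @return For `readAbundanceTable`, a numeric matrix with population
#'   rownames and sample colnames.
#' @export
readAbundanceTable <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(raw)[1] != "population_id")
    .stopf("abundance table must start with a population_id column")
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) .stopf("abundance values must be numeric")
  rownames(m) <- raw$population_id
  m
}

#' @rdname readAbundanceTable
#' @param x Numeric matrix, populations x samples, with dimnames.
#' @export
writeAbundanceTable <- function(x, path) {
  df <- data.frame(population_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' Accepts either JSON (detected by a leading `{` or a `.json` extension)
#' or a flat `key=value` file (one pair per line, `#` comments allowed;
#' values are coerced to numeric/logical when unambiguous).
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  txt <- readLines(path, warn = FALSE)
  first <- trimws(paste(txt, collapse = " "))
  if (grepl("\\.json$", path, ignore.case = TRUE) ||
      startsWith(first, "{")) {
    return(jsonlite::fromJSON(paste(txt, collapse = "\n"),
                              simplifyVector = TRUE))
  }
  txt <- sub("#.*$", "", txt)
  txt <- trimws(txt)
  txt <- txt[nzchar(txt)]
  bad <- !grepl("=", txt, fixed = TRUE)
  if (any(bad)) .stopf("config line without '=': %s", txt[which(bad)[1]])
  keys <- trimws(sub("=.*$", "", txt))
  vals <- trimws(sub("^[^=]*=", "", txt))
  coerce <- function(v) {
    if (tolower(v) %in% c("true", "false")) return(as.logical(v))
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) return(n)
    v
  }
  setNames(lapply(vals, coerce), keys)
}
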