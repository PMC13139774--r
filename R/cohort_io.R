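#' @importFrom data.table fread fwrite
#' @importFrom stats kmeans dist hclust cutree prcomp rnorm runif rpois rgamma sd
#' @importFrom utils head
NULL

#' Default column mapping for COSMIC-style mutation tables
#'
#' Maps the canonical record fields to column names in the input file.
#'
#' @return Named character vector (field -> column name).
#' @export
default_dialect <- function() {
  c(cohort = "cohort", sample_id = "sample_id", gene = "gene",
    chromosome = "chromosome", position = "position",
    ref = "ref", alt = "alt")
}

#' Normalize chromosome labels
#'
#' Strips a leading "chr" prefix (any case) and upper-cases X/Y. Labels that
#' are not one of the 24 canonical human chromosomes (1..22, X, Y) are left
#' as-is so that the filter step can count them under `bad_chromosome`
#' rather than dropping rows silently at parse time.
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @export
normalize_chromosome <- function(x) {
  x <- as.character(x)
  x <- sub("^[Cc][Hh][Rr]", "", x)
  x <- toupper(trimws(x))
  x
}

#' The 24 canonical human chromosome labels, in order
#' @return Character vector "1".."22", "X", "Y".
#' @export
chromosome_labels <- function() c(as.character(1:22), "X", "Y")

#' Read a COSMIC-style somatic mutation table
#'
#' Reads a TSV/CSV of somatic variants (one row per mutation call) into an
#' unfiltered record table. Chromosome labels are normalized; no rows are
#' dropped here — malformed rows are passed through for [filter_records()]
#' to count and exclude.
#'
#' @param path Path to a TSV or CSV file with a header.
#' @param dialect Named character vector mapping record fields to column
#'   names; see [default_dialect()]. A `coding_flag` entry is optional; when
#'   the input has no coding-status column every row is assumed coding.
#' @param sep Field separator; `"auto"` infers from the file extension
#'   (".csv" -> comma, otherwise tab).
#' @return A `data.frame` of mutation records with columns `cohort`,
#'   `sample_id`, `gene`, `chromosome`, `position`, `ref`, `alt`,
#'   `coding_flag`, in file order.
#' @export
read_mutation_table <- function(path, dialect = default_dialect(), sep = "auto") {
  if (!file.exists(path)) stop("mutation table not found: ", path)
  if (identical(sep, "auto")) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                          colClasses = "character", showProgress = FALSE)
  if (ncol(dt) == 0L) stop("empty header in ", path)
  required <- c("cohort", "sample_id", "gene", "chromosome", "position", "ref", "alt")
  for (f in required) {
    col <- dialect[[f]]
    if (is.null(col) || !col %in% names(dt)) {
      stop("mapped column for field '", f, "' (", col %||% "<unset>",
           ") not present in header of ", path)
    }
  }
  rec <- data.frame(
    cohort     = dt[[dialect[["cohort"]]]],
    sample_id  = dt[[dialect[["sample_id"]]]],
    gene       = dt[[dialect[["gene"]]]],
    chromosome = normalize_chromosome(dt[[dialect[["chromosome"]]]]),
    position   = suppressWarnings(as.integer(dt[[dialect[["position"]]]])),
    ref        = toupper(dt[[dialect[["ref"]]]]),
    alt        = toupper(dt[[dialect[["alt"]]]]),
    stringsAsFactors = FALSE
  )
  cf <- dialect["coding_flag"]
  if (!is.na(cf) && cf %in% names(dt)) {
    v <- toupper(dt[[cf]])
    rec$coding_flag <- v %in% c("TRUE", "T", "1", "YES", "Y", "CODING")
  } else {
    rec$coding_flag <- rep(TRUE, nrow(rec))
  }
  rec
}

#' Write mutation records to a TSV
#'
#' @param records Record table as returned by [read_mutation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(records, path) {
  out <- records[, c("cohort", "sample_id", "gene", "chromosome",
                     "position", "ref", "alt")]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

FILTER_RULES <- c("malformed", "bad_chromosome", "not_snv",
                  "ref_equals_alt", "alt_transcript", "non_coding")

#' Filter mutation records and account for every exclusion
#'
#' Applies the record-validity rules in a fixed order (structural validity
#' first): `malformed` -> `bad_chromosome` -> `not_snv` -> `ref_equals_alt`
#' -> `alt_transcript` -> `non_coding`. Each record is charged to the first
#' rule it violates, so the report is deterministic and conservative.
#'
#' Rules:
#' \describe{
#'   \item{malformed}{missing/empty required field or non-positive position.}
#'   \item{bad_chromosome}{chromosome not one of the 24 canonical labels
#'     (mitochondrial and alt contigs land here).}
#'   \item{not_snv}{ref or alt is not a single A/C/G/T base.}
#'   \item{ref_equals_alt}{ref and alt identical.}
#'   \item{alt_transcript}{gene symbol contains the alternative-transcript
#'     marker (default substring `"_ENST"`).}
#'   \item{non_coding}{`coding_flag` is FALSE (no-op when the input had no
#'     coding annotation).}
#' }
#'
#' @param records Record table.
#' @param rules Character vector of rules to apply (subset of the six above;
#'   `malformed` is always applied). Defaults to all.
#' @param transcript_marker Substring identifying alternative-transcript
#'   gene identifiers.
#' @param dedup `"none"` (default) keeps rows as-is; `"sample-variant"`
#'   collapses exact duplicate (sample, gene, chromosome, position, ref, alt)
#'   rows before filtering.
#' @return A list with `records` (retained rows, invariants guaranteed) and
#'   `report`, a `filter_report` object (`n_input`, `n_retained`,
#'   `dropped_by_rule`).
#' @export
filter_records <- function(records, rules = FILTER_RULES,
                           transcript_marker = "_ENST",
                           dedup = c("none", "sample-variant")) {
  dedup <- match.arg(dedup)
  stopifnot(all(rules %in% FILTER_RULES))
  if (dedup == "sample-variant" && nrow(records) > 0) {
    key <- paste(records$cohort, records$sample_id, records$gene,
                 records$chromosome, records$position, records$ref,
                 records$alt, sep = "\r")
    records <- records[!duplicated(key), , drop = FALSE]
  }
  n_input <- nrow(records)
  dropped <- stats::setNames(integer(length(FILTER_RULES)), FILTER_RULES)
  bases <- c("A", "C", "G", "T")
  assigned <- rep(NA_character_, n_input)

  viol <- list(
    malformed = is.na(records$cohort) | records$cohort == "" |
      is.na(records$gene) | records$gene == "" |
      is.na(records$chromosome) | records$chromosome == "" |
      is.na(records$position) | records$position < 1 |
      is.na(records$ref) | is.na(records$alt) |
      records$ref == "" | records$alt == "",
    bad_chromosome = !(records$chromosome %in% chromosome_labels()),
    not_snv = !(records$ref %in% bases) | !(records$alt %in% bases),
    ref_equals_alt = records$ref == records$alt,
    alt_transcript = grepl(transcript_marker, records$gene, fixed = TRUE),
    non_coding = !records$coding_flag
  )
  active <- FILTER_RULES[FILTER_RULES %in% union(rules, "malformed")]
  for (rule in active) {
    hit <- viol[[rule]]
    hit[is.na(hit)] <- TRUE  # NA field comparisons count as violations
    hit <- hit & is.na(assigned)
    assigned[hit] <- rule
    dropped[rule] <- dropped[rule] + sum(hit)
  }
  keep <- is.na(assigned)
  report <- structure(list(
    n_input = n_input,
    n_retained = sum(keep),
    dropped_by_rule = as.list(dropped)
  ), class = "filter_report")
  list(records = records[keep, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Mutation filter report\n")
  cat("  input rows:    ", x$n_input, "\n")
  cat("  retained rows: ", x$n_retained, "\n")
  for (r in names(x$dropped_by_rule)) {
    if (x$dropped_by_rule[[r]] > 0)
      cat(sprintf("  dropped [%s]: %d\n", r, x$dropped_by_rule[[r]]))
  }
  invisible(x)
}

#' Serialize a filter report to JSON
#' @param report A `filter_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
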