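## One-hot encoding of clinical metadata with a reproducible schema.
## A record is a named list (or data.frame row) of categorical values;
## the schema fixes field order and category order so the same record
## always encodes to the same bit pattern.

normalizeRecord <- function(record) {
  if (is.data.frame(record)) record <- as.list(record)
  vals <- lapply(record, function(v) {
    if (length(v) == 0L || (length(v) == 1L && is.na(v))) NA_character_
    else as.character(v)
  })
  bad <- vapply(vals, length, 1L) != 1L
  if (any(bad))
    stop("record values must be scalars; offending field(s): ",
         paste(names(vals)[bad], collapse = ", "))
  vals
}

#' Construct a metadata schema directly
#'
#' @param fields named list of character category vectors, in the exact
#'   field and category order to encode with.  Supplying an explicit
#'   order is how conventions such as `sex = c("male", "female")`
#'   (encoding male as `(1,0)` and female as `(0,1)`) are honoured;
#'   [buildSchema()] otherwise defaults to lexicographic order.
#' @return a [MetadataSchema-class].
#' @examples
#' sch <- metadataSchema(list(sex = c("male", "female")))
#' encodeRecord(list(sex = "male"), sch)   # (1, 0)
#' @export
metadataSchema <- function(fields) {
  fields <- lapply(fields, as.character)
  new("MetadataSchema", fields = fields,
      dMeta = as.integer(sum(lengths(fields))))
}

#' Build a metadata schema from observed records
#'
#' Enumerates every category observed for every field across `records`
#' and fixes a deterministic encoding order: fields and categories are
#' sorted lexicographically (byte order, locale-independent) unless an
#' explicit order is supplied.  The schema is therefore invariant to
#' the order of the records.
#'
#' @param records non-empty list of named lists (or a data.frame, one
#'   record per row) of categorical values; `NA` marks a missing value.
#' @param fieldOrder optional character vector naming the fields in the
#'   desired order (must be a permutation of the observed fields).
#' @param categoryOrder optional named list giving, per field, the
#'   category order to use instead of lexicographic.
#' @return a [MetadataSchema-class].
#' @examples
#' sch <- buildSchema(list(list(sex = "male"), list(sex = "female")))
#' sch@fields$sex   # "female" "male" (lexicographic)
#' @export
buildSchema <- function(records, fieldOrder = NULL, categoryOrder = NULL) {
  if (is.data.frame(records))
    records <- lapply(seq_len(nrow(records)), function(i) as.list(records[i, , drop = FALSE]))
  if (length(records) == 0L) stop("cannot build a schema from zero records")
  records <- lapply(records, normalizeRecord)
  fieldNames <- unique(unlist(lapply(records, names)))
  if (is.null(fieldNames) || length(fieldNames) == 0L)
    stop("records declare no fields")
  observed <- lapply(fieldNames, function(f) {
    v <- unlist(lapply(records, function(r) r[[f]]))
    sortC(unique(v[!is.na(v)]))
  })
  names(observed) <- fieldNames
  empty <- lengths(observed) == 0L
  if (any(empty))
    stop("field(s) with zero observed categories: ",
         paste(fieldNames[empty], collapse = ", "))
  if (!is.null(fieldOrder)) {
    if (!setequal(fieldOrder, fieldNames))
      stop("fieldOrder must be a permutation of the observed fields")
    observed <- observed[fieldOrder]
  } else {
    observed <- observed[sortC(fieldNames)]
  }
  if (!is.null(categoryOrder)) {
    for (f in names(categoryOrder)) {
      if (!f %in% names(observed))
        stop("categoryOrder names unknown field '", f, "'")
      if (!setequal(categoryOrder[[f]], observed[[f]]))
        stop("categoryOrder for '", f, "' must be a permutation of its observed categories")
      observed[[f]] <- as.character(categoryOrder[[f]])
    }
  }
  metadataSchema(observed)
}

## locale-independent lexicographic sort
sortC <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x)
}

#' @describeIn dMeta total one-hot dimension of the schema.
#' @export
setMethod("dMeta", "MetadataSchema", function(x) x@dMeta)

setMethod("show", "MetadataSchema", function(object) {
  cat("MetadataSchema:", length(object@fields), "field(s), dMeta =",
      object@dMeta, "\n")
  for (nm in names(object@fields))
    cat("  ", nm, ": ", paste(object@fields[[nm]], collapse = ", "), "\n",
        sep = "")
})

#' One-hot encode a single metadata record
#'
#' Each schema field contributes a block with exactly one bit set when
#' the record carries a known category, and an all-zero block when the
#' value is missing (`NA` or absent) — the least-informative neutral
#' code, keeping the encoded length fixed at `dMeta`.
#'
#' @param record named list (or 1-row data.frame) of categorical
#'   values.
#' @param schema a [MetadataSchema-class].
#' @return named numeric vector of length `dMeta(schema)`; names are
#'   `"field=category"`.
#' @examples
#' sch <- metadataSchema(list(sex = c("male", "female")))
#' encodeRecord(list(sex = "female"), sch)   # (0, 1)
#' @export
encodeRecord <- function(record, schema) {
  stopifnot(is(schema, "MetadataSchema"))
  record <- normalizeRecord(record)
  unknown <- setdiff(names(record), names(schema@fields))
  if (length(unknown))
    stop("record has field(s) unknown to the schema: ",
         paste(unknown, collapse = ", "))
  out <- numeric(schema@dMeta)
  names(out) <- unlist(lapply(names(schema@fields), function(f)
    paste(f, schema@fields[[f]], sep = "=")))
  offset <- 0L
  for (f in names(schema@fields)) {
    cats <- schema@fields[[f]]
    v <- record[[f]]
    if (!is.null(v) && !is.na(v)) {
      j <- match(v, cats)
      if (is.na(j))
        stop(sprintf("unknown category '%s' for field '%s'", v, f))
      out[offset + j] <- 1
    }
    offset <- offset + length(cats)
  }
  out
}

#' One-hot encode a batch of records
#'
#' @param records list of records (or a data.frame, one record per
#'   row); may be empty.
#' @param schema a [MetadataSchema-class].
#' @return numeric matrix `n x dMeta`; row `i` equals
#'   `encodeRecord(records[[i]], schema)`.
#' @export
encodeBatch <- function(records, schema) {
  stopifnot(is(schema, "MetadataSchema"))
  if (is.data.frame(records))
    records <- lapply(seq_len(nrow(records)), function(i) as.list(records[i, , drop = FALSE]))
  n <- length(records)
  out <- matrix(0, nrow = n, ncol = schema@dMeta)
  for (i in seq_len(n)) {
    row <- tryCatch(encodeRecord(records[[i]], schema), error = function(e)
      stop(sprintf("record %d: %s", i, conditionMessage(e)), call. = FALSE))
    if (i == 1L) colnames(out) <- names(row)
    out[i, ] <- row
  }
  if (n == 0L)
    colnames(out) <- unlist(lapply(names(schema@fields), function(f)
      paste(f, schema@fields[[f]], sep = "=")))
  out
}

#' Decode a one-hot vector back to categories
#'
#' Inverse of [encodeRecord()] for non-missing fields: within each
#' field block the set bit names the category; an all-zero block
#' decodes to `NA`.
#'
#' @param values numeric vector of length `dMeta(schema)`.
#' @param schema a [MetadataSchema-class].
#' @return named character vector, one entry per field.
#' @export
decodeVector <- function(values, schema) {
  stopifnot(is(schema, "MetadataSchema"), length(values) == schema@dMeta)
  out <- character(length(schema@fields))
  names(out) <- names(schema@fields)
  offset <- 0L
  for (f in names(schema@fields)) {
    cats <- schema@fields[[f]]
    block <- values[offset + seq_along(cats)]
    out[f] <- if (sum(block) == 0) NA_character_ else cats[which.max(block)]
    offset <- offset + length(cats)
  }
  out
}

#' Bin a numeric variable into labelled quantile bands
#'
#' Clinical age is recorded as a number but encoded one-hot; this
#' helper turns it into decile (by default) bands whose labels become
#' schema categories.  Bin edges can be supplied explicitly so that a
#' schema built on one cohort applies unchanged to another.
#'
#' @param x numeric vector.
#' @param nBins number of quantile bins when `edges` is `NULL`.
#' @param edges optional explicit, strictly increasing break points
#'   covering the data range.
#' @return list with `band` (character vector of labels, `NA` where `x`
#'   is `NA`) and `edges` (the break points used).
#' @export
binNumeric <- function(x, nBins = 10L, edges = NULL) {
  if (is.null(edges)) {
    edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nBins + 1L),
                                    na.rm = TRUE, names = FALSE))
    if (length(edges) < 2L) edges <- c(edges, edges + 1)
  }
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  labels <- sprintf("[%g,%g%s", edges[-length(edges)], edges[-1L],
                    c(rep(")", length(edges) - 2L), "]"))
  list(band = ifelse(is.na(x), NA_character_, labels[idx]), edges = edges)
}

#' Serialize / restore a metadata schema as JSON
#'
#' Stored alongside trained parameters so that the exact encoding
#' travels with a checkpoint.
#'
#' @param schema a [MetadataSchema-class].
#' @param path file path.
#' @return `writeSchema` returns `path` invisibly; `readSchema` the
#'   restored [MetadataSchema-class].
#' @export
writeSchema <- function(schema, path) {
  stopifnot(is(schema, "MetadataSchema"))
  jsonlite::write_json(schema@fields, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeSchema
#' @export
readSchema <- function(path) {
  fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  metadataSchema(as.list(fields))
}

#' Stable hash of a schema (hex string)
#'
#' Order-sensitive digest of the field/category layout, recorded in
#' checkpoint manifests to detect schema drift between training and
#' inference.
#'
#' @param schema a [MetadataSchema-class].
#' @return character(1) hex digest.
#' @export
schemaHash <- function(schema) {
  s <- paste(vapply(names(schema@fields), function(f)
    paste0(f, ":", paste(schema@fields[[f]], collapse = ",")), ""),
    collapse = ";")
  bytes <- utf8ToInt(s)
  h <- c(17L, 31L, 73L, 127L)
  for (i in seq_along(bytes))
    h <- (h * 131L + bytes[i] * c(1L, 3L, 7L, 11L)) %% 1048573L
  paste(sprintf("%05x", h), collapse = "")
}
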