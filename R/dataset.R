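## LesionDataset: accessors, subsetting, disk round trip.

#' Construct a dataset from components
#'
#' @param images numeric array `H x W x 3 x N` (values in \[0, 1\]).
#' @param meta data.frame of categorical metadata, one row per image.
#' @param labels class labels (coerced to factor).
#' @param provenance optional list of generator provenance.
#' @return a [LesionDataset-class].
#' @export
lesionDataset <- function(images, meta, labels, provenance = list()) {
  new("LesionDataset", images = images, meta = as.data.frame(meta),
      labels = as.factor(labels), provenance = provenance)
}

#' @describeIn lesionDataset number of samples.
#' @param x a [LesionDataset-class].
#' @export
setMethod("length", "LesionDataset", function(x) dim(x@images)[4])

#' @describeIn lesionDataset subset samples by index.
#' @param i integer or logical index vector.
#' @export
setMethod("[", "LesionDataset", function(x, i) {
  prov <- x@provenance
  if (!is.null(prov$templates)) prov$templates <- prov$templates[i]
  if (!is.null(prov$ids)) prov$ids <- prov$ids[i]
  new("LesionDataset",
      images = x@images[, , , i, drop = FALSE],
      meta = x@meta[i, , drop = FALSE],
      labels = x@labels[i],
      provenance = prov)
})

setMethod("show", "LesionDataset", function(object) {
  d <- dim(object@images)
  cat(sprintf("LesionDataset: %d samples, %dx%d RGB, %d metadata field(s)\n",
              d[4], d[1], d[2], ncol(object@meta)))
  print(table(object@labels))
})

#' Dataset accessors
#'
#' @param x a [LesionDataset-class].
#' @return `datasetImages` the `H x W x 3 x N` array, `datasetMeta` the
#'   metadata data.frame, `datasetLabels` the label factor.
#' @export
datasetImages <- function(x) x@images

#' @rdname datasetImages
#' @export
datasetMeta <- function(x) x@meta

#' @rdname datasetImages
#' @export
datasetLabels <- function(x) x@labels

#' Write a dataset in the standard on-disk layout
#'
#' `images/<id>.png` (8-bit PNG) plus `metadata.csv` with columns
#' `img_id`, `diagnostic` and one column per metadata field, plus a
#' `manifest.json` recording provenance — mirroring the distribution
#' layout of public skin-lesion collections so one reader serves real
#' and synthetic data alike.
#'
#' @param data a [LesionDataset-class].
#' @param outDir output directory (created if missing).
#' @return path of the manifest file, invisibly.
#' @export
writeDataset <- function(data, outDir) {
  dir.create(file.path(outDir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory ", outDir)
  n <- length(data)
  ids <- data@provenance$ids
  if (is.null(ids)) ids <- sprintf("img_%05d", seq_len(n))
  for (i in seq_len(n)) {
    img <- data@images[, , , i]
    png::writePNG(pmin(pmax(img, 0), 1),
                  file.path(outDir, "images", paste0(ids[i], ".png")))
  }
  df <- cbind(data.frame(img_id = ids,
                         diagnostic = as.character(data@labels),
                         stringsAsFactors = FALSE),
              data@meta)
  utils::write.csv(df, file.path(outDir, "metadata.csv"), row.names = FALSE)
  manifest <- file.path(outDir, "manifest.json")
  prov <- data@provenance
  prov$templates <- NULL   # generator-internal; not part of the data contract
  prov$ids <- NULL
  jsonlite::write_json(c(list(n_samples = n), prov), manifest,
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a dataset from the standard on-disk layout
#'
#' @param dir directory containing `images/` and `metadata.csv`.
#' @param idCol,labelCol column names of the image id and diagnosis
#'   label in the metadata table.
#' @return a [LesionDataset-class]; all metadata columns other than id
#'   and label are kept as character.
#' @export
readDataset <- function(dir, idCol = "img_id", labelCol = "diagnostic") {
  csv <- file.path(dir, "metadata.csv")
  if (!file.exists(csv)) stop("no metadata.csv under ", dir)
  df <- utils::read.csv(csv, colClasses = "character")
  if (!idCol %in% names(df)) stop("metadata table lacks id column '", idCol, "'")
  if (!labelCol %in% names(df)) stop("metadata table lacks label column '", labelCol, "'")
  n <- nrow(df)
  first <- png::readPNG(file.path(dir, "images", paste0(df[[idCol]][1], ".png")))
  images <- array(0, c(dim(first)[1], dim(first)[2], 3L, n))
  for (i in seq_len(n)) {
    img <- png::readPNG(file.path(dir, "images", paste0(df[[idCol]][i], ".png")))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    images[, , , i] <- img[, , 1:3]
  }
  meta <- df[, setdiff(names(df), c(idCol, labelCol)), drop = FALSE]
  lesionDataset(images, meta, df[[labelCol]],
                provenance = list(ids = df[[idCol]]))
}
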