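#' Read a feature/label CSV or TSV pair
#'
#' Both files must carry a header row and an instance-id first column; the
#' two files are matched row-by-row and must agree on instance count.
#' Canonical label coding is \{-1, 0, +1\} with all-zero rows marking
#' unlabeled instances. Files coded 0/1 are only remapped to -1/+1 when
#' \code{dialect01 = TRUE} is passed explicitly, because a silent remap
#' would conflate "label absent" with "instance unlabeled".
#'
#' @param featuresPath path to the feature table.
#' @param labelsPath path to the label table.
#' @param format \code{"csv"} or \code{"tsv"}.
#' @param dialect01 set \code{TRUE} when the label file codes
#'   absent/present as 0/1; entries are then mapped to -1/+1 and no row is
#'   treated as unlabeled.
#' @return A [MultiLabelSet-class].
#' @export
readMultiLabel <- function(featuresPath, labelsPath,
                           format = c("csv", "tsv"), dialect01 = FALSE) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  rd <- function(path) {
    tryCatch(
      read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e)))
  }
  ft <- rd(featuresPath)
  lt <- rd(labelsPath)
  if (nrow(ft) != nrow(lt))
    stop("feature and label tables disagree on instance count (",
         nrow(ft), " vs ", nrow(lt), ")")
  ids <- as.character(ft[[1]])
  X <- as.matrix(ft[, -1, drop = FALSE])
  Y <- as.matrix(lt[, -1, drop = FALSE])
  if (!is.numeric(X)) {
    bad <- which(!vapply(ft[, -1, drop = FALSE], is.numeric, logical(1)))
    stop("non-numeric feature column(s): ",
         paste(colnames(ft)[-1][bad], collapse = ", "))
  }
  if (dialect01) {
    if (!all(Y %in% c(0, 1)))
      stop("dialect01 requested but label entries are not all in {0, 1}")
    Y <- 2 * Y - 1
  }
  if (!all(Y %in% c(-1, 0, 1)))
    stop("label entries must be in {-1, 0, +1} (use dialect01 for 0/1 files)")
  multiLabelSet(X, Y, instanceIds = ids,
                metadata = list(featuresPath = featuresPath,
                                labelsPath = labelsPath, format = format,
                                dialect01 = dialect01))
}

#' Write the feature/label CSV (or TSV) pair
#'
#' Inverse of [readMultiLabel()]: header row, instance-id first column,
#' labels in the canonical \{-1, 0, +1\} coding.
#'
#' @param x a [MultiLabelSet-class].
#' @param featuresPath,labelsPath output paths.
#' @param format \code{"csv"} or \code{"tsv"}.
#' @return Invisibly, the two paths.
#' @export
writeMultiLabel <- function(x, featuresPath, labelsPath,
                            format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  X <- features(x)
  colnames(X) <- if (is.null(colnames(X)))
    paste0("f", seq_len(ncol(X))) else colnames(X)
  ft <- data.frame(id = x@instanceIds, X, check.names = FALSE)
  lt <- data.frame(id = x@instanceIds, labelMatrix(x), check.names = FALSE)
  write.table(ft, featuresPath, sep = sep, quote = FALSE, row.names = FALSE)
  write.table(lt, labelsPath, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(c(featuresPath, labelsPath))
}

#' Read a Mulan-dialect multi-label ARFF file
#'
#' Dense ARFF data file plus the companion XML header that lists which
#' attributes are labels (the Mulan convention). Label attributes coded
#' 0/1 are mapped to -1/+1.
#'
#' @param arffPath path to the ARFF data file.
#' @param xmlPath path to the XML label list.
#' @return A [MultiLabelSet-class].
#' @export
readMulan <- function(arffPath, xmlPath) {
  df <- foreign::read.arff(arffPath)
  doc <- xml2::read_xml(xmlPath)
  labs <- xml2::xml_attr(xml2::xml_find_all(doc, ".//*[local-name()='label']"),
                         "name")
  if (length(labs) == 0) stop("no <label> entries found in ", xmlPath)
  missing <- setdiff(labs, colnames(df))
  if (length(missing))
    stop("labels in XML not present in ARFF: ", paste(missing, collapse = ", "))
  Yraw <- df[, labs, drop = FALSE]
  Y <- vapply(Yraw, function(col) {
    v <- if (is.factor(col) || is.character(col))
      as.numeric(as.character(col)) else as.numeric(col)
    if (!all(v %in% c(0, 1))) stop("non-binary label column in ARFF")
    2 * v - 1
  }, numeric(nrow(df)))
  Xdf <- df[, setdiff(colnames(df), labs), drop = FALSE]
  num <- vapply(Xdf, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric feature attribute(s): ",
         paste(colnames(Xdf)[!num], collapse = ", "))
  multiLabelSet(as.matrix(Xdf), as.matrix(Y), labelNames = labs,
                metadata = list(arffPath = arffPath, xmlPath = xmlPath))
}

#' Write a provenance JSON file
#'
#' Records everything needed to reconstruct a run: configuration, seeds
#' and package version.
#'
#' @param config named list of settings.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeProvenance <- function(config, path) {
  config$package <- as.character(utils::packageVersion("mlmr"))
  config$rVersion <- as.character(getRversion())
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Load a YAML configuration file
#'
#' @param path YAML path.
#' @param defaults named list of defaults overridden by the file.
#' @return Named list.
#' @export
readConfig <- function(path, defaults = list()) {
  cfg <- yaml::read_yaml(path)
  modifyList(defaults, as.list(cfg))
}
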