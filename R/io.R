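#' Construct an expression dataset
#'
#' Bundles a genes-by-samples numeric matrix with a two-class sample
#' annotation.  This is the input container for network construction.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers).
#' @param labels Data frame with columns `sample` and `class` covering every
#'   column of `expr`; exactly two distinct classes are required.
#' @return An object of class `wgm_dataset`: a list with elements `expr`
#'   (matrix) and `samples` (tibble of `sample`, `class`).
#' @export
as_expression_dataset <- function(expr, labels) {
  expr <- as.matrix(expr)
  if (!is.numeric(expr)) abort("expression matrix must be numeric")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    abort("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    abort(paste0("duplicate gene identifiers: ",
                 paste(unique(rownames(expr)[duplicated(rownames(expr))]),
                       collapse = ", ")))
  if (anyDuplicated(colnames(expr))) abort("duplicate sample identifiers")
  labels <- as_tibble(labels)
  if (!all(c("sample", "class") %in% names(labels)))
    abort("labels need columns 'sample' and 'class'")
  labels$sample <- as.character(labels$sample)
  labels$class <- as.character(labels$class)
  cls <- sort(unique(labels$class))
  if (length(cls) != 2)
    abort(paste0("exactly two classes required, found ", length(cls), ": ",
                 paste(cls, collapse = ", ")))
  missing <- setdiff(colnames(expr), labels$sample)
  if (length(missing))
    abort(paste0("unlabeled sample(s): ", paste(missing, collapse = ", ")))
  samples <- labels[match(colnames(expr), labels$sample), c("sample", "class")]
  structure(list(expr = expr, samples = samples), class = "wgm_dataset")
}

#' @export
print.wgm_dataset <- function(x, ...) {
  tab <- table(x$samples$class)
  cat("<wgm_dataset> ", nrow(x$expr), " genes x ", ncol(x$expr), " samples (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Read an expression matrix from TSV/CSV
#'
#' @param path File path; the delimiter is taken from the extension (`.csv`
#'   uses comma, anything else tab).
#' @param orientation `"genes"` (rows are genes, default) or `"samples"`
#'   (rows are samples; the matrix is transposed after reading).
#' @return A genes-by-samples numeric matrix with identifiers.  Combine with
#'   [read_labels()] through [as_expression_dataset()].
#' @export
read_expression <- function(path, orientation = c("genes", "samples")) {
  orientation <- match.arg(orientation)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  nf <- utils::count.fields(path, sep = delim, quote = "\"")
  if (length(unique(nf)) != 1)
    abort(paste0("ragged row(s) at line(s) ",
                 paste(which(nf != nf[1]), collapse = ", "), " of ", path))
  # base parsing: strtod is correctly rounded, so 17-digit tables round-trip
  raw <- utils::read.delim(path, sep = delim, header = TRUE,
                           check.names = FALSE, colClasses = "character")
  ids <- as.character(raw[[1]])
  mat <- raw[, -1, drop = FALSE]
  for (j in seq_along(mat)) {
    v <- suppressWarnings(as.numeric(mat[[j]]))
    nn <- which(is.na(v) & !is.na(mat[[j]]) & !mat[[j]] %in% c("NA", ""))
    if (length(nn))
      abort(paste0("non-numeric value in column '", names(mat)[j],
                   "', line ", nn[1] + 1, " of ", path))
    mat[[j]] <- v
  }
  m <- as.matrix(mat)
  rownames(m) <- ids
  if (anyDuplicated(ids))
    abort(paste0("duplicate identifiers in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (anyNA(m)) warn(paste0(sum(is.na(m)), " missing value(s) in ", path))
  if (orientation == "samples") m <- t(m)
  m
}

#' Read a two-class sample label file
#'
#' Expects a delimited file whose first two columns are the sample identifier
#' and its class; a header line `sample<TAB>class` is accepted and dropped.
#'
#' @param path File path (TSV or CSV).
#' @return A tibble with columns `sample` and `class` (exactly two classes).
#' @export
read_labels <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = delim, header = FALSE,
                           colClasses = "character", strip.white = TRUE)
  if (ncol(raw) < 2) abort("label file needs two columns: sample, class")
  if (tolower(raw[1, 1]) %in% c("sample", "id") ) raw <- raw[-1, , drop = FALSE]
  out <- tibble(sample = raw[[1]], class = raw[[2]])
  cls <- sort(unique(out$class))
  if (length(cls) != 2)
    abort(paste0("exactly two classes required, found ", length(cls),
                 " (multi-class discrimination is out of scope): ",
                 paste(cls, collapse = ", ")))
  if (anyDuplicated(out$sample)) abort("duplicate sample in label file")
  out
}

#' Write an expression dataset to the standard TSV pair
#'
#' Writes `<prefix>_expression.tsv` (genes x samples, `gene` first column)
#' and `<prefix>_labels.tsv` (sample, class).
#'
#' @param dataset A [wgm_dataset].
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_expression <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "wgm_dataset"))
  ef <- paste0(prefix, "_expression.tsv")
  lf <- paste0(prefix, "_labels.tsv")
  num <- apply(dataset$expr, 2, function(x) sprintf("%.17g", x))
  df <- data.frame(gene = rownames(dataset$expr), num, check.names = FALSE)
  readr::write_tsv(df, ef)  # 17 significant digits: exact binary round-trip
  readr::write_tsv(dataset$samples, lf)
  invisible(c(expression = ef, labels = lf))
}
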