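#' Read a delimited genotype matrix
#'
#' Expects delimited text (tab or comma autodetected) with a header row of
#' marker IDs and the first column holding line IDs.
#'
#' @param path file path.
#' @param sep field separator; `NULL` autodetects between tab and comma.
#' @return numeric matrix with rownames = line IDs, colnames = marker IDs.
#' @export
read_genotypes <- function(path, sep = NULL) {
  df <- read_delim_checked(path, sep)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicated line IDs in ", path)
  X <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(X) <- "double"
  check_numeric_cells(X, path)
  rownames(X) <- ids
  X
}

#' Read a two-column phenotype table (ID, value)
#' @inheritParams read_genotypes
#' @return named numeric vector.
#' @export
read_phenotypes <- function(path, sep = NULL) {
  df <- read_delim_checked(path, sep)
  if (ncol(df) < 2L) stop("phenotype file must have at least 2 columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicated IDs in ", path)
  y <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(y)) {
    bad <- which(is.na(y))[1L]
    stop("malformed numeric value in ", path, " at row ", bad)
  }
  names(y) <- ids
  y
}

#' Read a square kernel/relationship matrix with ID header row and column
#' @inheritParams read_genotypes
#' @return symmetric numeric matrix with matching row/col IDs.
#' @export
read_kernel <- function(path, sep = NULL) {
  K <- read_genotypes(path, sep)
  if (nrow(K) != ncol(K)) stop("kernel file is not square")
  if (!identical(rownames(K), colnames(K)))
    stop("kernel row and column IDs differ")
  K
}

read_delim_checked <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

check_numeric_cells <- function(X, path) {
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1L, ]
    stop("malformed or missing numeric cell in ", path,
         " at row ", bad[1L], ", column ", bad[2L])
  }
  invisible(TRUE)
}

#' Align genotype/kernel rows with a phenotype vector by ID
#'
#' Intersects IDs and returns both objects in phenotype order; dropped IDs
#' are reported via message.
#'
#' @param M genotype or kernel matrix with rownames (kernels are subset on
#'   both dimensions).
#' @param y named phenotype vector.
#' @return list with `M`, `y`, `dropped` (IDs present in only one input).
#' @export
align_ids <- function(M, y) {
  if (is.null(rownames(M)) || is.null(names(y)))
    stop("both inputs must carry IDs")
  common <- intersect(names(y), rownames(M))
  if (length(common) == 0L) stop("no IDs shared between inputs")
  dropped <- union(setdiff(names(y), common), setdiff(rownames(M), common))
  if (length(dropped))
    message(length(dropped), " unmatched ID(s) dropped")
  M2 <- if (nrow(M) == ncol(M) && identical(rownames(M), colnames(M)))
    M[common, common, drop = FALSE] else M[common, , drop = FALSE]
  list(M = M2, y = y[common], dropped = dropped)
}

#' Write a cross-validation result to a delimited file
#'
#' Writes a TSV with a commented header block carrying run metadata (method,
#' seed, package version, any extra config) followed by one row per scored
#' case: observed, predicted, error, and replicate/pmse columns for
#' replicated layouts.  Round-trips through [read_cv_result()] at full
#' precision.
#'
#' @param x a [cv_result].
#' @param path output path.
#' @param config optional named list written into the header.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(x, path, config = list()) {
  stopifnot(inherits(x, "cv_result"))
  hdr <- c(
    paste0("# method=", x$method),
    paste0("# pmse=", format(x$pmse, digits = 17)),
    paste0("# pred_corr=", format(x$pred_corr, digits = 17)),
    paste0("# package=oneshotcv ",
           as.character(utils::packageVersion("oneshotcv"))),
    vapply(names(config), function(k)
      paste0("# ", k, "=", paste(format(config[[k]]), collapse = ",")),
      character(1))
  )
  df <- data.frame(case = seq_along(x$predictions),
                   observed = x$observed,
                   predicted = x$predictions,
                   error = x$errors)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(df, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a written cross-validation result
#' @param path file written by [write_cv_result()].
#' @return data.frame of the per-case table, with attribute `"header"`
#'   holding the parsed metadata lines.
#' @export
read_cv_result <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  meta <- sub("^# ?", "", hdr)
  attr(df, "header") <- meta
  df
}
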