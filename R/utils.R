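#' @importFrom stats rmultinom rpois rbinom rlnorm quantile median prcomp
#'   kmeans phyper pchisq p.adjust lowess approx optimize dnbinom glm.fit
#'   runif sd var setNames
#' @importFrom methods as is
#' @importFrom utils read.delim write.table modifyList read.csv
NULL

# data.table queries are used directly inside package code
.datatable.aware <- TRUE

# Run code with a temporary RNG state so callers' streams are not disturbed.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("ductalsc_config_error", "error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("ductalsc_format_error", "error")))
}

assert_count_matrix <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry gene rownames and barcode colnames")
  }
  invisible(counts)
}

# Column totals that work for both base and Matrix classes.
col_totals <- function(m) {
  if (inherits(m, "Matrix")) Matrix::colSums(m) else colSums(m)
}

row_means <- function(m) {
  if (inherits(m, "Matrix")) Matrix::rowMeans(m) else rowMeans(m)
}

row_sums <- function(m) {
  if (inherits(m, "Matrix")) Matrix::rowSums(m) else rowSums(m)
}

as_sparse <- function(m) {
  if (inherits(m, "Matrix")) {
    methods::as(m, "CsparseMatrix")
  } else {
    Matrix::Matrix(m, sparse = TRUE)
  }
}
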