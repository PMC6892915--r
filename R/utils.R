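#' @importFrom rlang abort warn inform .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows distinct rename n
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_chr map2
NULL

# Convert an expression table (first column = gene id, remaining columns =
# numeric sample values) or a numeric matrix into a named matrix.
as_expr_matrix <- function(x, arg = "x") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      abort(sprintf("`%s` must have gene identifiers as rownames", arg))
    }
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.data.frame(x)) {
    genes <- as.character(x[[1L]])
    m <- as.matrix(x[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
    return(m)
  }
  abort(sprintf("`%s` must be a matrix or a data frame", arg))
}

# Inverse of as_expr_matrix(): matrix -> tibble with a leading gene column.
expr_as_tibble <- function(m, id = "gene") {
  out <- as_tibble(m, rownames = id)
  out
}

check_no_missing <- function(m, what) {
  if (anyNA(m)) abort(sprintf("%s contains missing values; imputation is not supported", what))
  invisible(m)
}

check_unique <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup)) {
    abort(sprintf("duplicate %s: %s", what, paste(utils::head(dup, 5), collapse = ", ")))
  }
  invisible(x)
}

# Named numeric vector from a two-column data frame or a named vector.
as_named_numeric <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    v <- as.numeric(x[[2L]])
    names(v) <- as.character(x[[1L]])
    return(v)
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  abort(sprintf("`%s` must be a named numeric vector or a two-column data frame", arg))
}

# Moore-Penrose pseudo-inverse via SVD; returns the pinv and the numerical rank.
pseudo_inverse <- function(m, tol = NULL) {
  sv <- svd(m)
  if (is.null(tol)) tol <- max(dim(m)) * .Machine$double.eps * sv$d[1L]
  keep <- sv$d > tol
  rank <- sum(keep)
  if (rank == 0L) {
    return(list(pinv = matrix(0, ncol(m), nrow(m)), rank = 0L))
  }
  pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  list(pinv = pinv, rank = rank)
}

# Deterministic seed stream: k seeds derived from one master seed, all < 2^31.
derive_seeds <- function(master_seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, k)
}

# Run code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# Write a numeric matrix as TSV with a leading id column, at a fixed number of
# significant digits so repeated runs are byte-identical.
write_matrix_tsv <- function(m, path, id = "gene", digits = 10) {
  df <- as.data.frame(signif(m, digits))
  df <- cbind(stats::setNames(data.frame(rownames(m), stringsAsFactors = FALSE), id), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path, id = "gene") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}
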