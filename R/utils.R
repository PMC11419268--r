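# Internal helpers shared across the package.

#' @keywords internal
"_PACKAGE"

# Validate and normalize a feature-by-sample data matrix.
# Features in rows, samples in columns; ids are required downstream, so
# deterministic placeholders are generated when dimnames are absent.
as_data_matrix <- function(x, arg = deparse(substitute(x))) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric feature-by-sample matrix", arg),
         call. = FALSE)
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop(sprintf("`%s` must have at least 2 features and 2 samples (got %d x %d)",
                 arg, nrow(x), ncol(x)), call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- sprintf("feature_%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("sample_%d", seq_len(ncol(x)))
  check_finite(x, arg)
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    stop(sprintf("`%s` has duplicated feature ids: %s", arg,
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    dup <- unique(colnames(x)[duplicated(colnames(x))])
    stop(sprintf("`%s` has duplicated sample ids: %s", arg,
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
  x
}

check_finite <- function(x, arg) {
  bad <- which(!is.finite(x))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(x)) + 1L
    stop(sprintf(
      "`%s` contains %d non-finite value(s); first at feature '%s', sample '%s'",
      arg, length(bad),
      if (is.null(rownames(x))) i else rownames(x)[i],
      if (is.null(colnames(x))) j else colnames(x)[j]), call. = FALSE)
  }
  invisible(x)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Fix loading signs: the entry of largest absolute value in each column is
# made positive; ties break at the lowest feature index (which.max's rule).
fix_signs <- function(loadings) {
  flip <- vapply(seq_len(ncol(loadings)), function(j) {
    col <- loadings[, j]
    col[which.max(abs(col))] < 0
  }, logical(1L))
  loadings[, flip] <- -loadings[, flip, drop = FALSE]
  list(loadings = loadings, flipped = flip)
}

paca_version <- function() {
  as.character(utils::packageVersion("paca"))
}
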