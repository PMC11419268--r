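#' Read a feature-by-sample matrix from delimited text
#'
#' Reads a TSV (default) or CSV matrix with features in rows: the first
#' column holds feature ids, the header row holds sample ids. Gzip
#' compression is handled transparently. All values are parsed as doubles
#' and validated (finite, unique ids).
#'
#' @param path file path; `.csv` / `.csv.gz` extensions switch the
#'   delimiter to comma unless `sep` is given.
#' @param sep field delimiter; inferred from the extension when `NULL`.
#' @param samples_in_rows transpose on read, for tables stored with
#'   samples in rows.
#' @return A validated numeric matrix with feature rownames and sample
#'   colnames.
#' @export
read_matrix <- function(path, sep = NULL, samples_in_rows = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(sep)) sep <- infer_sep(path)
  d <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "",
                      comment.char = "", check.names = FALSE,
                      stringsAsFactors = FALSE, colClasses = NA),
    error = function(e) {
      stop(sprintf("failed to parse '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  if (nrow(d) == 0L || ncol(d) < 2L) {
    stop(sprintf("'%s' holds no data rows/columns", path), call. = FALSE)
  }
  ids <- as.character(d[[1L]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicated feature id(s) in '%s': %s", path,
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
  samples <- colnames(d)[-1L]
  if (anyDuplicated(samples)) {
    dup <- unique(samples[duplicated(samples)])
    stop(sprintf("duplicated sample id(s) in '%s': %s", path,
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
  vals <- d[, -1L, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1L))
  if (any(nonnum)) {
    j <- which(nonnum)[1L]
    col <- suppressWarnings(as.numeric(vals[[j]]))
    i <- which(is.na(col) & !is.na(vals[[j]]))[1L]
    stop(sprintf("non-numeric value '%s' in '%s' (feature '%s', sample '%s')",
                 vals[[j]][i], path, ids[i], samples[j]), call. = FALSE)
  }
  x <- as.matrix(vals)
  dimnames(x) <- list(ids, samples)
  if (samples_in_rows) x <- t(x)
  as_data_matrix(x, path)
}

infer_sep <- function(path) {
  if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
}

#' Write a feature-by-sample matrix as delimited text
#'
#' Inverse of [read_matrix()]: writes feature ids in the first column
#' (header `feature_id`) and sample ids in the header. Values are written
#' with 17 significant digits, so a read/write round trip is lossless.
#' A `.gz` extension triggers gzip compression.
#'
#' @param x numeric matrix with feature rownames and sample colnames.
#' @param path output path.
#' @param sep field delimiter; inferred from the extension when `NULL`.
#' @export
write_matrix <- function(x, path, sep = NULL) {
  x <- as_data_matrix(x, "x")
  if (is.null(sep)) sep <- infer_sep(path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(x)), collapse = sep), con)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = sep)
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Align two matrices to a common feature set
#'
#' Reorders (and optionally subsets) two feature-by-sample matrices so that
#' both carry the identical, lexicographically sorted feature list —
#' the precondition of [paca()] and of projecting a model across cohorts.
#'
#' @param X,Y feature-by-sample matrices.
#' @param policy `"intersect"` keeps the common features (error when the
#'   intersection is empty, message with drop counts otherwise);
#'   `"strict"` requires identical feature sets and errors on any
#'   difference.
#' @return A list with the two aligned matrices `X` and `Y`.
#' @export
align_features <- function(X, Y, policy = c("intersect", "strict")) {
  policy <- match.arg(policy)
  X <- as_data_matrix(X, "X")
  Y <- as_data_matrix(Y, "Y")
  fx <- rownames(X); fy <- rownames(Y)
  common <- intersect(fx, fy)
  if (policy == "strict") {
    only_x <- setdiff(fx, fy); only_y <- setdiff(fy, fx)
    if (length(only_x) || length(only_y)) {
      fmt <- function(v) paste(utils::head(v, 5L), collapse = ", ")
      stop(sprintf(
        "strict alignment failed: %d feature(s) only in X (%s), %d only in Y (%s)",
        length(only_x), fmt(only_x), length(only_y), fmt(only_y)),
        call. = FALSE)
    }
  }
  if (length(common) == 0L) {
    stop("the feature sets of X and Y do not intersect", call. = FALSE)
  }
  dropped_x <- length(fx) - length(common)
  dropped_y <- length(fy) - length(common)
  if (dropped_x || dropped_y) {
    message(sprintf("align_features: dropping %d feature(s) from X and %d from Y",
                    dropped_x, dropped_y))
  }
  common <- sort(common, method = "radix")
  list(X = X[common, , drop = FALSE], Y = Y[common, , drop = FALSE])
}

#' Save a fitted PACA model as a structured JSON archive
#'
#' Serializes everything [predict.paca()] needs (feature ids, bases,
#' centering and sign conventions, version tag) with full double precision,
#' so a load/save round trip reproduces scores exactly.
#'
#' @param object a fitted `"paca"` or `"rpaca"` model.
#' @param path output path (conventionally `.json`).
#' @export
write_paca_model <- function(object, path) {
  stopifnot(inherits(object, "paca"))
  pack <- function(m) list(dim = dim(m), values = as.vector(m))
  archive <- list(
    package = "paca",
    version = paca_version(),
    class = class(object),
    feature_ids = object$feature_ids,
    sample_ids = object$sample_ids,
    k = object$k,
    k1 = object$k1,
    ridge = object$ridge,
    centering = object$centering,
    center_features = isTRUE(object$center_features),
    feature_means = object$feature_means,
    sign_convention = object$sign_convention,
    u0 = pack(object$u0),
    u1 = pack(object$u1),
    eigenvalues = object$eigenvalues,
    correlations = if (is.null(object$cca)) numeric(0) else object$cca$cor
  )
  jsonlite::write_json(archive, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a PACA model archive written by [write_paca_model()]
#'
#' @param path archive path.
#' @return A `"paca"` (or `"rpaca"`) model usable with [predict.paca()].
#' @export
read_paca_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  archive <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop(sprintf("corrupted model archive '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
                      })
  if (!identical(archive$package, "paca") || is.null(archive$u1)) {
    stop(sprintf("'%s' is not a PACA model archive", path), call. = FALSE)
  }
  major <- function(v) as.integer(strsplit(v, ".", fixed = TRUE)[[1L]][1L])
  if (major(archive$version) > major(paca_version())) {
    stop(sprintf("model archive version %s is newer than the installed package (%s)",
                 archive$version, paca_version()), call. = FALSE)
  }
  unpack <- function(p) {
    matrix(as.numeric(unlist(p$values)), p$dim[1L], p$dim[2L])
  }
  u0 <- unpack(archive$u0)
  u1 <- unpack(archive$u1)
  rownames(u0) <- rownames(u1) <- archive$feature_ids
  colnames(u1) <- sprintf("PACA%d", seq_len(ncol(u1)))
  fm <- archive$feature_means
  if (length(fm)) names(fm) <- archive$feature_ids else fm <- NULL
  structure(list(
    feature_ids = archive$feature_ids,
    sample_ids = archive$sample_ids,
    k = archive$k,
    k1 = archive$k1,
    ridge = archive$ridge,
    centering = archive$centering,
    center_features = isTRUE(archive$center_features),
    feature_means = fm,
    sign_convention = archive$sign_convention,
    cca = if (length(archive$correlations)) list(cor = archive$correlations),
    u0 = u0,
    u1 = u1,
    eigenvalues = archive$eigenvalues,
    scores = NULL,
    version = archive$version
  ), class = archive$class)
}

#' Write component scores as TSV
#'
#' @param scores a score matrix with sample rownames (or a fitted `"paca"`
#'   model, whose training scores are written).
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  if (inherits(scores, "paca")) scores <- scores$scores
  scores <- as.matrix(scores)
  if (is.null(rownames(scores))) {
    stop("`scores` must carry sample ids as rownames", call. = FALSE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(scores)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(scores)), function(i) {
    paste(c(rownames(scores)[i], sprintf("%.17g", scores[i, ])),
          collapse = "\t")
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}
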