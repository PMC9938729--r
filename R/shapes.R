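#' Helmert submatrix
#'
#' The (k-1) x k submatrix of the Helmert matrix (Dryden-Mardia convention):
#' row j has j leading entries h_j = -(j(j+1))^{-1/2} followed by -j h_j and
#' zeros.  Rows are orthonormal and annihilate the constant vector, so left
#' multiplication removes the centroid (translation) of a configuration.
#'
#' @param k number of landmarks, k >= 2.
#' @export
helmert_submatrix <- function(k) {
  if (k < 2) stop_dim("k must be at least 2")
  H <- matrix(0, k - 1, k)
  for (j in seq_len(k - 1)) {
    h <- -1 / sqrt(j * (j + 1))
    H[j, seq_len(j)] <- h
    H[j, j + 1] <- -j * h
  }
  H
}

#' Planar shape as a point of the complex Grassmannian
#'
#' Kendall's shape space of k planar landmarks modulo similarity transforms
#' is isometric to CP^{k-2} = Gr(1, C^{k-1}): complexify the landmarks as
#' x + iy, remove translation with the Helmert submatrix, remove scale by
#' normalization (the pre-shape), and quotient rotation algebraically --
#' rotating a shape multiplies the pre-shape by a unit-modulus scalar, which
#' leaves the spanned complex line unchanged.
#'
#' @param landmarks a k x 2 real matrix, k > 2, not all rows identical.
#' @return a (k-1) x 1 complex unit-norm matrix representing a point of
#'   Gr(1, C^{k-1}).
#' @export
shape_to_grassmann <- function(landmarks) {
  X <- as.matrix(landmarks)
  if (ncol(X) != 2) stop_dim("landmarks must be a k x 2 matrix")
  k <- nrow(X)
  if (k <= 2) stop_dim("at least 3 landmarks required")
  z <- complex(real = X[, 1], imaginary = X[, 2])
  w <- helmert_submatrix(k) %*% z
  nw <- sqrt(sum(Mod(w)^2))
  if (nw < 1e-12) stop("degenerate configuration: all landmarks coincide", call. = FALSE)
  canonical_line(matrix(w / nw, ncol = 1))
}

#' Read landmark configurations from a directory
#'
#' Expects a \code{manifest.txt} listing one shape file per line (optionally
#' followed by an integer label, whitespace separated) and, per shape, a
#' k x 2 whitespace-delimited text file of landmark coordinates.
#'
#' @param dir directory containing \code{manifest.txt} and the shape files.
#' @return list with \code{shapes} (list of k x 2 matrices, in manifest
#'   order) and \code{labels} (integer vector or NULL).
#' @export
read_landmarks <- function(dir) {
  mf <- file.path(dir, "manifest.txt")
  if (!file.exists(mf)) stop(sprintf("manifest not found: %s", mf), call. = FALSE)
  lines <- readLines(mf)
  lines <- lines[nzchar(trimws(lines))]
  shapes <- list(); labels <- integer(0); any_label <- FALSE
  for (ln in seq_along(lines)) {
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    f <- file.path(dir, parts[1])
    if (!file.exists(f))
      stop(sprintf("manifest entry %d: file not found: %s", ln, parts[1]), call. = FALSE)
    shapes[[ln]] <- read_matrix_file(f, what = "landmarks")
    if (ncol(shapes[[ln]]) != 2)
      stop(sprintf("%s: expected 2 columns of coordinates", parts[1]), call. = FALSE)
    if (length(parts) > 1) {
      any_label <- TRUE
      labels[ln] <- as.integer(parts[2])
    } else labels[ln] <- NA_integer_
  }
  list(shapes = shapes, labels = if (any_label) labels else NULL)
}

#' Write landmark configurations to a directory
#'
#' Inverse of \code{\link{read_landmarks}}; values are written with full
#' precision so a read/write round trip is exact.
#'
#' @param shapes list of k x 2 matrices.
#' @param dir output directory (created if needed).
#' @param labels optional integer labels recorded in the manifest.
#' @export
write_landmarks <- function(shapes, dir, labels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("shape_%03d.txt", seq_along(shapes))
  for (i in seq_along(shapes)) {
    write_matrix_file(as.matrix(shapes[[i]]), file.path(dir, files[i]))
  }
  entries <- if (is.null(labels)) files else paste(files, as.integer(labels))
  writeLines(entries, file.path(dir, "manifest.txt"))
  invisible(files)
}

# -- plain-text matrix files (real or complex) -------------------------------

write_matrix_file <- function(M, path) {
  fmt <- function(x) {
    if (is.complex(x)) sprintf("%.17g%+.17gi", Re(x), Im(x)) else sprintf("%.17g", x)
  }
  rows <- apply(M, 1, function(r) paste(fmt(r), collapse = "\t"))
  writeLines(rows, path)
}

read_matrix_file <- function(path, what = "matrix") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
    vals <- suppressWarnings(as.complex(sub("j$", "i", parts)))
    if (anyNA(vals))
      stop(sprintf("%s: non-numeric value on line %d of %s", what, i, path),
           call. = FALSE)
    vals
  })
  len <- lengths(rows)
  if (any(len != len[1]))
    stop(sprintf("%s: ragged row on line %d of %s", what, which(len != len[1])[1], path),
         call. = FALSE)
  M <- do.call(rbind, rows)
  if (all(Im(M) == 0)) M <- Re(M)
  M
}

#' Read/write a dataset of subspaces
#'
#' Subspace datasets are stored as a directory of per-sample delimited-text
#' basis matrices (rows = ambient dimension, columns = subspace dimension;
#' complex entries as \code{a+bi} or \code{a+bj}) plus a \code{manifest.txt}
#' fixing sample order (with optional integer labels) and a JSON sidecar
#' \code{dataset.json} recording n, p and the field.
#'
#' @param dir dataset directory.
#' @return \code{read_subspaces}: list with \code{data}, \code{labels},
#'   \code{n}, \code{p}, \code{field}.
#' @export
read_subspaces <- function(dir) {
  mf <- file.path(dir, "manifest.txt")
  if (!file.exists(mf)) stop(sprintf("manifest not found: %s", mf), call. = FALSE)
  lines <- readLines(mf)
  lines <- lines[nzchar(trimws(lines))]
  data <- list(); labels <- integer(0); any_label <- FALSE
  for (ln in seq_along(lines)) {
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    f <- file.path(dir, parts[1])
    if (!file.exists(f))
      stop(sprintf("manifest entry %d: file not found: %s", ln, parts[1]), call. = FALSE)
    data[[ln]] <- read_matrix_file(f, what = "subspace")
    if (length(parts) > 1) { any_label <- TRUE; labels[ln] <- as.integer(parts[2]) }
    else labels[ln] <- NA_integer_
  }
  info <- check_dataset(data)
  list(data = data, labels = if (any_label) labels else NULL,
       n = info$n, p = info$p, field = info$field)
}

#' @rdname read_subspaces
#' @param data list of basis matrices.
#' @param labels optional integer labels.
#' @export
write_subspaces <- function(data, dir, labels = NULL) {
  info <- check_dataset(data)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("sample_%04d.txt", seq_along(data))
  for (i in seq_along(data)) write_matrix_file(data[[i]], file.path(dir, files[i]))
  entries <- if (is.null(labels)) files else paste(files, as.integer(labels))
  writeLines(entries, file.path(dir, "manifest.txt"))
  writeLines(jsonlite::toJSON(list(n = info$n, p = info$p, field = info$field,
                                   N = length(data)), auto_unbox = TRUE),
             file.path(dir, "dataset.json"))
  invisible(files)
}
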