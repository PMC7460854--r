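#' Read a dense or MatrixMarket matrix
#'
#' Reads an expression or similarity matrix from disk. Dense CSV/TSV files
#' must have a header of column ids and a first column of row ids; the
#' delimiter is inferred from the extension (`.csv` vs `.tsv`/`.txt`) or from
#' the header line. MatrixMarket (`.mtx`) input is densified and requires
#' companion id files (one id per line): `<stem>_rows.txt` / `<stem>_cols.txt`
#' next to the file, or paths given explicitly.
#'
#' @param path File path.
#' @param cells_in For expression matrices, `"rows"` (default) or
#'   `"columns"`; the matrix is transposed to cells-in-rows on read.
#' @param type `"expression"` (default) or `"kernel"`. Kernel ingest applies
#'   the symmetrization policy of [as_kernel()].
#' @param row_ids,col_ids Optional paths to id files for MTX input.
#' @return A numeric matrix with dimnames; for `type = "kernel"`, symmetrized
#'   with the `symmetrized` attribute set.
#' @export
read_matrix <- function(path, cells_in = c("rows", "columns"),
                        type = c("expression", "kernel"),
                        row_ids = NULL, col_ids = NULL) {
  cells_in <- match.arg(cells_in)
  type <- match.arg(type)
  if (!file.exists(path)) stop(sprintf("File not found: %s", path), call. = FALSE)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- read_mtx_dense(path, row_ids, col_ids)
  } else {
    m <- read_dense(path)
  }
  if (cells_in == "columns" && type == "expression") m <- t(m)
  if (type == "kernel") {
    if (nrow(m) != ncol(m)) {
      stop(sprintf("Kernel matrix must be square; got %d x %d.", nrow(m), ncol(m)),
           call. = FALSE)
    }
    dn <- rownames(m)
    m <- as_kernel(m)
    rownames(m) <- colnames(m) <- dn
  }
  m
}

read_dense <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else
    if (grepl("\t", header, fixed = TRUE)) "\t" else if (grepl(",", header, fixed = TRUE)) "," else "\t"
  # utils::read.table parses doubles via strtod (correctly rounded), so
  # write -> read round-trips are bit-exact
  df <- utils::read.table(path, header = TRUE, sep = delim, check.names = FALSE,
                          comment.char = "", quote = "\"")
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad)) {
    stop(sprintf("Non-numeric values in column(s): %s of %s",
                 paste(names(vals)[bad], collapse = ", "), path), call. = FALSE)
  }
  m <- as.matrix(vals)
  if (anyNA(m)) {
    i <- which(rowSums(is.na(m)) > 0)[1L]
    stop(sprintf("Missing/unparseable value at data line %d of %s", i, path),
         call. = FALSE)
  }
  rownames(m) <- ids
  m
}

read_mtx_dense <- function(path, row_ids = NULL, col_ids = NULL) {
  m <- as.matrix(Matrix::readMM(path))
  stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
  row_ids <- row_ids %||% paste0(stem, "_rows.txt")
  col_ids <- col_ids %||% paste0(stem, "_cols.txt")
  if (file.exists(row_ids)) {
    ids <- readLines(row_ids)
    if (length(ids) != nrow(m)) {
      stop(sprintf("Row id file %s has %d ids but matrix has %d rows.",
                   row_ids, length(ids), nrow(m)), call. = FALSE)
    }
    rownames(m) <- ids
  }
  if (file.exists(col_ids)) {
    ids <- readLines(col_ids)
    if (length(ids) != ncol(m)) {
      stop(sprintf("Column id file %s has %d ids but matrix has %d columns.",
                   col_ids, length(ids), ncol(m)), call. = FALSE)
    }
    colnames(m) <- ids
  }
  m
}

#' Write a matrix as delimited text
#'
#' Writes with row ids in the first column (`id`) and column ids in the
#' header, at full double precision so that write-then-read round-trips are
#' bit-exact. Delimiter follows the extension (`.csv` comma, else tab).
#'
#' @param m Numeric matrix with dimnames (defaults generated if absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  rn <- rownames(m) %||% paste0("row", seq_len(nrow(m)))
  cn <- colnames(m) %||% paste0("col", seq_len(ncol(m)))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  fm <- apply(m, 2L, function(col) sprintf("%.17g", col))
  if (nrow(m) == 1L) fm <- matrix(fm, nrow = 1L)
  df <- data.frame(id = rn, fm, check.names = FALSE)
  colnames(df) <- c("id", cn)
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read cluster labels
#'
#' Reads a two-column delimited file `(cell_id, cluster)`; a header line is
#' detected and skipped when present. When `cell_ids` is given, labels are
#' joined to that order and unmatched ids on either side are an error.
#'
#' @param path File path (TSV or CSV).
#' @param cell_ids Optional character vector giving the matrix's row order.
#' @return A named character vector of labels (names = cell ids) with a
#'   `"classes"` attribute in first-appearance order.
#' @export
read_labels <- function(path, cell_ids = NULL) {
  if (!file.exists(path)) stop(sprintf("File not found: %s", path), call. = FALSE)
  first <- strsplit(readLines(path, n = 1L), "[\t,]")[[1]]
  has_header <- length(first) >= 2 &&
    any(tolower(first) %in% c("cell_id", "cell", "id", "cluster", "label", "branch"))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_names = has_header,
                          col_types = readr::cols(.default = readr::col_character()),
                          show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) stop("Label file needs two columns (cell_id, cluster).", call. = FALSE)
  lab <- stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  if (anyDuplicated(names(lab))) {
    stop(sprintf("Duplicate cell ids in %s: %s", path,
                 paste(unique(names(lab)[duplicated(names(lab))]), collapse = ", ")),
         call. = FALSE)
  }
  lab <- as_cluster_labels(lab)
  if (!is.null(cell_ids)) lab <- align_labels(lab, cell_ids, length(cell_ids))
  lab
}

#' Write an embedding as CSV
#'
#' Columns `cell_id`, `dim1..dimk`, `cluster`, at full precision.
#'
#' @param fit Fitted `"sspca"` object, or a tibble from [augment.sspca()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(fit, path) {
  df <- if (inherits(fit, "sspca")) augment(fit) else fit
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ sprintf("%.17g", .x)))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Save and load a fitted ssPCA model
#'
#' Plain-text, versioned persistence of a fit: header lines (`#sspca-model`
#' version, lambda, k, class order) followed by a tab-separated table with
#' cell ids, cluster labels and the columns of `W`; eigenvalues on a header
#' line. Values are written at full double precision, so `Z = K_X W` is
#' bit-reproducible from the reloaded model and the kernel.
#'
#' @param fit Fitted `"sspca"` object.
#' @param path Output path.
#' @return `write_sspca_model()` returns `path` invisibly;
#'   `read_sspca_model()` returns an `"sspca"` object (without the cached
#'   embedding — recompute with `predict(model, kx)`).
#' @export
write_sspca_model <- function(fit, path) {
  stopifnot(inherits(fit, "sspca"))
  hdr <- c(
    "#sspca-model v1",
    paste0("#lambda\t", sprintf("%.17g", fit$lambda)),
    paste0("#k\t", fit$k),
    paste0("#eigenvalues\t", paste(sprintf("%.17g", fit$eigenvalues), collapse = "\t")),
    paste0("#classes\t", paste(fit$class_order, collapse = "\t"))
  )
  body <- data.frame(cell_id = fit$cell_ids, cluster = fit$labels,
                     apply(fit$W, 2L, sprintf, fmt = "%.17g"),
                     check.names = FALSE)
  colnames(body) <- c("cell_id", "cluster", paste0("w", seq_len(fit$k)))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(body, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_sspca_model
#' @export
read_sspca_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "#sspca-model")) {
    stop(sprintf("%s is not an ssPCA model file.", path), call. = FALSE)
  }
  hdr <- lines[startsWith(lines, "#")]
  get_field <- function(name) {
    ln <- hdr[startsWith(hdr, paste0("#", name, "\t"))]
    strsplit(sub(paste0("^#", name, "\t"), "", ln), "\t")[[1]]
  }
  lambda <- as.numeric(get_field("lambda"))
  k <- as.integer(get_field("k"))
  eigenvalues <- as.numeric(get_field("eigenvalues"))
  classes <- get_field("classes")
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            header = TRUE, sep = "\t", colClasses = "character")
  W <- as.matrix(vapply(body[, paste0("w", seq_len(k)), drop = FALSE],
                        as.numeric, numeric(nrow(body))))
  rownames(W) <- body$cell_id
  structure(list(
    W = W, eigenvalues = eigenvalues, embedding = NULL,
    lambda = lambda, k = k, n = nrow(W),
    cell_ids = body$cell_id, labels = body$cluster, class_order = classes,
    kernel = "precomputed", sigma = NULL, eig_tol = 1e-10,
    n_degenerate = sum(eigenvalues < 1e-10)
  ), class = "sspca")
}

#' Write tree-simulation artifacts
#'
#' Writes `<prefix>_X.tsv` (data matrix), `<prefix>_labels.tsv`
#' (cell_id, branch) and `<prefix>_topology.tsv` (branch, parent).
#'
#' @param sim A `"tree_sim"` object.
#' @param prefix Output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_tree <- function(sim, prefix) {
  stopifnot(inherits(sim, "tree_sim"))
  paths <- paste0(prefix, c("_X.tsv", "_labels.tsv", "_topology.tsv"))
  colnames(sim$X) <- paste0("dim", seq_len(ncol(sim$X)))
  write_matrix(sim$X, paths[1])
  readr::write_tsv(tibble::tibble(cell_id = rownames(sim$X),
                                  cluster = paste0("branch", sim$branch)),
                   paths[2], progress = FALSE)
  readr::write_tsv(sim$topology, paths[3], progress = FALSE)
  invisible(paths)
}
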