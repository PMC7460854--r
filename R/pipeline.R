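#' Run the full ssPCA pipeline
#'
#' End-to-end run: read (or accept in-memory) inputs, build the kernel, fit
#' ssPCA, and write the artifacts — embedding CSV, plain-text model file,
#' scatter plot of dims 1-2 colored by cluster, a JSON structure report, and
#' a log recording every defaulted parameter (kernel spec, bandwidth, lambda,
#' k, eigenvalues, warnings) so runs are reconstructible. Identical inputs
#' and configuration produce byte-identical text outputs (the plot, being an
#' image, is excluded from that guarantee).
#'
#' @param x Expression or kernel input: a file path (dense CSV/TSV or `.mtx`)
#'   or an in-memory matrix.
#' @param labels Labels: a file path (two-column TSV/CSV) or an in-memory
#'   vector / two-column data frame.
#' @param out_prefix Output path prefix; artifacts are written as
#'   `<prefix>_embedding.csv`, `<prefix>_model.tsv`, `<prefix>_plot.png`,
#'   `<prefix>_report.json`, `<prefix>_log.txt`.
#' @param lambda,k,kernel,sigma,poly_c,poly_d Passed to [sspca()].
#' @param cells_in Orientation of an expression input file.
#' @param reference Optional reference coordinates (matrix or file path) for
#'   the global structure metric.
#' @param knn_k Neighbors for the k-NN agreement metric (default 10).
#' @param write_plot Write the PNG scatter plot (default TRUE).
#' @return Invisibly, a list with the fitted `model`, the `embedding` tibble,
#'   the `report` tibble, and the artifact `paths`.
#' @export
run_sspca_pipeline <- function(x, labels, out_prefix,
                               lambda = 0.75, k = 2,
                               kernel = c("precomputed", "linear", "poly", "rbf"),
                               sigma = "median", poly_c = 1, poly_d = 2,
                               cells_in = "rows", reference = NULL, knn_k = 10,
                               write_plot = TRUE) {
  kernel <- match.arg(kernel)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (is.character(x) && length(x) == 1L) {
    note("input: %s (%s)", x, if (kernel == "precomputed") "kernel" else "expression")
    x <- read_matrix(x, cells_in = cells_in,
                     type = if (kernel == "precomputed") "kernel" else "expression")
  }
  if (is.character(labels) && length(labels) == 1L) {
    note("labels: %s", labels)
    labels <- read_labels(labels, cell_ids = rownames(x))
  }

  warn_log <- character()
  fit <- withCallingHandlers(
    sspca(x, labels, lambda = lambda, k = k, kernel = kernel,
          sigma = sigma, poly_c = poly_c, poly_d = poly_d),
    warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  note("kernel: %s%s", kernel,
       if (!is.null(fit$sigma)) sprintf(" (sigma = %.17g)", fit$sigma) else "")
  note("lambda: %g; k: %d; n: %d; clusters: %d", fit$lambda, fit$k, fit$n,
       length(fit$class_order))
  note("eigenvalues: %s", paste(format(fit$eigenvalues, digits = 17), collapse = ", "))
  for (w in warn_log) note("warning: %s", w)

  if (is.character(reference) && length(reference) == 1L) {
    reference <- read_matrix(reference, cells_in = cells_in, type = "expression")
  }
  report <- structure_report(fit$embedding, fit$labels, reference = reference, k = knn_k)
  note("report: knn_agreement = %.6f; silhouette = %.6f; centroid_dist_corr = %s",
       report$knn_agreement, report$silhouette,
       if (is.na(report$centroid_dist_corr)) "NA" else sprintf("%.6f", report$centroid_dist_corr))

  paths <- list(
    embedding = paste0(out_prefix, "_embedding.csv"),
    model = paste0(out_prefix, "_model.tsv"),
    plot = paste0(out_prefix, "_plot.png"),
    report = paste0(out_prefix, "_report.json"),
    log = paste0(out_prefix, "_log.txt")
  )
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  write_embedding(fit, paths$embedding)
  write_sspca_model(fit, paths$model)
  jsonlite::write_json(as.list(report), paths$report, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  if (write_plot) {
    p <- autoplot(fit)
    suppressMessages(ggplot2::ggsave(paths$plot, p, width = 7, height = 5, dpi = 150))
  } else {
    paths$plot <- NULL
  }
  writeLines(log_lines, paths$log)

  invisible(list(model = fit, embedding = augment(fit), report = report,
                 paths = paths))
}

#' Compare ssPCA embeddings over a lambda grid
#'
#' Fits ssPCA at each value of `lambda_grid` on a fixed kernel and labels and
#' reports the structure metrics per lambda — the standard robustness check
#' that the embedding is stable over the trade-off parameter.
#'
#' @inheritParams run_sspca_pipeline
#' @param lambda_grid Numeric vector of lambda values (default
#'   `c(0.25, 0.5, 0.75, 1)`).
#' @return A tibble with one row per lambda: the metrics of
#'   [structure_report()] plus `lambda`, and the fitted models as an
#'   attribute `"fits"`.
#' @export
lambda_robustness <- function(x, labels, lambda_grid = c(0.25, 0.5, 0.75, 1),
                              k = 2, kernel = "precomputed", sigma = "median",
                              reference = NULL, knn_k = 10) {
  fits <- purrr::map(lambda_grid, function(lam) {
    suppressWarnings(sspca(x, labels, lambda = lam, k = k, kernel = kernel,
                           sigma = sigma))
  })
  out <- purrr::map2_dfr(fits, lambda_grid, function(fit, lam) {
    dplyr::mutate(
      structure_report(fit$embedding, fit$labels, reference = reference, k = knn_k),
      lambda = lam, .before = 1
    )
  })
  attr(out, "fits") <- fits
  out
}
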