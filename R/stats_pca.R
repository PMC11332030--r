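#' Principal-component analysis with varimax rotation
#'
#' Summarizes per-participant condition scores (canonically the normalized
#' PLVs in the eight synchronization conditions) in a small number of
#' components. Variables are standardized, the correlation matrix is
#' eigen-decomposed, components are retained by the Kaiser-Guttman
#' criterion (eigenvalue >= 1) or a fixed count, and retained components
#' are varimax-rotated (orthogonal, Kaiser-normalized). Each rotated
#' component's sign is fixed so its largest-magnitude loading is positive.
#'
#' @param scores numeric matrix or data frame, participants x conditions.
#' @param retain `"kaiser"` (eigenvalue >= 1) or `"fixed"`.
#' @param k number of components when `retain = "fixed"`.
#' @param rotate `"varimax"` or `"none"`.
#' @return A `component_solution`: `eigenvalues`, `n_retained`,
#'   `rotated_loadings` (condition x component), `unrotated_loadings`,
#'   `variance_explained` (fraction of total variance in the retained
#'   components), `rotation`, `communalities`.
#' @export
pca_varimax <- function(scores, retain = c("kaiser", "fixed"), k = NULL,
                        rotate = c("varimax", "none")) {
  retain <- match.arg(retain)
  rotate <- match.arg(rotate)
  x <- as.matrix(scores)
  if (anyNA(x)) stop_invalid("scores must have no missing cells")
  p <- ncol(x)
  sds <- apply(x, 2, sd)
  if (any(sds < .Machine$double.eps^0.5)) {
    stop_invalid("constant column(s): ",
                 toString(colnames(x)[sds < .Machine$double.eps^0.5]))
  }
  if (nrow(x) < 2 * p) {
    warning("fewer than 2x as many participants as conditions; ",
            "component solution may be unstable")
  }
  C <- cor(x)
  ee <- eigen(C, symmetric = TRUE)
  evals <- ee$values
  m <- if (retain == "kaiser") sum(evals >= 1) else {
    if (is.null(k)) stop_invalid("k required when retain = 'fixed'")
    as.integer(k)
  }
  if (m < 1) stop_invalid("no components retained")
  load_unrot <- ee$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(evals[seq_len(m)]), m)
  rownames(load_unrot) <- colnames(x)
  if (rotate == "varimax" && m > 1) {
    rot <- varimax(load_unrot, normalize = TRUE, eps = 1e-6)
    load_rot <- unclass(rot$loadings)
  } else {
    load_rot <- load_unrot
  }
  # sign convention: largest-magnitude loading per component positive
  for (j in seq_len(ncol(load_rot))) {
    i <- which.max(abs(load_rot[, j]))
    if (load_rot[i, j] < 0) load_rot[, j] <- -load_rot[, j]
  }
  # order components by explained variance after rotation
  ssq <- colSums(load_rot^2)
  ord <- order(ssq, decreasing = TRUE)
  load_rot <- load_rot[, ord, drop = FALSE]
  colnames(load_rot) <- paste0("RC", seq_len(m))
  structure(list(eigenvalues = evals, n_retained = m,
                 rotated_loadings = load_rot,
                 unrotated_loadings = load_unrot,
                 variance_explained = sum(evals[seq_len(m)]) / p,
                 rotation = if (m > 1) rotate else "none",
                 communalities = rowSums(load_rot^2)),
            class = "component_solution")
}

#' @export
print.component_solution <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Component solution: %d retained (%s rotation), %.1f%% variance\n",
    x$n_retained, x$rotation, 100 * x$variance_explained))
  cat("Eigenvalues:", paste(round(x$eigenvalues, digits), collapse = ", "),
      "\n\nRotated loadings:\n")
  print(round(x$rotated_loadings, digits))
  invisible(x)
}

#' Export a component solution as CSV + JSON
#'
#' Writes `<stem>_loadings.csv` (rotated loadings with condition names) and
#' `<stem>.json` (eigenvalues, retention, variance explained).
#'
#' @param solution a `component_solution`.
#' @param stem output path stem.
#' @return `stem`, invisibly.
#' @export
write_component_solution <- function(solution, stem) {
  stopifnot(inherits(solution, "component_solution"))
  df <- data.frame(condition = rownames(solution$rotated_loadings),
                   solution$rotated_loadings,
                   communality = solution$communalities)
  write.csv(df, paste0(stem, "_loadings.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(eigenvalues = solution$eigenvalues,
         n_retained = solution$n_retained,
         variance_explained = solution$variance_explained,
         rotation = solution$rotation),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
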