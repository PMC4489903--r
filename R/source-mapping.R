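#' Minimum-norm inverse operator
#'
#' Tikhonov-regularized pseudoinverse of a leadfield,
#' `W = L' (L L' + lambda I)^-1`, mapping sensor data to vertex
#' currents. With `lambda = 0` and a full-rank square leadfield this is
#' the exact inverse. Any externally computed vertices x sensors matrix
#' can be wrapped with [inverse_operator()] instead; the sensor-to-vertex
#' conversion used downstream is linear either way.
#'
#' @param leadfield sensors x vertices gain matrix (finite entries).
#' @param lambda regularization (>= 0). The default (`NULL`) uses the
#'   mean diagonal of the sensor Gram matrix `L L'` — the average
#'   sensor power produced by unit sources — which keeps the operator's
#'   noise amplification of the same order as its signal gain.
#' @param hemisphere optional factor of vertex hemisphere labels
#'   (`contra`/`ipsi`); taken from `source` when built from a
#'   [source_model()] via [inverse_operator()].
#' @return An `inverse_operator`: list with `matrix`
#'   (vertices x sensors), `hemisphere`, `lambda` and `provenance`.
#' @export
build_min_norm_operator <- function(leadfield, lambda = NULL,
                                    hemisphere = NULL) {
  if (any(!is.finite(leadfield))) stop("`leadfield` must be finite")
  ns <- nrow(leadfield)
  gram0 <- leadfield %*% t(leadfield)
  if (is.null(lambda)) lambda <- mean(diag(gram0))
  if (lambda < 0) stop("`lambda` must be non-negative")
  gram <- gram0 + diag(lambda, ns)
  w <- t(leadfield) %*% solve(gram)
  inverse_operator(w, hemisphere, provenance = sprintf("minimum-norm(%g)", lambda),
                   lambda = lambda)
}

#' Wrap a vertices x sensors matrix as an inverse operator
#'
#' @param matrix vertices x sensors linear operator.
#' @param hemisphere optional factor (`contra`/`ipsi`) per vertex.
#' @param provenance character tag (default `"user-supplied"`).
#' @param lambda regularization used, if known.
#' @return An `inverse_operator`.
#' @export
inverse_operator <- function(matrix, hemisphere = NULL,
                             provenance = "user-supplied", lambda = NA_real_) {
  if (any(!is.finite(matrix))) stop("operator entries must be finite")
  if (!is.null(hemisphere)) {
    hemisphere <- factor(hemisphere, levels = c("contra", "ipsi"))
    if (length(hemisphere) != nrow(matrix) || anyNA(hemisphere))
      stop("`hemisphere` must assign every vertex to contra or ipsi")
  }
  structure(
    list(matrix = matrix, hemisphere = hemisphere,
         provenance = provenance, lambda = lambda),
    class = "inverse_operator"
  )
}

#' Convert sensor features to estimated slow cortical potentials
#'
#' Applies the linear inverse operator to every trial x lag SMF vector,
#' giving estimated slow cortical potentials (eSCPs) on the vertices.
#'
#' @param smf an `smf_set`.
#' @param op an `inverse_operator` whose sensor dimension matches.
#' @return An `escp_set` with `values` (trials x vertices x lags), the
#'   same lag grid and labels, and the operator's hemisphere labels.
#' @export
apply_inverse <- function(smf, op) {
  stopifnot(inherits(op, "inverse_operator"))
  n_sens <- dim(smf$values)[2]
  if (ncol(op$matrix) != n_sens)
    stop(sprintf("operator expects %d sensors, features have %d",
                 ncol(op$matrix), n_sens))
  dm <- dim(smf$values)
  nv <- nrow(op$matrix)
  out <- array(NA_real_, c(dm[1], nv, dm[3]),
               dimnames = list(NULL, rownames(op$matrix), smf$lags))
  for (j in seq_len(dm[3])) {
    m <- smf$values[, , j, drop = FALSE]; dim(m) <- dm[1:2]
    out[, , j] <- m %*% t(op$matrix)
  }
  structure(
    list(values = out, lags = smf$lags, window_ms = smf$window_ms,
         labels = smf$labels,
         channels = rownames(op$matrix) %||% sprintf("V%03d", seq_len(nv)),
         hemisphere = op$hemisphere, feature = "escp"),
    class = c("escp_set", "smf_set")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Keep the vertices of one hemisphere
#'
#' @param escp an `escp_set` with hemisphere labels.
#' @param hemisphere `"contra"` or `"ipsi"`.
#' @return An `escp_set` restricted to that hemisphere's vertices; it
#'   can be fed to the decoders exactly like an `smf_set`.
#' @export
subset_hemisphere <- function(escp, hemisphere = c("contra", "ipsi")) {
  hemisphere <- match.arg(hemisphere)
  if (is.null(escp$hemisphere)) stop("`escp` carries no hemisphere labels")
  keep <- escp$hemisphere == hemisphere
  out <- escp
  out$values <- escp$values[, keep, , drop = FALSE]
  out$channels <- escp$channels[keep]
  out$hemisphere <- escp$hemisphere[keep]
  out
}

#' Per-vertex movement-type contrast map
#'
#' One-way ANOVA of the eSCP across movement types at a single lag
#' (by default the execution cue, 0 ms), one test per vertex. Following
#' the display convention for these maps, vertices are flagged at
#' p < 0.05 without multiple-comparison correction.
#'
#' @param escp an `escp_set`.
#' @param lag lag in ms (must be on the grid; default 0).
#' @param alpha significance threshold for the `significant` flag.
#' @return data.frame with `vertex`, `hemisphere` (if available), `F`,
#'   `p` and `significant`.
#' @export
anova_f_map <- function(escp, lag = 0, alpha = 0.05) {
  check_two_classes(escp$labels)
  x <- smf_at_lag(escp, lag)
  res <- t(apply(x, 2, function(v) {
    ft <- stats::oneway.test(v ~ escp$labels, var.equal = TRUE)
    c(ft$statistic, ft$p.value)
  }))
  out <- data.frame(vertex = escp$channels, F = res[, 1], p = res[, 2],
                    significant = res[, 2] < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(escp$hemisphere))
    out <- cbind(out[1], hemisphere = escp$hemisphere, out[-1])
  out
}

#' Write or read an inverse operator as delimited text
#'
#' The operator matrix is stored as a CSV (vertices in rows) and the
#' vertex table (id, hemisphere) as a TSV sidecar next to it.
#'
#' @param op an `inverse_operator`.
#' @param path CSV path for the matrix; the sidecar gets suffix
#'   `_vertices.tsv`.
#' @return `read_operator_csv` returns the operator; the writer returns
#'   `path` invisibly.
#' @export
write_operator_csv <- function(op, path) {
  utils::write.csv(op$matrix, path, row.names = FALSE)
  side <- sub("\\.csv$", "", path)
  hemi <- if (is.null(op$hemisphere)) NA else as.character(op$hemisphere)
  utils::write.table(
    data.frame(vertex = seq_len(nrow(op$matrix)), hemisphere = hemi),
    paste0(side, "_vertices.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' @rdname write_operator_csv
#' @export
read_operator_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path))
  side <- utils::read.table(paste0(sub("\\.csv$", "", path), "_vertices.tsv"),
                            sep = "\t", header = TRUE)
  hemi <- if (all(is.na(side$hemisphere))) NULL else side$hemisphere
  inverse_operator(unname(m), hemi, provenance = "file")
}
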