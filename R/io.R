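# Plain-text readers and writers. All writers are deterministic: fixed
# column ordering and fixed numeric formatting, so identical inputs yield
# byte-identical files. Dataset matrices use 17 significant digits (exact
# double round-trip); report tables use 10.

fmt_full <- function(x) sprintf("%.17g", x)
fmt_short <- function(x) sprintf("%.10g", x)

#' Write an epoch dataset to a directory container
#'
#' The container is a directory holding `manifest.json` plus one
#' tab-delimited matrix file (electrodes x samples) per signal under
#' `signals/`. The manifest records the sampling rate, baseline length in
#' milliseconds, electrode names, labels and per-signal file references;
#' numbers are written at full precision so [read_dataset()] recovers the
#' arrays exactly and rewriting produces byte-identical files.
#'
#' @param ds an [epoch_dataset()].
#' @param path directory to create (must not be a regular file).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "epoch_dataset"))
  d <- dim(ds$data)
  dir.create(file.path(path, "signals"), recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("signals/sig_%04d.tsv", seq_len(d[1L]))
  manifest <- list(
    version = "erpssid-epochs-1",
    n_signals = d[1L],
    electrode_names = ds$electrode_names,
    sampling_rate_hz = 1 / ds$dt,
    baseline_ms = ds$baseline_samples * ds$dt * 1000,
    n_samples = d[3L],
    labels = ds$labels,
    files = files
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (p in seq_len(d[1L])) {
    m <- matrix(fmt_full(ds$data[p, , ]), d[2L], d[3L])
    writeLines(apply(m, 1L, paste, collapse = "\t"), file.path(path, files[p]))
  }
  invisible(path)
}

#' Read an epoch dataset from a directory container
#'
#' Inverse of [write_dataset()]. Shape inconsistencies are reported naming
#' the offending signal file; both LF and CRLF line endings are accepted.
#'
#' @param path container directory.
#' @return An [epoch_dataset()].
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  rate <- manifest$sampling_rate_hz
  dt <- 1 / rate
  baseline_samples <- manifest$baseline_ms * rate / 1000
  if (abs(baseline_samples - round(baseline_samples)) > 1e-9)
    stop("baseline length ", manifest$baseline_ms,
         " ms is not a whole number of samples at ", rate, " Hz", call. = FALSE)
  Ne <- length(manifest$electrode_names)
  Tn <- manifest$n_samples
  data <- array(0, dim = c(manifest$n_signals, Ne, Tn))
  for (p in seq_len(manifest$n_signals)) {
    f <- file.path(path, manifest$files[p])
    if (!file.exists(f)) stop("missing signal file ", manifest$files[p], call. = FALSE)
    lines <- sub("\r$", "", readLines(f))
    if (length(lines) != Ne)
      stop("signal ", manifest$files[p], ": expected ", Ne,
           " electrode rows, found ", length(lines), call. = FALSE)
    for (e in seq_len(Ne)) {
      v <- as.numeric(strsplit(lines[e], "\t", fixed = TRUE)[[1L]])
      if (length(v) != Tn || anyNA(v))
        stop("signal ", manifest$files[p], ", electrode ",
             manifest$electrode_names[e], ": expected ", Tn,
             " numeric samples", call. = FALSE)
      data[p, e, ] <- v
    }
  }
  epoch_dataset(data, labels = manifest$labels, dt = dt,
                baseline_samples = round(baseline_samples),
                electrode_names = manifest$electrode_names)
}

#' Write a feature matrix as delimited text
#'
#' Tab-separated with a header row: a `label` column followed by the
#' feature names. Deterministic formatting at 10 significant digits.
#'
#' @param fm a `feature_matrix` from [build_feature_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  header <- paste(c("label", fm$feature_names), collapse = "\t")
  rows <- vapply(seq_len(nrow(fm$values)), function(p)
    paste(c(fm$labels[p], fmt_short(fm$values[p, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#'
#' @param path input file.
#' @return A `feature_matrix` (without fit logs).
#' @export
read_features <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  labels <- vapply(body, `[`, character(1), 1L)
  values <- t(vapply(body, function(r) as.numeric(r[-1L]),
                     numeric(length(header) - 1L)))
  colnames(values) <- header[-1L]
  structure(list(values = values, feature_names = header[-1L], labels = labels,
                 fit_orders = NULL, fit_mse = NULL,
                 failed = matrix(FALSE, nrow(values), 0L)),
            class = "feature_matrix")
}

#' Write an evaluation report as delimited text
#'
#' Dispatches on the object: a [compute_metrics()] report becomes a
#' two-line table with the keys in the fixed order ACC, ERR, PRE, SEN, SPE,
#' F1; a [sweep_pcs()] table keeps the fixed column order PC(n), KNN, NB,
#' DT, LDA, SVM, RF; a [knn_grid()] surface is written with its axis
#' labels. All output is tab-separated and deterministic.
#'
#' @param x a `metrics_report`, `sweep_table` or `knn_grid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "metrics_report")) {
    writeLines(c(paste(c("ACC", "ERR", "PRE", "SEN", "SPE", "F1"), collapse = "\t"),
                 paste(fmt_short(c(x$acc, x$err, x$pre, x$sen, x$spe, x$f1)),
                       collapse = "\t")),
               path)
  } else if (inherits(x, "sweep_table")) {
    cols <- c("PC", intersect(algo_names, names(x)))
    header <- paste(c("PC (n)", cols[-1L]), collapse = "\t")
    rows <- vapply(seq_len(nrow(x)), function(r)
      paste(c(x$PC[r], fmt_short(unlist(x[r, cols[-1L]]))), collapse = "\t"),
      character(1))
    writeLines(c(header, rows), path)
  } else if (inherits(x, "knn_grid")) {
    header <- paste(c("k \\ PC", colnames(x)), collapse = "\t")
    rows <- vapply(seq_len(nrow(x)), function(r)
      paste(c(rownames(x)[r], fmt_short(x[r, ])), collapse = "\t"),
      character(1))
    writeLines(c(header, rows), path)
  } else stop("unsupported report object of class ", paste(class(x), collapse = "/"),
              call. = FALSE)
  invisible(path)
}

# complex vector <-> list of [re, im] pairs for JSON
cplx_to_json <- function(x) lapply(seq_along(x), function(i) c(Re(x[i]), Im(x[i])))
cplx_from_json <- function(l) {
  m <- do.call(rbind, l)
  maybe_real(complex(real = m[, 1L], imaginary = m[, 2L]))
}

#' Serialize models and transfer functions to JSON
#'
#' Complex arrays are flattened as `[re, im]` pairs; matrices are stored
#' column-major with their dimensions.
#'
#' @param x a [state_space()] model or [transfer_function()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(x, path) {
  if (inherits(x, "state_space")) {
    obj <- list(type = "state_space", order = x$order, dt = x$dt,
                A = cplx_to_json(as.vector(x$A)), B = cplx_to_json(as.vector(x$B)),
                C = cplx_to_json(as.vector(x$C)))
  } else if (inherits(x, "transfer_function")) {
    obj <- list(type = "transfer_function", order = x$order,
                numerator = cplx_to_json(x$numerator),
                denominator = cplx_to_json(x$denominator))
  } else stop("unsupported object", call. = FALSE)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model or transfer function written by [write_model()]
#'
#' @param path input file.
#' @return A [state_space()] or [transfer_function()] object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (identical(obj$type, "state_space")) {
    n <- obj$order
    state_space(A = matrix(cplx_from_json(obj$A), n, n),
                B = cplx_from_json(obj$B), C = cplx_from_json(obj$C),
                dt = obj$dt)
  } else if (identical(obj$type, "transfer_function")) {
    transfer_function(cplx_from_json(obj$numerator),
                      cplx_from_json(obj$denominator))
  } else stop("unrecognized model file", call. = FALSE)
}
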