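# TSV readers/writers (tab-separated, '.' decimal, no quoting — matching the
# public DTI gold-standard distribution files) and model serialization.

#' Read a binary interaction matrix from TSV
#'
#' Expected layout: first row holds target identifiers, first column drug
#' identifiers, cells are 0 or 1 (drugs-as-rows convention).
#'
#' @param path file path.
#' @param transpose set `TRUE` for target-major files.
#' @return binary matrix with identifier dimnames, validated by the same
#'   checks as [vbmklmf()] (non-binary cells and duplicate ids are errors).
#' @export
read_interactions <- function(path, transpose = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = NULL,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- ids
  if (transpose) M <- t(M)
  check_interactions(M)
}

#' Write a binary interaction matrix as TSV
#' @param R binary matrix with dimnames.
#' @param path output path.
#' @export
write_interactions <- function(R, path) {
  write_id_matrix(R, path, fmt = "%d")
}

#' Read a similarity kernel from TSV
#'
#' Square matrix with identifiers on both axes. The matrix is reordered to
#' `expected_ids`; missing or extra identifiers are an error. Asymmetry
#' beyond 1e-8 is symmetrized by averaging with a warning.
#'
#' @param path file path.
#' @param expected_ids identifiers the kernel must cover (typically the rows
#'   or columns of the interaction matrix).
#' @return kernel matrix aligned with `expected_ids`.
#' @export
read_kernel <- function(path, expected_ids = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- ids
  storage.mode(M) <- "double"
  if (nrow(M) != ncol(M)) stop("kernel file is not square: ", path)
  if (anyDuplicated(ids)) stop("duplicate identifiers in kernel file: ", path)
  asym <- max(abs(M - t(M)))
  if (asym > 1e-8) {
    warning("kernel ", basename(path), " asymmetric by ", signif(asym, 3),
            "; symmetrized by averaging")
    M <- (M + t(M)) / 2
  }
  if (!is.null(expected_ids)) {
    missing <- setdiff(expected_ids, ids)
    extra <- setdiff(ids, expected_ids)
    if (length(missing) || length(extra)) {
      stop("kernel ids do not match: missing [",
           paste(missing, collapse = ", "), "], extra [",
           paste(extra, collapse = ", "), "]")
    }
    M <- M[expected_ids, expected_ids]
  }
  validate_kernel(M)
}

#' Write a kernel matrix as TSV
#' @param K kernel matrix with dimnames.
#' @param path output path.
#' @export
write_kernel <- function(K, path) {
  write_id_matrix(K, path, fmt = "%.17g")
}

#' @keywords internal
#' Full-precision TSV writer: %.17g round-trips doubles exactly.
write_id_matrix <- function(M, path, fmt = "%.17g") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(M)), collapse = "\t"), con)
  for (i in seq_len(nrow(M))) {
    writeLines(paste(c(rownames(M)[i], sprintf(fmt, M[i, ])), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' @keywords internal
read_id_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- as.character(df[[1]])
  storage.mode(M) <- "double"
  M
}

#' Serialize a fitted model to a directory
#'
#' Writes posterior means, full covariances, local parameters and the
#' training matrix as full-precision TSVs plus a JSON metadata file (ids,
#' hyperparameters, Gamma posteriors, bound trace, seed, package version).
#' The round trip through [read_vbmklmf()] reproduces predictions bitwise.
#'
#' @param object fitted [vbmklmf()] model.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_vbmklmf <- function(object, dir) {
  stopifnot(inherits(object, "vbmklmf"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- function(M, name, rows = NULL, cols = NULL) {
    if (!is.null(rows)) rownames(M) <- rows
    if (!is.null(cols)) colnames(M) <- cols
    if (is.null(rownames(M))) rownames(M) <- paste0("r", seq_len(nrow(M)))
    if (is.null(colnames(M))) colnames(M) <- paste0("c", seq_len(ncol(M)))
    write_id_matrix(M, file.path(dir, paste0(name, ".tsv")))
  }
  L <- object$hyper$L
  dims <- paste0("dim_", seq_len(L))
  mat(object$mean_u, "mean_u", dims, object$drug_ids)
  mat(object$mean_v, "mean_v", dims, object$target_ids)
  mat(object$cov_u, "cov_u")
  mat(object$cov_v, "cov_v")
  mat(object$xi, "xi", object$drug_ids, object$target_ids)
  write_id_matrix(object$R, file.path(dir, "R.tsv"), fmt = "%d")
  for (n in names(object$drug_kernels)) {
    mat(object$drug_kernels[[n]], paste0("drug_kernel_", n))
  }
  for (n in names(object$target_kernels)) {
    mat(object$target_kernels[[n]], paste0("target_kernel_", n))
  }
  meta <- list(
    package = "vbmklmf",
    version = as.character(utils::packageVersion("vbmklmf")),
    drug_ids = object$drug_ids, target_ids = object$target_ids,
    drug_kernel_names = names(object$drug_kernels),
    target_kernel_names = names(object$target_kernels),
    hyper = object$hyper, seed = object$seed, sweeps_run = object$sweeps_run,
    gamma_u = object$gamma_u, gamma_v = object$gamma_v,
    logdet_cov_u = object$logdet_cov_u, logdet_cov_v = object$logdet_cov_v,
    m_u = object$m_u, m_v = object$m_v,
    elbo = object$elbo
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a serialized model
#' @param dir directory written by [write_vbmklmf()].
#' @return the fitted `vbmklmf` object.
#' @export
read_vbmklmf <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  rd <- function(name) unname(read_id_matrix(file.path(dir, paste0(name, ".tsv"))))
  Ku <- stats::setNames(lapply(meta$drug_kernel_names, function(n) {
    K <- read_id_matrix(file.path(dir, paste0("drug_kernel_", n, ".tsv")))
    dimnames(K) <- list(meta$drug_ids, meta$drug_ids); K
  }), meta$drug_kernel_names)
  Kv <- stats::setNames(lapply(meta$target_kernel_names, function(n) {
    K <- read_id_matrix(file.path(dir, paste0("target_kernel_", n, ".tsv")))
    dimnames(K) <- list(meta$target_ids, meta$target_ids); K
  }), meta$target_kernel_names)
  R <- read_id_matrix(file.path(dir, "R.tsv"))
  dimnames(R) <- list(meta$drug_ids, meta$target_ids)
  xi <- rd("xi")
  dimnames(xi) <- list(meta$drug_ids, meta$target_ids)
  structure(list(
    mean_u = rd("mean_u"), cov_u = rd("cov_u"),
    logdet_cov_u = meta$logdet_cov_u,
    mean_v = rd("mean_v"), cov_v = rd("cov_v"),
    logdet_cov_v = meta$logdet_cov_v,
    gamma_u = as.list(meta$gamma_u), gamma_v = as.list(meta$gamma_v),
    xi = xi,
    elbo = as.data.frame(meta$elbo),
    R = R, m_u = meta$m_u, m_v = meta$m_v,
    drug_ids = meta$drug_ids, target_ids = meta$target_ids,
    drug_kernels = Ku, target_kernels = Kv,
    hyper = as.list(meta$hyper), seed = meta$seed,
    sweeps_run = meta$sweeps_run
  ), class = "vbmklmf")
}
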