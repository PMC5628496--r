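# Probabilistic post-processing of a fitted model: expected interaction
# counts (promiscuity / druggability), ranked novel predictions, and export
# of the latent coordinates.

#' Expected number of interactions per drug or per target
#'
#' Sums posterior interaction probabilities along one axis, treating cells
#' as independent. Row sums estimate drug promiscuity (expected number of
#' targets hit); column sums estimate target druggability. The independence
#' assumption is recorded in the result's attributes.
#'
#' @param P probability matrix from [predict.vbmklmf()], or a fitted
#'   `vbmklmf` object.
#' @param axis `"drug"` sums over targets for each drug; `"target"` sums
#'   over drugs for each target.
#' @param subset optional identifiers restricting the opposite axis (e.g. a
#'   target family when `axis = "drug"`).
#' @return named numeric vector of expected counts, with attributes
#'   `axis`, `subset` and `assumption`.
#' @export
expected_interactions <- function(P, axis = c("drug", "target"), subset = NULL) {
  axis <- match.arg(axis)
  if (inherits(P, "vbmklmf")) P <- predict(P)
  opp <- if (axis == "drug") colnames(P) else rownames(P)
  if (!is.null(subset)) {
    unknown <- setdiff(subset, opp)
    if (length(unknown)) {
      stop("unknown identifiers in subset: ", paste(unknown, collapse = ", "))
    }
    P <- if (axis == "drug") P[, subset, drop = FALSE] else P[subset, , drop = FALSE]
  }
  out <- if (axis == "drug") rowSums(P) else colSums(P)
  attr(out, "axis") <- axis
  attr(out, "subset") <- subset
  attr(out, "assumption") <- "independent Bernoulli cells"
  out
}

#' Top novel interaction predictions
#'
#' Ranks the cells with no known interaction (`R_ij = 0`) by predicted
#' probability. Ties are broken deterministically by drug index, then
#' target index.
#'
#' @param P probability matrix aligned with `R`.
#' @param R binary training matrix (or a fitted `vbmklmf` object in place of
#'   `P`, in which case `R` is taken from it).
#' @param top_k number of predictions to return; truncated to the number of
#'   zero cells.
#' @return data.frame with columns `drug_id`, `target_id`, `probability`,
#'   sorted by decreasing probability.
#' @export
rank_novel <- function(P, R = NULL, top_k = 5) {
  if (inherits(P, "vbmklmf")) {
    if (is.null(R)) R <- P$R
    P <- predict(P)
  }
  stopifnot(all(dim(P) == dim(R)))
  zero <- which(R == 0, arr.ind = TRUE)
  if (nrow(zero) == 0L) {
    return(data.frame(drug_id = character(0), target_id = character(0),
                      probability = numeric(0), stringsAsFactors = FALSE))
  }
  p <- P[zero]
  ord <- order(-p, zero[, 1], zero[, 2])
  ord <- ord[seq_len(min(top_k, length(ord)))]
  data.frame(drug_id = rownames(P)[zero[ord, 1]],
             target_id = colnames(P)[zero[ord, 2]],
             probability = p[ord],
             stringsAsFactors = FALSE)
}

#' Export posterior-mean latent coordinates
#'
#' One row per drug and per target with its posterior-mean coordinates in
#' the shared latent space, suitable for 2D scatter or parallel-coordinates
#' visualization.
#'
#' @param object fitted [vbmklmf()] model.
#' @param annotations optional named character vector mapping entity ids to
#'   labels; ids absent from the model are reported and skipped.
#' @return data.frame with columns `id`, `side` (`drug`/`target`),
#'   `dim_1 ... dim_L`, `label`.
#' @export
export_latent <- function(object, annotations = NULL) {
  stopifnot(inherits(object, "vbmklmf"))
  L <- object$hyper$L
  coords <- rbind(t(object$mean_u), t(object$mean_v))
  colnames(coords) <- paste0("dim_", seq_len(L))
  ids <- c(object$drug_ids, object$target_ids)
  out <- data.frame(
    id = ids,
    side = rep(c("drug", "target"),
               c(length(object$drug_ids), length(object$target_ids))),
    coords,
    label = "",
    stringsAsFactors = FALSE
  )
  if (!is.null(annotations)) {
    unknown <- setdiff(names(annotations), ids)
    if (length(unknown)) {
      message("skipping annotations for unknown ids: ",
              paste(unknown, collapse = ", "))
    }
    hit <- intersect(names(annotations), ids)
    out$label[match(hit, out$id)] <- unname(annotations[hit])
  }
  rownames(out) <- NULL
  out
}
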