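# K-nearest-neighbor classification over a descriptor subset, and the
# leave-one-out correct count used as the genetic algorithm's fitness.
#
# Determinism rules (the original analysis states neither k nor a tie
# policy, so these are declared package choices):
#   * k defaults to 1;
#   * distance ties go to the lower molecule index (stable matrix order);
#   * vote ties go to "non_permeant" when present (the conservative class),
#     otherwise to the lexicographically smallest tied label.

.resolve_subset <- function(matrix, subset) {
  p <- ncol(matrix$values)
  if (is.null(subset)) return(rep(TRUE, p))
  if (is.character(subset)) {
    unknown <- setdiff(subset, descriptor_names(matrix))
    if (length(unknown))
      stop("unknown descriptor(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    return(descriptor_names(matrix) %in% subset)
  }
  if (length(subset) != p)
    stop("subset length (", length(subset),
         ") does not match descriptor count (", p, ")", call. = FALSE)
  if (is.logical(subset)) return(subset)
  if (is.numeric(subset) && all(subset %in% c(0, 1))) return(subset == 1)
  stop("subset must be a 0/1 vector, logical vector or descriptor names",
       call. = FALSE)
}

.majority_vote <- function(neighbor_labels) {
  tab <- table(neighbor_labels)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) > 1L) {
    if ("non_permeant" %in% winners) return("non_permeant")
    return(sort(winners)[1L])
  }
  winners
}

#' KNN classification restricted to a descriptor subset
#'
#' Euclidean distance over the selected descriptors of a (pre-standardized)
#' training matrix, majority vote among the k nearest neighbors.
#'
#' @param train_matrix a labelled [descriptor_matrix()].
#' @param query numeric vector: either one value per descriptor of
#'   `train_matrix`, or one value per *selected* descriptor.
#' @param k number of neighbors (>= 1, <= number of training molecules).
#' @param subset descriptor subset: 0/1 or logical vector of full length,
#'   descriptor names, or `NULL` for all descriptors. Must select at least
#'   one descriptor.
#' @return The predicted class label (character scalar).
#' @export
knn_classify <- function(train_matrix, query, k = 1L, subset = NULL) {
  if (!inherits(train_matrix, "descriptor_matrix"))
    stop("`train_matrix` must be a descriptor_matrix", call. = FALSE)
  lab <- train_matrix$labels
  if (is.null(lab)) stop("training labels required", call. = FALSE)
  sel <- .resolve_subset(train_matrix, subset)
  if (!any(sel)) stop("empty descriptor subset", call. = FALSE)
  X <- train_matrix$values[, sel, drop = FALSE]
  n <- nrow(X)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds the training set size (", n, ")",
                  call. = FALSE)
  if (length(query) == ncol(train_matrix$values)) query <- query[sel]
  if (length(query) != ncol(X))
    stop("query length does not match the selected descriptors",
         call. = FALSE)
  d <- sqrt(colSums((t(X) - query)^2))
  nearest <- order(d)[seq_len(k)]   # order() is stable: ties -> lower index
  .majority_vote(lab[nearest])
}

#' Leave-one-out KNN fitness
#'
#' Predicts each molecule from the remaining n - 1 under the selected
#' descriptor subset and counts correct predictions; this count is the
#' genetic algorithm's fitness. An empty subset scores 0 by convention.
#'
#' @param matrix a labelled [descriptor_matrix()] with >= 3 molecules.
#' @param subset descriptor subset (see [knn_classify()]); empty allowed.
#' @param k number of neighbors.
#' @return An object of class `loo_result`: list with `n_correct`,
#'   `n_total`, and `per_molecule` (data frame of name, true label,
#'   predicted label).
#' @examples
#' dm <- standardize(load_descriptor_table())
#' loo_fitness(dm, subset = "TDB6e", k = 1)$n_correct
#' @export
loo_fitness <- function(matrix, subset = NULL, k = 1L) {
  if (!inherits(matrix, "descriptor_matrix"))
    stop("`matrix` must be a descriptor_matrix", call. = FALSE)
  lab <- matrix$labels
  if (is.null(lab)) stop("labels required for leave-one-out", call. = FALSE)
  n <- nrow(matrix$values)
  if (n < 3L) stop("need >= 3 molecules for leave-one-out", call. = FALSE)
  sel <- .resolve_subset(matrix, subset)
  mols <- molecule_names(matrix)
  if (!any(sel)) {
    per <- data.frame(name = mols, true = unname(lab),
                      predicted = NA_character_, stringsAsFactors = FALSE)
    return(structure(list(n_correct = 0L, n_total = n, per_molecule = per),
                     class = "loo_result"))
  }
  if (k > n - 1L) stop("k exceeds the leave-one-out training size",
                       call. = FALSE)
  X <- matrix$values[, sel, drop = FALSE]
  D <- as.matrix(stats::dist(X))
  pred <- character(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nearest <- others[order(D[i, others])[seq_len(k)]]
    pred[i] <- .majority_vote(lab[nearest])
  }
  per <- data.frame(name = mols, true = unname(lab), predicted = pred,
                    stringsAsFactors = FALSE)
  structure(list(n_correct = sum(pred == lab), n_total = n,
                 per_molecule = per),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("<loo_result: %d/%d correct>\n", x$n_correct, x$n_total))
  invisible(x)
}
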