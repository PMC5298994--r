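#' Descriptor matrix
#'
#' Container for a molecules x descriptors table of numeric (possibly missing)
#' values, with optional per-molecule class labels. This is the object the
#' descriptor filters, the KNN classifier and the genetic algorithm operate on.
#'
#' @param values numeric matrix with unique rownames (molecule names) and
#'   unique colnames (descriptor names). `NA` marks a missing value.
#' @param labels optional character vector of class labels, one per molecule,
#'   either named by molecule or in row order. The permeability pipeline uses
#'   the two classes `"permeant"` and `"non_permeant"`.
#' @return An object of class `descriptor_matrix`: a list with elements
#'   `values` (the matrix) and `labels` (named character vector or `NULL`).
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("a", "b", "c"), c("d1", "d2")))
#' dm <- descriptor_matrix(m, labels = c("permeant", "permeant", "non_permeant"))
#' dim(dm)
#' @export
descriptor_matrix <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("descriptor matrix must have at least one molecule and one descriptor",
         call. = FALSE)
  rn <- rownames(values); cn <- colnames(values)
  if (is.null(rn) || anyNA(rn) || any(rn == ""))
    stop("molecule names (rownames) are required", call. = FALSE)
  if (is.null(cn) || anyNA(cn) || any(cn == ""))
    stop("descriptor names (colnames) are required", call. = FALSE)
  if (anyDuplicated(rn)) stop("duplicate molecule names", call. = FALSE)
  if (anyDuplicated(cn)) stop("duplicate descriptor names", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(values))
      stop("`labels` must have one entry per molecule", call. = FALSE)
    if (is.null(names(labels))) names(labels) <- rn
    labels <- labels[rn]
    if (anyNA(names(labels)))
      stop("label names do not match molecule names", call. = FALSE)
  }
  structure(list(values = values, labels = labels),
            class = "descriptor_matrix")
}

#' @export
dim.descriptor_matrix <- function(x) dim(x$values)

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix: %d molecules x %d descriptors>\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels))
    cat("labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                 as.integer(table(x$labels))),
                         collapse = ", "), "\n")
  if (anyNA(x$values))
    cat("missing values:", sum(is.na(x$values)), "\n")
  invisible(x)
}

#' Molecule and descriptor names
#' @param x a `descriptor_matrix`
#' @return character vector of names.
#' @export
molecule_names <- function(x) rownames(x$values)

#' @rdname molecule_names
#' @export
descriptor_names <- function(x) colnames(x$values)
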