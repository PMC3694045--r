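#' @importFrom stats dist median rnorm runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

#' Label status vocabulary
#'
#' Per (protein, location) pair a label status is one of five strings:
#' `"experimental"` (positive, experimentally proven), `"probable"`,
#' `"potential"`, `"by_similarity"` (positive, carrying the corresponding
#' non-experimental evidence qualifier) or `"negative"` (the location is not
#' annotated for the protein).  Experimental positives and negatives are
#' *certain*; the three non-experimental statuses are uncertain and may be
#' corrected during risk evaluation.
#'
#' @return `label_statuses()` returns the five status strings;
#'   `evidence_types()` returns the four evidence types (the three
#'   non-experimental qualifiers plus `"experimental"`).
#' @export
label_statuses <- function() {
  c("experimental", "probable", "potential", "by_similarity", "negative")
}

#' @rdname label_statuses
#' @export
evidence_types <- function() {
  c("experimental", "probable", "potential", "by_similarity")
}

nonexp_types <- function() c("probable", "potential", "by_similarity")

#' Construct a multi-label protein dataset
#'
#' Bundles a feature matrix with a per-(protein, location) status matrix.
#' Rows are proteins, columns of `status` are the `Q` candidate subcellular
#' locations in a fixed, user-supplied order.
#'
#' @param features numeric `n x d` matrix of per-protein feature vectors.
#' @param status character `n x Q` matrix over [label_statuses()].
#' @param locations character vector of the `Q` location names (column
#'   order of `status`).
#' @param ids character vector of protein accessions (defaults to
#'   `rownames(features)`).
#' @param weights optional numeric `n x Q` matrix of per-label loss weights
#'   in `[0, 1]`; `NULL` means every weight is 1.
#' @param require_positive if `TRUE` (default) every protein must carry at
#'   least one positive status, as any training or candidate-pool protein
#'   does.
#' @return an object of class `pnea_labeled_set` with elements `ids`,
#'   `features`, `status`, `locations`, `weights`.
#' @export
labeled_set <- function(features, status, locations = colnames(status),
                        ids = rownames(features), weights = NULL,
                        require_positive = TRUE) {
  features <- as.matrix(features)
  status <- as.matrix(status)
  if (nrow(features) != nrow(status))
    stop("features and status must have the same number of rows")
  if (is.null(locations))
    stop("locations must be supplied (or set as colnames of status)")
  locations <- as.character(locations)
  if (length(locations) < 2L)
    stop("a multi-label dataset needs Q >= 2 locations")
  if (ncol(status) != length(locations))
    stop("status must have one column per location")
  bad <- !(status %in% label_statuses())
  if (any(bad))
    stop("unknown label status: ", paste(unique(status[bad]), collapse = ", "))
  if (is.null(ids)) ids <- paste0("P", seq_len(nrow(features)))
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("protein ids must be unique")
  if (require_positive && nrow(status) > 0L) {
    pos <- rowSums(status != "negative")
    if (any(pos == 0L))
      stop("protein(s) with no positive location: ",
           paste(head(ids[pos == 0L], 5L), collapse = ", "))
  }
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!all(dim(weights) == dim(status)))
      stop("weights must match the dimensions of status")
    if (any(weights < 0 | weights > 1))
      stop("weights must lie in [0, 1]")
  }
  rownames(features) <- ids
  dimnames(status) <- list(ids, locations)
  if (!is.null(weights)) dimnames(weights) <- list(ids, locations)
  structure(
    list(ids = ids, features = features, status = status,
         locations = locations, weights = weights),
    class = "pnea_labeled_set"
  )
}

#' @export
print.pnea_labeled_set <- function(x, ...) {
  cat(sprintf("<pnea_labeled_set> %d proteins x %d locations, %d features\n",
              nrow(x$features), length(x$locations), ncol(x$features)))
  cat("  locations:", paste(x$locations, collapse = ", "), "\n")
  ne <- sum(x$status %in% nonexp_types())
  cat(sprintf("  positives: %d experimental, %d non-experimental\n",
              sum(x$status == "experimental"), ne))
  invisible(x)
}

#' @export
`[.pnea_labeled_set` <- function(x, i, ...) {
  labeled_set(x$features[i, , drop = FALSE],
              x$status[i, , drop = FALSE],
              locations = x$locations,
              ids = x$ids[i],
              weights = if (!is.null(x$weights)) x$weights[i, , drop = FALSE],
              require_positive = FALSE)
}

#' @export
length.pnea_labeled_set <- function(x) length(x$ids)

#' Signed label matrix of a dataset
#'
#' @param x a `pnea_labeled_set` or a status matrix.
#' @return integer matrix with `+1` for any positive status and `-1` for
#'   `"negative"`.
#' @export
status_sign <- function(x) {
  status <- if (inherits(x, "pnea_labeled_set")) x$status else x
  out <- matrix(-1L, nrow(status), ncol(status), dimnames = dimnames(status))
  out[status != "negative"] <- 1L
  out
}

#' Certainty mask of a dataset
#'
#' @inheritParams status_sign
#' @return logical matrix, `TRUE` where the status is certain (experimental
#'   positive or negative), `FALSE` for non-experimental positives.
#' @export
status_certain <- function(x) {
  status <- if (inherits(x, "pnea_labeled_set")) x$status else x
  out <- status == "experimental" | status == "negative"
  dimnames(out) <- dimnames(status)
  out
}

#' Concatenate two labeled sets over the same locations
#'
#' @param a,b `pnea_labeled_set` objects with identical `locations` and
#'   feature dimension.
#' @return the row-bound `pnea_labeled_set`; weights are carried through
#'   (missing weights are taken as 1).
#' @export
bind_labeled_sets <- function(a, b) {
  if (!identical(a$locations, b$locations))
    stop("location vocabularies differ")
  if (ncol(a$features) != ncol(b$features))
    stop("feature dimensions differ (", ncol(a$features), " vs ",
         ncol(b$features), ")")
  wa <- set_weights(a)
  wb <- set_weights(b)
  labeled_set(rbind(a$features, b$features),
              rbind(a$status, b$status),
              locations = a$locations,
              ids = c(a$ids, b$ids),
              weights = rbind(wa, wb),
              require_positive = FALSE)
}

# weights with the all-ones default made explicit
set_weights <- function(x) {
  if (!is.null(x$weights)) return(x$weights)
  matrix(1, nrow(x$status), ncol(x$status), dimnames = dimnames(x$status))
}

#' Count locative proteins
#'
#' A protein residing in `N` locations counts as `N` locative proteins, the
#' convention used when tallying multi-location datasets: the result is the
#' total number of positive (protein, location) pairs, experimental and
#' non-experimental alike.
#'
#' @param x a `pnea_labeled_set`.
#' @return integer count.
#' @export
count_locative <- function(x) {
  stopifnot(inherits(x, "pnea_labeled_set"))
  sum(x$status != "negative")
}
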