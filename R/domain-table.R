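#' Labeled feature table for one domain
#'
#' The unit of data everywhere in the package: a numeric feature matrix
#' (rows = epochs, columns = features), an integer class label per row, and a
#' domain identifier. Source domains and the target domain are all
#' `domain_table` objects.
#'
#' @param features Numeric matrix (n x d), no missing values.
#' @param labels Integer vector of length n with class codes in `1..C`.
#' @param domain_id Single character token naming the domain.
#' @param C Number of classes; defaults to `max(labels)`.
#' @return An object of class `domain_table` with elements `features`,
#'   `labels`, `domain_id` and `C`.
#' @examples
#' dt <- domain_table(matrix(rnorm(12), 6, 2), c(1, 1, 1, 2, 2, 2), "s1")
#' nrow(dt$features)
#' @export
domain_table <- function(features, labels, domain_id = "domain", C = NULL) {
  features <- as_feature_matrix(features)
  if (nrow(features) < 1L) stop("a domain table needs at least one row", call. = FALSE)
  if (length(labels) != nrow(features)) {
    stop("labels must have one entry per feature row", call. = FALSE)
  }
  if (is.null(C)) C <- max(as.integer(labels))
  labels <- check_labels(labels, C)
  structure(
    list(features = features, labels = labels,
         domain_id = as.character(domain_id)[1L], C = as.integer(C)),
    class = "domain_table"
  )
}

#' @export
print.domain_table <- function(x, ...) {
  cat(sprintf("<domain_table '%s': %d objects, %d features, %d classes>\n",
              x$domain_id, nrow(x$features), ncol(x$features), x$C))
  invisible(x)
}

#' Row-bind several domain tables into one
#'
#' Used to pool source domains (e.g. for the source-only baseline). The
#' result keeps the common class count and a concatenated domain id.
#' @param tables List of `domain_table` objects sharing `d` and `C`.
#' @return A single `domain_table`.
#' @export
bind_domains <- function(tables) {
  stopifnot(length(tables) >= 1L)
  d <- ncol(tables[[1L]]$features)
  C <- max(vapply(tables, function(t) t$C, integer(1)))
  if (!all(vapply(tables, function(t) ncol(t$features) == d, logical(1)))) {
    stop("all domain tables must share the same feature count", call. = FALSE)
  }
  domain_table(
    do.call(rbind, lapply(tables, `[[`, "features")),
    unlist(lapply(tables, `[[`, "labels")),
    paste(vapply(tables, `[[`, character(1), "domain_id"), collapse = "+"),
    C = C
  )
}

#' Subset rows of a domain table
#' @param table A `domain_table`.
#' @param idx Integer row indices.
#' @return A `domain_table` with the selected rows.
#' @export
slice_domain <- function(table, idx) {
  domain_table(table$features[idx, , drop = FALSE], table$labels[idx],
               table$domain_id, C = table$C)
}
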