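#' Distance-based source-domain selection
#'
#' Transferring from every available source domain is wasteful and risks
#' negative transfer from domains too dissimilar to the target. Candidate
#' sources are therefore ranked by a class-mean distance to the target
#' calibration data and the closer of two 1-D k-means clusters of those
#' distances is selected.
#'
#' @name source-selection
NULL

#' Per-class feature means of a domain table
#'
#' @param table A `domain_table`.
#' @param C Class count; every requested class must be present.
#' @param classes Classes to compute means for (default all of `1..C`).
#' @return Numeric matrix (`length(classes)` x d); row i is the mean
#'   feature vector of `classes[i]`.
#' @export
class_means <- function(table, C = table$C, classes = seq_len(C)) {
  missing_c <- setdiff(classes, unique(table$labels))
  if (length(missing_c)) {
    stop("class ", paste(missing_c, collapse = ", "), " absent from domain '",
         table$domain_id, "'", call. = FALSE)
  }
  means <- matrix(0, length(classes), ncol(table$features))
  for (i in seq_along(classes)) {
    means[i, ] <- colMeans(table$features[table$labels == classes[i], , drop = FALSE])
  }
  means
}

#' Squared class-mean distance between two domains
#'
#' `d(z, t) = sum_c || v_{z,c} - v_{t,c} ||^2`: the sum over classes of the
#' squared Euclidean distance between class means.
#'
#' @param source_means,target_means Matrices (C x d) from [class_means()].
#' @return Nonnegative scalar.
#' @export
domain_distance <- function(source_means, target_means) {
  source_means <- as.matrix(source_means)
  target_means <- as.matrix(target_means)
  if (!all(dim(source_means) == dim(target_means))) {
    stop("class-mean matrices must have the same shape", call. = FALSE)
  }
  sum((source_means - target_means)^2)
}

#' Distances from each candidate source to the target
#'
#' Distances are summed over the classes actually present in the
#' calibration table (with few online calibration objects a class can be
#' momentarily absent; its term is then dropped rather than undefined).
#' Every such class must be present in every source.
#'
#' @param sources List of source `domain_table`s.
#' @param target_calib `domain_table` of target calibration rows.
#' @param C Class count.
#' @return List with `distances` (numeric, named by domain id) and
#'   `domain_ids`.
#' @export
domain_distances <- function(sources, target_calib, C) {
  classes <- sort(unique(target_calib$labels))
  vt <- class_means(target_calib, C, classes)
  d <- vapply(sources,
              function(s) domain_distance(class_means(s, C, classes), vt),
              numeric(1))
  ids <- vapply(sources, `[[`, character(1), "domain_id")
  names(d) <- ids
  list(distances = d, domain_ids = ids)
}

# Exact 1-D 2-means: clusters of sorted values are contiguous, so scan all
# split points and minimize the within-cluster sum of squares.
split_two_means <- function(x) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  best <- Inf
  best_m <- 1L
  for (m in seq_len(n - 1L)) {
    lo <- xs[seq_len(m)]
    hi <- xs[(m + 1L):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best - 1e-15) {
      best <- ss
      best_m <- m
    }
  }
  list(low_idx = ord[seq_len(best_m)], high_idx = ord[(best_m + 1L):n])
}

#' Select the source domains closest to the target
#'
#' The Z distances are partitioned into two groups by exact 1-D 2-means
#' (contiguity of optimal 1-D clusters makes the split-point scan exact; the
#' seed is accepted only for API symmetry) and all domains in the
#' smaller-center cluster are returned. `rule = "half"` instead returns the
#' `ceiling(Z/2)` closest domains.
#'
#' @param distances Named numeric vector of domain distances (names = domain
#'   ids), as from [domain_distances()].
#' @param k Cluster count; only `k = 2` is supported.
#' @param rule `"cluster"` (default: cluster membership decides how many are
#'   selected) or `"half"` (always the closest half).
#' @param seed Unused; kept for interface symmetry with the seeded trainers.
#' @return Character vector of selected domain ids, ordered by increasing
#'   distance.
#' @export
select_sources <- function(distances, k = 2L, rule = c("cluster", "half"),
                           seed = 1L) {
  rule <- match.arg(rule)
  if (length(distances) == 0L) stop("empty distance set", call. = FALSE)
  if (k != 2L) stop("only k = 2 is supported", call. = FALSE)
  ids <- names(distances)
  if (is.null(ids)) ids <- as.character(seq_along(distances))
  if (length(distances) == 1L) return(ids)
  if (diff(range(distances)) == 0) return(ids[order(distances)])
  if (rule == "half") {
    keep <- order(distances)[seq_len(ceiling(length(distances) / 2))]
    return(ids[keep])
  }
  sp <- split_two_means(as.numeric(distances))
  low <- sp$low_idx
  ids[low[order(distances[low])]]
}
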