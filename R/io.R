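#' File formats: CSV domain tables and JSON models
#'
#' Domain tables travel as CSV with header `domain,label,f1..fd` (one epoch
#' per row, 1-based integer labels). Trained ensembles travel as versioned
#' JSON listing, per member, the antecedent centers and widths, the
#' consequent matrix and the accuracy weight — the same parameter layout in
#' which fuzzy rules are conventionally reported, so a model file is
#' human-inspectable.
#'
#' @name cli-io
NULL

MODEL_FORMAT_VERSION <- 1L

#' Read a domain table from CSV
#'
#' Expects header `domain,label,f1,...,fd`. Any missing or non-finite cell
#' and any non-integer label is an error naming the offending row.
#'
#' @param path CSV file path.
#' @return A [domain_table()].
#' @export
read_domain_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("domain", "label")
  if (!all(need %in% names(df)) || ncol(df) < 3L) {
    stop("expected columns 'domain', 'label' and at least one feature column",
         call. = FALSE)
  }
  fcols <- setdiff(names(df), need)
  feats <- as.matrix(df[, fcols, drop = FALSE])
  storage.mode(feats) <- "double"
  bad <- which(!stats::complete.cases(feats) | rowSums(!is.finite(feats)) > 0)
  if (length(bad)) {
    stop("non-finite feature value in row ", bad[1L], call. = FALSE)
  }
  labs <- df$label
  if (any(labs != round(labs)) || anyNA(labs)) {
    stop("non-integer label in row ", which(labs != round(labs) | is.na(labs))[1L],
         call. = FALSE)
  }
  domain_table(unname(feats), as.integer(labs), as.character(df$domain[1L]))
}

#' Write a domain table to CSV
#' @param table A `domain_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(table, path) {
  d <- ncol(table$features)
  df <- data.frame(domain = table$domain_id, label = table$labels,
                   table$features)
  names(df) <- c("domain", "label", paste0("f", seq_len(d)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

member_to_list <- function(m) {
  list(domain_id = m$domain_id,
       alpha = m$alpha,
       omega_t = m$omega_t,
       K = m$antecedents$K,
       d = m$antecedents$d,
       h = m$antecedents$h,
       centers = m$antecedents$centers,
       widths = m$antecedents$widths,
       p_g = as.matrix(m$p_g))
}

#' Serialize an ensemble model to JSON text
#'
#' Full-precision, versioned representation; [write_model()] /
#' [read_model()] round-trip exactly.
#'
#' @param model A `tsk_ensemble`.
#' @return A JSON string.
#' @export
model_to_json <- function(model) {
  stopifnot(inherits(model, "tsk_ensemble"))
  payload <- list(format = "tsktransfer-ensemble",
                  version = MODEL_FORMAT_VERSION,
                  class_count = model$C,
                  members = lapply(model$members, member_to_list))
  # 17 significant digits: exact binary64 round trip
  jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE, matrix = "rowmajor")
}

#' Write an ensemble model to a JSON file
#' @param model A `tsk_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  writeLines(model_to_json(model), path)
  invisible(path)
}

#' Read an ensemble model from a JSON file
#' @param path Path to a file written by [write_model()].
#' @return A `tsk_ensemble`.
#' @export
read_model <- function(path) {
  payload <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = TRUE),
    error = function(e) {
      stop("cannot parse model file: ", conditionMessage(e), call. = FALSE)
    })
  if (!identical(payload$format, "tsktransfer-ensemble")) {
    stop("not a tsktransfer ensemble model file", call. = FALSE)
  }
  if (!identical(as.integer(payload$version), MODEL_FORMAT_VERSION)) {
    stop("unsupported model format version ", payload$version, call. = FALSE)
  }
  as_mat <- function(x, nr, nc) {
    if (is.matrix(x)) x else matrix(as.numeric(x), nr, nc, byrow = TRUE)
  }
  mk_member <- function(m) {
    K <- as.integer(m$K)
    d <- as.integer(m$d)
    ant <- structure(list(centers = as_mat(m$centers, K, d),
                          widths = as_mat(m$widths, K, d),
                          h = m$h, K = K, d = d),
                     class = "tsk_antecedents")
    pg <- m$p_g
    if (!is.matrix(pg)) pg <- matrix(as.numeric(pg), ncol = 1L)
    list(domain_id = m$domain_id, antecedents = ant, p_g = pg,
         alpha = m$alpha, omega_t = if (is.null(m$omega_t)) NA_real_ else m$omega_t)
  }
  new_ensemble(lapply(payload$members, mk_member), as.integer(payload$class_count))
}

#' Read an adaptation configuration from a JSON file
#'
#' Accepts either a top-level object or one nested under `"adaptation"`,
#' with any subset of `lambda1`, `lambda2`, `sigma`, `v`, `jitter`, `seed`;
#' unspecified fields take the package defaults.
#'
#' @param path JSON file path.
#' @return An [adaptation_config()].
#' @export
read_adaptation_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  if (!is.null(raw$adaptation)) raw <- raw$adaptation
  defaults <- adaptation_config()
  for (f in c("lambda1", "lambda2", "sigma", "v", "jitter", "seed")) {
    if (!is.null(raw[[f]])) defaults[[f]] <- raw[[f]]
  }
  adaptation_config(defaults$lambda1, defaults$lambda2, defaults$sigma,
                    defaults$v, defaults$jitter, defaults$seed)
}
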