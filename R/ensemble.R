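#' Multi-source ensemble training and the online calibration harness
#'
#' End-to-end training selects the source domains closest to the target
#' calibration data, fits one transfer model per selected source (antecedents
#' refit on the pooled source + calibration rows, closed-form consequents),
#' records each member's training accuracy alpha_z on its pooled rows, and
#' predicts by the alpha-weighted sum of member outputs. The harness
#' [run_online_calibration()] reproduces the batched online calibration
#' protocol and the three standard TSK baselines.
#'
#' @name ensemble-online
NULL

#' One-hot label encoding
#'
#' Maps integer class labels `1..C` to rows of the C-dimensional one-hot
#' code used as regression targets by every trainer in the package.
#'
#' @param labels Integer labels in `1..C`.
#' @param C Class count.
#' @return Binary matrix (n x C) with unit row sums.
#' @export
encode_labels <- function(labels, C) {
  labels <- check_labels(labels, C)
  diag(C)[labels, , drop = FALSE]
}

new_ensemble <- function(members, C) {
  stopifnot(length(members) >= 1L)
  structure(list(members = members, C = as.integer(C)), class = "tsk_ensemble")
}

#' @export
print.tsk_ensemble <- function(x, ...) {
  ids <- vapply(x$members, `[[`, character(1), "domain_id")
  al <- vapply(x$members, `[[`, numeric(1), "alpha")
  cat(sprintf("<tsk_ensemble: %d member(s), %d classes>\n", length(ids), x$C))
  for (i in seq_along(ids)) cat(sprintf("  %s  alpha = %.4f\n", ids[i], al[i]))
  invisible(x)
}

# Fit one transfer member on a single source plus calibration rows.
fit_member <- function(source, target_calib, K, h, config, C, seed) {
  M <- if (is.null(target_calib)) 0L else nrow(target_calib$features)
  pooled_x <- if (M > 0) rbind(source$features, target_calib$features) else source$features
  pooled_y <- if (M > 0) c(source$labels, target_calib$labels) else source$labels
  ant <- fit_antecedents(pooled_x, K = K, h = h, seed = seed)
  g <- map_to_g(pooled_x, ant)
  mats <- build_adaptation_matrices(source, target_calib, config, C)
  p_g <- solve_transfer(g, encode_labels(pooled_y, C), mats, config)
  pred <- scores_to_labels(tsk_output(g, p_g))
  list(domain_id = source$domain_id, antecedents = ant, p_g = p_g,
       alpha = mean(pred == pooled_y), omega_t = mats$omega_t)
}

#' Train the selective transfer ensemble
#'
#' (1) Rank sources by class-mean distance to the calibration data and keep
#' the closer 2-means cluster; (2) per selected source, fit a transfer model
#' on the pooled source + calibration rows; (3) weight each member by its
#' training accuracy alpha_z. With `M = 0` calibration rows (no
#' `target_calib`, or an empty one) selection is skipped — all sources are
#' used — and each member degenerates to source-only training (the
#' distribution-adaptation terms vanish; the manifold penalty remains,
#' computed on the source rows).
#'
#' @param sources List of source `domain_table`s sharing d and the class
#'   codes.
#' @param target_calib `domain_table` of the M labeled calibration rows, or
#'   `NULL`.
#' @param K Rule count per member.
#' @param config An [adaptation_config()]; `config$seed` drives antecedent
#'   clustering.
#' @param h Antecedent width scale.
#' @param select `TRUE` (default) to apply distance-based source selection
#'   when calibration rows are available.
#' @param selection_rule Passed to [select_sources()].
#' @return A `tsk_ensemble`.
#' @export
tsk_transfer_train <- function(sources, target_calib, K = 5L,
                               config = adaptation_config(), h = 0.5,
                               select = TRUE,
                               selection_rule = c("cluster", "half")) {
  selection_rule <- match.arg(selection_rule)
  stopifnot(length(sources) >= 1L)
  C <- max(vapply(sources, `[[`, integer(1), "C"),
           if (!is.null(target_calib)) target_calib$C else 0L)
  M <- if (is.null(target_calib)) 0L else nrow(target_calib$features)
  if (M == 0L) target_calib <- NULL
  if (select && M > 0L && length(sources) >= 2L) {
    dd <- domain_distances(sources, target_calib, C)
    keep_ids <- select_sources(dd$distances, rule = selection_rule)
    sources <- sources[match(keep_ids, dd$domain_ids)]
  }
  if (length(sources) == 0L) stop("no source domains selected", call. = FALSE)
  members <- vector("list", length(sources))
  for (z in seq_along(sources)) {
    members[[z]] <- fit_member(sources[[z]], target_calib, K, h, config, C,
                               seed = derive_seed(config$seed, z))
  }
  new_ensemble(members, C)
}

#' Ensemble output scores
#'
#' Each member maps the inputs with its own antecedents and contributes
#' `alpha_z` times its output matrix; columns are per-class scores.
#'
#' @param model A `tsk_ensemble`.
#' @param features Numeric matrix (n x d).
#' @return Numeric matrix (n x C).
#' @export
ensemble_scores <- function(model, features) {
  features <- as_feature_matrix(features)
  scores <- matrix(0, nrow(features), model$C)
  for (m in model$members) {
    g <- map_to_g(features, m$antecedents)
    scores <- scores + m$alpha * tsk_output(g, m$p_g)
  }
  scores
}

#' Predict class labels with a trained ensemble
#'
#' Argmax of [ensemble_scores()] with ties toward the lowest class index;
#' scale-invariant in the member weights, so an all-zero-weight ensemble
#' degenerates to class 1 everywhere.
#'
#' @param model A `tsk_ensemble`.
#' @param features Numeric matrix (n x d).
#' @return Integer label vector.
#' @export
predict_ensemble <- function(model, features) {
  scores_to_labels(ensemble_scores(model, features))
}

#' @export
predict.tsk_ensemble <- function(object, newdata, ...) {
  predict_ensemble(object, newdata)
}

#' Train one of the three reference baselines
#'
#' * `bl1` — source-only: one plain ridge TSK fit on all sources pooled;
#'   ignores the calibration data entirely.
#' * `bl2` — target-only: one plain ridge TSK fit on the calibration rows;
#'   undefined without calibration rows.
#' * `bl3` — pooled per source: a ridge TSK fit per (source + calibration)
#'   pool, combined with the same training-accuracy weighting as the
#'   transfer ensemble.
#'
#' @param kind `"bl1"`, `"bl2"` or `"bl3"`.
#' @param sources List of source `domain_table`s (ignored by `bl2`).
#' @param target_calib Calibration `domain_table` or `NULL` (ignored by
#'   `bl1`).
#' @param K Rule count.
#' @param eta Ridge error weight of [solve_ridge()].
#' @param h Antecedent width scale.
#' @param seed Integer seed for antecedent clustering.
#' @return A `tsk_ensemble` (single member for `bl1`/`bl2`).
#' @export
train_baseline <- function(kind = c("bl1", "bl2", "bl3"), sources = NULL,
                           target_calib = NULL, K = 5L, eta = 100, h = 0.5,
                           seed = 1L) {
  kind <- match.arg(kind)
  M <- if (is.null(target_calib)) 0L else nrow(target_calib$features)
  fit_plain <- function(table, member_seed) {
    ant <- fit_antecedents(table$features, K = min(K, nrow(table$features)),
                           h = h, seed = member_seed)
    g <- map_to_g(table$features, ant)
    p_g <- solve_ridge(g, encode_labels(table$labels, table$C), eta = eta)
    pred <- scores_to_labels(tsk_output(g, p_g))
    list(domain_id = table$domain_id, antecedents = ant, p_g = p_g,
         alpha = mean(pred == table$labels), omega_t = NA_real_)
  }
  if (kind == "bl1") {
    stopifnot(length(sources) >= 1L)
    pooled <- bind_domains(sources)
    member <- fit_plain(pooled, derive_seed(seed, 1L))
    member$alpha <- 1
    return(new_ensemble(list(member), pooled$C))
  }
  if (kind == "bl2") {
    if (M == 0L) stop("target-only baseline needs calibration rows", call. = FALSE)
    member <- fit_plain(target_calib, derive_seed(seed, 1L))
    member$alpha <- 1
    return(new_ensemble(list(member), target_calib$C))
  }
  stopifnot(length(sources) >= 1L)
  C <- max(vapply(sources, `[[`, integer(1), "C"), if (M > 0) target_calib$C else 0L)
  members <- vector("list", length(sources))
  for (z in seq_along(sources)) {
    pooled <- if (M > 0) bind_domains(list(sources[[z]], target_calib)) else sources[[z]]
    pooled$C <- C
    members[[z]] <- fit_plain(pooled, derive_seed(seed, z))
    members[[z]]$domain_id <- sources[[z]]$domain_id
  }
  new_ensemble(members, C)
}

#' Online calibration schedule
#'
#' @param M_total Total number of calibration objects drawn per repeat
#'   (default 20).
#' @param batch Calibration batch size; must divide `M_total` (default 4).
#' @param repeats Number of repeats, each with its own random starting
#'   position (default 10).
#' @param seed Integer seed controlling the draws.
#' @return Object of class `calibration_schedule`.
#' @export
calibration_schedule <- function(M_total = 20L, batch = 4L, repeats = 10L,
                                 seed = 1L) {
  if (M_total %% batch != 0L) stop("batch must divide M_total", call. = FALSE)
  if (repeats < 1L) stop("repeats must be at least 1", call. = FALSE)
  structure(list(M_total = as.integer(M_total), batch = as.integer(batch),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "calibration_schedule")
}

#' Simulate batched online calibration on a target domain
#'
#' Per repeat: the target rows are shuffled, a circular window of `M_total`
#' rows starting at a random position m0 forms the calibration pool, and the
#' remaining rows form the test set (fixed across M within a repeat so the
#' accuracy curve is comparable). For each M in `0, batch, 2*batch, ...,
#' M_total` the chosen method is trained with the first M pool rows and its
#' accuracy on the test set is recorded. The target-only baseline is
#' undefined at M = 0 and recorded as `NA`.
#'
#' @param sources List of source `domain_table`s.
#' @param target Target `domain_table` with at least `M_total + 1` rows.
#' @param schedule A [calibration_schedule()].
#' @param method `"os-jda-mr"` (the transfer ensemble), `"bl1"`, `"bl2"`,
#'   `"bl3"`, or a function `f(sources, target_calib, seed)` returning a
#'   `tsk_ensemble`.
#' @param K Rule count.
#' @param config [adaptation_config()] for the transfer method.
#' @param eta Ridge weight for the baselines.
#' @param h Antecedent width scale.
#' @return List of class `calibration_result`: `accuracy` (repeats x grid
#'   matrix, columns named by M), `M` (grid), `mean` (column means,
#'   `NA`-removed), `method`.
#' @export
run_online_calibration <- function(sources, target, schedule = calibration_schedule(),
                                   method = "os-jda-mr", K = 5L,
                                   config = adaptation_config(), eta = 100,
                                   h = 0.5) {
  n_t <- nrow(target$features)
  if (n_t <= schedule$M_total) {
    stop("target needs more than M_total rows", call. = FALSE)
  }
  grid <- seq(0L, schedule$M_total, by = schedule$batch)
  acc <- matrix(NA_real_, schedule$repeats, length(grid),
                dimnames = list(NULL, paste0("M", grid)))
  trainer <- if (is.function(method)) {
    method
  } else {
    meth <- match.arg(method, c("os-jda-mr", "ablation", "bl1", "bl2", "bl3"))
    function(sources, calib, seed) {
      switch(meth,
        "os-jda-mr" = {
          cfg <- config; cfg$seed <- seed
          tsk_transfer_train(sources, calib, K = K, config = cfg, h = h)
        },
        "ablation" = {
          cfg <- config; cfg$lambda1 <- 0; cfg$lambda2 <- 0; cfg$seed <- seed
          tsk_transfer_train(sources, calib, K = K, config = cfg, h = h)
        },
        "bl1" = train_baseline("bl1", sources, NULL, K = K, eta = eta, h = h, seed = seed),
        "bl2" = if (is.null(calib)) NULL else
          train_baseline("bl2", NULL, calib, K = K, eta = eta, h = h, seed = seed),
        "bl3" = train_baseline("bl3", sources, calib, K = K, eta = eta, h = h, seed = seed)
      )
    }
  }
  for (r in seq_len(schedule$repeats)) {
    rep_seed <- derive_seed(schedule$seed, r)
    draw <- with_seed(rep_seed, {
      perm <- sample.int(n_t)
      m0 <- sample.int(n_t, 1L)
      list(perm = perm, m0 = m0)
    })
    pool_pos <- ((draw$m0 - 1L + seq_len(schedule$M_total) - 1L) %% n_t) + 1L
    pool_idx <- draw$perm[pool_pos]
    test_idx <- setdiff(seq_len(n_t), pool_idx)
    test_x <- target$features[test_idx, , drop = FALSE]
    test_y <- target$labels[test_idx]
    for (gi in seq_along(grid)) {
      M <- grid[gi]
      calib <- if (M > 0L) slice_domain(target, pool_idx[seq_len(M)]) else NULL
      model <- trainer(sources, calib, rep_seed)
      if (is.null(model)) next
      acc[r, gi] <- mean(predict_ensemble(model, test_x) == test_y)
    }
  }
  structure(list(accuracy = acc, M = grid,
                 mean = colMeans(acc, na.rm = TRUE),
                 method = if (is.function(method)) "custom" else method),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result: method '%s', %d repeat(s)>\n",
              x$method, nrow(x$accuracy)))
  print(round(x$mean, 4))
  invisible(x)
}
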