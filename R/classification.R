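# Two-stage random-forest classification: forest/non-forest, then dominant
# leaf type within the forest mask, with explicit cross-scene model transfer.

#' Extract a per-sample feature table from multi-date stacks
#'
#' One row per sample point; one column per band per acquisition date
#' (`B2_d1`, ..., `B12_dK`). Rows touching an invalid pixel in any
#' acquisition are dropped (count reported in attribute `"n_dropped"`).
#'
#' @param stacks List of [band_stack()]s (the multi-date stack of one scene).
#' @param samples A `sample_set` tibble.
#' @return A tibble: sample columns (`row`, `col`, `class_id`, `forest`,
#'   `leaf_type`, `role`) followed by the feature columns; feature names in
#'   attribute `"feature_names"`.
#' @export
extract_features <- function(stacks, samples) {
  stopifnot(length(stacks) >= 1)
  feats <- lapply(seq_along(stacks), function(i) {
    sp <- spectra_at(stacks[[i]], samples$row, samples$col)
    colnames(sp) <- paste0(colnames(sp), "_d", i)
    sp
  })
  fm <- do.call(cbind, feats)
  ok <- stats::complete.cases(fm)
  if (!any(ok)) {
    abort_fc("no sample lies on valid pixels in every acquisition",
             "fc_empty_error")
  }
  out <- dplyr::bind_cols(
    samples[ok, c("row", "col", "class_id", "class", "forest", "leaf_type",
                  "role")],
    tibble::as_tibble(fm[ok, , drop = FALSE])
  )
  attr(out, "feature_names") <- colnames(fm)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Train a random-forest classifier for one task
#'
#' Fits a seeded random forest (default 100 trees, sqrt(p) candidate
#' features per split, unlimited depth) on the training-role rows of a
#' feature table. The label column depends on the task: `forest` ->
#' forest/non-forest, `leaf_type` -> coniferous/broadleaved (non-forest rows
#' are excluded), `change` -> the change class column. Out-of-bag and, when
#' validation rows exist, held-out accuracies are recorded in the model
#' metadata. The fitted model refuses feature tables whose schema differs
#' from its own.
#'
#' @param table Feature table from [extract_features()] (or
#'   [build_feature_stack()] sampling for the change task).
#' @param task One of `"forest"`, `"leaf_type"`, `"change"`.
#' @param n_trees Number of trees; default 100.
#' @param seed Integer RNG seed (single-threaded fit for determinism).
#' @param scene_id Free-text training-scene identifier kept in metadata.
#' @return An `fc_model` object.
#' @export
train_model <- function(table, task = c("forest", "leaf_type", "change"),
                        n_trees = 100, seed = 1L, scene_id = NA_character_) {
  task <- match.arg(task)
  feature_names <- attr(table, "feature_names")
  if (is.null(feature_names)) {
    feature_names <- grep("^(B\\d+A?_d\\d+|t[12]_B\\d+A?|dNDVI|dNBR)$",
                          names(table), value = TRUE)
  }
  lab <- switch(task,
    forest = factor(ifelse(table$forest, "forest", "non_forest"),
                    levels = c("forest", "non_forest")),
    leaf_type = {
      keep <- table$leaf_type %in% c("coniferous", "broadleaved")
      table <- table[keep, , drop = FALSE]
      factor(table$leaf_type[], levels = c("coniferous", "broadleaved"))
    },
    change = factor(table$change_class)
  )
  if (task == "leaf_type") lab <- droplevels(lab)
  is_train <- if (all(is.na(table$role))) rep(TRUE, nrow(table)) else
    table$role == "train"
  train_df <- data.frame(.label = lab[is_train],
                         table[is_train, feature_names, drop = FALSE],
                         check.names = FALSE)
  if (length(unique(train_df$.label)) < 2) {
    abort_fc("training requires at least two classes", "fc_training_error")
  }
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = train_df,
    num.trees = n_trees, seed = seed, num.threads = 1,
    respect.unordered.factors = "order"
  )
  val_acc <- NA_real_
  if (any(!is_train)) {
    val_df <- data.frame(table[!is_train, feature_names, drop = FALSE],
                         check.names = FALSE)
    pred <- predict(fit, val_df, num.threads = 1)$predictions
    val_acc <- mean(pred == lab[!is_train])
  }
  structure(
    list(engine = fit, task = task, feature_names = feature_names,
         levels = levels(lab), n_trees = n_trees, seed = seed,
         scene_id = scene_id,
         oob_accuracy = 1 - fit$prediction.error,
         validation_accuracy = val_acc),
    class = "fc_model"
  )
}

#' @export
print.fc_model <- function(x, ...) {
  cat(sprintf("<fc_model> task=%s, %d trees, %d features, OOB acc %.3f",
              x$task, x$n_trees, length(x$feature_names), x$oob_accuracy))
  if (!is.na(x$validation_accuracy)) {
    cat(sprintf(", validation acc %.3f", x$validation_accuracy))
  }
  cat("\n")
  invisible(x)
}

#' @rdname tidy_forestchange
#' @method glance fc_model
#' @export
glance.fc_model <- function(x, ...) {
  tibble::tibble(task = x$task, n_trees = x$n_trees,
                 n_features = length(x$feature_names),
                 oob_accuracy = x$oob_accuracy,
                 validation_accuracy = x$validation_accuracy)
}

# Stop unless `newdata` columns cover the model's schema exactly.
check_schema <- function(model, cols) {
  if (!identical(intersect(cols, model$feature_names), model$feature_names) ||
      !all(model$feature_names %in% cols)) {
    abort_fc("feature schema does not match the model's training schema",
             "fc_schema_error")
  }
}

# Predict labels for a feature matrix with schema checking.
predict_fc <- function(model, fm) {
  check_schema(model, colnames(fm))
  df <- data.frame(fm[, model$feature_names, drop = FALSE],
                   check.names = FALSE)
  as.character(predict(model$engine, df, num.threads = 1)$predictions)
}

#' Classify a full scene with a fitted model
#'
#' Applies a `"forest"` or `"leaf_type"` model to every valid pixel of a
#' multi-date stack. Applying a model fitted on another scene is the
#' cross-scene transfer regime: the model is used unchanged. For the
#' leaf-type task a forest mask must be supplied; pixels outside it are
#' labelled non-forest.
#'
#' @param stacks List of [band_stack()]s (same dates/bands as training).
#' @param model An `fc_model` with task `"forest"` or `"leaf_type"`.
#' @param within_mask Optional logical matrix (the forest mask) restricting
#'   leaf-type prediction.
#' @return A `classified_map`: integer matrix plus a code table. Forest task:
#'   1 forest, 0 non-forest, NA invalid. Leaf task: 1 coniferous,
#'   2 broadleaved, 0 non-forest, NA invalid.
#' @export
classify_scene <- function(stacks, model, within_mask = NULL) {
  stopifnot(inherits(model, "fc_model"))
  if (model$task == "change") {
    abort_fc("use classify_changes() for change models", "fc_param_error")
  }
  d <- dim(stacks[[1]]$values)
  valid <- Reduce(`&`, lapply(stacks, function(s) s$valid))
  fm <- do.call(cbind, lapply(seq_along(stacks), function(i) {
    m <- matrix(stacks[[i]]$values, nrow = d[1] * d[2])
    colnames(m) <- paste0(fc_bands(), "_d", i)
    m
  }))
  check_schema(model, colnames(fm))
  target <- which(as.vector(valid) &
                    (if (is.null(within_mask)) TRUE else as.vector(within_mask)))
  out <- matrix(NA_integer_, d[1], d[2])
  if (model$task == "forest") {
    codes <- c(non_forest = 0L, forest = 1L)
    out[as.vector(valid)] <- codes[["non_forest"]]
  } else {
    codes <- c(non_forest = 0L, coniferous = 1L, broadleaved = 2L)
    out[as.vector(valid)] <- codes[["non_forest"]]
  }
  if (length(target) > 0) {
    pred <- predict_fc(model, fm[target, , drop = FALSE])
    out[target] <- codes[pred]
  }
  structure(
    list(values = out, codes = codes, task = model$task,
         pixel_size = stacks[[1]]$pixel_size,
         transform = stacks[[1]]$transform),
    class = "classified_map"
  )
}

#' @export
print.classified_map <- function(x, ...) {
  tab <- table(factor(x$values, levels = x$codes,
                      labels = names(x$codes)), useNA = "ifany")
  cat(sprintf("<classified_map> task=%s: %s\n", x$task,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Logical forest mask from a forest-task classified map
#'
#' @param map A `classified_map` from the forest task.
#' @return Logical matrix, TRUE on forest pixels (FALSE on invalid).
#' @export
forest_mask <- function(map) {
  stopifnot(inherits(map, "classified_map"), map$task == "forest")
  m <- map$values == map$codes[["forest"]]
  m[is.na(m)] <- FALSE
  m
}
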