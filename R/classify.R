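#' Build the subject-by-feature matrix for classification
#'
#' One row per subject: the 50 ramp amplitudes ordered by dark duration,
#' optionally followed by age. Missing cycles are imputed by linear
#' interpolation over `dark_ms` from the subject's neighbouring cycles
#' (nearest value at the ends); subjects with more than 40% missing cycles
#' are excluded with a warning. Labels are kept as a factor and one-hot
#' encoded (columns Control, AMD).
#'
#' @param table Amplitude table with ramp rows, `group` and `age_years`.
#' @param include_age Append age as a 51st feature (default `FALSE`).
#' @return A `plr_features` list: `x` (matrix, rownames = subject ids),
#'   `labels` (factor Control/AMD), `y_onehot`, `feature_dark_ms`,
#'   `include_age`.
#' @export
build_features <- function(table, include_age = FALSE) {
  ramp <- table[table$phase == "ramp", ]
  if (nrow(ramp) == 0) stop("no ramp rows in the amplitude table")
  dark_grid <- sort(unique(ramp$dark_ms))
  subjects <- unique(ramp[, c("subject_id", "group", "age_years")])

  rows <- list()
  dropped <- character(0)
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    sub <- ramp[ramp$subject_id == sid, ]
    sub <- sub[order(sub$dark_ms), ]
    ok <- !sub$missing & !is.na(sub$amplitude)
    n_missing <- length(dark_grid) - sum(ok)
    if (n_missing > 0.4 * length(dark_grid)) {
      dropped <- c(dropped, sid)
      next
    }
    if (n_missing > 0) {
      amp <- approx(x = sub$dark_ms[ok], y = sub$amplitude[ok],
                    xout = dark_grid, rule = 2)$y
    } else {
      amp <- sub$amplitude[match(dark_grid, sub$dark_ms)]
    }
    rows[[sid]] <- amp
  }
  if (length(dropped)) {
    warning("excluded subject(s) with > 40% missing cycles: ",
            paste(dropped, collapse = ", "))
    subjects <- subjects[!subjects$subject_id %in% dropped, ]
  }
  x <- do.call(rbind, rows[subjects$subject_id])
  colnames(x) <- paste0("amp_", dark_grid)
  if (include_age) {
    x <- cbind(x, age = subjects$age_years)
  }
  labels <- factor(subjects$group, levels = c("Control", "AMD"))
  y_onehot <- cbind(Control = as.numeric(labels == "Control"),
                    AMD = as.numeric(labels == "AMD"))
  rownames(y_onehot) <- subjects$subject_id
  structure(
    list(x = x, labels = labels, y_onehot = y_onehot,
         feature_dark_ms = dark_grid, include_age = include_age),
    class = "plr_features"
  )
}

#' Standardize features with training-set statistics
#'
#' Per-feature z-scoring using the mean and SD of the training matrix only,
#' applied to any other matrix (no information from held-out data enters the
#' transform). Zero-variance features are centered and left unscaled.
#'
#' @param train Training feature matrix (defines the statistics).
#' @param apply_to Matrix to transform (default: `train` itself).
#' @return The standardized `apply_to` matrix.
#' @export
standardize_features <- function(train, apply_to = train) {
  stopifnot(nrow(train) >= 1, ncol(train) == ncol(apply_to))
  mu <- colMeans(train)
  sdev <- apply(train, 2, sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  sweep(sweep(apply_to, 2, mu, "-"), 2, sdev, "/")
}

# Stratified fold assignment: members of each class are shuffled and dealt
# to folds cyclically, with the cycle start rotated per class so the
# remainder folds differ between classes. For 14 + 14 subjects and 5 folds
# this yields sizes 6,6,6,5,5 with class counts balanced within one in
# every fold.
make_folds <- function(labels, k, stratified = TRUE) {
  n <- length(labels)
  fold <- integer(n)
  if (stratified) {
    cls <- levels(labels)
    for (j in seq_along(cls)) {
      members <- sample(which(labels == cls[j]))
      fold[members] <- ((seq_along(members) - 1L + (j - 1L)) %% k) + 1L
    }
  } else {
    fold <- sample(rep(seq_len(k), length.out = n))
  }
  fold
}

# Stratified inner split: indices of the validation subset within `idx`.
inner_val_split <- function(idx, labels, fraction) {
  val <- integer(0)
  for (cl in levels(labels)) {
    cl_idx <- idx[labels[idx] == cl]
    n_val <- max(1L, round(fraction * length(cl_idx)))
    n_val <- min(n_val, length(cl_idx) - 1L)
    if (n_val < 1) {
      stop("configuration error: fold too small to carve a validation subset")
    }
    val <- c(val, sample(cl_idx, n_val))
  }
  val
}

confusion_metrics <- function(cm) {
  # cm: 2x2, rows = truth (Control, AMD), cols = prediction
  tp <- cm["AMD", "AMD"]; fn <- cm["AMD", "Control"]
  tn <- cm["Control", "Control"]; fp <- cm["Control", "AMD"]
  list(
    accuracy = (tp + tn) / sum(cm),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' Cross-validated CNN classification of recovery curves
#'
#' Stratified k-fold cross-validation: for every fold, features are
#' standardized with the training-fold statistics, an inner stratified
#' validation split (for early stopping) is carved from the training
#' portion, the network is trained, and the held-out fold is evaluated.
#' Held-out data never enter standardization or early stopping. AMD is the
#' positive class for sensitivity.
#'
#' @param features A [build_features()] object.
#' @param cfg A [cv_config()].
#' @return A `plr_cv_result`: `folds` tibble (per-fold `accuracy`,
#'   `sensitivity`, `specificity`, `n`), `confusion` (per-fold 2x2 matrices,
#'   rows = truth), `mean_accuracy`, `sd_accuracy`, `mean_sensitivity`,
#'   `mean_specificity`, `pooled_confusion` and `pooled_accuracy` (the
#'   aggregate over all held-out predictions, reported separately from the
#'   mean of per-fold accuracies), and `fold_assignment`.
#' @export
cross_validate <- function(features, cfg = cv_config()) {
  stopifnot(inherits(features, "plr_features"))
  x <- features$x
  labels <- features$labels
  y <- features$y_onehot
  counts <- table(labels)
  if (cfg$stratified && any(counts < cfg$n_folds)) {
    stop("stratified ", cfg$n_folds, "-fold CV needs at least ",
         cfg$n_folds, " subjects per class")
  }
  with_local_seed(cfg$seed, {
    fold <- make_folds(labels, cfg$n_folds, cfg$stratified)
    fold_rows <- list()
    confusions <- list()
    for (f in seq_len(cfg$n_folds)) {
      test_idx <- which(fold == f)
      train_idx <- which(fold != f)
      if (length(unique(labels[test_idx])) < 2 && !cfg$stratified) {
        stop("fold ", f, " lost a class under non-stratified splitting; ",
             "use stratified = TRUE")
      }
      if (length(unique(labels[train_idx])) < 2) {
        stop("fold ", f, " leaves a single-class training set")
      }
      x_tr_all <- x[train_idx, , drop = FALSE]
      x_tr_std <- standardize_features(x_tr_all)
      x_te_std <- standardize_features(x_tr_all, x[test_idx, , drop = FALSE])
      val_global <- inner_val_split(train_idx, labels, cfg$val_fraction)
      val_pos <- match(val_global, train_idx)
      tr_pos <- setdiff(seq_along(train_idx), val_pos)
      model <- build_and_train_cnn(
        x_tr_std[tr_pos, , drop = FALSE], y[train_idx[tr_pos], , drop = FALSE],
        x_tr_std[val_pos, , drop = FALSE], y[train_idx[val_pos], , drop = FALSE],
        cfg, seed = sample.int(.Machine$integer.max - 1L, 1)
      )
      probs <- predict(model, x_te_std)
      pred <- factor(colnames(probs)[max.col(probs, ties.method = "first")],
                     levels = levels(labels))
      cm <- table(truth = labels[test_idx], prediction = pred)
      cm <- as.matrix(cm)
      met <- confusion_metrics(cm)
      fold_rows[[f]] <- tibble(
        fold = f, n = length(test_idx),
        accuracy = met$accuracy, sensitivity = met$sensitivity,
        specificity = met$specificity
      )
      confusions[[f]] <- cm
    }
    folds <- dplyr::bind_rows(fold_rows)
    pooled <- Reduce(`+`, confusions)
    pooled_met <- confusion_metrics(pooled)
    structure(
      list(
        folds = folds,
        confusion = confusions,
        mean_accuracy = mean(folds$accuracy),
        sd_accuracy = sd(folds$accuracy),
        mean_sensitivity = mean(folds$sensitivity, na.rm = TRUE),
        sd_sensitivity = sd(folds$sensitivity),
        mean_specificity = mean(folds$specificity, na.rm = TRUE),
        sd_specificity = sd(folds$specificity),
        pooled_confusion = pooled,
        pooled_accuracy = pooled_met$accuracy,
        fold_assignment = fold,
        include_age = features$include_age,
        config = cfg
      ),
      class = "plr_cv_result"
    )
  })
}

#' @export
print.plr_cv_result <- function(x, ...) {
  cat("<plr_cv_result>", nrow(x$folds), "folds",
      if (x$include_age) "(amplitudes + age)" else "(amplitudes only)", "\n")
  print(as.data.frame(x$folds), row.names = FALSE)
  cat(sprintf("  mean accuracy %.1f%% (sd %.1f%%), sensitivity %.3f, specificity %.3f\n",
              100 * x$mean_accuracy, 100 * x$sd_accuracy,
              x$mean_sensitivity, x$mean_specificity))
  cat(sprintf("  pooled accuracy %.1f%% over %d held-out subjects\n",
              100 * x$pooled_accuracy, sum(x$pooled_confusion)))
  invisible(x)
}

#' Serialize a cross-validation result to JSON
#'
#' @param result A `plr_cv_result`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(result, path) {
  obj <- list(
    folds = result$folds,
    confusion = lapply(result$confusion, function(m) {
      list(tn = m["Control", "Control"], fp = m["Control", "AMD"],
           fn = m["AMD", "Control"], tp = m["AMD", "AMD"])
    }),
    mean_accuracy = result$mean_accuracy,
    sd_accuracy = result$sd_accuracy,
    mean_sensitivity = result$mean_sensitivity,
    mean_specificity = result$mean_specificity,
    pooled_accuracy = result$pooled_accuracy,
    include_age = result$include_age
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
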