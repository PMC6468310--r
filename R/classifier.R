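## Bootstrap random-forest operon classifier. One ensemble per pair group
## (pure-CDS vs mixed); ten bootstrap rounds of a random 70/30
## train/cross-validation split, 1000 trees per forest, majority voting at
## prediction time.

## simple random split, redrawn (bounded) if the train part ends up
## one-class, which random 70/30 draws can do on small imbalanced groups
draw_two_class_split <- function(y, n_train) {
  for (i in 1:100) {
    tr <- sample.int(length(y), n_train)
    if (length(unique(y[tr])) == 2L) return(tr)
  }
  stop2("could not draw a two-class train split")
}

derive_seeds <- function(seed, n) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max %/% 2L, 1L)
  set.seed(seed)
  sample.int(.Machine$integer.max %/% 2L, n)
}

prepare_features <- function(x, quiet = FALSE) {
  stopifnot(is.data.frame(x))
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  all_na <- vapply(x, function(col) all(is.na(col)), logical(1))
  if (any(all_na)) {
    if (!quiet)
      message("dropping all-missing feature(s): ",
              paste(names(x)[all_na], collapse = ", "))
    x <- x[, !all_na, drop = FALSE]
  }
  if (ncol(x) == 0L) stop2("no usable numeric features")
  x
}

impute_medians <- function(x, med) {
  for (nm in names(x)) {
    miss <- is.na(x[[nm]])
    if (any(miss)) x[[nm]][miss] <- med[[nm]]
  }
  x
}

#' Fit a bootstrap random-forest operon classifier
#'
#' Repeats, for `rounds` bootstrap rounds: draw a fresh simple random
#' train/cross-validation split (`train_frac` of the labelled pairs, not
#' stratified), fit a random forest of `trees` trees on the train part, and
#' record classification accuracy on the held-out part. The headline metric
#' is the arithmetic mean of the round accuracies. All randomness flows from
#' `seed`, expanded into per-round seeds that are stored in the fitted
#' object.
#'
#' Missing feature values are median-imputed (columns that are entirely
#' missing, e.g. CDS-only features in a mixed-group dataset or conservation
#' without a reference panel, are dropped); the imputation medians are stored
#' and reused by [predict.operon_rf()].
#'
#' @param x data.frame of features. Identifier columns (`pair_id`, `gene5`,
#'   `gene3`, `pair_group`, `label`) are ignored if present.
#' @param y 0/1 labels (1 = co-transcribed pair), aligned with rows of `x`.
#' @param rounds bootstrap rounds (default 10).
#' @param train_frac fraction of pairs in each train split (default 0.7).
#' @param trees trees per forest (default 1000).
#' @param seed integer root seed.
#' @param group optional group tag (`"CDS"` or `"mixed"`) recorded in the
#'   model.
#' @return an object of class `operon_rf` with components `members` (the
#'   fitted forests), `cv_accuracies`, `seeds`, `feature_names`, `medians`,
#'   `group`.
#' @export
operon_rf <- function(x, y, rounds = 10L, train_frac = 0.7, trees = 1000L,
                      seed = NULL, group = NULL) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop2("labels must be 0/1")
  x <- prepare_features(x)
  n <- nrow(x)
  if (length(y) != n) stop2("labels and feature rows disagree")
  if (n < 20L) stop2("need at least 20 labelled pairs, got ", n)
  if (length(unique(y)) < 2L) stop2("both classes must be present")
  n_train <- floor(train_frac * n)
  if (n_train < 2L || n_train >= n)
    stop2("train_frac leaves an empty train or cross-validation set")
  seeds <- derive_seeds(seed, rounds)
  med <- vapply(x, function(col) median(col, na.rm = TRUE), numeric(1))
  members <- vector("list", rounds)
  acc <- numeric(rounds)
  for (r in seq_len(rounds)) {
    set.seed(seeds[r])
    tr <- draw_two_class_split(y, n_train)
    med_tr <- vapply(x[tr, , drop = FALSE],
                     function(col) median(col, na.rm = TRUE), numeric(1))
    med_tr[is.na(med_tr)] <- 0
    xtr <- impute_medians(x[tr, , drop = FALSE], med_tr)
    xcv <- impute_medians(x[-tr, , drop = FALSE], med_tr)
    fit <- randomForest::randomForest(xtr, factor(y[tr], levels = c(0L, 1L)),
                                      ntree = trees)
    pred <- as.integer(as.character(predict(fit, xcv)))
    acc[r] <- mean(pred == y[-tr])
    members[[r]] <- fit
  }
  med[is.na(med)] <- 0
  structure(list(members = members, cv_accuracies = acc, seeds = seeds,
                 feature_names = names(x), medians = med,
                 group = group, rounds = rounds, train_frac = train_frac,
                 trees = trees, n = n, call = match.call()),
            class = "operon_rf")
}

#' @export
print.operon_rf <- function(x, ...) {
  cat(sprintf("<operon_rf>%s %d bootstrap rounds x %d trees on %d pairs, %d features\n",
              if (!is.null(x$group)) paste0(" [", x$group, "]") else "",
              x$rounds, x$trees, x$n, length(x$feature_names)))
  cat(sprintf("  mean cross-validation accuracy: %.3f (sd %.3f)\n",
              mean(x$cv_accuracies), sd(x$cv_accuracies)))
  invisible(x)
}

#' @export
summary.operon_rf <- function(object, ...) {
  imp <- importance_operon_rf(object)
  out <- list(group = object$group, rounds = object$rounds,
              cv_accuracies = object$cv_accuracies,
              mean_accuracy = mean(object$cv_accuracies),
              sd_accuracy = sd(object$cv_accuracies),
              importance = imp)
  class(out) <- "summary.operon_rf"
  out
}

#' @export
print.summary.operon_rf <- function(x, ...) {
  cat(sprintf("Bootstrap random-forest operon classifier%s\n",
              if (!is.null(x$group)) paste0(" (", x$group, " group)") else ""))
  cat(sprintf("  round accuracies: %s\n",
              paste(sprintf("%.2f", x$cv_accuracies), collapse = " ")))
  cat(sprintf("  mean %.3f, sd %.3f\n", x$mean_accuracy, x$sd_accuracy))
  cat("  top features by mean impurity importance:\n")
  top <- head(sort(x$importance, decreasing = TRUE), 8L)
  for (nm in names(top)) cat(sprintf("    %-28s %8.2f\n", nm, top[[nm]]))
  invisible(x)
}

importance_operon_rf <- function(object) {
  imps <- vapply(object$members, function(m)
    randomForest::importance(m)[, "MeanDecreaseGini"],
    numeric(length(object$feature_names)))
  rowMeans(matrix(imps, nrow = length(object$feature_names),
                  dimnames = list(object$feature_names)))
}

#' Ensemble feature importance
#'
#' Mean impurity-decrease importance averaged over the bootstrap members.
#'
#' @param x an `operon_rf`.
#' @param ... ignored.
#' @return named numeric vector.
#' @export
importance.operon_rf <- function(x, ...) importance_operon_rf(x)

#' Predict operon pairs by majority vote
#'
#' Each bootstrap member votes 0 or 1 per pair; `score` is the fraction of
#' votes for 1 and the label is 1 when the score reaches `threshold`
#' (default 0.5, so an exact 10-member tie is called 1 - a fixed documented
#' rule rather than platform-dependent rounding).
#'
#' @param object an `operon_rf`.
#' @param newdata data.frame containing the model's feature columns (extra
#'   columns are ignored; missing model features are an error).
#' @param threshold vote threshold in `[0, 1]`.
#' @param ... ignored.
#' @return data.frame with `score` and `label` (plus `pair_id` when present
#'   in `newdata`).
#' @export
predict.operon_rf <- function(object, newdata, threshold = 0.5, ...) {
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols))
    stop2("newdata lacks model feature(s): ", paste(missing_cols, collapse = ", "))
  x <- impute_medians(newdata[, object$feature_names, drop = FALSE],
                      object$medians)
  votes <- vapply(object$members, function(m)
    as.integer(as.character(predict(m, x))), integer(nrow(x)))
  votes <- matrix(votes, nrow = nrow(x))
  score <- rowMeans(votes)
  out <- data.frame(score = score,
                    label = as.integer(score >= threshold))
  if (!is.null(newdata$pair_id)) out <- cbind(pair_id = newdata$pair_id, out)
  out
}

#' Classification accuracy
#'
#' `(TP + TN) / N`: true positives are co-transcribed pairs classified
#' correctly, true negatives are independent pairs classified correctly, N
#' is the number of labelled observations.
#'
#' @param tp,tn,n non-negative integers with `tp + tn <= n`, `n > 0`.
#' @return fraction in `[0, 1]`.
#' @export
accuracy <- function(tp, tn, n) {
  if (any(n <= 0)) stop2("n must be positive")
  if (any(tp + tn > n)) stop2("tp + tn exceeds n")
  (tp + tn) / n
}

## -- feature selection ------------------------------------------------------

#' Wrapped backward feature elimination
#'
#' Iterates: (a) fit a bootstrap ensemble on the current feature set and
#' record its mean cross-validation accuracy, (b) drop the
#' `drop_per_iter` feature(s) with the lowest mean impurity importance.
#' Constant (zero-variance) features are dropped first with a warning. The
#' full `(n_features, accuracy)` trace is returned; the selected set is the
#' smallest one whose mean accuracy is within one standard deviation of the
#' best iteration, a deterministic stand-in for choosing "a high-accuracy,
#' small" set by eye. The trace lets a user override the choice.
#'
#' @inheritParams operon_rf
#' @param rounds_per_iter bootstrap rounds per elimination step.
#' @param drop_per_iter features removed per step.
#' @param trees trees per forest (a few hundred suffice for ranking).
#' @param sd_rule multiples of the best iteration's accuracy SD that still
#'   count as "as good as the best" (default 1).
#' @return object of class `backward_elimination`: `selected` (feature
#'   names), `trace` (data.frame of n_features, mean/sd accuracy, dropped
#'   features), `sets` (feature set at each iteration).
#' @export
backward_elimination <- function(x, y, rounds_per_iter = 10L,
                                 drop_per_iter = 1L, trees = 500L,
                                 train_frac = 0.7, seed = NULL, sd_rule = 1) {
  x <- prepare_features(x)
  if (ncol(x) < 2L) stop2("need at least 2 features to eliminate")
  const <- vapply(x, function(col) sd(col, na.rm = TRUE) == 0 ||
                    all(is.na(col)), logical(1))
  if (any(const)) {
    warning("dropping constant feature(s) before elimination: ",
            paste(names(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  seeds <- derive_seeds(seed, 10000L)
  seed_i <- 0L
  next_seed <- function() { seed_i <<- seed_i + 1L; seeds[seed_i] }
  current <- names(x)
  trace <- list(); sets <- list()
  while (length(current) >= 1L) {
    fit <- operon_rf(x[, current, drop = FALSE], y, rounds = rounds_per_iter,
                     train_frac = train_frac, trees = trees,
                     seed = next_seed())
    imp <- importance_operon_rf(fit)
    trace[[length(trace) + 1L]] <- data.frame(
      n_features = length(current),
      mean_accuracy = mean(fit$cv_accuracies),
      sd_accuracy = sd(fit$cv_accuracies), stringsAsFactors = FALSE)
    sets[[length(sets) + 1L]] <- current
    if (length(current) == 1L) break
    drop_n <- min(drop_per_iter, length(current) - 1L)
    dropped <- names(sort(imp))[seq_len(drop_n)]
    trace[[length(trace)]]$dropped <- paste(dropped, collapse = ",")
    current <- setdiff(current, dropped)
  }
  trace <- do.call(rbind, lapply(trace, function(d) {
    if (is.null(d$dropped)) d$dropped <- ""
    d
  }))
  best <- which.max(trace$mean_accuracy)
  ok <- trace$mean_accuracy >= trace$mean_accuracy[best] -
    sd_rule * trace$sd_accuracy[best]
  pick <- which(ok)[which.min(trace$n_features[ok])]
  structure(list(selected = sets[[pick]], trace = trace, sets = sets,
                 picked_iteration = pick),
            class = "backward_elimination")
}

#' @export
print.backward_elimination <- function(x, ...) {
  cat(sprintf("<backward_elimination> %d -> %d features\n",
              x$trace$n_features[1L], length(x$selected)))
  cat(sprintf("  best mean accuracy %.3f at %d features; selected (1-SD rule): %s\n",
              max(x$trace$mean_accuracy),
              x$trace$n_features[which.max(x$trace$mean_accuracy)],
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

## -- label-error robustness -------------------------------------------------

#' Robustness to injected label errors
#'
#' For each error count 0..`max_errors`, flips that many labels in a fresh
#' copy of the dataset - type I errors turn true non-operon labels (0) into
#' 1, type II errors turn true operon labels (1) into 0 - retrains the
#' bootstrap ensemble on the corrupted labels, and records the mean
#' cross-validation accuracy measured against the ORIGINAL labels.
#'
#' @inheritParams operon_rf
#' @param max_errors largest number of injected errors (default 19).
#' @param error_type `"type_I"` (false positives) or `"type_II"` (false
#'   negatives).
#' @param rounds bootstrap rounds per error count.
#' @return data.frame with `n_errors`, `mean_accuracy`, `sd_accuracy`.
#' @export
error_robustness <- function(x, y, max_errors = 19L,
                             error_type = c("type_I", "type_II"),
                             rounds = 10L, train_frac = 0.7, trees = 500L,
                             seed = NULL) {
  error_type <- match.arg(error_type)
  y <- as.integer(y)
  x <- prepare_features(x, quiet = TRUE)
  target <- if (error_type == "type_I") 0L else 1L
  pool <- which(y == target)
  if (max_errors > length(pool))
    stop2("max_errors (", max_errors, ") exceeds available ", target,
          "-labelled pairs (", length(pool), ")")
  seeds <- derive_seeds(seed, (max_errors + 1L) * (rounds + 1L))
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }
  n <- nrow(x)
  n_train <- floor(train_frac * n)
  res <- lapply(0:max_errors, function(ne) {
    set.seed(next_seed())
    flip <- if (ne > 0L) sample(pool, ne) else integer(0)
    y_err <- y
    y_err[flip] <- 1L - y_err[flip]
    acc <- vapply(seq_len(rounds), function(r) {
      set.seed(next_seed())
      tr <- draw_two_class_split(y_err, n_train)
      med_tr <- vapply(x[tr, , drop = FALSE],
                       function(col) median(col, na.rm = TRUE), numeric(1))
      med_tr[is.na(med_tr)] <- 0
      xtr <- impute_medians(x[tr, , drop = FALSE], med_tr)
      xcv <- impute_medians(x[-tr, , drop = FALSE], med_tr)
      fit <- randomForest::randomForest(
        xtr, factor(y_err[tr], levels = c(0L, 1L)), ntree = trees)
      pred <- as.integer(as.character(predict(fit, xcv)))
      mean(pred == y[-tr])          # scored against the original labels
    }, numeric(1))
    data.frame(n_errors = ne, mean_accuracy = mean(acc),
               sd_accuracy = sd(acc))
  })
  do.call(rbind, res)
}

## -- group routing ----------------------------------------------------------

#' Train per-group ensembles (CDS and mixed)
#'
#' Splits a labelled feature matrix by `pair_group` and fits one
#' [operon_rf()] ensemble per group that has both classes and at least 20
#' pairs.
#'
#' @param features data.frame from [compute_pair_features()].
#' @param labels 0/1 vector aligned with rows.
#' @inheritParams operon_rf
#' @return object of class `operon_classifier`: a list with `CDS` and
#'   `mixed` ensembles (either may be NULL, with a warning).
#' @export
train_operon_classifier <- function(features, labels, rounds = 10L,
                                    train_frac = 0.7, trees = 1000L,
                                    seed = NULL) {
  stopifnot(nrow(features) == length(labels))
  seeds <- derive_seeds(seed, 2L)
  fit_group <- function(grp, s) {
    sel <- features$pair_group == grp
    if (sum(sel) < 20L || length(unique(labels[sel])) < 2L) {
      warning("skipping ", grp, " group: too few pairs or one class only")
      return(NULL)
    }
    operon_rf(features[sel, feature_columns(features), drop = FALSE],
              labels[sel], rounds = rounds, train_frac = train_frac,
              trees = trees, seed = s, group = grp)
  }
  structure(list(CDS = fit_group("CDS", seeds[1L]),
                 mixed = fit_group("mixed", seeds[2L])),
            class = "operon_classifier")
}

#' @export
print.operon_classifier <- function(x, ...) {
  cat("<operon_classifier>\n")
  for (grp in c("CDS", "mixed")) {
    if (is.null(x[[grp]])) cat(sprintf("  %s group: not fitted\n", grp))
    else cat(sprintf("  %s group: mean cv accuracy %.3f (%d pairs)\n",
                     grp, mean(x[[grp]]$cv_accuracies), x[[grp]]$n))
  }
  invisible(x)
}

#' Predict all pairs of a genome, routed by pair group
#'
#' @param object an `operon_classifier`.
#' @param newdata feature data.frame with a `pair_group` column.
#' @param threshold vote threshold (default 0.5, ties called 1).
#' @param strict_strand when TRUE, opposite-strand pairs are forced to label
#'   0 regardless of their score.
#' @param ... ignored.
#' @return data.frame `pair_id`, `gene5`, `gene3`, `pair_group`, `score`,
#'   `label`.
#' @export
predict.operon_classifier <- function(object, newdata, threshold = 0.5,
                                      strict_strand = FALSE, ...) {
  out <- newdata[, intersect(c("pair_id", "gene5", "gene3", "pair_group"),
                             names(newdata)), drop = FALSE]
  out$score <- NA_real_; out$label <- NA_integer_
  for (grp in c("CDS", "mixed")) {
    sel <- newdata$pair_group == grp
    if (!any(sel)) next
    model <- object[[grp]] %||% object[["CDS"]] %||% object[["mixed"]]
    if (is.null(model)) stop2("no fitted ensemble available for group ", grp)
    pr <- predict(model, newdata[sel, , drop = FALSE], threshold = threshold)
    out$score[sel] <- pr$score
    out$label[sel] <- pr$label
  }
  if (strict_strand && !is.null(newdata$same_strand))
    out$label[newdata$same_strand == 0] <- 0L
  rownames(out) <- NULL
  out
}

#' Write pair predictions as TSV
#' @param predictions data.frame from [predict.operon_classifier()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(predictions, path) {
  write.table(predictions, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
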