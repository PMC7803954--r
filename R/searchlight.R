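#' Classifier specification for speaker decoding
#'
#' A soft-margin support vector machine with one-vs-one multiclass
#' reduction. Defaults: linear kernel, C = 1, no feature scaling, ties in
#' the OvO vote broken towards the lexicographically smallest class label.
#'
#' @param kernel "linear" or "rbf".
#' @param C soft-margin parameter (> 0).
#' @param scale_features if TRUE, per-feature standardization estimated on
#'   the training fold only.
#' @param tie_break currently only "lexicographic".
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kernel = c("linear", "rbf"), C = 1,
                            scale_features = FALSE,
                            tie_break = "lexicographic") {
  kernel <- match.arg(kernel)
  vl_assert(C > 0, "C must be positive")
  tie_break <- match.arg(tie_break, "lexicographic")
  structure(list(kernel = kernel, C = C, scale_features = scale_features,
                 tie_break = tie_break),
            class = "classifier_spec")
}

#' Cross-validation scheme
#'
#' Leave-one-run-out ("loro") folds on the run label test generalization to
#' new acquisitions of the same stimuli; leave-one-word-out ("lowo") folds on
#' the word label test generalization of speaker identity to unheard words.
#'
#' @param kind "loro" / "leave_one_run_out" or "lowo" / "leave_one_word_out".
#' @return An object of class `cv_scheme` with fields `kind` and `group_key`
#'   ("run" or "word").
#' @export
cv_scheme <- function(kind = c("loro", "lowo", "leave_one_run_out",
                               "leave_one_word_out")) {
  kind <- match.arg(kind)
  kind <- switch(kind, leave_one_run_out = "loro",
                 leave_one_word_out = "lowo", kind)
  structure(list(kind = kind,
                 group_key = if (kind == "loro") "run" else "word"),
            class = "cv_scheme")
}

#' Voxels inside a searchlight sphere
#'
#' Integer voxel offsets whose physical distance from the center is below
#' (`exclusive`, the default) or up to (`inclusive`) `radius_mm`, intersected
#' with the mask. At 12 mm radius and 2-mm isotropic voxels the exclusive
#' sphere holds 895 voxels and the inclusive one 925 ("about 900").
#'
#' @param mask 3D logical array.
#' @param center length-3 voxel index (1-based), inside the mask.
#' @param radius_mm sphere radius in mm.
#' @param voxel_size_mm per-axis voxel spacing in mm.
#' @param boundary "exclusive" (strict inequality) or "inclusive".
#' @return Integer vector of linear voxel indices (center included).
#' @export
sphere_members <- function(mask, center, radius_mm = 12,
                           voxel_size_mm = c(2, 2, 2),
                           boundary = c("exclusive", "inclusive")) {
  boundary <- match.arg(boundary)
  dims <- dim(mask)
  center <- as.integer(center)
  if (any(center < 1 | center > dims) || mask[matrix(center, 1)] == 0) {
    vl_error("sphere center must lie inside the mask",
             "voicelight_geometry_error")
  }
  off <- sphere_offsets(radius_mm, voxel_size_mm, boundary)
  pts <- sweep(off, 2, center, `+`)
  keep <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
    pts[, 2] >= 1 & pts[, 2] <= dims[2] &
    pts[, 3] >= 1 & pts[, 3] <= dims[3]
  pts <- pts[keep, , drop = FALSE]
  lin <- ijk_to_lin(pts, dims)
  lin[mask[lin] != 0]
}

# Offsets of the sphere around the origin, in voxels.
sphere_offsets <- function(radius_mm, voxel_size_mm,
                           boundary = c("exclusive", "inclusive")) {
  boundary <- match.arg(boundary)
  r_vox <- ceiling(radius_mm / voxel_size_mm)
  g <- expand.grid(dx = -r_vox[1]:r_vox[1],
                   dy = -r_vox[2]:r_vox[2],
                   dz = -r_vox[3]:r_vox[3])
  d2 <- (g$dx * voxel_size_mm[1])^2 + (g$dy * voxel_size_mm[2])^2 +
    (g$dz * voxel_size_mm[3])^2
  keep <- if (boundary == "inclusive") d2 <= radius_mm^2 else d2 < radius_mm^2
  as.matrix(g[keep, , drop = FALSE])
}

#' One-vs-one multiclass SVM prediction
#'
#' Fits one binary soft-margin SVM per class pair on the training set and
#' assigns each test sample the class with the most pairwise votes; vote
#' ties go to the lexicographically smallest label.
#'
#' @param train_x,train_y training features (matrix) and labels.
#' @param test_x test features.
#' @param spec a [classifier_spec()].
#' @return Character vector of predicted labels.
#' @export
ovo_predict <- function(train_x, train_y, test_x, spec = classifier_spec()) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  train_y <- as.character(train_y)
  classes <- sort(unique(train_y))
  vl_assert(length(classes) >= 2, "need at least 2 classes in training")
  counts <- table(train_y)
  if (any(counts < 2)) {
    vl_error("every class needs at least 2 training samples",
             "voicelight_data_error")
  }
  if (spec$scale_features) {
    mu <- colMeans(train_x)
    sdv <- apply(train_x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    train_x <- sweep(sweep(train_x, 2, mu), 2, sdv, "/")
    test_x <- sweep(sweep(test_x, 2, mu), 2, sdv, "/")
  }
  kern <- if (spec$kernel == "linear") "linear" else "radial"
  votes <- matrix(0L, nrow(test_x), length(classes),
                  dimnames = list(NULL, classes))
  for (a in seq_len(length(classes) - 1)) {
    for (b in (a + 1):length(classes)) {
      sel <- train_y %in% classes[c(a, b)]
      fit <- e1071::svm(train_x[sel, , drop = FALSE],
                        factor(train_y[sel], levels = classes[c(a, b)]),
                        type = "C-classification", kernel = kern,
                        cost = spec$C, scale = FALSE)
      pred <- as.character(stats::predict(fit, test_x))
      for (cl in classes[c(a, b)]) {
        votes[, cl] <- votes[, cl] + (pred == cl)
      }
    }
  }
  # max.col with ties.method = "first" on sorted labels = lexicographic
  classes[apply(votes, 1, which.max)]
}

new_confusion_matrix3 <- function(counts, classes) {
  n <- sum(counts)
  cells <- 100 * counts / n
  structure(cells, class = "confusion_matrix3", n_trials = n,
            dimnames = list(presented = classes, answered = classes))
}

#' Cross-validated decoding accuracy on a feature set
#'
#' Splits trials by the scheme's grouping key (run or word), trains the OvO
#' SVM on all other groups and tests on the held-out group, and pools
#' predictions over folds: accuracy = pooled correct / pooled test trials.
#' Also returns the pooled presented-vs-predicted confusion matrix.
#'
#' @param features n_trials x n_features matrix (or a `beta_series`, whose
#'   `betas` are used with its `meta`).
#' @param meta per-trial data frame with `speaker` and the grouping column.
#' @param scheme a [cv_scheme()].
#' @param spec a [classifier_spec()].
#' @return List with `accuracy`, `confusion` (a `confusion_matrix3`),
#'   `n_folds`, `fold_accuracy`.
#' @export
cross_validated_accuracy <- function(features, meta = NULL,
                                     scheme = cv_scheme("loro"),
                                     spec = classifier_spec()) {
  if (inherits(features, "beta_series")) {
    meta <- features$meta
    features <- features$betas  # already trials x voxels
  }
  features <- as.matrix(features)
  stopifnot(is.data.frame(meta), nrow(meta) == nrow(features))
  key <- scheme$group_key
  vl_assert(key %in% names(meta), paste("meta lacks grouping column", key))
  groups <- meta[[key]]
  labels <- as.character(meta$speaker)
  classes <- sort(unique(labels))
  folds <- sort(unique(groups))
  preds <- character(nrow(features))
  fold_acc <- numeric(length(folds))
  for (f in seq_along(folds)) {
    test <- groups == folds[f]
    train_labels <- labels[!test]
    if (length(unique(train_labels)) < length(classes)) {
      vl_error(sprintf("fold '%s': class missing from training set", folds[f]),
               "voicelight_fold_error")
    }
    p <- ovo_predict(features[!test, , drop = FALSE], train_labels,
                     features[test, , drop = FALSE], spec)
    preds[test] <- p
    fold_acc[f] <- mean(p == labels[test])
  }
  counts <- table(factor(labels, classes), factor(preds, classes))
  acc <- sum(diag(counts)) / sum(counts)
  stopifnot(isTRUE(all.equal(acc, mean(preds == labels))))
  list(accuracy = acc,
       confusion = new_confusion_matrix3(unclass(counts), classes),
       n_folds = length(folds),
       fold_accuracy = stats::setNames(fold_acc, folds))
}

#' Searchlight map of cross-validated decoding accuracy
#'
#' Centers a sphere at every mask voxel, decodes speaker identity from the
#' trial betas of the sphere's voxels, and writes the cross-validated
#' accuracy at the center. Deterministic given its inputs.
#'
#' @param betas a `beta_series` from [fit_beta_series()].
#' @param mask 3D logical array of candidate centers (defaults to the beta
#'   series' mask). Features are likewise restricted to mask voxels.
#' @param radius_mm searchlight radius in mm.
#' @param voxel_size_mm voxel spacing in mm.
#' @param scheme,spec see [cross_validated_accuracy()].
#' @param boundary sphere boundary rule, see [sphere_members()].
#' @param min_sphere_voxels spheres clipped below this size are still
#'   classified but collected in the result's `flagged` attribute.
#' @return An `accuracy_map`: 3D array of accuracies (NA outside the mask)
#'   with attributes `chance`, `scheme`, `radius_mm`.
#' @export
run_searchlight <- function(betas, mask = NULL, radius_mm = 12,
                            voxel_size_mm = c(2, 2, 2),
                            scheme = cv_scheme("loro"),
                            spec = classifier_spec(),
                            boundary = "exclusive",
                            min_sphere_voxels = 10L) {
  stopifnot(inherits(betas, "beta_series"))
  if (is.null(mask)) mask <- betas$mask
  dims <- dim(mask)
  vl_assert(any(mask != 0), "mask is empty")
  feat_all <- betas$betas  # n_trials x n_voxels(in betas$voxel_index)
  col_of <- integer(prod(dims))
  col_of[betas$voxel_index] <- seq_along(betas$voxel_index)
  centers <- which(mask != 0 & col_of > 0)
  off <- sphere_offsets(radius_mm, voxel_size_mm, boundary)
  values <- array(NA_real_, dims)
  flagged <- integer(0)
  failed <- integer(0)
  ctr_ijk <- lin_to_ijk(centers, dims)
  for (i in seq_along(centers)) {
    pts <- sweep(off, 2, ctr_ijk[i, ], `+`)
    keep <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
      pts[, 2] >= 1 & pts[, 2] <= dims[2] &
      pts[, 3] >= 1 & pts[, 3] <= dims[3]
    lin <- ijk_to_lin(pts[keep, , drop = FALSE], dims)
    cols <- col_of[lin[mask[lin] != 0]]
    cols <- cols[cols > 0]
    if (length(cols) < min_sphere_voxels) flagged <- c(flagged, centers[i])
    res <- tryCatch(
      cross_validated_accuracy(feat_all[, cols, drop = FALSE], betas$meta,
                               scheme, spec),
      voicelight_fold_error = function(e) NULL)
    if (is.null(res)) failed <- c(failed, centers[i]) else {
      values[centers[i]] <- res$accuracy
    }
  }
  structure(values, class = "accuracy_map",
            chance = 1 / length(unique(betas$meta$speaker)),
            scheme = scheme$kind, radius_mm = radius_mm,
            flagged = flagged, failed = failed)
}

#' Region-of-interest decoding accuracy
#'
#' As [cross_validated_accuracy()], with features taken from every voxel of
#' an explicit ROI instead of local spheres — one accuracy per subject.
#'
#' @param betas a `beta_series`.
#' @param roi_mask 3D logical array.
#' @inheritParams cross_validated_accuracy
#' @return As [cross_validated_accuracy()].
#' @export
roi_accuracy <- function(betas, roi_mask, scheme = cv_scheme("loro"),
                         spec = classifier_spec()) {
  stopifnot(inherits(betas, "beta_series"))
  vl_assert(all(dim(roi_mask) == dim(betas$mask)), "ROI grid mismatch")
  cols <- match(which(roi_mask != 0), betas$voxel_index)
  cols <- cols[!is.na(cols)]
  vl_assert(length(cols) > 0, "ROI contains no voxels of the beta series")
  cross_validated_accuracy(betas$betas[, cols, drop = FALSE], betas$meta,
                           scheme, spec)
}

#' Compare accuracies between schemes, and against chance
#'
#' `scheme_comparison` runs a paired two-sided t-test between two per-subject
#' accuracy vectors; `one_sample_vs_chance` tests one vector against the
#' chance level (one-sided "greater" by default).
#'
#' @param acc_a,acc_b paired per-subject accuracy vectors.
#' @return List with `t`, `df`, `p`.
#' @export
scheme_comparison <- function(acc_a, acc_b) {
  vl_assert(length(acc_a) == length(acc_b) && length(acc_a) >= 2,
            "paired vectors of equal length >= 2 required")
  d <- acc_a - acc_b
  if (stats::sd(d) == 0) {
    return(list(t = 0, df = length(d) - 1, p = 1, degenerate = TRUE))
  }
  ht <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' @rdname scheme_comparison
#' @param acc per-subject accuracies.
#' @param chance chance level on the same scale as `acc` (100/3 for
#'   percentages, 1/3 for proportions).
#' @param alternative "greater" (default), "two.sided" or "less".
#' @export
one_sample_vs_chance <- function(acc, chance = 100 / 3,
                                 alternative = "greater") {
  vl_assert(length(acc) >= 2, "need at least 2 subjects")
  if (stats::sd(acc) == 0) {
    t <- if (mean(acc) == chance) 0 else sign(mean(acc) - chance) * Inf
    p <- if (t > 0) 0 else 1
    return(list(t = t, df = length(acc) - 1, p = p, degenerate = TRUE))
  }
  ht <- stats::t.test(acc, mu = chance, alternative = alternative)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' @export
print.accuracy_map <- function(x, ...) {
  v <- x[!is.na(x)]
  cat("Searchlight accuracy map (", paste(dim(x), collapse = " x "),
      " grid): ", length(v), " defined voxels\n", sep = "")
  cat("  scheme =", attr(x, "scheme"), "; radius =", attr(x, "radius_mm"),
      "mm; chance =", round(attr(x, "chance"), 4), "\n")
  if (length(v)) {
    cat("  accuracy: mean", round(mean(v), 4), "range [",
        round(min(v), 4), ",", round(max(v), 4), "]\n")
  }
  invisible(x)
}
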