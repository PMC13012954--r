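# Five-class NETosis stage classifier: random forest on the per-cell
# FeatureTable, with stratified cross-validation, Gini importances and
# per-image stage-count tables (HitTable).

metaColumns <- function() c("plate", "well", "field", "hours_elapsed",
                            "treatment", "cell_id")

featureColumns <- function(features) {
  setdiff(names(features)[vapply(features, is.numeric, logical(1))],
          metaColumns())
}

# Median imputation for missing child features; medians are computed on the
# training split only and frozen into the model so test folds cannot leak.
fitImputer <- function(X) {
  med <- vapply(X, function(v) {
    m <- stats::median(v[is.finite(v)])
    if (is.finite(m)) m else 0
  }, numeric(1))
  med
}

applyImputer <- function(X, med) {
  for (j in names(med)) {
    v <- X[[j]]
    v[!is.finite(v)] <- med[[j]]
    X[[j]] <- v
  }
  X
}

#' Train the five-class NETosis stage classifier
#'
#' Random forest with 100 trees on the per-cell features; stratified
#' bootstrap per class and a fixed seed make training deterministic.
#' Missing child features are imputed with training-split medians frozen
#' into the model.
#'
#' @param features FeatureTable data.frame (one row per annotated cell)
#' @param labels character/factor vector of stage labels (negative, spread,
#'   disintegrated, netosis, dead), parallel to \code{features} rows;
#'   or an annotation data.frame with columns \code{cell_ref} (row index
#'   into features) and \code{label}
#' @param nTrees number of trees
#' @param seed integer seed
#' @return stageClassifier object
#' @export
trainStageClassifier <- function(features, labels, nTrees = 100L, seed = 1L) {
  if (is.data.frame(labels)) {
    if (any(labels$cell_ref < 1 | labels$cell_ref > nrow(features)))
      stop("annotation references a cell that is not in the feature table",
           call. = FALSE)
    idx <- labels$cell_ref
    y <- labels$label
    features <- features[idx, , drop = FALSE]
  } else {
    stopifnot(length(labels) == nrow(features))
    y <- labels
  }
  if (is.factor(y)) {
    # explicit factor levels declare the expected classes: none may be empty
    cnt <- table(y)
    if (any(cnt == 0))
      stop("class '", names(cnt)[cnt == 0][1], "' has 0 examples",
           call. = FALSE)
  }
  y <- factor(as.character(y), levels = stageLevels())
  if (anyNA(y)) stop("labels must be one of: ",
                     paste(stageLevels(), collapse = ", "), call. = FALSE)
  y <- droplevels(y)
  if (nlevels(y) < 2L)
    stop("need at least two classes to train", call. = FALSE)
  fcols <- featureColumns(features)
  X <- features[, fcols, drop = FALSE]
  keepCol <- vapply(X, function(v) any(is.finite(v)), logical(1))
  X <- X[, keepCol, drop = FALSE]
  med <- fitImputer(X)
  X <- applyImputer(X, med)
  # drop zero-variance features so an all-constant column cannot perturb
  # candidate-variable sampling (predictions are then invariant to its removal)
  informative <- vapply(X, function(v) max(v) > min(v), logical(1))
  if (!any(informative))
    stop("no informative (non-constant) features", call. = FALSE)
  X <- X[, informative, drop = FALSE]
  med <- med[names(X)]
  df <- X
  df$.class <- y
  set.seed(seed)
  fit <- ranger::ranger(dependent.variable.name = ".class", data = df,
                        num.trees = nTrees, probability = TRUE,
                        importance = "impurity", seed = as.integer(seed),
                        num.threads = 1L)
  structure(list(forest = fit, featureNames = names(X), imputeMedians = med,
                 classes = levels(y), nTrees = nTrees, seed = seed,
                 schemaHash = schemaHash(names(X))),
            class = "stageClassifier")
}

schemaHash <- function(cols) {
  # order-sensitive rolling checksum of the feature schema
  v <- utf8ToInt(paste(cols, collapse = "|"))
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647
  h
}

#' @export
print.stageClassifier <- function(x, ...) {
  cat(sprintf("stageClassifier: %d trees, %d features, classes: %s\n",
              x$nTrees, length(x$featureNames),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

predictStageMatrix <- function(model, features) {
  if (!all(model$featureNames %in% names(features)))
    stop("feature schema mismatch between model and feature table",
         call. = FALSE)
  X <- features[, model$featureNames, drop = FALSE]
  if (schemaHash(names(X)) != model$schemaHash)
    stop("feature schema mismatch between model and feature table",
         call. = FALSE)
  X <- applyImputer(X, model$imputeMedians)
  predict(model$forest, X, num.threads = 1L)$predictions
}

#' Classify cells and tally per-image stage counts
#'
#' Each cell receives exactly one stage by majority vote of the forest;
#' exact vote ties break by the fixed class order negative < spread <
#' disintegrated < netosis < dead. The HitTable has one row per image key
#' with the five class counts and the total cell count (counts sum to the
#' total by construction).
#'
#' @param model from \code{\link{trainStageClassifier}}
#' @param features FeatureTable for the cells to classify
#' @return list: \code{labels} (factor per cell), \code{hitTable}
#'   (data.frame per image)
#' @export
classifyAndTally <- function(model, features) {
  lv <- stageLevels()
  if (nrow(features) == 0L) {
    ht <- data.frame(matrix(0L, 0, 5, dimnames = list(NULL, lv)))
    ht$total <- integer(0)
    return(list(labels = factor(character(0), lv), hitTable = ht))
  }
  pr <- predictStageMatrix(model, features)
  full <- matrix(0, nrow(pr), length(lv), dimnames = list(NULL, lv))
  full[, colnames(pr)] <- pr
  # which.max takes the first maximum, i.e. ties resolve to the earlier
  # class in the fixed order negative < spread < disintegrated < netosis < dead
  lab <- apply(full, 1, function(p) lv[which.max(p)])
  labels <- factor(lab, levels = lv)
  keys <- features[, intersect(c("plate", "well", "field", "hours_elapsed",
                                 "treatment"), names(features)), drop = FALSE]
  if (ncol(keys) == 0L) keys <- data.frame(image = rep(1L, nrow(features)))
  keyStr <- do.call(paste, c(keys, sep = "\r"))
  ht <- do.call(rbind, lapply(split(seq_along(keyStr), keyStr), function(ix) {
    cnt <- table(labels[ix])
    cbind(keys[ix[1], , drop = FALSE],
          as.data.frame(t(as.integer(cnt[lv]))) |>
            stats::setNames(lv),
          data.frame(total = length(ix)))
  }))
  rownames(ht) <- NULL
  list(labels = labels, hitTable = ht)
}

#' Stratified k-fold cross-validation of the stage classifier
#'
#' Folds are stratified by class (each fold holds about 1/k of every class,
#' so 5 folds give the 80/20 train-test split per fold). Per-class
#' precision, recall and F1 are computed on each held-out fold and averaged
#' over folds; confusion matrices are summed across folds and
#' row-normalised (rows = true classes, summing to 1).
#'
#' @param features FeatureTable of annotated cells
#' @param labels stage labels parallel to rows
#' @param k number of folds
#' @param nTrees trees per fold model
#' @param seed integer seed (fold assignment and training)
#' @return list: \code{metrics} (per-class precision/recall/F1 averaged over
#'   folds), \code{confusion} (row-normalised), \code{confusionCounts},
#'   \code{foldMetrics}
#' @export
crossValidate <- function(features, labels, k = 5L, nTrees = 100L, seed = 1L) {
  if (is.data.frame(labels)) {
    features <- features[labels$cell_ref, , drop = FALSE]
    labels <- labels$label
  }
  y <- factor(as.character(labels), levels = stageLevels())
  y <- droplevels(y)
  tab <- table(y)
  if (any(tab < k))
    stop("class '", names(tab)[which.min(tab)], "' has fewer than k = ", k,
         " members", call. = FALSE)
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    ix <- sample(which(y == cl))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  classes <- levels(y)
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  fm <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- trainStageClassifier(features[tr, , drop = FALSE], y[tr],
                                  nTrees = nTrees, seed = seed + f)
    pred <- classifyAndTally(model, features[!tr, , drop = FALSE])$labels
    pred <- factor(as.character(pred), levels = classes)
    cm <- table(true = y[!tr], predicted = pred)
    conf <- conf + as.matrix(cm)
    fm[[f]] <- perClassMetrics(as.matrix(cm))
  }
  metrics <- Reduce(`+`, fm) / k
  confN <- conf / pmax(rowSums(conf), 1)
  list(metrics = as.data.frame(metrics), confusion = confN,
       confusionCounts = conf,
       foldMetrics = lapply(fm, as.data.frame))
}

perClassMetrics <- function(cm) {
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  m <- cbind(precision = prec, recall = rec, f1 = f1)
  rownames(m) <- rownames(cm)
  m
}

#' Normalised Gini feature importances
#'
#' Mean reduction in Gini impurity per feature across all trees, normalised
#' to sum to 1 and sorted descending.
#'
#' @param model from \code{\link{trainStageClassifier}}
#' @param top optionally return only the top-n features
#' @return named numeric vector
#' @export
featureImportances <- function(model, top = NULL) {
  imp <- ranger::importance(model$forest)
  imp <- pmax(imp, 0)
  imp <- sort(imp / sum(imp), decreasing = TRUE)
  if (!is.null(top)) imp <- imp[seq_len(min(top, length(imp)))]
  imp
}

#' Pairwise univariate feature comparisons across classes
#'
#' Rank-sum (Mann-Whitney) comparison of each feature between every pair of
#' classes, with Holm step-down adjustment across the pair set per feature.
#'
#' @param features FeatureTable (or any numeric data.frame)
#' @param labels class labels parallel to rows
#' @param whichFeatures optional subset of feature columns
#' @return data.frame: feature, class_a, class_b, p, p_adjusted
#' @export
pairwiseFeatureTests <- function(features, labels, whichFeatures = NULL) {
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least two classes", call. = FALSE)
  fcols <- whichFeatures %||% featureColumns(features)
  prs <- utils::combn(levels(y), 2, simplify = FALSE)
  out <- list()
  for (fc in fcols) {
    v <- features[[fc]]
    p <- vapply(prs, function(pr) {
      a <- v[y == pr[1] & is.finite(v)]
      b <- v[y == pr[2] & is.finite(v)]
      if (length(a) < 2L || length(b) < 2L) {
        warning("pair ", pr[1], "/", pr[2], " skipped for ", fc,
                ": too few observations")
        return(NA_real_)
      }
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }, numeric(1))
    out[[fc]] <- data.frame(
      feature = fc,
      class_a = vapply(prs, `[`, character(1), 1),
      class_b = vapply(prs, `[`, character(1), 2),
      p = p, p_adjusted = stats::p.adjust(p, "holm"))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
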