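# Group-difference statistics (Kruskal-Wallis gatekeeping Dunn's pairwise
# rank tests) and the proof-of-concept one-vs-one ECOC Gaussian-SVM
# three-group classifier with stratified cross-validation.

#' Kruskal-Wallis screening with Dunn's post-hoc test
#'
#' For every feature column, groups are compared with the Kruskal-Wallis
#' rank test (tie-corrected). Features whose KW p-value falls below `alpha`
#' receive Dunn's multiple-comparison z-tests on mean ranks for every group
#' pair; pairwise p-values are only reported where KW rejected
#' (gatekeeping). Constant features or features observed in fewer than two
#' groups are skipped.
#'
#' @param table A tibble with a `group` column and numeric feature columns
#'   (e.g. from [cohort_features()]). A `subject` column is ignored.
#' @param alpha Significance level for both stages (default 0.05).
#' @param features Feature columns to test; default all numeric columns.
#' @param p_adjust Multiplicity correction for the Dunn p-values
#'   (`"none"`, the historical convention here, or any [stats::p.adjust()]
#'   method such as `"holm"`).
#' @return A tibble of class `last_significance`: one row per feature with
#'   `H`, `p_kw`, `significant` and one `p_<A>_<B>` column per group pair.
#' @export
kruskal_dunn <- function(table, alpha = 0.05, features = NULL,
                         p_adjust = "none") {
  if (!"group" %in% names(table)) stop_validation("feature table needs a 'group' column")
  grp <- as.factor(table$group)
  if (is.null(features)) {
    features <- names(table)[vapply(table, is.numeric, logical(1))]
    features <- setdiff(features, c("subject"))
  }
  lv <- levels(grp)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  pair_names <- vapply(pairs, function(p) paste0("p_", p[1], "_", p[2]),
                       character(1))
  rows <- list()
  for (f in features) {
    v <- table[[f]]
    ok <- !is.na(v)
    g <- droplevels(grp[ok])
    v <- v[ok]
    if (nlevels(g) < 2L || length(unique(v)) < 2L) next   # skipped, degenerate
    kw <- suppressWarnings(kruskal.test(v, g))
    row <- tibble(feature = f, H = unname(kw$statistic),
                  p_kw = kw$p.value, significant = kw$p.value < alpha)
    dunn <- setNames(rep(NA_real_, length(pairs)), pair_names)
    if (isTRUE(row$significant)) {
      dp <- dunn_pairwise(v, g, p_adjust)
      for (k in seq_along(pairs)) {
        key <- paste(pairs[[k]], collapse = "|")
        if (key %in% names(dp)) dunn[pair_names[k]] <- dp[[key]]
      }
    }
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(row, as_tibble(as.list(dunn)))
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(feature = character(), H = numeric(), p_kw = numeric(),
           significant = logical())
  attr(out, "alpha") <- alpha
  class(out) <- c("last_significance", class(out))
  out
}

# Dunn's z-test on mean ranks with tie correction; returns named p-values
# ("A|B") for every pair of levels present.
dunn_pairwise <- function(v, g, p_adjust = "none") {
  r <- rank(v)
  n <- length(v)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_ranks <- tapply(r, g, mean)
  ns <- table(g)
  lv <- levels(g)
  ps <- c()
  for (i in seq_len(length(lv) - 1L)) for (j in (i + 1L):length(lv)) {
    a <- lv[i]; b <- lv[j]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
    ps[paste(a, b, sep = "|")] <- 2 * pnorm(-abs(z))
  }
  stats::p.adjust(ps, method = p_adjust)
}

#' @export
tidy.last_significance <- function(x, ...) {
  as_tibble(unclass2(x))
}

#' @export
glance.last_significance <- function(x, ...) {
  tibble(n_features = nrow(x),
         n_significant = sum(x$significant),
         alpha = attr(x, "alpha"))
}

unclass2 <- function(x) {
  class(x) <- setdiff(class(x), "last_significance")
  x
}

# One-vs-one ECOC codebook for k classes: one dichotomizer per class pair;
# +1 for the pair's first class, -1 for the second, 0 elsewhere.
ecoc_codebook <- function(classes) {
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  M <- matrix(0L, nrow = length(classes), ncol = length(pairs),
              dimnames = list(classes,
                              vapply(pairs, paste, character(1), collapse = "_vs_")))
  for (j in seq_along(pairs)) {
    M[pairs[[j]][1], j] <- 1L
    M[pairs[[j]][2], j] <- -1L
  }
  M
}

#' Train the one-vs-one ECOC Gaussian-SVM classifier
#'
#' The three-group problem is reduced to one binary Gaussian-kernel SVM per
#' class pair; each dichotomizer trains on its two classes only. Features
#' are median-imputed and standardized with training-set statistics. The
#' kernel is `k(x, x') = exp(-gamma * |x - x'|^2)`; `gamma_mode = "medium"`
#' uses the Medium-Gaussian convention `gamma = 1/n_features` (kernel scale
#' `sqrt(n)`), `gamma_mode = "paper"` the literal `gamma = n_features`.
#'
#' @param x Numeric feature matrix or tibble (rows = subjects).
#' @param y Group labels; all classes must be present.
#' @param gamma_mode `"medium"` (default) or `"paper"`.
#' @param cost SVM box constraint (default 1).
#' @return An object of class `last_ecoc`.
#' @export
train_ecoc_svm <- function(x, y, gamma_mode = c("medium", "paper"), cost = 1) {
  gamma_mode <- match.arg(gamma_mode)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 3L) {
    stop_validation("ECOC training needs all three classes present (got %d)",
                    length(classes))
  }
  med <- apply(x, 2, median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  sg[sg == 0 | is.na(sg)] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
  nfeat <- ncol(x)
  gamma <- if (gamma_mode == "paper") nfeat else 1 / nfeat
  M <- ecoc_codebook(classes)
  fits <- list()
  for (j in seq_len(ncol(M))) {
    pos <- classes[M[, j] == 1L]
    neg <- classes[M[, j] == -1L]
    sel <- y %in% c(pos, neg)
    yy <- factor(ifelse(y[sel] == pos, "pos", "neg"), levels = c("pos", "neg"))
    fits[[colnames(M)[j]]] <- e1071::svm(
      x = xs[sel, , drop = FALSE], y = yy, type = "C-classification",
      kernel = "radial", gamma = gamma, cost = cost, scale = FALSE
    )
  }
  structure(list(fits = fits, codebook = M, classes = classes,
                 center = mu, scale = sg, impute = med,
                 gamma = gamma, gamma_mode = gamma_mode, cost = cost,
                 class_sizes = table(factor(y, levels = classes))),
            class = "last_ecoc")
}

#' Predict group labels from an ECOC model
#'
#' Each dichotomizer votes +1/-1; the predicted class minimizes the Hamming
#' distance between the vote vector and the class codeword (zero entries
#' excluded). Ties break toward the class with more training samples.
#'
#' @param object A `last_ecoc` model.
#' @param newdata Feature matrix/tibble with the training columns.
#' @param ... Unused.
#' @return Character vector of predicted classes.
#' @export
predict.last_ecoc <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (ncol(x) != length(object$center)) {
    stop_validation("prediction input has %d features; model expects %d",
                    ncol(x), length(object$center))
  }
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- object$impute[j]
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  M <- object$codebook
  votes <- matrix(0L, nrow(x), ncol(M))
  for (j in seq_len(ncol(M))) {
    pr <- predict(object$fits[[j]], xs)
    votes[, j] <- ifelse(pr == "pos", 1L, -1L)
  }
  out <- character(nrow(x))
  sizes <- as.numeric(object$class_sizes)
  for (i in seq_len(nrow(x))) {
    dist <- vapply(seq_len(nrow(M)), function(cl) {
      nz <- M[cl, ] != 0L
      sum(votes[i, nz] != M[cl, nz])
    }, numeric(1))
    cand <- which(dist == min(dist))
    if (length(cand) > 1L) cand <- cand[order(-sizes[cand], cand)][1]
    out[i] <- object$classes[cand]
  }
  out
}

#' @exportS3Method base::print
print.last_ecoc <- function(x, ...) {
  cat(sprintf("<last_ecoc> %d classes, %d dichotomizers, gamma = %g (%s)\n",
              length(x$classes), length(x$fits), x$gamma, x$gamma_mode))
  invisible(x)
}

#' @export
tidy.last_ecoc <- function(x, ...) {
  tibble(dichotomizer = names(x$fits),
         n_support_vectors = vapply(x$fits, function(f) f$tot.nSV, numeric(1)),
         gamma = x$gamma, cost = x$cost)
}

#' @export
glance.last_ecoc <- function(x, ...) {
  tibble(n_classes = length(x$classes), n_features = length(x$center),
         gamma = x$gamma, gamma_mode = x$gamma_mode, cost = x$cost)
}

# Stratified fold assignment: within each class, shuffled round-robin.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated accuracy of the ECOC classifier
#'
#' Stratified k-fold cross-validation. Imputation, standardization and
#' (optionally) feature selection are fitted inside each training fold only;
#' by default the features entering the classifier are those flagged
#' significant by [kruskal_dunn()] on the training fold.
#'
#' @param table Feature table with `group` and numeric features.
#' @param k Number of folds (default 5).
#' @param seed Integer seed fixing the fold assignment.
#' @param gamma_mode,cost Passed to [train_ecoc_svm()].
#' @param select_features Select KW-significant features inside each
#'   training fold (default TRUE). When FALSE all features are used.
#' @param alpha Selection level (default 0.05).
#' @return An object of class `last_cv`: list with `accuracy` (percent),
#'   `per_fold`, `confusion` and `predictions`.
#' @export
cross_validate <- function(table, k = 5L, seed = 1L,
                           gamma_mode = c("medium", "paper"), cost = 1,
                           select_features = TRUE, alpha = 0.05) {
  gamma_mode <- match.arg(gamma_mode)
  if (!"group" %in% names(table)) stop_validation("feature table needs a 'group' column")
  y <- as.character(table$group)
  feats <- names(table)[vapply(table, is.numeric, logical(1))]
  if (k < 2L) stop_validation("need at least 2 folds")
  if (any(table(y) < k)) {
    stop_validation("every class needs at least k = %d members", k)
  }
  fold <- stratified_folds(y, k, seed)
  pred <- character(length(y))
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    use <- feats
    if (select_features) {
      sig <- kruskal_dunn(table[tr, , drop = FALSE], alpha = alpha,
                          features = feats)
      use <- sig$feature[sig$significant]
      if (length(use) < 2L) use <- feats   # fall back when selection collapses
    }
    model <- train_ecoc_svm(table[tr, use, drop = FALSE], y[tr],
                            gamma_mode = gamma_mode, cost = cost)
    pred[te] <- predict(model, table[te, use, drop = FALSE])
    per_fold[f] <- mean(pred[te] == y[te]) * 100
  }
  confusion <- table(truth = y, predicted = pred)
  structure(list(accuracy = mean(pred == y) * 100,
                 per_fold = per_fold,
                 confusion = confusion,
                 predictions = tibble(truth = y, predicted = pred,
                                      fold = fold),
                 k = k, seed = seed, gamma_mode = gamma_mode),
            class = "last_cv")
}

#' @exportS3Method base::print
print.last_cv <- function(x, ...) {
  cat(sprintf("<last_cv> %d-fold accuracy %.1f%% (folds: %s)\n",
              x$k, x$accuracy, paste(sprintf("%.0f", x$per_fold), collapse = ", ")))
  invisible(x)
}

#' @export
glance.last_cv <- function(x, ...) {
  tibble(accuracy = x$accuracy, k = x$k, seed = x$seed,
         gamma_mode = x$gamma_mode,
         fold_sd = sd(x$per_fold))
}

#' Chance-level accuracy estimate by label permutation
#'
#' Runs [cross_validate()] on the table with group labels permuted, giving
#' an empirical chance baseline for the observed accuracy.
#'
#' @param table Feature table with `group`.
#' @param k,seed,... Passed to [cross_validate()]; the permutation also uses
#'   `seed`.
#' @return A `last_cv` object on the permuted labels.
#' @export
permuted_baseline <- function(table, k = 5L, seed = 1L, ...) {
  set.seed(seed + 1000003L)
  table$group <- sample(table$group)
  cross_validate(table, k = k, seed = seed, ...)
}
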