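## Fisher linear discriminant analysis of the three duet features with
## lineage as the class.  The discriminant directions are the leading
## eigenvectors of W^-1 B (pooled within-class scatter W, between-class
## scatter B); for two univariate classes this maximizes the Fisher
## criterion (mu1 - mu2)^2 / (s1^2 + s2^2).  Directions are scaled so the
## within-class covariance of the scores is spherical, which makes
## nearest-centroid (plus log-prior) allocation the Gaussian equal-
## covariance rule.

#' Fisher criterion of two univariate samples
#'
#' `(mean(x1) - mean(x2))^2 / (var(x1) + var(x2))`: squared group
#' separation over the summed scatter.
#'
#' @param x1,x2 Numeric samples.
#' @return The criterion value.
#' @export
fisher_criterion <- function(x1, x2) {
  (mean(x1) - mean(x2))^2 / (var(x1) + var(x2))
}

#' Fit a Fisher linear discriminant model
#'
#' @param data Data frame containing the feature columns and the class
#'   column.
#' @param features Character vector of feature column names.
#' @param class Name of the class column.
#' @param standardize Z-standardize each feature before fitting (default
#'   `TRUE`); with standardization the fit is invariant to feature
#'   rescaling.
#' @return An `lda_model`: class means and priors (in the transformed
#'   space), discriminant directions (`scaling`, one column per LD) with
#'   `proportion_of_trace`, the pooled within-class covariance, and the
#'   transform parameters.
#' @export
fit_lda <- function(data, features, class, standardize = TRUE) {
  stopifnot(all(features %in% names(data)), class %in% names(data))
  X <- as.matrix(data[, features, drop = FALSE])
  storage.mode(X) <- "double"
  cl <- factor(data[[class]])
  k <- nlevels(cl)
  if (k < 2L) stop("need at least two classes", call. = FALSE)
  counts <- table(cl)
  if (any(counts < 2L)) {
    stop("every class needs n >= 2: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  centre <- if (standardize) colMeans(X) else rep(0, ncol(X))
  scale_ <- if (standardize) apply(X, 2L, sd) else rep(1, ncol(X))
  if (any(scale_ == 0)) {
    stop("constant feature(s): ", paste(features[scale_ == 0], collapse = ", "),
         call. = FALSE)
  }
  Z <- sweep(sweep(X, 2L, centre), 2L, scale_, "/")
  sc <- .scatter_matrices(Z, cl)
  n <- nrow(Z)
  Winv <- tryCatch(solve(sc$W), error = function(e) {
    stop("singular pooled within-class scatter; features may be collinear: ",
         paste(features, collapse = ", "), call. = FALSE)
  })
  eg <- eigen(Winv %*% sc$B)
  lam <- Re(eg$values)
  vec <- Re(eg$vectors)
  r <- min(k - 1L, ncol(Z))
  ord <- order(lam, decreasing = TRUE)[seq_len(r)]
  lam <- pmax(lam[ord], 0)
  A <- vec[, ord, drop = FALSE]
  # scale each direction so scores have unit pooled within-class variance
  Sw <- sc$W / (n - k)
  for (j in seq_len(r)) {
    A[, j] <- A[, j] / sqrt(drop(t(A[, j]) %*% Sw %*% A[, j]))
  }
  means <- do.call(rbind, lapply(levels(cl), function(g) {
    colMeans(Z[cl == g, , drop = FALSE])
  }))
  rownames(means) <- levels(cl)
  # sign convention: first class centroid non-negative on each LD
  sm <- means %*% A
  for (j in seq_len(r)) if (sm[1L, j] < 0) A[, j] <- -A[, j]
  dimnames(A) <- list(features, paste0("LD", seq_len(r)))
  prop <- if (sum(lam) > 1e-10) lam / sum(lam) else rep(NA_real_, r)
  structure(
    list(means = means, scaling = A, eigenvalues = lam,
         proportion_of_trace = prop, priors = as.vector(counts) / n,
         classes = levels(cl), features = features, class = class,
         within_cov = Sw, centre = centre, scale = scale_,
         standardize = standardize,
         degenerate = sum(lam) < 1e-10),
    class = "lda_model"
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes, %d feature(s), %d discriminant direction(s)\n",
              length(x$classes), length(x$features), ncol(x$scaling)))
  cat("proportion of trace:",
      paste(sprintf("%s %.1f%%", colnames(x$scaling),
                    100 * x$proportion_of_trace), collapse = ", "), "\n")
  invisible(x)
}

#' Project rows into discriminant space
#'
#' @param model An [fit_lda()] model.
#' @param data Data frame with the model's feature columns.
#' @return Matrix of LD scores (one row per observation).
#' @export
lda_scores <- function(model, data) {
  miss <- setdiff(model$features, names(data))
  if (length(miss)) {
    stop("missing feature column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(data[, model$features, drop = FALSE])
  storage.mode(X) <- "double"
  Z <- sweep(sweep(X, 2L, model$centre), 2L, model$scale, "/")
  Z %*% model$scaling
}

#' Classify observations and build the confusion matrix
#'
#' Allocation is by the Gaussian equal-covariance rule in score space:
#' nearest class centroid penalized by `-2 log(prior)`.  When `data`
#' carries the true class column, a (resubstitution) confusion matrix and
#' the misclassified row ids are included.
#'
#' @param model An [fit_lda()] model.
#' @param data Data frame with the model's features (and optionally the
#'   class column).
#' @return List with `assigned` (factor), and when truth is available
#'   `confusion` (true x assigned counts), `misclassified` (row ids) and
#'   `accuracy` (fraction correct).
#' @export
lda_classify <- function(model, data) {
  S <- lda_scores(model, data)
  centroids <- model$means %*% model$scaling
  d2 <- sapply(seq_along(model$classes), function(j) {
    rowSums(sweep(S, 2L, centroids[j, ], "-")^2) - 2 * log(model$priors[j])
  })
  d2 <- matrix(d2, nrow = nrow(S))
  assigned <- factor(model$classes[max.col(-d2, ties.method = "first")],
                     levels = model$classes)
  out <- list(assigned = assigned, scores = S)
  if (model$class %in% names(data)) {
    truth <- factor(data[[model$class]], levels = model$classes)
    out$confusion <- table(truth = truth, assigned = assigned)
    out$misclassified <- which(as.character(truth) != as.character(assigned))
    out$accuracy <- mean(as.character(truth) == as.character(assigned))
  }
  out
}

#' Biplot data: scores, loadings, and 95% class ellipses
#'
#' @param model An [fit_lda()] model with >= 2 discriminant directions.
#' @param data Data frame with features (and the class column for
#'   ellipses).
#' @return List with `scores` (LD1/LD2 per row), `loadings` (per-feature
#'   direction vectors), and `ellipses` (per class: centre, axis lengths,
#'   angle of the 95% normal-theory ellipse).
#' @export
biplot_data <- function(model, data) {
  if (ncol(model$scaling) < 2L) {
    stop("biplot needs at least two discriminant directions", call. = FALSE)
  }
  S <- lda_scores(model, data)[, 1:2, drop = FALSE]
  loadings <- model$scaling[, 1:2, drop = FALSE]
  ellipses <- NULL
  if (model$class %in% names(data)) {
    cl <- factor(data[[model$class]], levels = model$classes)
    rad <- sqrt(qchisq(0.95, 2))
    ellipses <- lapply(levels(cl), function(g) {
      Sg <- S[cl == g, , drop = FALSE]
      ctr <- colMeans(Sg)
      cv <- if (nrow(Sg) > 2L) cov(Sg) else diag(2L)
      eg <- eigen(cv, symmetric = TRUE)
      list(class = g, centre = ctr,
           axes = rad * sqrt(pmax(eg$values, 0)),
           angle = atan2(eg$vectors[2L, 1L], eg$vectors[1L, 1L]))
    })
    names(ellipses) <- levels(cl)
  }
  list(scores = S, loadings = loadings, ellipses = ellipses)
}
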