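#' Fit a shared-covariance linear discriminant model
#'
#' Classic LDA in which every class shares one pooled within-class covariance
#' estimate, so the fitted class means are the only discriminative
#' parameters. A small ridge (`lambda` times the mean diagonal variance) is
#' added to the pooled covariance to guarantee invertibility on small ROI
#' slices.
#'
#' @param x Numeric matrix, observations x features (typically z-scored).
#' @param labels Class label per row.
#' @param classes Optional class order (default: sorted unique labels); the
#'   order fixes tie-breaking in prediction and the sign convention of mean
#'   differences.
#' @param lambda Ridge fraction (default 1e-3).
#' @return An object of class `lda_shared` with elements `means` (classes x
#'   features), `cov`, `priors`, `classes`.
#' @export
fit_lda_shared <- function(x, labels, classes = NULL, lambda = 1e-3) {
  x <- as.matrix(x)
  if (is.null(classes)) classes <- sort(unique(labels))
  if (length(classes) < 2L) stop_input("need at least 2 classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L)) {
    stop_input("every class needs >= 2 observations (short: ",
               paste(names(counts)[counts < 2], collapse = ", "), ")")
  }
  p <- ncol(x)
  means <- matrix(NA_real_, length(classes), p,
                  dimnames = list(classes, colnames(x)))
  S <- matrix(0, p, p)
  for (cl in classes) {
    xi <- x[labels == cl, , drop = FALSE]
    mu <- colMeans(xi)
    means[cl, ] <- mu
    xc <- sweep(xi, 2, mu)
    S <- S + crossprod(xc)
  }
  S <- S / (nrow(x) - length(classes))
  ridge <- lambda * mean(diag(S))
  if (!is.finite(ridge) || ridge <= 0) ridge <- lambda
  S <- S + diag(ridge, p)
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok) stop("pooled covariance singular even after shrinkage; raise lambda")
  structure(list(means = means, cov = S,
                 priors = as.numeric(counts) / nrow(x), classes = classes,
                 lambda = lambda),
            class = "lda_shared")
}

#' @export
print.lda_shared <- function(x, ...) {
  cat(sprintf("<lda_shared> %d classes, %d features; priors: %s\n",
              length(x$classes), ncol(x$means),
              paste(sprintf("%s=%.2f", x$classes, x$priors), collapse = ", ")))
  invisible(x)
}

#' @export
coef.lda_shared <- function(object, ...) object$means

#' Classify with a shared-covariance discriminant
#'
#' Scores each class by `x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log prior_c`
#' and returns the argmax; ties go to the earlier class in model order.
#'
#' @param object An [fit_lda_shared()] model.
#' @param newdata Matrix of observations x features.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.lda_shared <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != ncol(object$means)) stop_input("feature count mismatch")
  A <- solve(object$cov, t(object$means))          # p x C
  scores <- X %*% A
  const <- -0.5 * colSums(t(object$means) * A) + log(object$priors)
  scores <- sweep(scores, 2, const, "+")
  object$classes[max.col(scores, ties.method = "first")]
}
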