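# Evaluation statistics: 3-class confusion matrices, overall and per-class
# accuracy, and Bland-Altman agreement between algorithm and observed
# per-session counts. The difference convention is fixed as
# algorithm - observed, so undercounting shows up as a negative mean
# difference.

#' Confusion matrix over gesture classes
#'
#' Rows are the true class, columns the predicted class, in the order
#' Throw, Serve, Neither.
#'
#' @param true,pred Label vectors of equal length with values among the
#'   gesture classes.
#' @param classes Class order (default `c("Throw", "Serve", "Neither")`).
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(true, pred, classes = GESTURE_CLASSES) {
  if (length(true) != length(pred))
    stop("true and pred must have equal length", call. = FALSE)
  bad <- setdiff(unique(c(as.character(true), as.character(pred))), classes)
  if (length(bad))
    stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  cm <- table(factor(true, levels = classes), factor(pred, levels = classes))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("true", "predicted")
  storage.mode(cm) <- "integer"
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted)\n")
  print(unclass(x))
  cat(sprintf("accuracy: %.2f%%\n", accuracy(x)))
  invisible(x)
}

#' Overall accuracy of a confusion matrix
#'
#' Sum of the diagonal divided by the overall sum, as a percentage.
#'
#' @param cm A square count matrix (e.g. [confusion_matrix()]).
#' @return Accuracy in percent.
#' @examples
#' cm <- matrix(c(131, 3, 0, 2, 134, 3, 5, 4, 3), 3, byrow = TRUE)
#' accuracy(cm)  # 94.04
#' @export
accuracy <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(cm)) / total
}

#' Per-class correct fraction
#'
#' Diagonal element divided by the row total (per-class recall), in percent.
#'
#' @param cm A square count matrix with named rows.
#' @param class Row name (or index).
#' @return Percent of that class's events predicted correctly.
#' @export
class_fraction <- function(cm, class) {
  cm <- as.matrix(cm)
  row <- cm[class, ]
  if (sum(row) <= 0) stop("class has no events", call. = FALSE)
  100 * row[[if (is.character(class)) class else class]] / sum(row)
}

#' Bland-Altman agreement between algorithm and observed counts
#'
#' For paired per-session counts, computes the differences
#' `d = algorithm - observed`, their mean, the 95% confidence interval of the
#' mean (t distribution, n - 1 df), the classical limits of agreement
#' `mean +/- 1.96 sd(d)`, and the Pearson correlation of the two count
#' vectors. Both interval flavours are reported because a printed "95%
#' confidence interval" around a mean difference may refer to either.
#'
#' @param algorithm,observed Integer count vectors, one entry per session
#'   (length >= 2).
#' @return An object of class `bland_altman`: list with `n`, `mean_diff`,
#'   `sd_diff`, `ci` (length-2, t-based CI of the mean), `loa` (length-2
#'   limits of agreement), `r` (Pearson; `NA` with `r_defined = FALSE` when
#'   either vector is constant), `degenerate` (TRUE when all differences are
#'   equal, collapsing both intervals to the mean).
#' @export
bland_altman <- function(algorithm, observed) {
  if (length(algorithm) != length(observed))
    stop("paired count vectors must have equal length", call. = FALSE)
  n <- length(algorithm)
  if (n < 2L)
    stop("Bland-Altman agreement needs at least 2 paired sessions",
         call. = FALSE)
  d <- as.numeric(algorithm) - as.numeric(observed)
  m <- mean(d)
  s <- stats::sd(d)
  degenerate <- s == 0
  se <- s / sqrt(n)
  tq <- stats::qt(0.975, df = n - 1L)
  ci <- c(m - tq * se, m + tq * se)
  loa <- c(m - 1.96 * s, m + 1.96 * s)
  r_defined <- stats::sd(algorithm) > 0 && stats::sd(observed) > 0
  r <- if (r_defined) stats::cor(algorithm, observed) else NA_real_
  structure(list(n = n, mean_diff = m, sd_diff = s, ci = ci, loa = loa,
                 r = r, r_defined = r_defined, degenerate = degenerate),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement over %d sessions (algorithm - observed)\n",
              x$n))
  cat(sprintf("  mean difference %.3f (95%% CI %.3f to %.3f)%s\n",
              x$mean_diff, x$ci[1L], x$ci[2L],
              if (x$degenerate) " [constant differences]" else ""))
  cat(sprintf("  limits of agreement %.3f to %.3f\n", x$loa[1L], x$loa[2L]))
  if (x$r_defined) cat(sprintf("  Pearson r %.3f\n", x$r))
  else cat("  Pearson r undefined (constant counts)\n")
  invisible(x)
}

#' Reference confusion matrices for the sport-activity classifier
#'
#' Reference 3-class confusion matrices from a human-subject evaluation of
#' this detector/classifier architecture, bundled as plain-text data:
#' `"training"` is the matrix over the combined training/testing control
#' datasets and `"validation"` the matrix over the blinded randomized
#' validation dataset.
#'
#' @param which `"training"` or `"validation"`.
#' @return A [confusion_matrix()].
#' @examples
#' accuracy(reference_confusion("training"))  # 94.04
#' @export
reference_confusion <- function(which = c("training", "validation")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      sprintf("sport_confusion_%s.csv", which),
                      package = "armspot", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  cm <- as.matrix(df)
  storage.mode(cm) <- "integer"
  names(dimnames(cm)) <- c("true", "predicted")
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}
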