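# Feature space over FC matrices: canonical lower-triangle vectorisation,
# the two-class F-score, and top-fraction selection.

#' Canonical feature index map for p parcels
#'
#' The feature space of a symmetric p x p FC matrix is its lower triangle
#' including the main diagonal, traversed row-major (rows `i = 1..p`,
#' columns `j = 1..i`), giving `p(p+1)/2` features; for 74 parcels this is
#' 2,775. Diagonal features are identically zero under imaginary coherency
#' but are retained so that the feature count and index arithmetic stay
#' canonical.
#'
#' @param n_parcels Number of parcels p.
#' @return Data frame with columns `feature`, `parcel_i`, `parcel_j`
#'   (`parcel_i >= parcel_j`), one row per feature, in canonical order.
#' @examples
#' nrow(fc_index_map(74))  # 2775
#' @export
fc_index_map <- function(n_parcels) {
  p <- as.integer(n_parcels)
  stopifnot(p >= 1L)
  i <- rep.int(seq_len(p), seq_len(p))
  j <- sequence(seq_len(p))
  data.frame(feature = seq_along(i), parcel_i = i, parcel_j = j)
}

#' Vectorise a symmetric FC matrix
#'
#' Extracts the lower triangle and main diagonal in the canonical row-major
#' order of [fc_index_map()].
#'
#' @param fc Symmetric numeric matrix.
#' @param tol Maximum tolerated asymmetry `max |fc - t(fc)|` (default
#'   1e-8).
#' @return Numeric vector of length `p(p+1)/2`.
#' @export
vectorize_fc <- function(fc, tol = 1e-8) {
  fc <- as.matrix(fc)
  if (nrow(fc) != ncol(fc)) stop("`fc` must be square")
  if (max(abs(fc - t(fc))) > tol)
    stop("`fc` is asymmetric beyond tolerance")
  # for a symmetric matrix, the column-major upper triangle visits entries
  # in exactly the canonical row-major lower-triangle order
  fc[upper.tri(fc, diag = TRUE)]
}

#' Rebuild a symmetric FC matrix from its feature vector
#'
#' Inverse of [vectorize_fc()].
#'
#' @param v Feature vector of length `p(p+1)/2`.
#' @return Symmetric p x p matrix.
#' @export
devectorize_fc <- function(v) {
  m <- length(v)
  p <- (sqrt(8 * m + 1) - 1) / 2
  if (abs(p - round(p)) > 1e-9)
    stop("length of `v` is not p(p+1)/2 for any integer p")
  p <- as.integer(round(p))
  fc <- matrix(0, p, p)
  fc[upper.tri(fc, diag = TRUE)] <- v
  fc[lower.tri(fc)] <- t(fc)[lower.tri(fc)]
  fc
}

#' Assemble a labelled feature table
#'
#' Container for the segments x features matrix the classification stages
#' consume. CPS is the positive class.
#'
#' @param x Numeric matrix, one row per segment (sample), one column per
#'   canonical feature.
#' @param labels Character or factor of group labels, one per row.
#' @param subject_ids Character vector of subject identifiers, one per row.
#' @return A `fc_feature_table`: list with `x`, `labels` (factor with CPS
#'   first), and `subject_ids`.
#' @export
feature_table <- function(x, labels, subject_ids) {
  x <- as.matrix(x)
  if (anyNA(x) || !all(is.finite(x))) stop("feature values must be finite")
  if (length(labels) != nrow(x) || length(subject_ids) != nrow(x))
    stop("`labels` and `subject_ids` must have one entry per row of `x`")
  lv <- unique(as.character(labels))
  levels <- if (setequal(lv, c("CPS", "SPS"))) c("CPS", "SPS") else sort(lv)
  structure(list(x = x,
                 labels = factor(as.character(labels), levels = levels),
                 subject_ids = as.character(subject_ids)),
            class = "fc_feature_table")
}

#' @export
print.fc_feature_table <- function(x, ...) {
  cat(sprintf("fc_feature_table: %d segments x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s: %d", levels(x$labels),
                            tabulate(x$labels)), collapse = ", ")))
  invisible(x)
}

# Row subset of a feature table.
ft_subset <- function(ft, rows) {
  feature_table(ft$x[rows, , drop = FALSE], ft$labels[rows],
                ft$subject_ids[rows])
}

#' Two-class F-score of every feature
#'
#' For feature i with class means `m+`, `m-`, pooled mean `m`, and
#' within-class sample variances `v+`, `v-` (denominator n-1), the score is
#'
#'   `F_i = ((m+ - m)^2 + (m- - m)^2) / (v+ + v-)`.
#'
#' Larger scores mark features whose class means separate well relative to
#' their within-class spread. A feature whose pooled within-class variance
#' is zero carries no usable contrast and scores 0 by default
#' (`zero_denominator = "zero"`); set `"inf"` to score such features
#' infinite when their class means differ.
#'
#' @param x A `fc_feature_table`, or a samples x features matrix.
#' @param labels Group labels (ignored when `x` is a feature table).
#' @param positive Positive-class label (default `"CPS"`).
#' @param zero_denominator `"zero"` (default) or `"inf"`: score convention
#'   for zero within-class variance.
#' @return Numeric vector of non-negative scores, one per feature.
#' @examples
#' f_score(rbind(0, 2, 1, 3), labels = c("CPS", "CPS", "SPS", "SPS"))  # 0.125
#' @export
f_score <- function(x, labels = NULL, positive = "CPS",
                    zero_denominator = c("zero", "inf")) {
  zero_denominator <- match.arg(zero_denominator)
  if (inherits(x, "fc_feature_table")) {
    labels <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("one label per row is required")
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos < 2L || n_neg < 2L)
    stop("each class needs at least 2 samples for within-class variances")
  xp <- x[pos, , drop = FALSE]; xn <- x[!pos, , drop = FALSE]
  mp <- colMeans(xp); mn <- colMeans(xn); mall <- colMeans(x)
  vp <- colSums(sweep(xp, 2, mp)^2) / (n_pos - 1)
  vn <- colSums(sweep(xn, 2, mn)^2) / (n_neg - 1)
  num <- (mn - mall)^2 + (mp - mall)^2
  den <- vp + vn
  out <- ifelse(den > 0, num / den,
                if (zero_denominator == "zero") 0
                else ifelse(num > 0, Inf, 0))
  as.numeric(out)
}

#' Select the top fraction of features by score
#'
#' Keeps the `k = ceiling(fraction * m)` features with the largest scores.
#' Score ties are broken by ascending feature index; the result is ordered
#' by descending score.
#'
#' @param scores Numeric score vector (e.g. from [f_score()]).
#' @param fraction Fraction of features to keep, in `(0, 1]` (default 0.01:
#'   the "top 1%" rule, which keeps 28 of 2,775 features).
#' @return Integer vector of selected feature indices, descending by
#'   score.
#' @export
select_top_fraction <- function(scores, fraction = 0.01) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must lie in (0, 1]")
  m <- length(scores)
  k <- as.integer(ceiling(fraction * m))
  ord <- order(-scores, seq_len(m))
  ord[seq_len(k)]
}
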