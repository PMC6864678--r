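#' k-nearest-neighbor classification
#'
#' Majority vote among the `k` training points nearest to each query under
#' the chosen metric. Vote ties are broken by the smallest mean distance of
#' the tied labels' neighbors (within the k), then by lexicographic label
#' order. Written out explicitly so the tie-break semantics are fixed and
#' testable against an exhaustive scan.
#'
#' @param train_scores Training observations x features matrix.
#' @param train_labels Labels, one per training row.
#' @param query_scores Query observations x features matrix.
#' @param k Neighbor count (default 5); must be <= number of training rows.
#' @param metric Distance: `"euclidean"` (default) or `"manhattan"`.
#' @return Factor of predicted labels, one per query row, with the training
#'   label levels.
#' @export
knn_predict <- function(train_scores, train_labels, query_scores,
                        k = 5, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  train_scores <- as.matrix(train_scores)
  query_scores <- as.matrix(query_scores)
  if (nrow(train_scores) == 0L) stop("empty training set")
  if (k > nrow(train_scores)) stop("k exceeds the number of training points")
  train_labels <- as.factor(train_labels)
  stopifnot(length(train_labels) == nrow(train_scores),
            ncol(query_scores) == ncol(train_scores))

  D <- if (metric == "euclidean") {
    # squared distances via the cross-term expansion; monotone in distance
    q2 <- rowSums(query_scores^2)
    t2 <- rowSums(train_scores^2)
    pmax(outer(q2, t2, "+") - 2 * tcrossprod(query_scores, train_scores), 0)
  } else {
    t(apply(query_scores, 1, function(q) colSums(abs(t(train_scores) - q))))
  }
  if (metric == "euclidean") D <- sqrt(D)

  lev <- levels(train_labels)
  out <- character(nrow(query_scores))
  for (i in seq_len(nrow(query_scores))) {
    nn <- order(D[i, ])[seq_len(k)]
    votes <- table(factor(train_labels[nn], levels = lev))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      mean_d <- vapply(top, function(l) {
        mean(D[i, nn[train_labels[nn] == l]])
      }, numeric(1))
      top <- top[mean_d == min(mean_d)]
      top <- sort(top)[1L]   # lexicographic as the final tie-break
    }
    out[i] <- top
  }
  factor(out, levels = lev)
}
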