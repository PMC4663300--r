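#' Mean squared error between two images
#'
#' @param x,y Numeric matrices of equal shape.
#' @return `mean((x - y)^2)`.
#' @export
img_mse <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop("images must have the same shape")
  mean((x - y)^2)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 * log10(xmax^2 / MSE)` in decibels; identical images give
#' `Inf`.
#'
#' @inheritParams img_mse
#' @param xmax Peak gray value (default 255).
#' @return PSNR in dB.
#' @export
img_psnr <- function(x, y, xmax = 255) {
  mse <- img_mse(x, y)
  if (mse == 0) return(Inf)
  10 * log10(xmax^2 / mse)
}

#' Partition coefficient and partition entropy
#'
#' Cluster-validity indices of a fuzzy membership matrix:
#' `vpc = sum(u^2) / n` (1 for a hard partition, `1/c` for maximal
#' fuzziness) and `vpe = -sum(u * log(u)) / n` (0 for hard, `log c` for
#' uniform memberships), with `0 * log 0 := 0`.
#'
#' @param membership c x n membership matrix with unit column sums.
#' @param base Logarithm base for `vpe` (default `exp(1)`, nats).
#' @return A scalar.
#' @export
vpc <- function(membership) {
  sum(membership^2) / ncol(membership)
}

#' @rdname vpc
#' @export
vpe <- function(membership, base = exp(1)) {
  u <- membership[membership > 0]
  -sum(u * log(u, base = base)) / ncol(membership)
}

#' Match predicted cluster labels to reference labels
#'
#' Cluster indices are arbitrary, so predicted and reference partitions are
#' aligned before scoring: the permutation of predicted labels maximizing
#' the total overlap on the c x c contingency table is found by exhaustive
#' search (fine for the small `c` of gray-level segmentation; `c <= 8`).
#'
#' @param pred Integer matrix of predicted labels in `1..c`.
#' @param ref Integer matrix of reference labels, same shape.
#' @return An integer vector `sigma` such that predicted label `i`
#'   corresponds to reference label `sigma[i]`.
#' @export
match_labels <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) stop("label maps must share a shape")
  c_n <- max(pred, ref)
  if (c_n > 8) stop("exhaustive label matching supports at most 8 clusters")
  tab <- table(factor(pred, levels = seq_len(c_n)),
               factor(ref, levels = seq_len(c_n)))
  perms <- all_permutations(c_n)
  overlap <- apply(perms, 1, function(p) sum(tab[cbind(seq_len(c_n), p)]))
  as.integer(perms[which.max(overlap), ])
}

#' Segmentation accuracy
#'
#' Fraction of pixels whose (label-matched) predicted cluster equals the
#' reference cluster. Label matching via [match_labels()] is always
#' applied, so the score is invariant to relabeling of the prediction.
#'
#' @inheritParams match_labels
#' @return Accuracy in `[0, 1]`.
#' @export
seg_accuracy <- function(pred, ref) {
  sigma <- match_labels(pred, ref)
  mean(sigma[pred] == ref)
}

#' Multi-class Jaccard similarity
#'
#' After label matching, each reference cluster contributes the Jaccard
#' index (intersection over union) of its pixel set and the matched
#' predicted set; the per-cluster indices are averaged with weights
#' proportional to the reference cluster sizes.
#'
#' @inheritParams match_labels
#' @return Jaccard similarity in `[0, 1]`.
#' @export
seg_jaccard <- function(pred, ref) {
  sigma <- match_labels(pred, ref)
  mapped <- sigma[pred]
  labs <- sort(unique(as.integer(ref)))
  js <- w <- numeric(length(labs))
  for (k in seq_along(labs)) {
    a <- mapped == labs[k]
    b <- ref == labs[k]
    js[k] <- sum(a & b) / sum(a | b)
    w[k] <- sum(b)
  }
  sum(js * w) / sum(w)
}

#' Score a segmentation with the seven evaluation indexes
#'
#' Computes the full metric report for a `segmentation_result`: the c-means
#' objective on the final working image (`J`) and on the untouched input
#' (`J_input`), PSNR and MSE between the reference (clean) image and the
#' cluster-center reconstruction, the partition coefficient and entropy of
#' the membership matrix, and — when ground-truth labels are supplied —
#' label-matched accuracy and Jaccard similarity.
#'
#' @param result A `segmentation_result` from [run_hafsa()] or
#'   [run_baseline()].
#' @param reference_image Clean image for PSNR/MSE (default: the result's
#'   own denoised image, which makes PSNR/MSE a reconstruction-fidelity
#'   measure).
#' @param reference_labels Optional ground-truth label matrix.
#' @return A one-row data.frame: `J`, `J_input`, `psnr`, `mse`, `vpc`,
#'   `vpe`, `accuracy`, `js` (the last two `NA` without a reference).
#' @export
evaluate_segmentation <- function(result, reference_image = NULL,
                                  reference_labels = NULL) {
  stopifnot(inherits(result, "segmentation_result"))
  refimg <- if (is.null(reference_image)) result$denoised_image
            else as_gray_image(reference_image)
  out <- data.frame(
    J = result$objective,
    J_input = result$objective_on_input,
    psnr = img_psnr(refimg, result$reconstruction),
    mse = img_mse(refimg, result$reconstruction),
    vpc = vpc(result$membership),
    vpe = vpe(result$membership),
    accuracy = NA_real_,
    js = NA_real_
  )
  if (!is.null(reference_labels)) {
    out$accuracy <- seg_accuracy(result$cluster_map, reference_labels)
    out$js <- seg_jaccard(result$cluster_map, reference_labels)
  }
  out
}
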