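# Shifted-copy helpers over the 8-neighborhood. Each shift aligns a
# neighbor into the pixel's own position; positions falling outside the
# image are NA (border pixels simply have fewer neighbors).
neighbor_shifts <- list(
  c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
  c( 0L, -1L),             c( 0L, 1L),
  c( 1L, -1L), c( 1L, 0L), c( 1L, 1L)
)

shift_matrix <- function(mat, di, dj, fill = NA) {
  m <- nrow(mat); n <- ncol(mat)
  out <- matrix(fill, m, n)
  ri <- seq_len(m) + di
  cj <- seq_len(n) + dj
  keep_i <- ri >= 1L & ri <= m
  keep_j <- cj >= 1L & cj <= n
  out[which(keep_i), which(keep_j)] <- mat[ri[keep_i], cj[keep_j]]
  out
}

#' Detect noise pixels from a hard clustering
#'
#' A pixel is flagged as noise when fewer than `k_min` of its 8-neighbors
#' (fewer at image borders) share its cluster attribute. With the default
#' `k_min = 1` this flags pixels whose label is isolated in its
#' neighborhood; `k_min = 2` additionally catches pairs of adjacent
#' impulse pixels.
#'
#' @param cluster_map Integer matrix of cluster labels in `1..c`.
#' @param k_min Neighbor-agreement threshold, `1 <= k_min <= 8`.
#' @return Logical matrix: `TRUE` marks noise pixels.
#' @export
detect_noise <- function(cluster_map, k_min = 1) {
  stopifnot(k_min >= 1, k_min <= 8)
  if (nrow(cluster_map) < 3 || ncol(cluster_map) < 3)
    stop("noise detection needs an image of at least 3 x 3 pixels")
  agree <- matrix(0L, nrow(cluster_map), ncol(cluster_map))
  for (s in neighbor_shifts) {
    nb <- shift_matrix(cluster_map, s[1], s[2])
    agree <- agree + (!is.na(nb) & nb == cluster_map)
  }
  agree < k_min
}

#' Replacement value for one noise pixel
#'
#' Groups the available neighbors of pixel `(i, j)` by cluster attribute,
#' picks the largest group (ties broken toward the lowest cluster index)
#' and returns the arithmetic mean of that group's gray values.
#'
#' @param image Numeric matrix of gray values.
#' @param cluster_map Integer matrix of cluster labels, same shape.
#' @param i,j Pixel coordinates (row, column).
#' @return The replacement gray value.
#' @export
replace_pixel <- function(image, cluster_map, i, j) {
  m <- nrow(image); n <- ncol(image)
  vals <- list()
  for (s in neighbor_shifts) {
    ii <- i + s[1]; jj <- j + s[2]
    if (ii >= 1 && ii <= m && jj >= 1 && jj <= n) {
      k <- as.character(cluster_map[ii, jj])
      vals[[k]] <- c(vals[[k]], image[ii, jj])
    }
  }
  sizes <- vapply(vals, length, integer(1))
  labs <- as.integer(names(vals))
  best <- labs[sizes == max(sizes)]
  mean(vals[[as.character(min(best))]])
}

#' One sweep of the neighborhood noise-reduction mechanism
#'
#' Hard-assigns the image to the given centers, flags noise pixels via
#' [detect_noise()], and replaces all flagged pixels simultaneously by the
#' mean gray value of their dominant-cluster neighbors (computed from the
#' pre-sweep image, so the result is independent of sweep order).
#' Un-flagged pixels are never modified.
#'
#' @param image Numeric matrix of gray values.
#' @param centers Cluster centers of the current best fish.
#' @param k_min Neighbor-agreement threshold (default 1).
#' @return A list: `image` (after replacement) and `n_replaced`.
#' @export
apply_noise_reduction <- function(image, centers, k_min = 1) {
  image <- as_gray_image(image)
  cmap <- hard_assign(image, centers)
  flags <- detect_noise(cmap, k_min)
  if (!any(flags)) return(list(image = image, n_replaced = 0L))

  c_n <- length(centers)
  m <- nrow(image); n <- ncol(image)
  counts <- array(0L, c(m, n, c_n))
  sums <- array(0, c(m, n, c_n))
  for (s in neighbor_shifts) {
    nb_lab <- shift_matrix(cmap, s[1], s[2])
    nb_val <- shift_matrix(image, s[1], s[2])
    for (k in seq_len(c_n)) {
      hit <- !is.na(nb_lab) & nb_lab == k
      counts[, , k] <- counts[, , k] + hit
      sums[, , k] <- sums[, , k] + ifelse(hit, nb_val, 0)
    }
  }
  idx <- which(flags)
  cnt <- matrix(counts, m * n, c_n)[idx, , drop = FALSE]
  sm <- matrix(sums, m * n, c_n)[idx, , drop = FALSE]
  best <- max.col(cnt, ties.method = "first") # lowest index wins ties
  pick <- cbind(seq_along(idx), best)
  image[idx] <- sm[pick] / cnt[pick]
  list(image = image, n_replaced = length(idx))
}
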