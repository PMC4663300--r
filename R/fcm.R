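#' Fuzzy membership update
#'
#' Computes the c x n fuzzy membership matrix minimizing the c-means
#' objective for fixed centers:
#' `u_ij = ( sum_k (d_ij / d_kj)^(2/(m-1)) )^-1` with
#' `d_ij = |v_i - x_j|`. A pixel lying exactly on a center gets membership 1
#' for that center (the first one, if several coincide) and 0 elsewhere.
#'
#' @param centers Numeric vector of cluster-center gray values.
#' @param image Numeric matrix or vector of gray values.
#' @param m Fuzzy weighting exponent, `> 1` (default 2).
#' @return A `length(centers)` x `n` matrix with unit column sums.
#' @export
fcm_membership <- function(centers, image, m = 2) {
  stopifnot(m > 1, length(centers) >= 1)
  x <- as.numeric(image)
  d2 <- (outer(centers, x, "-"))^2
  w <- d2^(-1 / (m - 1))
  on_center <- !is.finite(w)
  hit <- which(colSums(on_center) > 0)
  u <- sweep(w, 2, colSums(w), "/")
  if (length(hit)) {
    u[, hit] <- 0
    first_zero <- apply(on_center[, hit, drop = FALSE], 2, which.max)
    u[cbind(first_zero, hit)] <- 1
  }
  u
}

#' Cluster-center update
#'
#' `v_i = sum_j u_ij^m x_j / sum_j u_ij^m` — the weighted mean of the pixels
#' under the fuzzified memberships. Each center is a convex combination of
#' pixel values, so it always lies inside the data range.
#'
#' @param membership c x n membership matrix.
#' @inheritParams fcm_membership
#' @return Numeric vector of updated centers.
#' @export
fcm_centers <- function(membership, image, m = 2) {
  x <- as.numeric(image)
  stopifnot(ncol(membership) == length(x))
  um <- membership^m
  mass <- rowSums(um)
  if (any(mass == 0))
    stop("degenerate cluster: a membership row has zero total mass")
  as.numeric(um %*% x) / mass
}

#' c-means objective function
#'
#' `J(V) = sum_i sum_j u_ij^m d_ij^2` with the memberships the minimizing
#' ones for the given centers (so `J` is a function of the centers alone).
#' This is the "food concentration" driving the fish swarm search.
#'
#' @inheritParams fcm_membership
#' @return Nonnegative scalar.
#' @examples
#' fcm_objective(c(0, 20), 10) # 50: memberships (.5, .5), both distances 10
#' @export
fcm_objective <- function(centers, image, m = 2) {
  stopifnot(m > 1, length(centers) >= 1, all(is.finite(centers)))
  cpp_fcm_objective(as.numeric(centers), as.numeric(image), m)
}

#' Hard cluster assignment
#'
#' Converts a fuzzy clustering into the hard cluster-attribute matrix C:
#' each pixel gets the cluster of maximal membership, equivalently the
#' nearest center. Ties go to the lowest cluster index.
#'
#' @param image Numeric matrix of gray values (used for its values when
#'   `centers` is given, and for its shape otherwise).
#' @param centers Cluster centers; mutually exclusive with `membership`.
#' @param membership c x n membership matrix in raster (column-major) order.
#' @return Integer matrix of cluster labels in `1..c`, shaped like `image`.
#' @export
hard_assign <- function(image, centers = NULL, membership = NULL) {
  image <- as_gray_image(image)
  if (is.null(centers) == is.null(membership))
    stop("supply exactly one of `centers` or `membership`")
  if (!is.null(centers)) {
    d <- abs(outer(as.numeric(image), centers, "-"))
    lab <- max.col(-d, ties.method = "first")
  } else {
    stopifnot(ncol(membership) == length(image))
    lab <- max.col(t(membership), ties.method = "first")
  }
  matrix(as.integer(lab), nrow(image), ncol(image))
}

run_fcm_engine <- function(image, c, m, tol, max_iter, init, seed, alpha = NULL) {
  x <- as.numeric(as_gray_image(image))
  stopifnot(c >= 2, m > 1, tol > 0, max_iter >= 1)
  with_seed(seed, {
    v <- if (is.null(init)) runif(c, 0, 255) else as.numeric(init)
    stopifnot(length(v) == c)
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      u <- fcm_membership(v, x, m)
      if (!is.null(alpha)) u <- suppress_membership(u, alpha)
      mass <- rowSums(u^m)
      dead <- which(mass == 0)
      if (length(dead)) {
        # keep c clusters alive: restart empty centers at random
        v[dead] <- runif(length(dead), 0, 255)
        next
      }
      v_new <- fcm_centers(u, x, m)
      trace <- c(trace, cpp_fcm_objective(v_new, x, m))
      delta <- max(abs(v_new - v))
      v <- v_new
      if (delta < tol) { converged <- TRUE; break }
    }
    u <- fcm_membership(v, x, m)
    structure(list(
      centers = v,
      membership = u,
      objective = cpp_fcm_objective(v, x, m),
      n_iter = length(trace),
      objective_trace = trace,
      converged = converged
    ), class = "fcm_fit")
  })
}

#' Run fuzzy c-means clustering
#'
#' Alternates the membership and center updates from a random (or given)
#' initialization until the maximum absolute center change drops below
#' `tol` or `max_iter` is reached. The per-iteration objective trace is
#' non-increasing (alternating minimization).
#'
#' @param image Numeric matrix of gray values in `[0, 255]`.
#' @param c Number of clusters, `>= 2`.
#' @param m Fuzzy weighting exponent (default 2).
#' @param tol Convergence threshold on `max |delta V|` (default 1e-5).
#' @param max_iter Iteration cap (default 200).
#' @param init Optional initial centers; default: `c` values drawn uniformly
#'   in `[0, 255]`.
#' @param seed Optional RNG seed for the initialization.
#' @return An object of class `fcm_fit`: list with `centers`, `membership`,
#'   `objective`, `n_iter`, `objective_trace`, `converged`.
#' @examples
#' gg <- grid_graph(lump_size = 8)
#' fit <- run_fcm(gg$image, c = 3, seed = 1)
#' sort(fit$centers)
#' @export
run_fcm <- function(image, c, m = 2, tol = 1e-5, max_iter = 200,
                    init = NULL, seed = NULL) {
  run_fcm_engine(image, c, m, tol, max_iter, init, seed, alpha = NULL)
}

suppress_membership <- function(u, alpha) {
  n <- ncol(u)
  win <- max.col(t(u), ties.method = "first")
  u <- alpha * u
  idx <- cbind(win, seq_len(n))
  u[idx] <- (1 - alpha) + u[idx]
  u
}

#' Run suppressed fuzzy c-means (SFCM)
#'
#' FCM with a suppression step after each membership update: for every pixel
#' the winning membership `u_p` is boosted to `1 - alpha + alpha * u_p` and
#' all others shrunk to `alpha * u`, which sharpens the partition and speeds
#' convergence. `alpha = 1` reproduces plain FCM exactly; `alpha = 0`
#' hardens the memberships each iteration.
#'
#' @inheritParams run_fcm
#' @param alpha Suppression factor in `[0, 1]` (default 0.5).
#' @return An `fcm_fit` object (the objective trace is not guaranteed
#'   monotone under suppression).
#' @export
run_sfcm <- function(image, c, alpha = 0.5, m = 2, tol = 1e-5, max_iter = 200,
                     init = NULL, seed = NULL) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  run_fcm_engine(image, c, m, tol, max_iter, init, seed, alpha = alpha)
}
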