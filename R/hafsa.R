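#' Segment a grayscale image with the hybrid artificial fish swarm algorithm
#'
#' Runs the full hybrid pipeline: a school of `pop_size` artificial fish
#' (candidate cluster-center vectors, initialized uniformly in
#' `[0, 255]^c`) searches for the centers minimizing the c-means objective.
#' Each generation every fish evaluates both its swarm and follow proposals
#' (each falling back to prey and, past `try_number` failed attempts, to the
#' random behavior), keeps the better of the two, and submits it to the
#' Metropolis rule at the current temperature of a geometric cooling
#' schedule. After the school moves, one sweep of the neighborhood noise
#' reduction is applied to the working image using the generation's best
#' centers, and the global best is updated elitistically on the (possibly
#' modified) working image.
#'
#' Because noise reduction mutates the working image, all cached objective
#' values are refreshed whenever pixels were replaced, and the recorded
#' global-best objective is always evaluated against the current working
#' image; the final report re-evaluates the best centers on the final image.
#'
#' @param image Numeric matrix of gray values in `[0, 255]`, at least 3 x 3.
#' @param c Number of clusters, `2 <= c <= 255`.
#' @param params An [afsa_params()] record.
#' @param anneal An [anneal_schedule()]; its `maxgen` should match
#'   `params$maxgen` (the default is built from it).
#' @param k_min Noise-reduction neighbor-agreement threshold (default 1).
#' @param m Fuzzy weighting exponent (default 2).
#' @param denoise Apply the in-loop noise reduction? (default `TRUE`;
#'   `FALSE` gives the plain annealed fish swarm).
#' @param acceptance `"metropolis"` (default) or `"greedy"` (only improving
#'   moves accepted).
#' @param patience Early stop after this many consecutive generations with a
#'   relative global-best improvement below 1e-8. Default `Inf`: the search
#'   always runs its full `maxgen` generations, because a stalled global
#'   best frequently resumes improving once the cooled school refines
#'   locally — stall detection would cut that refinement short.
#' @param seed Optional RNG seed; fixes every stochastic draw of the run.
#' @return An object of class `segmentation_result`: list with
#'   `algorithm`, `best_centers` (sorted ascending), `membership`,
#'   `cluster_map`, `reconstruction` (each pixel replaced by its cluster
#'   center), `denoised_image` (final working image), `objective` (best
#'   centers on the final working image), `objective_on_input` (same centers
#'   on the untouched input), `objective_trace` (global best per
#'   generation), `replaced_trace`, `n_generations`, `seed`, `params`.
#' @examples
#' gg <- grid_graph(lump_size = 8)
#' res <- run_hafsa(gg$image, c = 3, params = afsa_params(maxgen = 10),
#'                  seed = 1)
#' sort(res$best_centers)
#' @export
run_hafsa <- function(image, c, params = afsa_params(),
                      anneal = anneal_schedule(maxgen = params$maxgen),
                      k_min = 1, m = 2, denoise = TRUE,
                      acceptance = c("metropolis", "greedy"),
                      patience = Inf, seed = NULL) {
  image <- as_gray_image(image)
  check_gray_range(image)
  stopifnot(c >= 2, c <= 255)
  acceptance <- match.arg(acceptance)
  work <- image
  x <- as.numeric(work)

  with_seed(seed, {
    positions <- matrix(runif(params$pop_size * c, 0, 255),
                        params$pop_size, c)
    foods <- apply(positions, 1, cpp_fcm_objective, x = x, m = m)
    gbest <- NULL; gbest_j <- Inf
    obj_trace <- numeric(0); rep_trace <- integer(0)
    stall <- 0L

    for (t in seq_len(params$maxgen)) {
      temp <- cooling_temperature(anneal, t)
      for (i in seq_len(params$pop_size)) {
        prop_s <- swarm_step(i, positions, foods, x, m, params)
        prop_f <- follow_step(i, positions, foods, x, m, params)
        j_s <- cpp_fcm_objective(prop_s, x, m)
        j_f <- cpp_fcm_objective(prop_f, x, m)
        if (j_s <= j_f) { prop <- prop_s; j_new <- j_s }
        else { prop <- prop_f; j_new <- j_f }
        ok <- if (acceptance == "metropolis")
          metropolis_accept(foods[i], j_new, temp, anneal$boltzmann_k)
        else j_new <= foods[i]
        if (ok) { positions[i, ] <- prop; foods[i] <- j_new }
      }
      best_i <- which.min(foods)
      if (denoise) {
        nr <- apply_noise_reduction(work, positions[best_i, ], k_min)
        rep_trace <- c(rep_trace, nr$n_replaced)
        if (nr$n_replaced > 0) {
          work <- nr$image
          x <- as.numeric(work)
          foods <- apply(positions, 1, cpp_fcm_objective, x = x, m = m)
          best_i <- which.min(foods)
        }
      } else rep_trace <- c(rep_trace, 0L)

      # elitist global best, evaluated on the current working image
      cand_j <- foods[best_i]
      inc_j <- if (is.null(gbest)) Inf else cpp_fcm_objective(gbest, x, m)
      if (cand_j <= inc_j) { gbest <- positions[best_i, ]; new_j <- cand_j }
      else new_j <- inc_j
      improved <- is.finite(gbest_j) &&
        (gbest_j - new_j) > 1e-8 * max(gbest_j, 1e-300)
      stall <- if (improved || !is.finite(gbest_j)) 0L else stall + 1L
      gbest_j <- new_j
      obj_trace <- c(obj_trace, gbest_j)
      if (stall >= patience) break
    }

    finalize_segmentation(
      algorithm = "hafsa", centers = gbest, image = image, work = work,
      m = m, objective_trace = obj_trace, replaced_trace = rep_trace,
      seed = seed,
      params = list(c = c, m = m, afsa = unclass(params),
                    anneal = unclass(anneal), k_min = k_min,
                    acceptance = acceptance, patience = patience)
    )
  })
}

finalize_segmentation <- function(algorithm, centers, image, work, m,
                                  objective_trace, replaced_trace, seed,
                                  params, membership = NULL) {
  ord <- order(centers)
  centers <- centers[ord]
  u <- fcm_membership(centers, work, m)
  cmap <- hard_assign(work, membership = u)
  structure(list(
    algorithm = algorithm,
    best_centers = centers,
    membership = u,
    cluster_map = cmap,
    reconstruction = matrix(centers[cmap], nrow(image)),
    denoised_image = work,
    objective = cpp_fcm_objective(centers, as.numeric(work), m),
    objective_on_input = cpp_fcm_objective(centers, as.numeric(image), m),
    objective_trace = objective_trace,
    replaced_trace = replaced_trace,
    n_generations = length(objective_trace),
    seed = seed,
    params = params
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result: %s, c = %d>\n",
              x$algorithm, length(x$best_centers)))
  cat("  centers:  ", paste(sprintf("%.3f", x$best_centers), collapse = ", "),
      "\n")
  cat(sprintf("  objective: %.6g (on input image: %.6g)\n",
              x$objective, x$objective_on_input))
  cat(sprintf("  generations/iterations: %d, pixels replaced: %d\n",
              x$n_generations, sum(x$replaced_trace)))
  invisible(x)
}

#' Run a baseline segmentation (FCM or SFCM)
#'
#' Wraps [run_fcm()] / [run_sfcm()] into the same `segmentation_result`
#' record as [run_hafsa()] so the three algorithms can be compared through
#' one interface. Baselines perform no noise reduction, so
#' `denoised_image` is the input image.
#'
#' @inheritParams run_hafsa
#' @param algorithm `"fcm"` or `"sfcm"`.
#' @param alpha SFCM suppression factor (ignored for FCM).
#' @param tol,max_iter Solver controls, see [run_fcm()].
#' @return A `segmentation_result`.
#' @export
run_baseline <- function(image, c, algorithm = c("fcm", "sfcm"), m = 2,
                         alpha = 0.5, tol = 1e-5, max_iter = 200,
                         seed = NULL) {
  image <- as_gray_image(image)
  check_gray_range(image)
  algorithm <- match.arg(algorithm)
  fit <- if (algorithm == "fcm")
    run_fcm(image, c, m = m, tol = tol, max_iter = max_iter, seed = seed)
  else
    run_sfcm(image, c, alpha = alpha, m = m, tol = tol, max_iter = max_iter,
             seed = seed)
  finalize_segmentation(
    algorithm = algorithm, centers = fit$centers, image = image,
    work = image, m = m, objective_trace = fit$objective_trace,
    replaced_trace = integer(length(fit$objective_trace)), seed = seed,
    params = list(c = c, m = m, algorithm = algorithm,
                  alpha = if (algorithm == "sfcm") alpha else NULL,
                  tol = tol, max_iter = max_iter)
  )
}

#' Benchmark the three algorithms on the synthetic grid graph
#'
#' For each noise specification and each algorithm: generate the grid
#' graph, inject noise with a per-repetition derived seed, segment, and
#' score all seven evaluation indexes against the clean image and
#' ground-truth labels; report the mean over repetitions. Within a
#' repetition all algorithms see the same noisy image.
#'
#' @param reps Repetitions per condition (the reference protocol averages
#'   30).
#' @param noise A list of noise specifications, each a list with `kind`
#'   (`"none"`, `"gaussian"`, `"speckle"`, `"salt_pepper"`) and `intensity`.
#' @param algorithms Character subset of `c("fcm", "sfcm", "hafsa")`.
#' @param c Number of clusters.
#' @param lump_size,levels Grid-graph geometry, see [grid_graph()].
#' @param seed Master seed; per-rep noise and per-run seeds are derived
#'   from it.
#' @param ... Further arguments passed to [run_hafsa()] (e.g. `params`) —
#'   baselines take their defaults.
#' @return A data.frame with one row per (algorithm, noise spec):
#'   mean `J`, `J_input`, `psnr`, `mse`, `vpc`, `vpe`, `accuracy`, `js`.
#'   Per-repetition rows are attached as `attr(, "per_rep")`.
#' @export
benchmark_grid <- function(reps = 30,
                           noise = list(list(kind = "none", intensity = 0)),
                           algorithms = c("fcm", "sfcm", "hafsa"),
                           c = 3, lump_size = 64, levels = c(0, 127, 255),
                           seed = 1, ...) {
  stopifnot(reps >= 1)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  gg <- grid_graph(lump_size = lump_size, levels = levels)
  n_cond <- length(noise)
  seeds <- matrix(derive_seeds(seed, reps * n_cond * (1 + length(algorithms))),
                  nrow = reps)
  rows <- list()
  for (si in seq_len(n_cond)) {
    spec <- noise[[si]]
    for (r in seq_len(reps)) {
      scol <- (si - 1) * (1 + length(algorithms))
      noisy <- switch(spec$kind,
        none = gg$image,
        gaussian = add_gaussian_noise(gg$image, spec$intensity,
                                      seed = seeds[r, scol + 1]),
        speckle = add_speckle_noise(gg$image, spec$intensity,
                                    seed = seeds[r, scol + 1]),
        salt_pepper = add_salt_pepper(gg$image, spec$intensity,
                                      seed = seeds[r, scol + 1]),
        stop("unknown noise kind: ", spec$kind)
      )
      for (ai in seq_along(algorithms)) {
        alg <- algorithms[ai]
        run_seed <- seeds[r, scol + 1 + ai]
        res <- if (alg == "hafsa")
          run_hafsa(noisy, c, seed = run_seed, ...)
        else run_baseline(noisy, c, algorithm = alg, seed = run_seed)
        met <- evaluate_segmentation(res, reference_image = gg$image,
                                     reference_labels = gg$labels)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(algorithm = alg, noise_kind = spec$kind,
                     intensity = spec$intensity, rep = r), met)
      }
    }
  }
  per_rep <- do.call(rbind, rows)
  metric_cols <- c("J", "J_input", "psnr", "mse", "vpc", "vpe",
                   "accuracy", "js")
  agg <- aggregate(per_rep[metric_cols],
                   per_rep[c("algorithm", "noise_kind", "intensity")], mean)
  agg <- agg[order(match(agg$noise_kind, vapply(noise, `[[`, "", "kind")),
                   agg$intensity,
                   match(agg$algorithm, algorithms)), ]
  rownames(agg) <- NULL
  attr(agg, "per_rep") <- per_rep
  agg
}
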