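#' Artificial fish swarm parameters
#'
#' Bundles the swarm-search knobs with their standard defaults for 8-bit
#' images: a population of 20 fish run for 50 generations, a perception
#' radius (`visual`) of one tenth of the gray range (256/10 = 25.6), a
#' maximum move length of half the visual (12.8), 3 prey retries and a
#' congestion level of 0.75.
#'
#' @param pop_size Number of artificial fish (candidate center vectors).
#' @param maxgen Maximum number of generations.
#' @param visual Perception radius in gray levels: fish sample prey
#'   candidates and see partners within this distance.
#' @param step Maximum move length per behavior.
#' @param try_number Prey-behavior resampling attempts before falling back
#'   to the random behavior.
#' @param delta Congestion level in `[0, 1]`; larger values make crowded
#'   high-quality regions more attractive.
#' @return A list of class `afsa_params`.
#' @export
afsa_params <- function(pop_size = 20, maxgen = 50, visual = 25.6,
                        step = visual / 2, try_number = 3, delta = 0.75) {
  stopifnot(pop_size >= 1, maxgen >= 1, visual > 0, step > 0,
            try_number >= 1, delta >= 0, delta <= 1)
  structure(list(pop_size = as.integer(pop_size), maxgen = as.integer(maxgen),
                 visual = visual, step = step,
                 try_number = as.integer(try_number), delta = delta),
            class = "afsa_params")
}

#' Geometric annealing schedule
#'
#' Temperature decays geometrically from `T0` to `T_end` over `maxgen`
#' steps: `T_t = T0 * q^t` with refrigeration level
#' `q = (T_end / T0)^(1/maxgen)`, so `T_maxgen = T_end` exactly.
#'
#' @param T0 Initial temperature (default 1e4).
#' @param T_end Final temperature (default 1e2).
#' @param maxgen Number of cooling steps (default 50).
#' @param boltzmann_k Boltzmann constant in the acceptance rule (default 1).
#' @return A list of class `anneal_schedule` with the derived `q`.
#' @export
anneal_schedule <- function(T0 = 1e4, T_end = 1e2, maxgen = 50,
                            boltzmann_k = 1) {
  stopifnot(T0 > T_end, T_end > 0, maxgen >= 1, boltzmann_k > 0)
  structure(list(T0 = T0, T_end = T_end, maxgen = as.integer(maxgen),
                 q = (T_end / T0)^(1 / maxgen), boltzmann_k = boltzmann_k),
            class = "anneal_schedule")
}

#' Temperature at generation t
#'
#' @param schedule An [anneal_schedule()].
#' @param t Generation index, `0 <= t <= maxgen`.
#' @return `T0 * q^t`.
#' @export
cooling_temperature <- function(schedule, t) {
  stopifnot(t >= 0, t <= schedule$maxgen)
  schedule$T0 * schedule$q^t
}

#' Move a fish one step toward a target position
#'
#' `V <- V + xi * step * (V_target - V) / ||V_target - V||`: a move of
#' random length at most `step` along the unit vector toward the target,
#' clipped to the gray-value box `[0, 255]^c`.
#'
#' @param current,target Center vectors of equal length.
#' @param step Maximum move length.
#' @param xi Random scalar in `[0, 1]`; defaults to a fresh uniform draw.
#' @return The new position; `current` unchanged if `target == current`.
#' @export
move_toward <- function(current, target, step, xi = runif(1)) {
  d <- target - current
  nd <- sqrt(sum(d^2))
  if (nd == 0) return(current)
  clip_gray(current + xi * step * d / nd)
}

#' Random (default) behavior
#'
#' Perturbs each coordinate independently by `visual * eta` with
#' `eta ~ U(-1, 1)`, clipped to `[0, 255]^c`.
#'
#' @param current Center vector.
#' @param visual Perception radius.
#' @return The perturbed position.
#' @export
random_move <- function(current, visual) {
  clip_gray(current + visual * runif(length(current), -1, 1))
}

#' Metropolis acceptance rule
#'
#' A proposal at least as good as the incumbent (`j_new <= j_old`) is always
#' accepted; a worse one is accepted with probability
#' `exp(-(j_new - j_old) / (k * temperature))`, so uphill moves become ever
#' rarer as the temperature cools.
#'
#' @param j_old,j_new Objective values of the incumbent and the proposal.
#' @param temperature Current temperature, `> 0`.
#' @param boltzmann_k Boltzmann constant (default 1).
#' @return Logical: accept the proposal?
#' @export
metropolis_accept <- function(j_old, j_new, temperature, boltzmann_k = 1) {
  stopifnot(temperature > 0)
  if (j_new <= j_old) return(TRUE)
  runif(1) < exp(-(j_new - j_old) / (boltzmann_k * temperature))
}

# Prey behavior: up to try_number candidates drawn uniformly in the
# axis-aligned +/- visual box around the fish; the first candidate with a
# strictly better objective pulls the fish one step toward it. If none
# improves, the random behavior is the default.
prey_step <- function(position, food, x, m, params) {
  cc <- length(position)
  for (k in seq_len(params$try_number)) {
    cand <- clip_gray(position + runif(cc, -params$visual, params$visual))
    if (cpp_fcm_objective(cand, x, m) < food)
      return(move_toward(position, cand, params$step))
  }
  random_move(position, params$visual)
}

# Swarm behavior: move toward the centroid of the partners in visual range
# if it is both better and uncrowded (J(Vc)/num < delta * J(Vi)); otherwise
# prey. `positions` is the pop x c matrix of school positions.
swarm_step <- function(i, positions, foods, x, m, params) {
  vi <- positions[i, ]
  partners <- partners_in_visual(i, positions, params$visual)
  if (length(partners)) {
    vc <- colMeans(positions[partners, , drop = FALSE])
    if (cpp_fcm_objective(vc, x, m) / length(partners) <
        params$delta * foods[i])
      return(move_toward(vi, vc, params$step))
  }
  prey_step(vi, foods[i], x, m, params)
}

# Follow behavior: move toward the best partner in visual range under the
# same congestion test; otherwise prey. Partner objective values are the
# cached school foods.
follow_step <- function(i, positions, foods, x, m, params) {
  vi <- positions[i, ]
  partners <- partners_in_visual(i, positions, params$visual)
  if (length(partners)) {
    best <- partners[which.min(foods[partners])]
    if (foods[best] / length(partners) < params$delta * foods[i])
      return(move_toward(vi, positions[best, ], params$step))
  }
  prey_step(vi, foods[i], x, m, params)
}

partners_in_visual <- function(i, positions, visual) {
  d2 <- colSums((t(positions) - positions[i, ])^2)
  out <- which(d2 <= visual^2)
  out[out != i]
}
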