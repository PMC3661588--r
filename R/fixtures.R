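#' Generate reference trajectory fixtures
#'
#' Writes fixed-step RK4 reference trajectories for a set of canonical
#' scenarios -- baseline, no apoptosis (\code{sigma = 0}), no resorption
#' (\code{k1 = 0}), and a treated diseased run -- as plain CSV, plus a
#' manifest recording the settings and a seed-governed set of random
#' osteocyte-deficit values for perturbation checks. The model itself is
#' deterministic; the seed only controls those perturbation draws.
#'
#' @param seed integer seed for the perturbation draws.
#' @param out_dir directory to write into (created if needed).
#' @param step RK4 step size (days); default 0.01.
#' @param horizon reference horizon (days); default 300.
#' @return Invisibly, the manifest list.
#' @export
generate_fixtures <- function(seed, out_dir, step = 0.01, horizon = 300) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  base <- remodeling_params()
  scenarios <- list(
    baseline = list(params = base, init = initial_condition()),
    sigma_zero = list(params = base, init = initial_condition(sigma = 0)),
    no_resorption = list(params = remodeling_params(k1 = 0),
                         init = initial_condition()))
  files <- character(0)
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    traj <- rk4_reference(sc$params, sc$init, horizon, step)
    f <- file.path(out_dir, paste0(nm, ".csv"))
    write_trajectory(traj, f)
    files <- c(files, f)
  }
  # Treated scenario: segment-wise RK4 across the dosing window boundaries.
  sched <- treatment_schedule(
    windows = list(dose_window("g22", 0, 30, 0.7),
                   dose_window("g44", 0, 30, 1.5)),
    disease = list(g42 = 1.1))
  traj <- rk4_schedule_reference(sched, horizon, step)
  f <- file.path(out_dir, "treated.csv")
  write_trajectory(traj, f)
  files <- c(files, f)
  manifest <- list(
    seed = seed, step = step, horizon = horizon,
    files = basename(files),
    perturbation_sigmas = sort(round(stats::runif(5, 1, 199), 3)),
    schedule = list(disease = sched$disease,
                    windows = lapply(sched$windows, unclass))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Fixed-step RK4 across dosing-window boundaries, restarting at each edge.
rk4_schedule_reference <- function(schedule, horizon, step,
                                   base = remodeling_params(),
                                   init = initial_condition()) {
  edges <- sort(unique(c(0, unlist(lapply(schedule$windows,
                                          function(w) c(w$start, w$end))),
                         horizon)))
  edges <- edges[edges >= 0 & edges <= horizon]
  y <- unname(initial_state(base, init))
  record_every <- max(1L, as.integer(round(0.1 / step)))
  times <- 0
  states <- matrix(y, 1L, 5L)
  for (i in seq_len(length(edges) - 1L)) {
    p_seg <- effective_params(mean(edges[i:(i + 1L)]), base, schedule)
    f <- make_derivs(p_seg)
    n_steps <- as.integer(round((edges[i + 1L] - edges[i]) / step))
    h <- step; h2 <- h / 2
    seg_states <- matrix(NA_real_, n_steps %/% record_every + 1L, 5L)
    seg_times <- numeric(nrow(seg_states))
    j <- 0L
    for (k in seq_len(n_steps)) {
      t <- edges[i] + (k - 1L) * h
      k1 <- f(t, y)
      k2 <- f(t + h2, y + h2 * k1)
      k3 <- f(t + h2, y + h2 * k2)
      k4 <- f(t + h, y + h * k3)
      y <- y + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
      if (k %% record_every == 0L) {
        j <- j + 1L
        seg_states[j, ] <- y
        seg_times[j] <- edges[i] + k * h
      }
    }
    times <- c(times, seg_times[seq_len(j)])
    states <- rbind(states, seg_states[seq_len(j), , drop = FALSE])
  }
  colnames(states) <- c("S", "P", "B", "C", "z")
  structure(list(times = times, states = states, params = base, init = init,
                 solver = list(method = "rk4", step = step,
                               rtol = NA_real_, atol = NA_real_,
                               dt_out = step * record_every,
                               horizon = horizon, segments = edges,
                               n_steps = NA_integer_,
                               termination = "completed",
                               min_cell = min(states[, c("P", "B", "C")]),
                               negativity_ok = TRUE)),
            class = "bmu_trajectory")
}
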