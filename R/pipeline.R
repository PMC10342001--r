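# Pipeline orchestration: run configuration, stage functions mirroring the
# simulate / measures / geometric / transfer workflow, persistence and a
# summary report.

#' Run configuration with the study defaults
#'
#' Collects every knob of a simulation-plus-analysis run. The defaults are
#' the study conditions: hierarchy depth D = 4, integration step
#' \eqn{10^{-4}} ps, 15 ps of dynamics stored every \eqn{10^{-3}} ps, bath
#' cutoff 50 cm\eqn{^{-1}}, reorganization energy 35 cm\eqn{^{-1}}
#' (literature range 35--65), trapping 1 ps\eqn{^{-1}} on sites 3 and 4,
#' temperature 77 K, and the dephased entry state through site 8
#' (`"fret:8"`).
#'
#' @param species Packaged species label or path to a Hamiltonian file.
#' @param lambda,gamma Bath parameters in cm\eqn{^{-1}} (scalar or 8-vector).
#' @param temperature Kelvin.
#' @param r_trap Trapping rate, ps\eqn{^{-1}}.
#' @param trap_sites Trapped sites.
#' @param depth Hierarchy depth D.
#' @param dt Integration step, ps.
#' @param t_end Final time, ps.
#' @param store_stride Storage stride, ps (multiple of `dt`).
#' @param initial_state `"fret:i"` or `"localized:k"`.
#' @param seed Integer seed for stochastic analysis stages.
#' @return A validated list of class `fmo_run_config`.
#' @export
fmo_run_config <- function(species = "P_aestuarii", lambda = 35,
                           gamma = 50, temperature = 77, r_trap = 1,
                           trap_sites = c(3, 4), depth = 4, dt = 1e-4,
                           t_end = 15, store_stride = 1e-3,
                           initial_state = "fret:8", seed = 1) {
  cfg <- list(species = species, lambda = lambda, gamma = gamma,
              temperature = temperature, r_trap = r_trap,
              trap_sites = as.integer(trap_sites),
              depth = as.integer(depth), dt = dt, t_end = t_end,
              store_stride = store_stride, initial_state = initial_state,
              seed = as.integer(seed))
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg A list with the fields of [fmo_run_config()].
#' @return The validated config, classed `fmo_run_config`.
#' @export
validate_run_config <- function(cfg) {
  bad <- character(0)
  need <- c("species", "lambda", "gamma", "temperature", "r_trap",
            "trap_sites", "depth", "dt", "t_end", "store_stride",
            "initial_state", "seed")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config misses fields: ",
                         paste(miss, collapse = ", "))
  if (!is.character(cfg$species)) bad <- c(bad, "species")
  if (any(cfg$lambda < 0)) bad <- c(bad, "lambda")
  if (any(cfg$gamma <= 0)) bad <- c(bad, "gamma")
  if (cfg$temperature <= 0) bad <- c(bad, "temperature")
  if (cfg$r_trap < 0) bad <- c(bad, "r_trap")
  if (cfg$depth < 0) bad <- c(bad, "depth")
  if (cfg$dt <= 0 || cfg$t_end < 0) bad <- c(bad, "dt/t_end")
  if (cfg$store_stride < cfg$dt) bad <- c(bad, "store_stride")
  if (!grepl("^(fret|localized):[1-8]$", cfg$initial_state)) {
    bad <- c(bad, "initial_state")
  }
  if (length(bad)) stop("invalid config fields: ",
                        paste(bad, collapse = ", "))
  class(cfg) <- "fmo_run_config"
  cfg
}

#' Write / read a run configuration as JSON
#'
#' Round-trips unchanged through serialization.
#'
#' @param cfg A [fmo_run_config()].
#' @param path File path.
#' @return `read_run_config` returns the validated config.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "fmo_run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$trap_sites <- as.integer(cfg$trap_sites)
  cfg$depth <- as.integer(cfg$depth)
  cfg$seed <- as.integer(cfg$seed)
  validate_run_config(cfg)
}

.initial_state_of <- function(cfg, H) {
  parts <- strsplit(cfg$initial_state, ":")[[1]]
  k <- as.integer(parts[2])
  switch(parts[1],
         fret = initial_state_fret(H, k),
         localized = initial_state_localized(k, H$site_count))
}

#' Simulate a configured run
#'
#' Loads the Hamiltonian, assembles the HEOM generator at the configured
#' depth and propagates the configured initial state. Deterministic: a
#' rerun with the same config reproduces the trajectory bit for bit.
#'
#' @param cfg A [fmo_run_config()].
#' @return A `heom_trajectory`.
#' @export
simulate_fmo <- function(cfg) {
  stopifnot(inherits(cfg, "fmo_run_config"))
  H <- load_hamiltonian(cfg$species)
  bath <- bath_parameters(cfg$lambda, cfg$gamma, cfg$temperature,
                          cfg$r_trap, cfg$trap_sites, H$site_count)
  hier <- enumerate_hierarchy(H$site_count, cfg$depth)
  gen <- assemble_heom_generator(H, bath, hier)
  propagate(gen, .initial_state_of(cfg, H), dt = cfg$dt,
            t_end = cfg$t_end,
            store_every = max(1L, round(cfg$store_stride / cfg$dt)))
}

#' Evaluate entanglement and coherence measures along a trajectory
#'
#' @param traj A `heom_trajectory`.
#' @param measures Character vector among `"l1_coherence"`,
#'   `"meyer_wallach"`, `"relative_entropy"`, `"wae_negativity"` (the
#'   bipartition-averaged negativity, with per-bipartition breakdown).
#' @param time_stride Evaluate every `time_stride`-th frame.
#' @return Tidy data frame with columns `time`, `measure`,
#'   `bipartition` (`""` for global measures) and `value`.
#' @export
measure_trajectory <- function(traj,
                               measures = c("l1_coherence",
                                            "meyer_wallach",
                                            "relative_entropy",
                                            "wae_negativity"),
                               time_stride = 1) {
  stopifnot(inherits(traj, "heom_trajectory"))
  known <- c("l1_coherence", "meyer_wallach", "relative_entropy",
             "wae_negativity")
  unknown <- setdiff(measures, known)
  if (length(unknown)) stop("unknown measure(s): ",
                            paste(unknown, collapse = ", "))
  n <- dim(traj$rho)[1]
  catalog <- if ("wae_negativity" %in% measures)
    enumerate_bipartitions(n) else NULL
  sel <- seq(1, length(traj$times), by = max(1L, as.integer(time_stride)))
  rows <- list()
  for (s in sel) {
    rho <- traj$rho[, , s]; tt <- traj$times[s]
    if ("l1_coherence" %in% measures) {
      rows[[length(rows) + 1L]] <- data.frame(
        time = tt, measure = "l1_coherence", bipartition = "",
        value = l1_coherence(rho))
    }
    if ("meyer_wallach" %in% measures) {
      rows[[length(rows) + 1L]] <- data.frame(
        time = tt, measure = "meyer_wallach", bipartition = "",
        value = meyer_wallach(rho))
    }
    if ("relative_entropy" %in% measures) {
      rows[[length(rows) + 1L]] <- data.frame(
        time = tt, measure = "relative_entropy", bipartition = "",
        value = relative_entropy_measure(rho))
    }
    if ("wae_negativity" %in% measures) {
      wae <- weighted_average_entanglement(rho, "negativity", catalog)
      rows[[length(rows) + 1L]] <- data.frame(
        time = tt, measure = "wae_negativity", bipartition = "",
        value = wae$total)
      rows[[length(rows) + 1L]] <- data.frame(
        time = tt, measure = "wae_negativity_contribution",
        bipartition = wae$breakdown$A, value = wae$breakdown$contribution)
    }
  }
  do.call(rbind, rows)
}

#' Geometric entanglement of site triples along a trajectory
#'
#' Reduces each sampled frame to the selected three-site qubit states and
#' computes the maximum fidelity to the closest fully separable state.
#' The packaged default triples are the large-final-population group
#' (3, 6, 7) and the entry/exit group (3, 4, 8).
#'
#' @param traj A `heom_trajectory`.
#' @param triples List of site triples.
#' @param time_stride Sample every `time_stride`-th frame.
#' @param restarts,max_iter,tol See [lambda_mixed()].
#' @param seed Integer seed (recorded in the output).
#' @return Data frame with `time`, `sites`, `lambda`, `converged`, `seed`.
#' @export
geometric_series <- function(traj,
                             triples = list(c(3, 6, 7), c(3, 4, 8)),
                             time_stride = 100, restarts = 10,
                             max_iter = 100, tol = 1e-6, seed = 1) {
  stopifnot(inherits(traj, "heom_trajectory"))
  sel <- seq(1, length(traj$times), by = max(1L, as.integer(time_stride)))
  rows <- list()
  set.seed(seed)
  for (tri in triples) {
    stopifnot(length(tri) == 3)
    for (s in sel) {
      red <- reduce_to_sites(traj$rho[, , s], tri)
      res <- lambda_mixed(red, restarts = restarts, max_iter = max_iter,
                          tol = tol)
      rows[[length(rows) + 1L]] <- data.frame(
        time = traj$times[s], sites = paste(tri, collapse = ","),
        lambda = res$value, converged = res$converged, seed = seed)
    }
  }
  do.call(rbind, rows)
}

#' State-transference track of a configured run
#'
#' Convenience wrapper of [fidelity_track()] using the trajectory's own
#' initial frame as the reference.
#'
#' @param traj A `heom_trajectory`.
#' @param time_stride Sample every `time_stride`-th stored frame.
#' @param ... Passed to [fidelity_track()].
#' @return A `permutation_track`.
#' @export
transfer_track <- function(traj, time_stride = 10, ...) {
  fidelity_track(traj, trajectory_frame(traj, 1),
                 time_stride = time_stride, ...)
}

#' Write / read a trajectory as CSV + JSON
#'
#' Long-format CSV (`time`, `i`, `j`, `re`, `im`) paired with a JSON
#' metadata file (`<path>.meta.json`).
#'
#' @param traj A `heom_trajectory`.
#' @param path CSV file path.
#' @return `read_trajectory_csv` returns the `heom_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "heom_trajectory"))
  n <- dim(traj$rho)[1]; nt <- length(traj$times)
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  df <- data.frame(
    time = rep(traj$times, each = n * n),
    i = rep(grid$i, times = nt), j = rep(grid$j, times = nt),
    re = as.vector(Re(traj$rho)), im = as.vector(Im(traj$rho)))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(traj$metadata, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  times <- unique(df$time)
  n <- max(df$i)
  rho <- array(complex(real = df$re, imaginary = df$im),
               dim = c(n, n, length(times)))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  structure(list(times = times, rho = rho, metadata = meta),
            class = "heom_trajectory")
}

#' Summary report of the desk-scale quantities
#'
#' Assembles the quickly reproducible summaries of the analysis: the
#' bipartition and permutation counts, the dephased entry-state populations
#' of both packaged Hamiltonians, and (optionally) the geometric
#' entanglement of all eigenvectors of one species.
#'
#' @param species Species whose eigenvector table to compute, or `NULL` to
#'   skip that (slower) part.
#' @param restarts Restarts for [lambda_of_eigenvectors()].
#' @param seed Integer seed.
#' @return A list with `counts`, `fret_populations` and (optionally)
#'   `eigenvector_lambda`.
#' @export
fmo_report <- function(species = NULL, restarts = 100, seed = 1) {
  cat8 <- enumerate_bipartitions(8)
  counts <- list(bipartitions = sum(cat8$counts),
                 bipartitions_by_order = cat8$counts,
                 permutations = factorial(8))
  fret <- lapply(c("P_aestuarii", "C_tepidum"), function(sp) {
    H <- load_hamiltonian(sp)
    data.frame(species = sp, site = 1:8,
               population = Re(diag(initial_state_fret(H, 8))))
  })
  out <- list(counts = counts, fret_populations = do.call(rbind, fret))
  if (!is.null(species)) {
    out$eigenvector_lambda <-
      lambda_of_eigenvectors(load_hamiltonian(species),
                             restarts = restarts, seed = seed)
  }
  out
}
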