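#' Write a trajectory as tidy CSV
#'
#' Long format: `time, species, value, unit` — one row per time and species.
#'
#' @param traj A `count_trajectory`, `conc_trajectory` or
#'   `ensemble_summary` (the mean is written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (inherits(traj, "ensemble_summary")) {
    times <- traj$times; vals <- traj$mean; unit <- traj$unit
  } else if (inherits(traj, "conc_trajectory")) {
    times <- traj$time; vals <- as.matrix(traj[c("P", "Pm")])
    unit <- attr(traj, "unit")
  } else {
    times <- traj$times; vals <- traj$counts; unit <- traj$unit
  }
  long <- data.frame(
    time = rep(times, ncol(vals)),
    species = rep(colnames(vals), each = length(times)),
    value = as.vector(vals),
    unit = unit)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an FSP solution as long-format CSV
#'
#' One row per (time, state): `time, state, P, Pm, probability`. Zero
#' probabilities below `drop_below` are omitted to keep files small.
#'
#' @param sol An `fsp_solution` from [fsp_propagate()].
#' @param path Output file path.
#' @param drop_below Omit entries below this probability (default 0 keeps
#'   everything).
#' @return `path`, invisibly.
#' @export
write_probability_csv <- function(sol, path, drop_below = 0) {
  st <- state_at(seq_len(sol$space$n_states), sol$space)
  rows <- lapply(seq_along(sol$times), function(k) {
    keep <- sol$probs[, k] > drop_below
    data.frame(time = sol$times[k], state = which(keep),
               P = st[keep, "i"], Pm = st[keep, "j"],
               probability = sol$probs[keep, k])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write the time-by-state probability matrix for heat-map display
#'
#' Rows are output times, columns enumerated states. Raw probabilities are
#' always preserved; with `clipped = TRUE` an additional matrix clipped at
#' 0.25 (the display ceiling used for the study's heat map) is appended
#' below the raw block, separated by a comment line.
#'
#' @param sol An `fsp_solution`.
#' @param path Output file path.
#' @param clipped Also write the display-clipped copy.
#' @return `path`, invisibly.
#' @export
write_heatmap_matrix <- function(sol, path, clipped = FALSE) {
  m <- t(sol$probs)
  df <- data.frame(time = sol$times, m, check.names = FALSE)
  colnames(df) <- c("time", paste0("s", seq_len(ncol(m))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (clipped) {
    cat("# display copy, clipped at 0.25\n", file = path, append = TRUE)
    dfc <- df
    dfc[, -1] <- pmin(as.matrix(df[, -1]), 0.25)
    utils::write.table(dfc, path, append = TRUE, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Run one or more analysis stages of a scenario and write their outputs
#'
#' Thin orchestration over the package's analysis functions: resolves a
#' configuration to a [scenario()], executes the requested stages and
#' writes CSV/JSON outputs plus a `manifest.json` recording every
#' parameter, seed, output file and its MD5 content hash, so any output can
#' be regenerated from the manifest alone.
#'
#' @param config Named list with elements `scenario` (preset name), and
#'   optionally `stages` (subset of `"ode"`, `"fsp"`, `"ssa"`, `"cle"`,
#'   `"fcd"`, `"ergodicity"`), `F_i`, `seed`, `n_cells`, `space` (bounds
#'   `c(MP, MPm)`), `t_star`, `dt`, `n` (ergodicity sampling), plus any
#'   [scenario()] override.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  stopifnot(is.list(config), !is.null(config$scenario))
  stages <- config$stages %||% "ode"
  bad <- setdiff(stages, c("ode", "fsp", "ssa", "cle", "fcd", "ergodicity"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  space <- if (!is.null(config$space))
    state_space(config$space[1], config$space[2]) else state_space()
  sc <- scenario(config$scenario, F_i = config$F_i %||% 1,
                 seed = config$seed %||% 1L,
                 n_cells = config$n_cells %||% 1L, space = space)
  files <- character(0)
  out <- function(name) {
    f <- file.path(out_dir, name)
    files <<- c(files, f)
    f
  }

  for (stage in stages) {
    switch(stage,
      ode = {
        traj <- solve_piecewise(sc$rates, sc$signal, sc$init_conc, sc$grid)
        write_trajectory_csv(traj, out("ode_trajectory.csv"))
        eq <- lapply(unique(sc$signal$level),
                     function(a) equilibrium(sc$rates, a))
        jsonlite::write_json(eq, out("equilibria.json"), auto_unbox = TRUE,
                             digits = NA)
      },
      fsp = {
        p0 <- fsp_initial(sc$space, sc$init["P"], sc$init["Pm"])
        sol <- fsp_propagate(p0, sc$rates, sc$signal, sc$space, sc$grid,
                             sc$ctx)
        write_heatmap_matrix(sol, out("fsp_heatmap.csv"))
        utils::write.csv(data.frame(time = sol$times, mass = sol$mass),
                         out("fsp_mass.csv"), row.names = FALSE)
      },
      ssa = {
        if (sc$n_cells > 1L) {
          ens <- ensemble_mean(sc)
          write_trajectory_csv(ens, out("ssa_ensemble_mean.csv"))
        } else {
          write_trajectory_csv(ssa_run(sc, record = "grid"),
                               out("ssa_trajectory.csv"))
        }
      },
      cle = {
        write_trajectory_csv(cle_run(sc, dt = config$cle_dt %||% 1e-3),
                             out("cle_trajectory.csv"))
      },
      fcd = {
        s1 <- scenario("fcd_A1", seed = sc$seed)
        s2 <- scenario("fcd_A2", seed = sc$seed)
        t1 <- solve_piecewise(s1$rates, s1$signal, s1$init_conc)
        t2 <- solve_piecewise(s2$rates, s2$signal, s2$init_conc)
        m1 <- interval_peaks(t1, s1$signal)
        m2 <- interval_peaks(t2, s2$signal)
        rel <- relative_difference_statistics(m1, m2)
        rep <- fcd_verdict(c(rel$rel_fwd, rel$cross),
                           statistic = "relative difference, A1 vs A2")
        jsonlite::write_json(
          list(statistic = rep$statistic, per_interval = rel,
               max_value = rep$max_value, threshold = rep$threshold,
               pass = rep$pass),
          out("fcd_report.json"), auto_unbox = TRUE, digits = NA,
          dataframe = "columns")
      },
      ergodicity = {
        rep <- compare_sampling_schemes(
          sc, t_star = config$t_star %||% 50,
          n = config$n %||% 1000L, dt = config$dt %||% 5)
        utils::write.csv(
          data.frame(count = rep$support, snapshot = rep$snapshot_hist,
                     timeseries = rep$timeseries_hist),
          out("ergodicity_histograms.csv"), row.names = FALSE)
        jsonlite::write_json(
          rep[c("tv_distance", "t_star", "n", "dt", "species", "scenario",
                "seed")],
          out("ergodicity_report.json"), auto_unbox = TRUE, digits = NA)
      })
  }

  manifest <- list(config = config, scenario = sc$name, seed = sc$seed,
                   F_i = sc$F_i, n_cells = sc$n_cells,
                   files = lapply(stats::setNames(files, basename(files)),
                                  function(f)
                                    unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
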