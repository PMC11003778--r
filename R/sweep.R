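## Sweep orchestration: parameter grids, replicate/seed management and all
## file output (trajectory TSVs, run manifest JSON, classified grid summary
## TSV).

#' Derive a replicate seed deterministically
#'
#' Stable integer mix of (base seed, grid-cell index, replicate index), so
#' that adding grid cells never changes the streams of existing replicates.
#' All arithmetic stays exact in doubles and the result is below 2^31.
#'
#' @param base_seed Integer base seed.
#' @param cell Grid-cell index (0 for standalone runs).
#' @param replicate Replicate index (vectorized).
#' @return Integer seed(s) in `[1, 2147483628]`.
#' @export
derive_seed <- function(base_seed, cell, replicate) {
  m <- 2147483629
  x <- (abs(as.numeric(base_seed)) %% m)
  x <- (x * 1000003 + as.numeric(cell) * 10007) %% m
  x <- (x * 48271 + as.numeric(replicate) * 97 + 12345) %% m
  as.integer(x %% (m - 1)) + 1L
}

#' Specify a parameter sweep
#'
#' A grid over model parameters; every combination of the supplied values
#' becomes one cell, expanded into `replicates` runs of a config derived
#' from `base` by overriding those fields.
#'
#' @param u,s Transposition rates and selection coefficients to cross.
#' @param fitness_mode Fitness interaction modes to cross.
#' @param b,k Silencing multipliers to cross.
#' @param r_e Ectopic rates to cross.
#' @param base A [te_config()] template supplying every other field.
#' @param replicates Replicates per cell (default from `base`).
#' @param base_seed Base seed for [derive_seed()] (default `base$seed`).
#' @param out_dir Output directory for [run_sweep()]; `NULL` keeps results
#'   in memory only.
#' @return A list of class `"te_sweep_spec"` with the expanded `grid`
#'   (data frame, one row per cell).
#' @export
sweep_spec <- function(u, s, fitness_mode = "additive", b = 0, k = 0,
                       r_e = 0, base = te_profile("desk"),
                       replicates = base$replicates,
                       base_seed = base$seed, out_dir = NULL) {
  base <- validate_te_config(base)
  if (replicates < 1) stop("`replicates` must be >= 1; nothing to run")
  grid <- expand.grid(u = u, s = s, fitness_mode = fitness_mode, b = b,
                      k = k, r_e = r_e, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cell <- seq_len(nrow(grid))
  # every cell must expand to a valid configuration
  for (i in seq_len(nrow(grid))) cell_config(grid[i, ], base)
  structure(list(grid = grid, base = base, replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), out_dir = out_dir),
            class = "te_sweep_spec")
}

cell_config <- function(row, base) {
  ov <- list(u = row$u, s = row$s, fitness_mode = row$fitness_mode,
             b = row$b, k = row$k, r_e = row$r_e)
  cfg <- utils::modifyList(unclass(base), ov)
  class(cfg) <- "te_config"
  validate_te_config(cfg)
  cfg
}

#' Run a parameter sweep
#'
#' Runs every (cell, replicate) with seed `derive_seed(base_seed, cell,
#' replicate)`, classifies each cell with [classify_outcome()], and (when
#' `out_dir` is set) writes per-replicate trajectory TSVs, a JSON run
#' manifest echoing the full configuration, and the classified grid summary
#' TSV.  A rerun skips cells whose trajectory files are already complete,
#' so interrupted sweeps are resumable.
#'
#' @param spec A [sweep_spec()].
#' @param window,alpha Plateau-detection settings for [classify_outcome()].
#' @param adaptive_horizon If `TRUE`, each cell runs for
#'   an analytically suggested settling horizon (capped at
#'   `max_generations`) instead of the full maximum; loss and crash runs
#'   terminate early regardless.
#' @param quiet Suppress per-cell progress lines.
#' @return Data frame of class `"te_grid_summary"`: one row per cell with
#'   the outcome label, mean copy number, mean fitness, the analytical
#'   `n_hat` for the cell, and the two effective-rate ratios at `n_hat`
#'   (`NA` where undefined).
#' @export
run_sweep <- function(spec, window = 1500, alpha = 0.01,
                      adaptive_horizon = TRUE, quiet = FALSE) {
  stopifnot(inherits(spec, "te_sweep_spec"))
  out_dir <- spec$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (file.access(out_dir, mode = 2L) != 0L)
      stop("output directory is not writable: ", out_dir)
    write_manifest(spec, file.path(out_dir, "manifest.json"))
  }
  rows <- vector("list", nrow(spec$grid))
  for (i in seq_len(nrow(spec$grid))) {
    row <- spec$grid[i, ]
    cfg <- cell_config(row, spec$base)
    horizon <- if (adaptive_horizon) suggest_horizon(cfg, window = window)
               else cfg$max_generations
    seeds <- derive_seed(spec$base_seed, row$cell, seq_len(spec$replicates))
    traj_paths <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("cell%03d_rep%03d.tsv", row$cell,
                                 seq_len(spec$replicates)))
    t0 <- proc.time()[["elapsed"]]
    if (!is.null(out_dir) && all(file.exists(traj_paths))) {
      runs <- lapply(traj_paths, read_trajectory_run)
    } else {
      runs <- lapply(seq_len(spec$replicates), function(j) {
        run_simulation(cfg, generations = horizon, seed = seeds[j])
      })
      if (!is.null(out_dir))
        for (j in seq_along(runs)) write_trajectory(runs[[j]], traj_paths[j])
    }
    out <- classify_outcome(runs, cfg$N, cfg$s, window = window, alpha = alpha)
    eq <- analytic_equilibrium(cfg$u, cfg$s, cfg$a, cfg$b, cfg$k,
                               mode = cfg$fitness_mode)
    ratios <- if (!is.na(eq$n_hat))
      effective_rate_ratios(eq$n_hat, cfg$u, cfg$s, cfg$a, cfg$b, cfg$k)
    else list(effective_s_over_u = NA_real_, s_over_effective_u = NA_real_)
    final_fit <- vapply(runs, function(r)
      r$trajectory$mean_fitness[nrow(r$trajectory)], numeric(1))
    rows[[i]] <- data.frame(
      cell = row$cell, u = row$u, s = row$s, mode = row$fitness_mode,
      b = row$b, k = row$k, r_e = row$r_e, label = out$label,
      mean_copy_number = out$mean_copy_number,
      mean_fitness = mean(final_fit),
      relative_variance = out$relative_variance,
      analytic_n_hat = eq$n_hat,
      analytic_stable = isTRUE(eq$stable),
      effective_s_over_u = ratios$effective_s_over_u,
      s_over_effective_u = ratios$s_over_effective_u
    )
    if (!quiet)
      message(sprintf(
        "cell %d/%d (u=%g s=%g %s b=%g k=%g): %s [%.1fs]",
        row$cell, nrow(spec$grid), row$u, row$s, row$fitness_mode, row$b,
        row$k, out$label, proc.time()[["elapsed"]] - t0))
  }
  summary <- do.call(rbind, rows)
  class(summary) <- c("te_grid_summary", class(summary))
  if (!is.null(out_dir)) {
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary
}

#' Write one replicate trajectory as TSV
#'
#' Columns: generation, mean_copy_number, mean_fitness, modifier_frequency,
#' status (terminal status repeated on every row for self-containment).
#'
#' @param run A `te_run` (or `te_invasion`, which adds its `phase` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(run, path) {
  tr <- run$trajectory
  tr$status <- run$status
  utils::write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_trajectory_run <- function(path) {
  tr <- utils::read.delim(path)
  status <- tr$status[nrow(tr)]
  tr$status <- NULL
  structure(list(trajectory = tr, status = status,
                 generations_run = tr$generation[nrow(tr)],
                 final_population = NULL),
            class = "te_run")
}

write_manifest <- function(spec, path) {
  manifest <- list(
    package = "tesim",
    version = as.character(utils::packageVersion("tesim")),
    base_seed = spec$base_seed,
    replicates = spec$replicates,
    base_config = unclass(spec$base),
    grid = spec$grid
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a sweep manifest back into a sweep specification
#'
#' Round-trips the JSON manifest written by [run_sweep()], so a sweep is
#' fully reproducible from its manifest alone.
#'
#' @param path Path to `manifest.json`.
#' @param out_dir Output directory for the reconstructed spec.
#' @return A `te_sweep_spec`.
#' @export
read_manifest <- function(path, out_dir = NULL) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- m$base_config
  class(base) <- "te_config"
  validate_te_config(base)
  grid <- as.data.frame(m$grid)
  spec <- sweep_spec(u = unique(grid$u), s = unique(grid$s),
                     fitness_mode = unique(grid$fitness_mode),
                     b = unique(grid$b), k = unique(grid$k),
                     r_e = unique(grid$r_e), base = base,
                     replicates = m$replicates, base_seed = m$base_seed,
                     out_dir = out_dir)
  stopifnot(identical(dim(spec$grid), dim(grid)))
  spec
}

#' Tabulate outcomes of a classified grid
#'
#' Counts each outcome label per fitness mode and silencing setting, and
#' reports how the set of stable cells changes relative to the no-silencing
#' (`b = 0, k = 0`) setting — the "expanded conditions" comparison made
#' countable.
#'
#' @param summary A grid summary from [run_sweep()] (or any data frame with
#'   columns `mode`, `b`, `k`, `label`, `u`, `s`).
#' @return A list with `counts` (data frame of label counts per
#'   mode/silencing setting) and `stable_expansion` (data frame comparing
#'   stable-cell counts of each silencing setting against its no-silencing
#'   baseline mode).
#' @export
summarize_grid <- function(summary) {
  if (nrow(summary) == 0L) {
    warning("empty grid summary")
    return(list(counts = data.frame(), stable_expansion = data.frame()))
  }
  setting <- interaction(summary$mode, summary$b, summary$k, drop = TRUE)
  counts <- as.data.frame(table(setting = setting, label = summary$label))
  counts <- counts[counts$Freq > 0 | TRUE, ]
  stable_cells <- function(df) {
    df <- df[df$label == "stable_equilibrium", , drop = FALSE]
    paste(df$u, df$s)
  }
  settings <- unique(summary[, c("mode", "b", "k")])
  exp_rows <- lapply(seq_len(nrow(settings)), function(i) {
    st <- settings[i, ]
    sub <- summary[summary$mode == st$mode & summary$b == st$b &
                     summary$k == st$k, ]
    baseline <- summary[summary$mode == st$mode & summary$b == 0 &
                          summary$k == 0, ]
    data.frame(mode = st$mode, b = st$b, k = st$k,
               n_stable = length(stable_cells(sub)),
               n_stable_baseline = length(stable_cells(baseline)),
               gained = length(setdiff(stable_cells(sub),
                                       stable_cells(baseline))),
               lost = length(setdiff(stable_cells(baseline),
                                     stable_cells(sub))))
  })
  list(counts = counts, stable_expansion = do.call(rbind, exp_rows))
}
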