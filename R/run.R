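#' Simulation run configuration
#'
#' Collects everything one simulation run needs: the vessel (a mesh file or
#' an in-package tube phantom), the base pose, material parameters,
#' discretization, solver settings, the scripted inputs, and optional output
#' paths. Configs round-trip through YAML ([read_run_config()],
#' [write_run_config()]) so a run is fully reproducible from its emitted
#' config.
#'
#' Input scripts may be a numeric vector of signed steps (mm) or shorthand
#' strings `"push D by h"` / `"pull D by h"`, expanded to `round(D / h)`
#' equal steps.
#'
#' @param mesh list: either `list(file = path)` or a tube description
#'   `list(tube = list(...))` with [tube_spec()] arguments; NULL for free
#'   space.
#' @param base_position,base_tangent catheter base pose (tangent normalized
#'   here).
#' @param alpha,kappa material parameters (see [material_params()]).
#' @param segment_length nominal element length l (mm).
#' @param initial_length inserted length at step 0 (mm).
#' @param margin contact-retention margin for the solver's active set (mm);
#'   see [solver_config()]. The default scales with the discretization,
#'   `min(0.05, segment_length / 10)`: the band must stay well below the
#'   element length or near-wall nodes get held onto their contact planes
#'   and the fine-discretization limit degrades.
#' @param script input script (numeric steps or shorthand strings).
#' @param solver list of [solver_config()] overrides.
#' @param trace_csv,positions_csv,summary_json optional output paths.
#' @return object of class `run_config`.
#' @export
run_config <- function(mesh = NULL,
                       base_position = c(0, 0, 0),
                       base_tangent = c(1, 0, 0),
                       alpha = 1, kappa = 100,
                       segment_length = 1,
                       initial_length = segment_length,
                       margin = NULL,
                       script = numeric(),
                       solver = list(),
                       trace_csv = NULL, positions_csv = NULL,
                       summary_json = NULL) {
  if (segment_length <= 0) stop("segment_length must be > 0", call. = FALSE)
  if (is.null(margin)) margin <- min(0.05, segment_length / 10)
  base_tangent <- as.numeric(base_tangent)
  nt <- sqrt(sum(base_tangent^2))
  if (nt == 0) stop("base_tangent must be nonzero", call. = FALSE)
  if (!is.null(mesh) && !is.null(mesh$file) && !file.exists(mesh$file)) {
    stop(sprintf("mesh file does not exist: %s", mesh$file), call. = FALSE)
  }
  steps <- expand_script(script, segment_length)
  if (length(steps) > 0L && any(abs(steps) > segment_length + 1e-12)) {
    stop("every scripted step must satisfy |step| <= segment_length",
         call. = FALSE)
  }
  structure(
    list(mesh = mesh, base_position = as.numeric(base_position),
         base_tangent = base_tangent / nt, alpha = alpha, kappa = kappa,
         segment_length = segment_length, initial_length = initial_length,
         margin = margin, script = script, steps = steps, solver = solver,
         trace_csv = trace_csv, positions_csv = positions_csv,
         summary_json = summary_json),
    class = "run_config")
}

expand_script <- function(script, l) {
  if (is.numeric(script)) return(as.numeric(script))
  out <- numeric(0)
  for (item in script) {
    if (is.numeric(item)) {
      out <- c(out, item)
      next
    }
    m <- regmatches(item,
      regexec("^\\s*(push|pull)\\s+([0-9.eE+-]+)\\s+by\\s+([0-9.eE+-]+)\\s*$",
              item))[[1L]]
    if (length(m) != 4L) {
      stop(sprintf("cannot parse script entry '%s'", item), call. = FALSE)
    }
    dist <- as.numeric(m[3L])
    h <- as.numeric(m[4L])
    if (!is.finite(dist) || !is.finite(h) || h <= 0 || dist <= 0) {
      stop(sprintf("bad distances in script entry '%s'", item), call. = FALSE)
    }
    n <- round(dist / h)
    out <- c(out, rep(if (m[2L] == "push") h else -h, n))
  }
  out
}

config_mesh <- function(config) {
  if (is.null(config$mesh)) return(NULL)
  if (!is.null(config$mesh$file)) return(load_mesh(config$mesh$file))
  if (!is.null(config$mesh$tube)) {
    return(make_tube(do.call(tube_spec, config$mesh$tube)))
  }
  stop("mesh must give either a file or a tube spec", call. = FALSE)
}

config_solver <- function(config) {
  do.call(solver_config, c(config$solver, list(margin = config$margin)))
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_run_config()] returns a `run_config`;
#'   [write_run_config()] returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$steps <- NULL            # derived from script
  if (length(out$script) > 0L) out$script <- as.list(out$script)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run one configured simulation
#'
#' Loads or generates the vessel, initializes the catheter, runs the scripted
#' push/pull sequence through the equilibrium solver, and (optionally) writes
#' the diagnostics trace CSV, the long-format node-position CSV and a JSON
#' run summary. Non-converged steps are reported in the summary, not fatal.
#'
#' @param config a [run_config()].
#' @return the [simulate_sequence()] trace, invisibly gaining attribute
#'   `files` with any paths written.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  mesh <- config_mesh(config)
  init <- init_catheter(config$base_position, config$base_tangent,
                        config$initial_length, config$segment_length)
  trace <- simulate_sequence(
    init, mesh, material_params(config$alpha, config$kappa),
    inputs = config$steps, cfg = config_solver(config))
  files <- character(0)
  if (!is.null(config$trace_csv)) {
    write_trace(trace, config$trace_csv)
    files <- c(files, config$trace_csv)
  }
  if (!is.null(config$positions_csv)) {
    write_positions(trace, config$positions_csv)
    files <- c(files, config$positions_csv)
  }
  if (!is.null(config$summary_json)) {
    n <- nrow(trace$table)
    summary <- list(
      steps = n - 1L,
      converged_steps = sum(trace$table$converged),
      non_converged_steps = sum(!trace$table$converged),
      final_n_nodes = trace$table$n_nodes[n],
      final_potential = trace$table$potential[n],
      final_U_e = trace$table$U_e[n],
      final_U_p = trace$table$U_p[n],
      final_max_penetration = trace$table$max_penetration[n],
      max_gradient_residual = max(trace$table$gradient_residual),
      max_tangent_norm_drift = max(trace$table$tangent_norm_drift))
    jsonlite::write_json(summary, config$summary_json, auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, config$summary_json)
  }
  attr(trace, "files") <- files
  invisible(trace)
}

#' Write / read the per-step diagnostics trace
#'
#' Numbers are formatted with 17 significant digits, so the CSV parses back
#' to the identical doubles and reruns of a deterministic config are
#' byte-identical.
#'
#' @param trace a `simulation_trace`.
#' @param path CSV path.
#' @return `path` (write) or a data frame (read).
#' @export
write_trace <- function(trace, path) {
  tab <- trace$table
  num <- vapply(tab, is.double, logical(1))
  out <- tab
  out[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write node positions of every step, long format
#'
#' Columns `step, node, x, y, z` (node 0 is the base), full float precision.
#'
#' @param trace a `simulation_trace`.
#' @param path CSV path.
#' @export
write_positions <- function(trace, path) {
  rows <- lapply(seq_along(trace$results), function(k) {
    p <- trace$results[[k]]$state$positions
    data.frame(step = k - 1L, node = seq_len(nrow(p)) - 1L,
               x = p[, 1], y = p[, 2], z = p[, 3])
  })
  out <- do.call(rbind, rows)
  out$x <- sprintf("%.17g", out$x)
  out$y <- sprintf("%.17g", out$y)
  out$z <- sprintf("%.17g", out$z)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a positions CSV as a list of per-step matrices
#' @param path CSV written by [write_positions()].
#' @return list of N x 3 matrices, one per step.
#' @export
read_positions <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$step), function(s) {
    unname(as.matrix(s[order(s$node), c("x", "y", "z")]))
  })
}

#' Convergence sweep over segment length and input stepsize
#'
#' Runs the scripted navigation of a template config over a grid of segment
#' lengths `l` and stepsize ratios `h/l`, then measures each run's final
#' catheter shape against a high-resolution reference run (segment length
#' `min(l) / refinement`, stepped at the same `h/l` ratio). Both final
#' curves are arc-length-resampled at the run's `l` before the node-wise
#' comparison, mirroring how simulated catheters are scored against a
#' resampled ground-truth curve.
#'
#' @param template a [run_config()] whose `script` uses push/pull shorthand
#'   with `h` given as a *fraction of l* (e.g. "push 20 by 0.2" means steps
#'   of `0.2 * l`); plain numeric scripts are also scaled by `l`.
#' @param l_values segment lengths to test (mm).
#' @param h_over_l stepsize ratios to test.
#' @param refinement reference refinement factor (reference l = min(l) /
#'   refinement).
#' @param report_csv optional output CSV path.
#' @return data frame with columns `l`, `h_over_l`, `rms_mm`, `max_mm`,
#'   `n_steps`.
#' @export
run_sweep <- function(template, l_values, h_over_l, refinement = 8,
                      report_csv = NULL) {
  stopifnot(inherits(template, "run_config"))
  if (length(l_values) == 0L || length(h_over_l) == 0L) {
    out <- data.frame(l = numeric(0), h_over_l = numeric(0),
                      rms_mm = numeric(0), max_mm = numeric(0),
                      n_steps = integer(0))
    if (!is.null(report_csv)) {
      utils::write.csv(out, report_csv, row.names = FALSE)
    }
    return(out)
  }
  run_at <- function(l, ratio) {
    cfg <- template
    cfg$segment_length <- l
    cfg$margin <- min(cfg$margin, l / 10)   # retention band stays below l
    cfg$initial_length <- max(cfg$initial_length, l)
    cfg$steps <- expand_scaled_script(template$script, l, ratio)
    cfg$trace_csv <- cfg$positions_csv <- cfg$summary_json <- NULL
    run_simulation(cfg)
  }
  refs <- new.env(parent = emptyenv())
  out <- data.frame()
  for (ratio in h_over_l) {
    key <- sprintf("%.12g", ratio)
    if (is.null(refs[[key]])) {
      l_ref <- min(l_values) / refinement
      refs[[key]] <- run_at(l_ref, ratio)
    }
    ref_trace <- refs[[key]]
    ref_final <- ref_trace$results[[length(ref_trace$results)]]$state$positions
    for (l in l_values) {
      tr <- run_at(l, ratio)
      sim_final <- tr$results[[length(tr$results)]]$state$positions
      spacing <- l
      sim_r <- resample_polyline(sim_final, spacing)
      ref_r <- resample_polyline(ref_final, spacing)
      n <- min(nrow(sim_r), nrow(ref_r))
      cmp <- compare_curves(sim_r[seq_len(n), , drop = FALSE],
                            ref_r[seq_len(n), , drop = FALSE])
      out <- rbind(out, data.frame(l = l, h_over_l = ratio,
                                   rms_mm = cmp$rms,
                                   max_mm = cmp$max_displacement,
                                   n_steps = length(tr$steps) - 1L))
    }
  }
  if (!is.null(report_csv)) utils::write.csv(out, report_csv, row.names = FALSE)
  out
}

# Expand a template script where step sizes are fractions of l.
expand_scaled_script <- function(script, l, ratio) {
  h <- l * ratio
  if (is.numeric(script)) {
    total <- sum(script)
    n <- round(abs(total) / h)
    return(rep(sign(total) * h, n))
  }
  out <- numeric(0)
  for (item in script) {
    m <- regmatches(item,
      regexec("^\\s*(push|pull)\\s+([0-9.eE+-]+)\\s+by\\s+([0-9.eE+-]+)\\s*$",
              item))[[1L]]
    if (length(m) != 4L) {
      stop(sprintf("cannot parse script entry '%s'", item), call. = FALSE)
    }
    dist <- as.numeric(m[3L])
    n <- round(dist / h)
    out <- c(out, rep(if (m[2L] == "push") h else -h, n))
  }
  out
}
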