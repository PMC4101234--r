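#' Experiment configuration
#'
#' Describes one simulation study: phantom size, scan geometry, noise
#' setting, the algorithms to run and their parameters. `snr_db = Inf`
#' means noise-free. `noise_reference` selects the signal-power reference of
#' [add_noise()]; the head-phantom protocol uses `"unit"` (see the methods
#' vignette).
#'
#' @param phantom_size phantom edge length in pixels.
#' @param n_views number of projection angles (interleaved schedule).
#' @param n_detectors detectors per view; defaults to `phantom_size`.
#' @param snr_db noise level in dB, `Inf` for noise-free.
#' @param noise_reference `"unit"` or `"measured"`, see [add_noise()].
#' @param algorithms subset of `c("art", "art-tv", "spbr-nact")`.
#' @param params a [recon_params()] or a list of its arguments.
#' @param nact list of NACT settings: `levels`, `dirs_per_level`, `a`.
#' @param output_dir optional directory for CSV/plot output.
#' @param seed integer seed for the noise realization.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(phantom_size = 200, n_views = 60,
                              n_detectors = phantom_size, snr_db = Inf,
                              noise_reference = "unit",
                              algorithms = c("art", "art-tv", "spbr-nact"),
                              params = recon_params(),
                              nact = list(levels = 3,
                                          dirs_per_level = c(4, 8, 8),
                                          a = 0.2 * pi),
                              output_dir = NULL, seed = 0) {
  if (is.list(params) && !inherits(params, "recon_params")) {
    params$threshold_convention <- params$threshold_convention %||% "as_printed"
    params <- do.call(recon_params, params)
  }
  algorithms <- match.arg(algorithms, c("art", "art-tv", "spbr-nact"),
                          several.ok = TRUE)
  structure(
    list(phantom_size = as.integer(phantom_size),
         n_views = as.integer(n_views),
         n_detectors = as.integer(n_detectors),
         snr_db = as.numeric(snr_db),
         noise_reference = noise_reference,
         algorithms = algorithms, params = params,
         nact = nact, output_dir = output_dir, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## assemble phantom, system matrix and (optionally noisy) sinogram
setup_experiment <- function(config, n_views = config$n_views,
                             noisy = is.finite(config$snr_db)) {
  ph <- make_phantom(config$phantom_size)
  g <- projection_geometry(n_views = n_views,
                           n_detectors = config$n_detectors)
  A <- build_system_matrix(dim(ph), g)
  p <- project(A, ph)
  if (noisy) {
    p <- add_noise(p, config$snr_db, seed = config$seed,
                   reference = config$noise_reference)
  }
  list(phantom = ph, A = A, p = p, noisy = noisy)
}

## residual-based stopping tolerance: used for noise-free runs only
default_sigma <- function(p, noisy) {
  if (noisy) NULL else sqrt(1e-8 * l2sq(p))
}

run_algorithm <- function(algorithm, setup, params, nact_cfg,
                          reference = NULL) {
  params$sigma <- params$sigma %||% default_sigma(setup$p, setup$noisy)
  switch(algorithm,
    "art" = art_reconstruct(setup$A, setup$p, params, reference = reference),
    "art-tv" = art_tv_reconstruct(setup$A, setup$p, params,
                                  reference = reference),
    "spbr-nact" = {
      sp <- nact_spec(dim(setup$phantom),
                      levels = nact_cfg$levels %||% 3,
                      dirs_per_level = nact_cfg$dirs_per_level %||% c(4, 8, 8),
                      a = nact_cfg$a %||% (0.2 * pi))
      spbr_nact_reconstruct(setup$A, setup$p, params,
                            transform = nact_transform(sp),
                            reference = reference)
    },
    stop_invalid("unknown algorithm '", algorithm, "'")
  )
}

#' Reproduce the head-phantom comparison table
#'
#' Runs the configured algorithms on the noise-free sinogram and on a noisy
#' realization at `config$snr_db` (skipped when `snr_db = Inf`), and
#' tabulates RMSE and UQI of each reconstruction against the phantom. With
#' `config$output_dir` set, the table is also written to `table1.csv` there.
#'
#' @param config an [experiment_config()]; `snr_db` defaults to 10 dB here
#'   when the config leaves it at `Inf`.
#' @return A data frame with columns `noise`, `algorithm`, `rmse`, `uqi`.
#' @export
run_table1 <- function(config = experiment_config()) {
  snr <- if (is.finite(config$snr_db)) config$snr_db else 10
  rows <- list()
  for (noise in c("noise-free", "noisy")) {
    cfg <- config
    cfg$snr_db <- if (noise == "noisy") snr else Inf
    setup <- setup_experiment(cfg)
    for (alg in config$algorithms) {
      fR <- run_algorithm(alg, setup, config$params, config$nact)
      rows[[length(rows) + 1]] <- data.frame(
        noise = noise, algorithm = alg,
        rmse = rmse(setup$phantom, fR), uqi = uqi(setup$phantom, fR)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out, file.path(config$output_dir, "table1.csv"),
              row.names = FALSE)
  }
  out
}

#' Metric curves over iteration count or view count
#'
#' For `over = "iterations"` each algorithm is run once for `max(grid)`
#' outer iterations at the configured view count and the per-iteration
#' metric log is sampled at the grid points. For `over = "views"` each
#' algorithm is rerun per grid value with the configured iteration count.
#' With `config$output_dir` set, the curves are written to
#' `sweep_<over>.csv` and, when ggplot2 is available, plotted to
#' `sweep_<over>.pdf`.
#'
#' @param config an [experiment_config()].
#' @param over `"iterations"` or `"views"`.
#' @param grid increasing vector of grid points (iteration counts or view
#'   counts).
#' @return Data frame with columns `noise`, `algorithm`, `grid`, `rmse`,
#'   `uqi`.
#' @export
run_sweep <- function(config = experiment_config(),
                      over = c("iterations", "views"), grid) {
  over <- match.arg(over)
  if (length(grid) < 1 || is.unsorted(grid, strictly = TRUE)) {
    stop_invalid("'grid' must be a nonempty increasing vector")
  }
  rows <- list()
  add_row <- function(noise, alg, g, r, u) {
    rows[[length(rows) + 1]] <<- data.frame(
      noise = noise, algorithm = alg, grid = g, rmse = r, uqi = u
    )
  }
  noise_lab <- if (is.finite(config$snr_db)) "noisy" else "noise-free"
  if (over == "iterations") {
    setup <- setup_experiment(config)
    params <- config$params
    params$n_outer <- max(grid)
    params$sigma <- 0  # run every outer iteration; sample the log
    for (alg in config$algorithms) {
      fR <- run_algorithm(alg, setup, params, config$nact,
                          reference = setup$phantom)
      log <- attr(fR, "metrics")
      for (g in grid) add_row(noise_lab, alg, g, log$rmse[g], log$uqi[g])
    }
  } else {
    for (g in grid) {
      setup <- setup_experiment(config, n_views = g)
      for (alg in config$algorithms) {
        fR <- run_algorithm(alg, setup, config$params, config$nact)
        add_row(noise_lab, alg, g, rmse(setup$phantom, fR),
                uqi(setup$phantom, fR))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out, file.path(config$output_dir,
                             paste0("sweep_", over, ".csv")),
              row.names = FALSE)
    plot_sweep(out, over, file.path(config$output_dir,
                                    paste0("sweep_", over, ".pdf")))
  }
  out
}

## convenience plot; the acceptance surface never depends on it
plot_sweep <- function(curves, over, path) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    message("ggplot2 not available; skipping plot")
    return(invisible(NULL))
  }
  long <- rbind(
    data.frame(curves[c("algorithm", "grid")], metric = "rmse",
               value = curves$rmse),
    data.frame(curves[c("algorithm", "grid")], metric = "uqi",
               value = curves$uqi)
  )
  gp <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$grid, y = .data$value, colour = .data$algorithm
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = over, y = NULL)
  ggplot2::ggsave(path, gp, width = 8, height = 4)
  invisible(path)
}

#' Extract a horizontal profile line
#'
#' Returns one image row (1-based index, row 1 at the top) as a numeric
#' vector, e.g. for comparing a reconstruction against the phantom along
#' line 140.
#'
#' @param image numeric matrix.
#' @param row 1-based row index.
#' @return Numeric vector of length `ncol(image)`.
#' @export
profile_line <- function(image, row) {
  if (!is.matrix(image)) stop_invalid("'image' must be a matrix")
  if (!is.numeric(row) || length(row) != 1 || is.na(row) ||
      row < 1 || row > nrow(image)) {
    stop_invalid("'row' must be a row index between 1 and ", nrow(image))
  }
  as.numeric(image[as.integer(row), ])
}
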