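#' Load a run configuration from a YAML file
#'
#' Reads and validates a full run configuration: model parameters, variant
#' parameters, run length, seed(s), recorders and output directory.
#' Unknown keys are rejected by name so that typos cannot silently change
#' a run.
#'
#' Recognised keys: \code{variant}, \code{N}, \code{gamma}, \code{n_steps},
#' \code{seed} (or \code{seeds}, a list), \code{burn_in},
#' \code{equalize_at_wave_start}, \code{variant_params} (mapping),
#' \code{recorders} (list), \code{wave_threshold},
#' \code{substantial_threshold}, \code{sad_bins_per_decade},
#' \code{out_dir}.
#'
#' @param path path to a YAML file.
#' @return an object of class \code{"run_config"}.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' Build and validate a run configuration
#'
#' @param x a named list of configuration values (see
#'   \code{\link{load_config}} for the recognised keys).
#' @return an object of class \code{"run_config"}.
#' @export
as_run_config <- function(x) {
  allowed <- c("variant", "N", "gamma", "n_steps", "seed", "seeds",
               "burn_in", "equalize_at_wave_start", "variant_params",
               "recorders", "wave_threshold", "substantial_threshold",
               "sad_bins_per_decade", "out_dir")
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in c("N", "gamma", "n_steps"))
    if (is.null(x[[k]])) stop("missing required configuration key: ", k)
  if (is.null(x$seed) && is.null(x$seeds))
    stop("missing required configuration key: seed (or seeds)")
  params <- model_params(N = x$N, gamma = x$gamma,
                         variant = x$variant %||% "basic",
                         variant_params = x$variant_params %||% list(),
                         equalize_at_wave_start =
                           isTRUE(x$equalize_at_wave_start))
  seeds <- as.integer(if (!is.null(x$seeds)) unlist(x$seeds) else x$seed)
  n_steps <- as.integer(x$n_steps)
  burn_in <- as.integer(x$burn_in %||% min(10L * params$N,
                                           n_steps %/% 2L))
  if (!(n_steps > burn_in && burn_in >= 0))
    stop("configuration requires n_steps > burn_in >= 0")
  recorders <- unlist(x$recorders %||%
                        list("events", "diversity", "sad", "snapshots"))
  recorders <- match.arg(recorders,
                         c("events", "diversity", "sad", "snapshots",
                           "species_stats"), several.ok = TRUE)
  if (length(recorders) == 0) stop("at least one recorder must be enabled")
  structure(list(params = params, n_steps = n_steps, burn_in = burn_in,
                 seeds = seeds,
                 recorders = recorders,
                 wave_threshold = x$wave_threshold %||%
                   (1 - 1 / params$N),
                 substantial_threshold = x$substantial_threshold %||% 1e-10,
                 sad_bins_per_decade = x$sad_bins_per_decade %||% 5,
                 out_dir = x$out_dir %||% "."),
            class = "run_config")
}

#' Write a run configuration to YAML (canonical form)
#'
#' \code{write_config(load_config(p), p2)} round-trips: reading \code{p2}
#' yields an identical configuration.
#'
#' @param config a \code{run_config}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  vp <- unclass(p$variant_params)
  vp$name <- NULL
  out <- list(variant = p$variant, N = p$N, gamma = p$gamma,
              n_steps = config$n_steps, burn_in = config$burn_in,
              seeds = as.list(config$seeds),
              equalize_at_wave_start = p$equalize_at_wave_start,
              variant_params = vp,
              recorders = as.list(config$recorders),
              wave_threshold = config$wave_threshold,
              substantial_threshold = config$substantial_threshold,
              sad_bins_per_decade = config$sad_bins_per_decade,
              out_dir = config$out_dir)
  yaml::write_yaml(out, path)
  invisible(path)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) read.delim(path, sep = "\t")

#' Write the tabular outputs of a run
#'
#' Emits the stable TSV schema: \code{events.tsv} (step,
#' victim_species_id, pre_collapse_size, rescale_factor, is_wave_boundary,
#' ...), \code{diversity.tsv} (step, D, P_max), \code{sad.tsv} and the
#' snapshot histograms (bin_low, bin_high, count, density), plus a
#' \code{manifest.json} with the configuration, seed, package version and
#' wall time — enough to reproduce every file byte-identically.
#'
#' @param run a \code{\link{simulate_community}} result.
#' @param dir output directory (created if missing).
#' @param elapsed optional wall time in seconds recorded in the manifest.
#' @return character vector of the files written, invisibly.
#' @export
write_run_tables <- function(run, dir, elapsed = NA_real_) {
  stopifnot(inherits(run, "divwave_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (!is.null(run$events))
    files <- c(files, .write_tsv(run$events, file.path(dir, "events.tsv")))
  if (!is.null(run$diversity))
    files <- c(files, .write_tsv(run$diversity,
                                 file.path(dir, "diversity.tsv")))
  hist_tsv <- function(h, name) {
    d <- sad_density(h)
    .write_tsv(data.frame(bin_low = 10^d$log10_low,
                          bin_high = 10^d$log10_high,
                          count = d$count, density = d$density),
               file.path(dir, name))
  }
  if (!is.null(run$sad)) files <- c(files, hist_tsv(run$sad, "sad.tsv"))
  if (!is.null(run$green)) {
    files <- c(files, hist_tsv(run$green, "sad_green.tsv"),
               hist_tsv(run$red, "sad_red.tsv"))
  }
  if (!is.null(run$species_stats))
    files <- c(files, .write_tsv(run$species_stats,
                                 file.path(dir, "species_stats.tsv")))
  vp <- unclass(run$params$variant_params)
  vp$name <- NULL
  manifest <- list(
    package = "divwave",
    version = as.character(packageVersion("divwave")),
    config = list(variant = run$params$variant, N = run$params$N,
                  gamma = run$params$gamma, n_steps = run$n_steps,
                  burn_in = run$burn_in, seed = run$seed,
                  equalize_at_wave_start =
                    run$params$equalize_at_wave_start,
                  variant_params = vp,
                  wave_threshold = run$wave_threshold,
                  substantial_threshold = run$substantial_threshold,
                  engine = run$engine),
    files = basename(files),
    elapsed_seconds = elapsed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(dir, "manifest.json"))
  invisible(files)
}

#' Read a SAD table written by \code{\link{write_run_tables}}
#'
#' @param path path to a \code{sad.tsv}-schema file.
#' @return a \code{\link{sad_histogram}} (snapshot count is reconstructed
#'   as total count; densities are re-derivable from counts).
#' @export
read_sad_tsv <- function(path) {
  d <- .read_tsv(path)
  edges <- log10(c(d$bin_low, d$bin_high[nrow(d)]))
  sad_histogram(edges, counts = d$count, n_snapshots = NA_real_)
}
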