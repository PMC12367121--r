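# Serialization with embedded provenance: every artifact carries the
# resolved configuration and package version so a run can be reproduced
# from its own output.

resolve_config <- function(x) {
  cfg <- list()
  p <- attr(x, "params")
  if (!is.null(p)) cfg$params <- unclass(p)
  d <- attr(x, "drive")
  if (!is.null(d)) cfg$drive <- unclass(d)
  nc <- attr(x, "config")
  if (!is.null(nc)) {
    nc <- unclass(nc)
    nc$drive <- unclass(nc$drive)
    cfg$network <- nc
  }
  for (nm in c("model", "backend", "sweep", "transient", "horizon",
               "guard_bits", "n_saturated")) {
    if (!is.null(attr(x, nm))) cfg[[nm]] <- attr(x, nm)
  }
  cfg
}

#' Write and read result tables with an embedded configuration header
#'
#' `write_result_csv()` writes any package result tibble as CSV preceded by
#' `#`-prefixed header lines holding the package version and the resolved
#' configuration (as JSON). `write_result_json()` writes nested results as a
#' JSON object with `config`, `results` and `version` keys.
#' `read_result_csv()` reads the CSV back and re-attaches the header as the
#' `"config"` attribute. Writes are atomic (temp file + rename).
#'
#' @param x A result tibble (trajectory, sweep table, raster, ...).
#' @param path Output file.
#' @return `path`, invisibly; `read_result_csv()` returns a tibble.
#' @export
write_result_csv <- function(x, path) {
  cfg <- jsonlite::toJSON(resolve_config(x), auto_unbox = TRUE, digits = NA)
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  on.exit(if (!is.null(con)) close(con), add = TRUE)
  writeLines(c(
    sprintf("# package: cordicfhn %s",
            as.character(utils::packageVersion("cordicfhn"))),
    sprintf("# config: %s", cfg)
  ), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  close(con)
  con <- NULL
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_result_csv
#' @export
read_result_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  out <- as_tibble(utils::read.csv(path, comment.char = "#"))
  cfgline <- grep("^# config: ", hdr, value = TRUE)
  if (length(cfgline)) {
    attr(out, "config") <- jsonlite::fromJSON(sub("^# config: ", "", cfgline[1]))
  }
  out
}

#' @rdname write_result_csv
#' @export
write_result_json <- function(x, path) {
  payload <- list(
    config = resolve_config(x),
    results = if (is.data.frame(x)) as.data.frame(x) else x,
    version = as.character(utils::packageVersion("cordicfhn"))
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, path)
  invisible(path)
}

#' Generate the small reference fixtures used by the test-suite
#'
#' Produces, under `dir`: short reference trajectories of both models (real
#' backend) and of the CORDIC model on the fixed backend; a 20-neuron
#' mini-network raster pair on identical wiring; and a reduced cube error
#' sweep on a coarse grid. Everything is derived deterministically from
#' `seed`, so regenerating with the same seed reproduces the files exactly.
#'
#' @param seed Integer seed for the network fixtures.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list with the generated objects and the file
#'   paths.
#' @export
fhn_fixtures <- function(seed = 1L, dir = tempdir()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- fhn_params()
  drive <- drive_constant(0.5)
  traj_fhn <- simulate_discrete("fhn", params, drive, duration = 200)
  traj_cordic <- simulate_discrete("cordic", params, drive, duration = 200)
  traj_fixed <- simulate_discrete("cordic", params, drive, duration = 200,
                                  backend = "fixed")
  cfg <- network_config(n_neurons = 20L, in_degree = 5L, seed = seed,
                        duration = 150, crop = 100)
  net <- build_network(cfg)
  raster_fhn <- simulate_network(net, "fhn")
  raster_cordic <- simulate_network(net, "cordic")
  sweep <- cube_error_sweep(iterations = c(12L, 16L), grid_step = 2^-4)
  paths <- list(
    traj_fhn = file.path(dir, "traj_fhn_real.csv"),
    traj_cordic = file.path(dir, "traj_cordic_real.csv"),
    traj_fixed = file.path(dir, "traj_cordic_fixed.csv"),
    raster_fhn = file.path(dir, "raster_fhn.json"),
    raster_cordic = file.path(dir, "raster_cordic.json"),
    cube_sweep = file.path(dir, "cube_error_sweep.csv")
  )
  write_result_csv(traj_fhn, paths$traj_fhn)
  write_result_csv(traj_cordic, paths$traj_cordic)
  write_result_csv(traj_fixed, paths$traj_fixed)
  write_result_json(raster_fhn, paths$raster_fhn)
  write_result_json(raster_cordic, paths$raster_cordic)
  write_result_csv(sweep, paths$cube_sweep)
  invisible(list(
    paths = paths,
    traj_fhn = traj_fhn, traj_cordic = traj_cordic, traj_fixed = traj_fixed,
    raster_fhn = raster_fhn, raster_cordic = raster_cordic,
    cube_sweep = sweep, network = net
  ))
}
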