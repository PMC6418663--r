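#' Write frames as an XYZ trajectory
#'
#' Plain-text XYZ: bead count line, comment line (`step=<s>` plus any extra
#' tokens), then one `X x y z` record per bead. Coordinates are absolute
#' (the system is unbounded, no periodic box).
#'
#' @param x a frame, [chain_state], `np_traj` or list of frames.
#' @param path output file.
#' @param comments optional character vector of per-frame comment lines;
#'   defaults to `step=<k>` (using recorded step indices for trajectories).
#' @param digits coordinate precision.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, comments = NULL, digits = 10) {
  frames <- as_frames(x)
  if (is.null(comments)) {
    steps <- if (inherits(x, "np_traj")) x$steps else seq_along(frames)
    comments <- sprintf("step=%d", steps)
  }
  stopifnot(length(comments) == length(frames))
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("X %%.%dg %%.%dg %%.%dg", digits, digits, digits)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    writeLines(c(as.character(nrow(f)), comments[k],
                 sprintf(fmt, f[, 1], f[, 2], f[, 3])), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path XYZ file written by [write_xyz()] (or any standard XYZ).
#' @return list with `frames` (list of N x 3 matrices) and `comments`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); comments <- character(0)
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0)
      stop(sprintf("XYZ parse error at line %d: expected a bead count", i))
    if (i + 1L + n > length(lines))
      stop(sprintf("XYZ parse error: frame starting at line %d is truncated", i))
    comments <- c(comments, lines[i + 1L])
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad) > 0)
      stop(sprintf("XYZ parse error at line %d: malformed atom record",
                   i + 1L + bad[1]))
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(m)))
      stop(sprintf("XYZ parse error: non-numeric coordinate in frame starting at line %d", i))
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + n
  }
  list(frames = frames, comments = comments)
}

config_defaults <- function() {
  list(
    chain = list(topology = "linear", n_beads = 100L, b = 0),
    geometry = NULL,
    forcefield = list(epsilon = 1, sigma = 1, kappa = 30, R_o = 1.5,
                      w = 0.9, l = 0.97),
    simulation = list(dt = 0.005, temperature = 1,
                      thermostat = "nose_hoover", relaxation = 0.1,
                      friction = 0.5, n_equil = 2e5, n_prod = 1e6,
                      sample_every = 1000L, seed = 1L,
                      orientation = "parallel"),
    analysis = list(n_blocks = 10L, q_points = 200L)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with blocks `chain`, `geometry` (optional;
#' omit for a free chain), `forcefield`, `simulation` and `analysis`,
#' fills in defaults, and validates every field, collecting all violations
#' into one deterministic error message. The geometry block may give any
#' two of `S_p`, `d_p`, `w_p` (all three only if consistent).
#'
#' @param path YAML file path.
#' @return validated config list (class `run_config`) with all defaults
#'   resolved.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_run_config(raw)
}

#' @rdname load_run_config
#' @param config a raw config list (as parsed from YAML).
#' @export
validate_run_config <- function(config) {
  def <- config_defaults()
  errs <- character(0)
  unknown_blocks <- setdiff(names(config), names(def))
  if (length(unknown_blocks) > 0)
    errs <- c(errs, sprintf("unknown block(s): %s",
                            paste(unknown_blocks, collapse = ", ")))
  cfg <- def
  for (blk in intersect(names(config), names(def))) {
    if (is.null(config[[blk]])) next
    if (blk == "geometry") {
      cfg$geometry <- config$geometry
      next
    }
    unknown <- setdiff(names(config[[blk]]), names(def[[blk]]))
    if (length(unknown) > 0)
      errs <- c(errs, sprintf("unknown key(s) in '%s': %s", blk,
                              paste(unknown, collapse = ", ")))
    cfg[[blk]] <- utils::modifyList(def[[blk]], config[[blk]])
  }

  if (!cfg$chain$topology %in% c("linear", "circular"))
    errs <- c(errs, "chain.topology must be 'linear' or 'circular'")
  if (!is.numeric(cfg$chain$n_beads) || cfg$chain$n_beads < 3)
    errs <- c(errs, "chain.n_beads must be an integer >= 3")
  if (!is.numeric(cfg$chain$b) || cfg$chain$b < 0)
    errs <- c(errs, "chain.b must be >= 0")

  if (!is.null(cfg$geometry)) {
    g <- cfg$geometry
    unknown <- setdiff(names(g), c("S_p", "d_p", "w_p", "w"))
    if (length(unknown) > 0)
      errs <- c(errs, sprintf("unknown key(s) in 'geometry': %s",
                              paste(unknown, collapse = ", ")))
    given <- intersect(c("S_p", "d_p", "w_p"), names(g))
    if (length(given) < 2) {
      errs <- c(errs, "geometry needs at least two of S_p, d_p, w_p")
    } else {
      arr <- tryCatch(
        post_array(S_p = g$S_p, d_p = g$d_p, w_p = g$w_p,
                   w = g$w %||% cfg$forcefield$w),
        error = function(e) conditionMessage(e))
      if (is.character(arr)) errs <- c(errs, paste("geometry:", arr))
    }
  }

  s <- cfg$simulation
  if (!is.numeric(s$dt) || s$dt <= 0) errs <- c(errs, "simulation.dt must be > 0")
  if (!is.numeric(s$temperature) || s$temperature <= 0)
    errs <- c(errs, "simulation.temperature must be > 0")
  if (!s$thermostat %in% c("nose_hoover", "langevin", "none"))
    errs <- c(errs, "simulation.thermostat must be nose_hoover, langevin or none")
  if (!s$orientation %in% c("parallel", "perpendicular"))
    errs <- c(errs, "simulation.orientation must be parallel or perpendicular")

  if (length(errs) > 0)
    stop(paste(c("invalid run configuration:",
                 paste0("  - ", errs)), collapse = "\n"))
  class(cfg) <- "run_config"
  cfg
}

#' Write a resolved configuration back to YAML
#'
#' Round-trips losslessly through [load_run_config()].
#'
#' @param config a `run_config`.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
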