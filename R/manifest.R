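# Run manifests: a YAML description of an experiment (seed, replication
# count, factor levels, clinic-parameter overrides) that the command-line
# tool and batch runs consume. Factor levels must stay on the studied
# lattice; clinic parameters (opening times, reception staffing) may be
# overridden.

MANIFEST_KEYS <- c("master_seed", "n_reps", "output_dir", "fixture_path",
                   "factor_levels", "overrides")
FACTOR_KEYS <- c("x0", "x1", "x2", "x3", "x4", "x5")
OVERRIDE_KEYS <- c("open_time", "close_time", "horizon", "reception_staff",
                   "background_stream_enabled", "background_rate")

FACTOR_LATTICE <- list(
  x0 = 2:20,
  x1 = c("All", "Half"),
  x2 = c("Mid", "Doc"),
  x3 = c(2L, 3L),
  x4 = c(2L, 3L),
  x5 = c(3L, 4L)
)

#' Default run manifest
#'
#' @param master_seed Integer master seed.
#' @return A `run_manifest`: the full factorial design (demand 2-20, all
#'   pattern/order/resource levels), 10,000 replications, packaged
#'   service-time fixtures, no overrides.
#' @export
default_run_manifest <- function(master_seed = 1) {
  structure(
    list(
      master_seed = as.integer(master_seed),
      n_reps = 10000L,
      output_dir = ".",
      fixture_path = NULL,
      factor_levels = FACTOR_LATTICE,
      overrides = list()
    ),
    class = "run_manifest"
  )
}

#' Read and validate a run manifest
#'
#' Parses a YAML manifest, fills defaults (10,000 replications, demand range
#' 2-20, base resource levels included), and validates that every key is
#' known and every factor level lies on the studied lattice.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_manifest`.
#' @export
read_run_manifest <- function(path) {
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("cannot parse manifest '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(raw)) stop("manifest must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(raw), MANIFEST_KEYS)
  if (length(unknown) > 0) {
    stop("unknown manifest keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$master_seed)) {
    stop("manifest must set master_seed", call. = FALSE)
  }
  mf <- default_run_manifest(raw$master_seed)
  if (!is.null(raw$n_reps)) mf$n_reps <- as.integer(raw$n_reps)
  if (!is.null(raw$output_dir)) mf$output_dir <- raw$output_dir
  if (!is.null(raw$fixture_path)) mf$fixture_path <- raw$fixture_path
  if (!is.null(raw$factor_levels)) {
    unknown_f <- setdiff(names(raw$factor_levels), FACTOR_KEYS)
    if (length(unknown_f) > 0) {
      stop("unknown factor keys: ", paste(unknown_f, collapse = ", "),
           call. = FALSE)
    }
    for (f in names(raw$factor_levels)) {
      lv <- raw$factor_levels[[f]]
      lattice <- FACTOR_LATTICE[[f]]
      if (is.numeric(lattice)) lv <- as.integer(lv)
      bad <- setdiff(lv, lattice)
      if (length(bad) > 0) {
        stop("factor ", f, " has out-of-lattice levels: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      mf$factor_levels[[f]] <- lv
    }
  }
  if (!is.null(raw$overrides)) {
    unknown_o <- setdiff(names(raw$overrides), OVERRIDE_KEYS)
    if (length(unknown_o) > 0) {
      stop("unknown override keys: ", paste(unknown_o, collapse = ", "),
           call. = FALSE)
    }
    mf$overrides <- raw$overrides
  }
  if (mf$n_reps < 2) stop("n_reps must be at least 2", call. = FALSE)
  mf
}

#' Write a run manifest to YAML
#'
#' @param manifest A `run_manifest`.
#' @param path Output path.
#' @return `path`, invisibly. Round-trips losslessly through
#'   [read_run_manifest()].
#' @export
write_run_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  out <- unclass(manifest)
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out$overrides) == 0) out$overrides <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Configurations described by a manifest
#'
#' @param manifest A `run_manifest`.
#' @return The configuration tibble for the manifest's factor levels, as
#'   from [enumerate_factorial_configurations()].
#' @export
manifest_configurations <- function(manifest) {
  fl <- manifest$factor_levels
  enumerate_factorial_configurations(
    x0_range = range(fl$x0),
    x1_levels = fl$x1, x2_levels = fl$x2,
    x3_levels = fl$x3, x4_levels = fl$x4, x5_levels = fl$x5
  ) |>
    dplyr::filter(.data$arrivals %in% fl$x0)
}

#' @export
print.run_manifest <- function(x, ...) {
  n_cfg <- prod(lengths(x$factor_levels))
  cat("<run_manifest> seed ", x$master_seed, ", ", x$n_reps,
      " reps, ", n_cfg, " configurations\n", sep = "")
  invisible(x)
}
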