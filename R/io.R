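#' Write end trajectories to a tab-separated file
#'
#' Columns: `time_s`, `position_nm`, `rodlet_id`, `end_label`, `category`,
#' `context`. One row per sampled frame; trajectories are identified by the
#' combination of `rodlet_id` and `end_label`.
#'
#' @param trajs A single `end_trajectory` or a list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "end_trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    data.frame(time_s = tr$times, position_nm = tr$positions,
               rodlet_id = tr$rodlet_id, end_label = tr$end_label,
               category = tr$category, context = tr$context,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

trajectory_columns <- c("time_s", "position_nm", "rodlet_id", "end_label",
                        "category", "context")

#' Read end trajectories from a tab-separated file
#'
#' Reads the format written by [write_trajectories()], validates it, sorts
#' each trajectory by time and checks for uniform frame spacing.
#'
#' @param path Input file.
#' @param spacing_tol Relative tolerance on frame-interval uniformity.
#' @return A list of `end_trajectory` objects (without latent phases).
#' @export
read_trajectories <- function(path, spacing_tol = 1e-6) {
  if (!file.exists(path)) stop_rk("file not found: %s", class = "format", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(trajectory_columns, names(df))
  if (length(missing))
    stop_rk("missing column(s): %s", class = "format", paste(missing, collapse = ", "))
  for (col in c("time_s", "position_nm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad))
      stop_rk("malformed numeric value '%s' in column '%s' at line %d",
              class = "format", df[[col]][bad[1L]], col, bad[1L] + 1L)
    if (anyNA(v))
      stop_rk("missing value in column '%s' at line %d", class = "format", col,
              which(is.na(v))[1L] + 1L)
    df[[col]] <- v
  }
  key <- paste(df$rodlet_id, df$end_label, sep = "\r")
  lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, , drop = FALSE]
    sub <- sub[order(sub$time_s), , drop = FALSE]
    dt <- diff(sub$time_s)
    if (length(dt) < 2L)
      stop_rk("trajectory %s/%s has fewer than 3 samples", class = "format",
              sub$rodlet_id[1L], sub$end_label[1L])
    if (any(dt <= 0) || diff(range(dt)) > spacing_tol * dt[1L])
      stop_rk("trajectory %s/%s: nonuniform time spacing (row with time %g)",
              class = "format", sub$rodlet_id[1L], sub$end_label[1L],
              sub$time_s[which.max(abs(dt - dt[1L])) + 1L])
    structure(list(times = sub$time_s, positions = sub$position_nm,
                   latent = NULL, params = NULL,
                   rodlet_id = sub$rodlet_id[1L],
                   end_label = sub$end_label[1L],
                   category = sub$category[1L], context = sub$context[1L]),
              class = "end_trajectory")
  })
}

#' Write latent phases of a generated trajectory
#'
#' Companion TSV to [write_trajectories()] with columns `phase_kind`,
#' `start_s`, `duration_s`, `delta_nm`.
#'
#' @param traj An `end_trajectory` carrying latent phases.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_latent_phases <- function(traj, path) {
  if (is.null(traj$latent)) stop_rk("trajectory has no latent phases")
  out <- data.frame(phase_kind = traj$latent$kind,
                    start_s = traj$latent$start,
                    duration_s = traj$latent$duration,
                    delta_nm = traj$latent$delta)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a lattice orientation grid
#'
#' Grids are stored as headerless tab-separated integer matrices with values
#' in `{-1, 0, 1}`.
#'
#' @param path File path.
#' @return `read_lattice` returns an integer matrix; `write_lattice` returns
#'   `path` invisibly.
#' @export
read_lattice <- function(path) {
  if (!file.exists(path)) stop_rk("file not found: %s", class = "format", path)
  m <- as.matrix(read.delim(path, header = FALSE))
  dimnames(m) <- NULL
  if (!is.numeric(m) || anyNA(m) || any(m != round(m)))
    stop_rk("lattice file contains non-integer values", class = "format")
  m <- matrix(as.integer(m), nrow(m), ncol(m))
  if (!all(m %in% c(-1L, 0L, 1L)))
    stop_rk("lattice values must be in {-1, 0, 1} (found %d)", class = "format",
            m[which(!m %in% c(-1L, 0L, 1L))[1L]])
  m
}

#' @rdname read_lattice
#' @param grid Integer matrix with values in `{-1, 0, 1}` (or a
#'   `lattice_sim`).
#' @export
write_lattice <- function(grid, path) {
  if (inherits(grid, "lattice_sim")) grid <- grid$grid
  check_grid(grid)
  write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read or write a thioflavin-T curve
#'
#' TSV with columns `time_s` and `fluorescence_au`.
#'
#' @param curve A `tht_curve` or list with `times` and `fluorescence`.
#' @param path File path.
#' @return `read_tht_curve` returns a `tht_curve`; `write_tht_curve` returns
#'   `path` invisibly.
#' @export
write_tht_curve <- function(curve, path) {
  write.table(data.frame(time_s = curve$times,
                         fluorescence_au = curve$fluorescence),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tht_curve
#' @export
read_tht_curve <- function(path) {
  if (!file.exists(path)) stop_rk("file not found: %s", class = "format", path)
  df <- read.delim(path)
  if (!all(c("time_s", "fluorescence_au") %in% names(df)))
    stop_rk("expected columns time_s, fluorescence_au", class = "format")
  structure(list(times = df$time_s, fluorescence = df$fluorescence_au,
                 interface_on_at = NA, seeded = NA, M = NULL),
            class = "tht_curve")
}

#' Write a G2 correlation profile
#'
#' TSV with columns `r`, `G2`, `n_pairs`.
#'
#' @param profile A `g2_profile` from [angle_pair_correlation()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_g2 <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# write a reproducibility manifest next to a subcommand's outputs
write_manifest <- function(dir, subcommand, params, seed) {
  manifest <- list(package = "rodletkin",
                   version = as.character(packageVersion("rodletkin")),
                   subcommand = subcommand, seed = seed, parameters = params,
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
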