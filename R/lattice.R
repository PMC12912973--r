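#' Configuration for the lattice Monte Carlo simulator
#'
#' The simulator fills an `L x L` lattice whose cells are empty (0) or hold a
#' horizontal (+1) or vertical (-1) rodlet segment. Per step, one random
#' empty cell is selected and an insertion is attempted: the attempt passes a
#' probability gate (`P_ext` when an extension placement is geometrically
#' available, `P_other` when neighbours exist without an extension site,
#' `P_iso` when the cell is isolated, i.e. random nucleation), the
#' orientation is drawn from the two-state Boltzmann distribution of the
#' insertion energies (uniform when isolated), and the insertion is
#' Metropolis-accepted with probability `min(1, exp(-delta_E / kBT))`.
#' Insertions are irreversible; the run stops at `max_steps` or when the
#' lattice is full.
#'
#' @param L Lattice side, cells.
#' @param P_iso Attempt probability for an isolated cell (random nucleation).
#' @param P_ext Attempt probability when the placement can extend a
#'   neighbouring rodlet along its axis.
#' @param P_other Attempt probability next to neighbours without an
#'   extension site.
#' @param eps_elongation Depth (<= 0) of the end-to-end contact energy.
#' @param eps_lateral Depth (<= 0) of the side-by-side contact energy.
#' @param kBT Thermal energy.
#' @param max_steps Maximum number of attempted insertions.
#' @param seed Integer RNG seed or `NULL`.
#' @param snapshot_every Steps between stored grid snapshots (0 = none).
#' @param periodic Logical; wrap the lattice boundaries? Default `FALSE`
#'   (cells outside the lattice count as empty).
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(L = 100, P_iso = 0.005, P_ext = 0.1,
                           P_other = 0.005, eps_elongation = -1.0,
                           eps_lateral = -0.5, kBT = 0.1, max_steps = 1e6,
                           seed = NULL, snapshot_every = 0, periodic = FALSE) {
  check_number(L, "L", 2)
  check_number(P_iso, "P_iso", 0, 1)
  check_number(P_ext, "P_ext", 0, 1)
  check_number(P_other, "P_other", 0, 1)
  check_number(eps_elongation, "eps_elongation", upper = 0)
  check_number(eps_lateral, "eps_lateral", upper = 0)
  check_number(kBT, "kBT", 0, allow_lower = FALSE)
  check_number(max_steps, "max_steps", 1)
  check_number(snapshot_every, "snapshot_every", 0)
  check_flag(periodic, "periodic")
  structure(list(L = as.integer(L), P_iso = P_iso, P_ext = P_ext,
                 P_other = P_other, eps_elongation = eps_elongation,
                 eps_lateral = eps_lateral, kBT = kBT,
                 max_steps = max_steps, seed = check_seed(seed),
                 snapshot_every = as.integer(snapshot_every),
                 periodic = periodic),
            class = "lattice_config")
}

event_class_levels <- c("nucleation", "elongation_independent",
                        "elongation_surface_catalyzed", "lateral_attachment",
                        "misaligned")

check_grid <- function(grid) {
  if (!is.matrix(grid) || !all(grid %in% c(-1L, 0L, 1L)))
    stop_rk("'grid' must be an integer matrix with values in {-1, 0, 1}",
            class = "format")
  grid
}

#' Insertion energy and event classification for one cell
#'
#' Computes the total interaction energy of placing a rodlet of orientation
#' `v` into the empty cell `(i, j)` and classifies the placement. For each
#' occupied von Neumann neighbour with matching orientation, an end-to-end
#' (parallel to the rodlet axis) contact contributes `eps_elongation` and a
#' side-by-side contact `eps_lateral`; mismatched orientations contribute
#' nothing. Classes: `nucleation` (no occupied neighbour),
#' `elongation_independent` (elongation contact only),
#' `elongation_surface_catalyzed` (elongation and lateral contacts, energy
#' `eps_elongation + eps_lateral` per contact pair), `lateral_attachment`
#' (lateral only) and `misaligned` (occupied neighbours, no matching
#' orientation).
#'
#' @param grid Integer matrix with values in `{-1, 0, 1}`.
#' @param i,j Row and column (1-based) of the empty target cell.
#' @param orientation `+1` (horizontal) or `-1` (vertical).
#' @param eps_elongation,eps_lateral Contact energies (<= 0 in simulations;
#'   arbitrary values are accepted here for analysis).
#' @param periodic Logical; wrap boundaries.
#' @return List with `delta_E` and `classification`.
#' @export
interaction_energy <- function(grid, i, j, orientation,
                               eps_elongation = -1.0, eps_lateral = -0.5,
                               periodic = FALSE) {
  check_grid(grid)
  if (!orientation %in% c(-1, 1)) stop_rk("'orientation' must be -1 or +1")
  L1 <- nrow(grid); L2 <- ncol(grid)
  if (i < 1 || i > L1 || j < 1 || j > L2) stop_rk("cell (%d, %d) outside grid", i, j)
  if (grid[i, j] != 0) stop_rk("target cell (%d, %d) is occupied", i, j)
  di <- c(0, 0, 1, -1); dj <- c(1, -1, 0, 0)
  dE <- 0; ne <- 0L; nl <- 0L; nocc <- 0L
  for (t in 1:4) {
    ii <- i + di[t]; jj <- j + dj[t]
    if (periodic) {
      ii <- (ii - 1) %% L1 + 1; jj <- (jj - 1) %% L2 + 1
    } else if (ii < 1 || ii > L1 || jj < 1 || jj > L2) next
    w <- grid[ii, jj]
    if (w == 0) next
    nocc <- nocc + 1L
    if (w != orientation) next
    # joint vector b = (j - jj, i - ii); +1 is the (1, 0) axis, -1 the (0, 1) axis
    parallel <- if (orientation == 1) ii == i else jj == j
    if (parallel) { dE <- dE + eps_elongation; ne <- ne + 1L }
    else { dE <- dE + eps_lateral; nl <- nl + 1L }
  }
  cls <- if (nocc == 0L) "nucleation"
  else if (ne > 0L && nl > 0L) "elongation_surface_catalyzed"
  else if (ne > 0L) "elongation_independent"
  else if (nl > 0L) "lateral_attachment"
  else "misaligned"
  list(delta_E = dE, classification = cls)
}

#' Boltzmann choice of orientation for an insertion
#'
#' With no occupied neighbour the orientation is uniform on `{-1, +1}`;
#' otherwise `+1` is chosen with probability
#' `exp(-E(+1)/kBT) / (exp(-E(+1)/kBT) + exp(-E(-1)/kBT))`.
#'
#' @inheritParams interaction_energy
#' @param kBT Thermal energy.
#' @return `-1` or `+1`.
#' @export
choose_orientation <- function(grid, i, j, kBT = 0.1, eps_elongation = -1.0,
                               eps_lateral = -0.5, periodic = FALSE) {
  check_number(kBT, "kBT", 0, allow_lower = FALSE)
  ep <- interaction_energy(grid, i, j, 1, eps_elongation, eps_lateral, periodic)
  em <- interaction_energy(grid, i, j, -1, eps_elongation, eps_lateral, periodic)
  if (ep$classification == "nucleation")
    return(if (runif(1) < 0.5) -1 else 1)
  p_plus <- 1 / (1 + exp((ep$delta_E - em$delta_E) / kBT))
  if (runif(1) < p_plus) 1 else -1
}

#' Metropolis acceptance rule
#'
#' Accepts a move of energy change `delta_E` with probability
#' `min(1, exp(-delta_E / kBT))`.
#'
#' @param delta_E Energy change of the proposed move.
#' @param kBT Thermal energy (> 0).
#' @return `TRUE` or `FALSE`.
#' @export
metropolis_accept <- function(delta_E, kBT = 0.1) {
  check_number(delta_E, "delta_E")
  check_number(kBT, "kBT", 0, allow_lower = FALSE)
  if (delta_E <= 0) TRUE else runif(1) < exp(-delta_E / kBT)
}

assemble_sim <- function(res, config) {
  event_log <- data.frame(
    step = res$log_step, i = res$log_i, j = res$log_j,
    orientation = res$log_orientation,
    event_class = factor(event_class_levels[res$log_class],
                         levels = event_class_levels),
    delta_E = res$log_delta_E,
    accepted = res$log_accepted == 1L,
    stringsAsFactors = FALSE)
  snaps <- res$snapshots
  if (length(snaps)) names(snaps) <- paste0("step_", res$snapshot_steps)
  structure(list(grid = res$grid, step_count = res$step_count,
                 event_log = event_log, snapshots = snaps,
                 config = config),
            class = "lattice_sim")
}

#' Run the lattice Monte Carlo simulation
#'
#' Starts from an empty lattice and performs attempted insertions as
#' described in [lattice_config()] until the lattice is full or `max_steps`
#' is reached. Every gate-passing attempt is logged with its cell,
#' orientation, energy, classification and acceptance.
#'
#' @param config A [lattice_config()] object.
#' @return An object of class `lattice_sim`: list with the final `grid`,
#'   `step_count`, `event_log` (data frame), `snapshots` (list of grids) and
#'   the `config`.
#' @examples
#' sim <- run_simulation(lattice_config(L = 20, max_steps = 5e4, seed = 1))
#' mean(sim$grid != 0)  # occupancy
#' @export
run_simulation <- function(config) {
  if (!inherits(config, "lattice_config"))
    stop_rk("'config' must be created by lattice_config()")
  grid0 <- matrix(0L, config$L, config$L)
  res <- with_seed(config$seed,
    .lattice_run_cpp(grid0, config$P_iso, config$P_ext, config$P_other,
                     config$eps_elongation, config$eps_lateral, config$kBT,
                     config$max_steps, config$periodic, config$snapshot_every))
  assemble_sim(res, config)
}

#' @export
print.lattice_sim <- function(x, ...) {
  cat(sprintf("<lattice_sim> %dx%d, %d/%d cells filled after %.0f steps, %d logged attempts\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid != 0), length(x$grid),
              x$step_count, nrow(x$event_log)))
  invisible(x)
}

#' @export
plot.lattice_sim <- function(x, ...) {
  graphics::image(t(x$grid)[, nrow(x$grid):1, drop = FALSE],
                  col = c("#1f78b4", "grey95", "#e31a1c"),
                  zlim = c(-1, 1), axes = FALSE, asp = 1, ...)
  invisible(x)
}

#' Orientational angle pair correlation function
#'
#' `G2(r) = < cos 2(theta_i - theta_j) >` over all pairs of occupied cells
#' whose Euclidean distance falls in the bin centred at `r`, with `theta = 0`
#' for horizontal (+1) and `90` degrees for vertical (-1) rodlets, so each
#' pair contributes +1 when aligned and -1 when orthogonal. `G2 = 1` is a
#' perfectly ordered structure, `G2 = 0` a random one.
#'
#' @param grid Integer orientation matrix (or a `lattice_sim`).
#' @param max_r Largest pair distance considered (lattice units).
#' @param bin_width Width of the distance bins; pairs are assigned to the
#'   nearest bin centre `k * bin_width`.
#' @return A data frame of class `g2_profile` with columns `r`, `G2` and
#'   `n_pairs` (`G2` is `NA` for empty bins).
#' @export
angle_pair_correlation <- function(grid, max_r = 30, bin_width = 1) {
  if (inherits(grid, "lattice_sim")) grid <- grid$grid
  check_grid(grid)
  check_number(max_r, "max_r", 1)
  check_number(bin_width, "bin_width", 0, allow_lower = FALSE)
  if (sum(grid != 0) < 2L)
    stop_rk("G2 undefined: fewer than 2 occupied cells", class = "degenerate")
  L1 <- nrow(grid); L2 <- ncol(grid)
  nb <- as.integer(ceiling(max_r / bin_width))
  sums <- numeric(nb); cnts <- numeric(nb)
  md <- floor(max_r + bin_width / 2)
  for (dx in 0:min(md, L2 - 1L)) {
    dy_range <- if (dx == 0) seq_len(min(md, L1 - 1L))
                else seq.int(-min(md, L1 - 1L), min(md, L1 - 1L))
    for (dy in dy_range) {
      b <- as.integer(round(sqrt(dx^2 + dy^2) / bin_width))
      if (b < 1L || b > nb) next
      ri <- seq_len(L1 - abs(dy)); rj <- seq_len(L2 - dx)
      if (dy >= 0) {
        A <- grid[ri, rj, drop = FALSE]
        B <- grid[ri + dy, rj + dx, drop = FALSE]
      } else {
        A <- grid[ri - dy, rj, drop = FALSE]
        B <- grid[ri, rj + dx, drop = FALSE]
      }
      m <- A != 0L & B != 0L
      sums[b] <- sums[b] + sum(A[m] * B[m])
      cnts[b] <- cnts[b] + sum(m)
    }
  }
  out <- data.frame(r = seq_len(nb) * bin_width,
                    G2 = ifelse(cnts > 0, sums / cnts, NA_real_),
                    n_pairs = cnts)
  class(out) <- c("g2_profile", "data.frame")
  out
}

#' Tally accepted insertion events by class
#'
#' @param x A `lattice_sim` or its `event_log` data frame.
#' @return List with `n_nucleation`, `n_independent`, `n_surface_catalyzed`,
#'   `n_lateral` and `n_misaligned` (accepted events only).
#' @export
count_elongation_events <- function(x) {
  log <- if (inherits(x, "lattice_sim")) x$event_log else x
  if (!is.data.frame(log) || !all(c("event_class", "accepted") %in% names(log)))
    stop_rk("'x' must be a lattice_sim or an event-log data frame", class = "format")
  acc <- log[log$accepted, , drop = FALSE]
  tb <- table(factor(acc$event_class, levels = event_class_levels))
  list(n_nucleation = unname(tb[["nucleation"]]),
       n_independent = unname(tb[["elongation_independent"]]),
       n_surface_catalyzed = unname(tb[["elongation_surface_catalyzed"]]),
       n_lateral = unname(tb[["lateral_attachment"]]),
       n_misaligned = unname(tb[["misaligned"]]))
}

#' Simplified tip-elongation experiment
#'
#' Reproduces the simplified system probing surface-catalyzed elongation:
#' `n_long` long horizontal rodlets (length `long_len`) are laid out at equal
#' vertical intervals; each gets a short rodlet (length `short_len`) in
#' lateral contact ("bundled" tips) and, in a separate empty lane, an
#' isolated short rodlet of the same length ("single" tips). Random
#' nucleation is turned off (`P_iso = 0`), so growth occurs only by extension
#' at tips and by lateral attachment alongside existing rodlets; a bundled
#' rodlet's lane runs along the flank of a long rodlet, so it also grows by
#' surface-catalyzed deposition, whereas a single rodlet can only extend at
#' its tips.
#'
#' The length of each tracked rodlet is the maximal contiguous run of
#' correctly oriented cells through its seed; its elongation increment per
#' simulation step is `(final length - initial length) / steps`.
#'
#' @param config A [lattice_config()]; `P_iso` is forced to 0. The default
#'   `max_steps = 1e6` is more than needed; 2e5 is typical here.
#' @param n_long Number of long rodlets (default 10).
#' @param long_len Length of the long rodlets (default 100 = full row at the
#'   default `L`).
#' @param short_len Length of the tracked short rodlets (default 2).
#' @param seed Integer RNG seed overriding `config$seed` if given.
#' @return List of class `tip_experiment` with `tips` (data frame: `tip_id`,
#'   `type`, `row`, `initial_length`, `final_length`, `increment_per_step`),
#'   `mean_increment` (named vector, bundled/single), `sim` (the underlying
#'   `lattice_sim`) and `step_count`.
#' @export
run_tip_experiment <- function(config = lattice_config(), n_long = 10,
                               long_len = 100, short_len = 2, seed = NULL) {
  if (!inherits(config, "lattice_config"))
    stop_rk("'config' must be created by lattice_config()")
  check_number(n_long, "n_long", 1)
  check_number(long_len, "long_len", 1)
  check_number(short_len, "short_len", 1)
  L <- config$L
  block <- L %/% n_long
  if (block < 8L)
    stop_rk("layout does not fit: need at least 8 rows per long rodlet (L = %d, n_long = %d)",
            L, n_long)
  if (long_len > L || short_len > L) stop_rk("rodlet length exceeds lattice side")
  grid0 <- matrix(0L, L, L)
  tips <- NULL
  for (k in seq_len(n_long)) {
    b <- (k - 1L) * block
    r_long <- b + 3L
    grid0[r_long, seq_len(long_len)] <- 1L
    r_bun <- r_long + 1L
    grid0[r_bun, seq_len(short_len)] <- 1L
    r_sin <- b + 8L
    grid0[r_sin, seq_len(short_len)] <- 1L
    tips <- rbind(tips,
                  data.frame(tip_id = sprintf("bundled_%d", k), type = "bundled",
                             row = r_bun, stringsAsFactors = FALSE),
                  data.frame(tip_id = sprintf("single_%d", k), type = "single",
                             row = r_sin, stringsAsFactors = FALSE))
  }
  res <- with_seed(check_seed(seed) %||% config$seed,
    .lattice_run_cpp(grid0, 0, config$P_ext, config$P_other,
                     config$eps_elongation, config$eps_lateral, config$kBT,
                     config$max_steps, config$periodic, config$snapshot_every))
  sim <- assemble_sim(res, config)
  run_len <- function(grid, row) {
    v <- grid[row, ] == 1L
    r <- rle(v)
    ends <- cumsum(r$lengths); starts <- c(1L, head(ends, -1L) + 1L)
    hit <- which(r$values & starts <= 1L)  # run through the seed at column 1
    if (length(hit)) r$lengths[hit[1L]] else 0L
  }
  tips$initial_length <- vapply(tips$row, function(r) run_len(grid0, r), 0L)
  tips$final_length <- vapply(tips$row, function(r) run_len(sim$grid, r), 0L)
  tips$increment_per_step <-
    (tips$final_length - tips$initial_length) / sim$step_count
  mi <- tapply(tips$increment_per_step, tips$type, mean)
  structure(list(tips = tips, mean_increment = mi, sim = sim,
                 step_count = sim$step_count),
            class = "tip_experiment")
}
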