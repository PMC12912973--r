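# Independent oracles used across the suite. These re-derive expected values
# by brute force or closed form, on code paths separate from the package
# implementation.

# --- lattice -----------------------------------------------------------------

# independent energy/classification: enumerate neighbours explicitly
oracle_energy <- function(grid, i, j, v, eps_e, eps_l, periodic = FALSE) {
  L1 <- nrow(grid); L2 <- ncol(grid)
  offs <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  dE <- 0; n_e <- 0; n_l <- 0; n_occ <- 0
  for (o in offs) {
    ii <- i + o[1]; jj <- j + o[2]
    b <- c(-o[2], -o[1])                 # (x, y) joint vector as printed,
    if (periodic) {                      # taken before any boundary wrap
      ii <- (ii - 1) %% L1 + 1; jj <- (jj - 1) %% L2 + 1
    } else if (ii < 1 || ii > L1 || jj < 1 || jj > L2) next
    w <- grid[ii, jj]
    if (w == 0) next
    n_occ <- n_occ + 1
    if (w != v) next
    vaxis <- if (v == 1) c(1, 0) else c(0, 1)
    if (abs(sum(b * vaxis)) == 1) { dE <- dE + eps_e; n_e <- n_e + 1 }
    else { dE <- dE + eps_l; n_l <- n_l + 1 }
  }
  cls <- if (n_occ == 0) "nucleation"
  else if (n_e > 0 && n_l > 0) "elongation_surface_catalyzed"
  else if (n_e > 0) "elongation_independent"
  else if (n_l > 0) "lateral_attachment"
  else "misaligned"
  list(delta_E = dE, classification = cls)
}

oracle_ext_avail <- function(grid, i, j, periodic = FALSE) {
  L1 <- nrow(grid); L2 <- ncol(grid)
  for (o in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
    ii <- i + o[1]; jj <- j + o[2]
    b <- c(-o[2], -o[1])
    if (periodic) {
      ii <- (ii - 1) %% L1 + 1; jj <- (jj - 1) %% L2 + 1
    } else if (ii < 1 || ii > L1 || jj < 1 || jj > L2) next
    w <- grid[ii, jj]
    if (w == 0) next
    waxis <- if (w == 1) c(1, 0) else c(0, 1)
    if (abs(sum(b * waxis)) == 1) return(TRUE)
  }
  FALSE
}

# pure-R replay of the simulator, drawing from R's RNG in the same order as
# the compiled stepper (cell, gate, orientation, Metropolis-only-if-dE>0)
oracle_lattice_run <- function(grid, P_iso, P_ext, P_other, eps_e, eps_l,
                               kBT, max_steps, periodic = FALSE) {
  L1 <- nrow(grid); L2 <- ncol(grid)
  empties <- which(grid == 0)
  log <- list()
  step <- 0
  while (step < max_steps && length(empties) > 0) {
    step <- step + 1
    k <- min(floor(runif(1) * length(empties)) + 1, length(empties))
    id <- empties[k]
    i <- (id - 1) %% L1 + 1; j <- (id - 1) %/% L1 + 1
    en_p <- oracle_energy(grid, i, j, 1, eps_e, eps_l, periodic)
    has_nb <- en_p$classification != "nucleation"
    pgate <- if (!has_nb) P_iso
             else if (oracle_ext_avail(grid, i, j, periodic)) P_ext else P_other
    if (pgate <= 0) next
    if (pgate < 1 && runif(1) >= pgate) next
    if (!has_nb) {
      v <- if (runif(1) < 0.5) -1L else 1L
    } else {
      en_m <- oracle_energy(grid, i, j, -1, eps_e, eps_l, periodic)
      p_plus <- 1 / (1 + exp((en_p$delta_E - en_m$delta_E) / kBT))
      v <- if (runif(1) < p_plus) 1L else -1L
    }
    en <- oracle_energy(grid, i, j, v, eps_e, eps_l, periodic)
    acc <- if (en$delta_E > 0) runif(1) < exp(-en$delta_E / kBT) else TRUE
    log[[length(log) + 1]] <- data.frame(
      step = step, i = i, j = j, orientation = v,
      event_class = en$classification, delta_E = en$delta_E, accepted = acc,
      stringsAsFactors = FALSE)
    if (acc) {
      grid[i, j] <- v
      empties[k] <- empties[length(empties)]
      empties <- empties[-length(empties)]
    }
  }
  list(grid = grid, step_count = step,
       event_log = if (length(log)) do.call(rbind, log) else NULL)
}

# brute-force pair loop for G2
oracle_g2 <- function(grid, max_r, bin_width = 1) {
  occ <- which(grid != 0, arr.ind = TRUE)
  s <- grid[occ]
  nb <- ceiling(max_r / bin_width)
  sums <- numeric(nb); cnts <- numeric(nb)
  n <- nrow(occ)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    d <- sqrt(sum((occ[a, ] - occ[b, ])^2))
    k <- round(d / bin_width)
    if (k < 1 || k > nb) next
    sums[k] <- sums[k] + s[a] * s[b]
    cnts[k] <- cnts[k] + 1
  }
  data.frame(r = seq_len(nb) * bin_width,
             G2 = ifelse(cnts > 0, sums / cnts, NA), n_pairs = cnts)
}

# --- kinetics ----------------------------------------------------------------

# build an end_trajectory directly from an explicit phase table
traj_from_phases <- function(kind, duration, delta, frame_interval = 12.75,
                             noise_sigma = 0) {
  start <- cumsum(c(0, duration[-length(duration)]))
  latent <- data.frame(kind = kind, start = start, duration = duration,
                       delta = delta, stringsAsFactors = FALSE)
  total <- sum(duration)
  times <- seq(0, total, by = frame_interval)
  cumdelta <- cumsum(c(0, delta))
  idx <- findInterval(times, start)
  frac <- pmin((times - start[idx]) / duration[idx], 1)
  pos <- cumdelta[idx] + delta[idx] * frac
  if (noise_sigma > 0) pos <- pos + rnorm(length(pos), 0, noise_sigma)
  structure(list(times = times, positions = pos, latent = latent,
                 params = NULL, rodlet_id = "manual", end_label = "unassigned",
                 category = "preexisting", context = "single"),
            class = "end_trajectory")
}

# permutation distribution of the Brunner-Munzel statistic
oracle_bm_permutation_p <- function(x, y, n_perm = 1e5) {
  obs <- abs(brunner_munzel(x, y)$statistic)
  z <- c(x, y); n1 <- length(x)
  hits <- 0
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(z), n1)
    st <- brunner_munzel(z[idx], z[-idx])$statistic
    if (abs(st) >= obs - 1e-12) hits <- hits + 1
  }
  hits / n_perm
}

# --- dock-lock ---------------------------------------------------------------

# linearized (m << K_M) closed form
oracle_docklock_linear <- function(kappa, m_total, M0, times) {
  m_total - (m_total - M0) * exp(-kappa * (times - times[1]))
}
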