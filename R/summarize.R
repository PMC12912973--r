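#' Assign fast/slow end labels within each rodlet
#'
#' For every rodlet with two or more tracked ends, the end with the larger
#' apparent elongation rate is labelled `"fast"` and the other `"slow"`
#' (ties broken by position in the list). Rodlets with a single end keep
#' their label.
#'
#' @param trajs List of `end_trajectory` objects.
#' @param threshold_nm,min_frames Passed to [detect_phases()].
#' @return The list with updated `end_label` fields.
#' @export
assign_end_labels <- function(trajs, threshold_nm = 0.6, min_frames = 1) {
  ids <- vapply(trajs, `[[`, "", "rodlet_id")
  rates <- vapply(trajs, function(tr) {
    tryCatch(apparent_elongation_rate(detect_phases(tr, threshold_nm, min_frames)),
             rodletkin_no_steps = function(e) NA_real_)
  }, 0)
  for (id in unique(ids)) {
    k <- which(ids == id)
    if (length(k) < 2L) next
    fast <- k[which.max(rates[k])]
    for (j in k) trajs[[j]]$end_label <- if (j == fast) "fast" else "slow"
  }
  trajs
}

#' Per-group kinetic summary table
#'
#' Runs the full per-end pipeline (segmentation, exponential fits, rates) for
#' every group of trajectories and assembles one row per group: number of
#' ends, mean/SE apparent elongation rate, MLE means of dwell time, step time
#' and step size (censored phases excluded), mean/SE within-step rate, the
#' state rate constants `k_open = 1/tau_dwell` and `k_close = 1/tau_step`,
#' and the equilibrium constant `K_d = tau_dwell/tau_step`.
#'
#' @param trajs List of `end_trajectory` objects (at least one per group).
#' @param group_by Field to group on: `"category"`, `"context"` or
#'   `"end_label"`.
#' @param threshold_nm,min_frames Passed to [detect_phases()].
#' @return A data frame with one row per group.
#' @export
summarize_group <- function(trajs, group_by = c("category", "context", "end_label"),
                            threshold_nm = 0.6, min_frames = 1) {
  group_by <- match.arg(group_by)
  if (!is.list(trajs) || length(trajs) == 0L)
    stop_rk("'trajs' must be a non-empty list of end trajectories")
  groups <- vapply(trajs, `[[`, "", group_by)
  out <- lapply(unique(groups), function(g) {
    sub <- trajs[groups == g]
    evs <- lapply(sub, detect_phases, threshold_nm = threshold_nm,
                  min_frames = min_frames)
    dwell <- unlist(lapply(evs, function(e) uncensored(e, "dwell")$duration))
    stepd <- unlist(lapply(evs, function(e) uncensored(e, "step")$duration))
    sizes <- unlist(lapply(evs, function(e) uncensored(e, "step")$delta))
    srates <- unlist(lapply(evs, function(e) {
      st <- uncensored(e, "step"); st$delta / st$duration * 60
    }))
    arates <- vapply(evs, function(e) {
      tryCatch(apparent_elongation_rate(e),
               rodletkin_no_steps = function(cnd) NA_real_)
    }, 0)
    arates <- arates[is.finite(arates)]
    tau_d <- if (length(dwell) >= 2L) fit_exponential(dwell)$tau else NA_real_
    tau_s <- if (length(stepd) >= 2L) fit_exponential(stepd)$tau else NA_real_
    msz <- if (length(sizes) >= 2L) fit_exponential(sizes)$tau else NA_real_
    data.frame(
      group = g, n_ends = length(sub),
      apparent_rate = mean(arates),
      apparent_rate_se = if (length(arates) > 1L) sd(arates) / sqrt(length(arates)) else 0,
      tau_dwell = tau_d, tau_step = tau_s, mean_step_size = msz,
      step_rate_mean = mean(srates),
      step_rate_se = if (length(srates) > 1L) sd(srates) / sqrt(length(srates)) else 0,
      k_open = 1 / tau_d, k_close = 1 / tau_s,
      K_d = if (is.finite(tau_d) && is.finite(tau_s))
        equilibrium_constant(tau_d, tau_s) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
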