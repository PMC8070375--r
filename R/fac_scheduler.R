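#' Timing model for the imaging + classification schedule
#'
#' Describes the per-frame timing of a mobile imaging pipeline: the probe
#' streams each frame's IQ data to the device over `t_transfer` ms, the
#' image rendering pipeline (IRP) reconstructs and displays it in `t_irp`
#' ms, and an optional classification pipeline (CP) of non-preemptive
#' per-layer GPU tasks takes `layer_times` ms each.  Because `t_irp` is
#' short relative to `t_transfer`, each frame leaves an idle window of
#' `t_transfer - t_irp` ms on the GPU.
#'
#' @param t_transfer Per-frame data transfer period, ms (> 0).
#' @param t_irp Image-rendering-pipeline time per frame, ms (> 0).
#' @param layer_times Numeric vector of per-layer classification times, ms
#'   (all > 0); empty for an imaging-only pipeline.
#' @param jitter Optional per-task delay model: a list with `sd` (ms) and
#'   `seed`; each task gains an independent truncated-normal (at 0) delay.
#' @return An object of class `timing_model`.
#' @examples
#' timing_model(t_transfer = 25, t_irp = 4, layer_times = c(20, 20, 20))
#' @export
timing_model <- function(t_transfer, t_irp, layer_times = numeric(0),
                         jitter = NULL) {
  stopifnot(t_transfer > 0, t_irp > 0, all(layer_times > 0))
  if (!is.null(jitter))
    stopifnot(is.list(jitter), jitter$sd >= 0, is.numeric(jitter$seed))
  structure(list(t_transfer = as.numeric(t_transfer),
                 t_irp = as.numeric(t_irp),
                 layer_times = as.numeric(layer_times), jitter = jitter),
            class = "timing_model")
}

#' Split a classification pipeline into sub-pipelines for idle windows
#'
#' Greedy order-preserving packing: consecutive layers accumulate into a
#' sub-classification pipeline (sCP) while the running total stays within
#' `idle_budget`; the next layer then opens a new sCP.  Layer tasks are
#' non-preemptive, so a single layer longer than the budget cannot be cut —
#' it forms its own sCP, flagged as overrunning.  Greedy first-fit on an
#' ordered list uses the minimum possible number of contiguous sub-pipelines
#' under the budget.
#'
#' @param layer_times Numeric vector of per-layer times (ms), non-empty.
#' @param idle_budget Idle window length (ms, > 0) each sCP must fit.
#' @return A list of class `scp_split`: `scps` (list of numeric vectors
#'   whose concatenation is `layer_times`), `overrun` (logical per sCP),
#'   `m` (number of sCPs).
#' @examples
#' split_pipeline(c(5, 5, 5, 5), idle_budget = 10)
#' @export
split_pipeline <- function(layer_times, idle_budget) {
  if (length(layer_times) == 0) stop("layer_times must be non-empty")
  stopifnot(idle_budget > 0, all(layer_times > 0))
  scps <- list(); cur <- numeric(0)
  for (lt in layer_times) {
    if (length(cur) > 0 && sum(cur) + lt > idle_budget) {
      scps[[length(scps) + 1L]] <- cur
      cur <- numeric(0)
    }
    cur <- c(cur, lt)
    if (lt > idle_budget) {           # non-splittable overrunning layer
      scps[[length(scps) + 1L]] <- cur
      cur <- numeric(0)
    }
  }
  if (length(cur) > 0) scps[[length(scps) + 1L]] <- cur
  structure(list(scps = scps,
                 overrun = vapply(scps, function(s) sum(s) > idle_budget,
                                  logical(1)),
                 m = length(scps)),
            class = "scp_split")
}

task_jitter <- function(n, jitter) {
  if (is.null(jitter) || jitter$sd == 0) return(numeric(n))
  abs(stats::rnorm(n, 0, jitter$sd))
}

new_schedule_result <- function(display_times, classification_times, m,
                                overruns, structure_name, eq4 = NA_real_) {
  n <- length(display_times)
  f_image <- if (n >= 2)
    1000 * (n - 1) / (display_times[n] - display_times[1]) else NA_real_
  nc <- length(classification_times)
  f_cp <- if (nc >= 2)
    1000 * (nc - 1) /
      (classification_times[nc] - classification_times[1])
  else if (nc == 1 && n >= 2)
    f_image / m                       # single completion: nominal rate
  else NA_real_
  structure(list(structure = structure_name,
                 display_times = display_times,
                 classification_times = classification_times,
                 f_image = f_image, f_cp = f_cp, m = m,
                 overruns = overruns, eq4_residual = eq4),
            class = "schedule_result")
}

#' @export
print.schedule_result <- function(x, ...) {
  cat(sprintf("<schedule_result> %s: %d frames, %d classifications\n",
              x$structure, length(x$display_times),
              length(x$classification_times)))
  cat(sprintf("  f_image = %.2f fps, f_cp = %.2f cps, M = %d, overruns = %d\n",
              x$f_image, x$f_cp, x$m, x$overruns))
  invisible(x)
}

#' Simulate the frame-synchronous classification (FSC) schedule
#'
#' Discrete-event simulation of the structure in which every frame's entire
#' classification pipeline runs after its rendering, before the next frame
#' can be processed: frame k's IQ data is available at `k * t_transfer`; the
#' GPU then runs IRP (display) followed by all CP layers.  The steady-state
#' frame period is `max(t_transfer, t_irp + sum(layer_times))`, and exactly
#' one classification completes per frame (`f_cp == f_image`).  With an
#' empty layer list this degenerates to plain imaging.
#'
#' @param model A [timing_model()].
#' @param n_frames Number of frames to simulate, >= 1.
#' @return A `schedule_result` with display/classification timestamps (ms)
#'   and measured mean rates (fps / cps).
#' @export
simulate_fsc <- function(model, n_frames) {
  stopifnot(inherits(model, "timing_model"), n_frames >= 1)
  run <- function() {
    gpu_free <- 0
    disp <- numeric(n_frames); cls <- numeric(0)
    has_cp <- length(model$layer_times) > 0
    for (k in seq_len(n_frames)) {
      arrival <- k * model$t_transfer
      start <- max(arrival, gpu_free)
      disp[k] <- start + model$t_irp + sum(task_jitter(1, model$jitter))
      gpu_free <- disp[k]
      if (has_cp) {
        gpu_free <- gpu_free + sum(model$layer_times) +
          sum(task_jitter(length(model$layer_times), model$jitter))
        cls <- c(cls, gpu_free)
      }
    }
    new_schedule_result(disp, cls, m = 1L, overruns = 0L,
                        structure_name = "fsc")
  }
  if (!is.null(model$jitter)) with_local_seed(model$jitter$seed, run())
  else run()
}

#' Simulate the frame-asynchronous classification (FAC) schedule
#'
#' The classification pipeline is first split by [split_pipeline()] into
#' sub-pipelines sized for the per-frame idle window
#' (`t_transfer - t_irp`), then the simulation interleaves exactly one sCP
#' into each window: after frame k's IRP the next sCP in order runs; a
#' classification completes when its last sCP finishes, so one result spans
#' `M` frames.  When no sCP overruns its window, imaging is unimpeded
#' (`f_image = 1000 / t_transfer`) and the schedule satisfies
#' `f_image ~= M * f_cp`; the result reports the measured relative residual
#' of that relation.
#'
#' @inheritParams simulate_fsc
#' @return A `schedule_result`; `$m` is the number of sub-pipelines,
#'   `$overruns` the count of frames whose start was delayed by an
#'   overrunning sCP, `$eq4_residual` the relative frame-rate /
#'   classification-rate mismatch `|f_image - M * f_cp| / f_image`.
#' @export
simulate_fac <- function(model, n_frames) {
  stopifnot(inherits(model, "timing_model"), n_frames >= 1)
  idle <- model$t_transfer - model$t_irp
  if (idle <= 0) {
    stop(errorCondition(
      "no idle window: t_irp >= t_transfer",
      class = c("usrsc_no_idle_window_error", "usrsc_error")))
  }
  has_cp <- length(model$layer_times) > 0
  split <- if (has_cp) split_pipeline(model$layer_times, idle) else NULL
  m <- if (has_cp) split$m else 1L
  run <- function() {
    gpu_free <- 0; scp_i <- 1L; overruns <- 0L
    disp <- numeric(n_frames); cls <- numeric(0)
    for (k in seq_len(n_frames)) {
      arrival <- k * model$t_transfer
      if (gpu_free > arrival) overruns <- overruns + 1L
      start <- max(arrival, gpu_free)
      disp[k] <- start + model$t_irp + sum(task_jitter(1, model$jitter))
      gpu_free <- disp[k]
      if (has_cp) {
        sc <- split$scps[[scp_i]]
        gpu_free <- gpu_free + sum(sc) +
          sum(task_jitter(length(sc), model$jitter))
        if (scp_i == split$m) {
          cls <- c(cls, gpu_free)
          scp_i <- 1L
        } else scp_i <- scp_i + 1L
      }
    }
    res <- new_schedule_result(disp, cls, m = m, overruns = overruns,
                               structure_name = "fac")
    if (is.finite(res$f_image) && is.finite(res$f_cp) && res$f_image > 0)
      res$eq4_residual <- abs(res$f_image - m * res$f_cp) / res$f_image
    res
  }
  if (!is.null(model$jitter)) with_local_seed(model$jitter$seed, run())
  else run()
}
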