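#' Build an intervention schedule
#'
#' A schedule is a list of hold episodes. Each episode names a variable, a
#' half-open tick range `[start, end)` (0-based ticks) and the values the
#' variable is held at: a single number (constant hold) or a numeric vector of
#' length `end - start` (e.g. a drag/ramp). Episodes on the same variable must
#' not overlap; by default at most one variable may be intervened on per tick,
#' mirroring the one-at-a-time constraint of slider experiments.
#'
#' @param episodes List of episodes, each a list with elements `variable`,
#'   `start`, `end`, `values`.
#' @param one_at_a_time Enforce that no two episodes (on any variables)
#'   overlap in time. Default `TRUE`.
#' @return Object of class `intervention_schedule`.
#' @examples
#' sch <- intervention_schedule(list(
#'   list(variable = "X", start = 10, end = 40, values = 100),
#'   list(variable = "Y", start = 50, end = 80, values = -100)
#' ))
#' @export
intervention_schedule <- function(episodes = list(), one_at_a_time = TRUE) {
  for (ep in episodes) {
    if (!all(c("variable", "start", "end", "values") %in% names(ep))) {
      stop_contract("each episode needs variable, start, end, values")
    }
    if (ep$start < 0 || ep$end <= ep$start) {
      stop_contract("episode ticks must satisfy 0 <= start < end")
    }
    len <- ep$end - ep$start
    if (!length(ep$values) %in% c(1L, len)) {
      stop_contract("episode values must have length 1 or end - start")
    }
  }
  # per-variable overlap is always forbidden; global overlap optionally
  check_overlap <- function(eps, what) {
    if (length(eps) < 2L) return(invisible())
    ord <- order(vapply(eps, `[[`, 0, "start"))
    eps <- eps[ord]
    for (k in seq_len(length(eps) - 1L)) {
      if (eps[[k + 1L]]$start < eps[[k]]$end) {
        stop_contract("overlapping episodes ", what)
      }
    }
  }
  if (one_at_a_time) {
    check_overlap(episodes, "(one-at-a-time constraint)")
  } else {
    for (v in unique(vapply(episodes, `[[`, "", "variable"))) {
      check_overlap(Filter(function(e) e$variable == v, episodes),
                    paste0("on variable ", v))
    }
  }
  structure(list(episodes = episodes, one_at_a_time = one_at_a_time),
            class = "intervention_schedule")
}

#' @export
print.intervention_schedule <- function(x, ...) {
  cat("intervention_schedule: ", length(x$episodes), " episode(s)\n", sep = "")
  for (ep in x$episodes) {
    cat(sprintf("  %s [%d, %d) %s\n", ep$variable, ep$start, ep$end,
                if (length(ep$values) == 1L) paste0("held at ", ep$values)
                else "ramped"))
  }
  invisible(x)
}

# T x n matrix of scheduled values; NA where the variable is free.
schedule_values <- function(schedule, ticks, variables) {
  held <- matrix(NA_real_, ticks, length(variables),
                 dimnames = list(NULL, variables))
  if (is.null(schedule)) return(held)
  for (ep in schedule$episodes) {
    i <- match(ep$variable, variables)
    if (is.na(i)) stop_contract("schedule names unknown variable ", ep$variable)
    if (ep$end > ticks) stop_contract("episode extends past the trial length")
    rows <- (ep$start + 1L):ep$end # ticks are 0-based, rows 1-based
    held[rows, i] <- rep_len(as.numeric(ep$values), length(rows))
  }
  held
}

#' Intervention mask implied by a schedule
#'
#' @param schedule An [intervention_schedule()].
#' @param ticks Trial length T.
#' @param variables Variable names.
#' @return T x n 0/1 matrix.
#' @export
schedule_mask <- function(schedule, ticks, variables) {
  (!is.na(schedule_values(schedule, ticks, variables))) * 1L
}
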