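# Cohort-level statistics: pattern frequency time courses, the log2
# central/invagination ratio, cumulative off-interface lamellae and
# condition comparisons.

#' Per-timepoint pattern frequencies of a cohort
#'
#' Counts couples per (aligned time, pattern) and converts to percentages
#' with binomial standard errors. An additional `"any"` row per timepoint
#' gives the percentage of couples with accumulation in any pattern
#' (100 x (n_total - n_none) / n_total).
#'
#' @param timelines data.frame with columns `couple_id`, `time_rel_s`,
#'   `pattern` (and optionally `condition`).
#' @param condition condition label for the output (defaults to the one in
#'   `timelines`).
#' @param se_mode `"binomial"` (default): binomial standard error pooling all
#'   couples; `"experiment"`: SEM across per-experiment percentages (requires
#'   an `experiment` column).
#' @return data.frame (class `cohort_table`) with columns `condition`,
#'   `time_rel_s`, `pattern`, `n_total`, `count`, `percent`, `se`.
#' @export
pattern_frequencies <- function(timelines, condition = NULL,
                                se_mode = c("binomial", "experiment")) {
  se_mode <- match.arg(se_mode)
  if (se_mode == "experiment" && !"experiment" %in% names(timelines))
    stop("se_mode = 'experiment' requires an 'experiment' column")
  stopifnot(all(c("time_rel_s", "pattern") %in% names(timelines)))
  timelines$pattern <- normalize_pattern(timelines$pattern)
  if (is.null(condition))
    condition <- if ("condition" %in% names(timelines))
      timelines$condition[1] else "cohort"
  times <- sort(unique(timelines$time_rel_s))
  rows <- lapply(times, function(tt) {
    sub <- timelines[timelines$time_rel_s == tt, ]
    n <- nrow(sub)
    if (n == 0) return(NULL)
    cnt <- table(factor(sub$pattern, levels = PATTERNS))
    cnt <- c(cnt, any = n - as.integer(cnt["none"]))
    p <- as.numeric(cnt) / n
    se <- 100 * sqrt(p * (1 - p) / n)
    if (se_mode == "experiment") {
      exps <- unique(sub$experiment)
      per <- vapply(names(cnt), function(pat) {
        pc <- vapply(exps, function(e) {
          s2 <- sub[sub$experiment == e, ]
          if (pat == "any") 100 * mean(s2$pattern != "none")
          else 100 * mean(s2$pattern == pat)
        }, numeric(1))
        stats::sd(pc) / sqrt(length(pc))
      }, numeric(1))
      se <- as.numeric(per)
    }
    data.frame(condition = condition, time_rel_s = tt,
               pattern = names(cnt), n_total = n,
               count = as.integer(cnt), percent = 100 * p,
               se = se)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Log2 central/invagination ratio time course
#'
#' Per aligned timepoint, `log2((n_central + c) / (n_invagination + c))` with
#' the Haldane-Anscombe continuity constant `c = 0.5` couples. Values above 0
#' indicate preferential central accumulation.
#'
#' @param table a [pattern_frequencies()] result.
#' @param continuity continuity constant in couples.
#' @return data.frame with columns `condition`, `time_rel_s`, `log2_ratio`.
#' @export
central_invagination_ratio <- function(table, continuity = 0.5) {
  ce <- table[table$pattern == "central", ]
  iv <- table[table$pattern == "invagination", ]
  stopifnot(nrow(ce) > 0, nrow(iv) > 0)
  m <- merge(ce[c("condition", "time_rel_s", "count")],
             iv[c("time_rel_s", "count")],
             by = "time_rel_s", suffixes = c("_central", "_invagination"))
  data.frame(condition = m$condition, time_rel_s = m$time_rel_s,
             log2_ratio = log2((m$count_central + continuity) /
                                 (m$count_invagination + continuity)))
}

#' Cumulative off-interface lamella time course
#'
#' Percentage of couples having shown at least one off-interface lamella at
#' any time in (0, t] relative to tight coupling; non-decreasing in t.
#'
#' @param flags data.frame with columns `couple_id`, `time_rel_s`,
#'   `has_off_interface_lamella`.
#' @param grid aligned timepoints to evaluate (default the positive part of
#'   [alignment_grid()]).
#' @return data.frame with columns `time_rel_s`, `n_total`,
#'   `cumulative_percent`.
#' @export
cumulative_off_interface <- function(flags, grid = NULL) {
  stopifnot(all(c("couple_id", "time_rel_s", "has_off_interface_lamella")
                %in% names(flags)))
  if (is.null(grid)) grid <- alignment_grid()[alignment_grid() > 0]
  ids <- unique(flags$couple_id)
  n <- length(ids)
  first_flag <- vapply(ids, function(id) {
    tt <- flags$time_rel_s[flags$couple_id == id &
                             flags$has_off_interface_lamella &
                             flags$time_rel_s > 0]
    if (length(tt)) min(tt) else Inf
  }, numeric(1))
  data.frame(time_rel_s = grid,
             n_total = n,
             cumulative_percent = vapply(grid, function(tt)
               100 * sum(first_flag <= tt) / n, numeric(1)))
}

#' Compare pattern frequencies between two conditions
#'
#' Two-sided exact two-proportion test (Fisher) per timepoint and pattern,
#' with Holm adjustment within each pattern's time course.
#'
#' @param table_a,table_b [pattern_frequencies()] results on the same grid.
#' @param timepoints aligned times to test (default: those present in both).
#' @param patterns patterns to test (default: all plus `"any"`).
#' @return data.frame with columns `pattern`, `time_rel_s`, `p_raw`,
#'   `p_adjusted`.
#' @export
compare_conditions <- function(table_a, table_b, timepoints = NULL,
                               patterns = c(PATTERNS, "any")) {
  if (is.null(timepoints))
    timepoints <- intersect(unique(table_a$time_rel_s),
                            unique(table_b$time_rel_s))
  rows <- list()
  for (pat in patterns) {
    ps <- numeric(0); ts <- numeric(0)
    for (tt in timepoints) {
      a <- table_a[table_a$pattern == pat & table_a$time_rel_s == tt, ]
      b <- table_b[table_b$pattern == pat & table_b$time_rel_s == tt, ]
      if (!nrow(a) || !nrow(b) || a$n_total == 0 || b$n_total == 0) next
      m <- matrix(c(a$count, a$n_total - a$count,
                    b$count, b$n_total - b$count), 2, 2)
      ps <- c(ps, fisher.test(m)$p.value)
      ts <- c(ts, tt)
    }
    if (!length(ps)) next
    rows[[pat]] <- data.frame(pattern = pat, time_rel_s = ts, p_raw = ps,
                              p_adjusted = p.adjust(ps, method = "holm"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot the pattern frequency time course
#'
#' Percent of cell couples per pattern versus time relative to tight cell
#' coupling, with binomial standard error ribbons.
#'
#' @param table a [pattern_frequencies()] result.
#' @param patterns patterns to show.
#' @return a ggplot object.
#' @export
plot_pattern_timecourse <- function(table,
                                    patterns = c("any", "central",
                                                 "invagination")) {
  df <- table[table$pattern %in% patterns, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_rel_s, y = .data$percent,
                                   colour = .data$pattern,
                                   fill = .data$pattern)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$percent - .data$se, 0),
                                      ymax = pmin(.data$percent + .data$se, 100)),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time relative to tight coupling (s)",
                  y = "% of cell couples",
                  title = unique(df$condition)[1]) +
    ggplot2::theme_classic()
}

#' Plot the log2 central/invagination ratio
#'
#' @param ratio a [central_invagination_ratio()] result (one or more
#'   conditions row-bound).
#' @return a ggplot object.
#' @export
plot_ratio_series <- function(ratio) {
  ggplot2::ggplot(ratio, ggplot2::aes(x = .data$time_rel_s,
                                      y = .data$log2_ratio,
                                      colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time relative to tight coupling (s)",
                  y = "log2 central / invagination") +
    ggplot2::theme_classic()
}

#' @importFrom rlang .data
NULL
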