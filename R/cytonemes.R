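#' Cytoneme number and normalised maximum length for one cell
#'
#' Cytonemes are scored at sampled timepoints (10 samples, 10 min apart, in
#' the source protocol): at each sample the centre-to-tip distance of every
#' cytoneme and the centre-to-membrane distance are recorded. The summary per
#' cell is the mean cytoneme count over samples and the maximum tip distance
#' across all samples minus the mean centre-to-membrane distance (so lengths
#' are measured from the membrane, not the cell centre). A negative
#' normalised length is floored at 0 and flagged.
#'
#' @param samples a list of samples, each a list with elements
#'   `tip_distances` (numeric vector of centre-to-tip distances, um; may be
#'   empty) and `centre_membrane_distance` (scalar, um).
#' @return A list: `avg_count`, `max_length_normalized` (`NA` when no
#'   cytoneme was seen in any sample), `floored` (logical flag).
#' @examples
#' s <- list(list(tip_distances = c(18, 25), centre_membrane_distance = 10),
#'           list(tip_distances = 21,        centre_membrane_distance = 10))
#' cytoneme_stats(s)
#' @export
cytoneme_stats <- function(samples) {
  if (length(samples) == 0L) stop("at least one sample is required", call. = FALSE)
  counts <- vapply(samples, function(s) length(s$tip_distances), 0L)
  cmd <- vapply(samples, function(s) {
    d <- s$centre_membrane_distance
    if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d < 0) {
      stop("each sample needs a non-negative centre_membrane_distance",
           call. = FALSE)
    }
    as.numeric(d)
  }, 0)
  tips <- unlist(lapply(samples, function(s) s$tip_distances))
  if (length(tips) && any(!is.finite(tips) | tips < 0)) {
    stop("tip distances must be finite and >= 0", call. = FALSE)
  }
  if (length(tips) == 0L) {
    return(list(avg_count = 0, max_length_normalized = NA_real_, floored = FALSE))
  }
  raw <- max(tips) - mean(cmd)
  list(avg_count = mean(counts),
       max_length_normalized = max(raw, 0),
       floored = raw < 0)
}

#' Population percentage of cells with cytonemes or beads over time
#'
#' Counts are first summed across imaging positions within each experiment
#' and timepoint (so the percentage is count-weighted, not a mean of
#' per-position percentages), then the per-experiment percentage series are
#' averaged with SEM across experiments — experiments, not cells, being the
#' replication unit.
#'
#' @param counts a population-count table (see [read_population_counts()]).
#' @param which `"cytonemes"` or `"beads"`.
#' @param timepoints optional minute grid to evaluate (default: every
#'   timepoint present). Hourly kinetics use `seq(0, 240, 60)` for cytonemes
#'   and `seq(0, 720, 60)` for bead contact.
#' @return A `data.frame` with columns `t_min`, `mean_percent`, `sem_percent`,
#'   `n_experiments`; per-experiment values are in attribute `per_experiment`.
#'   Timepoints where every position has zero cells yield `NA`.
#' @examples
#' pop <- data.frame(experiment_id = "e1", position_id = c("p1", "p2"),
#'                   t_min = 0, n_total = c(20, 30),
#'                   n_with_cytonemes = c(5, 10), n_with_beads = c(0, 0))
#' population_percent(pop, "cytonemes")  # 15/50 = 30%
#' @export
population_percent <- function(counts, which = c("cytonemes", "beads"),
                               timepoints = NULL) {
  which <- match.arg(which)
  col <- if (which == "cytonemes") "n_with_cytonemes" else "n_with_beads"
  if (is.null(timepoints)) timepoints <- sort(unique(counts$t_min))
  grid_ok <- vapply(split(counts$t_min, paste(counts$experiment_id, counts$position_id)),
                    function(tt) all(timepoints %in% tt), TRUE)
  if (!all(grid_ok)) {
    stop("all positions must share the requested timepoint grid", call. = FALSE)
  }
  sub <- counts[counts$t_min %in% timepoints, , drop = FALSE]
  agg_e <- stats::aggregate(cbind(n_event = sub[[col]], n_total = sub$n_total),
                            by = list(experiment_id = sub$experiment_id,
                                      t_min = sub$t_min),
                            FUN = sum)
  agg_e$percent <- ifelse(agg_e$n_total > 0,
                          100 * agg_e$n_event / agg_e$n_total, NA_real_)
  out <- do.call(rbind, lapply(timepoints, function(tt) {
    v <- agg_e$percent[agg_e$t_min == tt]
    v_ok <- v[!is.na(v)]
    data.frame(
      t_min = tt,
      mean_percent = if (length(v_ok)) mean(v_ok) else NA_real_,
      sem_percent = if (length(v_ok) > 1)
        stats::sd(v_ok) / sqrt(length(v_ok)) else NA_real_,
      n_experiments = length(v_ok)
    )
  }))
  rownames(out) <- NULL
  attr(out, "per_experiment") <- agg_e[order(agg_e$experiment_id, agg_e$t_min),
                                       c("experiment_id", "t_min", "percent")]
  out
}
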