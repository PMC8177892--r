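#' Percentage of marker signal partitioned to the bead-proximal daughter
#'
#' Mean channel intensities of the two daughter cells are background
#' subtracted (one background value per doublet record); negative residuals
#' clamp to 0 since dim distal cells are biologically expected. The partition
#' percentage is the proximal share of the summed background-corrected
#' signal:
#' `100 * (I_p - B)+ / ((I_p - B)+ + (I_d - B)+)`.
#'
#' @param I_proximal,I_distal mean fluorescence of the bead-proximal and
#'   bead-distal daughter cells.
#' @param I_background background intensity for the doublet.
#' @return The proximal partition percentage in \[0, 100\]. Vectorised.
#' @examples
#' partition_percent(70, 50, 10)  # 60
#' @export
partition_percent <- function(I_proximal, I_distal, I_background) {
  if (any(!is.finite(c(I_proximal, I_distal, I_background)))) {
    stop("intensities must be finite", call. = FALSE)
  }
  p <- pmax(I_proximal - I_background, 0)
  d <- pmax(I_distal - I_background, 0)
  if (any(p + d == 0)) {
    stop("undefined partition: both daughters at or below background",
         call. = FALSE)
  }
  100 * p / (p + d)
}

#' Classify a doublet by its proximal partition percentage
#'
#' `Proximal` (a bead-oriented asymmetric division) above 55%, `Distributed`
#' for 45-55% inclusive, `Distal` below 45%.
#'
#' @param percent proximal partition percentage(s) in \[0, 100\].
#' @return Character vector in `{"Proximal", "Distributed", "Distal"}`.
#' @examples
#' classify_doublet(c(40, 50, 60))
#' @export
classify_doublet <- function(percent) {
  if (any(!is.finite(percent)) || any(percent < 0) || any(percent > 100)) {
    stop("percent must lie in [0, 100]", call. = FALSE)
  }
  ifelse(percent > 55, "Proximal",
         ifelse(percent >= 45, "Distributed", "Distal"))
}

#' Score every doublet record
#'
#' Computes the partition percentage and category for each row of a doublet
#' table.
#'
#' @param doublets a doublet table (see [read_doublets()]).
#' @return The table with `percent_proximal` and `category` columns appended.
#' @export
doublet_calls <- function(doublets) {
  doublets$percent_proximal <- vapply(seq_len(nrow(doublets)), function(i) {
    partition_percent(doublets$I_proximal[i], doublets$I_distal[i],
                      doublets$I_background[i])
  }, 0)
  doublets$category <- classify_doublet(doublets$percent_proximal)
  doublets
}

#' Per-experiment category rates
#'
#' For each experiment x channel (x condition) group, the percentage of
#' doublets in each of the three categories; percentages sum to 100 per
#' group. Cross-experiment mean and SEM per category are attached.
#'
#' @param calls a [doublet_calls()] result.
#' @return A `data.frame` with columns `condition`, `channel`,
#'   `experiment_id`, `category`, `n`, `percent`; attribute `summary` holds
#'   the cross-experiment mean +/- SEM per condition x channel x category.
#' @export
category_rates <- function(calls) {
  if (nrow(calls) == 0L) stop("no doublet calls to summarise", call. = FALSE)
  cats <- c("Proximal", "Distributed", "Distal")
  groups <- unique(calls[c("condition", "channel", "experiment_id")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- calls[calls$condition == g$condition & calls$channel == g$channel &
                   calls$experiment_id == g$experiment_id, ]
    n_cat <- vapply(cats, function(cc) sum(sub$category == cc), 0L)
    data.frame(condition = g$condition, channel = g$channel,
               experiment_id = g$experiment_id, category = cats,
               n = n_cat, percent = 100 * n_cat / sum(n_cat),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  sm_groups <- unique(out[c("condition", "channel", "category")])
  smry <- do.call(rbind, lapply(seq_len(nrow(sm_groups)), function(i) {
    g <- sm_groups[i, ]
    v <- out$percent[out$condition == g$condition & out$channel == g$channel &
                       out$category == g$category]
    data.frame(condition = g$condition, channel = g$channel,
               category = g$category, mean_percent = mean(v),
               sem_percent = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
               else NA_real_,
               n_experiments = length(v),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  attr(out, "summary") <- smry
  out
}

#' qPCR relative expression by the 2^-ddCt method
#'
#' Threshold cycles of the target gene are normalised to the reference gene
#' (`dCt = Ct_target - Ct_ref`), then to the mean dCt of the control
#' condition (`ddCt = dCt - mean_dct_control`); relative expression is
#' `2^-ddCt`. Vectorised over replicates.
#'
#' @param ct_target,ct_ref threshold cycles of target and reference gene.
#' @param mean_dct_control mean dCt of the control condition.
#' @return Numeric fold changes.
#' @examples
#' qpcr_fold_change(25, 20, 6)  # ddCt = -1, fold = 2
#' @export
qpcr_fold_change <- function(ct_target, ct_ref, mean_dct_control) {
  if (any(!is.finite(c(ct_target, ct_ref, mean_dct_control)))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  2^(-((ct_target - ct_ref) - mean_dct_control))
}

#' Summarise replicate fold changes
#'
#' Fold changes are ratios, so replicates are summarised by geometric mean
#' and geometric SD.
#'
#' @param folds positive numeric fold changes.
#' @return A list: `geo_mean`, `geo_sd` (`NA` for a single replicate), `n`.
#' @export
fold_change_summary <- function(folds) {
  if (any(!is.finite(folds)) || any(folds <= 0)) {
    stop("fold changes must be positive and finite", call. = FALSE)
  }
  lg <- log(folds)
  list(geo_mean = exp(mean(lg)),
       geo_sd = if (length(folds) > 1) exp(stats::sd(lg)) else NA_real_,
       n = length(folds))
}
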