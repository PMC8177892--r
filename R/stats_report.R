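#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact test of association for a 2x2 contingency table (rows = conditions,
#' columns = drops/retains in the retention analysis). The two-sided p-value
#' follows the conventional probability-mass ordering: the sum of
#' hypergeometric probabilities of every table with the observed margins that
#' is no more probable than the observed one. Computed via
#' [stats::fisher.test()], which implements exactly this definition.
#'
#' @param table a 2x2 matrix of non-negative integer counts, or four counts
#'   `c(a, b, c, d)` filled by row.
#' @return A list: `p` (two-sided), `odds_ratio` (conditional MLE), `table`.
#' @examples
#' fisher_exact(c(10, 0, 0, 10))$p
#' @export
fisher_exact <- function(table) {
  if (is.numeric(table) && length(table) == 4L) {
    table <- matrix(table, nrow = 2, byrow = TRUE)
  }
  if (!is.matrix(table) || !all(dim(table) == 2L)) {
    stop("fisher_exact() expects a 2x2 table", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(table) == 0) stop("empty table", call. = FALSE)
  ft <- stats::fisher.test(table)
  list(p = unname(ft$p.value), odds_ratio = unname(ft$estimate), table = table)
}

#' Pearson chi-squared goodness-of-fit test
#'
#' Tests observed counts against expected counts (which must be positive in
#' every cell), with `df = cells - 1` and no continuity correction.
#'
#' @param observed non-negative integer counts.
#' @param expected positive expected counts, same length; rescaled to the
#'   observed total if needed.
#' @return A list: `chi2`, `df`, `p`.
#' @examples
#' chisq_gof(c(30, 0, 0), c(10, 10, 10))$chi2  # 60
#' @export
chisq_gof <- function(observed, expected) {
  if (length(observed) != length(expected) || length(observed) < 2) {
    stop("observed and expected must be equal-length vectors (>= 2 cells)",
         call. = FALSE)
  }
  if (any(expected <= 0)) stop("expected counts must be > 0 in every cell",
                               call. = FALSE)
  if (any(observed < 0)) stop("observed counts must be >= 0", call. = FALSE)
  res <- suppressWarnings(
    stats::chisq.test(observed, p = expected / sum(expected)))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Assemble a deterministic report bundle
#'
#' Writes each summary table as CSV into `out_dir` together with a YAML run
#' manifest recording the configuration, seed, package version, the tables
#' written, any empty optional sections omitted, and a timestamp. Given the
#' same inputs and configuration, the tables are byte-identical across runs
#' (the manifest timestamp excepted).
#'
#' @param summaries a named list of `data.frame`s; `NULL` or zero-row entries
#'   are omitted and noted in the manifest.
#' @param out_dir output directory, created if needed.
#' @param config optional [sim_config()] (or plain list) recorded in the
#'   manifest.
#' @param seed seed recorded in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
build_report <- function(summaries, out_dir, config = NULL, seed = NULL) {
  if (!is.list(summaries) || length(summaries) == 0L ||
      is.null(names(summaries)) || any(names(summaries) == "")) {
    stop("summaries must be a non-empty named list of tables", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  omitted <- character()
  for (nm in names(summaries)) {
    tab <- summaries[[nm]]
    if (is.null(tab) || nrow(tab) == 0L) {
      omitted <- c(omitted, nm)
      next
    }
    f <- file.path(out_dir, paste0(nm, ".csv"))
    tab2 <- as.data.frame(lapply(tab, format_csv_field),
                          stringsAsFactors = FALSE, check.names = FALSE)
    con <- file(f, open = "wb")
    utils::write.csv(tab2, con, row.names = FALSE, quote = FALSE)
    close(con)
    written <- c(written, basename(f))
  }
  manifest <- list(
    package = "cytobead",
    version = as.character(utils::packageVersion("cytobead")),
    seed = seed,
    config = if (inherits(config, "sim_config")) unclass(config) else config,
    tables = as.list(written),
    omitted_sections = as.list(omitted),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
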