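#' @name tracks_io
#' @title CSV formats for tracks, population counts, divisions and doublets
#'
#' @description
#' All tables travel as plain UTF-8 CSV with a fixed header. Conventions,
#' chosen for unambiguous cross-language parsing:
#' * absent values are empty fields — a zero is always a real coordinate,
#'   never "missing";
#' * booleans are serialised as lowercase `true`/`false`;
#' * numeric fields are written at full double precision (`%.17g`), so a
#'   write/read cycle reproduces the values bit-for-bit;
#' * coordinates are micrometres; any pixel-to-micrometre conversion happens
#'   upstream.
#'
#' Readers validate the header and every row, and reject rather than coerce:
#' a malformed value or a broken invariant (e.g. non-consecutive minutes
#' within a cell) raises an error naming the offending column, row or cell.
#' @keywords internal
NULL

.schemas <- list(
  tracks = list(
    required = c("experiment_id", "position_id", "cell_id", "condition",
                 "t_min", "x_cell", "y_cell", "x_bead", "y_bead",
                 "x_membrane", "y_membrane", "in_contact", "divided_at"),
    numeric = c("t_min", "x_cell", "y_cell", "x_bead", "y_bead",
                "x_membrane", "y_membrane", "divided_at"),
    boolean = "in_contact",
    optional = character()
  ),
  population = list(
    required = c("experiment_id", "position_id", "t_min", "n_total",
                 "n_with_cytonemes", "n_with_beads"),
    numeric = c("t_min", "n_total", "n_with_cytonemes", "n_with_beads"),
    boolean = character(),
    optional = character()
  ),
  divisions = list(
    required = c("event_id", "condition", "experiment_id",
                 "x_pole_a", "y_pole_a", "x_pole_b", "y_pole_b",
                 "x_bead", "y_bead"),
    numeric = c("x_pole_a", "y_pole_a", "x_pole_b", "y_pole_b",
                "x_bead", "y_bead", "true_angle_deg"),
    boolean = character(),
    optional = "true_angle_deg"
  ),
  doublets = list(
    required = c("doublet_id", "condition", "experiment_id", "channel",
                 "I_proximal", "I_distal", "I_background"),
    numeric = c("I_proximal", "I_distal", "I_background"),
    boolean = character(),
    optional = character()
  )
)

format_csv_field <- function(x) {
  if (is.logical(x)) {
    out <- ifelse(is.na(x), "", ifelse(x, "true", "false"))
  } else if (is.numeric(x)) {
    out <- ifelse(is.na(x), "", sprintf("%.17g", x))
  } else {
    out <- ifelse(is.na(x), "", as.character(x))
  }
  if (any(grepl("[,\"\n]", out))) {
    stop("field values may not contain commas, quotes or newlines", call. = FALSE)
  }
  out
}

write_table_csv <- function(df, path, format) {
  sch <- .schemas[[format]]
  missing_cols <- setdiff(sch$required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s table is missing column(s): %s", format,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  cols <- c(sch$required, intersect(sch$optional, names(df)))
  if (nrow(df) > 0L) {
    out <- vapply(df[cols], format_csv_field, character(nrow(df)))
    if (nrow(df) == 1L) out <- matrix(out, nrow = 1)
  } else {
    out <- matrix(character(), ncol = length(cols))
  }
  con <- file(path, open = "wb")   # binary: byte-identical across platforms
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = ","),
               apply(out, 1, paste, collapse = ",")),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_table_csv <- function(path, format) {
  sch <- .schemas[[format]]
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  missing_cols <- setdiff(sch$required, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(names(raw), c(sch$required, sch$optional))
  if (length(unknown)) {
    stop(sprintf("schema error in %s: unknown column(s) %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  df <- raw
  for (col in intersect(sch$numeric, names(df))) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(num))
    if (length(bad)) {
      stop(sprintf("invalid numeric value '%s' in column '%s', row %d of %s",
                   v[bad[1]], col, bad[1], path), call. = FALSE)
    }
    num[v == ""] <- NA_real_
    df[[col]] <- num
  }
  for (col in sch$boolean) {
    v <- df[[col]]
    bad <- which(!v %in% c("true", "false"))
    if (length(bad)) {
      stop(sprintf("invalid boolean value '%s' in column '%s', row %d of %s",
                   v[bad[1]], col, bad[1], path), call. = FALSE)
    }
    df[[col]] <- v == "true"
  }
  df
}

#' Read or write a track table
#'
#' The track table is the machine-readable equivalent of a manual-tracking
#' export: one row per cell per minute with cell-centre, bead and
#' membrane-reference coordinates (micrometres), a contact flag, and the
#' division minute if any. See [tracks_io] for the CSV conventions.
#'
#' `read_tracks()` validates that, within each cell, `t_min` is a run of
#' consecutive integers, that cell/membrane coordinates are present and
#' finite, and that bead coordinates are present whenever `in_contact` is
#' true. Rows are returned sorted by `(cell_id, t_min)`.
#'
#' @param path CSV file path.
#' @return `read_tracks()` returns the validated `data.frame`;
#'   `write_tracks()` returns `path` invisibly.
#' @examples
#' cfg <- sim_config(n_cells = 2, duration_min = 10, seed = 3)
#' f <- tempfile(fileext = ".csv")
#' write_tracks(simulate_tracks(cfg), f)
#' tr <- read_tracks(f)
#' @export
read_tracks <- function(path) {
  df <- read_table_csv(path, "tracks")
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$cell_id, df$t_min), , drop = FALSE]
  rownames(df) <- NULL
  for (col in c("t_min", "x_cell", "y_cell", "x_membrane", "y_membrane")) {
    if (anyNA(df[[col]]) || any(!is.finite(df[[col]]))) {
      stop(sprintf("integrity error: column '%s' has missing or non-finite values",
                   col), call. = FALSE)
    }
  }
  for (cid in unique(df$cell_id)) {
    tt <- df$t_min[df$cell_id == cid]
    if (any(diff(tt) != 1)) {
      stop(sprintf("integrity error: cell '%s' has non-consecutive t_min", cid),
           call. = FALSE)
    }
    sub <- df[df$cell_id == cid, ]
    bad <- sub$in_contact & (is.na(sub$x_bead) | is.na(sub$y_bead))
    if (any(bad)) {
      stop(sprintf("integrity error: cell '%s' is in contact at t=%d with absent bead coordinates",
                   cid, sub$t_min[which(bad)[1]]), call. = FALSE)
    }
  }
  df
}

#' @rdname read_tracks
#' @param table a track-table `data.frame`.
#' @export
write_tracks <- function(table, path) {
  tab <- table[order(table$cell_id, table$t_min), , drop = FALSE]
  write_table_csv(tab, path, "tracks")
}

#' Read or write a population-count table
#'
#' Per-position, per-minute counts of cells in frame, cells with cytonemes,
#' and cells in contact with a bead. Counts must satisfy
#' `0 <= count <= n_total`.
#'
#' @param path CSV file path.
#' @return `read_population_counts()` returns the validated `data.frame`.
#' @export
read_population_counts <- function(path) {
  df <- read_table_csv(path, "population")
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$experiment_id, df$position_id, df$t_min), , drop = FALSE]
  rownames(df) <- NULL
  for (col in c("n_with_cytonemes", "n_with_beads")) {
    bad <- which(df[[col]] < 0 | df[[col]] > df$n_total)
    if (length(bad)) {
      stop(sprintf("integrity error: %s out of [0, n_total] at row %d",
                   col, bad[1]), call. = FALSE)
    }
  }
  df
}

#' @rdname read_population_counts
#' @param table a population-count `data.frame`.
#' @export
write_population_counts <- function(table, path) {
  tab <- table[order(table$experiment_id, table$position_id, table$t_min), ,
               drop = FALSE]
  write_table_csv(tab, path, "population")
}

#' Read or write a division-event table
#'
#' One row per anaphase event: two spindle pole coordinates and the bead
#' coordinate, micrometres. Poles must be distinct. A `true_angle_deg`
#' column (present in simulator output) is carried through when present.
#'
#' @param path CSV file path.
#' @return `read_divisions()` returns the validated `data.frame`.
#' @export
read_divisions <- function(path) {
  df <- read_table_csv(path, "divisions")
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$event_id), , drop = FALSE]
  rownames(df) <- NULL
  coord <- c("x_pole_a", "y_pole_a", "x_pole_b", "y_pole_b", "x_bead", "y_bead")
  for (col in coord) {
    if (anyNA(df[[col]]) || any(!is.finite(df[[col]]))) {
      stop(sprintf("integrity error: column '%s' has missing or non-finite values",
                   col), call. = FALSE)
    }
  }
  same <- df$x_pole_a == df$x_pole_b & df$y_pole_a == df$y_pole_b
  if (any(same)) {
    stop(sprintf("integrity error: event '%s' has coincident poles",
                 df$event_id[which(same)[1]]), call. = FALSE)
  }
  df
}

#' @rdname read_divisions
#' @param table a division-event `data.frame`.
#' @export
write_divisions <- function(table, path) {
  tab <- table[order(table$event_id), , drop = FALSE]
  write_table_csv(tab, path, "divisions")
}

#' Read or write a doublet intensity table
#'
#' One row per doublet per channel: mean fluorescence of the bead-proximal
#' cell, the bead-distal cell, and the background. Intensities must be
#' non-negative; a doublet may not appear twice for the same channel.
#'
#' @param path CSV file path.
#' @return `read_doublets()` returns the validated `data.frame`.
#' @export
read_doublets <- function(path) {
  df <- read_table_csv(path, "doublets")
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$doublet_id, df$channel), , drop = FALSE]
  rownames(df) <- NULL
  for (col in c("I_proximal", "I_distal", "I_background")) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0)
    if (length(bad)) {
      stop(sprintf("integrity error: %s missing or negative at row %d", col, bad[1]),
           call. = FALSE)
    }
  }
  key <- paste(df$doublet_id, df$channel)
  if (anyDuplicated(key)) {
    stop(sprintf("integrity error: duplicate doublet x channel row '%s'",
                 key[which(duplicated(key))[1]]), call. = FALSE)
  }
  df
}

#' @rdname read_doublets
#' @param table a doublet `data.frame`.
#' @export
write_doublets <- function(table, path) {
  tab <- table[order(table$doublet_id, table$channel), , drop = FALSE]
  write_table_csv(tab, path, "doublets")
}
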