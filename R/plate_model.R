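# Plate, well and screen-run containers plus the long-format CSV readers and
# writers every downstream module consumes.

WELL_TYPES <- c("compound", "untreated_control", "vehicle_control",
                "positive_control", "empty")

GEOMETRIES <- list(
  w384 = list(n_row = 16L, n_col = 24L),
  w96  = list(n_row = 8L,  n_col = 12L)
)

PLATE_COLUMNS <- c("plate_id", "replicate", "row", "col", "well_type",
                   "compound_id", "concentration_uM", "signal")

#' Microtiter plate geometry
#'
#' @param geometry `"w384"` (16 rows x 24 columns) or `"w96"` (8 x 12).
#' @return A list with elements `n_row`, `n_col` and `capacity`.
#' @export
plate_geometry <- function(geometry = c("w384", "w96")) {
  geometry <- match.arg(geometry)
  g <- GEOMETRIES[[geometry]]
  g$name <- geometry
  g$capacity <- g$n_row * g$n_col
  g
}

#' Canonical well address string
#'
#' Formats row letter + zero-padded column, e.g. `"A01"`, the standard
#' microtiter convention.
#'
#' @param row Row letter(s), `"A"`--`"P"`.
#' @param col 1-based column number(s).
#' @return Character vector of addresses.
#' @export
well_address <- function(row, col) {
  sprintf("%s%02d", row, as.integer(col))
}

#' Assemble and validate a screen run
#'
#' A screen run holds every measured well of a (possibly multi-plate,
#' multi-replicate) screen in one long table, together with its geometry and
#' replicate count. Validation enforces the well-level invariants: known well
#' types, addresses inside the plate geometry, unique (plate, row, col),
#' compound wells annotated with a compound and concentration, control wells
#' free of compound annotations, and non-negative signals. Missing signals
#' are retained (flagged via `NA`) and excluded from statistics downstream.
#'
#' @param wells Data frame with columns `plate_id`, `replicate`, `row`,
#'   `col`, `well_type`, `compound_id`, `concentration_uM`, `signal`.
#' @param geometry Plate geometry name, see [plate_geometry()].
#' @param n_replicates Number of independent experiments (default 3).
#' @param compound_catalog Optional data frame of per-compound annotations
#'   (must contain `compound_id`).
#' @return An object of class `screen_run`.
#' @export
screen_run <- function(wells, geometry = "w384", n_replicates = 3L,
                       compound_catalog = NULL) {
  geom <- plate_geometry(geometry)
  wells <- validate_wells(wells, geom)
  if (any(wells$replicate > n_replicates)) {
    stop("replicate index exceeds n_replicates (", n_replicates, ")")
  }
  # a compound may appear at most once per physical plate
  cw <- wells[wells$well_type == "compound", ]
  if (nrow(cw) > 0) {
    key <- paste(cw$plate_id, cw$compound_id)
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      stop("compound appears more than once on a plate: ",
           paste(utils::head(dup, 5), collapse = ", "))
    }
  }
  structure(
    list(wells = wells, geometry = geom$name,
         n_replicates = as.integer(n_replicates),
         compound_catalog = compound_catalog),
    class = "screen_run"
  )
}

validate_wells <- function(wells, geom) {
  missing_cols <- setdiff(PLATE_COLUMNS, names(wells))
  if (length(missing_cols) > 0) {
    stop("plate table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  wells <- as.data.frame(wells)[, PLATE_COLUMNS]
  wells$plate_id <- as.character(wells$plate_id)
  wells$replicate <- as.integer(wells$replicate)
  wells$row <- toupper(as.character(wells$row))
  wells$col <- as.integer(wells$col)
  wells$well_type <- as.character(wells$well_type)
  wells$compound_id <- as.character(wells$compound_id)
  wells$compound_id[!is.na(wells$compound_id) & wells$compound_id == ""] <- NA
  wells$concentration_uM <- as.numeric(wells$concentration_uM)
  wells$signal <- as.numeric(wells$signal)

  bad_type <- setdiff(unique(wells$well_type), WELL_TYPES)
  if (length(bad_type) > 0) {
    stop("unknown well_type: ", paste(bad_type, collapse = ", "))
  }
  row_ok <- match(wells$row, LETTERS) <= geom$n_row
  if (any(!row_ok | is.na(row_ok))) {
    stop("row outside ", geom$name, " geometry: ",
         paste(unique(wells$row[!row_ok | is.na(row_ok)]), collapse = ", "))
  }
  if (any(is.na(wells$col) | wells$col < 1L | wells$col > geom$n_col)) {
    stop("column outside ", geom$name, " geometry")
  }
  addr <- paste(wells$plate_id, well_address(wells$row, wells$col))
  if (anyDuplicated(addr)) {
    dup <- unique(addr[duplicated(addr)])
    stop("duplicate well address: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(wells$signal < 0, na.rm = TRUE)) {
    stop("negative signal in well(s) ",
         paste(utils::head(addr[!is.na(wells$signal) & wells$signal < 0], 5),
               collapse = ", "))
  }
  is_cmpd <- wells$well_type == "compound"
  if (any(is_cmpd & is.na(wells$compound_id))) {
    stop("compound well without compound_id")
  }
  if (any(is_cmpd & (is.na(wells$concentration_uM) | wells$concentration_uM < 0))) {
    stop("compound well without a non-negative concentration_uM")
  }
  is_ctrl <- wells$well_type %in% c("untreated_control", "vehicle_control")
  if (any(is_ctrl & !is.na(wells$compound_id))) {
    stop("control well carries a compound_id")
  }
  n_missing <- sum(is.na(wells$signal) & wells$well_type != "empty")
  if (n_missing > 0) {
    message(n_missing, " well(s) with missing signal retained and flagged")
  }
  wells
}

#' Read a long-format plate table
#'
#' Expects a UTF-8 CSV with header columns `plate_id`, `replicate`, `row`,
#' `col`, `well_type`, `compound_id`, `concentration_uM`, `signal` (all
#' concentrations in micromolar). Lines starting with `#` are treated as
#' comments (the synthetic generator records its seed there). Malformed rows
#' abort with an error; nothing is silently dropped.
#'
#' @param path CSV file path.
#' @param geometry Plate geometry name (declared, never inferred).
#' @param n_replicates Number of replicate experiments in the run.
#' @return A validated [screen_run()].
#' @export
read_plate_table <- function(path, geometry = "w384", n_replicates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE,
                         colClasses = c(compound_id = "character"))
  if (is.null(n_replicates)) {
    n_replicates <- max(as.integer(tab$replicate), 1L)
  }
  screen_run(tab, geometry = geometry, n_replicates = n_replicates)
}

#' Write a screen run back to its long CSV form
#'
#' The on-disk table is canonically sorted by plate, row, column so that a
#' read/write round trip is the identity up to column order.
#'
#' @param run A [screen_run()].
#' @param path Output CSV path.
#' @param header_comment Optional comment line(s) written before the header
#'   (prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(run, path, header_comment = NULL) {
  stopifnot(inherits(run, "screen_run"))
  w <- canonical_well_order(run$wells)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.csv(w, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

canonical_well_order <- function(wells) {
  wells[order(wells$plate_id, match(wells$row, LETTERS), wells$col), ,
        drop = FALSE]
}

#' Extract one plate from a run
#'
#' @param run A [screen_run()].
#' @param plate_id Plate identifier.
#' @return Data frame of that plate's wells, with the run geometry attached
#'   as attribute `geometry`.
#' @export
plate_wells <- function(run, plate_id) {
  stopifnot(inherits(run, "screen_run"))
  w <- run$wells[run$wells$plate_id == plate_id, , drop = FALSE]
  if (nrow(w) == 0) stop("no such plate: ", plate_id)
  attr(w, "geometry") <- run$geometry
  w
}

#' Plate identifiers of a run
#' @param run A [screen_run()].
#' @return Character vector of plate ids, in canonical order.
#' @export
plate_ids <- function(run) {
  stopifnot(inherits(run, "screen_run"))
  sort(unique(run$wells$plate_id))
}

#' Control wells of a plate
#'
#' @param plate Plate data frame, as returned by [plate_wells()].
#' @param kind One of the well types, typically `"untreated_control"` or
#'   `"vehicle_control"`.
#' @return The (possibly empty) subset of wells of that type.
#' @export
control_wells <- function(plate, kind = "untreated_control") {
  kind <- match.arg(kind, WELL_TYPES)
  plate[plate$well_type == kind, , drop = FALSE]
}

#' Check the minimum control complement of every plate
#'
#' Normalization divides by the per-plate mean control signal; plates with
#' fewer than `min_controls` usable (non-missing) control wells are rejected
#' before any normalization is attempted.
#'
#' @param run A [screen_run()].
#' @param control_type Well type used as the normalization reference.
#' @param min_controls Minimum usable control wells per plate (default 3).
#' @return `TRUE` invisibly, or an error naming the offending plate.
#' @export
assert_control_complement <- function(run, control_type = "untreated_control",
                                      min_controls = 3L) {
  for (pid in plate_ids(run)) {
    pl <- plate_wells(run, pid)
    ctrl <- control_wells(pl, control_type)
    n_ok <- sum(!is.na(ctrl$signal))
    if (n_ok < min_controls) {
      stop("plate ", pid, " has ", n_ok, " usable ", control_type,
           " wells; >= ", min_controls, " required for normalization")
    }
  }
  invisible(TRUE)
}

#' Flag compounds that never moved between replicates
#'
#' Compound placement is re-randomized per replicate in the study design to
#' avoid well-location effects; a compound occupying the same address in all
#' replicates is legal input but suspicious, so it is reported as a QC
#' warning rather than an error.
#'
#' @param run A [screen_run()].
#' @return Character vector of flagged compound ids (invisibly); warns when
#'   non-empty.
#' @export
qc_static_placement <- function(run) {
  stopifnot(inherits(run, "screen_run"))
  cw <- run$wells[run$wells$well_type == "compound", ]
  if (nrow(cw) == 0 || run$n_replicates < 2) return(invisible(character(0)))
  addr <- well_address(cw$row, cw$col)
  per_cmpd <- split(addr, cw$compound_id)
  flagged <- names(per_cmpd)[vapply(
    per_cmpd, function(a) length(a) >= 2 && length(unique(a)) == 1L, logical(1)
  )]
  if (length(flagged) > 0) {
    warning("compound(s) at a fixed address in every replicate: ",
            paste(utils::head(flagged, 5), collapse = ", "),
            if (length(flagged) > 5) ", ..." else "")
  }
  invisible(flagged)
}

#' @export
print.screen_run <- function(x, ...) {
  cat("<screen_run> ", x$geometry, ", ",
      length(plate_ids(x)), " plate(s), ",
      x$n_replicates, " replicate(s), ",
      nrow(x$wells), " wells (",
      sum(x$wells$well_type == "compound"), " compound wells, ",
      length(unique(x$wells$compound_id[x$wells$well_type == "compound"])),
      " compounds)\n", sep = "")
  invisible(x)
}
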