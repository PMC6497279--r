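#' @importFrom rlang .data
#' @importFrom stats sd setNames
#' @importFrom utils head tail
NULL

# Canonical sediment vocabulary and read-time synonym map.  Field notes use
# "shells" and "boulders"; the canonical set is {clay, silt, sand, gravel,
# shell}, with boulders folded into gravel by default.

#' Canonical sediment classes
#'
#' The ordered sediment vocabulary used throughout: clay, silt, sand,
#' gravel, shell.
#'
#' @return Character vector of the five canonical class labels.
#' @export
sediment_classes <- function() c("clay", "silt", "sand", "gravel", "shell")

#' Default sediment synonym map
#'
#' Maps field-annotation synonyms onto the canonical vocabulary
#' (`"shells"` to `"shell"`, `"boulders"` to `"gravel"`).
#'
#' @return Named character vector: names are synonyms, values canonical labels.
#' @export
sediment_synonyms <- function() c(shells = "shell", boulders = "gravel")

#' Normalize sediment labels
#'
#' @param labels Character vector of sediment labels as annotated.
#' @param synonyms Named character vector mapping synonyms to canonical
#'   labels; defaults to [sediment_synonyms()].
#' @return Character vector of canonical labels.
#' @export
normalize_sediment <- function(labels, synonyms = sediment_synonyms()) {
  out <- tolower(labels)
  hit <- out %in% names(synonyms)
  out[hit] <- unname(synonyms[out[hit]])
  unknown <- setdiff(unique(out), sediment_classes())
  if (length(unknown) > 0) {
    stop("unknown sediment class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out
}

# ---- frame records -------------------------------------------------------

#' Build a frame-record table
#'
#' A frame-record table holds one annotated video frame per row: a transect
#' id, a 1-based frame index, optional time from transect start, a `usable`
#' flag, one non-negative integer count column per taxon, and optional
#' per-frame sediment percentages in `sed_*` columns (0-100).
#'
#' @param transect_id Character vector of transect labels.
#' @param frame_index Integer vector of 1-based frame positions.
#' @param counts Data frame or matrix of per-taxon counts (one column per
#'   taxon), or NULL for all-empty frames.
#' @param time_s Optional numeric seconds from transect start.
#' @param sediment_pct Optional data frame of per-class percentages; column
#'   names are sediment classes (synonyms accepted).
#' @param usable Logical vector; frames flagged `FALSE` are excluded from
#'   analyses. Default all `TRUE`.
#' @return A tibble of class `frame_records`.
#' @export
frame_records <- function(transect_id, frame_index, counts = NULL,
                          time_s = NULL, sediment_pct = NULL, usable = TRUE) {
  n <- length(frame_index)
  rec <- tibble::tibble(
    transect_id = as.character(rep_len(transect_id, n)),
    frame_index = as.integer(frame_index),
    usable = rep_len(as.logical(usable), n)
  )
  if (!is.null(time_s)) rec$time_s <- as.numeric(rep_len(time_s, n))
  if (!is.null(counts)) {
    counts <- tibble::as_tibble(as.data.frame(counts))
    stopifnot(nrow(counts) == n)
    rec <- dplyr::bind_cols(rec, counts)
  }
  if (!is.null(sediment_pct)) {
    sediment_pct <- tibble::as_tibble(as.data.frame(sediment_pct))
    stopifnot(nrow(sediment_pct) == n)
    names(sediment_pct) <- paste0("sed_", normalize_sediment(names(sediment_pct)))
    rec <- dplyr::bind_cols(rec, sediment_pct)
  }
  validate_frame_records(rec)
}

#' Column roles in a frame-record table
#'
#' @param records A frame-record tibble.
#' @return Character vector of taxon column names.
#' @export
taxon_columns <- function(records) {
  reserved <- c("transect_id", "frame_index", "time_s", "usable")
  cols <- setdiff(names(records), reserved)
  cols[!startsWith(cols, "sed_")]
}

#' @rdname taxon_columns
#' @return For `sediment_columns`, the `sed_*` column names.
#' @export
sediment_columns <- function(records) {
  cols <- setdiff(names(records), c("transect_id", "frame_index", "time_s", "usable"))
  cols[startsWith(cols, "sed_")]
}

validate_frame_records <- function(rec) {
  stopifnot(all(c("transect_id", "frame_index") %in% names(rec)))
  if (any(rec$frame_index < 1L)) {
    stop("frame_index must be >= 1", call. = FALSE)
  }
  dup <- duplicated(rec[c("transect_id", "frame_index")])
  if (any(dup)) {
    stop("duplicate (transect_id, frame_index) pairs at row(s): ",
         paste(head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  for (col in taxon_columns(rec)) {
    bad <- which(is.na(rec[[col]]) | rec[[col]] < 0)
    if (length(bad) > 0) {
      stop("negative or missing count in column '", col, "' at row ",
           bad[1], call. = FALSE)
    }
  }
  for (col in sediment_columns(rec)) {
    v <- rec[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      stop("sediment percentage outside [0,100] in column '", col, "'",
           call. = FALSE)
    }
  }
  if (!"usable" %in% names(rec)) rec$usable <- TRUE
  rec <- rec[order(rec$transect_id, rec$frame_index), ]
  class(rec) <- unique(c("frame_records", class(rec)))
  rec
}

#' Read frame annotations from CSV
#'
#' Wide format: one row per frame, columns `transect_id`, `frame_index`,
#' optional `time_s` and `usable`, per-taxon count columns, and `sed_*`
#' sediment percentage columns. Rows are sorted by (transect, frame);
#' duplicate frames and negative counts are rejected.
#'
#' @param path Path to a CSV file (UTF-8, header row required).
#' @return A `frame_records` tibble.
#' @export
read_frame_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("transect_id", "frame_index")) {
    if (!col %in% names(rec)) {
      stop("schema error: required column '", col, "' missing from ", path,
           call. = FALSE)
    }
  }
  rec$transect_id <- as.character(rec$transect_id)
  rec$frame_index <- as.integer(rec$frame_index)
  if ("usable" %in% names(rec)) rec$usable <- as.logical(rec$usable)
  validate_frame_records(rec)
}

#' Write frame annotations to CSV
#'
#' Inverse of [read_frame_annotations()]; write-then-read round-trips all
#' fields.
#'
#' @param records A `frame_records` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frame_annotations <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

# ---- taxonomy ------------------------------------------------------------

#' Read a taxonomy table
#'
#' Columns: `common_name`, `scientific_name`, and rank columns `species`,
#' `order`, `class`. Taxa in annotation tables are keyed by `common_name`.
#'
#' @param path CSV path; defaults to the packaged survey taxonomy.
#' @return A tibble of class `taxonomy`.
#' @export
read_taxonomy <- function(path = towcam_fixture("taxonomy.csv")) {
  tax <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("common_name", "species", "order", "class")
  miss <- setdiff(need, names(tax))
  if (length(miss) > 0) {
    stop("taxonomy missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tax$common_name)) {
    stop("taxonomy has duplicated common_name entries", call. = FALSE)
  }
  if (any(!nzchar(tax$class)) || any(!nzchar(tax$order))) {
    stop("taxonomy class/order labels must be non-empty", call. = FALSE)
  }
  class(tax) <- unique(c("taxonomy", class(tax)))
  tax
}

#' Path to a packaged fixture
#'
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path to the installed fixture.
#' @export
towcam_fixture <- function(file) {
  p <- system.file("extdata", file, package = "towcam", mustWork = TRUE)
  p
}

#' Published survey count table
#'
#' Per-taxon organism totals from a Maryland wind-energy-area benthic
#' survey: beam-trawl catches pooled over 15 stations (`beam_trawl`), the
#' fully annotated 9155-frame camera test set (`test_set`), and the
#' every-30th-frame counts pooled over Transects 1-7 (`transects_1_7`).
#' The table is preserved exactly as published, including its small
#' internal inconsistencies with the survey's summary text.
#'
#' @return Tibble with columns common_name, scientific_name, beam_trawl,
#'   test_set, transects_1_7.
#' @export
survey_counts <- function() {
  readr::read_csv(towcam_fixture("survey_counts.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Published transect and station summaries
#'
#' Per-transect mean depth, frames annotated at the 30th-frame interval,
#' and class-level diversity (`transect_summary`); per-station depth and
#' nearest-taxon diversity for beam-trawl sites BT1-BT15
#' (`station_summary`). Values are as published, including "All" rows
#' whose derivation from the printed counts is not stated.
#'
#' @return A tibble.
#' @export
transect_summary <- function() {
  readr::read_csv(towcam_fixture("transect_summary.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname transect_summary
#' @export
station_summary <- function() {
  readr::read_csv(towcam_fixture("station_summary.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

# ---- catch records -------------------------------------------------------

#' Build or read beam-trawl catch records
#'
#' Long format: one row per (station, taxon) with a non-negative count and
#' an `estimated` flag marking counts expanded from a subsample.
#'
#' @param station_id,taxon,count,estimated Vectors of equal length.
#' @return A tibble of class `catch_records`.
#' @export
catch_records <- function(station_id, taxon, count, estimated = FALSE) {
  if (any(count < 0)) stop("catch counts must be >= 0", call. = FALSE)
  rec <- tibble::tibble(
    station_id = as.character(station_id),
    taxon = as.character(taxon),
    count = as.numeric(count),
    estimated = rep_len(as.logical(estimated), length(station_id))
  )
  class(rec) <- unique(c("catch_records", class(rec)))
  rec
}

#' @rdname catch_records
#' @param path CSV path with columns station_id, taxon, count and optional
#'   estimated.
#' @export
read_catch_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("station_id", "taxon", "count")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("catch table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  catch_records(x$station_id, x$taxon, x$count,
                if ("estimated" %in% names(x)) x$estimated else FALSE)
}

#' Expand a subsampled catch to a whole-tow estimate
#'
#' Large catches are split into equal trays and one tray is counted; the
#' tow total is the tray count times the number of trays.
#'
#' @param tray_count Organisms counted in the one counted tray (>= 0).
#' @param n_trays Number of equal trays (>= 1).
#' @return The estimated total count.
#' @export
expand_subsampled_catch <- function(tray_count, n_trays) {
  if (n_trays < 1) stop("n_trays must be >= 1", call. = FALSE)
  if (tray_count < 0) stop("tray_count must be >= 0", call. = FALSE)
  tray_count * n_trays
}

# ---- aggregation and filtering ------------------------------------------

#' Aggregate counts to a taxonomic rank
#'
#' Sums per-taxon counts to `taxon` (no regrouping), `order`, or `class`
#' level using a taxonomy table. Total count is conserved at every rank.
#' Accepts frame records (usable frames only), catch records, or a named
#' abundance vector.
#'
#' @param x `frame_records`, `catch_records`, or a named numeric vector.
#' @param taxonomy A taxonomy tibble from [read_taxonomy()]. Not needed for
#'   `rank = "taxon"`.
#' @param rank One of `"taxon"`, `"order"`, `"class"`.
#' @return Named numeric abundance vector at the requested rank.
#' @export
aggregate_counts <- function(x, taxonomy = NULL, rank = c("taxon", "order", "class")) {
  rank <- match.arg(rank)
  v <- as_abundance(x)
  if (rank == "taxon") return(v)
  if (is.null(taxonomy)) taxonomy <- read_taxonomy()
  key <- setNames(taxonomy[[rank]], taxonomy$common_name)
  unresolved <- setdiff(names(v), names(key))
  if (length(unresolved) > 0) {
    stop("taxa not resolvable at rank '", rank, "': ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  grp <- key[names(v)]
  out <- tapply(v, grp, sum)
  setNames(as.numeric(out), names(out))
}

#' Coerce to a named abundance vector
#'
#' @param x `frame_records` (usable frames only), `catch_records`, or a
#'   named numeric vector.
#' @return Named non-negative numeric vector.
#' @export
as_abundance <- function(x) {
  if (inherits(x, "frame_records")) {
    use <- x[x$usable %||% TRUE, , drop = FALSE]
    cols <- taxon_columns(x)
    if (length(cols) == 0) return(setNames(numeric(0), character(0)))
    return(vapply(use[cols], sum, numeric(1)))
  }
  if (inherits(x, "catch_records")) {
    out <- tapply(x$count, x$taxon, sum)
    return(setNames(as.numeric(out), names(out)))
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("cannot interpret input as an abundance vector", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter an abundance vector by minimum count
#'
#' @param v Named abundance vector.
#' @param min_count Minimum count to retain a taxon (>= 0).
#' @return List with `filtered` (vector of taxa with count >= min_count),
#'   `n_taxa_nonzero` (taxa with count > 0) and `n_taxa_above` (taxa
#'   meeting the threshold, zero-count taxa never counted).
#' @export
taxa_filters <- function(v, min_count) {
  if (min_count < 0) stop("min_count must be >= 0", call. = FALSE)
  keep <- v >= min_count
  list(
    filtered = v[keep],
    n_taxa_nonzero = sum(v > 0),
    n_taxa_above = sum(v > 0 & keep)
  )
}
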