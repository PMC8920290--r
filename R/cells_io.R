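#' Cell-level mIF tables
#'
#' A `cell_table` is a validated data frame with one row per segmented cell
#' and columns `sample_id`, `subject_id`, `x`, `y` (microns), one 0/1
#' column per marker, and `compartment` (`tumor`, `stroma` or `unknown`).
#' The marker column names are recorded in the `"markers"` attribute.
#'
#' @param df data frame with the columns above.
#' @param markers character vector naming the 0/1 marker columns; by
#'   default every column other than the reserved ones is treated as a
#'   marker.
#' @return A `cell_table`.
#' @export
cell_table <- function(df, markers = NULL) {
  reserved <- c("sample_id", "subject_id", "cell_id", "x", "y", "compartment")
  for (col in c("sample_id", "subject_id", "x", "y")) {
    if (!col %in% names(df)) stop("missing required column: ", col, call. = FALSE)
  }
  if (is.null(markers)) markers <- setdiff(names(df), reserved)
  if (length(markers) == 0L) stop("no marker columns found", call. = FALSE)
  missing_m <- setdiff(markers, names(df))
  if (length(missing_m)) stop("missing marker column: ", missing_m[1L], call. = FALSE)

  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  for (col in c("x", "y")) {
    v <- df[[col]]
    if (is.character(v) || is.factor(v)) {
      num <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric coordinate in column '", col, "' at row ", bad[1L],
             call. = FALSE)
      }
      v <- num
    }
    if (any(!is.finite(v))) {
      stop("non-finite coordinate in column '", col, "' at row ",
           which(!is.finite(v))[1L], call. = FALSE)
    }
    df[[col]] <- as.numeric(v)
  }
  for (m in markers) {
    f <- df[[m]]
    if (is.logical(f)) f <- as.integer(f)
    f <- suppressWarnings(as.integer(as.character(f)))
    if (any(is.na(f)) || !all(f %in% c(0L, 1L))) {
      stop("marker column '", m, "' must be 0/1", call. = FALSE)
    }
    df[[m]] <- f
  }
  if (is.null(df$compartment)) {
    df$compartment <- rep("unknown", nrow(df))
    attr_comp <- FALSE
  } else {
    df$compartment <- as.character(df$compartment)
    bad <- setdiff(unique(df$compartment), c("tumor", "stroma", "unknown"))
    if (length(bad)) stop("unknown compartment label: ", bad[1L], call. = FALSE)
    attr_comp <- TRUE
  }
  if (nrow(df) < 1L) stop("cell table must contain at least one cell", call. = FALSE)
  structure(df,
            markers = markers,
            has_compartment = attr_comp,
            units = "microns",
            class = c("cell_table", "data.frame"))
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells, %d sample(s)\n",
              nrow(x), length(unique(x$sample_id))))
  cat("  markers:", paste(attr(x, "markers"), collapse = ", "), "\n")
  comp <- table(x$compartment)
  cat("  compartment:",
      paste(sprintf("%s=%d", names(comp), as.integer(comp)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a cell-level mIF export
#'
#' Reads a delimited text file (comma or tab separated, header row, `#`
#' comment lines ignored) with one row per cell, in the style of a HALO
#' object export: `sample_id`, `subject_id`, optional `cell_id`, `x`, `y`,
#' one 0/1 column per marker, optional `compartment`. Coordinates given in
#' pixels are converted to microns at read time using the microns-per-pixel
#' scale of the imaging platform (0.4977 um/pixel for the Vectra system
#' used with HALO exports), so that every downstream radius is in microns.
#'
#' @param path file path.
#' @param coord_units `"microns"` (default) or `"pixels"`.
#' @param mpp microns per pixel; used only when `coord_units = "pixels"`.
#' @param markers optional character vector of marker column names;
#'   defaults to all non-reserved columns.
#' @param sep field separator; guessed from the header line when `NULL`.
#' @return A [cell_table()] with coordinates in microns.
#' @export
read_cell_table <- function(path, coord_units = c("microns", "pixels"),
                            mpp = 0.4977, markers = NULL, sep = NULL) {
  coord_units <- match.arg(coord_units)
  if (coord_units == "pixels" && (!is.numeric(mpp) || mpp <= 0)) {
    stop("mpp must be a positive number", call. = FALSE)
  }
  if (is.null(sep)) {
    hdr <- readLines(path, n = 5L)
    hdr <- hdr[!startsWith(hdr, "#")][1L]
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.delim(path, sep = sep, header = TRUE, comment.char = "#",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  tab <- cell_table(raw, markers = markers)
  if (coord_units == "pixels") {
    tab$x <- tab$x * mpp
    tab$y <- tab$y * mpp
  }
  tab
}

#' Write a cell table as tab-separated text
#'
#' A `# units: microns` metadata line precedes the header so round-trips
#' through [read_cell_table()] keep the coordinate unit explicit.
#'
#' @param x a [cell_table()].
#' @param path output path.
#' @export
write_cell_table <- function(x, path) {
  stopifnot(inherits(x, "cell_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", attr(x, "units")), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-subject clinical table
#'
#' Expects columns `subject_id`, `time_months` (> 0), `event` (0/1),
#' `age_dx` (years) and `stage` (I--IV).
#'
#' @param path delimited text file (comma or tab).
#' @return data frame with `stage` as a factor with levels I, II, III, IV.
#' @export
read_clinical_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  d <- utils::read.delim(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  clinical_table(d)
}

#' @rdname read_clinical_table
#' @param df data frame holding the clinical columns.
#' @export
clinical_table <- function(df) {
  for (col in c("subject_id", "time_months", "event", "age_dx", "stage")) {
    if (!col %in% names(df)) stop("missing required column: ", col, call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop("duplicated subject_id in clinical table", call. = FALSE)
  }
  df$time_months <- as.numeric(df$time_months)
  if (any(!is.finite(df$time_months)) || any(df$time_months <= 0)) {
    stop("time_months must be finite and > 0", call. = FALSE)
  }
  df$event <- as.integer(df$event)
  if (!all(df$event %in% c(0L, 1L))) stop("event must be 0/1", call. = FALSE)
  df$age_dx <- as.numeric(df$age_dx)
  df$stage <- as.character(df$stage)
  if (!all(df$stage %in% c("I", "II", "III", "IV"))) {
    stop("stage must be one of I, II, III, IV", call. = FALSE)
  }
  df$stage <- factor(df$stage, levels = c("I", "II", "III", "IV"))
  df
}

#' Resolve conflicting CD8+FOXP3+ phenotype calls
#'
#' A segmented cell cannot plausibly be both a cytotoxic (CD3+CD8+) and a
#' regulatory (CD3+FOXP3+) T cell; when the upstream classifier flags both
#' CD8 and FOXP3 on one cell, the cell's location is retained but its
#' phenotype is demoted to CD3+ only (CD3 = 1, CD8 = 0, FOXP3 = 0).
#'
#' @param x a [cell_table()] with CD3, CD8 and FOXP3 marker columns.
#' @return list with elements `table` (the corrected `cell_table`) and
#'   `conflict_count` (number of rewritten cells).
#' @export
resolve_conflicting_phenotypes <- function(x) {
  stopifnot(inherits(x, "cell_table"))
  need <- c("CD3", "CD8", "FOXP3")
  if (!all(need %in% attr(x, "markers"))) {
    stop("cell table must have CD3, CD8 and FOXP3 marker columns", call. = FALSE)
  }
  conflict <- x$CD8 == 1L & x$FOXP3 == 1L
  x$CD3[conflict] <- 1L
  x$CD8[conflict] <- 0L
  x$FOXP3[conflict] <- 0L
  list(table = x, conflict_count = sum(conflict))
}

#' Restrict a cell table to a tissue compartment
#'
#' Tumor-restricted analyses keep only the cells classified into the tumor
#' compartment by the PanCK marker. A result with zero cells is returned
#' as an empty table (the empty-sample signal); downstream per-sample
#' summaries flag such samples as not estimable.
#'
#' @param x a [cell_table()].
#' @param compartment `"all"`, `"tumor"` or `"stroma"`.
#' @return a `cell_table` (possibly with zero rows).
#' @export
filter_compartment <- function(x, compartment = c("all", "tumor", "stroma")) {
  stopifnot(inherits(x, "cell_table"))
  compartment <- match.arg(compartment)
  if (compartment == "all") return(x)
  if (!isTRUE(attr(x, "has_compartment"))) {
    stop("cell table has no compartment column; only compartment = \"all\" ",
         "is available", call. = FALSE)
  }
  keep <- x$compartment == compartment
  out <- x[keep, , drop = FALSE]
  attributes_to_keep <- c("markers", "has_compartment", "units")
  for (a in attributes_to_keep) attr(out, a) <- attr(x, a)
  class(out) <- class(x)
  out
}

#' Coordinates of phenotype-positive cells
#'
#' A phenotype is a conjunction of marker flags: `c("CD3", "CD8")` selects
#' cells positive for both CD3 and CD8. Lineage subsets are strict
#' conjunctions, so a CD8+ cell lacking CD3 is not a cytotoxic T cell.
#'
#' @param x a [cell_table()].
#' @param phenotype non-empty character vector of marker names.
#' @return two-column matrix of (x, y) coordinates in microns.
#' @export
phenotype_positive_cells <- function(x, phenotype) {
  stopifnot(inherits(x, "cell_table"))
  if (length(phenotype) == 0L) stop("phenotype must name at least one marker",
                                    call. = FALSE)
  unknown <- setdiff(phenotype, attr(x, "markers"))
  if (length(unknown)) stop("unknown marker: ", unknown[1L], call. = FALSE)
  if (nrow(x) == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  pos <- rep(TRUE, nrow(x))
  for (m in phenotype) pos <- pos & x[[m]] == 1L
  cbind(x = x$x[pos], y = x$y[pos])
}

#' Split a multi-sample cell table into per-sample tables
#'
#' @param x a [cell_table()].
#' @return named list of single-sample `cell_table`s.
#' @export
split_samples <- function(x) {
  stopifnot(inherits(x, "cell_table"))
  ids <- unique(x$sample_id)
  out <- lapply(ids, function(id) {
    s <- x[x$sample_id == id, , drop = FALSE]
    for (a in c("markers", "has_compartment", "units")) attr(s, a) <- attr(x, a)
    class(s) <- class(x)
    s
  })
  names(out) <- ids
  out
}

# single-sample guard used by the spatial estimators
one_sample <- function(x) {
  ids <- unique(x$sample_id)
  if (length(ids) != 1L) {
    stop("expected a single-sample cell table; got ", length(ids),
         " sample ids (use split_samples())", call. = FALSE)
  }
  invisible(ids)
}
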