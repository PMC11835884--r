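#' Canonical CSV schemas of the branch-growth pipeline
#'
#' @return Named list: for each table, the required column names and types.
#' @export
table_schemas <- function() {
  list(
    plots = c(plot_id = "integer", area_ha = "numeric", radius_m = "numeric"),
    trees = c(tree_id = "character", plot_id = "integer", x_m = "numeric",
              y_m = "numeric", dbh_felling_cm = "numeric",
              ht_felling_m = "numeric"),
    rings = c(tree_id = "character", year = "integer",
              orientation = "character", width_mm = "numeric"),
    branches = c(branch_id = "character", tree_id = "character",
                 whorl_age = "integer", bh_m = "numeric", dinc_m = "numeric",
                 year = "integer", age = "integer", dbl_cm = "numeric",
                 dbd_mm = "numeric", bl_cm = "numeric", bd_mm = "numeric"),
    climate = c(plot_id = "integer", year = "integer")
  )
}

#' Write the pipeline tables to a directory
#'
#' @param data named list holding any of `plots`, `trees`, `rings`,
#'   `branches`, `climate` data frames.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_growth_tables <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in intersect(names(table_schemas()), names(data))) {
    utils::write.csv(data[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read and validate the pipeline tables
#'
#' Checks required columns, coercible types, and referential integrity
#' (branches and rings reference known trees; trees reference known plots;
#' climate references known plots). Errors name the offending table, column
#' or row numbers.
#'
#' @param dir directory holding the CSV files.
#' @param tables which tables to read (default: all present).
#' @return Named list of validated data frames.
#' @export
read_growth_tables <- function(dir, tables = NULL) {
  schemas <- table_schemas()
  if (is.null(tables)) {
    tables <- names(schemas)[file.exists(file.path(dir, paste0(names(schemas),
                                                               ".csv")))]
  }
  out <- list()
  for (nm in tables) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("missing table: ", path, call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    sch <- schemas[[nm]]
    missing_cols <- setdiff(names(sch), names(df))
    if (length(missing_cols)) {
      stop(nm, ".csv lacks required columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    for (cn in names(sch)) {
      if (sch[[cn]] %in% c("numeric", "integer")) {
        v <- suppressWarnings(as.numeric(df[[cn]]))
        bad <- which(is.na(v) & !is.na(df[[cn]]) & df[[cn]] != "")
        if (length(bad)) {
          stop(sprintf("%s.csv column %s: non-numeric values at rows %s",
                       nm, cn, paste(utils::head(bad, 5), collapse = ", ")),
               call. = FALSE)
        }
        df[[cn]] <- if (sch[[cn]] == "integer") as.integer(round(v)) else v
      }
    }
    out[[nm]] <- df
  }
  .check_integrity(out)
  out
}

.check_integrity <- function(tabs) {
  key_check <- function(child, col, parent_keys, label) {
    bad <- which(!(child[[col]] %in% parent_keys))
    if (length(bad)) {
      stop(sprintf("%s: unresolved %s at rows %s", label, col,
                   paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  if (!is.null(tabs$trees) && !is.null(tabs$plots)) {
    key_check(tabs$trees, "plot_id", tabs$plots$plot_id, "trees.csv")
  }
  if (!is.null(tabs$branches) && !is.null(tabs$trees)) {
    key_check(tabs$branches, "tree_id", tabs$trees$tree_id, "branches.csv")
  }
  if (!is.null(tabs$rings) && !is.null(tabs$trees)) {
    key_check(tabs$rings, "tree_id", tabs$trees$tree_id, "rings.csv")
  }
  if (!is.null(tabs$climate) && !is.null(tabs$plots)) {
    key_check(tabs$climate, "plot_id", tabs$plots$plot_id, "climate.csv")
  }
  invisible(TRUE)
}

#' Read a Tucson-style decadal ring-width file
#'
#' Parses the classic dendrochronology exchange format: one series per block,
#' rows of `series_id decade_year v1 v2 ...` with up to ten values per row,
#' terminated by a `999` (units 0.01 mm) or `-9999` (units 0.001 mm)
#' sentinel. Returns the long schema used by `rings.csv` with a single
#' synthetic orientation.
#'
#' @param path file path.
#' @return Data frame `tree_id, year, orientation, width_mm`.
#' @export
read_rwl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  series <- list()   # id -> list(start_year, values)
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(toks) < 3) next
    id <- toks[1]
    yr0 <- suppressWarnings(as.integer(toks[2]))
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (is.na(yr0) || anyNA(vals)) next
    if (is.null(series[[id]])) {
      series[[id]] <- list(start = yr0, values = vals)
    } else {
      series[[id]]$values <- c(series[[id]]$values, vals)
    }
  }
  out <- lapply(names(series), function(id) {
    s <- series[[id]]
    v <- s$values
    last <- v[length(v)]
    unit <- if (isTRUE(last == -9999)) 0.001 else 0.01   # per-series terminator
    if (last %in% c(999, -9999)) v <- v[-length(v)]
    if (!length(v)) return(NULL)
    data.frame(tree_id = id, year = s$start + seq_along(v) - 1L,
               orientation = "RWL", width_mm = v * unit)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
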