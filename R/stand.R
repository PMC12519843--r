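#' Validate a table of tree records
#'
#' The tree table is the package's central data structure: one row per tree
#' with identifiers, age group (1 = young ... 5 = over-mature), LiDAR tree
#' height `lh` (m), LiDAR crown diameter `lcd` (m), and the four component
#' biomasses plus total (kg). Validation enforces the structural invariants:
#' positive covariates, non-negative masses, age group in 1..5, total equal
#' to the component sum within relative tolerance 1e-9, and unique `tree_id`
#' within each `plot_id` (duplicate entries are a data-cleaning defect).
#'
#' @param records data.frame with the tree-table columns.
#' @param lh_range permissible `lh` envelope in metres, default roughly the
#'   range observed for the study system (2.7 to 31.7 m).
#' @param additivity_tol relative tolerance for `m_total` vs the component
#'   sum.
#' @param action `"error"` to stop on any violation, `"drop"` to drop
#'   offending rows with a warning listing row numbers.
#' @return the validated (possibly filtered) data.frame, invisibly classed
#'   `tree_stand`.
#' @export
validate_tree_records <- function(records, lh_range = c(2.7, 31.7),
                                  additivity_tol = 1e-9,
                                  action = c("error", "drop")) {
  action <- match.arg(action)
  missing_cols <- setdiff(.tree_csv_header, names(records))
  if (length(missing_cols))
    stop("tree table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num_cols <- c("lh", "lcd", .mass_cols)
  bad <- rep(FALSE, nrow(records))
  msgs <- character(0)
  flag <- function(idx, why) {
    idx <- which(idx)
    if (length(idx)) {
      bad[idx] <<- TRUE
      msgs <<- c(msgs, paste0(why, " (rows ",
                              paste(head(idx, 10L), collapse = ", "),
                              if (length(idx) > 10L) ", ..." else "", ")"))
    }
  }
  for (cc in num_cols) flag(!is.finite(records[[cc]]), paste0("non-numeric ", cc))
  flag(!(records$age_group %in% 1:5), "age_group outside 1..5")
  flag(is.finite(records$lh) &
         (records$lh < lh_range[1] | records$lh > lh_range[2]),
       sprintf("lh outside [%g, %g] m", lh_range[1], lh_range[2]))
  flag(is.finite(records$lcd) & records$lcd <= 0, "non-positive lcd")
  for (cc in .mass_cols)
    flag(is.finite(records[[cc]]) & records[[cc]] < 0, paste0("negative ", cc))
  comp_sum <- records$m_bark + records$m_trunk + records$m_branch + records$m_leaf
  rel <- abs(records$m_total - comp_sum) / pmax(abs(records$m_total), 1e-12)
  flag(is.finite(rel) & rel > additivity_tol,
       "m_total does not equal the component sum (additivity violation)")
  flag(duplicated(paste(records$plot_id, records$tree_id, sep = "\r")),
       "duplicate tree_id within plot")
  if (any(bad)) {
    msg <- paste(msgs, collapse = "; ")
    if (action == "error")
      stop("invalid tree records: ", msg, call. = FALSE)
    warning("dropping ", sum(bad), " invalid tree record(s): ", msg,
            call. = FALSE)
    records <- records[!bad, , drop = FALSE]
    rownames(records) <- NULL
  }
  class(records) <- unique(c("tree_stand", class(records)))
  invisible(records)
}

#' Read and write tree tables as CSV
#'
#' CSV schema: header `tree_id,plot_id,age_group,lh,lcd,m_bark,m_trunk,
#' m_branch,m_leaf,m_total`, UTF-8, '.' decimal, one row per tree, units m
#' and kg. Numbers are written with 15 significant digits, so a write/read
#' round trip is lossless well beyond 12 significant digits. Rows violating
#' the tree-record invariants are rejected with row numbers (`action =
#' "drop"`) or abort the read (`action = "error"`).
#'
#' @param path CSV file path.
#' @param records tree table (see [validate_tree_records()]).
#' @param ... passed to [validate_tree_records()] (e.g. `lh_range`).
#' @param action on invalid rows at read time: `"drop"` (default; warn and
#'   skip) or `"error"`.
#' @return `read_tree_csv` returns the validated data.frame;
#'   `write_tree_csv` returns `path` invisibly.
#' @export
read_tree_csv <- function(path, ..., action = "drop") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(hdr, .tree_csv_header))
    stop("malformed header in ", path, ": expected '",
         paste(.tree_csv_header, collapse = ","), "'", call. = FALSE)
  df <- read.csv(path, colClasses = c(tree_id = "character",
                                      plot_id = "character"))
  validate_tree_records(df, ..., action = action)
}

#' @rdname read_tree_csv
#' @export
write_tree_csv <- function(records, path) {
  records <- as.data.frame(records)[, .tree_csv_header]
  num <- vapply(.tree_csv_header[-(1:2)], function(cc) {
    if (cc == "age_group") sprintf("%d", as.integer(records[[cc]]))
    else sprintf("%.15g", records[[cc]])
  }, character(nrow(records)))
  if (nrow(records) == 1L) num <- matrix(num, nrow = 1L)
  lines <- c(paste(.tree_csv_header, collapse = ","),
             apply(cbind(records$tree_id, records$plot_id, num), 1L,
                   paste, collapse = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Per-age-group, per-component summary statistics
#'
#' One row per (age group, component) with max, min, mean and the n-1
#' standard deviation, mirroring field-survey biomass summary tables. Groups
#' with a single tree report `NA` for the SD (undefined, not zero).
#'
#' @param records tree table.
#' @return data.frame: age_group, component, n, max, min, mean, sd.
#' @export
summarize_by_age_group <- function(records) {
  if (nrow(records) == 0L)
    stop("summarize_by_age_group() needs a non-empty table", call. = FALSE)
  rows <- list()
  for (g in sort(unique(records$age_group))) {
    sub <- records[records$age_group == g, , drop = FALSE]
    for (comp in .all_components) {
      x <- sub[[paste0("m_", comp)]]
      rows[[length(rows) + 1L]] <- data.frame(
        age_group = g, component = comp, n = length(x),
        max = max(x), min = min(x), mean = mean(x),
        sd = if (length(x) >= 2L) sd(x) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
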