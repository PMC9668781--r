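#' Assemble and validate a cassava trial dataset
#'
#' Bundles the three tables of a multi-environment augmented-design
#' evaluation — trial metadata, germplasm entries and plot records — into a
#' validated `cassava_dataset`.
#'
#' Validation rules: trial ids unique with `n_blocks >= 1`; genotype ids
#' unique; every plot references an existing trial and genotype; percent
#' traits lie in \[0, 100\]; counts are non-negative; every trial contains
#' at least one check plot. In `"strict"` mode (default) any violation is
#' an error naming the offending rows; in `"lenient"` mode offending plot
#' rows are dropped with a warning. Missing values (empty fields) mean "not
#' measured" and are never treated as zero.
#'
#' @param trials data frame with columns `trial_id`, `n_blocks` and
#'   optionally `year`, `location`.
#' @param germplasm data frame with columns `genotype_id`, `is_check`
#'   (logical) and optionally `pulp_color_class` (1, 2 or 3).
#' @param plots data frame with columns `trial_id`, `block_id`,
#'   `genotype_id` plus raw measurement and/or trait columns.
#' @param mode `"strict"` or `"lenient"`.
#' @return an object of class `cassava_dataset`: a list with elements
#'   `trials`, `germplasm`, `plots`.
#' @export
cassava_dataset <- function(trials, germplasm, plots,
                            mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(trials), is.data.frame(germplasm),
            is.data.frame(plots))
  if (nrow(plots) == 0) stop("no records: plot table is empty")
  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop("missing mandatory column(s) in ", what, ": ",
           paste(miss, collapse = ", "))
    }
  }
  req(trials, c("trial_id", "n_blocks"), "trials")
  req(germplasm, c("genotype_id", "is_check"), "germplasm")
  req(plots, c("trial_id", "block_id", "genotype_id"), "plots")

  if (anyDuplicated(trials$trial_id)) stop("duplicate trial_id in trials")
  if (anyDuplicated(germplasm$genotype_id)) {
    stop("duplicate genotype_id in germplasm")
  }
  if (any(trials$n_blocks < 1)) stop("n_blocks must be >= 1 for every trial")
  germplasm$is_check <- as.logical(germplasm$is_check)
  if ("pulp_color_class" %in% names(germplasm)) {
    pc <- germplasm$pulp_color_class
    if (any(!is.na(pc) & !pc %in% 1:3)) {
      stop("pulp_color_class must be 1, 2 or 3 when present")
    }
  }

  bad <- rep(FALSE, nrow(plots))
  why <- character(nrow(plots))
  flag <- function(idx, msg) {
    idx <- which(idx & !bad)
    bad[idx] <<- TRUE
    why[idx] <<- msg
  }
  flag(!plots$trial_id %in% trials$trial_id, "unknown trial_id")
  flag(!plots$genotype_id %in% germplasm$genotype_id, "unknown genotype_id")
  pct_cols <- intersect(c("humidity", "DMC.OD", "HI", "StC",
                          "starch_content"), names(plots))
  for (cc in pct_cols) {
    v <- plots[[cc]]
    flag(!is.na(v) & (v < 0 | v > 100), paste0(cc, " outside [0, 100]"))
  }
  cnt_cols <- intersect(c("n_roots", "n_plants_harvested", "NRP"),
                        names(plots))
  for (cc in cnt_cols) {
    v <- plots[[cc]]
    flag(!is.na(v) & v < 0, paste0("negative ", cc))
  }
  if (any(bad)) {
    desc <- paste0("row ", which(bad), ": ", why[bad], collapse = "; ")
    if (mode == "strict") {
      stop("invalid plot record(s): ", desc)
    }
    warning("dropping ", sum(bad), " invalid plot record(s): ", desc)
    plots <- plots[!bad, , drop = FALSE]
    if (nrow(plots) == 0) stop("no records survive validation")
  }

  is_chk <- germplasm$is_check[match(plots$genotype_id,
                                     germplasm$genotype_id)]
  no_check <- setdiff(unique(plots$trial_id),
                      unique(plots$trial_id[is_chk]))
  if (length(no_check)) {
    msg <- paste0("trial(s) without any check plot: ",
                  paste(no_check, collapse = ", "))
    if (mode == "strict") stop(msg) else warning(msg)
  }
  structure(list(trials = trials, germplasm = germplasm, plots = plots),
            class = "cassava_dataset")
}

#' @export
print.cassava_dataset <- function(x, ...) {
  cat("cassava_dataset:", nrow(x$trials), "trials,",
      nrow(x$germplasm), "genotypes (",
      sum(x$germplasm$is_check), "checks ),",
      nrow(x$plots), "plots\n")
  tr <- intersect(trait_names(), names(x$plots))
  if (length(tr)) cat("traits:", paste(tr, collapse = ", "), "\n")
  invisible(x)
}

#' Canonical trait names
#'
#' The eleven traits of the evaluation pipeline, in their conventional
#' order.
#' @return character vector.
#' @export
trait_names <- function() {
  c("DMC.Grav", "DMC.OD", "TCC", "FRY", "ShY", "HI", "DRY", "NRP",
    "StC", "PulpColor", "HCN")
}

#' Read a cassava trial dataset from CSV files
#'
#' Reads `trials.csv`, `germplasm.csv` and `plots.csv` from a directory
#' (comma-delimited, UTF-8, `.` decimal separator, empty field = missing)
#' and validates them via [cassava_dataset()].
#'
#' @param dir directory containing the three CSV files.
#' @param mode validation mode, `"strict"` or `"lenient"`.
#' @return a `cassava_dataset`.
#' @export
read_cassava_dataset <- function(dir, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  paths <- file.path(dir, c("trials.csv", "germplasm.csv", "plots.csv"))
  miss <- paths[!file.exists(paths)]
  if (length(miss)) {
    stop("missing file(s): ", paste(miss, collapse = ", "))
  }
  rd <- function(p) {
    utils::read.csv(p, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
  }
  cassava_dataset(rd(paths[1]), rd(paths[2]), rd(paths[3]), mode = mode)
}

#' Write a cassava trial dataset to CSV files
#'
#' Inverse of [read_cassava_dataset()]: writes `trials.csv`,
#' `germplasm.csv` and `plots.csv` into `dir`.
#'
#' @param ds a `cassava_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cassava_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "cassava_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table(ds$trials, file.path(dir, "trials.csv"))
  write_table(ds$germplasm, file.path(dir, "germplasm.csv"))
  write_table(ds$plots, file.path(dir, "plots.csv"))
  invisible(dir)
}

#' Write a result table as CSV
#'
#' Comma-delimited, UTF-8, `.` decimal separator, one header row, empty
#' field for missing values. Numeric columns are written with 15
#' significant digits so that a write/read round trip preserves values to
#' at least 12 significant digits.
#'
#' @param rows data frame (may have zero rows: a header-only file is
#'   written).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (is.null(rows)) stop("write_table: rows must be non-null")
  rows <- as.data.frame(rows)
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- formatC(out[[j]], digits = 15, format = "g")
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}
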