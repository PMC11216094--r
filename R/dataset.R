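#' Load a BDE table in the fixture schema
#'
#' Reads a CSV of bond dissociation energies keyed by (skeleton, halogen,
#' transfer group). Cells printed as an en/em dash or `/` in the source tables
#' are missing; the two sentinels are preserved verbatim in the `sentinel`
#' column for provenance. Any other non-numeric cell is a parse error reported
#' with its (skeleton, halogen, group) address.
#'
#' @param path CSV path with header
#'   `skeleton_id,halogen,group_id,group_label,bde_kcal_mol,sentinel`.
#' @param bde_type `"homolytic"` or `"heterolytic"`; attached to every record.
#' @param exclude Character vector of record keys (`"skeleton-halogen-group"`)
#'   to drop, for reconciling documented exclusions. Default keeps all rows.
#' @return A data frame of records: key columns, `bde_kcal_mol` (NA when
#'   missing), `missing` flag, `sentinel`, and `bde_type`.
#' @examples
#' tab <- load_bde_table(bde_fixture_path("homolytic"), "homolytic")
#' sum(!tab$missing)
#' @export
load_bde_table <- function(path, bde_type = c("homolytic", "heterolytic"),
                           exclude = character(0)) {
  bde_type <- match.arg(bde_type)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("skeleton_id", "halogen", "group_id", "group_label", "bde_kcal_mol")
  if (!all(need %in% names(raw))) {
    stop("fixture schema mismatch; expected columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(raw$sentinel)) raw$sentinel <- ""
  raw$sentinel[is.na(raw$sentinel)] <- ""
  key <- paste(raw$skeleton_id, raw$halogen, raw$group_id, sep = "-")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate record key(s): ", paste(unique(key[dup]), collapse = ", "),
         call. = FALSE)
  }
  cell <- trimws(raw$bde_kcal_mol)
  cell[is.na(raw$bde_kcal_mol)] <- ""
  sentinels <- c("-", "–", "—", "/")
  is_missing <- cell %in% sentinels | (cell == "" & raw$sentinel %in% sentinels)
  value <- suppressWarnings(as.numeric(cell))
  malformed <- !is_missing & is.na(value)
  if (any(malformed)) {
    stop("malformed BDE cell at ", paste(key[malformed], collapse = ", "),
         ": ", paste(sQuote(cell[malformed]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    skeleton_id = raw$skeleton_id,
    halogen = raw$halogen,
    group_id = raw$group_id,
    group_label = raw$group_label,
    key = key,
    bde_kcal_mol = ifelse(is_missing, NA_real_, value),
    missing = is_missing,
    sentinel = ifelse(is_missing, ifelse(raw$sentinel %in% sentinels,
                                         raw$sentinel, cell), ""),
    bde_type = bde_type,
    stringsAsFactors = FALSE
  )
  if (length(exclude)) out <- out[!out$key %in% exclude, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Path to a packaged BDE table
#'
#' @param bde_type `"homolytic"` (Table of gas-phase homolytic BDEs) or
#'   `"heterolytic"` (acetonitrile-solvated heterolytic BDEs).
#' @return File path of the packaged CSV fixture.
#' @export
bde_fixture_path <- function(bde_type = c("homolytic", "heterolytic")) {
  bde_type <- match.arg(bde_type)
  extdata_file(paste0("bde_", bde_type, ".csv"))
}

#' Load a packaged BDE table
#'
#' Convenience wrapper around [load_bde_table()] for the two shipped tables.
#'
#' @inheritParams load_bde_table
#' @return See [load_bde_table()].
#' @export
bde_table <- function(bde_type = c("homolytic", "heterolytic"),
                      exclude = character(0)) {
  bde_type <- match.arg(bde_type)
  load_bde_table(bde_fixture_path(bde_type), bde_type, exclude = exclude)
}

#' Min-max scaling of BDE targets
#'
#' Fits the affine map `(v - min) / (max - min)` sending the observed minimum
#' to 0 and maximum to 1. Refuses constant input rather than dividing by zero.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return A list with `scaled` (values mapped into `[0, 1]`) and `params`, a
#'   `scaler_params` object usable with [minmax_apply()] and [minmax_invert()].
#' @examples
#' minmax_scale(c(0, 5, 10))$scaled
#' @export
minmax_scale <- function(values) {
  stopifnot(is.numeric(values))
  v <- values[is.finite(values)]
  if (length(v) < 2 || length(unique(v)) < 2) {
    stop("min-max scaling requires at least two distinct finite values",
         call. = FALSE)
  }
  params <- structure(list(min = min(v), max = max(v)), class = "scaler_params")
  list(scaled = minmax_apply(params, values), params = params)
}

#' @rdname minmax_scale
#' @param params A `scaler_params` object.
#' @export
minmax_apply <- function(params, values) {
  stopifnot(inherits(params, "scaler_params"))
  (values - params$min) / (params$max - params$min)
}

#' @rdname minmax_scale
#' @param scaled Values on the scaled `[0, 1]` axis.
#' @export
minmax_invert <- function(params, scaled) {
  stopifnot(inherits(params, "scaler_params"))
  scaled * (params$max - params$min) + params$min
}

#' @export
print.scaler_params <- function(x, ...) {
  cat(sprintf("<scaler_params> min = %.4g, max = %.4g kcal/mol\n", x$min, x$max))
  invisible(x)
}

#' Random train/test split of BDE records
#'
#' Partitions records into training and testing sets at the study's 9:1 ratio
#' by default. The test size is `round(test_fraction * n)`; the split is
#' reproducible for a fixed seed and leaves the session RNG untouched. No
#' stratification is applied: sampling is uniform over records.
#'
#' @param records Data frame of non-missing records (or anything with rows).
#' @param test_fraction Fraction of records held out, in (0, 1).
#' @param seed Integer seed controlling the partition.
#' @return A `dataset_split` list: integer row indices `train` and `test`,
#'   plus `seed` and `test_fraction`.
#' @examples
#' sp <- split_dataset(data.frame(x = 1:10), 0.1, seed = 1)
#' length(sp$test)  # 1
#' @export
split_dataset <- function(records, test_fraction = 0.1, seed = 1) {
  n <- if (is.data.frame(records) || is.matrix(records)) nrow(records) else length(records)
  if (n < 2) stop("need at least two records to split", call. = FALSE)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n_test <- max(1L, round(test_fraction * n))
  test <- sort(with_seed(seed, sample.int(n, n_test)))
  structure(list(train = setdiff(seq_len(n), test), test = test,
                 seed = as.integer(seed), test_fraction = test_fraction),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test (seed %d)\n",
              length(x$train), length(x$test), x$seed))
  invisible(x)
}
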