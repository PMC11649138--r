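#' Read an omics matrix from delimited text
#'
#' Parses a CSV/TSV file whose first row holds feature IDs and whose first
#' column holds sample IDs. Empty cells and the sentinels `"NA"`/`"NaN"`
#' become missing values (`NA`), never zero. The delimiter is chosen from
#' the file extension (`.tsv`/`.txt` = tab, otherwise comma) unless given.
#'
#' @param path path to the file.
#' @param omicsName label for the layer.
#' @param sep field delimiter; `NULL` (default) auto-detects from extension.
#' @return an [OmicsMatrix-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,g1,g2", "S1,1,2", "S2,NA,4"), f)
#' readOmicsMatrix(f, "mRNA")
#' @export
readOmicsMatrix <- function(path, omicsName = "omics", sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("", "NA", "NaN"),
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop("matrix file needs an ID column plus >= 1 feature")
  ids <- df[[1L]]
  feats <- colnames(df)[-1L]
  dupS <- unique(ids[duplicated(ids)])
  if (length(dupS))
    stop("duplicate sample IDs: ", paste(dupS, collapse = ", "))
  dupF <- unique(feats[duplicated(feats)])
  if (length(dupF))
    stop("duplicate feature IDs: ", paste(dupF, collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), length(feats),
                 dimnames = list(ids, feats))
  for (j in seq_along(feats)) {
    raw <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d (sample '%s'), column '%s'",
                   raw[bad[1L]], bad[1L], ids[bad[1L]], feats[j]))
    vals[, j] <- num
  }
  OmicsMatrix(vals, omicsName)
}

#' Write an omics matrix as delimited text
#'
#' Inverse of [readOmicsMatrix()]: first column `id`, then one column per
#' feature. Finite values round-trip bit-exactly (written at full
#' precision); missing values are written as `NA`.
#'
#' @param x an [OmicsMatrix-class].
#' @param path output path; extension picks the delimiter unless `sep` given.
#' @param sep field delimiter; `NULL` auto-detects as in [readOmicsMatrix()].
#' @return `path`, invisibly.
#' @export
writeOmicsMatrix <- function(x, path, sep = NULL) {
  stopifnot(is(x, "OmicsMatrix"))
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  vals <- assayValues(x)
  chr <- matrix(vapply(vals, function(v)
    if (is.na(v)) "NA" else sprintf("%.17g", v), character(1L)),
    nrow = nrow(vals))
  lines <- c(paste(c("id", colnames(vals)), collapse = sep),
             vapply(seq_len(nrow(vals)), function(i)
               paste(c(rownames(vals)[i], chr[i, ]), collapse = sep),
               character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table
#'
#' Expects a CSV with at least the columns `sample_id`, `survival_time`
#' (days, finite and non-negative) and `event` (1 = death observed,
#' 0 = censored). One record per sample.
#'
#' @param path path to the CSV file.
#' @return a validated `data.frame`.
#' @export
readClinicalTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(sample_id = "character"))
  validateClinical(df)
}

#' Validate a clinical table
#'
#' @param df data.frame with columns `sample_id`, `survival_time`, `event`.
#' @return the validated data.frame (sample_id coerced to character).
#' @export
validateClinical <- function(df) {
  need <- c("sample_id", "survival_time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("clinical table has duplicate sample IDs")
  if (any(!is.finite(df$survival_time)) || any(df$survival_time < 0))
    stop("survival_time must be finite and non-negative")
  if (!all(df$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (death observed)")
  df
}

#' Derive binary risk labels from survival data
#'
#' Labels a sample high risk (1) if death was observed at or before
#' `horizonDays`, and low risk (0) if it survived past the horizon
#' (regardless of the event indicator). Samples censored at or before the
#' horizon carry no information about horizon survival and are excluded.
#'
#' The horizon defaults to 3 years (1095 days); survival-risk dichotomies
#' depend on this choice, so it is explicit and tunable.
#'
#' @param clinical clinical data.frame (see [readClinicalTable()]).
#' @param horizonDays positive horizon in days.
#' @return list with `labels` (named 0/1 integer vector, names = sample IDs)
#'   and `excluded` (IDs of indeterminate, censored-early samples).
#' @examples
#' cl <- data.frame(sample_id = c("a", "b", "c"),
#'                  survival_time = c(400, 2000, 500), event = c(1, 0, 0))
#' deriveRiskLabels(cl, 1095)
#' @export
deriveRiskLabels <- function(clinical, horizonDays = 1095) {
  clinical <- validateClinical(clinical)
  stopifnot(length(horizonDays) == 1L, horizonDays > 0)
  hi <- clinical$event == 1 & clinical$survival_time <= horizonDays
  lo <- clinical$survival_time > horizonDays
  keep <- hi | lo
  if (!any(keep))
    stop("no labelable samples at horizon ", horizonDays)
  labels <- as.integer(hi[keep])
  names(labels) <- clinical$sample_id[keep]
  list(labels = labels, excluded = clinical$sample_id[!keep])
}
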