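## Cohort CSV I/O.
##
## Wide dialect columns:  mouse_id,line,sex,genotype,bw6,bw8,...,bw48
## Long dialect columns:  mouse_id,line,sex,genotype,week,weight_g
## UTF-8, header row required. write -> read round-trips exactly (weights
## are written with full precision; up to 4 decimals are typical).

.requireCols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    ccwStop("ccweight_invalid_data", "%s: missing required column(s): %s",
            path, paste(miss, collapse = ", "))
}

.parseWeights <- function(x, rows, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad))
    ccwStop("ccweight_invalid_data",
            "%s: non-numeric weight at data row %s", path,
            paste(rows[bad], collapse = ", "))
  out
}

.warnIncomplete <- function(bw) {
  inc <- colnames(bw)[colSums(is.na(bw)) > 0L]
  if (length(inc))
    warning(sprintf("%d incomplete record(s) (missing weights): %s",
                    length(inc), paste(inc, collapse = ", ")),
            call. = FALSE)
}

#' Read a cohort from CSV
#'
#' @param path CSV file path.
#' @param dialect `"wide"` (one `bw<week>` column per scheduled week) or
#'   `"long"` (one row per mouse x week).
#' @param schedule Optional integer schedule; by default it is inferred from
#'   the `bw*` columns (wide) or the observed weeks (long).
#' @return A [BWCohort-class]. Records with missing weights load with a
#'   warning and are flagged incomplete.
#' @export
#' @examples
#' co <- simulateCohort(TrajectorySimParam(micePerCell = 1L, seed = 1L))
#' f <- tempfile(fileext = ".csv")
#' writeCohort(co, f, dialect = "wide")
#' co2 <- readCohort(f, dialect = "wide")
readCohort <- function(path, dialect = c("wide", "long"), schedule = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    ccwStop("ccweight_invalid_data", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  .requireCols(df, c("mouse_id", "line", "sex", "genotype"), path)
  if (dialect == "wide") {
    bwCols <- grep("^bw[0-9]+$", names(df), value = TRUE)
    if (!length(bwCols))
      ccwStop("ccweight_invalid_data", "%s: no bw<week> columns found", path)
    weeks <- sort(as.integer(sub("^bw", "", bwCols)))
    if (!is.null(schedule)) weeks <- checkScheduleWeeks(schedule)
    bw <- sapply(paste0("bw", weeks), function(cn)
      .parseWeights(df[[cn]], seq_len(nrow(df)), path))
    bw <- matrix(bw, ncol = length(weeks),
                 dimnames = list(df$mouse_id, paste0("wk", weeks)))
    wm <- t(bw)
    co <- BWCohort(wm, line = df$line, sex = df$sex,
                   genotype = .parseGenotype(df$genotype),
                   mouseIds = df$mouse_id, schedule = weeks)
  } else {
    .requireCols(df, c("week", "weight_g"), path)
    weeks <- if (is.null(schedule)) sort(unique(as.integer(df$week)))
             else checkScheduleWeeks(schedule)
    w <- .parseWeights(df$weight_g, seq_len(nrow(df)), path)
    meta <- unique(df[, c("mouse_id", "line", "sex", "genotype")])
    if (anyDuplicated(meta$mouse_id))
      ccwStop("ccweight_invalid_data",
              "%s: inconsistent line/sex/genotype for mouse_id %s", path,
              paste(meta$mouse_id[duplicated(meta$mouse_id)], collapse = ", "))
    key <- paste(df$mouse_id, df$week)
    if (anyDuplicated(key))
      ccwStop("ccweight_invalid_data",
              "%s: duplicate mouse_id x week row(s): %s", path,
              paste(unique(key[duplicated(key)]), collapse = ", "))
    wm <- matrix(NA_real_, nrow = length(weeks), ncol = nrow(meta),
                 dimnames = list(paste0("wk", weeks), meta$mouse_id))
    ri <- match(as.integer(df$week), weeks)
    ci <- match(df$mouse_id, meta$mouse_id)
    wm[cbind(ri, ci)] <- w
    co <- BWCohort(wm, line = meta$line, sex = meta$sex,
                   genotype = .parseGenotype(meta$genotype),
                   mouseIds = meta$mouse_id, schedule = weeks)
  }
  .warnIncomplete(weightMatrix(co))
  co
}

.parseGenotype <- function(x) {
  bad <- setdiff(unique(x), c("0", "1", 0L, 1L))
  if (length(bad))
    ccwStop("ccweight_invalid_data", "invalid genotype code: %s",
            paste(bad, collapse = ", "))
  as.integer(x)
}

#' Write a cohort to CSV
#'
#' Inverse of [readCohort()]; the wide dialect writes one `bw<week>` column
#' per scheduled week in schedule order, the long dialect one row per
#' mouse x week (missing weights are written as empty fields in wide form
#' and omitted in long form).
#'
#' @param cohort A [BWCohort-class].
#' @param path Output CSV path.
#' @param dialect `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  weeks <- schedule(cohort)
  bw <- weightMatrix(cohort)
  base <- data.frame(mouse_id = mouseIds(cohort), line = mouseLine(cohort),
                     sex = mouseSex(cohort), genotype = mouseGenotype(cohort),
                     stringsAsFactors = FALSE)
  if (dialect == "wide") {
    wdf <- as.data.frame(t(bw))
    names(wdf) <- paste0("bw", weeks)
    out <- cbind(base, wdf)
  } else {
    out <- data.frame(
      base[rep(seq_len(nrow(base)), each = length(weeks)), , drop = FALSE],
      week = rep(weeks, times = nrow(base)),
      weight_g = as.vector(bw), stringsAsFactors = FALSE)
    out <- out[!is.na(out$weight_g), , drop = FALSE]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
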