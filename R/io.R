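# CSV dialects: comma-separated, UTF-8, dot decimal, header required.
# Clinical: patient_id,age,menopausal_status,stage,ca125,treatment,
#           tfip_months,status
# Transitions: run_id,patient_id,protein,peptide,fragment,channel,area,rt

#' Read and validate a clinical cohort CSV
#'
#' Derives the response group from the treatment-free interval to platinum
#' (TFIp): `< 6` months is chemoresistant, `> 6` chemosensitive, a missing
#' TFIp means no recurrence (chemosensitive_no_recurrence). A TFIp of
#' exactly 6 months belongs to neither group and is refused with an error
#' rather than silently assigned. Rows failing validation are collected in
#' the `"invalid_rows"` attribute, not silently dropped; a missing CA125
#' only flags the record (it is excluded from clinical models downstream).
#'
#' @param path CSV path with header `patient_id,age,menopausal_status,
#'   stage,ca125,treatment,tfip_months,status` (case-insensitive).
#' @return Validated cohort `data.frame` with derived `group` column and
#'   logical `ca125_missing`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  req <- c("patient_id", "age", "menopausal_status", "stage", "ca125",
           "treatment", "tfip_months", "status")
  if (!all(req %in% names(df))) {
    stop("clinical CSV lacks column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(df$tfip_months) & df$tfip_months == 6)) {
    stop("TFIp of exactly 6 months is assigned to neither response group",
         " (rows: ",
         paste(which(!is.na(df$tfip_months) & df$tfip_months == 6),
               collapse = ", "), ")", call. = FALSE)
  }
  bad <- !(df$menopausal_status %in% c("pre", "post")) |
    !(df$treatment %in% c("surgery", "neoadjuvant")) |
    !(df$status %in% c("alive", "dead")) |
    is.na(df$age) | df$age <= 0
  df$group <- ifelse(is.na(df$tfip_months), "chemosensitive_no_recurrence",
                     ifelse(df$tfip_months < 6, "chemoresistant",
                            "chemosensitive"))
  df$ca125_missing <- is.na(df$ca125)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "invalid_rows") <- df[bad, , drop = FALSE]
  if (any(bad)) {
    warning(sum(bad), " clinical row(s) failed validation; see",
            " attr(, 'invalid_rows')", call. = FALSE)
  }
  out
}

#' Write a clinical cohort CSV
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @export
write_clinical <- function(cohort, path) {
  cols <- c("patient_id", "age", "menopausal_status", "stage", "ca125",
            "treatment", "tfip_months", "status")
  utils::write.csv(cohort[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a transition-level CSV
#'
#' Accepts the native dialect (header `run_id,patient_id,protein,peptide,
#' fragment,channel,area,rt`) or a foreign export (e.g. a Skyline
#' transition report) through `column_map`, a named character vector
#' mapping native names to the file's column names. Channel tokens are
#' normalized to lower case and must be `endogenous`/`standard` (`light`/
#' `heavy` are accepted as synonyms).
#'
#' @param path CSV path.
#' @param column_map Optional named character vector, e.g.
#'   `c(run_id = "Replicate Name", ...)`.
#' @return Validated transition `data.frame`.
#' @export
read_transitions <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("run_id", "patient_id", "protein", "peptide", "fragment",
           "channel", "area", "rt")
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(df))
    if (length(missing_src)) {
      stop("column_map refers to absent column(s): ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    df <- df[, unname(column_map[req]), drop = FALSE]
    names(df) <- req
  } else {
    names(df) <- tolower(names(df))
  }
  if (!all(req %in% names(df))) {
    stop("transition CSV lacks column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  }
  df <- df[, req, drop = FALSE]
  if (nrow(df) == 0L) return(df)
  df$channel <- tolower(df$channel)
  df$channel[df$channel == "light"] <- "endogenous"
  df$channel[df$channel == "heavy"] <- "standard"
  bad_chan <- !df$channel %in% c("endogenous", "standard")
  if (any(bad_chan)) {
    stop("unknown channel token(s): ",
         paste(unique(df$channel[bad_chan]), collapse = ", "),
         call. = FALSE)
  }
  neg <- which(df$area < 0)
  if (length(neg)) {
    stop("negative area at row(s): ", paste(neg, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$run_id, df$peptide, df$fragment, df$channel, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (run, peptide, fragment, channel) rows", call. = FALSE)
  }
  df
}

#' Write a transition-level CSV
#' @param tt Transition data.frame.
#' @param path Output path.
#' @export
write_transitions <- function(tt, path) {
  cols <- c("run_id", "patient_id", "protein", "peptide", "fragment",
            "channel", "area", "rt")
  out <- as.data.frame(tt)[, cols]
  # %.17g guarantees an exact numeric round trip through the text file
  out$area <- sprintf("%.17g", out$area)
  out$rt <- sprintf("%.17g", out$rt)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
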