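# half-up rounding to `digits` decimals (base round() is half-even)
roundHalfUp <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Read RECIST response records from CSV
#'
#' Expected columns: \code{patient_id}, \code{cycle_checkpoint},
#' \code{category} (one of CR, PR, SD, PD).
#'
#' @param path CSV file.
#' @return data.frame of response records.
#' @seealso [tallyResponses()]
#' @export
readResponseRecords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "cycle_checkpoint", "category")
  if (!all(need %in% names(df)))
    stop("response CSV must have columns: ", paste(need, collapse = ", "))
  df$category <- toupper(trimws(df$category))
  df
}

#' Tally RECIST response categories at a treatment checkpoint
#'
#' Counts the evaluable patients in each RECIST class (CR complete
#' remission, PR partial remission, SD stable disease, PD progressive
#' disease) at the given cycle checkpoint and computes each class's
#' percentage of the evaluable total, rounded half-up to one decimal
#' (so a class can print as e.g. 59.3 or, when the decimal is zero, as
#' the integer 37). The tally is invariant to record order; duplicate
#' patients at a checkpoint are an error.
#'
#' @param records data.frame with columns \code{patient_id},
#'   \code{cycle_checkpoint}, \code{category} (see
#'   [readResponseRecords()]).
#' @param checkpoint integer cycle checkpoint to tally (e.g. 3 or 6).
#' @return an [EfficacyTally-class].
#' @examples
#' rec <- data.frame(patient_id = sprintf("P%02d", 1:27),
#'                   cycle_checkpoint = 3,
#'                   category = rep(c("PR", "SD", "PD"), c(1, 16, 10)))
#' tallyResponses(rec, 3)
#' @export
tallyResponses <- function(records, checkpoint) {
  stopifnot(is.data.frame(records))
  cats <- c("CR", "PR", "SD", "PD")
  rec <- records[records$cycle_checkpoint == checkpoint, , drop = FALSE]
  if (nrow(rec) == 0)
    stop("no records at checkpoint ", checkpoint)
  if (!all(rec$category %in% cats))
    stop("unknown response category: ",
         paste(setdiff(rec$category, cats), collapse = ", "))
  dup <- rec$patient_id[duplicated(rec$patient_id)]
  if (length(dup))
    stop("duplicate patient at checkpoint ", checkpoint, ": ",
         paste(unique(dup), collapse = ", "))
  counts <- vapply(cats, function(k) sum(rec$category == k), integer(1))
  n <- nrow(rec)
  new("EfficacyTally", checkpoint = as.integer(checkpoint),
      n = as.integer(n), counts = counts,
      percentages = roundHalfUp(counts / n * 100, 1))
}

setMethod("show", "EfficacyTally", function(object) {
  cat(sprintf("EfficacyTally: %d evaluable patients after %d cycles\n",
              object@n, object@checkpoint))
  for (k in names(object@counts)) {
    pct <- object@percentages[[k]]
    pctStr <- if (pct == round(pct)) sprintf("%d%%", as.integer(pct))
              else sprintf("%.1f%%", pct)
    cat(sprintf("  %s: %2d (%s)\n", k, object@counts[[k]], pctStr))
  }
})
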