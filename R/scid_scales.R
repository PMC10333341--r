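# ---- Symptom subscale scoring ----------------------------------------------

#' Subscale specifications
#'
#' Four symptom subscales scored by summing item responses on a 1-3 scale:
#' re-experiencing (10 items, range 10-30), avoidance (14, 14-42),
#' hyperarousal (10, 10-30), negative thoughts (8, 8-24).
#'
#' @return Data frame with `scale`, `prefix`, `n_items`, `min_score`,
#'   `max_score`.
#' @export
subscale_spec <- function() {
  d <- subscale_defs()
  d$min_score <- d$n_items * 1L
  d$max_score <- d$n_items * 3L
  d
}

#' Score one subscale
#'
#' The continuous score is the plain sum of the item responses; by
#' construction it lies in `[n_items, 3 * n_items]`. No imputation: a
#' missing or out-of-range item is an error naming the item.
#'
#' @param items Integer responses in 1..3.
#' @param scale One of `"reexperiencing"`, `"avoidance"`,
#'   `"hyperarousal"`, `"negative_thoughts"`.
#' @return Integer score.
#' @export
score_subscale <- function(items, scale) {
  spec <- subscale_spec()
  row <- spec[spec$scale == scale, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown scale '", scale, "'; expected one of ",
         paste(spec$scale, collapse = ", "))
  if (length(items) != row$n_items)
    stop(scale, " requires ", row$n_items, " items, got ", length(items))
  if (anyNA(items))
    stop("missing response at item ", which(is.na(items))[1L])
  bad <- which(items < 1L | items > 3L | items != round(items))
  if (length(bad))
    stop("response out of range 1..3 at item ", bad[1L],
         " (value ", items[bad[1L]], ")")
  as.integer(sum(items))
}

#' Score all subscales for an item-level table
#'
#' Expects columns `re01..re10`, `av01..av14`, `hy01..hy10`, `nt01..nt08`
#' plus `subject_id`. Subjects whose items fail validation are collected
#' into an error report; the rest are scored.
#'
#' @param items_table Data frame of item responses.
#' @return Data frame with `subject_id` and the four subscale scores. If
#'   any subject failed, the failures are attached as attribute `errors`
#'   (data frame `subject_id`, `message`) and a warning is raised.
#' @export
score_all <- function(items_table) {
  spec <- subscale_spec()
  need <- unlist(lapply(seq_len(nrow(spec)), function(k)
    sprintf("%s%02d", spec$prefix[k], seq_len(spec$n_items[k]))))
  miss <- setdiff(need, names(items_table))
  if (length(miss))
    stop("item table missing columns: ", paste(miss, collapse = ", "))
  out <- data.frame(subject_id = items_table$subject_id,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(spec))) out[[spec$scale[k]]] <- NA_integer_
  errs <- list()
  for (i in seq_len(nrow(items_table))) {
    res <- tryCatch({
      for (k in seq_len(nrow(spec))) {
        cols <- sprintf("%s%02d", spec$prefix[k], seq_len(spec$n_items[k]))
        out[i, spec$scale[k]] <- score_subscale(
          as.integer(unlist(items_table[i, cols])), spec$scale[k])
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      out[i, spec$scale] <- NA_integer_
      errs[[length(errs) + 1L]] <- data.frame(
        subject_id = items_table$subject_id[i], message = res,
        stringsAsFactors = FALSE)
    }
  }
  if (length(errs)) {
    attr(out, "errors") <- do.call(rbind, errs)
    warning(length(errs), " subject(s) failed scoring; see attr(, 'errors')")
  }
  out
}
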