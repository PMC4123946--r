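#' @name correct_disallowed_transitions
#' @title Temporal-consistency correction of disallowed transitions
#'
#' @description
#' Over multi-year observation gaps a pixel labelled SF or NF cannot
#' plausibly return to mature forest: regrowth old enough to be confused
#' with MF is, by definition, secondary forest. Scanning date pairs in
#' chronological order, any cell labelled SF or NF at one date and MF at the
#' next is relabelled SF (never NF: spectral confusion between NF and MF is
#' assumed unlikely). The scan is sequential, so a correction at date k
#' feeds the comparison at date k+1 and chains of spurious MF collapse to
#' SF in a single pass (equivalent to iterating to fixpoint).
#'
#' NODATA dates are skipped: the comparison uses the most recent non-NODATA
#' label for the pixel. WATER never participates.
#'
#' @param stack a `classified_stack`.
#' @return list with `stack` (corrected `classified_stack`) and
#'   `corrections`: data frame (date, n_corrected, area_ha) per date.
#' @export
correct_disallowed_transitions <- function(stack) {
  stopifnot(inherits(stack, "classified_stack"))
  nd <- n_dates(stack)
  dm <- dim(stack$codes)
  lab <- matrix(stack$codes, nrow = dm[1] * dm[2], ncol = nd)
  res <- correct_label_matrix(lab)
  stack$codes <- array(res$labels, dim = dm)
  data_frame <- data.frame(
    date = format_ymd(stack$dates),
    n_corrected = res$n_corrected,
    area_ha = res$n_corrected * stack$pixel_area_ha,
    stringsAsFactors = FALSE
  )
  list(stack = stack, corrections = data_frame)
}

#' Core correction on a label matrix
#'
#' Operates on an integer matrix with one row per pixel and one column per
#' date (chronological). Exposed separately so the rule can be checked
#' exhaustively on small label sequences.
#'
#' @param labels integer matrix of class codes, pixels x dates.
#' @return list with `labels` (corrected matrix) and `n_corrected`
#'   (integer vector per date).
#' @export
correct_label_matrix <- function(labels) {
  storage.mode(labels) <- "integer"
  nd <- ncol(labels)
  mf <- LCC_CODES[["MF"]]; nf <- LCC_CODES[["NF"]]; sf <- LCC_CODES[["SF"]]
  n_corrected <- integer(nd)
  last <- rep(NA_integer_, nrow(labels))
  for (k in seq_len(nd)) {
    cur <- labels[, k]
    fix <- !is.na(last) & (last == nf | last == sf) & cur == mf
    if (any(fix)) {
      cur[fix] <- sf
      labels[, k] <- cur
      n_corrected[k] <- sum(fix)
    }
    obs <- cur == mf | cur == nf | cur == sf
    last[obs] <- cur[obs]
  }
  list(labels = labels, n_corrected = n_corrected)
}

#' Fixpoint oracle for the correction rule
#'
#' Independent reference implementation: in each pass, every disallowed
#' transition present in the pass-start matrix (most recent non-NODATA label
#' SF or NF followed by MF) is fixed simultaneously; passes repeat until no
#' change. Used in tests to show the one-pass sequential scan reaches the
#' same fixpoint.
#'
#' @param labels integer matrix of class codes, pixels x dates.
#' @return corrected integer matrix.
#' @export
correct_fixpoint_oracle <- function(labels) {
  storage.mode(labels) <- "integer"
  mf <- LCC_CODES[["MF"]]; nf <- LCC_CODES[["NF"]]; sf <- LCC_CODES[["SF"]]
  nd <- ncol(labels)
  repeat {
    # most recent thematic label strictly before each date, at pass start
    prev <- matrix(NA_integer_, nrow(labels), nd)
    last <- rep(NA_integer_, nrow(labels))
    for (k in seq_len(nd)) {
      prev[, k] <- last
      cur <- labels[, k]
      obs <- cur == mf | cur == nf | cur == sf
      last[obs] <- cur[obs]
    }
    fix <- !is.na(prev) & (prev == nf | prev == sf) & labels == mf
    if (!any(fix)) break
    labels[fix] <- sf
  }
  labels
}
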