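## Lead-to-view partitioning. A "view" is a fixed subset of leads (here a
## pair) processed by one shared-structure encoder branch; a 12-lead record
## yields M = 6 two-lead views.

#' Define a lead-to-view partition scheme
#'
#' Built-in schemes pair consecutive leads in standard order:
#' `pairs_12` = (I,II), (III,aVR), (aVL,aVF), (V1,V2), (V3,V4), (V5,V6);
#' `pairs_8` pairs leads 1..8 the same way. `custom` takes an explicit
#' partition as a list of 1-based lead-index vectors.
#'
#' @param scheme `"pairs_12"`, `"pairs_8"`, or `"custom"`.
#' @param partition for `custom`: list of integer vectors partitioning
#'   `1:n_leads`.
#' @return an object of class `view_scheme`.
#' @export
view_scheme <- function(scheme = c("pairs_12", "pairs_8", "custom"),
                        partition = NULL) {
  scheme <- match.arg(scheme)
  partition <- switch(scheme,
    pairs_12 = lapply(seq_len(6L), function(i) c(2L * i - 1L, 2L * i)),
    pairs_8  = lapply(seq_len(4L), function(i) c(2L * i - 1L, 2L * i)),
    custom   = {
      if (is.null(partition) || !is.list(partition))
        stop("custom scheme requires `partition` as a list of index vectors",
             call. = FALSE)
      lapply(partition, as.integer)
    })
  structure(list(scheme_name = scheme, partition = partition,
                 n_leads = max(unlist(partition))),
            class = "view_scheme")
}

#' Split an ECG recording into views
#'
#' Every lead index appears in exactly one view; all views share the signal
#' length L. For 12-lead input under `pairs_12` this yields M = 6 views of
#' 2 leads each.
#'
#' @param record an [ecg_record()].
#' @param scheme a [view_scheme()] or a scheme name.
#' @return a `view_set`: list with `views` (list of `n_v x L` matrices) and
#'   `scheme_name`.
#' @export
split_views <- function(record, scheme = "pairs_12") {
  stopifnot(inherits(record, "ecg_record"))
  if (!inherits(scheme, "view_scheme")) scheme <- view_scheme(scheme)
  idx <- unlist(scheme$partition)
  n_leads <- nrow(record$signals)
  if (anyDuplicated(idx))
    stop("partition repeats lead indices: ",
         paste(unique(idx[duplicated(idx)]), collapse = ", "), call. = FALSE)
  missing <- setdiff(seq_len(n_leads), idx)
  extra <- setdiff(idx, seq_len(n_leads))
  if (length(missing) || length(extra))
    stop("partition must cover each lead exactly once; missing: {",
         paste(missing, collapse = ", "), "}, out of range: {",
         paste(extra, collapse = ", "), "}", call. = FALSE)
  views <- lapply(scheme$partition, function(ix)
    record$signals[ix, , drop = FALSE])
  structure(list(views = views, scheme_name = scheme$scheme_name,
                 partition = scheme$partition),
            class = "view_set")
}

#' Reassemble the original signal matrix from a view set
#' @param vs a `view_set` from [split_views()].
#' @return the leads x samples matrix in original lead order.
#' @export
unsplit_views <- function(vs) {
  stopifnot(inherits(vs, "view_set"))
  idx <- unlist(vs$partition)
  m <- do.call(rbind, vs$views)
  m[order(idx), , drop = FALSE]
}
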