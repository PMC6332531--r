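#' Module-vs-complex overlap table
#'
#' Integer matrix `t` with `t[i, j]` the number of proteins shared by
#' predicted module i and reference complex j.
#'
#' @param predicted,reference A `module_set` / `complex_catalog`, a tibble
#'   with a `members` list-column, or a plain list of character vectors.
#' @return Integer matrix, predicted modules in rows.
#' @export
overlap_table <- function(predicted, reference) {
  pr <- as_member_list(predicted)
  rf <- as_member_list(reference)
  tt <- matrix(0L, length(pr), length(rf))
  for (j in seq_along(rf)) {
    tt[, j] <- vapply(pr, function(mi) length(intersect(mi, rf[[j]])),
                      integer(1))
  }
  tt
}

as_member_list <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("members" %in% names(x))
    return(x$members)
  }
  stopifnot(is.list(x))
  x
}

#' Clustering-wise sensitivity, positive predictive value and accuracy
#'
#' With overlap table `t` (r predicted modules by s reference complexes)
#' and `w_j` the size of reference complex j:
#'
#'   `Sn  = sum_j max_i t_ij / sum_j w_j`
#'   `PPV = sum_i max_j t_ij / sum_i sum_j t_ij`
#'   `Acc = sqrt(Sn * PPV)`
#'
#' Sn asks how completely the best-matching module covers each complex;
#' PPV how exclusively each module maps to a single complex.  A predicted
#' module intersecting no reference complex contributes nothing to either.
#' If no module intersects any complex, PPV is defined as 0.  Reference
#' complexes are never shrunk to the predicted network's proteins: `w_j`
#' is the full complex size, the conservative choice.
#'
#' @inheritParams overlap_table
#' @return One-row tibble: `sn`, `ppv`, `acc`, `n_predicted`,
#'   `n_reference`.
#' @export
sn_ppv_acc <- function(predicted, reference) {
  pr <- as_member_list(predicted)
  rf <- as_member_list(reference)
  if (length(pr) == 0) rlang::abort("no predicted modules")
  if (length(rf) == 0) rlang::abort("no reference complexes")
  tt <- overlap_table(pr, rf)
  w <- lengths(rf)
  sn <- sum(apply(tt, 2, max)) / sum(w)
  tot <- sum(tt)
  ppv <- if (tot == 0) 0 else sum(apply(tt, 1, max)) / tot
  tibble::tibble(
    sn = sn, ppv = ppv, acc = geometric_accuracy(sn, ppv),
    n_predicted = length(pr), n_reference = length(rf)
  )
}

#' Geometric accuracy from sensitivity and PPV
#'
#' `Acc = sqrt(Sn * PPV)`, the geometric mean balancing coverage of the
#' reference complexes against module specificity.
#'
#' @param sn,ppv Values in \[0, 1\] (vectorized).
#' @return `sqrt(sn * ppv)`.
#' @export
geometric_accuracy <- function(sn, ppv) {
  stopifnot(all(sn >= 0 & sn <= 1), all(ppv >= 0 & ppv <= 1))
  sqrt(sn * ppv)
}

#' Score predicted interactions against labeled edge sets
#'
#' Confusion-matrix scores for an edge-level classifier: every edge of
#' the labeled universe is positive or negative; an edge is "called" if
#' it appears in `predicted`.  Pairs are compared without orientation.
#' MCC is defined as 0 when any confusion-matrix marginal is zero.
#'
#' @param predicted A `ppi_network` or 2-column data frame of predicted
#'   edges.
#' @param positive,negative Labeled edge sets (same forms); they must be
#'   disjoint.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `precision`, `recall`,
#'   `mcc`.
#' @export
edge_prediction_scores <- function(predicted, positive, negative) {
  key <- function(x) {
    if (inherits(x, "ppi_network")) x <- x$edges
    a <- pmin(as.character(x[[1]]), as.character(x[[2]]))
    b <- pmax(as.character(x[[1]]), as.character(x[[2]]))
    unique(paste0(a, "\r", b))
  }
  pred <- key(predicted)
  pos <- key(positive)
  neg <- key(negative)
  if (length(intersect(pos, neg)) > 0) {
    rlang::abort("positive and negative edge sets overlap")
  }
  tp <- length(intersect(pred, pos))
  fn <- length(setdiff(pos, pred))
  fp <- length(intersect(pred, neg))
  tn <- length(setdiff(neg, pred))
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = precision, recall = recall, mcc = mcc)
}
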