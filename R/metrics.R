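#' One-to-one instance matching by lenient IoU
#'
#' Computes pairwise IoU between predicted and ground-truth instances, keeps
#' candidate pairs with IoU strictly greater than the threshold, and accepts
#' them greedily in descending IoU order (ties broken by smaller gt id, then
#' smaller pred id), skipping pairs whose prediction or ground truth is
#' already matched. Each prediction matches at most one label and vice
#' versa; leftovers are false positives (predictions) and false negatives
#' (labels). The default threshold 0.25 is deliberately lenient, tolerating
#' label sets whose boundaries are cropped differently.
#'
#' @param pred,gt \code{instance_map}s of identical shape.
#' @param iou_threshold Strict lower bound on IoU, in (0, 1); default 0.25.
#' @return An object of class \code{match_result}: list with \code{pairs}
#'   (data frame \code{pred_id, gt_id, iou}), \code{unmatched_pred},
#'   \code{unmatched_gt}, \code{iou_threshold}.
#' @export
match_instances <- function(pred, gt, iou_threshold = 0.25) {
  if (!identical(dim(pred), dim(gt))) {
    stop("dimension error: pred and gt maps differ in shape")
  }
  if (iou_threshold <= 0 || iou_threshold >= 1) {
    stop("iou_threshold must be in (0, 1)")
  }
  pred_ids <- instance_ids(pred)
  gt_ids <- instance_ids(gt)
  pairs <- data.frame(pred_id = integer(), gt_id = integer(), iou = numeric())
  if (length(pred_ids) && length(gt_ids)) {
    both <- pred > 0L & gt > 0L
    if (any(both)) {
      p <- factor(pred[both], levels = pred_ids)
      g <- factor(gt[both], levels = gt_ids)
      inter <- table(p, g)
      pa <- tabulate(factor(pred[pred > 0L], levels = pred_ids),
                     nbins = length(pred_ids))
      ga <- tabulate(factor(gt[gt > 0L], levels = gt_ids),
                     nbins = length(gt_ids))
      hit <- which(inter > 0, arr.ind = TRUE)
      iou <- inter[hit] / (pa[hit[, 1]] + ga[hit[, 2]] - inter[hit])
      cand <- data.frame(pred_id = pred_ids[hit[, 1]], gt_id = gt_ids[hit[, 2]],
                         iou = as.numeric(iou))
      cand <- cand[cand$iou > iou_threshold, , drop = FALSE]
      cand <- cand[order(-cand$iou, cand$gt_id, cand$pred_id), , drop = FALSE]
      used_p <- integer(); used_g <- integer()
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        if (cand$pred_id[i] %in% used_p || cand$gt_id[i] %in% used_g) next
        keep[i] <- TRUE
        used_p <- c(used_p, cand$pred_id[i])
        used_g <- c(used_g, cand$gt_id[i])
      }
      pairs <- cand[keep, , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  structure(list(pairs = pairs,
                 unmatched_pred = setdiff(pred_ids, pairs$pred_id),
                 unmatched_gt = setdiff(gt_ids, pairs$gt_id),
                 iou_threshold = iou_threshold),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d matched pair(s), %d FP, %d FN (IoU > %g)\n",
              nrow(x$pairs), length(x$unmatched_pred), length(x$unmatched_gt),
              x$iou_threshold))
  invisible(x)
}

#' Detection metrics from a match result
#'
#' Precision = TP / (TP + FP), recall = TP / (TP + FN), F1 their harmonic
#' mean, and the mean IoU over matched (true positive) pairs. Empty
#' denominators yield 0 with a warning.
#'
#' @param match A \code{match_result}.
#' @return Named numeric vector \code{c(precision, recall, f1, mean_iou)}.
#' @export
detection_metrics <- function(match) {
  tp <- nrow(match$pairs)
  fp <- length(match$unmatched_pred)
  fn <- length(match$unmatched_gt)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("empty denominator for ", what, "; reporting 0")
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  mean_iou <- if (tp == 0) 0 else mean(match$pairs$iou)
  c(precision = precision, recall = recall, f1 = f1, mean_iou = mean_iou)
}

#' Per-class classification metrics
#'
#' Confusion matrix and per-class accuracy, positive predictive value,
#' negative predictive value and prevalence over a set of evaluated
#' (prediction, ground truth) pairs. For class c: PPV = TP / (TP + FP),
#' NPV = TN / (TN + FN), prevalence = gt count of c / total. A class absent
#' from both vectors but present in \code{classes} gets prevalence 0 and an
#' NPV whose denominator is the full population.
#'
#' @param pred_class,gt_class Character vectors of equal positive length.
#' @param classes Class list fixing row/column order; every observed class
#'   must belong to it.
#' @return List with \code{confusion} (rows = gt, cols = pred) and
#'   \code{per_class} data frame (\code{class, n_gt, prevalence, accuracy,
#'   ppv, npv}). Undefined rates (0/0) are \code{NA}.
#' @export
classification_metrics <- function(pred_class, gt_class, classes = NULL) {
  if (length(pred_class) == 0L || length(pred_class) != length(gt_class)) {
    stop("pred_class and gt_class must be non-empty and of equal length")
  }
  classes <- classes %||% sort(unique(c(pred_class, gt_class)))
  bad <- setdiff(unique(c(pred_class, gt_class)), classes)
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  gt <- factor(gt_class, levels = classes)
  pr <- factor(pred_class, levels = classes)
  confusion <- table(gt = gt, pred = pr)
  n <- length(gt_class)
  per <- lapply(classes, function(cl) {
    tp <- sum(gt == cl & pr == cl)
    fp <- sum(gt != cl & pr == cl)
    fn <- sum(gt == cl & pr != cl)
    tn <- n - tp - fp - fn
    data.frame(class = cl, n_gt = tp + fn, prevalence = (tp + fn) / n,
               accuracy = (tp + tn) / n,
               ppv = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
               npv = if (tn + fn == 0) NA_real_ else tn / (tn + fn),
               stringsAsFactors = FALSE)
  })
  list(confusion = confusion, per_class = do.call(rbind, per))
}

#' Bounded metrics for fine predictions against parent ground truth
#'
#' When ground truth carries only coarse parent labels, PPV and NPV of a
#' fine class c with parent P = mapping(c) cannot be computed directly, only
#' bounded. \code{ppv_upper} counts every prediction of c whose gt parent is
#' P as a (possibly optimistic) true positive. Over the negatives
#' (predictions != c): pairs with gt parent != P are definite true
#' negatives; pairs with gt parent P are ambiguous. \code{npv_lower} treats
#' all ambiguous negatives as false negatives; \code{npv_upper} additionally
#' credits as true negatives the ambiguous pairs predicted as a sibling of c
#' (a fine class c' != c with the same parent), since those are coherently
#' explained without any hidden c.
#'
#' @param fine_pred Character vector of fine predicted classes.
#' @param parent_gt Character vector of parent ground-truth labels.
#' @param mapping A \code{class_mapping} covering every fine predicted
#'   class.
#' @param classes Fine classes to report (default: those in the mapping's
#'   domain).
#' @return Data frame \code{class, parent, n_pred, ppv_upper, npv_lower,
#'   npv_upper} (\code{ppv_upper} is \code{NA} when c is never predicted).
#' @export
bounded_metrics <- function(fine_pred, parent_gt, mapping,
                            classes = NULL) {
  if (length(fine_pred) != length(parent_gt) || length(fine_pred) == 0L) {
    stop("fine_pred and parent_gt must be non-empty and of equal length")
  }
  pred_parent <- apply_class_mapping(fine_pred, mapping)
  classes <- classes %||% intersect(names(mapping$map), unique(fine_pred))
  n <- length(fine_pred)
  rows <- lapply(classes, function(cl) {
    P <- unname(mapping$map[[cl]])
    if (is.null(P)) stop("mapping error: no parent for class '", cl, "'")
    is_pred <- fine_pred == cl
    n_pred <- sum(is_pred)
    ppv_upper <- if (n_pred == 0) NA_real_ else
      sum(is_pred & parent_gt == P) / n_pred
    neg <- !is_pred
    n_neg <- sum(neg)
    definite_tn <- sum(neg & parent_gt != P)
    sibling_cred <- sum(neg & parent_gt == P &
                          !is.na(pred_parent) & pred_parent == P)
    npv_lower <- if (n_neg == 0) NA_real_ else definite_tn / n_neg
    npv_upper <- if (n_neg == 0) NA_real_ else (definite_tn + sibling_cred) / n_neg
    data.frame(class = cl, parent = P, n_pred = n_pred,
               ppv_upper = ppv_upper, npv_lower = npv_lower,
               npv_upper = npv_upper, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Prevalence-normalized upper-bound PPV
#'
#' Divides an upper-bound PPV by the class prevalence, giving a
#' chance-normalized score: 1 is chance level, larger is better. Undefined
#' (reported as \code{NA}) when prevalence is 0.
#'
#' @param ppv_upper,prevalence Numeric vectors (recycled).
#' @return Numeric vector of ratios.
#' @export
prevalence_normalized_ppv <- function(ppv_upper, prevalence) {
  out <- ppv_upper / prevalence
  out[prevalence <= 0] <- NA_real_
  out
}

#' Per-class detection quality (DQ+)
#'
#' The detection term of panoptic quality restricted to one class:
#' DQ+ = TP / (TP + FP/2 + FN/2) under the instance matching, where a true
#' positive is a matched pair whose prediction and ground truth agree on the
#' class (in parent mode: the gt parent label equals the parent of the
#' predicted fine class), a false positive is any other prediction of the
#' class, and a false negative is any other ground-truth instance of it.
#'
#' @param match A \code{match_result} between prediction and ground truth.
#' @param pred_class Named character vector: class per predicted instance id
#'   (names are the ids).
#' @param gt_class Named character vector: class per ground-truth instance
#'   id.
#' @param parent_mode If \code{TRUE}, \code{gt_class} holds parent labels
#'   and agreement means \code{gt == mapping(pred)} — an upper-bound DQ+.
#' @param mapping A \code{class_mapping}; required in parent mode.
#' @param classes Classes to report (default: predicted classes union fine
#'   gt classes, or the mapping domain in parent mode).
#' @param fn_mode Parent-mode false-negative attribution.
#'   \code{"optimistic"} (default) attributes every non-true-positive parent
#'   instance to a sibling fine class, so FN_c = 0 and the result is a
#'   guaranteed upper bound on the (uncomputable) fine-grained DQ+.
#'   \code{"pooled"} charges the class with every gt parent instance not
#'   matched to an agreeing prediction; this is pessimistic for classes with
#'   populous siblings and is not a bound.
#' @return Data frame \code{class, tp, fp, fn, dq_plus} (\code{dq_plus} is
#'   \code{NA} for a class with no instances on either side).
#' @export
dq_plus <- function(match, pred_class, gt_class, parent_mode = FALSE,
                    mapping = NULL, classes = NULL,
                    fn_mode = c("optimistic", "pooled")) {
  fn_mode <- match.arg(fn_mode)
  if (parent_mode && is.null(mapping)) stop("parent_mode requires a mapping")
  all_pred <- c(match$pairs$pred_id, match$unmatched_pred)
  all_gt <- c(match$pairs$gt_id, match$unmatched_gt)
  if (length(bad <- setdiff(as.character(all_pred), names(pred_class)))) {
    stop("missing predicted class for instance id(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (length(bad <- setdiff(as.character(all_gt), names(gt_class)))) {
    stop("missing ground-truth class for instance id(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  classes <- classes %||% if (parent_mode) {
    sort(unique(names(mapping$map)))
  } else {
    sort(unique(c(unname(pred_class), unname(gt_class))))
  }
  pair_pred <- pred_class[as.character(match$pairs$pred_id)]
  pair_gt <- gt_class[as.character(match$pairs$gt_id)]
  rows <- lapply(classes, function(cl) {
    target <- if (parent_mode) {
      P <- mapping$map[[cl]]
      if (is.null(P)) stop("mapping error: no parent for class '", cl, "'")
      P
    } else cl
    agree <- pair_pred == cl & pair_gt == target
    tp <- sum(agree)
    fp <- sum(pred_class == cl) - tp
    fn <- if (parent_mode && fn_mode == "optimistic") {
      # ambiguous parent instances are optimistically sibling cells, not
      # missed cells of this fine class; this is what makes the parent-mode
      # value a true upper bound on fine-grained DQ+
      0L
    } else {
      sum(gt_class == target) - tp
    }
    denom <- tp + 0.5 * fp + 0.5 * fn
    has_any <- tp + fp + fn > 0 ||
      (parent_mode && sum(gt_class == target) + sum(pred_class == cl) > 0)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               dq_plus = if (!has_any || denom == 0) NA_real_ else tp / denom,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Friedman rank test across matched blocks
#'
#' Nonparametric test for differences among k treatments over n matched
#' blocks: values are ranked within each block (ties get average ranks), the
#' chi-square statistic is computed from the column rank sums with the
#' standard tie correction, and the p-value is the upper chi-square tail on
#' k - 1 degrees of freedom.
#'
#' @param values Numeric matrix, n blocks (rows) x k treatments (columns),
#'   no missing cells, n >= 2 and k >= 2.
#' @return List with \code{statistic}, \code{df}, \code{p_value}.
#' @export
friedman_test <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("input error: missing cells are not allowed")
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("need at least 2 blocks and 2 treatments")
  R <- t(apply(values, 1L, rank))
  Rj <- colSums(R)
  stat_raw <- 12 / (n * k * (k + 1)) * sum((Rj - n * (k + 1) / 2)^2)
  # tie correction: C = 1 - sum(t^3 - t) / (n k (k^2 - 1))
  ties <- sum(apply(values, 1L, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  C <- 1 - ties / (n * k * (k^2 - 1))
  stat <- if (C <= 0) 0 else stat_raw / C
  list(statistic = stat, df = k - 1,
       p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE))
}
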