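# Independent oracles used across tests: these deliberately avoid the code
# paths they check.

# paint filled disks into an integer label matrix (later disks overwrite)
draw_disks <- function(h, w, centers, radii, ids = seq_len(nrow(centers))) {
  m <- matrix(0L, h, w)
  for (k in seq_len(nrow(centers))) {
    rr <- row(m) - centers[k, 1]; cc <- col(m) - centers[k, 2]
    m[rr^2 + cc^2 <= radii[k]^2] <- ids[k]
  }
  m
}

# brute-force pairwise IoU between two label matrices
iou_matrix_oracle <- function(pred, gt) {
  pids <- sort(unique(pred[pred > 0])); gids <- sort(unique(gt[gt > 0]))
  out <- matrix(0, length(pids), length(gids), dimnames = list(pids, gids))
  for (i in seq_along(pids)) {
    for (j in seq_along(gids)) {
      a <- pred == pids[i]; b <- gt == gids[j]
      inter <- sum(a & b)
      if (inter > 0) out[i, j] <- inter / sum(a | b)
    }
  }
  out
}

# exhaustive optimal one-to-one matching: maximize pair count, then total
# IoU, over all injective assignments with IoU strictly above the threshold
optimal_match_oracle <- function(pred, gt, thr = 0.25) {
  iou <- iou_matrix_oracle(pred, gt)
  np <- nrow(iou); ng <- ncol(iou)
  best <- list(count = -1L, total = -Inf)
  recurse <- function(i, used_g, count, total) {
    if (i > np) {
      if (count > best$count ||
          (count == best$count && total > best$total)) {
        best <<- list(count = count, total = total)
      }
      return(invisible())
    }
    recurse(i + 1L, used_g, count, total)          # leave pred i unmatched
    for (j in seq_len(ng)) {
      if (!used_g[j] && iou[i, j] > thr) {
        used_g[j] <- TRUE
        recurse(i + 1L, used_g, count + 1L, total + iou[i, j])
        used_g[j] <- FALSE
      }
    }
  }
  if (np > 0 && ng > 0) recurse(1L, rep(FALSE, ng), 0L, 0) else
    best <- list(count = 0L, total = 0)
  best
}

# textbook Friedman rank statistic with tie correction, computed directly
friedman_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- t(apply(m, 1, rank))
  Rj <- colSums(R)
  s <- 12 / (n * k * (k + 1)) * sum((Rj - n * (k + 1) / 2)^2)
  Tsum <- sum(apply(m, 1, function(r) { t <- table(r); sum(t^3 - t) }))
  C <- 1 - Tsum / (n * k * (k^2 - 1))
  if (C <= 0) 0 else s / C
}
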