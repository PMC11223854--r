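# Independent oracles, deliberately written as direct transcriptions of the
# definitions (brute force, no shared code with the implementation).

# ROC AUC as the probability that a random positive outranks a random
# negative, ties counted one half.
oracle_auc_pairwise <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Exhaustive Youden search over mid-point thresholds (plus outer sentinels),
# classifying by score >= threshold.
oracle_youden <- function(scores, truth) {
  s <- sort(unique(scores))
  cand <- c(min(s) - 1, (head(s, -1) + tail(s, -1)) / 2, s, max(s) + 1)
  best_j <- -Inf
  best_labels <- NULL
  for (th in cand) {
    pred <- as.integer(scores >= th)
    tp <- sum(pred == 1 & truth == 1); fn <- sum(pred == 0 & truth == 1)
    tn <- sum(pred == 0 & truth == 0); fp <- sum(pred == 1 & truth == 0)
    j <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_labels <- list(pred)
    } else if (abs(j - best_j) <= 1e-12) {
      best_labels <- c(best_labels, list(pred))
    }
  }
  list(J = best_j, label_sets = unique(best_labels))
}

# PR AUC by direct sweep over all distinct thresholds with step summation.
oracle_pr_auc <- function(scores, truth) {
  th <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  total <- 0
  np <- sum(truth == 1)
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & truth == 1)
    rec <- tp / np
    prec <- tp / sum(pred)
    total <- total + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  total
}

# Per-residue aggregation by explicit enumeration of the covering windows.
oracle_coverage_mean <- function(window_scores, L) {
  nw <- L - 5
  sapply(seq_len(L), function(i) {
    covering <- Filter(function(j) j <= i && i <= j + 5, seq_len(nw))
    mean(window_scores[covering])
  })
}

# Refined segment-overlap score, written independently from the published
# definition: per overlapping pair, (minov + delta)/maxov weighted by the
# reference segment length; delta capped by maxov - minov, minov and half
# of either segment length.
oracle_sov <- function(pred, truth, positive) {
  segs <- function(v) {
    out <- list()
    i <- 1
    while (i <= length(v)) {
      if (v[i] == positive) {
        j <- i
        while (j < length(v) && v[j + 1] == positive) j <- j + 1
        out[[length(out) + 1]] <- c(i, j)
        i <- j + 1
      } else i <- i + 1
    }
    out
  }
  ref <- segs(truth)
  prd <- segs(pred)
  if (length(ref) == 0) return(if (length(prd) == 0) 100 else 0)
  num <- 0
  den <- 0
  for (s1 in ref) {
    l1 <- s1[2] - s1[1] + 1
    partners <- Filter(function(s2) min(s1[2], s2[2]) >= max(s1[1], s2[1]), prd)
    if (length(partners) == 0) {
      den <- den + l1
      next
    }
    for (s2 in partners) {
      l2 <- s2[2] - s2[1] + 1
      minov <- min(s1[2], s2[2]) - max(s1[1], s2[1]) + 1
      maxov <- max(s1[2], s2[2]) - min(s1[1], s2[1]) + 1
      delta <- min(maxov - minov, minov, l1 %/% 2, l2 %/% 2)
      num <- num + (minov + delta) / maxov * l1
      den <- den + l1
    }
  }
  100 * num / den
}

# Random binary segmentation with a few runs, for SOV property tests.
random_segmentation <- function(L) {
  v <- integer(L)
  n_seg <- sample(0:3, 1)
  for (k in seq_len(n_seg)) {
    len <- sample(2:12, 1)
    if (len >= L) next
    s <- sample(seq_len(L - len + 1), 1)
    v[s:(s + len - 1)] <- 1L
  }
  v
}
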