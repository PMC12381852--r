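# Naive, independent reference implementations used to cross-check the
# package's metric battery. All are written in the most literal way
# possible and share no code with the package internals.

naive_confusion <- function(y, calls) {
  list(tp = sum(y == 1 & calls == 1), fp = sum(y == 0 & calls == 1),
       tn = sum(y == 0 & calls == 0), fn = sum(y == 1 & calls == 0))
}

naive_mcc <- function(y, calls) {
  cm <- naive_confusion(y, calls)
  den <- sqrt(cm$tp + cm$fp) * sqrt(cm$tp + cm$fn) *
    sqrt(cm$tn + cm$fp) * sqrt(cm$tn + cm$fn)
  if (den == 0) return(0)
  (cm$tp * cm$tn - cm$fp * cm$fn) / den
}

naive_precision <- function(y, calls) {
  cm <- naive_confusion(y, calls)
  if (cm$tp + cm$fp == 0) return(NA_real_)
  cm$tp / (cm$tp + cm$fp)
}

naive_recall <- function(y, calls) {
  cm <- naive_confusion(y, calls)
  if (cm$tp + cm$fn == 0) return(NA_real_)
  cm$tp / (cm$tp + cm$fn)
}

naive_f1 <- function(y, calls) {
  p <- naive_precision(y, calls); r <- naive_recall(y, calls)
  if (is.na(p) || is.na(r) || p + r == 0) return(NA_real_)
  2 * p * r / (p + r)
}

# probability that a random positive outranks a random negative,
# counting ties as 1/2 (pairwise enumeration)
naive_roc_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# average precision via explicit threshold enumeration
naive_pr_auc <- function(y, s) {
  n_pos <- sum(y == 1)
  if (n_pos == 0) return(NA_real_)
  thr <- sort(unique(s), decreasing = TRUE)
  ap <- 0; prev_rec <- 0
  for (t in thr) {
    calls <- as.integer(s >= t)
    tp <- sum(y == 1 & calls == 1)
    prec <- tp / sum(calls)
    rec <- tp / n_pos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

naive_brier <- function(y, p) sum((p - y)^2) / length(y)

naive_top2 <- function(y, s, ids, k = 2) {
  hits <- c(); n_elig <- 0
  for (mid in unique(ids)) {
    yy <- y[ids == mid]; ss <- s[ids == mid]
    if (sum(yy) == 0) next
    n_elig <- n_elig + 1
    ranked <- order(-ss, seq_along(ss))
    hits <- c(hits, any(yy[ranked[seq_len(min(k, length(ss)))]] == 1))
  }
  if (n_elig == 0) return(NA_real_)
  mean(hits)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# Monte-Carlo oracle for the limiting epistemic uncertainty of
# logit-uniform ensemble members (plug-in sample means)
mc_epistemic_max <- function(x, n = 1e6, seed = 0) {
  set.seed(seed)
  s <- 1 / (1 + exp(-runif(n, -x, x)))
  h2 <- function(p) {
    out <- numeric(length(p))
    ok <- p > 0 & p < 1
    out[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
    out
  }
  h2(mean(s)) - mean(h2(s))
}
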