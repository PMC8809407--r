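# Brute-force metric oracles: literal pair counting for the ROC area and
# literal step-curve construction for the PR area.

bruteROC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

brutePR <- function(scores, labels) {
  nPos <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  area <- 0; prevRec <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / nPos
    area <- area + (rec - prevRec) * prec
    prevRec <- rec
  }
  area
}
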