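# Shared fixtures, built in code at test time.

# deterministic toy gene FASTA in the native header dialect
writeToyFasta <- function(path, n = 3, pseudo = logical(n), seed = 99) {
  set.seed(seed)
  lines <- character()
  for (i in seq_len(n)) {
    body <- paste(sample(c("A", "C", "G", "T"), 70, replace = TRUE),
                  collapse = "")
    lines <- c(lines,
               sprintf(">g%02d|Ala|AGC|pseudo=%d", i, as.integer(pseudo[i])),
               paste0(body, "CCA"))
  }
  writeLines(lines, path)
  path
}

# brute-force reference enumeration: every (gene, k) by direct slicing
bruteTruncations <- function(matureByGene, K) {
  out <- list()
  for (g in sort(names(matureByGene))) {
    s <- matureByGene[[g]]
    for (k in 0:K)
      out[[sprintf("%s::miss%d", g, k)]] <- substr(s, 1, nchar(s) - k)
  }
  out
}

# draw a disk mask into a matrix
paintDisk <- function(img, cx, cy, r, value = 1) {
  ri <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  ci <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  img[(ri - cx)^2 + (ci - cy)^2 <= r^2] <- value
  img
}

# brute-force BH step-up, independent of stats::p.adjust
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  pmin(adj, 1)[order(o)]
}
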