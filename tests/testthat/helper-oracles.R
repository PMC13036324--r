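# Independent oracles used across the suite.  These deliberately take
# different computational routes than the package implementations.

# RED by brute force: full node-distance matrix + descendant-tip sets
red_oracle <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  D <- ape::dist.nodes(tree)
  desc <- phangorn::Descendants(tree, (n + 1):(n + m), type = "tips")
  mean_leaf <- function(node) {
    if (node <= n) return(0)
    mean(D[node, desc[[node - n]]])
  }
  out <- rep(NA_real_, n + m)
  out[n + 1] <- 0
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1]; ch <- edges[i, 2]; d <- lens[i]
    if (ch <= n) {
      out[ch] <- 1
    } else {
      u <- d + mean_leaf(ch)
      out[ch] <- out[p] + (d / u) * (1 - out[p])
    }
  }
  out
}

# elementwise Bray-Curtis, written independently of bray_curtis()
bc_oracle <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  num / den
}

# exhaustive ungapped scan (one strand) returning mismatch counts of
# every qualifying alignment position
brute_scan <- function(pattern, subject, max_mm) {
  w <- nchar(pattern)
  L <- nchar(subject)
  if (L < w) return(integer(0))
  pc <- strsplit(pattern, "")[[1]]
  mm <- integer(0)
  for (s in seq_len(L - w + 1)) {
    d <- sum(strsplit(substr(subject, s, s + w - 1), "")[[1]] != pc)
    if (d <= max_mm) mm <- c(mm, d)
  }
  mm
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# window counting by explicit enumeration
window_count_brute <- function(L, window = 30, step = 15) {
  k <- 0L
  s <- 0L
  while (s + window <= L) {
    k <- k + 1L
    s <- s + step
  }
  k
}

expect_same_files <- function(dir1, dir2) {
  f1 <- sort(list.files(dir1))
  expect_identical(f1, sort(list.files(dir2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     info = paste("file differs:", f))
  }
}
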