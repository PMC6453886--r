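# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops and full enumeration, used to freeze expected values.

## O(m^2) Benjamini-Hochberg: adj_(i) = min over j >= i of (m/j) p_(j).
bruteBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m)
      best <- min(best, m / j * p[ord[j]])
    adj[ord[i]] <- min(1, best)
  }
  adj
}

## Exact two-sided Mann-Whitney p by enumeration over all C(n1+n2, n1)
## assignments of the pooled (tie-free) values to group A.
enumMWp <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a); n <- length(pool)
  r <- rank(pool)
  uOf <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  uObs <- uOf(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, uOf)
  pLo <- mean(us <= uObs)
  pHi <- mean(us >= uObs)
  min(1, 2 * min(pLo, pHi))
}

## Does every composition of db double bonds over nChains chains force some
## chain to carry >= 2? (exhaustive enumeration of compositions)
brutePufa <- function(db, nChains) {
  if (nChains == 1) return(db >= 2)
  splits <- if (nChains == 2) {
    lapply(0:db, function(i) c(i, db - i))
  } else {
    out <- list()
    for (i in 0:db) for (j in 0:(db - i))
      out[[length(out) + 1]] <- c(i, j, db - i - j)
    out
  }
  all(vapply(splits, function(s) any(s >= 2), logical(1)))
}

## Plain-loop reimplementation of the gene-level hit rule. stats is a list of
## per-condition data.frames with sgrna_id, gene_id, log2fc, p_value.
bruteHitCaller <- function(stats, foldThreshold = 2, pThreshold = 0.05,
                           minSg = 3, maxSg = 10, minPass = 2,
                           mode = "intersection") {
  map <- stats[[1]]
  genes <- sort(unique(map$gene_id))
  res <- list()
  for (g in genes) {
    n <- 0
    for (i in seq_len(nrow(map))) if (map$gene_id[i] == g) n <- n + 1
    if (n < minSg || n > maxSg) next
    hitsPerCond <- logical(length(stats))
    for (k in seq_along(stats)) {
      s <- stats[[k]]
      passing <- 0
      for (i in seq_len(nrow(s))) {
        if (s$gene_id[i] == g &&
            s$log2fc[i] >= log2(foldThreshold) &&
            s$p_value[i] < pThreshold)
          passing <- passing + 1
      }
      hitsPerCond[k] <- passing >= minPass
    }
    hit <- if (mode == "intersection") all(hitsPerCond) else any(hitsPerCond)
    res[[g]] <- hit
  }
  res
}

## Random per-condition sgRNA stat tables for oracle comparisons.
randomStatsTables <- function(nGenes, sgPerGeneRange = c(2L, 6L),
                              nConds = 2L) {
  genes <- paste0("g", seq_len(nGenes))
  nSg <- sample(sgPerGeneRange[1]:sgPerGeneRange[2], nGenes, replace = TRUE)
  geneOf <- rep(genes, times = nSg)
  ids <- paste0(geneOf, "_", unlist(lapply(nSg, seq_len)))
  lapply(seq_len(nConds), function(k) {
    data.frame(sgrna_id = ids, gene_id = geneOf,
               condition = paste0("c", k),
               log2fc = rnorm(length(ids), 0.5, 1.5),
               p_value = runif(length(ids)))
  })
}
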