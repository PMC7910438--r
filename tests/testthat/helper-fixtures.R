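## Shared fixtures and independent oracles, built in code at test time.

fixtureCatalog <- function(nGenes = 10, seed = 2) {
  randomReferenceCatalog(nGenes, width = 150L, seed = seed)
}

## Independent rule-table oracle for tail decomposition: per-character
## walk from the 3' end, no shared code with decomposeTail().
oracleDecompose <- function(tail) {
  ch <- strsplit(tail, "", fixed = TRUE)[[1]]
  n <- length(ch)
  i <- n
  while (i >= 1L && ch[i] == "U") i <- i - 1L
  nU <- n - i
  j <- i
  while (j >= 1L && ch[j] %in% c("C", "G")) j <- j - 1L
  nOther <- i - j
  core <- if (j >= 1) ch[1:j] else character(0)
  nA <- sum(core == "A")
  nonA <- length(core) - nA
  cls <- if (n == 0) "untailed"
         else if (nonA > 0) "a_rich"
         else if (nOther > 0) "other_3p_addition"
         else if (nU > 0) "uridylated"
         else "non_uridylated"
  list(polyA = nA, termU = nU, other = nOther, class = cls)
}

## Exhaustive enumeration of all tails over {A,C,G,U} with lengths 1..k.
allTailsUpTo <- function(k) {
  bases <- c("A", "C", "G", "U")
  unlist(lapply(seq_len(k), function(len)
    do.call(paste0, expand.grid(rep(list(bases), len)))))
}

## Exact two-sided rank-sum p value by full enumeration of all
## assignments of the pooled ranks to the first group.
oracleWilcoxEnum <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  Wobs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(pooled), nx)
  Wall <- apply(combs, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  mu <- mean(Wall)
  min(1, 2 * min(mean(Wall <= Wobs), mean(Wall >= Wobs)))
}

## Independent step-up BH oracle.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- cummin(p[o] * n / (n - seq_len(n) + 1))
  pmin(1, adj)[ro]
}

## Independent single-feature NB IRLS via stats::glm + MASS family.
oracleNbFit <- function(y, X, offset, phi) {
  fam <- if (phi <= 0) stats::poisson()
         else MASS::negative.binomial(theta = 1 / phi)
  fit <- suppressWarnings(stats::glm.fit(
    X, y, offset = offset, family = fam,
    control = list(epsilon = 1e-14, maxit = 200)))
  fit$fitted.values
}
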