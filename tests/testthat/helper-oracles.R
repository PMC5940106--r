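# Independent brute-force oracles used to check the package's fast paths.
# These deliberately use the naive closed forms, not the package's internals.

# GLS by explicit inverse: beta-hat = (X' V^-1 X)^-1 X' V^-1 y,
# sigma2 on the ML scale, SE on the (n-2) scale, loglik with log|V|.
oracle_gls <- function(y, x, V) {
  n <- length(y)
  X <- cbind(1, x)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX) %*% t(X) %*% Vi %*% y
  e <- y - X %*% b
  rss <- drop(t(e) %*% Vi %*% e)
  s2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * s2) +
                  as.numeric(determinant(V, logarithm = TRUE)$modulus) + n)
  covb <- rss / (n - 2) * solve(XtViX)
  se <- sqrt(covb[2, 2])
  tval <- b[2] / se
  list(beta = b[2], alpha = b[1], se = se, t = tval,
       p = 2 * pt(-abs(tval), n - 2), sigma2 = s2, loglik = ll)
}

# Lambda profile using only the oracle likelihood (same search protocol).
oracle_profile <- function(y, x, C) {
  lamC <- function(l) { V <- l * C; diag(V) <- diag(C); V }
  f <- function(l) oracle_gls(y, x, lamC(l))$loglik
  grid <- seq(0, 1, length.out = 21)
  ll <- vapply(grid, f, 0)
  if (max(ll) - min(ll) < 1e-6) return(list(lambda = 1, loglik = f(1)))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(21, i + 1)]
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-7)
  lam <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  if (lam < 1e-6) lam <- 0
  if (lam > 1 - 1e-6) lam <- 1
  list(lambda = lam, loglik = f(lam))
}

# Benjamini-Hochberg by the O(m^2) definition: q_i = min over all j with
# p_j >= p_i of p_j * m / rank(p_j), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(r)
    min(1, min(ps[r:m] * m / (r:m))), 0)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Regex-free CpG scan.
oracle_cpg <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) return(0L)
  sum(ch[-length(ch)] == "C" & ch[-1] == "G")
}

# Random sequence over ACGTN.
rand_seq <- function(len, p_n = 0.02) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# A tiny valid hit-table row as a data.frame (fields in dialect order).
make_hit <- function(query_id = "P1", species = "sp_a", bitscore = 200,
                     evalue = 1e-50, aln_len = 12L, pct_identity = 98.5,
                     subject_acc = "chr1", s_start = 100L,
                     s_seq = "ACGTACGTACGT") {
  data.frame(query_id = query_id, query_len = 600L, q_start = 1L,
             q_end = aln_len, subject_acc = subject_acc,
             s_start = s_start, s_end = s_start + aln_len - 1L,
             evalue = evalue, bitscore = bitscore, aln_len = aln_len,
             pct_identity = pct_identity, q_coverage = 100,
             q_seq = substr("ACGTACGTACGTACGTACGT", 1, aln_len),
             s_seq = s_seq, species = species,
             stringsAsFactors = FALSE)
}

# Reverse complement (base R), for composition symmetry checks.
revcomp <- function(s) {
  ch <- rev(strsplit(s, "")[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(comp[ch], collapse = "")
}
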