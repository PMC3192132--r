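# Independent oracles: plain-R re-implementations of the contracts, sharing
# no code path with the package internals (no seeding, no C++).

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    b <- rev(strsplit(s, "")[[1]])
    paste(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# All fully-contained ungapped placements of `query` (both orientations)
# in one target with Hamming distance <= max_mm. Vectorized matrix scan.
oracle_scan_one <- function(query, target, max_mm) {
  out <- list()
  tb <- charToRaw(target)
  nN <- charToRaw("N")
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else oracle_revcomp(query)
    qb <- charToRaw(q)
    L <- length(qb)
    if (L > length(tb)) next
    starts <- 0:(length(tb) - L)
    idx <- outer(starts, seq_len(L), "+")
    W <- matrix(tb[idx], nrow = length(starts))
    Q <- matrix(rep(qb, each = length(starts)), nrow = length(starts))
    mism <- W != Q | W == nN | Q == nN
    d <- rowSums(mism)
    keep <- which(d <= max_mm)
    if (length(keep))
      out[[strand]] <- data.frame(
        start = starts[keep], strand = strand, n_mm = d[keep],
        mm = vapply(keep, function(i)
          paste(starts[i] + which(mism[i, ]) - 1L, collapse = ","),
          character(1)),
        stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

oracle_scan <- function(query, targets, max_mm) {
  res <- lapply(names(targets), function(tn) {
    r <- oracle_scan_one(query, targets[[tn]], max_mm)
    if (!is.null(r) && nrow(r)) cbind(target = tn, r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(target = character(), start = integer(),
                      strand = character(), n_mm = integer(),
                      mm = character(), stringsAsFactors = FALSE)
  out
}

# Best-placement semantics: min distance; >1 distinct target at the minimum
# => NULL (ambiguous/unmapped); within a target leftmost, then "+".
oracle_map_read <- function(read, targets, max_mm) {
  pl <- oracle_scan(read, targets, max_mm)
  if (!nrow(pl)) return(NULL)
  pl <- pl[pl$n_mm == min(pl$n_mm), , drop = FALSE]
  if (length(unique(pl$target)) > 1) return(NULL)
  pl <- pl[order(pl$start, pl$strand), , drop = FALSE]
  pl[1, , drop = FALSE]
}

# Exact hypergeometric enumeration from binomial coefficients (log scale).
oracle_fisher_two_sided <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c; N <- m1 + m2
  if (m1 == 0 || m2 == 0 || n1 == 0 || n1 == N) return(1)
  k <- max(0, n1 - m2):min(m1, n1)
  lp <- lchoose(m1, k) + lchoose(m2, n1 - k) - lchoose(N, n1)
  p <- exp(lp)
  p_obs <- exp(lchoose(m1, a) + lchoose(m2, n1 - a) - lchoose(N, n1))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# The three published calling inequalities as exact integer comparisons
# (0.9 = 9/10, 0.1 = 1/10).
oracle_call <- function(n_A, n_B, total) {
  ab <- n_A + n_B
  total >= 10 && 10 * ab >= 9 * total && ab > 0 && 10 * n_B >= ab
}

oracle_stringent <- function(n_A, n_B, total) {
  ab <- n_A + n_B
  total > 0 && 10 * ab >= 9 * total && ab > 0 && 10 * n_B >= ab && n_B > 0
}

# Build a one-row RNA/DNA pileup data.frame for an A -> G site from counts
# (other-base reads are C's).
make_pile <- function(n_A, n_B, n_other, site_id = "s1", individual = "i1",
                      source = "RNA") {
  data.frame(site_id = site_id, individual = individual, source = source,
             count_A = n_A, count_C = n_other, count_G = n_B, count_T = 0L,
             count_N = 0L, n_A = n_A, n_B = n_B,
             total = n_A + n_B + n_other, n_other = n_other,
             stringsAsFactors = FALSE)
}

# Exhaustive-ordering oracle for rarefaction curves.
oracle_perm_curve <- function(elim, baseline, perm) {
  n <- length(perm)
  out <- numeric(n + 1)
  acc <- unique(baseline)
  out[1] <- length(acc)
  for (k in seq_len(n)) {
    acc <- union(acc, elim[[perm[k]]])
    out[k + 1] <- length(acc)
  }
  out
}

oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i)
    lapply(oracle_perms(n - 1L), function(p)
      c(i, setdiff(seq_len(n), i)[p]))))
}

random_genome <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_positions <- function(seq, pos) {
  b <- strsplit(seq, "")[[1]]
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  paste(b, collapse = "")
}
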