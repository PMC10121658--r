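# Independent oracles and tiny fixture builders. Everything here is written
# from first principles (loops, sorting, hardcoded tables) so that it checks
# the package implementation without sharing code with it.

# --- brute-force TMM: doubly trimmed, weighted mean of per-gene log ratios ---
oracle_tmm_factors <- function(mat, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(mat)
  mat <- mat[rowSums(mat > 0) > 0, , drop = FALSE]
  q75 <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    q75[j] <- quantile(mat[, j], 0.75, names = FALSE) / lib[j]
  }
  ref <- which.min(abs(q75 - mean(q75)))
  f <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    o <- mat[, j]; r <- mat[, ref]
    both <- o > 0 & r > 0
    o <- o[both]; r <- r[both]
    M <- log2((o / lib[j]) / (r / lib[ref]))
    A <- (log2(o / lib[j]) + log2(r / lib[ref])) / 2
    w <- 1 / ((lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r))
    if (length(M) == 0 || max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * abs_trim) + 1; hi_a <- n + 1 - lo_a
    keep <- rank(M) >= lo_m & rank(M) <= hi_m &
      rank(A) >= lo_a & rank(A) <= hi_a
    f[j] <- 2^(sum(M[keep] * w[keep]) / sum(w[keep]))
  }
  f / exp(mean(log(f)))
}

# --- row-by-row re-evaluation of the three CQ filter clauses ---
oracle_cq_filter <- function(tab, male_total, female_total, normalize,
                             cq_max = 0.2, male_min = 20, female_max = 20) {
  pass <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    m <- tab$male_count[i]; f <- tab$female_count[i]
    if (m == 0) { pass[i] <- FALSE; next }
    cq <- if (normalize) (f / female_total) / (m / male_total) else f / m
    pass[i] <- (cq < cq_max) && (m > male_min) && (f < female_max)
  }
  pass
}

# --- standard genetic code as an independent table walk ---
# amino acids in TCAG x TCAG x TCAG codon order
ORACLE_AA <- strsplit(paste0(
  "FFLLSSSSYY**CC*W",   # TTT..TGG
  "LLLLPPPPHHQQRRRR",   # CTT..CGG
  "IIIMTTTTNNKKSSRR",   # ATT..AGG
  "VVVVAAAADDEEGGGG"    # GTT..GGG
), "")[[1]]
oracle_translate <- function(dna, frame = 0) {
  bases <- c(T = 0L, C = 1L, A = 2L, G = 3L)
  chars <- strsplit(toupper(dna), "")[[1]]
  out <- character(0)
  i <- frame + 1L
  while (i + 2L <= length(chars)) {
    idx <- bases[chars[i:(i + 2L)]]
    out <- c(out, if (anyNA(idx)) "X" else ORACLE_AA[sum(idx * c(16L, 4L, 1L)) + 1L])
    i <- i + 3L
  }
  paste(out, collapse = "")
}

# --- exhaustive ORF enumeration: every ATG walked codon by codon ---
oracle_longest_orf <- function(seq) {
  chars <- toupper(seq)
  n <- nchar(chars)
  best <- NULL
  for (s in seq_len(max(n - 5, 0))) {
    if (substr(chars, s, s + 2) != "ATG") next
    i <- s
    while (i + 2 <= n) {
      codon <- substr(chars, i, i + 2)
      if (codon %in% c("TAA", "TAG", "TGA") && i > s) {
        len <- i + 3 - s
        if (is.null(best) || len > best$len ||
            (len == best$len && s < best$start1)) {
          best <- list(start1 = s, end1 = i + 2, len = len)
        }
        break
      }
      i <- i + 3
    }
  }
  best
}

# --- exhaustive amplicon scan over all substring positions ---
oracle_pcr_products <- function(template, fwd, rev, max_product = 3000) {
  template <- toupper(template); fwd <- toupper(fwd)
  rev_site <- oracle_revcomp(rev)
  n <- nchar(template)
  lf <- nchar(fwd); lr <- nchar(rev_site)
  products <- integer(0)
  for (i in seq_len(n - lf + 1)) {
    if (substr(template, i, i + lf - 1) != fwd) next
    for (j in seq_len(n - lr + 1)) {
      if (substr(template, j, j + lr - 1) != rev_site) next
      if (j < i + lf) next
      len <- (j + lr - 1) - i + 1
      if (len <= max_product) products <- c(products, len)
    }
  }
  sort(products)
}
oracle_revcomp <- function(dna) {
  comp <- chartr("ACGTN", "TGCAN", toupper(dna))
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# --- tiny file builders ---
write_toy_sam <- function(path, refs, rows) {
  # rows: data.frame(flag, rname, mapq)
  header <- sprintf("@SQ\tSN:%s\tLN:1000", refs)
  aln <- sprintf("r%d\t%d\t%s\t1\t%d\t10M\t*\t0\t0\tACGTACGTAC\t**********",
                 seq_len(nrow(rows)), rows$flag, rows$rname, rows$mapq)
  writeLines(c("@HD\tVN:1.6", header, aln), path)
  path
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
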