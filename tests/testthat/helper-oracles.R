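# Independent brute-force implementations used as oracles. These are kept
# deliberately plain (nested loops, no shared code with the package
# internals beyond the rank table).

RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

# Contig taxonomy voting, rules (a)-(c) with hierarchical tie-breaking:
# walk ranks species -> domain; at each rank tabulate the lineage prefixes
# of genes reaching that rank; a unique plurality of size >= 2 wins. A lone
# assigned gene wins unopposed at its own lowest rank.
oracle_vote <- function(lineages, min_frac = 0.3) {
  n <- length(lineages)
  assigned <- lineages[!is.na(lineages)]
  if (n == 0 || length(assigned) / n < min_frac) {
    return(list(lineage = NA_character_, rank = "unassigned"))
  }
  if (length(assigned) == 1) {
    k <- length(strsplit(assigned, ";")[[1]])
    return(list(lineage = assigned, rank = RANKS[k]))
  }
  split_lin <- strsplit(assigned, ";")
  for (d in 7:1) {
    votes <- c()
    for (s in split_lin) {
      if (length(s) >= d) votes <- c(votes, paste(s[1:d], collapse = ";"))
    }
    if (length(votes) == 0) next
    counts <- table(votes)
    top <- max(counts)
    if (top >= 2 && sum(counts == top) == 1) {
      return(list(lineage = names(counts)[which.max(counts)],
                  rank = RANKS[d]))
    }
  }
  list(lineage = NA_character_, rank = "unassigned")
}

# Gotoh-style affine local alignment DP with the classic convention: a gap
# of length L costs open + extend*(L-1), both negative. Score-only.
oracle_local_align <- function(a, b, match = 2, mismatch = -1,
                               open = -0.5, extend = -0.1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (A consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    s <- if (A[i] == B[j]) match else mismatch
    M[i + 1, j + 1] <- max(0, s + max(M[i, j], X[i, j], Y[i, j]))
    X[i + 1, j + 1] <- max(M[i, j + 1] + open, X[i, j + 1] + extend,
                           Y[i, j + 1] + open)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + open, Y[i + 1, j] + extend,
                           X[i + 1, j] + open)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# All-offset ungapped scan of one spacer against contigs, both strands,
# full spacer footprint clipped at contig ends.
oracle_spacer_scan <- function(spacer_id, spacer, contigs,
                               min_identity = 97, min_fraction = 0.97) {
  L <- nchar(spacer)
  out <- list()
  for (ct_id in names(contigs)) {
    ct <- contigs[[ct_id]]
    n <- nchar(ct)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") spacer else oracle_revcomp(spacer)
      for (a in (1 - L + 1):n) {
        t1 <- max(1, a); t2 <- min(n, a + L - 1)
        len <- t2 - t1 + 1
        if (len <= 0) next
        qs <- substring(q, t1 - a + 1, t2 - a + 1)
        ts <- substring(ct, t1, t2)
        mat <- sum(strsplit(qs, "")[[1]] == strsplit(ts, "")[[1]])
        ident <- mat / len * 100
        frac <- len / L
        if (ident >= min_identity && frac >= min_fraction) {
          out[[length(out) + 1]] <- data.frame(
            spacer_id = spacer_id, target_contig = ct_id,
            identity_pct = ident, alignment_fraction = frac,
            start = t1 - 1, end = t2, strand = strand)
        }
      }
    }
  }
  if (length(out) == 0) return(NULL)
  unique(do.call(rbind, out))
}

# Direct Bray-Curtis similarity (%) between two rows of sqrt-transformed
# abundances.
oracle_bray_pair <- function(ra1, ra2) {
  y1 <- sqrt(ra1); y2 <- sqrt(ra2)
  100 * 2 * sum(pmin(y1, y2)) / sum(y1 + y2)
}

# all multisets of size r from n states (combinations with repetition)
multisets <- function(n, r) {
  idx <- utils::combn(n + r - 1, r)
  t(apply(idx, 2, function(col) col - seq_len(r) + 1))
}

random_abundance_table <- function(n_samples, n_taxa) {
  m <- matrix(stats::rexp(n_samples * n_taxa), n_samples, n_taxa)
  m <- m / rowSums(m) * 100
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- paste0("taxon_", seq_len(n_taxa))
  dplyr::bind_cols(tibble::tibble(sample_id = paste0("s", seq_len(n_samples))),
                   out)
}
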