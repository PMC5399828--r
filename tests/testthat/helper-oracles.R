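# Independent reference implementations used as oracles. These are written
# against the operation definitions, not against the package code paths.

# --- codon-table translation ------------------------------------------------

ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

oracle_translate <- function(s, frame) {
  if (frame < 0) s <- oracle_revcomp(s)
  k <- abs(frame)
  n_codons <- (nchar(s) - k + 1) %/% 3
  if (n_codons <= 0) return("")
  out <- character(n_codons)
  for (i in seq_len(n_codons)) {
    codon <- substr(s, k + 3 * (i - 1), k + 3 * i - 1)
    aa <- ORACLE_CODONS[codon]
    out[i] <- if (is.na(aa)) "X" else aa
  }
  paste(out, collapse = "")
}

# --- global alignment identity ----------------------------------------------

# Same objective as the package kernel -- lexicographic (score, matches,
# -columns) under match +1 / mismatch -1 / gap open 5 / gap extend 1 -- but
# computed with a completely different mechanism: every state value is packed
# into one exactly-representable integer key so the DP is a plain max.
# All step costs are integers, which makes the packing loss-free.
oracle_gotoh <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  SC <- 1e7   # weight of one score unit
  MA <- 1e4   # weight of one identical pair
  base <- 5000 * SC + 2000 # offsets keep keys positive
  stp <- function(key, ds, dm) key + ds * SC + dm * MA - 1
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1) # gap in a (consumes b)
  M[1, 1] <- base
  for (i in seq_len(n)) X[i + 1, 1] <- base - (5 + i) * SC - i
  for (j in seq_len(m)) Y[1, j + 1] <- base - (5 + j) * SC - j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      eq <- A[i] == B[j]
      s <- if (eq) 1 else -1
      d <- max(M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- if (is.finite(d)) stp(d, s, as.integer(eq)) else NEG
      o <- max(M[i, j + 1], Y[i, j + 1])
      X[i + 1, j + 1] <- max(if (is.finite(o)) stp(o, -6, 0) else NEG,
                             if (is.finite(X[i, j + 1])) stp(X[i, j + 1], -1, 0) else NEG)
      o2 <- max(M[i + 1, j], X[i + 1, j])
      Y[i + 1, j + 1] <- max(if (is.finite(o2)) stp(o2, -6, 0) else NEG,
                             if (is.finite(Y[i + 1, j])) stp(Y[i + 1, j], -1, 0) else NEG)
    }
  }
  key <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  score <- key %/% SC - 5000
  rem <- key %% SC
  matches <- rem %/% MA
  cols <- 2000 - rem %% MA
  c(identity = matches / cols, score = score, matches = matches, columns = cols)
}

oracle_identity <- function(a, b) unname(oracle_gotoh(a, b)[["identity"]])

# --- greedy centroid clustering ---------------------------------------------

oracle_greedy <- function(seqs, cutoff) {
  ord <- names(seqs)[order(-nchar(seqs), names(seqs))]
  centroids <- character(0)
  assign <- list()
  for (id in ord) {
    placed <- FALSE
    for (cen in centroids) {
      if (oracle_identity(seqs[[id]], seqs[[cen]]) >= cutoff) {
        assign[[cen]] <- c(assign[[cen]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, id)
      assign[[id]] <- id
    }
  }
  parts <- lapply(centroids, function(cen) sort(assign[[cen]]))
  parts[order(vapply(parts, `[[`, character(1), 1))]
}

# --- complete-linkage agglomeration (Lance-Williams updates) -----------------

oracle_complete_linkage <- function(seqs, cutoff) {
  ids <- sort(names(seqs))
  n <- length(ids)
  if (n == 1) return(list(ids))
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- 1 - oracle_identity(seqs[[ids[i]]], seqs[[ids[j]]])
    }
  }
  CD <- D
  memb <- as.list(seq_len(n))
  h <- 1 - cutoff + 1e-12
  repeat {
    k <- length(memb)
    if (k == 1) break
    best_i <- 0; best_j <- 0; best_d <- Inf
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        if (CD[i, j] < best_d - 1e-15) {
          best_d <- CD[i, j]; best_i <- i; best_j <- j
        }
      }
    }
    if (best_d > h) break
    newd <- pmax(CD[best_i, ], CD[best_j, ]) # complete-linkage update
    CD[best_i, ] <- newd
    CD[, best_i] <- newd
    CD[best_i, best_i] <- 0
    CD <- CD[-best_j, -best_j, drop = FALSE]
    memb[[best_i]] <- sort(c(memb[[best_i]], memb[[best_j]]))
    memb[best_j] <- NULL
  }
  memb <- memb[order(vapply(memb, min, numeric(1)))]
  lapply(memb, function(ix) ids[ix])
}

# --- Benjamini-Hochberg, definitional step-up --------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- greedy overlap resolution ----------------------------------------------

# Independent nucleotide projection of hit coordinates.
oracle_hit_interval <- function(frame, aa_start, aa_end, L) {
  k <- abs(frame)
  a <- (k - 1) + 3 * (aa_start - 1)
  b <- (k - 1) + 3 * aa_end
  if (frame < 0) c(L - b, L - a) else c(a, b)
}

oracle_resolve <- function(hits, p, ref_lengths) {
  iv <- t(vapply(seq_len(nrow(hits)), function(i) {
    oracle_hit_interval(hits$frame[i], hits$aa_start[i], hits$aa_end[i],
                        ref_lengths[[hits$reference_id[i]]])
  }, numeric(2)))
  ord <- order(-hits$bitscore, hits$evalue, hits$reference_id,
               iv[, 1], iv[, 2], hits$domain_id)
  kept <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (j in kept) {
      if (hits$reference_id[i] != hits$reference_id[j]) next
      ov <- min(iv[i, 2], iv[j, 2]) - max(iv[i, 1], iv[j, 1])
      ml <- min(iv[i, 2] - iv[i, 1], iv[j, 2] - iv[j, 1])
      if (ov > p * ml) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) kept <- c(kept, i)
  }
  sort(kept)
}

# --- closed-form two-group Poisson GLM ---------------------------------------

# With a group indicator and offsets, the score equations force fitted group
# totals to equal observed totals, giving a closed form for the fit.
oracle_two_group_fit <- function(y, grp, off) {
  t1 <- sum(y[grp == 1]); t0 <- sum(y[grp == 0])
  o1 <- sum(exp(off[grp == 1])); o0 <- sum(exp(off[grp == 0]))
  b1 <- log(t1 / o1) - log(t0 / o0)
  mu <- exp(ifelse(grp == 1, log(t1 / o1), log(t0 / o0)) + off)
  phi <- max(1, sum((y - mu)^2 / mu) / (length(y) - 2))
  se <- sqrt(phi) * sqrt(1 / t1 + 1 / t0)
  c(logFC = b1, se = se, dispersion = phi)
}

# --- small shared utilities --------------------------------------------------

random_aa_str <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE),
        collapse = "")
}

random_nt_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Canonical partition (set of sorted member sets, sorted by first member)
# from a clustering tibble.
partition_of <- function(cl) {
  parts <- lapply(split(cl$region_id, cl$cluster), sort)
  names(parts) <- NULL
  parts[order(vapply(parts, `[[`, character(1), 1))]
}
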