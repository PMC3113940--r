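# Independent brute-force oracles.  These re-enumerate every descriptor
# tuple with explicit nested loops and direct array indexing -- a separate
# code path from the package's vectorized enumeration -- so that agreement
# is evidence, not tautology.

# descriptor indices recomputed from first principles
oracle_desc <- function(s, scheme) {
  res <- s$residues
  list(si = match(res$aa, AA_ALPHABET),
       ti = match(res$t, scheme$torsion_alphabet),
       ai = {
         b <- findInterval(res$a, scheme$acc_breaks, rightmost.closed = TRUE)
         b[!is.na(b) & (b < 1 | b > length(scheme$acc_breaks) - 1)] <- NA
         b
       })
}

# total energy of every term by explicit loops
oracle_term_totals <- function(s, pot) {
  scheme <- pot$scheme
  d <- oracle_desc(s, scheme)
  res <- s$residues
  n <- nrow(res)
  W <- pot$energies
  tot <- setNames(numeric(13), names(W))
  nt <- length(scheme$torsion_alphabet)
  naa <- 20

  for (i in seq_len(n)) {                      # single-residue terms
    si <- d$si[i]; ti <- d$ti[i]; ai <- d$ai[i]
    if (!is.na(ti)) tot["st"] <- tot["st"] + W$st[si, ti]
    if (!is.na(ai)) tot["as"] <- tot["as"] + W$as[ai, si]
    if (!is.na(ai) && !is.na(ti))
      tot["ast"] <- tot["ast"] + W$ast[ai, si, ti]
  }
  for (i in seq_len(n - 1)) {                  # sequence neighbors
    if (res$chain[i] != res$chain[i + 1]) next
    s1 <- d$si[i]; s2 <- d$si[i + 1]
    t1 <- d$ti[i]; t2 <- d$ti[i + 1]
    a1 <- d$ai[i]; a2 <- d$ai[i + 1]
    if (!is.na(t1) && !is.na(t2)) tot["stt"] <- tot["stt"] + W$stt[s1, t1, t2]
    if (!is.na(t2)) tot["sst"] <- tot["sst"] + W$sst[s1, s2, t2]
    if (!is.na(a1) && !is.na(a2)) tot["aas"] <- tot["aas"] + W$aas[a1, a2, s2]
    if (!is.na(a1)) tot["ass"] <- tot["ass"] + W$ass[a1, s1, s2]
  }
  pr <- s$pairs
  for (p in seq_len(nrow(pr))) {               # distance pairs, both orders
    db <- findInterval(pr$d[p], scheme$dist_breaks, rightmost.closed = TRUE)
    if (db < 1 || db > length(scheme$dist_breaks) - 1) next
    for (ord in 1:2) {
      i <- if (ord == 1) pr$i[p] else pr$j[p]
      j <- if (ord == 1) pr$j[p] else pr$i[p]
      si <- d$si[i]; sj <- d$si[j]
      ti <- d$ti[i]; tj <- d$ti[j]
      ai <- d$ai[i]; aj <- d$ai[j]
      tot["sd"] <- tot["sd"] + W$sd[si, db]
      tot["sds"] <- tot["sds"] + W$sds[si, db, sj]
      if (!is.na(ai)) tot["asd"] <- tot["asd"] + W$asd[ai, si, db]
      if (!is.na(ti)) tot["std"] <- tot["std"] + W$std[si, ti, db]
      if (!is.na(ai) && !is.na(aj)) {
        u1 <- (ai - 1) * naa + si; u2 <- (aj - 1) * naa + sj
        tot["asdas"] <- tot["asdas"] + W$asdas[u1, db, u2]
      }
      if (!is.na(ti) && !is.na(tj)) {
        u1 <- (si - 1) * nt + ti; u2 <- (sj - 1) * nt + tj
        tot["stdst"] <- tot["stdst"] + W$stdst[u1, db, u2]
      }
    }
  }
  tot
}

# full-rescoring mutation delta: substitute the type and re-total
oracle_mutation_delta <- function(s, k, s_m, pot) {
  smut <- s
  smut$residues$aa[k] <- s_m
  oracle_term_totals(smut, pot) - oracle_term_totals(s, pot)
}

# naive unvectorized ddG: explicit sigmoid formula, term by term
oracle_predict <- function(s, k, s_m, pot, params) {
  res <- s$residues
  dw <- oracle_mutation_delta(s, k, s_m, pot)
  dv <- unname(AA_VOLUMES[s_m] - AA_VOLUMES[res$aa[k]])
  x <- c(dw, max(dv, 0), min(dv, 0), 1)
  A <- res$a[k]
  total <- 0
  for (i in 1:16) {
    th <- params$theta
    al <- th[i, "f"] / (1 + exp(-th[i, "r"] * (A - th[i, "c"]))) + th[i, "b"]
    total <- total + al * x[i]
  }
  unname(total)
}

# brute-force all-pairs centroid distances with the chain-separation rule
oracle_pair_map <- function(s, cutoff) {
  res <- s$residues
  out <- list()
  for (i in seq_len(nrow(res) - 1)) for (j in (i + 1):nrow(res)) {
    if (res$chain[i] == res$chain[j] && abs(i - j) < 2) next
    dd <- sqrt((res$cx[i] - res$cx[j])^2 + (res$cy[i] - res$cy[j])^2 +
               (res$cz[i] - res$cz[j])^2)
    if (dd <= cutoff) out[[length(out) + 1]] <- c(i, j, dd)
  }
  do.call(rbind, out)
}
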