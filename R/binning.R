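# Discretization of the continuous descriptors (accessibility a, centroid
# distance d) and the term-definition table shared by counting, potential
# derivation and mutation-delta evaluation.

#' Create a binning scheme for the statistical potentials
#'
#' @param acc_breaks Strictly increasing percent boundaries for the
#'   accessibility bins; first must be 0 and last 100.
#' @param dist_breaks Strictly increasing Angstrom boundaries for the
#'   centroid-distance bins; the first and last act as lower/upper cutoffs
#'   (pairs outside are not counted).
#' @param torsion_alphabet Defined torsion labels (the undefined label
#'   `"U"` is never counted).
#' @return A `binning_scheme` object.
#' @export
binning_scheme <- function(acc_breaks = ACC_BIN_BREAKS,
                           dist_breaks = seq(DISTANCE_LOWER, DISTANCE_UPPER,
                                             by = 0.5),
                           torsion_alphabet = setdiff(TORSION_ALPHABET, "U")) {
  stopifnot(all(diff(acc_breaks) > 0), all(diff(dist_breaks) > 0),
            length(acc_breaks) >= 2L, length(dist_breaks) >= 2L)
  structure(list(acc_breaks = acc_breaks, dist_breaks = dist_breaks,
                 torsion_alphabet = torsion_alphabet,
                 n_acc = length(acc_breaks) - 1L,
                 n_dist = length(dist_breaks) - 1L,
                 n_tor = length(torsion_alphabet), n_aa = 20L),
            class = "binning_scheme")
}

# accessibility percent -> bin index 1..n_acc (boundaries: [b_k, b_{k+1}),
# the topmost bin closed above); NA passes through
acc_bin <- function(a, scheme) {
  b <- findInterval(a, scheme$acc_breaks, rightmost.closed = TRUE)
  b[!is.na(b) & (b < 1L | b > scheme$n_acc)] <- NA_integer_
  b
}

# distance Angstrom -> bin index 1..n_dist or NA if outside the window
dist_bin <- function(d, scheme) {
  b <- findInterval(d, scheme$dist_breaks, rightmost.closed = TRUE)
  b[!is.na(b) & (b < 1L | b > scheme$n_dist)] <- NA_integer_
  b
}

# Descriptor-dimension kinds and the owning tuple member for each of the
# 13 terms.  kind: s / t / a / d / as (composite a x s) / st (composite
# s x t); who: 1 or 2 = tuple member owning the descriptor, 0 = the pair
# distance.  unit: single residue, consecutive sequence neighbors (i,i+1),
# or distance-map pair (counted in both orders, so tensors are symmetric).
TERM_DEFS <- list(
  st    = list(unit = "single",   kinds = c("s", "t"),      who = c(1, 1)),
  as    = list(unit = "single",   kinds = c("a", "s"),      who = c(1, 1)),
  sd    = list(unit = "pair",     kinds = c("s", "d"),      who = c(1, 0)),
  sds   = list(unit = "pair",     kinds = c("s", "d", "s"), who = c(1, 0, 2)),
  stt   = list(unit = "neighbor", kinds = c("s", "t", "t"), who = c(1, 1, 2)),
  sst   = list(unit = "neighbor", kinds = c("s", "s", "t"), who = c(1, 2, 2)),
  aas   = list(unit = "neighbor", kinds = c("a", "a", "s"), who = c(1, 2, 2)),
  ass   = list(unit = "neighbor", kinds = c("a", "s", "s"), who = c(1, 1, 2)),
  ast   = list(unit = "single",   kinds = c("a", "s", "t"), who = c(1, 1, 1)),
  asd   = list(unit = "pair",     kinds = c("a", "s", "d"), who = c(1, 1, 0)),
  std   = list(unit = "pair",     kinds = c("s", "t", "d"), who = c(1, 1, 0)),
  asdas = list(unit = "pair",     kinds = c("as", "d", "as"), who = c(1, 0, 2)),
  stdst = list(unit = "pair",     kinds = c("st", "d", "st"), who = c(1, 0, 2))
)

# size of one descriptor dimension under a scheme
.dim_size <- function(kind, scheme) {
  switch(kind,
         s = scheme$n_aa, t = scheme$n_tor, a = scheme$n_acc,
         d = scheme$n_dist, as = scheme$n_acc * scheme$n_aa,
         st = scheme$n_aa * scheme$n_tor)
}

# bin value of one descriptor for residue indices `r` (NA if undefined)
.dim_value <- function(kind, r, desc, scheme, dbin = NULL) {
  switch(kind,
         s  = desc$si[r],
         t  = desc$ti[r],
         a  = desc$ai[r],
         d  = dbin,
         as = (desc$ai[r] - 1L) * scheme$n_aa + desc$si[r],
         st = (desc$si[r] - 1L) * scheme$n_tor + desc$ti[r])
}

# recompute an s-bearing dimension after substituting amino acid sm_idx
.dim_value_mut <- function(kind, r, sm_idx, desc, scheme) {
  switch(kind,
         s  = sm_idx,
         as = (desc$ai[r] - 1L) * scheme$n_aa + sm_idx,
         st = (sm_idx - 1L) * scheme$n_tor + desc$ti[r],
         stop("dimension of kind '", kind, "' does not depend on s"))
}

# Enumerate, for one annotated structure, the descriptor tuples of every
# term: a bin-index matrix plus, per dimension, the residue owning it
# (0 for the pair distance).  Undefined descriptors (torsion "U", missing
# accessibility) drop the tuple; drops are tallied.
structure_tuples <- function(structure, scheme) {
  res <- structure$residues
  n <- nrow(res)
  desc <- data.frame(
    si = match(res$aa, AA_ALPHABET),
    ti = match(res$t, scheme$torsion_alphabet),
    ai = acc_bin(res$a, scheme))
  nb <- which(res$chain[-n] == res$chain[-1L])       # neighbor pairs (i, i+1)
  pr <- structure$pairs
  if (is.null(pr)) pr <- data.frame(i = integer(), j = integer(),
                                    d = numeric())
  pr$dbin <- dist_bin(pr$d, scheme)
  pr <- pr[!is.na(pr$dbin), , drop = FALSE]

  out <- list()
  for (id in names(TERM_DEFS)) {
    def <- TERM_DEFS[[id]]
    if (def$unit == "single") {
      m1 <- seq_len(n); m2 <- rep(0L, n); db <- NULL
    } else if (def$unit == "neighbor") {
      m1 <- nb; m2 <- nb + 1L; db <- NULL
    } else {
      m1 <- c(pr$i, pr$j); m2 <- c(pr$j, pr$i); db <- c(pr$dbin, pr$dbin)
    }
    k <- length(def$kinds)
    bins <- matrix(NA_integer_, length(m1), k)
    owners <- matrix(0L, length(m1), k)
    for (dd in seq_len(k)) {
      r <- if (def$who[dd] == 1) m1 else if (def$who[dd] == 2) m2 else NULL
      bins[, dd] <- if (def$who[dd] == 0) db
                    else .dim_value(def$kinds[dd], r, desc, scheme)
      if (def$who[dd] != 0 && def$kinds[dd] %in% c("s", "as", "st"))
        owners[, dd] <- r
    }
    ok <- !apply(bins, 1L, anyNA)
    out[[id]] <- list(bins = bins[ok, , drop = FALSE],
                      owners = owners[ok, , drop = FALSE],
                      n_skipped = sum(!ok))
  }
  list(desc = desc, terms = out, scheme = scheme)
}
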