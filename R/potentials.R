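# Derivation of the 13 statistical potentials from a structure collection
# (inverse-Boltzmann transform of descriptor co-occurrence frequencies)
# and evaluation of per-mutation energy differences.

#' Count descriptor co-occurrence frequencies
#'
#' Accumulates, over a collection of annotated structures, the raw
#' frequency tensor of every potential term: per residue for the
#' single-residue terms, per consecutive sequence-neighbor pair for the
#' neighbor terms, and per recorded centroid-distance pair (both orders,
#' so the tensors are symmetric in the two member slots) for the distance
#' terms.  Residues or pairs with an undefined descriptor (torsion `"U"`,
#' missing accessibility, distance outside the bin window) are skipped and
#' tallied.
#'
#' @param structures List of annotated `protein_structure` objects (see
#'   [annotate_structure()]).
#' @param scheme A [binning_scheme()].
#' @return Object of class `term_counts`: per term an integer array of
#'   counts, plus the scheme, total tuple counts and skip tallies.
#' @export
count_frequencies <- function(structures, scheme = binning_scheme()) {
  if (inherits(structures, "protein_structure")) structures <- list(structures)
  if (length(structures) == 0L) stop("empty structure collection")
  counts <- list()
  skipped <- stats::setNames(numeric(length(TERM_DEFS)), names(TERM_DEFS))
  for (id in names(TERM_DEFS)) {
    dims <- vapply(TERM_DEFS[[id]]$kinds, .dim_size, integer(1L),
                   scheme = scheme)
    counts[[id]] <- array(0L, dim = unname(dims))
  }
  for (s in structures) {
    tp <- structure_tuples(s, scheme)
    for (id in names(TERM_DEFS)) {
      b <- tp$terms[[id]]$bins
      skipped[id] <- skipped[id] + tp$terms[[id]]$n_skipped
      if (nrow(b) == 0L) next
      dims <- dim(counts[[id]])
      lin <- .linear_index(b, dims)
      tab <- tabulate(lin, nbins = prod(dims))
      counts[[id]] <- counts[[id]] + array(tab, dim = dims)
    }
  }
  structure(list(counts = counts, scheme = scheme, skipped = skipped,
                 totals = vapply(counts, sum, numeric(1L))),
            class = "term_counts")
}

# row-wise linear index into an array of dimension `dims`
.linear_index <- function(bins, dims) {
  stride <- cumprod(c(1L, dims[-length(dims)]))
  as.integer(1L + (bins - 1L) %*% stride)
}

#' Derive the statistical potentials from raw counts
#'
#' Applies the inverse-Boltzmann transform to each term's count tensor.
#' A pseudocount `p` is added to every joint cell and all marginals are
#' computed from the smoothed tensor, which realizes
#' \deqn{W(v,w) = -kT \ln\frac{(F(v,w)+p)\,(F+pB)}{(F(v)+pB_w)(F(w)+pB_v)}}
#' for the pairwise terms; triplet terms use the coupling form
#' \deqn{W(v,w,x) = -kT \ln\frac{P(v,w,x)P(v)P(w)P(x)}{P(v,w)P(v,x)P(w,x)}}
#' with probabilities taken from the smoothed tensor.  The composite-state
#' terms (`asdas`, `stdst`) are triplets over ((a,s), d, (a,s)) and
#' ((s,t), d, (s,t)).  Energies are finite everywhere whenever `p > 0`;
#' cells whose smoothed marginal mass is zero (possible only at `p = 0`)
#' are set to 0.
#'
#' The energy difference of a mutation under a term is the total term
#' energy with the mutant type minus that with the wild type, all other
#' descriptors held fixed; see [delta_energy_terms()].
#'
#' @param counts A `term_counts` object.
#' @param pseudocount Non-negative smoothing count per joint cell
#'   (default 1).
#' @param kT Energy scale in kcal/mol (default [KT_KCAL_MOL]).
#' @return Object of class `potential_set`: per term an energy array
#'   (kcal/mol) with the raw counts retained for audit, plus the scheme,
#'   `pseudocount` and `kT`.
#' @export
derive_potentials <- function(counts, pseudocount = 1, kT = KT_KCAL_MOL) {
  stopifnot(inherits(counts, "term_counts"))
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  energies <- list()
  for (id in names(counts$counts)) {
    A <- counts$counts[[id]] + pseudocount
    nd <- length(dim(A))
    energies[[id]] <- if (nd == 2L) .pair_energy(A, kT) else .triplet_energy(A, kT)
  }
  structure(list(energies = energies, counts = counts$counts,
                 scheme = counts$scheme, pseudocount = pseudocount, kT = kT),
            class = "potential_set")
}

# -kT ln[ A_vw * S / (A_v. * A_.w) ], zero where a marginal vanishes
.pair_energy <- function(A, kT) {
  S <- sum(A)
  mv <- rowSums(A); mw <- colSums(A)
  denom <- outer(mv, mw)
  W <- array(0, dim = dim(A))
  ok <- denom > 0 & A > 0
  W[ok] <- -kT * log((A * S / denom)[ok])
  W
}

# -kT ln[ P_vwx P_v P_w P_x / (P_vw P_vx P_wx) ] from smoothed counts
.triplet_energy <- function(A, kT) {
  S <- sum(A)
  m1 <- apply(A, 1L, sum); m2 <- apply(A, 2L, sum); m3 <- apply(A, 3L, sum)
  m12 <- apply(A, c(1L, 2L), sum)
  m13 <- apply(A, c(1L, 3L), sum)
  m23 <- apply(A, c(2L, 3L), sum)
  d <- dim(A)
  i1 <- slice.index(A, 1L); i2 <- slice.index(A, 2L); i3 <- slice.index(A, 3L)
  num <- A * m1[i1] * m2[i2] * m3[i3]
  den <- m12[cbind(c(i1), c(i2))] * m13[cbind(c(i1), c(i3))] *
    m23[cbind(c(i2), c(i3))] * S
  den <- array(den, dim = d)
  W <- array(0, dim = d)
  ok <- den > 0 & num > 0
  W[ok] <- -kT * log(num[ok] / den[ok])
  W
}

# total energy of one term over an enumerated tuple set
.term_total_energy <- function(W, bins) {
  if (nrow(bins) == 0L) return(0)
  sum(W[.linear_index(bins, dim(W))])
}

#' Score a structure under a potential set
#'
#' Total energy per term: the sum of the term's energy over every counted
#' descriptor tuple of the structure.  Mainly useful for auditing; the
#' mutation predictor uses energy differences only.
#'
#' @param structure Annotated `protein_structure`.
#' @param potentials A `potential_set`.
#' @return Named numeric vector, one total (kcal/mol) per term.
#' @export
score_structure <- function(structure, potentials) {
  tp <- structure_tuples(structure, potentials$scheme)
  vapply(names(TERM_DEFS), function(id)
    .term_total_energy(potentials$energies[[id]], tp$terms[[id]]$bins),
    numeric(1L))
}

# rows of a tuple set that involve residue k through an s-bearing dimension
.rows_involving <- function(term, k) {
  which(rowSums(term$owners == k) > 0L)
}

#' Per-term energy differences for a point mutation
#'
#' For each of the 13 potentials, computes the difference in total term
#' energy caused by substituting `s_m` for `s_w` at one position, with the
#' torsion domain, accessibility and all distances held at their wild-type
#' values.  Only tuples involving the mutated position contribute (all
#' others cancel exactly).
#'
#' @param structure Annotated `protein_structure`.
#' @param position Residue selector: either an internal index (single
#'   integer) or a list/character `"chain:resnum"` with author numbering.
#' @param s_w,s_m Wild-type and mutant one-letter amino-acid codes.
#' @param potentials A `potential_set`.
#' @param cache Optional precomputed [structure_tuples()] result (used by
#'   the batch drivers to avoid re-enumeration).
#' @return Named numeric 13-vector of energy differences, kcal/mol.
#' @export
delta_energy_terms <- function(structure, position, s_w, s_m, potentials,
                               cache = NULL) {
  k <- resolve_position(structure, position)
  res <- structure$residues
  if (res$aa[k] != s_w)
    stop("wild-type mismatch at ", res$chain[k], ":", res$resno[k],
         res$insert[k], ": structure has '", res$aa[k],
         "', mutation names '", s_w, "'")
  if (s_m == s_w) stop("self-mutation requested (", s_w, " -> ", s_m, ")")
  if (!(s_m %in% AA_ALPHABET)) stop("unknown amino acid '", s_m, "'")
  if (is.null(cache)) cache <- structure_tuples(structure, potentials$scheme)
  .mutation_delta(cache, potentials, k, match(s_m, AA_ALPHABET))
}

# core delta evaluation against a tuple cache
.mutation_delta <- function(cache, potentials, k, sm_idx) {
  scheme <- cache$scheme
  desc <- cache$desc
  out <- stats::setNames(numeric(length(TERM_DEFS)), names(TERM_DEFS))
  for (id in names(TERM_DEFS)) {
    term <- cache$terms[[id]]
    rows <- .rows_involving(term, k)
    if (length(rows) == 0L) next
    W <- potentials$energies[[id]]
    dims <- dim(W)
    kinds <- TERM_DEFS[[id]]$kinds
    wt <- term$bins[rows, , drop = FALSE]
    mut <- wt
    own <- term$owners[rows, , drop = FALSE]
    for (dd in seq_along(kinds)) {
      hit <- own[, dd] == k
      if (any(hit))
        mut[hit, dd] <- .dim_value_mut(kinds[dd], k, sm_idx, desc, scheme)
    }
    out[id] <- sum(W[.linear_index(mut, dims)]) -
      sum(W[.linear_index(wt, dims)])
  }
  out
}

#' Resolve a residue reference to an internal index
#'
#' @param structure A `protein_structure`.
#' @param position Integer index, `"chain:resnum"` string (resnum =
#'   author number plus optional insertion code), or
#'   `list(chain =, resnum =)`.
#' @return Integer index into `structure$residues`.
#' @export
resolve_position <- function(structure, position) {
  res <- structure$residues
  if (is.numeric(position)) {
    k <- as.integer(position)
    if (k < 1L || k > nrow(res)) stop("residue index ", k, " out of range")
    return(k)
  }
  if (is.character(position) && grepl(":", position)) {
    parts <- strsplit(position, ":", fixed = TRUE)[[1L]]
    position <- list(chain = parts[1L], resnum = parts[2L])
  }
  rn <- paste0(res$resno, res$insert)
  k <- which(res$chain == position$chain & rn == as.character(position$resnum))
  if (length(k) != 1L)
    stop("cannot resolve residue ", position$chain, ":", position$resnum,
         " (", length(k), " matches)")
  k
}

#' Serialize a potential set to versioned plain text (JSON)
#'
#' Stores the scheme, raw counts, energies, pseudocount, kT and a
#' provenance tag; [read_potentials()] restores it losslessly.
#'
#' @param potentials A `potential_set`.
#' @param path Output file.
#' @param provenance Optional character tag (e.g. a structure-list hash).
#' @export
write_potentials <- function(potentials, path, provenance = NULL) {
  obj <- list(
    format = "stabscan-potentials", version = 1L,
    provenance = provenance,
    kT = potentials$kT, pseudocount = potentials$pseudocount,
    scheme = list(acc_breaks = potentials$scheme$acc_breaks,
                  dist_breaks = potentials$scheme$dist_breaks,
                  torsion_alphabet = potentials$scheme$torsion_alphabet),
    terms = lapply(names(TERM_DEFS), function(id) list(
      id = id,
      dim = dim(potentials$energies[[id]]),
      counts = as.vector(potentials$counts[[id]]),
      energies = .num_text(as.vector(potentials$energies[[id]])))))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a potential set written by [write_potentials()]
#'
#' @param path File path.
#' @return A `potential_set`.
#' @export
read_potentials <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "stabscan-potentials"))
    stop("not a stabscan potential archive: ", path)
  scheme <- binning_scheme(acc_breaks = obj$scheme$acc_breaks,
                           dist_breaks = obj$scheme$dist_breaks,
                           torsion_alphabet = obj$scheme$torsion_alphabet)
  energies <- list(); counts <- list()
  for (i in seq_len(nrow(obj$terms))) {
    id <- obj$terms$id[i]
    d <- obj$terms$dim[[i]]
    counts[[id]] <- array(obj$terms$counts[[i]], dim = d)
    energies[[id]] <- array(as.numeric(obj$terms$energies[[i]]), dim = d)
  }
  structure(list(energies = energies, counts = counts, scheme = scheme,
                 pseudocount = obj$pseudocount, kT = obj$kT),
            class = "potential_set")
}

# full-precision decimal text for doubles (round-trips bit-exactly)
.num_text <- function(x) sprintf("%.17g", x)
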