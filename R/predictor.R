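# The ddG predictor: a linear combination of the 13 potential energy
# differences, two volume terms and an independent term, each weighted by
# a sigmoid function of the wild-type residue's solvent accessibility.

#' Coefficient (feature) names of the predictor
#'
#' The 13 potential terms, the positive/negative volume terms and the
#' independent (constant-feature) term, in model order.
#'
#' @format Character vector of length 16.
#' @export
COEFFICIENT_NAMES <- c(POTENTIAL_TERMS, "dVp", "dVm", "ind")

#' Construct a sigmoid-weight parameter set
#'
#' Each of the 16 coefficients is a logistic function of the relative
#' solvent accessibility A (percent):
#' \deqn{\alpha_i(A) = f_i / (1 + e^{-r_i (A - c_i)}) + b_i}
#' with inflection `c` (percent), slope `r` (per percent), scaling `f`
#' and vertical shift `b`.  The `active` mask records which of the 64
#' slots are free during fitting; frozen slots keep their stored value.
#'
#' @param c,r,f,b Numeric vectors of length 16 (recycled if length 1).
#' @param active Logical 16 x 4 matrix (columns c, r, f, b); default all
#'   active.
#' @return A `model_parameters` object (16 x 4 matrix plus mask).
#' @export
model_parameters <- function(c = 50, r = 0, f = 0, b = 0, active = NULL) {
  theta <- cbind(c = rep_len(c, 16L), r = rep_len(r, 16L),
                 f = rep_len(f, 16L), b = rep_len(b, 16L))
  rownames(theta) <- COEFFICIENT_NAMES
  if (is.null(active)) active <- matrix(TRUE, 16L, 4L)
  dimnames(active) <- dimnames(theta)
  stopifnot(identical(dim(active), c(16L, 4L)))
  structure(list(theta = theta, active = active), class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("model_parameters: 16 sigmoid coefficients,",
      sum(x$active), "of 64 parameters active\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' Sigmoid weight of one coefficient at accessibility A
#'
#' @param A Relative solvent accessibility, percent, in [0, 100].
#' @param c Inflection point (percent).
#' @param r Slope (per percent).
#' @param f Scaling factor.
#' @param b Vertical shift.
#' @return `f / (1 + exp(-r * (A - c))) + b`, vectorized over `A`.
#' @export
sigmoid_weight <- function(A, c, r, f, b) f / (1 + exp(-r * (A - c))) + b

#' All 16 coefficient values at accessibility A
#'
#' @param params A `model_parameters` object.
#' @param A Accessibility, percent (scalar or vector).
#' @return If `A` is scalar, a named 16-vector; otherwise a
#'   `length(A)` x 16 matrix.
#' @export
coefficient_weights <- function(params, A) {
  th <- params$theta
  out <- vapply(seq_len(16L), function(i)
    sigmoid_weight(A, th[i, "c"], th[i, "r"], th[i, "f"], th[i, "b"]),
    numeric(length(A)))
  if (length(A) == 1L) stats::setNames(as.numeric(out), COEFFICIENT_NAMES)
  else matrix(out, nrow = length(A), dimnames = list(NULL, COEFFICIENT_NAMES))
}

#' Volume terms of a mutation
#'
#' `dV = V_m - V_w`; the positive part `dV+` (steric accommodation of a
#' larger side chain) and negative part `dV-` (cavity creation) are
#' returned; exactly one is nonzero unless `dV = 0`.
#'
#' @param s_w,s_m One-letter wild-type and mutant amino-acid codes.
#' @param volumes Named volume table (default [AA_VOLUMES], Angstrom^3).
#' @return Named numeric vector `c(dVp, dVm)`.
#' @export
volume_terms <- function(s_w, s_m, volumes = AA_VOLUMES) {
  if (!(s_w %in% names(volumes)) || !(s_m %in% names(volumes)))
    stop("unknown amino acid in mutation ", s_w, " -> ", s_m)
  dv <- unname(volumes[s_m] - volumes[s_w])
  c(dVp = max(dv, 0), dVm = min(dv, 0))
}

# 16-feature vector for one mutation (13 deltas, dV+, dV-, 1)
.mutation_features <- function(structure, k, s_w, s_m, potentials, cache) {
  dw <- delta_energy_terms(structure, k, s_w, s_m, potentials, cache = cache)
  c(dw, volume_terms(s_w, s_m), ind = 1)
}

#' Predict the stability change of one point mutation
#'
#' Computes \eqn{\Delta\Delta G_P = \sum_{i=1}^{16} \alpha_i(A) x_i}
#' where the features x are the 13 per-term energy differences, the two
#' volume terms and the constant 1, and A is the wild-type residue's
#' relative accessibility.  Mutations involving proline (either side) are
#' flagged low-confidence: the backbone rearrangement they typically cause
#' is outside this model.
#'
#' @param structure Annotated `protein_structure`.
#' @param mutation List with `chain`, `resnum`, `s_w`, `s_m`, or a
#'   whitespace-separated token `"CHAIN RESNUM WT MUT"`.
#' @param potentials A `potential_set`.
#' @param params A `model_parameters` object.
#' @param cache Optional [structure_tuples()] cache.
#' @return A `ddg_prediction`: list with the mutation identity, `A`,
#'   `ddG` (kcal/mol), the 16-component weighted `breakdown` (summing to
#'   `ddG`) and `flags`.
#' @export
predict_ddg <- function(structure, mutation, potentials, params,
                        cache = NULL) {
  mutation <- parse_mutation(mutation)
  k <- resolve_position(structure,
                        list(chain = mutation$chain, resnum = mutation$resnum))
  res <- structure$residues
  if (is.na(res$a[k]))
    stop("accessibility undefined at ", mutation$chain, ":", mutation$resnum)
  if (is.null(cache)) cache <- structure_tuples(structure, potentials$scheme)
  x <- .mutation_features(structure, k, mutation$s_w, mutation$s_m,
                          potentials, cache)
  A <- res$a[k]
  alpha <- coefficient_weights(params, A)
  breakdown <- stats::setNames(alpha * x, COEFFICIENT_NAMES)
  flags <- character(0)
  if (mutation$s_w == "P" || mutation$s_m == "P") flags <- "proline"
  structure(list(chain = mutation$chain, resnum = mutation$resnum,
                 s_w = mutation$s_w, s_m = mutation$s_m, A = A,
                 ddG = sum(breakdown), breakdown = breakdown, flags = flags),
            class = "ddg_prediction")
}

#' @export
print.ddg_prediction <- function(x, ...) {
  cat(sprintf("%s:%s %s->%s  ddG = %+.3f kcal/mol  (A = %.1f%%%s)\n",
              x$chain, x$resnum, x$s_w, x$s_m, x$ddG, x$A,
              if (length(x$flags)) paste0("; ", paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Parse a mutation token
#'
#' @param mutation A list (passed through after validation) or a token
#'   `"CHAIN RESNUM WT MUT"`.
#' @return List with `chain`, `resnum`, `s_w`, `s_m`.
#' @export
parse_mutation <- function(mutation) {
  if (is.character(mutation) && length(mutation) == 1L) {
    parts <- strsplit(trimws(mutation), "[[:space:]]+")[[1L]]
    if (length(parts) != 4L)
      stop("malformed mutation token '", mutation,
           "' (expected: CHAIN RESNUM WT MUT)")
    mutation <- list(chain = parts[1L], resnum = parts[2L],
                     s_w = toupper(parts[3L]), s_m = toupper(parts[4L]))
  }
  stopifnot(all(c("chain", "resnum", "s_w", "s_m") %in% names(mutation)))
  if (!(mutation$s_w %in% AA_ALPHABET) || !(mutation$s_m %in% AA_ALPHABET))
    stop("unknown amino acid in mutation ", mutation$s_w, " -> ",
         mutation$s_m)
  if (mutation$s_w == mutation$s_m)
    stop("self-mutation requested (", mutation$s_w, " -> ", mutation$s_m, ")")
  mutation
}

#' Systematic saturation-mutagenesis scan
#'
#' Predicts the stability change of all 19 possible substitutions at every
#' scannable residue (defined amino-acid type and accessibility).
#'
#' @param structure Annotated `protein_structure`.
#' @param potentials A `potential_set`.
#' @param params A `model_parameters` object.
#' @param order `"sequential"` (chain, residue order, mutant alphabet) or
#'   `"by_ddg"` (nondecreasing predicted ddG).
#' @return Data frame with one row per mutation (`chain`, `resnum`, `wt`,
#'   `mut`, `A`, `ddG`, `flags`) and the 16-column weighted term
#'   breakdown as attribute `"breakdown"` (row-aligned).
#' @export
systematic_scan <- function(structure, potentials, params,
                            order = c("sequential", "by_ddg")) {
  order <- match.arg(order)
  res <- structure$residues
  cache <- structure_tuples(structure, potentials$scheme)
  scannable <- which(!is.na(res$a) & res$aa %in% AA_ALPHABET)
  rows <- vector("list", length(scannable))
  bds <- vector("list", length(scannable))
  for (ii in seq_along(scannable)) {
    k <- scannable[ii]
    s_w <- res$aa[k]
    muts <- setdiff(AA_ALPHABET, s_w)
    A <- res$a[k]
    alpha <- coefficient_weights(params, A)
    ddG <- numeric(length(muts))
    bd <- matrix(0, length(muts), 16L, dimnames = list(NULL, COEFFICIENT_NAMES))
    for (m in seq_along(muts)) {
      x <- .mutation_features(structure, k, s_w, muts[m], potentials, cache)
      bd[m, ] <- alpha * x
      ddG[m] <- sum(bd[m, ])
    }
    rows[[ii]] <- data.frame(
      chain = res$chain[k], resnum = paste0(res$resno[k], res$insert[k]),
      wt = s_w, mut = muts, A = A, ddG = ddG,
      flags = ifelse(s_w == "P" | muts == "P", "proline", ""),
      stringsAsFactors = FALSE)
    bds[[ii]] <- bd
  }
  out <- do.call(rbind, rows)
  bd <- do.call(rbind, bds)
  if (is.null(out)) {
    out <- data.frame(chain = character(), resnum = character(),
                      wt = character(), mut = character(), A = numeric(),
                      ddG = numeric(), flags = character())
    bd <- matrix(0, 0L, 16L, dimnames = list(NULL, COEFFICIENT_NAMES))
  }
  if (order == "by_ddg") {
    o <- order(out$ddG)
    out <- out[o, , drop = FALSE]
    bd <- bd[o, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "breakdown") <- bd
  out
}

#' Read a mutation-list file
#'
#' One mutation per line, whitespace-separated `CHAIN RESNUM WT MUT`;
#' `#` starts a comment; blank lines ignored.
#'
#' @param path File path.
#' @return Data frame with columns `chain`, `resnum`, `s_w`, `s_m` and
#'   the source `line` number.
#' @export
read_mutation_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  rows <- lapply(keep, function(i) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    if (length(parts) != 4L)
      return(data.frame(chain = NA_character_, resnum = NA_character_,
                        s_w = NA_character_, s_m = NA_character_, line = i))
    data.frame(chain = parts[1L], resnum = parts[2L],
               s_w = toupper(parts[3L]), s_m = toupper(parts[4L]), line = i)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chain = character(), resnum = character(),
                      s_w = character(), s_m = character(), line = integer())
  out
}

#' Write predictions in the tab-separated server format
#'
#' One line per mutation: `CHAIN RESNUM WT MUT DDG_PRED [FLAGS]`.
#'
#' @param predictions Data frame from [systematic_scan()] or a list of
#'   `ddg_prediction` objects.
#' @param path Output file.
#' @export
write_predictions <- function(predictions, path) {
  if (!is.data.frame(predictions)) {
    predictions <- do.call(rbind, lapply(predictions, function(p)
      data.frame(chain = p$chain, resnum = p$resnum, wt = p$s_w, mut = p$s_m,
                 ddG = p$ddG, flags = paste(p$flags, collapse = ","),
                 stringsAsFactors = FALSE)))
  }
  lines <- sprintf("%s\t%s\t%s\t%s\t%.4f%s",
                   predictions$chain, predictions$resnum, predictions$wt,
                   predictions$mut, predictions$ddG,
                   ifelse(nzchar(predictions$flags),
                          paste0("\t", predictions$flags), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize model parameters to versioned JSON
#'
#' Values are stored as full-precision decimal text so that
#' [read_model()] restores them bit-exactly.
#'
#' @param params A `model_parameters` object.
#' @param path Output file.
#' @param seed Optional seed recorded for provenance.
#' @param provenance Optional character tag.
#' @export
write_model <- function(params, path, seed = NULL, provenance = NULL) {
  obj <- list(format = "stabscan-model", version = 1L,
              seed = seed, provenance = provenance,
              coefficients = COEFFICIENT_NAMES,
              theta = lapply(c(c = "c", r = "r", f = "f", b = "b"),
                             function(cl) .num_text(params$theta[, cl])),
              active = params$active)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read model parameters written by [write_model()]
#'
#' @param path File path.
#' @return A `model_parameters` object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "stabscan-model"))
    stop("not a stabscan model archive: ", path)
  model_parameters(c = as.numeric(obj$theta$c), r = as.numeric(obj$theta$r),
                   f = as.numeric(obj$theta$f), b = as.numeric(obj$theta$b),
                   active = matrix(as.logical(obj$active), 16L, 4L))
}
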