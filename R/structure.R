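# Parsing of PDB structures and computation of the per-residue descriptors
# (amino-acid type s, torsion domain t, relative solvent accessibility a)
# and of the side-chain-centroid distance map d that all potentials use.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Parse a PDB structure into a residue-descriptor model
#'
#' Reads a PDB file (or PDB-format text) and builds a `protein_structure`
#' object: one record per standard amino-acid residue having the backbone
#' atoms N, CA and C.  Alternate locations are resolved to the
#' highest-occupancy conformer, HETATM records and waters are ignored, and
#' only the first MODEL of a multi-model file is used.  Author residue
#' numbering (including insertion codes) is preserved verbatim.
#'
#' @param pdb_source Path to a PDB file, or a character vector of PDB-format
#'   lines.
#' @param id Optional structure label; defaults to the file base name.
#' @param chain_filter Optional character vector of chain identifiers to
#'   retain.
#' @return An object of class `protein_structure` with components
#'   `id`, `atoms` (resolved heavy-atom table), `residues` (one row per
#'   usable residue: chain, resno, insert, aa, side-chain centroid; the
#'   `t` and `a` descriptors are filled by [assign_torsion_domain()] and
#'   [compute_accessibility()]), and `pairs` (filled by
#'   [pairwise_centroid_distances()]).  The number of records excluded
#'   for missing backbone atoms or non-standard type is kept in
#'   `n_excluded`.
#' @seealso [annotate_structure()] for the one-call pipeline.
#' @export
parse_structure <- function(pdb_source, id = NULL, chain_filter = NULL) {
  if (length(pdb_source) == 1L && !grepl("\n", pdb_source) &&
      file.exists(pdb_source)) {
    path <- pdb_source
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- unlist(strsplit(as.character(pdb_source), "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path), add = TRUE)
    if (is.null(id)) id <- "structure"
  }
  .check_pdb_lines(lines)

  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, rm.insert = FALSE,
                    verbose = FALSE),
    error = function(e) stop("cannot parse PDB input: ", conditionMessage(e),
                             call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[at$resid %in% names(AA_THREE_TO_ONE), , drop = FALSE]
  if (!is.null(chain_filter)) at <- at[at$chain %in% chain_filter, , drop = FALSE]
  # heavy atoms only
  elt <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                               substr(trimws(at$elety), 1L, 1L), at$elesy)))
  at <- at[elt != "H" & elt != "D", , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no usable protein residues in '", id, "'", call. = FALSE)

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$elesy <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                    substr(trimws(at$elety), 1L, 1L),
                                    at$elesy)))

  # resolve altlocs: within (chain, resno, insert, atom name) keep the
  # highest-occupancy record; ties resolved by file order
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  at$.row <- seq_len(nrow(at))
  ord <- order(key, -at$o, at$.row)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$.row), , drop = FALSE]   # restore file order
  at$.row <- NULL

  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  rkeys <- unique(rkey)
  n_excluded <- 0L
  res_rows <- vector("list", length(rkeys))
  for (k in seq_along(rkeys)) {
    sel <- rkey == rkeys[k]
    ra <- at[sel, , drop = FALSE]
    if (!all(c("N", "CA", "C") %in% trimws(ra$elety))) {
      n_excluded <- n_excluded + 1L
      next
    }
    sc <- ra[!(trimws(ra$elety) %in% BACKBONE_ATOMS), , drop = FALSE]
    if (nrow(sc) > 0L) {
      cen <- c(mean(sc$x), mean(sc$y), mean(sc$z))
    } else {
      ca <- ra[trimws(ra$elety) == "CA", , drop = FALSE]
      cen <- c(ca$x[1L], ca$y[1L], ca$z[1L])
    }
    res_rows[[k]] <- data.frame(
      chain = ra$chain[1L], resno = ra$resno[1L], insert = ra$insert[1L],
      aa = unname(AA_THREE_TO_ONE[ra$resid[1L]]),
      cx = cen[1L], cy = cen[2L], cz = cen[3L],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, res_rows)
  if (is.null(res) || nrow(res) == 0L)
    stop("no usable protein residues in '", id, "'", call. = FALSE)
  res$index <- seq_len(nrow(res))
  res$t <- NA_character_
  res$a <- NA_real_
  res$sasa <- NA_real_
  rownames(res) <- NULL

  # all heavy atoms are kept (they occlude in the SASA computation) even
  # when their residue is excluded from the descriptor table
  rownames(at) <- NULL

  structure(list(id = id, atoms = at, residues = res, pairs = NULL,
                 n_excluded = n_excluded),
            class = "protein_structure")
}

# reject obviously corrupt coordinate records, naming the offending line
.check_pdb_lines <- function(lines) {
  ish <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(ish)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) next
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords))))
      stop("unparseable coordinates at line ", i, ": ", trimws(ln),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure '", x$id, "': ", nrow(x$residues), " residues, ",
      length(unique(x$residues$chain)), " chain(s)", sep = "")
  if (!is.null(x$pairs)) cat(", ", nrow(x$pairs), " contact pairs", sep = "")
  cat("\n")
  invisible(x)
}

# dihedral angle (degrees, in (-180, 180]) defined by four points
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi   # IUPAC sign
}

.backbone_coords <- function(x) {
  at <- x$atoms
  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  skey <- paste(x$residues$chain, x$residues$resno, x$residues$insert,
                sep = "\r")
  get1 <- function(name) {
    sel <- trimws(at$elety) == name
    m <- matrix(NA_real_, nrow(x$residues), 3L)
    idx <- match(skey, rkey[sel])
    ok <- !is.na(idx)
    m[ok, ] <- as.matrix(at[sel, c("x", "y", "z")])[idx[ok], , drop = FALSE]
    m
  }
  list(N = get1("N"), CA = get1("CA"), C = get1("C"))
}

#' Compute backbone dihedrals and assign torsion domains
#'
#' Computes phi/psi for every residue and maps each pair onto the fixed
#' seven-domain partition of the Ramachandran plane given by
#' [TORSION_DOMAINS] (first matching box wins; unmatched angles are `"O"`).
#' Chain termini, residues next to a chain break (peptide C-N distance
#' above 2.5 Angstrom) and residues with missing backbone atoms receive
#' the dedicated label `"U"`; no input ever raises an error here.
#'
#' @param structure A `protein_structure`.
#' @return The structure with `residues$t`, `residues$phi` and
#'   `residues$psi` filled.
#' @export
assign_torsion_domain <- function(structure) {
  res <- structure$residues
  bb <- .backbone_coords(structure)
  n <- nrow(res)
  phi <- psi <- rep(NA_real_, n)
  same_chain_prev <- c(FALSE, res$chain[-1L] == res$chain[-n])
  for (i in seq_len(n)) {
    if (i > 1L && same_chain_prev[i] &&
        !anyNA(bb$C[i - 1L, ]) && !anyNA(c(bb$N[i, ], bb$CA[i, ], bb$C[i, ])) &&
        sqrt(sum((bb$C[i - 1L, ] - bb$N[i, ])^2)) < 2.5) {
      phi[i] <- .dihedral(bb$C[i - 1L, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    }
    if (i < n && same_chain_prev[i + 1L] &&
        !anyNA(c(bb$N[i, ], bb$CA[i, ], bb$C[i, ])) && !anyNA(bb$N[i + 1L, ]) &&
        sqrt(sum((bb$C[i, ] - bb$N[i + 1L, ])^2)) < 2.5) {
      psi[i] <- .dihedral(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1L, ])
    }
  }
  res$phi <- phi
  res$psi <- psi
  res$t <- mapply(torsion_domain_label, phi, psi)
  structure$residues <- res
  structure
}

#' Map a (phi, psi) pair to its torsion-domain label
#'
#' @param phi,psi Backbone dihedrals in degrees; `NA` yields `"U"`.
#' @return One label from [TORSION_ALPHABET].
#' @export
torsion_domain_label <- function(phi, psi) {
  if (is.na(phi) || is.na(psi)) return("U")
  for (nm in names(TORSION_DOMAINS)) {
    d <- TORSION_DOMAINS[[nm]]
    if (phi >= d$phi[1L] && phi < d$phi[2L] &&
        psi >= d$psi[1L] && psi < d$psi[2L])
      return(if (is.null(d$label)) nm else d$label)
  }
  "O"
}

#' Compute relative solvent accessibility
#'
#' Computes the solvent-accessible surface area of every heavy atom with an
#' analytic sphere-sampling (Shrake-Rupley) algorithm -- `n_points` points
#' on a Fibonacci lattice per atom, water-probe radius `probe` Angstrom --
#' sums it per residue, and normalizes by the residue's reference area in
#' an extended Gly-X-Gly tripeptide ([AA_REF_SASA]) to give a relative
#' accessibility in percent, clipped to [0, 100].
#'
#' @param structure A `protein_structure`.
#' @param n_points Sphere sample points per atom (default 960).
#' @param probe Probe radius in Angstrom (default 1.4).
#' @return The structure with `residues$sasa` (absolute, Angstrom^2) and
#'   `residues$a` (relative, percent) filled.
#' @export
compute_accessibility <- function(structure, n_points = SASA_N_POINTS,
                                  probe = SASA_PROBE_RADIUS) {
  at <- structure$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  radii <- ELEMENT_RADII[at$elesy]
  radii[is.na(radii)] <- ELEMENT_RADIUS_DEFAULT
  area <- .shrake_rupley(xyz, radii, n_points, probe)

  res <- structure$residues
  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  skey <- paste(res$chain, res$resno, res$insert, sep = "\r")
  res$sasa <- as.numeric(tapply(area, factor(rkey, levels = skey), sum))
  res$a <- pmin(100, pmax(0, 100 * res$sasa / AA_REF_SASA[res$aa]))
  structure$residues <- res
  structure
}

# Shrake-Rupley SASA: fraction of lattice points on each expanded sphere
# not buried inside any neighboring expanded sphere.
.shrake_rupley <- function(xyz, radii, n_points, probe) {
  n <- nrow(xyz)
  pts <- .fibonacci_sphere(n_points)
  rex <- radii + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rex + rex[i])^2 & seq_len(n) != i)
    p <- sweep(pts * rex[i], 2L, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dj2 >= rex[j]^2
    }
    area[i] <- 4 * pi * rex[i]^2 * sum(free) / n_points
  }
  area
}

# deterministic quasi-uniform unit-sphere lattice
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build the side-chain-centroid distance map
#'
#' Records every unordered residue pair whose side-chain geometric centers
#' (centroid of the side-chain heavy atoms; C-alpha for glycine) lie within
#' `cutoff` Angstrom.  Pairs closer than [MIN_SEQ_SEPARATION] positions
#' along the same chain are excluded; pairs across different chains are
#' always eligible.
#'
#' @param structure A `protein_structure`.
#' @param cutoff Distance cutoff in Angstrom (default 8).
#' @return The structure with `pairs`: a data frame of 0-based-free
#'   residue indices `i < j` (into `residues`) and the distance `d`.
#' @export
pairwise_centroid_distances <- function(structure, cutoff = DISTANCE_UPPER) {
  res <- structure$residues
  n <- nrow(res)
  cen <- as.matrix(res[, c("cx", "cy", "cz")])
  dm <- as.matrix(stats::dist(cen))
  keep <- upper.tri(dm) & dm <= cutoff
  # sequence-separation exclusion within a chain
  same <- outer(res$chain, res$chain, "==")
  sep <- abs(outer(res$index, res$index, "-"))
  keep <- keep & !(same & sep < MIN_SEQ_SEPARATION)
  idx <- which(keep, arr.ind = TRUE)
  structure$pairs <- data.frame(i = idx[, 1L], j = idx[, 2L], d = dm[idx])
  o <- order(structure$pairs$i, structure$pairs$j)
  structure$pairs <- structure$pairs[o, , drop = FALSE]
  rownames(structure$pairs) <- NULL
  structure$cutoff <- cutoff
  structure
}

#' Classify residues as core or surface
#'
#' Residues with relative accessibility strictly below `threshold` percent
#' are core; residues at or above it are surface (the boundary value 10
#' is surface).  Residues with undefined accessibility are `NA`.
#'
#' @param structure A `protein_structure` with accessibility computed.
#' @param threshold Percent relative accessibility (default 10).
#' @return Character vector, one of `"core"`/`"surface"`/`NA` per residue.
#' @export
classify_core_surface <- function(structure, threshold = 10) {
  a <- structure$residues$a
  ifelse(is.na(a), NA_character_, ifelse(a < threshold, "core", "surface"))
}

#' Parse and annotate a structure in one call
#'
#' Runs [parse_structure()], [assign_torsion_domain()],
#' [compute_accessibility()] and [pairwise_centroid_distances()] with the
#' given settings.
#'
#' @inheritParams parse_structure
#' @inheritParams compute_accessibility
#' @inheritParams pairwise_centroid_distances
#' @return A fully annotated `protein_structure`.
#' @export
annotate_structure <- function(pdb_source, id = NULL, chain_filter = NULL,
                               cutoff = DISTANCE_UPPER,
                               n_points = SASA_N_POINTS,
                               probe = SASA_PROBE_RADIUS) {
  s <- parse_structure(pdb_source, id = id, chain_filter = chain_filter)
  s <- assign_torsion_domain(s)
  s <- compute_accessibility(s, n_points = n_points, probe = probe)
  pairwise_centroid_distances(s, cutoff = cutoff)
}

#' Per-residue descriptor table
#'
#' @param structure An annotated `protein_structure`.
#' @param threshold Core/surface split in percent accessibility.
#' @return Data frame: chain, resnum (author numbering with insertion
#'   code), aa, t, a (percent), class.
#' @export
residue_descriptor_table <- function(structure, threshold = 10) {
  res <- structure$residues
  data.frame(chain = res$chain,
             resnum = paste0(res$resno, res$insert),
             aa = res$aa, t = res$t, a = res$a,
             class = classify_core_surface(structure, threshold),
             stringsAsFactors = FALSE)
}

#' Write the descriptor table as tab-separated text
#'
#' @inheritParams residue_descriptor_table
#' @param path Output file.
#' @export
write_residue_table <- function(structure, path, threshold = 10) {
  tab <- residue_descriptor_table(structure, threshold)
  tab$a <- formatC(tab$a, format = "f", digits = 3)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
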