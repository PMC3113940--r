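# Synthetic fixtures: toy backbones with computable descriptors, a
# documented ground-truth sigmoid model, and simulated mutant datasets.
# These emulate the study conditions of a measured-ddG training set
# (majority destabilizing, roughly -5..+5 kcal/mol) without any external
# downloads, and give every pipeline stage a known answer.

# ideal backbone geometry (Engh-Huber-style bond lengths/angles)
.BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_c_n_ca = 121.7, ang_n_ca_c = 111.0, ang_ca_c_n = 116.2,
            ang_ca_c_o = 120.8, omega = 180)

# ideal (phi, psi) per motif, degrees
.MOTIF_ANGLES <- list(helix = c(-57, -47), sheet = c(-120, 130))

# place atom x with |x-c| = bond, angle(b,c,x) = ang, dihedral(a,b,c,x) = tor
.place_atom <- function(a, b, c, bond, ang, tor) {
  ang <- ang * pi / 180; tor <- tor * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# pseudo-centroid distance from CA, scaled with the cube root of the
# residue volume (Ala calibrated to the C-beta distance 1.53 A)
.sidechain_length <- function(aa)
  1.53 * (AA_VOLUMES[aa] / AA_VOLUMES["A"])^(1 / 3)

#' Generate a toy protein structure in PDB format
#'
#' Builds an ideal backbone for the requested motif -- helix (-57, -47),
#' sheet (-120, 130), or mixed (alternating blocks of eight residues) --
#' with small seeded Gaussian jitter (sd 5 degrees) on every phi/psi, a
#' random sequence over the 20 standard types, and a single pseudo-centroid
#' side-chain atom (`SC`) per non-glycine residue at an amino-acid-specific
#' distance from the C-alpha.  The output parses with [parse_structure()]
#' and has fully computable descriptors.
#'
#' @param n_residues Number of residues (3 to 500).
#' @param motif `"helix"`, `"sheet"` or `"mixed"`.
#' @param seed Integer seed; identical seeds give identical file bytes.
#' @param chain Chain identifier (default `"A"`).
#' @param jitter_sd Torsion jitter in degrees (default 5).
#' @return Character vector of PDB lines.
#' @export
make_toy_structure <- function(n_residues, motif = c("mixed", "helix",
                                                     "sheet"),
                               seed = 1, chain = "A", jitter_sd = 5) {
  motif <- match.arg(motif)
  stopifnot(n_residues >= 3L, n_residues <= 500L)
  with_seed(seed, {
    seq_aa <- sample(AA_ALPHABET, n_residues, replace = TRUE)
    base <- switch(motif,
      helix = matrix(.MOTIF_ANGLES$helix, n_residues, 2L, byrow = TRUE),
      sheet = matrix(.MOTIF_ANGLES$sheet, n_residues, 2L, byrow = TRUE),
      mixed = {
        block <- ((seq_len(n_residues) - 1L) %/% 8L) %% 2L
        t(vapply(block, function(b)
          if (b == 0L) .MOTIF_ANGLES$helix else .MOTIF_ANGLES$sheet,
          numeric(2L)))
      })
    phi <- base[, 1L] + stats::rnorm(n_residues, 0, jitter_sd)
    psi <- base[, 2L] + stats::rnorm(n_residues, 0, jitter_sd)

    # build N, CA, C sequentially; O and SC hang off each residue
    N <- CA <- C <- O <- matrix(NA_real_, n_residues, 3L)
    N[1L, ] <- c(0, 0, 0)
    CA[1L, ] <- c(.BB$n_ca, 0, 0)
    ang <- .BB$ang_n_ca_c * pi / 180
    C[1L, ] <- CA[1L, ] + .BB$ca_c * c(-cos(ang), sin(ang), 0)
    for (i in seq_len(n_residues)) {
      if (i > 1L) {
        N[i, ] <- .place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                              .BB$c_n, .BB$ang_ca_c_n, psi[i - 1L])
        CA[i, ] <- .place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                               .BB$n_ca, .BB$ang_c_n_ca, .BB$omega)
        C[i, ] <- .place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                              .BB$ca_c, .BB$ang_n_ca_c, phi[i])
      }
      nxt <- if (i < n_residues)
        .place_atom(N[i, ], CA[i, ], C[i, ], .BB$c_n, .BB$ang_ca_c_n, psi[i])
      else
        .place_atom(N[i, ], CA[i, ], C[i, ], .BB$c_n, .BB$ang_ca_c_n, 180)
      O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], .BB$c_o,
                            .BB$ang_ca_c_o, psi[i] + 180)
      if (i < n_residues) { N[i + 1L, ] <- nxt }
    }

    lines <- character(0)
    serial <- 0L
    emit <- function(name, aa3, resno, xyz, element) {
      serial <<- serial + 1L
      sprintf("ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              serial, sprintf(" %-3s", name), aa3, chain, resno,
              xyz[1L], xyz[2L], xyz[3L], 1.00, 0.00, element)
    }
    for (i in seq_len(n_residues)) {
      aa3 <- AA_ONE_TO_THREE[seq_aa[i]]
      lines <- c(lines,
                 emit("N", aa3, i, N[i, ], "N"),
                 emit("CA", aa3, i, CA[i, ], "C"),
                 emit("C", aa3, i, C[i, ], "C"),
                 emit("O", aa3, i, O[i, ], "O"))
      if (seq_aa[i] != "G") {
        # pseudo-centroid along the ideal C-beta direction
        sc <- .place_atom(N[i, ], C[i, ], CA[i, ],
                          .sidechain_length(seq_aa[i]), 110.5, 122.5)
        lines <- c(lines, emit("SC", aa3, i, sc, "C"))
      }
    }
    c(lines, "END")
  })
}

#' Construct the default ground-truth model
#'
#' A documented `model_parameters` instance used to simulate measured
#' ddG values.  The coefficients vary visibly with accessibility (distinct
#' core and surface weights), the volume terms penalize burying larger
#' side chains in the core, and the independent term shifts predictions
#' toward destabilization so that simulated datasets reproduce the
#' majority-destabilizing skew of experimental mutant collections.
#'
#' @return A `model_parameters` object.
#' @export
default_truth_params <- function() {
  c_ <- rep(45, 16)               # buried/exposed transition mid-range
  r_ <- rep(-0.25, 16)            # most term weights shrink at the surface
  f_ <- c(rep(0.25, 13), 0.008, 0.007, -0.2)
  b_ <- c(rep(0.12, 13), 0.002, -0.0015, -0.6)
  # give a few terms contrasting profiles
  r_[c(2, 7)] <- 0.25             # as, aas: weight grows with accessibility
  f_[4] <- 0.4                    # sds: strong core weight
  model_parameters(c = c_, r = r_, f = f_, b = b_)
}

#' Build a ground-truth model over a set of toy structures
#'
#' Annotates the structures, derives the potential set from them, and
#' bundles it with ground-truth sigmoid parameters and a noise level: the
#' generating model for [simulate_mutant_dataset()].
#'
#' @param structures List of annotated `protein_structure` objects, or
#'   `NULL` to generate `n_structures` mixed-motif toys.
#' @param params Ground-truth `model_parameters`
#'   (default [default_truth_params()]).
#' @param noise_sd Gaussian noise of the simulated measurements, kcal/mol.
#' @param seed Seed used for structure generation (and recorded).
#' @param n_structures,n_residues Toy-set geometry when `structures` is
#'   `NULL`.
#' @param pseudocount,kT Passed to [derive_potentials()].
#' @return Object of class `ground_truth_model`: `structures`,
#'   `potentials`, `params`, `noise_sd`, `seed`.
#' @export
ground_truth_model <- function(structures = NULL,
                               params = default_truth_params(),
                               noise_sd = 0.3, seed = 1,
                               n_structures = 8L, n_residues = 45L,
                               pseudocount = 1, kT = KT_KCAL_MOL) {
  if (is.null(structures)) {
    structures <- lapply(seq_len(n_structures), function(i)
      annotate_structure(make_toy_structure(n_residues, "mixed",
                                            seed = seed * 1000L + i),
                         id = sprintf("toy%02d", i)))
  }
  counts <- count_frequencies(structures)
  potentials <- derive_potentials(counts, pseudocount = pseudocount, kT = kT)
  structure(list(structures = structures, potentials = potentials,
                 params = params, noise_sd = noise_sd, seed = seed),
            class = "ground_truth_model")
}

#' Simulate a mutant dataset from a ground-truth model
#'
#' Samples `n_mutants` distinct point mutations uniformly over the
#' scannable positions and 19 substitutions of the truth model's
#' structures, excluding any mutation that involves proline (mirroring the
#' training filter), and sets the simulated measurement to the truth
#' model's prediction plus Gaussian noise.  Records exceeding +5 kcal/mol
#' are redrawn so the set passes [filter_dataset()] unchanged.
#'
#' @param truth A `ground_truth_model`.
#' @param n_mutants Number of records to generate.
#' @param seed Integer seed.
#' @return Data frame of mutant records: `structure_id`, `chain`,
#'   `resnum`, `s_w`, `s_m`, `ddG_M`, `heme_protein`, `pseudo_wild_type`,
#'   plus hidden column `ddG_true` (the noiseless value) for closed-loop
#'   checks.
#' @export
simulate_mutant_dataset <- function(truth, n_mutants, seed = 1) {
  stopifnot(inherits(truth, "ground_truth_model"))
  # enumerate the eligible mutation universe
  univ <- list()
  for (si in seq_along(truth$structures)) {
    s <- truth$structures[[si]]
    res <- s$residues
    ok <- which(!is.na(res$a) & res$aa != "P")
    for (k in ok) {
      muts <- setdiff(AA_ALPHABET, c(res$aa[k], "P"))
      univ[[length(univ) + 1L]] <- data.frame(
        si = si, k = k, chain = res$chain[k],
        resnum = paste0(res$resno[k], res$insert[k]),
        s_w = res$aa[k], s_m = muts, stringsAsFactors = FALSE)
    }
  }
  univ <- do.call(rbind, univ)
  if (n_mutants > nrow(univ))
    stop("requested ", n_mutants, " mutants but only ", nrow(univ),
         " distinct eligible mutations exist")

  caches <- lapply(truth$structures, structure_tuples,
                   scheme = truth$potentials$scheme)
  truth_ddg <- function(rows) vapply(seq_len(nrow(rows)), function(i) {
    s <- truth$structures[[rows$si[i]]]
    x <- .mutation_features(s, rows$k[i], rows$s_w[i], rows$s_m[i],
                            truth$potentials, caches[[rows$si[i]]])
    A <- s$residues$a[rows$k[i]]
    sum(coefficient_weights(truth$params, A) * x)
  }, numeric(1L))
  with_seed(seed, {
    pool <- sample.int(nrow(univ))        # seeded sampling order, no repeats
    ds <- univ[pool[seq_len(n_mutants)], , drop = FALSE]
    next_free <- n_mutants + 1L
    ds$ddG_true <- truth_ddg(ds)
    # mutations whose noiseless value already breaches the +5 kcal/mol
    # training cutoff can never pass: replace them with fresh draws
    repeat {
      stuck <- which(ds$ddG_true > 5)
      if (length(stuck) == 0L) break
      if (next_free + length(stuck) - 1L > nrow(univ))
        stop("eligible mutation universe exhausted while enforcing the ",
             "+5 kcal/mol cutoff")
      repl <- univ[pool[next_free:(next_free + length(stuck) - 1L)], ,
                   drop = FALSE]
      next_free <- next_free + length(stuck)
      repl$ddG_true <- truth_ddg(repl)
      ds[stuck, ] <- repl
    }
    ds$ddG_M <- ds$ddG_true + stats::rnorm(nrow(ds), 0, truth$noise_sd)
    # redraw noise for records breaching the cutoff (terminates a.s.)
    for (rep in 1:100) {
      bad <- which(ds$ddG_M > 5)
      if (length(bad) == 0L) break
      ds$ddG_M[bad] <- ds$ddG_true[bad] +
        stats::rnorm(length(bad), 0, truth$noise_sd)
    }
    ds$structure_id <- vapply(ds$si, function(i) truth$structures[[i]]$id,
                              character(1L))
    ds$heme_protein <- FALSE
    ds$pseudo_wild_type <- FALSE
    rownames(ds) <- NULL
    ds[, c("structure_id", "chain", "resnum", "s_w", "s_m", "ddG_M",
           "heme_protein", "pseudo_wild_type", "ddG_true", "si", "k")]
  })
}

#' Write a complete demonstration workspace
#'
#' Generates toy structures, the ground-truth model, and a simulated
#' mutant dataset; writes the PDB files, the dataset, the potential
#' archive and the truth-model archive into `dir`.
#'
#' @param dir Output directory (created if needed).
#' @param n_structures,n_residues,n_mutants,noise_sd,seed Generation
#'   settings.
#' @return Invisibly, a list with the `ground_truth_model`, the dataset
#'   and the file paths.
#' @export
make_demo_workspace <- function(dir, n_structures = 8L, n_residues = 45L,
                                n_mutants = 600L, noise_sd = 0.3, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- ground_truth_model(noise_sd = noise_sd, seed = seed,
                              n_structures = n_structures,
                              n_residues = n_residues)
  pdb_paths <- character(0)
  for (i in seq_along(truth$structures)) {
    p <- file.path(dir, paste0(truth$structures[[i]]$id, ".pdb"))
    writeLines(make_toy_structure(n_residues, "mixed",
                                  seed = seed * 1000L + i), p)
    pdb_paths <- c(pdb_paths, p)
  }
  ds <- simulate_mutant_dataset(truth, n_mutants, seed = seed)
  ds_path <- file.path(dir, "mutants.tsv")
  write_mutant_dataset(ds, ds_path)
  pot_path <- file.path(dir, "potentials.json")
  write_potentials(truth$potentials, pot_path,
                   provenance = paste0("demo-seed-", seed))
  mod_path <- file.path(dir, "truth_model.json")
  write_model(truth$params, mod_path, seed = seed, provenance = "ground-truth")
  invisible(list(truth = truth, dataset = ds,
                 paths = list(pdb = pdb_paths, dataset = ds_path,
                              potentials = pot_path, model = mod_path)))
}
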