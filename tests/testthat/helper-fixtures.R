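# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# a mid-size annotated toy structure used across modules
fixture_structure <- function() memo("struct30", {
  annotate_structure(make_toy_structure(30, "mixed", seed = 11), id = "fix30")
})

fixture_potentials <- function() memo("pot30", {
  derive_potentials(count_frequencies(list(fixture_structure())))
})

# the default ground-truth model (noise 0.3) and a simulated dataset
fixture_truth <- function() memo("truth", {
  ground_truth_model(seed = 1, noise_sd = 0.3)
})

fixture_dataset <- function() memo("dataset", {
  simulate_mutant_dataset(fixture_truth(), 800, seed = 3)
})

fixture_features <- function() memo("features", {
  tr <- fixture_truth()
  compute_features(fixture_dataset(), tr$structures, tr$potentials)
})

# a tiny hand-assembled PDB: n_res alanines on a line, optionally with a
# record dropped or altloc variants injected
ala_line_pdb <- function(n_res = 5, drop_ca_at = NULL) {
  lines <- character(0)
  serial <- 0
  for (i in seq_len(n_res)) {
    x0 <- (i - 1) * 3.8
    at <- list(c("N", 0), c("CA", 1.46), c("C", 2.5), c("CB", 1.0))
    for (a in at) {
      if (identical(a[[1]], "CA") && !is.null(drop_ca_at) &&
          i == drop_ca_at) next
      serial <- serial + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
        serial, sprintf(" %-3s", a[[1]]), i, x0 + as.numeric(a[[2]]),
        ifelse(identical(a[[1]], "CB"), 1.5, 0), 0, 1.00, 0.00,
        substr(a[[1]], 1, 1)))
    }
  }
  c(lines, "END")
}

# rigid-body rotation + translation of all atom coordinates
rotate_structure_atoms <- function(pdb_lines, angle = 0.7, axis = c(1, 2, 3),
                                   shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  out <- vapply(pdb_lines, function(ln) {
    if (!grepl("^ATOM", ln)) return(ln)
    xyz <- as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                        substr(ln, 47, 54)))
    new <- as.numeric(R %*% xyz + shift)
    paste0(substr(ln, 1, 30),
           sprintf("%8.3f%8.3f%8.3f", new[1], new[2], new[3]),
           substr(ln, 55, nchar(ln)))
  }, character(1), USE.NAMES = FALSE)
  out
}
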