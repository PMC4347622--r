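# Small in-code fixtures shared across the suite.

# feature table with known linear signal: affinity = 2*X.1 - R.1 + noise
toy_table <- function(n = 30, blocks = c(X = 2, R = 2), seed = 1,
                      noise_sd = 0.3, family = TRUE) {
  withr::with_seed(seed, {
    cols <- list()
    for (b in names(blocks)) {
      for (j in seq_len(blocks[[b]])) {
        cols[[paste0(b, ".", j)]] <- rnorm(n)
      }
    }
    feats <- tibble::as_tibble(cols)
    y <- 5 + 2 * feats[["X.1"]] - feats[["R.1"]] + rnorm(n, 0, noise_sd)
    out <- tibble::tibble(complex_id = sprintf("T%03d", seq_len(n)),
                          affinity = y)
    if (family) {
      out$family <- sprintf("F%02d", rep_len(1:5, n))
      out <- out[, c("complex_id", "family", "affinity")]
    }
    dplyr::bind_cols(out, feats)
  })
}

quick_cfg <- function(seed = 1, epochs = 60, lambda = 0.005, ...) {
  train_config(epochs = epochs, lambda = lambda, seed = seed, ...)
}

# hand-built single network with chosen weights (features already named)
manual_net <- function(W1, w2, features,
                       scaler = list(min = setNames(rep(0, length(features)),
                                                    features),
                                     range = setNames(rep(1, length(features)),
                                                      features))) {
  structure(list(input_weights = W1, output_weights = w2,
                 hidden = ncol(W1) + 1L, features = features,
                 scaler = scaler, config = train_config(seed = 1),
                 objective = NA_real_, converged = TRUE),
            class = "snn_model")
}

# network that always outputs the constant `value` (all weights 0 except
# the output bias)
constant_net <- function(value, features) {
  H <- 2L
  manual_net(matrix(0, nrow = length(features) + 1, ncol = H),
             c(value, rep(0, H)), features)
}

toy_pdb_lines <- function() {
  c("HEADER    SYNTHETIC TEST STRUCTURE",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 20.00           N",
    "ATOM      2  CA  ALA A   1      12.560   6.351  -6.509  1.00 20.00           C",
    "ATOM      3  SG  CYS A   2      -3.210  -0.042   8.004  1.00 20.00           S",
    "HETATM    4  O   HOH A 101      20.000  20.000  20.000  1.00 20.00           O",
    "END")
}

toy_sdf_lines <- function(coords = rbind(c(12, 6, -6), c(13.5, 6, -6)),
                          elements = c("C", "O"), name = "lig") {
  atom_lines <- vapply(seq_len(nrow(coords)), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[i, 1], coords[i, 2], coords[i, 3], elements[i])
  }, character(1))
  c(name, "  generated", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(coords),
            max(0, nrow(coords) - 1)),
    atom_lines,
    if (nrow(coords) > 1) {
      vapply(seq_len(nrow(coords) - 1), function(i) {
        sprintf("%3d%3d  1  0  0  0  0", i, i + 1)
      }, character(1))
    },
    "M  END", "$$$$")
}

random_atom_set <- function(n, elements, lim = 15) {
  tibble::tibble(element = sample(elements, n, replace = TRUE),
                 x = runif(n, 0, lim), y = runif(n, 0, lim),
                 z = runif(n, 0, lim))
}

# independent all-pairs double-loop oracle for element-pair contact counts
pair_counts_oracle <- function(protein, ligand, protein_elements,
                               ligand_elements, cutoff) {
  labels <- as.vector(t(outer(protein_elements, ligand_elements,
                              function(p, l) paste0("R.", p, "_", l))))
  counts <- setNames(integer(length(labels)), labels)
  for (i in seq_len(nrow(protein))) {
    for (j in seq_len(nrow(ligand))) {
      ep <- protein$element[i]
      el <- ligand$element[j]
      if (!(ep %in% protein_elements) || !(el %in% ligand_elements)) next
      d <- sqrt((protein$x[i] - ligand$x[j])^2 +
                  (protein$y[i] - ligand$y[j])^2 +
                  (protein$z[i] - ligand$z[j])^2)
      if (d <= cutoff) {
        key <- paste0("R.", ep, "_", el)
        counts[key] <- counts[key] + 1L
      }
    }
  }
  counts
}
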